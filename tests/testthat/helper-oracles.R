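# Independent oracles and fixture builders shared across tests.

# Mixture log-likelihood computed from first principles (independent of
# the package's internal EM bookkeeping).
oracle_mixture_loglik <- function(x, sigma, mu, pi) {
  sum(vapply(seq_along(x), function(i) {
    log(sum(pi * dnorm(x[i], mu, sigma[i])))
  }, numeric(1)))
}

# Brute-force global optimum over hard partitions: for every assignment
# of n points into K non-empty clusters, set each cluster mean to the
# precision-weighted mean of its members and pi to the membership
# fractions, and evaluate the mixture log-likelihood at those parameters.
oracle_best_partition_loglik <- function(x, sigma, K) {
  n <- length(x)
  stopifnot(K <= 2, n <= 8)
  best <- -Inf
  if (K == 1) {
    mu <- sum(x / sigma^2) / sum(1 / sigma^2)
    return(oracle_mixture_loglik(x, sigma, mu, 1))
  }
  for (code in 0:(2^n - 1)) {
    z <- as.integer(intToBits(code))[1:n] + 1L
    if (length(unique(z)) < K) next
    mu <- vapply(1:K, function(k) {
      sel <- z == k
      sum(x[sel] / sigma[sel]^2) / sum(1 / sigma[sel]^2)
    }, numeric(1))
    pi <- tabulate(z, K) / n
    ll <- oracle_mixture_loglik(x, sigma, mu, pi)
    if (ll > best) best <- ll
  }
  best
}

# Exhaustive hypergeometric upper tail P(X >= k) by enumerating the pmf
# with choose(); independent of stats::phyper.
oracle_hyper_upper <- function(k, K, N, n) {
  kk <- max(k, max(0, n - (N - K))):min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# A two-map toy: scaffold plus a component sharing named anchors.
toy_scaffold <- function() {
  data.frame(marker = c("A", "B", "C", "D"), chr = 1L,
             pos_cm = c(0, 100, 120, 200), stringsAsFactors = FALSE)
}

toy_component <- function() {
  # anchors A (src 0), B (src 10), C (src 20); own markers M1, M2
  data.frame(map_id = "m1",
             marker = c("A", "M1", "B", "M2", "C"),
             chr = 1L, pos_cm = c(0, 5, 10, 15, 20),
             stringsAsFactors = FALSE)
}

# Minimal GFF3 with five genes on Chr1; one straddles 1e6.
write_toy_gff3 <- function(path) {
  lines <- c(
    "##gff-version 3",
    "Chr1\ttoy\tgene\t500000\t600000\t.\t+\t.\tID=g1;description=alpha",
    "Chr1\ttoy\tgene\t950000\t1050000\t.\t-\t.\tID=g2;description=beta",
    "Chr1\ttoy\tgene\t1200000\t1300000\t.\t+\t.\tID=g3;description=gamma",
    "Chr1\ttoy\tgene\t1900000\t2100000\t.\t+\t.\tID=g4;description=delta",
    "Chr1\ttoy\tgene\t2500000\t2600000\t.\t-\t.\tID=g5;description=eps",
    "Chr2\ttoy\tgene\t1500000\t1600000\t.\t+\t.\tID=g6;description=zeta")
  writeLines(lines, path)
  path
}

# A small valid compendium + studies pair used by round-trip tests.
toy_compendium <- function() {
  qtls <- data.frame(
    qtl_id = c("q1", "q2", "q3"), study_id = "S1",
    trait = c("SF", "TGW", "GNP"), chr = c(1L, 1L, 2L),
    peak_cm = c(10, 55, 30), lod = c(3.2, NA, 5.0),
    pve_pct = c(12.5, 8.0, NA), flank_left = c("A", "B", NA),
    flank_right = c("B", "C", NA), map_id = "m1",
    stringsAsFactors = FALSE)
  studies <- data.frame(
    study_id = "S1", parents = "P1 x P2", pop_type = "RIL",
    pop_size = 180L, n_markers = 120, marker_types = "SSR",
    traits = "SF,TGW,GNP", citation = "toy", stringsAsFactors = FALSE)
  list(qtls = qtls, studies = studies)
}
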