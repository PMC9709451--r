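# Per-chromosome consensus clustering of projected QTLs: a univariate
# Gaussian mixture over peak positions in which each observation carries
# its own KNOWN standard deviation (from its projected 95% CI). Only the
# cluster means mu_k and mixing proportions pi_k are estimated, so the
# free-parameter count is nu = 2K - 1.

SIGMA_FLOOR_CM <- 0.1

logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# Mixture log-likelihood at fixed parameters (used by tests' oracles too).
mixture_loglik <- function(x, sigma, mu, pi) {
  lp <- sapply(seq_along(mu), function(k)
    log(pi[k]) + stats::dnorm(x, mu[k], sigma, log = TRUE))
  lp <- matrix(lp, nrow = length(x))
  sum(logsumexp(lp))
}

em_once <- function(x, sigma, K, mu0, tol, max_iter) {
  n <- length(x)
  mu <- mu0
  pi <- rep(1 / K, K)
  prec <- 1 / sigma^2
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0
  r <- matrix(1 / K, n, K)
  repeat {
    iter <- iter + 1
    # E-step
    lp <- sapply(seq_len(K), function(k)
      log(pi[k]) + stats::dnorm(x, mu[k], sigma, log = TRUE))
    lp <- matrix(lp, nrow = n)
    lse <- logsumexp(lp)
    ll <- sum(lse)
    if (ll < ll_prev - 1e-9)
      stop(sprintf(
        "EM log-likelihood decreased at iteration %d (%.12g -> %.12g)",
        iter, ll_prev, ll))
    r <- exp(lp - lse)
    # M-step: precision-weighted means, mean responsibilities
    wk <- r * prec
    denom <- colSums(wk)
    mu_new <- ifelse(denom > 0, colSums(wk * x) / denom, mu)
    pi_new <- colMeans(r)
    done <- is.finite(ll_prev) &&
      abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-12)
    mu <- mu_new
    pi <- pi_new
    ll_prev <- ll
    if (done) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  list(mu = mu, pi = pi, loglik = ll_prev, r = r, converged = converged,
       n_iter = iter)
}

#' Fit a K-component position mixture by EM
#'
#' Model: each projected QTL peak \eqn{x_i} is drawn from
#' \eqn{\sum_k \pi_k N(\mu_k, \sigma_i^2)} with \eqn{\sigma_i} known
#' (derived from the QTL's projected 95% CI). The E-step computes
#' responsibilities \eqn{r_{ik} \propto \pi_k \phi(x_i; \mu_k,
#' \sigma_i^2)}; the M-step sets \eqn{\mu_k} to the responsibility- and
#' precision-weighted mean and \eqn{\pi_k} to the mean responsibility.
#' The best of `n_restarts` starts (one quantile-spread, the rest seeded
#' random draws from the data) is returned, with components sorted by
#' mean. A component left empty under hard assignment triggers a refit
#' with K-1 (flagged).
#'
#' @param x numeric vector of peak positions (cM).
#' @param sigma per-observation standard deviations (cM); floored at
#'   `sigma_floor`.
#' @param K number of components, `1 <= K <= length(x)`.
#' @param seed master seed for the restart draws.
#' @param n_restarts,tol,max_iter EM control.
#' @param sigma_floor minimum sigma (cM) guarding against degenerate
#'   likelihood spikes.
#' @return an object of class `mixture_fit`: `K, mu, pi, loglik,
#'   loglik_classified, n, nu, converged, n_iter, seed, responsibilities,
#'   assignment, empty_cluster_refit`.
#' @export
em_fit <- function(x, sigma, K, seed = 1L, n_restarts = 10L, tol = 1e-6,
                   max_iter = 500L, sigma_floor = SIGMA_FLOOR_CM) {
  n <- length(x)
  stopifnot(length(sigma) == n, K >= 1, n >= 1)
  if (K > n) stop("K must not exceed the number of observations")
  sigma <- pmax(sigma, sigma_floor)
  prec <- 1 / sigma^2

  if (K == 1) {
    # closed form: precision-weighted mean
    mu <- sum(prec * x) / sum(prec)
    ll <- sum(stats::dnorm(x, mu, sigma, log = TRUE))
    fit <- list(mu = mu, pi = 1, loglik = ll,
                r = matrix(1, n, 1), converged = TRUE, n_iter = 0L)
  } else {
    best <- NULL
    for (rs in seq_len(n_restarts)) {
      if (rs == 1) {
        mu0 <- stats::quantile(x, probs = (seq_len(K) - 0.5) / K,
                               names = FALSE, type = 7)
      } else {
        rseed <- (as.integer(seed) %% 100000L) * 10000L + K * 100L + rs
        set.seed(rseed %% .Machine$integer.max)
        mu0 <- sort(x[sample.int(n, K, replace = FALSE)])
      }
      cand <- em_once(x, sigma, K, mu0, tol, max_iter)
      if (is.null(best) || cand$loglik > best$loglik) best <- cand
    }
    fit <- best
  }

  ord <- order(fit$mu)
  mu <- fit$mu[ord]
  pi <- fit$pi[ord]
  r <- fit$r[, ord, drop = FALSE]
  assignment <- max.col(r, ties.method = "first")

  empty <- setdiff(seq_len(K), unique(assignment))
  if (length(empty) > 0 && K > 1) {
    sub <- em_fit(x, sigma, K - 1L, seed = seed, n_restarts = n_restarts,
                  tol = tol, max_iter = max_iter, sigma_floor = sigma_floor)
    sub$empty_cluster_refit <- TRUE
    return(sub)
  }

  ll_c <- sum(log(pi[assignment]) +
                stats::dnorm(x, mu[assignment], sigma, log = TRUE))
  structure(list(
    K = K, mu = mu, pi = pi, loglik = fit$loglik,
    loglik_classified = ll_c, n = n, nu = 2L * K - 1L,
    converged = fit$converged, n_iter = fit$n_iter, seed = seed,
    responsibilities = r, assignment = assignment, x = x, sigma = sigma,
    empty_cluster_refit = FALSE), class = "mixture_fit")
}

#' Information-criterion scores for a mixture fit
#'
#' With `nu = 2K - 1` free parameters and log-likelihood `L`:
#' AIC = -2L + 2nu; AIC3 = -2L + 3nu; AICc = AIC + 2nu(nu+1)/(n-nu-1)
#' (infinite when n - nu - 1 <= 0); BIC = -2L + nu log n; AWE uses the
#' classified (hard-assignment) log-likelihood Lc:
#' AWE = -2Lc + 2nu(3/2 + log n).
#'
#' @param fit a `mixture_fit`.
#' @return data frame row with `K, aic, aic3, aicc, bic, awe`.
#' @export
score_models <- function(fit) {
  nu <- fit$nu; n <- fit$n
  m2l <- -2 * fit$loglik
  aic <- m2l + 2 * nu
  aicc <- if (n - nu - 1 > 0) aic + 2 * nu * (nu + 1) / (n - nu - 1) else Inf
  data.frame(K = fit$K,
             aic = aic,
             aic3 = m2l + 3 * nu,
             aicc = aicc,
             bic = m2l + nu * log(n),
             awe = -2 * fit$loglik_classified + 2 * nu * (1.5 + log(n)))
}

#' Choose the number of MQTLs on a chromosome
#'
#' Two-branch rule: with at most 10 QTLs on the chromosome the K with the
#' lowest AIC wins; with more than 10 QTLs each of the five criteria
#' (AIC, AIC3, AICc, BIC, AWE) votes for its minimising K and the K with
#' most votes wins. All ties break toward the smaller K.
#'
#' @param scores data frame of [score_models()] rows for K = 1..Kmax.
#' @param n number of QTLs on the chromosome.
#' @return list with `K`, `branch` (`"aic"` or `"vote"`), and `votes`
#'   (named per-criterion choice; empty for branch A).
#' @export
select_model <- function(scores, n) {
  if (nrow(scores) == 0) stop("empty score list")
  scores <- scores[order(scores$K), , drop = FALSE]
  argmin_k <- function(v) scores$K[which.min(v)]  # which.min: first = smallest K
  if (n <= 10) {
    list(K = argmin_k(scores$aic), branch = "aic",
         votes = integer(0))
  } else {
    crit <- c("aic3", "aic", "bic", "awe", "aicc")
    votes <- vapply(crit, function(cn) argmin_k(scores[[cn]]), numeric(1))
    tab <- table(votes)
    winners <- as.numeric(names(tab)[tab == max(tab)])
    list(K = min(winners), branch = "vote", votes = votes)
  }
}

#' Build MQTLs from a chosen mixture fit
#'
#' Members are hard-assigned by maximum responsibility. Each MQTL takes
#' the cluster mean as its position; its 95% CI follows from precision
#' addition over members, `3.92 * sqrt(1 / sum(1/sigma_i^2))`, so a
#' multi-member MQTL is always tighter than its tightest member. Names
#' run MQTL{chr}.{k} in order of position. Flanking markers are the
#' nearest consensus markers outside the CI, when a consensus map is
#' supplied.
#'
#' @param fit a `mixture_fit` at the selected K.
#' @param projected the projected QTLs (rows aligned with `fit$x`).
#' @param consensus optional consensus map for flanking-marker lookup.
#' @return list with `mqtls` (summary data frame) and `members`
#'   (per-QTL assignment with percent membership).
#' @export
build_mqtls <- function(fit, projected, consensus = NULL) {
  stopifnot(nrow(projected) == fit$n)
  chr <- projected$chr[1]
  keep <- sort(unique(fit$assignment))
  rows <- list(); members <- list()
  for (idx in seq_along(keep)) {
    k <- keep[idx]
    sel <- fit$assignment == k
    sig <- fit$sigma[sel]
    ci <- CI95_Z_WIDTH * sqrt(1 / sum(1 / sig^2))
    pos <- fit$mu[k]
    name <- sprintf("MQTL%d.%d", chr, idx)
    fl <- c(NA_character_, NA_character_)
    if (!is.null(consensus)) {
      cc <- consensus[consensus$chr == chr, , drop = FALSE]
      lo <- pos - ci / 2; hi <- pos + ci / 2
      left <- cc[cc$pos_cm < lo, , drop = FALSE]
      right <- cc[cc$pos_cm > hi, , drop = FALSE]
      if (nrow(left)) fl[1] <- left$marker[which.max(left$pos_cm)]
      if (nrow(right)) fl[2] <- right$marker[which.min(right$pos_cm)]
    }
    traits <- sort(unique(projected$trait[sel]))
    rows[[idx]] <- data.frame(
      name = name, chr = chr, position_cm = pos,
      flank_left = fl[1], flank_right = fl[2],
      n_qtls = sum(sel), n_traits = length(traits),
      traits = paste(traits, collapse = ","),
      avg_pve = mean(projected$pve_pct[sel]),
      ci95_cm = ci, stringsAsFactors = FALSE)
    members[[idx]] <- data.frame(
      name = name, qtl_id = projected$qtl_id[sel],
      membership_pct = 100 * fit$responsibilities[sel, k],
      stringsAsFactors = FALSE)
  }
  list(mqtls = do.call(rbind, rows), members = do.call(rbind, members))
}

#' Meta-analysis of one chromosome
#'
#' Fits mixtures for K = 1..Kmax (Kmax = min(n, `k_max`)), scores them,
#' applies the two-branch selection rule, and builds the MQTLs. A single
#' projected QTL yields a single MQTL identical to that QTL.
#'
#' @param projected projected QTLs of one chromosome.
#' @param seed master seed.
#' @param k_max cap on the number of clusters considered.
#' @param consensus optional consensus map for flanking markers.
#' @param ... further arguments to [em_fit()].
#' @return list with `mqtls`, `members`, `fits`, `scores`, `selection`.
#' @export
run_chromosome <- function(projected, seed = 1L, k_max = 10L,
                           consensus = NULL, ...) {
  n <- nrow(projected)
  stopifnot(n >= 1)
  x <- projected$peak_cons_cm
  sigma <- projected$sigma_cm
  kmax <- min(n, k_max)
  fits <- lapply(seq_len(kmax), function(K)
    em_fit(x, sigma, K, seed = seed, ...))
  # a K slot may have collapsed to a smaller effective K; score as fitted
  scores <- do.call(rbind, lapply(fits, score_models))
  scores$K_requested <- seq_len(kmax)
  sel <- select_model(scores, n)
  chosen <- fits[[which(scores$K == sel$K)[1]]]
  built <- build_mqtls(chosen, projected, consensus)
  list(mqtls = built$mqtls, members = built$members, fits = fits,
       scores = scores, selection = sel)
}

#' Meta-analysis across all chromosomes
#'
#' @param projected projected QTLs (all chromosomes).
#' @param consensus optional consensus map.
#' @param seed master seed; each chromosome derives its own sub-seed.
#' @param k_max per-chromosome cluster cap.
#' @param ... passed to [em_fit()].
#' @return list with the combined `mqtls` table, `members`, and
#'   per-chromosome `chromosomes` results.
#' @export
run_meta_analysis <- function(projected, consensus = NULL, seed = 1L,
                              k_max = 10L, ...) {
  stopifnot(nrow(projected) >= 1)
  out <- list(); mqtls <- list(); members <- list()
  for (chr in sort(unique(projected$chr))) {
    pc <- projected[projected$chr == chr, , drop = FALSE]
    res <- run_chromosome(pc, seed = as.integer(seed) + chr,
                          k_max = k_max, consensus = consensus, ...)
    out[[as.character(chr)]] <- res
    mqtls[[as.character(chr)]] <- res$mqtls
    members[[as.character(chr)]] <- res$members
  }
  mqtl_table <- do.call(rbind, mqtls)
  rownames(mqtl_table) <- NULL
  list(mqtls = mqtl_table, members = do.call(rbind, members),
       chromosomes = out, seed = seed)
}
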