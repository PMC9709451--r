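# Synthetic multi-study QTL compendia with known ground truth. Noise
# enters at the reported-QTL level: each study re-detects a true locus
# with some probability and reports a peak displaced by exactly the
# Gaussian error implied by its design's 95% CI formula.

#' Construct a true MQTL architecture
#'
#' @param positions named list (one element per chromosome, names are
#'   chromosome numbers) of true locus positions (cM).
#' @param lengths named numeric vector of chromosome lengths (cM), same
#'   names as `positions`.
#' @param trait_weights sampling weights over the four trait codes.
#' @param expected_r2 median of the per-report R2 distribution
#'   (proportion).
#' @return an `architecture` list.
#' @export
new_architecture <- function(positions, lengths,
                             trait_weights = c(SF = 0.275, PN = 0.154,
                                               GNP = 0.184, TGW = 0.387),
                             expected_r2 = 0.08) {
  stopifnot(setequal(names(positions), names(lengths)))
  for (chr in names(positions)) {
    p <- positions[[chr]]
    if (any(p < 0) || any(p > lengths[[chr]]))
      stop("true positions outside chromosome length on chr ", chr)
  }
  tw <- trait_weights / sum(trait_weights)
  structure(list(positions = positions, lengths = lengths,
                 trait_weights = tw, expected_r2 = expected_r2),
            class = "architecture")
}

#' Default 12-chromosome architecture
#'
#' Emulates the published study's scale: twelve chromosomes summing to
#' 2,945.67 cM (individual lengths 144-383.8 cM), with per-chromosome
#' true locus counts between 2 and 9 (62 in total) and trait weights
#' matching the compendium's trait frequencies (TGW 179, SF 127, GNP 85,
#' PN 71 of 462).
#'
#' @return an `architecture`.
#' @export
default_architecture <- function() {
  lengths <- c(`1` = 383.80, `2` = 270.00, `3` = 300.00, `4` = 240.00,
               `5` = 250.00, `6` = 280.00, `7` = 235.00, `8` = 175.00,
               `9` = 200.00, `10` = 144.00, `11` = 230.00, `12` = 237.87)
  counts <- c(`1` = 8, `2` = 6, `3` = 9, `4` = 5, `5` = 5, `6` = 7,
              `7` = 6, `8` = 2, `9` = 4, `10` = 3, `11` = 4, `12` = 3)
  positions <- lapply(names(lengths), function(chr) {
    k <- counts[[chr]]; len <- lengths[[chr]]
    # evenly spread with a 7% margin at the telomeres
    seq(0.07 * len, 0.93 * len, length.out = k)
  })
  names(positions) <- names(lengths)
  new_architecture(positions, lengths,
                   trait_weights = c(SF = 127, PN = 71, GNP = 85,
                                     TGW = 179) / 462)
}

#' Construct a simulation scenario
#'
#' Defaults reflect the compiled study panel: 47 studies with population
#' types RIL/BC/F2/DH in proportions 26/11/9/1, sizes uniform on
#' [24, 472], log-normal R2 with median 0.08 clipped to [0.01, 0.52],
#' and per-study component maps obtained by subsampling the scaffold
#' with order-preserving per-interval length jitter.
#'
#' @param n_studies number of mapping studies.
#' @param pop_type_probs named sampling weights over RIL/DH/BC/F2.
#' @param n_range min/max population size.
#' @param r2_meanlog,r2_sdlog log-normal parameters of R2.
#' @param r2_clip lower/upper clip for R2 (proportion).
#' @param detection_prob probability a study re-detects a true locus.
#' @param marker_spacing_cm scaffold marker spacing.
#' @param map_keep_prob probability a scaffold marker enters a component
#'   map.
#' @param jitter_range per-interval multiplicative length jitter
#'   (uniform); `c(1, 1)` disables jitter (well-specified maps).
#' @param missing_lod_prob,missing_pve_prob probability a report omits
#'   its LOD / PVE value.
#' @param seed master seed: all randomness in [simulate_compendium()]
#'   flows from it.
#' @return a `sim_scenario` list.
#' @export
new_scenario <- function(n_studies = 47L,
                         pop_type_probs = c(RIL = 26, DH = 1, BC = 11,
                                            F2 = 9) / 47,
                         n_range = c(24L, 472L),
                         r2_meanlog = log(0.08), r2_sdlog = 0.8,
                         r2_clip = c(0.01, 0.52),
                         detection_prob = 0.16,
                         marker_spacing_cm = 5,
                         map_keep_prob = 0.5,
                         jitter_range = c(0.8, 1.25),
                         missing_lod_prob = 0.10,
                         missing_pve_prob = 0.05,
                         seed = 1L) {
  stopifnot(n_studies >= 1, all(pop_type_probs >= 0),
            abs(sum(pop_type_probs) - 1) < 1e-9,
            n_range[1] <= n_range[2], n_range[1] >= 2,
            detection_prob > 0, detection_prob <= 1,
            r2_clip[1] > 0, r2_clip[2] <= 1, r2_clip[1] <= r2_clip[2],
            jitter_range[1] > 0, jitter_range[1] <= jitter_range[2])
  structure(as.list(environment()), class = "sim_scenario")
}

# Truncated-normal draw via inverse CDF (one uniform per draw, so the
# consumed RNG stream does not depend on rejection counts).
rtruncnorm1 <- function(mean, sd, lo, hi) {
  a <- stats::pnorm(lo, mean, sd)
  b <- stats::pnorm(hi, mean, sd)
  stats::qnorm(a + stats::runif(1) * (b - a), mean, sd)
}

#' Simulate a multi-study QTL compendium with known truth
#'
#' For each study: a population type and size are drawn; each true locus
#' is re-detected with `detection_prob`; each detected report draws an
#' R2, takes `sigma = CI(pop_type, N, R2)/3.92` from the CI formula, and
#' observes a peak `~ Normal(true position, sigma^2)` truncated to the
#' chromosome. The component map is a scaffold subsample with jittered
#' interval lengths; the observed (consensus-frame) peak is re-expressed
#' in component coordinates, which is what the compendium records — the
#' pipeline must project it back.
#'
#' @param arch an `architecture` (see [new_architecture()]).
#' @param scenario a `sim_scenario` (see [new_scenario()]).
#' @return list with `qtls`, `studies`, `maps` (component maps),
#'   `scaffold`, `truth` (`architecture` plus a per-report latent table)
#'   and the echoed `scenario`.
#' @export
simulate_compendium <- function(arch, scenario = new_scenario()) {
  set.seed(as.integer(scenario$seed) %% .Machine$integer.max)
  chrs <- as.integer(names(arch$lengths))

  scaffold <- do.call(rbind, lapply(chrs, function(chr) {
    len <- arch$lengths[[as.character(chr)]]
    pos <- unique(c(seq(0, len, by = scenario$marker_spacing_cm), len))
    data.frame(map_id = "scaffold",
               marker = sprintf("C%02dM%03d", chr, seq_along(pos)),
               chr = chr, pos_cm = pos, stringsAsFactors = FALSE)
  }))

  qtls <- list(); studies <- list(); maps <- list(); truth_rows <- list()
  qtl_counter <- 0L
  for (s in seq_len(scenario$n_studies)) {
    study_id <- sprintf("S%02d", s)
    pop_type <- sample(names(scenario$pop_type_probs), 1,
                       prob = scenario$pop_type_probs)
    N <- sample(seq(scenario$n_range[1], scenario$n_range[2]), 1)
    map_id <- paste0("map_", study_id)

    comp <- list()
    for (chr in chrs) {
      sc <- scaffold[scaffold$chr == chr, , drop = FALSE]
      keep <- stats::runif(nrow(sc)) < scenario$map_keep_prob
      if (sum(keep) < 2) keep[sample.int(nrow(sc), 2)] <- TRUE
      sub <- sc[keep, , drop = FALSE]
      gaps <- diff(sub$pos_cm)
      jit <- stats::runif(length(gaps), scenario$jitter_range[1],
                          scenario$jitter_range[2])
      first <- sub$pos_cm[1] *
        stats::runif(1, scenario$jitter_range[1], scenario$jitter_range[2])
      comp[[as.character(chr)]] <- data.frame(
        map_id = map_id, marker = sub$marker, chr = chr,
        pos_cm = cumsum(c(first, gaps * jit)), stringsAsFactors = FALSE)
    }
    comp <- do.call(rbind, comp)
    maps[[s]] <- comp

    study_traits <- character(0)
    for (chr in chrs) {
      len <- arch$lengths[[as.character(chr)]]
      true_pos <- arch$positions[[as.character(chr)]]
      cc <- comp[comp$chr == chr, , drop = FALSE]
      sc <- scaffold[scaffold$chr == chr, , drop = FALSE]
      cons_of <- stats::setNames(sc$pos_cm, sc$marker)
      comp_anchor_cons <- cons_of[cc$marker]   # consensus coords of comp markers
      for (j in seq_along(true_pos)) {
        if (stats::runif(1) >= scenario$detection_prob) next
        r2 <- stats::rlnorm(1, scenario$r2_meanlog, scenario$r2_sdlog)
        r2 <- min(max(r2, scenario$r2_clip[1]), scenario$r2_clip[2])
        sigma <- unname(CI_CONSTANTS[pop_type]) / (N * r2) / CI95_Z_WIDTH
        peak_cons <- rtruncnorm1(true_pos[j], sigma, 0, len)
        # re-express in component coordinates (piecewise linear between
        # the component's markers, which all have known consensus coords)
        iL <- findInterval(peak_cons, comp_anchor_cons)
        if (iL < 1 || iL >= length(comp_anchor_cons)) {
          # outside the component span: the study could not have placed
          # this QTL on its own map; skip (contributes to non-detection)
          next
        }
        frac <- (peak_cons - comp_anchor_cons[iL]) /
          (comp_anchor_cons[iL + 1] - comp_anchor_cons[iL])
        peak_src <- cc$pos_cm[iL] + frac * (cc$pos_cm[iL + 1] - cc$pos_cm[iL])
        trait <- sample(names(arch$trait_weights), 1,
                        prob = arch$trait_weights)
        lod <- stats::rlnorm(1, log(5), 0.9)
        qtl_counter <- qtl_counter + 1L
        pve <- r2 * 100
        lod_rec <- if (stats::runif(1) < scenario$missing_lod_prob)
          NA_real_ else lod
        pve_rec <- if (stats::runif(1) < scenario$missing_pve_prob)
          NA_real_ else pve
        qtls[[qtl_counter]] <- data.frame(
          qtl_id = sprintf("q%04d", qtl_counter), study_id = study_id,
          trait = trait, chr = chr, peak_cm = peak_src,
          lod = lod_rec, pve_pct = pve_rec,
          flank_left = cc$marker[iL], flank_right = cc$marker[iL + 1],
          map_id = map_id, stringsAsFactors = FALSE)
        truth_rows[[qtl_counter]] <- data.frame(
          qtl_id = sprintf("q%04d", qtl_counter), chr = chr,
          true_position_cm = true_pos[j], true_locus = j,
          r2 = r2, sigma_cm = sigma, peak_cons_cm = peak_cons,
          stringsAsFactors = FALSE)
        study_traits <- union(study_traits, trait)
      }
    }
    studies[[s]] <- data.frame(
      study_id = study_id, parents = sprintf("SimA%02d x SimB%02d", s, s),
      pop_type = pop_type, pop_size = N,
      n_markers = sum(vapply(split(comp$marker, comp$chr), length,
                             integer(1))),
      marker_types = "SSR",
      traits = paste(sort(if (length(study_traits)) study_traits else
        TRAIT_CODES), collapse = ","),
      citation = "synthetic", stringsAsFactors = FALSE)
  }
  if (qtl_counter == 0L)
    stop("no QTLs generated; increase detection_prob, n_studies, or the ",
         "architecture size")
  list(qtls = do.call(rbind, qtls),
       studies = do.call(rbind, studies),
       maps = do.call(rbind, maps),
       scaffold = scaffold,
       truth = list(architecture = arch,
                    qtls = do.call(rbind, truth_rows)),
       scenario = scenario)
}

#' Compare pipeline MQTLs against simulation truth
#'
#' MQTLs are greedily matched to the nearest true positions on their
#' chromosome (closest pair first, each side used once). K-accuracy is
#' the fraction of chromosomes where the selected number of MQTLs equals
#' the number of true loci; coverage is the fraction of matched true
#' positions falling inside the matched MQTL's 95% CI.
#'
#' @param truth the `truth` element of [simulate_compendium()] output.
#' @param mqtls the pipeline's MQTL table.
#' @return list with `k_accuracy`, `rmse_cm`, `coverage`, `n_matched`
#'   and a `per_chromosome` table.
#' @export
recovery_metrics <- function(truth, mqtls) {
  arch <- truth$architecture
  chrs <- as.integer(names(arch$positions))
  per <- list(); errs <- numeric(0); covered <- logical(0)
  k_hits <- logical(0)
  for (chr in chrs) {
    true_pos <- arch$positions[[as.character(chr)]]
    est <- mqtls[mqtls$chr == chr, , drop = FALSE]
    k_hits <- c(k_hits, nrow(est) == length(true_pos))
    t_left <- seq_along(true_pos); e_left <- seq_len(nrow(est))
    while (length(t_left) > 0 && length(e_left) > 0) {
      d <- abs(outer(est$position_cm[e_left], true_pos[t_left], "-"))
      ij <- which(d == min(d), arr.ind = TRUE)[1, ]
      e <- e_left[ij[1]]; t <- t_left[ij[2]]
      err <- est$position_cm[e] - true_pos[t]
      errs <- c(errs, err)
      covered <- c(covered, abs(err) <= est$ci95_cm[e] / 2)
      e_left <- setdiff(e_left, e); t_left <- setdiff(t_left, t)
    }
    per[[as.character(chr)]] <- data.frame(
      chr = chr, k_true = length(true_pos), k_hat = nrow(est))
  }
  list(k_accuracy = mean(k_hits),
       rmse_cm = if (length(errs)) sqrt(mean(errs^2)) else NA_real_,
       coverage = if (length(covered)) mean(covered) else NA_real_,
       n_matched = length(errs),
       per_chromosome = do.call(rbind, per))
}
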