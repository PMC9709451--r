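# Stability filtering, CI fold-reduction statistics and GWAS co-location.

#' Filter MQTLs by member count (stability)
#'
#' An MQTL supported by at least `threshold` initial QTLs (default six)
#' from independent populations is considered stable and robust.
#'
#' @param mqtls MQTL table with `chr, position_cm, n_qtls` columns.
#' @param threshold minimum member count, at least 1.
#' @return list with `stable` (subset, sorted by chromosome then
#'   position), `threshold`, and `n_stable`.
#' @export
stable_filter <- function(mqtls, threshold = 6L) {
  stopifnot(threshold >= 1)
  keep <- mqtls[mqtls$n_qtls >= threshold, , drop = FALSE]
  keep <- keep[order(keep$chr, keep$position_cm), , drop = FALSE]
  rownames(keep) <- NULL
  list(stable = keep, threshold = threshold, n_stable = nrow(keep))
}

#' Mean-CI fold reduction of MQTLs over initial QTLs
#'
#' @param initial_cis 95% CI widths (cM) of the projected initial QTLs.
#' @param mqtl_cis 95% CI widths (cM) of the MQTLs.
#' @return `mean(initial_cis) / mean(mqtl_cis)`.
#' @export
ci_fold_reduction <- function(initial_cis, mqtl_cis) {
  stopifnot(length(initial_cis) > 0, length(mqtl_cis) > 0)
  m <- mean(mqtl_cis)
  if (m <= 0) stop("mean MQTL CI must be positive")
  mean(initial_cis) / m
}

#' CI fold reduction overall and per chromosome
#'
#' Reports the overall fold (ratio of dataset mean CIs), the fold per
#' chromosome, and the maximum per-chromosome fold (the "up to" figure).
#'
#' @param projected projected QTL table (`chr`, `ci95_cons_cm`).
#' @param mqtls MQTL table (`chr`, `ci95_cm`).
#' @return list with `overall`, `per_chromosome` data frame, `max_fold`.
#' @export
fold_reduction_summary <- function(projected, mqtls) {
  overall <- ci_fold_reduction(projected$ci95_cons_cm, mqtls$ci95_cm)
  chrs <- sort(intersect(unique(projected$chr), unique(mqtls$chr)))
  per <- do.call(rbind, lapply(chrs, function(chr) {
    data.frame(chr = chr,
               mean_initial_ci = mean(projected$ci95_cons_cm[
                 projected$chr == chr]),
               mean_mqtl_ci = mean(mqtls$ci95_cm[mqtls$chr == chr]))
  }))
  per$fold <- per$mean_initial_ci / per$mean_mqtl_ci
  list(overall = overall, per_chromosome = per, max_fold = max(per$fold))
}

#' Read a GWAS peak-locus table
#'
#' TSV columns: `locus_id, chr, pos_bp, trait, source`.
#' @param path TSV path.
#' @return validated data frame.
#' @export
read_gwas_table <- function(path) {
  df <- read_tsv_strict(path)
  missing_cols <- setdiff(c("locus_id", "chr", "pos_bp", "trait", "source"),
                          names(df))
  if (length(missing_cols) > 0)
    stop("GWAS table missing columns: ",
         paste(missing_cols, collapse = ", "))
  df$chr <- as.integer(df$chr)
  df$pos_bp <- as.numeric(df$pos_bp)
  stopifnot(all(df$pos_bp >= 1))
  df
}

#' Co-locate MQTL physical intervals with GWAS peak loci
#'
#' An MQTL co-locates with a locus when chromosomes match and the locus
#' lies within `window_bp` of the MQTL's physical interval (window 0 is
#' plain containment). Both trait-agnostic and trait-matched counts are
#' reported; a locus trait matches when it is among the MQTL's traits.
#'
#' @param intervals data frame `mqtl_name, chr, start_bp, end_bp` plus
#'   optionally `traits` (comma-separated codes).
#' @param loci GWAS locus table (see [read_gwas_table()]).
#' @param window_bp non-negative tolerance in bp.
#' @return list with `pairs` (one row per co-located MQTL x locus),
#'   `n_mqtls_colocated` and `n_mqtls_trait_matched`.
#' @export
gwas_colocate <- function(intervals, loci, window_bp = 0L) {
  stopifnot(window_bp >= 0)
  pairs <- list()
  for (i in seq_len(nrow(intervals))) {
    iv <- intervals[i, ]
    hit <- loci$chr == iv$chr &
      loci$pos_bp >= iv$start_bp - window_bp &
      loci$pos_bp <= iv$end_bp + window_bp
    if (!any(hit)) next
    mq_traits <- if ("traits" %in% names(iv))
      strsplit(iv$traits, ",", fixed = TRUE)[[1]] else character(0)
    sub <- loci[hit, , drop = FALSE]
    pairs[[length(pairs) + 1]] <- data.frame(
      mqtl_name = iv$mqtl_name, locus_id = sub$locus_id,
      chr = iv$chr, pos_bp = sub$pos_bp, locus_trait = sub$trait,
      trait_match = sub$trait %in% mq_traits, stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(mqtl_name = character(0), locus_id = character(0),
               chr = integer(0), pos_bp = numeric(0),
               locus_trait = character(0), trait_match = logical(0))
  list(pairs = pairs,
       n_mqtls_colocated = length(unique(pairs$mqtl_name)),
       n_mqtls_trait_matched = length(unique(
         pairs$mqtl_name[pairs$trait_match])))
}

#' Assemble the full pipeline report
#'
#' Bundles the outputs of every stage into one list ready for JSON
#' serialisation. Each required stage must be present; a missing stage is
#' an explicit error naming it.
#'
#' @param compendium_summary output of [summarize_compendium()].
#' @param projection_report output of [projection_report()].
#' @param fits per-chromosome fits/scores (from [run_meta_analysis()]).
#' @param mqtl_table the MQTL table.
#' @param stability output of [stable_filter()].
#' @param colocation output of [gwas_colocate()] (optional; empty list if
#'   no GWAS loci supplied).
#' @param config list of configuration values and seeds to echo.
#' @return a named list with the six report sections plus `config`.
#' @export
full_report <- function(compendium_summary, projection_report, fits,
                        mqtl_table, stability, colocation = list(),
                        config = list()) {
  if (is.null(compendium_summary)) stop("compendium stage output absent")
  if (is.null(projection_report)) stop("projection stage output absent")
  if (is.null(fits)) stop("cluster stage output absent")
  if (is.null(mqtl_table)) stop("MQTL table absent")
  if (is.null(stability)) stop("stability stage output absent")
  fit_summaries <- lapply(fits, function(res) list(
    K = res$selection$K, branch = res$selection$branch,
    votes = as.list(res$selection$votes),
    scores = res$scores))
  list(compendium_summary = compendium_summary,
       projection_report = projection_report,
       fits = fit_summaries,
       mqtl_table = mqtl_table,
       stability = list(threshold = stability$threshold,
                        n_stable = stability$n_stable,
                        stable = stability$stable),
       colocation = colocation,
       config = config)
}

#' Write a report to JSON, deterministically
#'
#' No timestamps: rerunning the pipeline with the same seed produces a
#' byte-identical file.
#'
#' @param report list from [full_report()].
#' @param path output path.
#' @export
write_report <- function(report, path) {
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
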