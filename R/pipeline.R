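# End-to-end orchestration: compendium -> CI -> consensus map ->
# projection -> clustering -> report.

#' Run the full meta-QTL pipeline on an in-memory dataset
#'
#' Convenience wrapper chaining every stage with one master seed:
#' validation, CI re-estimation and imputation, consensus-map
#' construction, QTL projection, per-chromosome mixture clustering with
#' information-criterion selection, stability filtering and the bundled
#' report.
#'
#' @param qtls compendium data frame (canonical columns).
#' @param studies study data frame.
#' @param scaffold scaffold map (`marker, chr, pos_cm`).
#' @param maps component source maps (`map_id, marker, chr, pos_cm`).
#' @param seed master seed for the clustering restarts.
#' @param k_max per-chromosome cluster cap.
#' @param stable_threshold member count defining a stable MQTL.
#' @param gwas_loci optional GWAS locus table for co-location (requires
#'   `marker_positions`).
#' @param marker_positions optional marker -> bp lookup.
#' @param window_bp co-location window.
#' @param ... passed to [em_fit()].
#' @return list with every stage's output: `compendium`, `consensus`,
#'   `projection`, `meta`, `stability`, `fold`, `colocation`, `report`.
#' @export
run_pipeline <- function(qtls, studies, scaffold, maps, seed = 1L,
                         k_max = 10L, stable_threshold = 6L,
                         gwas_loci = NULL, marker_positions = NULL,
                         window_bp = 0L, ...) {
  val <- validate_qtl_records(qtls)
  withci <- attach_ci(val$records, studies)
  cons <- build_consensus(
    scaffold,
    split(maps, maps$map_id))
  proj <- project_qtls(withci, maps, cons$map)
  if (nrow(proj$projected) == 0)
    stop("no QTLs could be projected onto the consensus map")
  meta <- run_meta_analysis(proj$projected, consensus = cons$map,
                            seed = seed, k_max = k_max, ...)
  stab <- stable_filter(meta$mqtls, stable_threshold)
  fold <- fold_reduction_summary(proj$projected, meta$mqtls)
  coloc <- list()
  if (!is.null(gwas_loci) && !is.null(marker_positions)) {
    phys <- resolve_physical(meta$mqtls, marker_positions)
    coloc <- gwas_colocate(phys$intervals, gwas_loci, window_bp)
  }
  report <- full_report(
    compendium_summary = summarize_compendium(val$records, studies),
    projection_report = proj$report,
    fits = meta$chromosomes,
    mqtl_table = meta$mqtls,
    stability = stab,
    colocation = coloc,
    config = list(seed = seed, k_max = k_max,
                  stable_threshold = stable_threshold,
                  sigma_floor_cm = SIGMA_FLOOR_CM,
                  window_bp = window_bp))
  list(compendium = val, with_ci = withci, consensus = cons,
       projection = proj, meta = meta, stability = stab, fold = fold,
       colocation = coloc, report = report)
}

#' Path to a packaged fixture file
#'
#' @param name file name under the package's `extdata` directory, e.g.
#'   `"table1.tsv"`.
#' @return absolute path.
#' @export
metaqtl_fixture <- function(name) {
  p <- system.file("extdata", name, package = "metaqtl")
  if (!nzchar(p)) stop("no packaged fixture called ", name)
  p
}
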