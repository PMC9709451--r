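# Compendium data model: literature-reported QTLs, their source studies,
# and the published MQTL summary table.

#' Trait codes recognised by the pipeline
#'
#' The four rice grain-yield component traits: spikelet fertility (SF),
#' panicles per plant (PN), grains per panicle (GNP) and thousand-grain
#' weight (TGW). Any other code in an input table is a validation error.
#'
#' @export
TRAIT_CODES <- c("SF", "PN", "GNP", "TGW")

#' Mapping-population type codes
#'
#' Recombinant inbred lines (RIL), doubled haploids (DH), backcross (BC)
#' and F2 populations. The code determines which confidence-interval
#' constant applies (see [estimate_ci()]).
#'
#' @export
POP_TYPES <- c("RIL", "DH", "BC", "F2")

# Columns of the canonical QTL compendium dialect, in order.
QTL_COLUMNS <- c("qtl_id", "study_id", "trait", "chr", "peak_cm", "lod",
                 "pve_pct", "flank_left", "flank_right", "map_id")

STUDY_COLUMNS <- c("study_id", "parents", "pop_type", "pop_size",
                   "n_markers", "marker_types", "traits", "citation")

MQTL_COLUMNS <- c("name", "chr", "position_cm", "flank_left", "flank_right",
                  "n_qtls", "n_traits", "traits", "avg_pve")

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    na.strings = c("", "NA"), stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "")
}

remap_columns <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  for (canonical in names(col_map)) {
    ext <- col_map[[canonical]]
    if (ext %in% names(df)) names(df)[names(df) == ext] <- canonical
  }
  df
}

split_traits <- function(x) {
  out <- strsplit(gsub("\\s+", "", x), ",", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

#' Read and validate a QTL compendium table
#'
#' Reads a tab-separated compendium of literature-reported QTLs (one row
#' per QTL). Rows that fail validation are not dropped silently: they are
#' returned in a `rejects` table with the offending row number and reason.
#'
#' Expected columns: `qtl_id, study_id, trait, chr, peak_cm, lod, pve_pct,
#' flank_left, flank_right, map_id`. Missing values may be encoded as an
#' empty field or `NA`. Other headers can be adapted with `col_map`, a
#' named list mapping canonical names to the file's column names.
#'
#' @param path path to a TSV file with a header row.
#' @param col_map optional named list remapping external column names onto
#'   the canonical ones, e.g. `list(pve_pct = "R2")`.
#' @return a list with `records` (validated data frame) and `rejects`
#'   (data frame with columns `row`, `qtl_id`, `reason`).
#' @export
read_qtl_table <- function(path, col_map = NULL) {
  df <- remap_columns(read_tsv_strict(path), col_map)
  missing_cols <- setdiff(QTL_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("compendium table missing columns: ",
         paste(missing_cols, collapse = ", "))
  df <- df[QTL_COLUMNS]
  df$chr <- suppressWarnings(as.integer(df$chr))
  for (col in c("peak_cm", "lod", "pve_pct"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  validate_qtl_records(df)
}

#' Validate an in-memory QTL compendium
#'
#' @param df data frame with the canonical compendium columns.
#' @return list of `records` and `rejects`, as for [read_qtl_table()].
#' @export
validate_qtl_records <- function(df) {
  reasons <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    reason <- NULL
    if (is.na(r$qtl_id) || !nzchar(r$qtl_id)) {
      reason <- "missing qtl_id"
    } else if (is.na(r$trait) || !(r$trait %in% TRAIT_CODES)) {
      reason <- "unknown trait code"
    } else if (is.na(r$chr) || r$chr < 1L || r$chr > 12L) {
      reason <- "chromosome out of range"
    } else if (!is.na(r$peak_cm) && r$peak_cm < 0) {
      reason <- "negative peak position"
    } else if (!is.na(r$pve_pct) && (r$pve_pct <= 0 || r$pve_pct > 100)) {
      reason <- "pve out of (0, 100]"
    } else if (!is.na(r$lod) && r$lod < 0) {
      reason <- "negative lod"
    }
    reasons[i] <- if (is.null(reason)) "" else reason
  }
  ok <- !nzchar(reasons)
  records <- df[ok, , drop = FALSE]
  rownames(records) <- NULL
  rejects <- data.frame(row = which(!ok),
                        qtl_id = df$qtl_id[!ok],
                        reason = reasons[!ok],
                        stringsAsFactors = FALSE)
  list(records = records, rejects = rejects)
}

#' Write a QTL compendium table
#'
#' Inverse of [read_qtl_table()]; missing values are written as empty
#' fields so that a write/read round trip reproduces all fields.
#'
#' @param records validated compendium data frame.
#' @param path output TSV path.
#' @export
write_qtl_table <- function(records, path) {
  utils::write.table(records[QTL_COLUMNS], path, sep = "\t", na = "",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a study table
#'
#' One row per mapping study: parents, population type and size, marker
#' counts and types, traits scored, citation. Population type must be one
#' of RIL/DH/BC/F2 and population size at least 2.
#'
#' @inheritParams read_qtl_table
#' @return list of `records` and `rejects`.
#' @export
read_study_table <- function(path, col_map = NULL) {
  df <- remap_columns(read_tsv_strict(path), col_map)
  missing_cols <- setdiff(STUDY_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("study table missing columns: ",
         paste(missing_cols, collapse = ", "))
  df <- df[STUDY_COLUMNS]
  df$pop_size <- suppressWarnings(as.integer(gsub(",", "", df$pop_size)))
  df$n_markers <- suppressWarnings(as.numeric(gsub(",", "", df$n_markers)))
  reasons <- character(nrow(df))
  trait_lists <- split_traits(df$traits)
  for (i in seq_len(nrow(df))) {
    reason <- NULL
    if (is.na(df$study_id[i]) || !nzchar(df$study_id[i])) {
      reason <- "missing study_id"
    } else if (is.na(df$pop_type[i]) || !(df$pop_type[i] %in% POP_TYPES)) {
      reason <- "unknown population type"
    } else if (is.na(df$pop_size[i]) || df$pop_size[i] < 2L) {
      reason <- "population size below 2"
    } else if (!is.na(df$n_markers[i]) && df$n_markers[i] <= 0) {
      reason <- "non-positive marker count"
    } else if (length(trait_lists[[i]]) == 0 ||
               !all(trait_lists[[i]] %in% TRAIT_CODES)) {
      reason <- "invalid trait list"
    }
    reasons[i] <- if (is.null(reason)) "" else reason
  }
  ok <- !nzchar(reasons)
  records <- df[ok, , drop = FALSE]
  rownames(records) <- NULL
  list(records = records,
       rejects = data.frame(row = which(!ok),
                            study_id = df$study_id[!ok],
                            reason = reasons[!ok],
                            stringsAsFactors = FALSE))
}

#' Read a published MQTL summary table
#'
#' One row per meta-QTL: name, chromosome, consensus position, flanking
#' markers, number of member QTLs, number and identity of traits, average
#' phenotypic variance explained (percent).
#'
#' @inheritParams read_qtl_table
#' @return validated data frame of MQTL summary rows.
#' @export
read_mqtl_table <- function(path, col_map = NULL) {
  df <- remap_columns(read_tsv_strict(path), col_map)
  missing_cols <- setdiff(MQTL_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("MQTL table missing columns: ",
         paste(missing_cols, collapse = ", "))
  df <- df[MQTL_COLUMNS]
  df$chr <- as.integer(df$chr)
  df$n_qtls <- as.integer(df$n_qtls)
  df$n_traits <- as.integer(df$n_traits)
  df$position_cm <- as.numeric(df$position_cm)
  df$avg_pve <- as.numeric(df$avg_pve)
  stopifnot(all(df$n_qtls >= 1L),
            all(df$n_traits >= 1L & df$n_traits <= length(TRAIT_CODES)),
            all(df$chr >= 1L & df$chr <= 12L))
  df
}

#' Summary statistics for a QTL compendium
#'
#' Aggregates the compendium the way a meta-analysis reports its inputs:
#' studies by population type, QTLs per chromosome and trait, ranges and
#' means of PVE, LOD and population size, and the fraction of minor-effect
#' QTLs (PVE below 10 percent).
#'
#' @param qtls validated QTL records.
#' @param studies validated study records.
#' @return a list of summary components.
#' @export
summarize_compendium <- function(qtls, studies) {
  if (nrow(qtls) == 0 || nrow(studies) == 0)
    stop("empty compendium: need at least one QTL and one study")
  num_stats <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(c(min = NA_real_, max = NA_real_,
                                 mean = NA_real_))
    c(min = min(x), max = max(x), mean = mean(x))
  }
  pop_counts <- table(factor(studies$pop_type, levels = POP_TYPES))
  list(
    n_studies = nrow(studies),
    n_qtls = nrow(qtls),
    pop_type_counts = stats::setNames(as.integer(pop_counts), POP_TYPES),
    pop_size_range = range(studies$pop_size),
    pop_size_stats = num_stats(studies$pop_size),
    qtls_per_chromosome = stats::setNames(
      as.integer(table(factor(qtls$chr, levels = 1:12))), 1:12),
    qtls_per_trait = stats::setNames(
      as.integer(table(factor(qtls$trait, levels = TRAIT_CODES))),
      TRAIT_CODES),
    pve_stats = num_stats(qtls$pve_pct),
    lod_stats = num_stats(qtls$lod),
    frac_pve_below_10 = mean(qtls$pve_pct[!is.na(qtls$pve_pct)] < 10)
  )
}

#' Summary statistics for an MQTL table
#'
#' @param rows MQTL summary rows (see [read_mqtl_table()]).
#' @param thresholds member-count thresholds at which to report how many
#'   MQTLs hold at least that many initial QTLs.
#' @return a list of summary components.
#' @export
summarize_mqtl_table <- function(rows, thresholds = c(2L, 6L)) {
  if (nrow(rows) == 0) stop("empty MQTL table")
  per_chr <- table(factor(rows$chr, levels = 1:12))
  per_chr <- per_chr[per_chr > 0]
  at_least <- vapply(thresholds, function(t) sum(rows$n_qtls >= t),
                     integer(1))
  list(
    n_mqtls = nrow(rows),
    total_member_qtls = sum(rows$n_qtls),
    per_chromosome = stats::setNames(as.integer(per_chr), names(per_chr)),
    avg_pve_stats = c(min = min(rows$avg_pve), max = max(rows$avg_pve),
                      mean = mean(rows$avg_pve)),
    n_with_at_least = stats::setNames(at_least, thresholds),
    n_singletons = sum(rows$n_qtls == 1L)
  )
}
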