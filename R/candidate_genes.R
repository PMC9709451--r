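# Candidate-gene mining: physical intervals for stable MQTLs, gene
# extraction from GFF3 annotation, GO-term enrichment, tissue-expression
# ranking.

#' Default yield-related target tissues for expression ranking
#' @export
DEFAULT_TARGET_TISSUES <- c("anther", "pistil", "seed_5dap", "seed_10dap",
                            "embryo", "endosperm",
                            "inflorescence_pre", "inflorescence_post")

#' Resolve MQTLs to physical intervals via a marker-position lookup
#'
#' Each MQTL's flanking markers are looked up in a marker -> bp table;
#' the physical interval is `[min, max]` of the two positions (1-based
#' inclusive). MQTLs whose markers are missing from the lookup, or whose
#' markers map to different chromosomes, are returned as unresolved with
#' a reason rather than dropped silently.
#'
#' @param mqtls MQTL table with `name, chr, flank_left, flank_right`.
#' @param marker_positions data frame `marker, chr, pos_bp`.
#' @return list with `intervals` (`mqtl_name, chr, start_bp, end_bp,
#'   flank_left, flank_right`, plus `traits` if present in `mqtls`) and
#'   `unresolved` (`mqtl_name, reason`).
#' @export
resolve_physical <- function(mqtls, marker_positions) {
  intervals <- list(); unresolved <- list()
  for (i in seq_len(nrow(mqtls))) {
    m <- mqtls[i, ]
    idx <- match(c(m$flank_left, m$flank_right), marker_positions$marker)
    if (anyNA(c(m$flank_left, m$flank_right)) || anyNA(idx)) {
      unresolved[[length(unresolved) + 1]] <- data.frame(
        mqtl_name = m$name, reason = "NO_MARKER_POSITION",
        stringsAsFactors = FALSE)
      next
    }
    chrs <- marker_positions$chr[idx]
    if (chrs[1] != chrs[2]) {
      unresolved[[length(unresolved) + 1]] <- data.frame(
        mqtl_name = m$name, reason = "MARKER_CHR_CONFLICT",
        stringsAsFactors = FALSE)
      next
    }
    pos <- marker_positions$pos_bp[idx]
    row <- data.frame(mqtl_name = m$name, chr = chrs[1],
                      start_bp = min(pos), end_bp = max(pos),
                      flank_left = m$flank_left,
                      flank_right = m$flank_right,
                      stringsAsFactors = FALSE)
    if ("traits" %in% names(m)) row$traits <- m$traits
    intervals[[length(intervals) + 1]] <- row
  }
  list(intervals = if (length(intervals)) do.call(rbind, intervals) else
    data.frame(mqtl_name = character(0), chr = integer(0),
               start_bp = numeric(0), end_bp = numeric(0),
               flank_left = character(0), flank_right = character(0)),
    unresolved = if (length(unresolved)) do.call(rbind, unresolved) else
      data.frame(mqtl_name = character(0), reason = character(0)))
}

#' Read a marker physical-position lookup table
#'
#' TSV columns: `marker, chr, pos_bp`.
#' @param path TSV path.
#' @return validated data frame.
#' @export
read_marker_positions <- function(path) {
  df <- read_tsv_strict(path)
  missing_cols <- setdiff(c("marker", "chr", "pos_bp"), names(df))
  if (length(missing_cols) > 0)
    stop("marker position table missing columns: ",
         paste(missing_cols, collapse = ", "))
  df$chr <- as.integer(df$chr)
  df$pos_bp <- as.numeric(df$pos_bp)
  stopifnot(all(df$pos_bp >= 1))
  df
}

#' Extract genes overlapping a physical interval from a GFF3 annotation
#'
#' Genes are `type == "gene"` features; any overlap of at least 1 bp with
#' the interval counts, on either strand. The result is independent of
#' feature order in the file.
#'
#' @param interval one row with `chr, start_bp, end_bp` (1-based
#'   inclusive).
#' @param annotation path to a GFF3 file, or a `GRanges` already imported.
#' @param chr_prefix prefix turning the integer chromosome into the
#'   annotation's seqnames (e.g. `"Chr"`); empty for bare numbers.
#' @return data frame `gene_id, chromosome, start_bp, end_bp, strand,
#'   description`, sorted by start.
#' @export
extract_genes <- function(interval, annotation, chr_prefix = "Chr") {
  gr <- if (is.character(annotation))
    rtracklayer::import(annotation, format = "gff3") else annotation
  genes <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  seqname <- paste0(chr_prefix, interval$chr)
  query <- GenomicRanges::GRanges(
    seqname, IRanges::IRanges(interval$start_bp, interval$end_bp))
  hits <- IRanges::subsetByOverlaps(genes, query, minoverlap = 1L)
  if (length(hits) == 0)
    return(data.frame(gene_id = character(0), chromosome = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      strand = character(0), description = character(0)))
  desc <- if (!is.null(hits$description)) as.character(hits$description)
    else if (!is.null(hits$Note)) vapply(hits$Note, function(v)
      paste(v, collapse = "; "), character(1))
    else rep(NA_character_, length(hits))
  ids <- if (!is.null(hits$ID)) as.character(hits$ID)
    else as.character(hits$Name)
  out <- data.frame(gene_id = ids,
                    chromosome = as.character(GenomicRanges::seqnames(hits)),
                    start_bp = GenomicRanges::start(hits),
                    end_bp = GenomicRanges::end(hits),
                    strand = as.character(GenomicRanges::strand(hits)),
                    description = desc, stringsAsFactors = FALSE)
  out <- out[order(out$start_bp, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric GO-term enrichment with BH correction
#'
#' For each GO term annotated in the background, tests over-representation
#' in the gene set with the one-sided hypergeometric upper tail
#' P(X >= k), where the population is the background (size N), successes
#' are the background genes carrying the term (K), and draws are the gene
#' set (size n). P-values are corrected across terms by
#' Benjamini-Hochberg; `significant` marks FDR <= `fdr_alpha`.
#'
#' @param gene_set character vector of gene ids (must all appear in
#'   `background`).
#' @param annotation data frame `gene_id, term_id` (one row per
#'   gene-term link).
#' @param background character vector of all assayable gene ids.
#' @param fdr_alpha significance level on the FDR.
#' @return data frame `term_id, k_in_set, K_in_background, n_set,
#'   N_background, p_value, fdr, significant`, sorted by p-value.
#' @export
go_enrichment <- function(gene_set, annotation, background,
                          fdr_alpha = 0.05) {
  gene_set <- unique(gene_set)
  background <- unique(background)
  offenders <- setdiff(gene_set, background)
  if (length(offenders) > 0)
    stop("gene set members absent from background: ",
         paste(offenders, collapse = ", "))
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term_id")])
  N <- length(background)
  n <- length(gene_set)
  terms <- unique(ann$term_id)
  if (length(terms) == 0)
    return(data.frame(term_id = character(0), k_in_set = integer(0),
                      K_in_background = integer(0), n_set = integer(0),
                      N_background = integer(0), p_value = numeric(0),
                      fdr = numeric(0), significant = logical(0)))
  res <- do.call(rbind, lapply(terms, function(tm) {
    genes_with <- ann$gene_id[ann$term_id == tm]
    K <- length(genes_with)
    k <- sum(gene_set %in% genes_with)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tm, k_in_set = k, K_in_background = K,
               n_set = n, N_background = N, p_value = p,
               stringsAsFactors = FALSE)
  }))
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$fdr <= fdr_alpha
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Rank candidate genes by tissue-expression fold change
#'
#' Scores each gene by the ratio of its mean expression over target
#' (yield-related) tissues to its mean over the remaining tissues, with a
#' pseudocount guarding zero expression:
#' `score = (mean_target + c) / (mean_other + c)`.
#'
#' @param genes gene ids to score; genes absent from the matrix are
#'   excluded and reported.
#' @param expr numeric matrix, genes in rows (rownames = gene ids),
#'   tissues in columns.
#' @param target_tissues column names counting as yield-related.
#' @param fold_threshold shortlist cut-off on the score.
#' @param pseudocount the additive constant c.
#' @return list with `scores` (all scored genes, descending),
#'   `shortlist` (score >= threshold) and `missing` (ids not in the
#'   matrix).
#' @export
expression_rank <- function(genes, expr,
                            target_tissues = DEFAULT_TARGET_TISSUES,
                            fold_threshold = 2.0, pseudocount = 0.1) {
  tgt <- intersect(colnames(expr), target_tissues)
  if (length(tgt) == 0) stop("no target tissue columns found in matrix")
  oth <- setdiff(colnames(expr), tgt)
  if (length(oth) == 0) stop("no non-target tissue columns in matrix")
  present <- genes[genes %in% rownames(expr)]
  missing <- setdiff(genes, present)
  if (length(present) == 0)
    return(list(scores = data.frame(gene_id = character(0),
                                    score = numeric(0)),
                shortlist = data.frame(gene_id = character(0),
                                       score = numeric(0)),
                missing = missing))
  m <- expr[present, , drop = FALSE]
  score <- (rowMeans(m[, tgt, drop = FALSE]) + pseudocount) /
    (rowMeans(m[, oth, drop = FALSE]) + pseudocount)
  scores <- data.frame(gene_id = present, score = unname(score),
                       stringsAsFactors = FALSE)
  scores <- scores[order(-scores$score, scores$gene_id), , drop = FALSE]
  rownames(scores) <- NULL
  list(scores = scores,
       shortlist = scores[scores$score >= fold_threshold, , drop = FALSE],
       missing = missing)
}

#' Export physical intervals as BED
#'
#' Converts the 1-based inclusive intervals to BED's 0-based half-open
#' convention.
#'
#' @param intervals data frame from [resolve_physical()].
#' @param path output path.
#' @param chr_prefix seqname prefix (default `"Chr"`).
#' @export
write_intervals_bed <- function(intervals, path, chr_prefix = "Chr") {
  bed <- data.frame(chrom = paste0(chr_prefix, intervals$chr),
                    start = as.integer(intervals$start_bp) - 1L,
                    end = as.integer(intervals$end_bp),
                    name = intervals$mqtl_name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
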