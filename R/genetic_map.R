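# Genetic maps and consensus-map construction by anchor interpolation.

#' Read a genetic-map table
#'
#' TSV with columns `map_id, marker, chr, pos_cm`. A file may hold several
#' maps (distinguished by `map_id`). Within each map, marker names must be
#' unique and positions non-negative.
#'
#' @param path TSV path.
#' @return data frame sorted by map, chromosome and position.
#' @export
read_map_table <- function(path) {
  df <- read_tsv_strict(path)
  missing_cols <- setdiff(c("map_id", "marker", "chr", "pos_cm"), names(df))
  if (length(missing_cols) > 0)
    stop("map table missing columns: ", paste(missing_cols, collapse = ", "))
  df$chr <- as.integer(df$chr)
  df$pos_cm <- as.numeric(df$pos_cm)
  validate_map(df)
}

#' Validate an in-memory genetic-map table
#' @param df data frame with `map_id, marker, chr, pos_cm`.
#' @return the table sorted by map, chromosome, position.
#' @export
validate_map <- function(df) {
  if (any(is.na(df$pos_cm)) || any(df$pos_cm < 0))
    stop("map positions must be non-negative")
  dup <- tapply(df$marker, df$map_id, function(m) anyDuplicated(m) > 0)
  if (any(dup))
    stop("duplicate marker names within map(s): ",
         paste(names(dup)[dup], collapse = ", "))
  df[order(df$map_id, df$chr, df$pos_cm, df$marker), , drop = FALSE]
}

# Enforce strictly increasing positions among sorted rows: scaffold rows
# are never moved; later (interpolated) rows at a tied position are bumped
# by the smallest workable offset.
resolve_ties <- function(pos, movable) {
  if (length(pos) < 2) return(pos)
  for (i in 2:length(pos)) {
    if (pos[i] <= pos[i - 1]) {
      bump <- max(abs(pos[i - 1]), 1) * .Machine$double.eps * 4
      if (!movable[i])
        stop("cannot tie-break an immovable (scaffold) marker")
      pos[i] <- pos[i - 1] + bump
    }
  }
  pos
}

#' Build a consensus map from a scaffold and component maps
#'
#' Scaffold markers keep their positions exactly. Each component marker
#' absent from the scaffold is placed by linear interpolation of its
#' component position between the two nearest shared (anchor) markers;
#' markers outside the terminal anchors are extrapolated with the
#' chromosome-level mean scaling ratio and dropped if that places them
#' beyond the scaffold chromosome ends. Component chromosomes whose
#' anchors are order-inconsistent with the scaffold contribute no markers
#' (reason `anchor order conflict`); chromosomes sharing fewer than two
#' anchors are skipped.
#'
#' @param scaffold data frame `marker, chr, pos_cm` (a `map_id` column is
#'   ignored) — the high-density backbone.
#' @param components list of component map data frames (same columns), or
#'   a single data frame with a `map_id` column holding several maps.
#' @return a list with `map` (data frame `marker, chr, pos_cm, source`,
#'   strictly ordered within chromosome), `report` (per map x chromosome:
#'   markers shared/added/dropped) and `dropped` (marker-level reasons).
#' @export
build_consensus <- function(scaffold, components = list()) {
  if (nrow(scaffold) == 0) stop("empty scaffold map")
  if (is.data.frame(components))
    components <- split(components, components$map_id)
  cons <- data.frame(marker = scaffold$marker, chr = scaffold$chr,
                     pos_cm = scaffold$pos_cm, source = "scaffold",
                     stringsAsFactors = FALSE)
  report <- list()
  dropped <- list()
  note_drop <- function(map_id, markers, chr, reason) {
    if (length(markers) == 0) return(NULL)
    data.frame(map_id = map_id, marker = markers, chr = chr,
               reason = reason, stringsAsFactors = FALSE)
  }
  for (map_id in names(components)) {
    comp <- components[[map_id]]
    for (chr in sort(unique(comp$chr))) {
      cc <- comp[comp$chr == chr, , drop = FALSE]
      cc <- cc[order(cc$pos_cm, cc$marker), , drop = FALSE]
      sc <- cons[cons$chr == chr & cons$source == "scaffold", , drop = FALSE]
      shared <- intersect(cc$marker, sc$marker)
      new_markers <- setdiff(cc$marker, cons$marker[cons$chr == chr])
      entry <- data.frame(map_id = map_id, chr = chr,
                          n_shared = length(shared), n_added = 0L,
                          n_dropped = 0L, note = "", stringsAsFactors = FALSE)
      if (length(shared) < 2) {
        entry$n_dropped <- length(new_markers)
        entry$note <- "fewer than 2 shared anchors; chromosome skipped"
        dropped[[length(dropped) + 1]] <-
          note_drop(map_id, new_markers, chr, "insufficient shared anchors")
        report[[length(report) + 1]] <- entry
        next
      }
      anchors <- data.frame(
        marker = shared,
        src = cc$pos_cm[match(shared, cc$marker)],
        cons = sc$pos_cm[match(shared, sc$marker)])
      anchors <- anchors[order(anchors$src), , drop = FALSE]
      if (is.unsorted(anchors$cons, strictly = FALSE) ||
          anyDuplicated(anchors$cons) > 0 || anyDuplicated(anchors$src) > 0) {
        entry$n_dropped <- length(new_markers)
        entry$note <- "anchor order conflict; chromosome skipped"
        dropped[[length(dropped) + 1]] <-
          note_drop(map_id, new_markers, chr, "anchor order conflict")
        report[[length(report) + 1]] <- entry
        next
      }
      chr_lo <- min(sc$pos_cm)
      chr_hi <- max(sc$pos_cm)
      span_ratio <- (max(anchors$cons) - min(anchors$cons)) /
        (max(anchors$src) - min(anchors$src))
      placed <- character(0)
      for (m in new_markers) {
        p <- cc$pos_cm[match(m, cc$marker)]
        if (p < min(anchors$src)) {
          est <- min(anchors$cons) - (min(anchors$src) - p) * span_ratio
        } else if (p > max(anchors$src)) {
          est <- max(anchors$cons) + (p - max(anchors$src)) * span_ratio
        } else {
          iL <- max(which(anchors$src <= p))
          iR <- min(which(anchors$src >= p))
          if (iL == iR) {
            est <- anchors$cons[iL]
          } else {
            est <- anchors$cons[iL] + (p - anchors$src[iL]) *
              (anchors$cons[iR] - anchors$cons[iL]) /
              (anchors$src[iR] - anchors$src[iL])
          }
        }
        if (est < chr_lo || est > chr_hi) {
          dropped[[length(dropped) + 1]] <-
            note_drop(map_id, m, chr, "extrapolation out of range")
          next
        }
        cons <- rbind(cons, data.frame(
          marker = m, chr = chr, pos_cm = est,
          source = paste0("interpolated:", map_id),
          stringsAsFactors = FALSE))
        placed <- c(placed, m)
      }
      entry$n_added <- length(placed)
      entry$n_dropped <- length(new_markers) - length(placed)
      report[[length(report) + 1]] <- entry
    }
  }
  # strict ordering per chromosome; scaffold first at ties, never moved
  out <- list()
  for (chr in sort(unique(cons$chr))) {
    cc <- cons[cons$chr == chr, , drop = FALSE]
    cc <- cc[order(cc$pos_cm, cc$source != "scaffold", cc$marker), ,
             drop = FALSE]
    cc$pos_cm <- resolve_ties(cc$pos_cm, movable = cc$source != "scaffold")
    out[[as.character(chr)]] <- cc
  }
  map <- do.call(rbind, out)
  rownames(map) <- NULL
  list(map = map,
       report = if (length(report)) do.call(rbind, report) else
         data.frame(map_id = character(0), chr = integer(0),
                    n_shared = integer(0), n_added = integer(0),
                    n_dropped = integer(0), note = character(0)),
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(map_id = character(0), marker = character(0),
                    chr = integer(0), reason = character(0)))
}

#' Per-chromosome statistics of a genetic map
#'
#' Chromosome length is taken as the maximum marker position; mean
#' inter-marker density is length/(markers - 1), undefined (NA) for a
#' single-marker chromosome.
#'
#' @param map data frame with `marker, chr, pos_cm`.
#' @return list with a `per_chromosome` table, `cumulative_length_cm` and
#'   `mean_density_cm` (mean of defined per-chromosome densities).
#' @export
map_statistics <- function(map) {
  if (nrow(map) == 0) stop("empty map")
  per <- do.call(rbind, lapply(split(map, map$chr), function(cc) {
    n <- nrow(cc)
    len <- max(cc$pos_cm)
    data.frame(chr = cc$chr[1], n_markers = n, length_cm = len,
               density_cm = if (n > 1) len / (n - 1) else NA_real_)
  }))
  rownames(per) <- NULL
  list(per_chromosome = per,
       cumulative_length_cm = sum(per$length_cm),
       mean_density_cm = mean(per$density_cm, na.rm = TRUE))
}
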