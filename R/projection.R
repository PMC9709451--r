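# Projection of QTL peaks and confidence intervals from source maps onto
# the consensus map, via flanking shared anchors.

REJECTION_CODES <- c("NO_SHARED_ANCHOR_LEFT", "NO_SHARED_ANCHOR_RIGHT",
                     "ANCHOR_ORDER_CONFLICT", "ZERO_INTERVAL",
                     "MISSING_PEAK")

#' Project one position through a flanking anchor pair
#'
#' Linear (homothetic) transfer of a source-map position into consensus
#' coordinates using two markers shared by both maps:
#' `cons = consL + (pos - srcL) * (consR - consL) / (srcR - srcL)`.
#'
#' @param pos_src position on the source map (cM), within the anchor span.
#' @param src_anchors numeric length-2: the anchors' source positions.
#' @param cons_anchors numeric length-2: the same anchors' consensus
#'   positions.
#' @return the consensus position (cM).
#' @export
project_position <- function(pos_src, src_anchors, cons_anchors) {
  srcL <- src_anchors[1]; srcR <- src_anchors[2]
  consL <- cons_anchors[1]; consR <- cons_anchors[2]
  if (srcR <= srcL) stop("source anchor interval must have positive length")
  if (consR < consL) stop("anchors inverted on consensus map")
  consL + (pos_src - srcL) * (consR - consL) / (srcR - srcL)
}

# Anchor table for one chromosome of one source map: markers present on
# both maps, with both coordinates, sorted by source position. Returns
# NULL on an order conflict.
shared_anchor_table <- function(source_chr, cons_chr) {
  shared <- intersect(source_chr$marker, cons_chr$marker)
  if (length(shared) == 0)
    return(data.frame(marker = character(0), src = numeric(0),
                      cons = numeric(0)))
  a <- data.frame(marker = shared,
                  src = source_chr$pos_cm[match(shared, source_chr$marker)],
                  cons = cons_chr$pos_cm[match(shared, cons_chr$marker)],
                  stringsAsFactors = FALSE)
  a <- a[order(a$src), , drop = FALSE]
  if (is.unsorted(a$cons, strictly = FALSE) && nrow(a) > 1) return(NULL)
  a
}

# Project a single point given the anchor table; returns the position or
# a rejection code string.
project_point <- function(p, anchors) {
  below <- which(anchors$src <= p)
  above <- which(anchors$src >= p)
  if (length(below) == 0) return("NO_SHARED_ANCHOR_LEFT")
  if (length(above) == 0) return("NO_SHARED_ANCHOR_RIGHT")
  iL <- max(below); iR <- min(above)
  if (iL == iR) return(anchors$cons[iL])
  if (anchors$src[iR] - anchors$src[iL] <= 0) return("ZERO_INTERVAL")
  project_position(p, c(anchors$src[iL], anchors$src[iR]),
                   c(anchors$cons[iL], anchors$cons[iR]))
}

#' Project one QTL (peak and CI endpoints) onto the consensus map
#'
#' The source CI is centred on the peak (peak +/- CI/2), clipped at the
#' source chromosome bounds, and peak and both endpoints are each
#' projected through their own nearest flanking shared anchors. A QTL
#' whose peak is missing is salvaged from its flanking markers when both
#' exist on the consensus map (midpoint, flag `PEAK_FROM_FLANKS`);
#' otherwise it is rejected. All failures return a rejection code rather
#' than an error.
#'
#' @param qtl one compendium row carrying `qtl_id, chr, peak_cm, trait,
#'   pve_pct, ci95_cm` (see [attach_ci()]) and flanking markers.
#' @param source_map the QTL's source map (`marker, chr, pos_cm`).
#' @param consensus consensus map data frame (`marker, chr, pos_cm`).
#' @return a list: either `list(projected = <one-row data frame>)` or
#'   `list(rejection = list(qtl_id, reason))`.
#' @export
project_qtl <- function(qtl, source_map, consensus) {
  reject <- function(reason)
    list(rejection = list(qtl_id = qtl$qtl_id, reason = reason))
  cons_chr <- consensus[consensus$chr == qtl$chr, , drop = FALSE]
  src_chr <- source_map[source_map$chr == qtl$chr, , drop = FALSE]

  if (is.na(qtl$peak_cm)) {
    fl <- c(qtl$flank_left, qtl$flank_right)
    pos <- cons_chr$pos_cm[match(fl, cons_chr$marker)]
    if (length(fl) < 2 || anyNA(fl) || anyNA(pos)) return(reject("MISSING_PEAK"))
    peak_cons <- mean(pos)
    ci <- qtl$ci95_cm
    out <- data.frame(qtl_id = qtl$qtl_id, chr = qtl$chr,
                      peak_cons_cm = peak_cons, ci95_cons_cm = ci,
                      sigma_cm = ci / CI95_Z_WIDTH, trait = qtl$trait,
                      pve_pct = qtl$pve_pct, flag = "PEAK_FROM_FLANKS",
                      stringsAsFactors = FALSE)
    return(list(projected = out))
  }
  if (nrow(src_chr) == 0) return(reject("NO_SHARED_ANCHOR_LEFT"))
  anchors <- shared_anchor_table(src_chr, cons_chr)
  if (is.null(anchors)) return(reject("ANCHOR_ORDER_CONFLICT"))

  half <- qtl$ci95_cm / 2
  left <- max(qtl$peak_cm - half, min(src_chr$pos_cm, 0))
  right <- min(qtl$peak_cm + half, max(src_chr$pos_cm))
  pts <- c(left = left, peak = qtl$peak_cm, right = right)
  proj <- numeric(3)
  for (j in seq_along(pts)) {
    res <- project_point(pts[[j]], anchors)
    if (is.character(res)) return(reject(res))
    proj[j] <- res
  }
  width <- proj[3] - proj[1]
  if (width <= 0) width <- .Machine$double.eps
  out <- data.frame(qtl_id = qtl$qtl_id, chr = qtl$chr,
                    peak_cons_cm = proj[2], ci95_cons_cm = width,
                    sigma_cm = width / CI95_Z_WIDTH, trait = qtl$trait,
                    pve_pct = qtl$pve_pct, flag = "",
                    stringsAsFactors = FALSE)
  list(projected = out)
}

#' Project a whole compendium onto the consensus map
#'
#' @param qtls compendium rows with CIs attached ([attach_ci()]) and a
#'   `map_id` column naming each QTL's source map.
#' @param maps data frame of all source maps (`map_id, marker, chr,
#'   pos_cm`).
#' @param consensus consensus map data frame.
#' @return list with `projected` (data frame of projected QTLs),
#'   `rejections` (data frame `qtl_id, reason`) and `report`
#'   (see [projection_report()]).
#' @export
project_qtls <- function(qtls, maps, consensus) {
  known_maps <- unique(maps$map_id)
  unknown <- setdiff(unique(qtls$map_id), known_maps)
  if (length(unknown) > 0)
    stop("QTLs reference unregistered source maps: ",
         paste(unknown, collapse = ", "))
  projected <- list(); rejections <- list()
  map_split <- split(maps, maps$map_id)
  for (i in seq_len(nrow(qtls))) {
    res <- project_qtl(qtls[i, ], map_split[[qtls$map_id[i]]], consensus)
    if (!is.null(res$projected)) {
      projected[[length(projected) + 1]] <- res$projected
    } else {
      rejections[[length(rejections) + 1]] <-
        data.frame(qtl_id = res$rejection$qtl_id,
                   reason = res$rejection$reason, stringsAsFactors = FALSE)
    }
  }
  projected <- if (length(projected)) do.call(rbind, projected) else
    data.frame(qtl_id = character(0), chr = integer(0),
               peak_cons_cm = numeric(0), ci95_cons_cm = numeric(0),
               sigma_cm = numeric(0), trait = character(0),
               pve_pct = numeric(0), flag = character(0))
  rejections <- if (length(rejections)) do.call(rbind, rejections) else
    data.frame(qtl_id = character(0), reason = character(0))
  rownames(projected) <- rownames(rejections) <- NULL
  list(projected = projected, rejections = rejections,
       report = projection_report(nrow(qtls), projected, rejections))
}

#' Summarise a projection run
#'
#' @param n_input number of QTLs attempted.
#' @param projected data frame of projected QTLs.
#' @param rejections data frame with a `reason` column.
#' @return list with conserved counts and a histogram of reasons.
#' @export
projection_report <- function(n_input, projected, rejections) {
  stopifnot(n_input == nrow(projected) + nrow(rejections))
  reasons <- table(factor(rejections$reason, levels = REJECTION_CODES))
  list(n_input = n_input,
       n_projected = nrow(projected),
       n_rejected = nrow(rejections),
       reasons = stats::setNames(as.integer(reasons), REJECTION_CODES))
}
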