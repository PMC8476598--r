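# Connected-component machinery for the digital-biomarker filter.
# Components use 8-connectivity; component size is measured as equivalent
# circular diameter (2 * sqrt(area/pi) * resolution), the rotation-invariant
# reading of a "contiguous focus at least 200 um in size".

#' Label connected components of a binary mask
#'
#' Components are computed over the pixel adjacency graph (igraph); 8- or
#' 4-connectivity.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix: 0 for background, 1..k component labels.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)                       # column-major pixel indices
  if (!length(idx)) return(matrix(0L, h, w))
  id_map <- integer(h * w)
  id_map[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- vector("list", length(shifts))
  for (k in seq_along(shifts)) {
    s <- shifts[[k]]
    r2 <- r + s[1]; c2 <- cc + s[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nidx <- (c2[ok] - 1L) * h + r2[ok]
    both <- id_map[nidx] > 0L
    edges[[k]] <- rbind(id_map[idx[ok][both]], id_map[nidx[both]])
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(em)) g <- igraph::add_edges(g, as.vector(em))
  memb <- igraph::components(g)$membership
  out <- matrix(0L, h, w)
  out[idx] <- as.integer(memb)
  out
}

#' Remove components below a physical size
#'
#' Drops every connected component whose equivalent circular diameter is
#' smaller than `min_focus_um`.
#'
#' @param mask Logical matrix.
#' @param min_focus_um Minimum focus size, micrometres.
#' @param resolution_um_per_px Resolution of the mask's slide.
#' @param connectivity 8 (default) or 4.
#' @return Logical matrix.
#' @export
filter_min_focus <- function(mask, min_focus_um, resolution_um_per_px,
                             connectivity = 8) {
  stopifnot(min_focus_um > 0)
  lab <- label_components(mask, connectivity)
  if (!any(lab > 0L)) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  keep <- equivalent_diameter_um(sizes, resolution_um_per_px) >= min_focus_um
  out <- lab > 0L
  out[lab > 0L] <- keep[lab[lab > 0L]]
  out
}

#' Filter a confidence map into digital-biomarker masks
#'
#' A digital biomarker is a tumor region associated with one outcome group
#' at high confidence: per class, pixels with confidence at or above the
#' threshold are kept, then contiguous foci smaller than `min_focus_um`
#' (equivalent circular diameter, 8-connectivity) are removed. The two
#' class masks are disjoint by construction (threshold > 0.5). Idempotent:
#' re-filtering its own output changes nothing.
#'
#' @param conf A `confidence_map`.
#' @param threshold Confidence threshold in `(0.5, 1]` (default 0.9).
#' @param min_focus_um Minimum focus size in micrometres (default 200).
#' @return An object of class `dbm_masks`: `class_mask`es `dbm_short` and
#'   `dbm_long` plus a `provenance` record (threshold, minimum focus).
#' @export
filter_high_confidence <- function(conf, threshold = 0.9,
                                   min_focus_um = 200) {
  stopifnot(inherits(conf, "confidence_map"),
            threshold > 0.5, threshold <= 1, min_focus_um > 0)
  res <- conf$resolution_um_per_px
  mk <- function(cm, cls) {
    raw <- !is.na(cm) & cm >= threshold
    class_mask(conf$slide_id, cls,
               filter_min_focus(raw, min_focus_um, res))
  }
  structure(
    list(dbm_short = mk(conf$conf_short, "dbm_short"),
         dbm_long = mk(conf$conf_long, "dbm_long"),
         provenance = list(threshold = threshold,
                           min_focus_um = min_focus_um,
                           resolution_um_per_px = res)),
    class = "dbm_masks"
  )
}

#' Curate biomarker masks against exclusion classes
#'
#' Emulates the pathologist's review: necrosis, stroma, artifact and blur
#' regions are removed from the biomarker masks, and because subtraction can
#' fragment a focus, the minimum-focus filter is re-applied.
#'
#' @param dbm A `dbm_masks` object.
#' @param exclusions List of logical matrices / `class_mask`es to subtract
#'   (any subset of necrosis, stroma, artifact, blur).
#' @return A curated `dbm_masks` object.
#' @export
curate_annotations <- function(dbm, exclusions) {
  stopifnot(inherits(dbm, "dbm_masks"))
  prov <- dbm$provenance
  excl <- NULL
  for (e in exclusions) {
    m <- as_mask_matrix(e)
    check_congruent(m, dbm$dbm_short$mask)
    excl <- if (is.null(excl)) m else excl | m
  }
  cur <- function(cm) {
    m <- cm$mask
    if (!is.null(excl)) m <- m & !excl
    cm$mask <- filter_min_focus(m, prov$min_focus_um,
                                prov$resolution_um_per_px)
    cm
  }
  dbm$dbm_short <- cur(dbm$dbm_short)
  dbm$dbm_long <- cur(dbm$dbm_long)
  dbm$provenance$curated <- TRUE
  dbm
}
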