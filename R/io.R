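# Raster and table I/O. Rasters are PNG or TIFF with a JSON sidecar holding
# the physical resolution and identity; a raster without its sidecar is an
# error, never a silent default. Round trips are bit-exact for masks and
# 8-bit RGB rasters.

sidecar_path <- function(path) paste0(sub("\\.(png|tif|tiff)$", "", path), ".json")

raster_format <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) "png"
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
  else stop("unsupported raster format for '", path, "' (use .png or .tif)")
}

#' Write a slide image to disk
#'
#' Pixels are quantised to 8 bits; the resolution and identity go to a JSON
#' sidecar next to the raster.
#'
#' @param slide A `slide_image`.
#' @param path Output path ending in `.png` or `.tif`.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path) {
  fmt <- raster_format(path)
  px <- round(slide$pixels * 255) / 255
  if (fmt == "png") png::writePNG(px, path) else tiff::writeTIFF(px, path)
  jsonlite::write_json(
    list(slide_id = slide$slide_id, patient_id = slide$patient_id,
         resolution_um_per_px = slide$resolution_um_per_px),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a slide image written by [write_slide()]
#'
#' @param path Raster path; the JSON sidecar must exist alongside it.
#' @return A `slide_image`.
#' @export
read_slide <- function(path) {
  fmt <- raster_format(path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop("missing resolution sidecar '", sc, "' for raster '", path, "'")
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$resolution_um_per_px)) {
    stop("sidecar '", sc, "' lacks resolution_um_per_px")
  }
  px <- if (fmt == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  slide_image(meta$slide_id, meta$patient_id, px,
              as.numeric(meta$resolution_um_per_px))
}

#' Write a binary class mask as a PNG
#' @param mask A `class_mask`.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "class_mask"))
  png::writePNG(mask$mask * 1, path)
  jsonlite::write_json(
    list(slide_id = mask$slide_id, class_name = mask$class_name),
    sidecar_path(path), auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a binary class mask written by [write_mask()]
#' @param path Mask `.png` path (JSON sidecar required).
#' @return A `class_mask`.
#' @export
read_mask <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing sidecar '", sc, "' for mask '", path, "'")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  class_mask(meta$slide_id, meta$class_name, m >= 0.5)
}

#' Export a biomarker-mask overlay for visual review
#'
#' Writes the slide raster with the candidate digital-biomarker masks
#' tinted (short-associated in red, long-associated in blue) plus a JSON
#' provenance sidecar — the review surface for a human curator inspecting
#' what the confidence filter proposed.
#'
#' @param slide A `slide_image`.
#' @param dbm A `dbm_masks` object for that slide.
#' @param path Output `.png` path.
#' @param alpha Tint strength in `[0, 1]`.
#' @return `path`, invisibly.
#' @export
write_dbm_overlay <- function(slide, dbm, path, alpha = 0.45) {
  stopifnot(inherits(dbm, "dbm_masks"))
  check_congruent(dbm$dbm_short$mask, slide$pixels[, , 1])
  px <- slide$pixels
  tint <- function(px, mask, rgb) {
    for (ch in 1:3) {
      m <- px[, , ch]
      m[mask] <- (1 - alpha) * m[mask] + alpha * rgb[ch]
      px[, , ch] <- m
    }
    px
  }
  px <- tint(px, dbm$dbm_short$mask, c(0.9, 0.1, 0.1))
  px <- tint(px, dbm$dbm_long$mask, c(0.1, 0.2, 0.9))
  png::writePNG(px, path)
  jsonlite::write_json(
    c(list(slide_id = slide$slide_id), dbm$provenance),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a cohort metadata table
#'
#' Expected columns: `patient_id`, `slide_id`, `group` (PFI_S or PFI_L) and
#' optionally `pfi_months`. Unknown group labels are an error naming the
#' offending row.
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "slide_id", "group")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!df$group %in% c("PFI_S", "PFI_L"))
  if (length(bad)) {
    stop("unknown outcome label '", df$group[bad[1]], "' in row ", bad[1],
         " (slide ", df$slide_id[bad[1]], ")")
  }
  if (anyDuplicated(df$slide_id)) {
    stop("duplicate slide_id in cohort table: ",
         df$slide_id[anyDuplicated(df$slide_id)][1])
  }
  df
}

#' Write a cohort metadata table
#' @param df Data frame with `patient_id`, `slide_id`, `group` columns.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write per-slide scores (Table-3-shaped)
#'
#' Columns mirror the printed results table: `slide_id`, `long_dbm_pct`,
#' `short_dbm_pct`, `ratio`, `outcome`, `prediction`.
#'
#' @param scores Data frame of slide scores.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  cols <- c("slide_id", "long_dbm_pct", "short_dbm_pct", "ratio",
            "outcome", "prediction")
  extra <- setdiff(names(scores), cols)
  utils::write.csv(scores[, c(cols, extra)], path, row.names = FALSE)
  invisible(path)
}

#' Read a per-slide score table written by [write_scores()]
#' @param path CSV path.
#' @return A data frame.
#' @export
read_scores <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
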