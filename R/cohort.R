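# Synthetic cohort generator.
#
# Emulates the structure of the motivating study: two patient groups at the
# extremes of platinum response (17 PFI-S and 13 PFI-L patients by default,
# 2-13 slides per patient), heterogeneous intra-tumor texture mixtures whose
# composition is biased by outcome group, and excludable artifact classes
# (necrosis, folds, blur, whitespace). Every slide carries full per-pixel
# ground truth, which is the oracle the real study lacks. Generation is a
# pure function of (spec, seed): each slide draws from its own RNG stream
# keyed by (seed, slide_id), so output is independent of generation order.

#' Specification of a synthetic cohort
#'
#' @param n_short_patients,n_long_patients Patients per outcome group
#'   (defaults mirror the study cohort: 17 PFI-S, 13 PFI-L).
#' @param slides_per_patient `(min, max)` slides per patient (default 2-13).
#' @param slide_size_px `(height, width)` of each slide in pixels.
#' @param resolution_um_per_px Physical resolution; the 2.0 um/px default
#'   makes a 200 um field of view exactly 100 px and 500 um exactly 250 px.
#' @param mixture_bias In `[0, 1]`: excess fraction of the outcome-concordant
#'   texture in each group's tumors. A PFI-S tumor contains on average
#'   `(1 + bias) / 2` short_like texture; PFI-L symmetrically. Bias 0 makes
#'   the groups statistically indistinguishable.
#' @param texture_contrast In `[0, 1]`: separation of the short_like and
#'   long_like textures (0 = identical distributions).
#' @param mixture_kappa Beta concentration of the per-slide texture fraction
#'   around its group mean (intra-tumor heterogeneity control).
#' @param neutral_frac Fraction of tumor rendered as outcome-neutral texture.
#' @param artifact_rates Named list of per-slide occurrence probabilities for
#'   `necrosis`, `whitespace`, `blur`, `fold`, each in `[0, 1]`.
#' @param necrosis_margin Luminance margin of necrosis over tumor textures.
#' @param tumor_cover `(min, max)` fraction of the slide covered by tumor.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_short_patients = 17,
                        n_long_patients = 13,
                        slides_per_patient = c(2, 13),
                        slide_size_px = c(384, 384),
                        resolution_um_per_px = 2.0,
                        mixture_bias = 0.6,
                        texture_contrast = 1.0,
                        mixture_kappa = 8,
                        neutral_frac = 0,
                        artifact_rates = list(necrosis = 0.3, whitespace = 0.1,
                                              blur = 0.1, fold = 0.15),
                        necrosis_margin = 0.15,
                        tumor_cover = c(0.2, 0.7)) {
  if (n_short_patients < 1 || n_long_patients < 1) {
    stop("degenerate spec: both outcome groups need at least one patient")
  }
  stopifnot(length(slides_per_patient) == 2, slides_per_patient[1] >= 1,
            slides_per_patient[2] >= slides_per_patient[1],
            resolution_um_per_px > 0,
            mixture_bias >= 0, mixture_bias <= 1,
            texture_contrast >= 0, texture_contrast <= 1,
            neutral_frac >= 0, neutral_frac < 1,
            tumor_cover[1] > 0, tumor_cover[2] <= 1)
  rates <- unlist(artifact_rates)
  if (any(rates < 0 | rates > 1)) stop("artifact rates must lie in [0, 1]")
  structure(
    list(n_short_patients = as.integer(n_short_patients),
         n_long_patients = as.integer(n_long_patients),
         slides_per_patient = as.integer(slides_per_patient),
         slide_size_px = as.integer(slide_size_px),
         resolution_um_per_px = resolution_um_per_px,
         mixture_bias = mixture_bias,
         texture_contrast = texture_contrast,
         mixture_kappa = mixture_kappa,
         neutral_frac = neutral_frac,
         artifact_rates = as.list(rates),
         necrosis_margin = necrosis_margin,
         tumor_cover = tumor_cover),
    class = "cohort_spec"
  )
}

group_short_mean <- function(spec, group) {
  m <- if (group == "PFI_S") (1 + spec$mixture_bias) / 2
       else (1 - spec$mixture_bias) / 2
  min(max(m, 0.02), 0.98)
}

#' Generate a synthetic cohort
#'
#' Draws patients, slides, pixels and ground-truth masks according to a
#' [cohort_spec()]. Deterministic given `(spec, seed)`.
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer seed.
#' @return An object of class `cohort`: a list with `slides` (named list of
#'   `slide_image`), `truth` (named list of per-slide ground truth: logical
#'   masks `tumor`, `short_like`, `long_like`, `neutral`, `necrosis`,
#'   `artifact`, `background` and the drawn `short_frac`), `metadata`
#'   (data frame `patient_id`, `slide_id`, `group`, `pfi_months`) and `spec`.
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c(rep("PFI_S", spec$n_short_patients),
              rep("PFI_L", spec$n_long_patients))
  pids <- c(sprintf("PS%02d", seq_len(spec$n_short_patients)),
            sprintf("PL%02d", seq_len(spec$n_long_patients)))
  meta <- with_seed(seed, "patients", {
    rng <- seq(spec$slides_per_patient[1], spec$slides_per_patient[2])
    n_slides <- if (length(rng) == 1L) rep(rng, length(pids))
                else sample(rng, length(pids), replace = TRUE)
    pfi <- ifelse(groups == "PFI_S",
                  round(stats::runif(length(pids), 0, 6), 1),
                  round(stats::runif(length(pids), 18, 60), 1))
    do.call(rbind, lapply(seq_along(pids), function(i) {
      data.frame(patient_id = pids[i],
                 slide_id = sprintf("%s-s%02d", pids[i], seq_len(n_slides[i])),
                 group = groups[i], pfi_months = pfi[i],
                 stringsAsFactors = FALSE)
    }))
  })
  slides <- vector("list", nrow(meta))
  truth <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    g <- generate_slide(spec, seed, meta$slide_id[i], meta$patient_id[i],
                        meta$group[i])
    slides[[i]] <- g$slide
    truth[[i]] <- g$truth
  }
  names(slides) <- meta$slide_id
  names(truth) <- meta$slide_id
  structure(list(slides = slides, truth = truth, metadata = meta, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d slides from %d patients (%d PFI_S / %d PFI_L)\n",
              nrow(x$metadata), length(unique(x$metadata$patient_id)),
              sum(tapply(x$metadata$group, x$metadata$patient_id, unique) == "PFI_S"),
              sum(tapply(x$metadata$group, x$metadata$patient_id, unique) == "PFI_L")))
  invisible(x)
}

generate_slide <- function(spec, seed, slide_id, patient_id, group) {
  h <- spec$slide_size_px[1]; w <- spec$slide_size_px[2]
  with_seed(seed, paste0("slide:", slide_id), {
    # tumor layout: smooth blobs covering a drawn fraction of the slide
    cover <- stats::runif(1, spec$tumor_cover[1], spec$tumor_cover[2])
    field <- smooth_noise(h, w, scale = h / 3.5)
    tumor <- field >= stats::quantile(field, 1 - cover)

    # per-slide texture mixture, biased by outcome group
    m <- group_short_mean(spec, group)
    k <- spec$mixture_kappa
    short_frac <- stats::rbeta(1, m * k, (1 - m) * k)
    assign_field <- smooth_noise(h, w, scale = h / 3)
    thr <- stats::quantile(assign_field[tumor], 1 - short_frac)
    short_mask <- tumor & (assign_field >= thr)
    long_mask <- tumor & !short_mask
    neutral_mask <- matrix(FALSE, h, w)
    if (spec$neutral_frac > 0) {
      nf <- smooth_noise(h, w, scale = h / 3)
      nthr <- stats::quantile(nf[tumor], 1 - spec$neutral_frac)
      neutral_mask <- tumor & (nf >= nthr)
      short_mask <- short_mask & !neutral_mask
      long_mask <- long_mask & !neutral_mask
    }

    ct <- spec$texture_contrast
    px <- render_textures(h, w, "background", ct, spec$necrosis_margin)
    px <- paint(px, short_mask,
                render_textures(h, w, "short_like", ct, spec$necrosis_margin))
    px <- paint(px, long_mask,
                render_textures(h, w, "long_like", ct, spec$necrosis_margin))
    if (any(neutral_mask)) {
      px <- paint(px, neutral_mask,
                  render_textures(h, w, "neutral", ct, spec$necrosis_margin))
    }

    art <- inject_artifacts_impl(px, spec)
    px <- art$pixels
    removed <- art$necrosis | art$artifact | art$whitespace
    tumor <- tumor & !removed
    short_mask <- short_mask & !removed
    long_mask <- long_mask & !removed
    neutral_mask <- neutral_mask & !removed

    slide <- slide_image(slide_id, patient_id, px, spec$resolution_um_per_px)
    truth <- list(
      tumor = tumor, short_like = short_mask, long_like = long_mask,
      neutral = neutral_mask, necrosis = art$necrosis,
      artifact = art$artifact,
      background = !(tumor | art$necrosis | art$artifact),
      short_frac = short_frac
    )
    list(slide = slide, truth = truth)
  })
}

paint <- function(px, mask, layer) {
  idx <- which(mask)
  if (!length(idx)) return(px)
  n <- length(mask)
  all_idx <- c(idx, idx + n, idx + 2L * n)
  px[all_idx] <- layer[all_idx]
  px
}

# Artifact injection: necrosis blob (quantile of smooth noise, exact area
# fraction), whitespace and blur discs (fully inside the frame), and a
# horizontal or vertical fold band. Later artifacts overwrite earlier ones.
# Uses the current RNG stream.
inject_artifacts_impl <- function(px, spec) {
  h <- dim(px)[1]; w <- dim(px)[2]
  rates <- spec$artifact_rates
  necrosis <- matrix(FALSE, h, w)
  whitespace <- matrix(FALSE, h, w)
  artifact <- matrix(FALSE, h, w)

  if (stats::runif(1) < rates$necrosis) {
    q <- stats::runif(1, 0.03, 0.08)
    nf <- smooth_noise(h, w, scale = h / 5)
    necrosis <- nf >= stats::quantile(nf, 1 - q)
    px <- paint(px, necrosis,
                render_textures(h, w, "necrosis", spec$texture_contrast,
                                spec$necrosis_margin))
  }
  if (stats::runif(1) < rates$whitespace) {
    d <- disc_mask(h, w, r_range = c(15, 30))
    whitespace <- d
    necrosis <- necrosis & !d
    px <- paint(px, d,
                render_textures(h, w, "background", spec$texture_contrast,
                                spec$necrosis_margin))
  }
  if (stats::runif(1) < rates$blur) {
    d <- disc_mask(h, w, r_range = c(20, 40))
    artifact <- artifact | d
    necrosis <- necrosis & !d
    whitespace <- whitespace & !d
    px <- blur_region(px, d, radius = 4L)
  }
  if (stats::runif(1) < rates$fold) {
    wd <- stats::runif(1, 6, 14)
    band <- band_mask(h, w, wd)
    artifact <- artifact | band
    necrosis <- necrosis & !band
    whitespace <- whitespace & !band
    px <- paint(px, band,
                render_textures(h, w, "fold", spec$texture_contrast,
                                spec$necrosis_margin))
  }
  list(pixels = px, necrosis = necrosis, artifact = artifact,
       whitespace = whitespace)
}

#' Inject artifacts into a slide
#'
#' Applies the spec's artifact model (necrosis blob, whitespace disc, blur
#' disc, fold band; later artifacts overwrite earlier ones) to an existing
#' slide, using the stream derived from `(seed, slide_id, "artifacts")`.
#' Primarily exercised through [generate_cohort()], which records the
#' resulting masks in the ground truth.
#'
#' @param slide A `slide_image`.
#' @param spec A `cohort_spec` carrying `artifact_rates`.
#' @param seed Integer seed.
#' @return List with the modified `slide` and logical masks `necrosis`,
#'   `artifact`, `whitespace`.
#' @export
inject_artifacts <- function(slide, spec, seed) {
  out <- with_seed(seed, paste0("artifacts:", slide$slide_id),
                   inject_artifacts_impl(slide$pixels, spec))
  slide$pixels <- out$pixels
  list(slide = slide, necrosis = out$necrosis, artifact = out$artifact,
       whitespace = out$whitespace)
}

# Expected per-slide area fraction contributed by each artifact class,
# ignoring (rare) overlap between artifact types; used by the Monte-Carlo
# calibration check.
artifact_expected_fractions <- function(spec) {
  h <- spec$slide_size_px[1]; w <- spec$slide_size_px[2]
  r <- spec$artifact_rates
  e_disc <- function(a, b) pi * (a^2 + a * b + b^2) / 3 / (h * w)
  list(
    necrosis = r$necrosis * 0.055,                       # q ~ U(0.03, 0.08)
    whitespace = r$whitespace * e_disc(15, 30),
    blur = r$blur * e_disc(20, 40),
    fold = r$fold * 10 * (1 / h + 1 / w) / 2             # width ~ U(6, 14)
  )
}

disc_mask <- function(h, w, r_range) {
  r <- stats::runif(1, r_range[1], r_range[2])
  cy <- stats::runif(1, r, h - r)
  cx <- stats::runif(1, r, w - r)
  dy <- (seq_len(h) - cy)^2
  dx <- (seq_len(w) - cx)^2
  outer(dy, dx, "+") <= r^2
}

band_mask <- function(h, w, width) {
  horizontal <- stats::runif(1) < 0.5
  if (horizontal) {
    c0 <- stats::runif(1, width, h - width)
    m <- abs(seq_len(h) - c0) <= width / 2
    matrix(m, h, w)
  } else {
    c0 <- stats::runif(1, width, w - width)
    m <- abs(seq_len(w) - c0) <= width / 2
    matrix(m, h, w, byrow = TRUE)
  }
}

blur_region <- function(px, mask, radius = 4L) {
  h <- dim(px)[1]; w <- dim(px)[2]
  for (ch in 1:3) {
    m <- px[, , ch]
    ii <- integral_image(m)
    r1 <- pmax(1L, row(m) - radius); r2 <- pmin(h, row(m) + radius)
    c1 <- pmax(1L, col(m) - radius); c2 <- pmin(w, col(m) + radius)
    sm <- window_sum(ii, as.vector(r1), as.vector(r2),
                     as.vector(c1), as.vector(c2)) /
      ((r2 - r1 + 1) * (c2 - c1 + 1))
    m[mask] <- matrix(sm, h, w)[mask]
    px[, , ch] <- m
  }
  px
}

#' Write a cohort to disk in the package's raster/table formats
#'
#' Slides as PNG + JSON sidecars, ground-truth masks under `ground_truth/`,
#' the metadata table as `cohort.csv` and true mixture fractions as
#' `truth.csv`.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "ground_truth"), recursive = TRUE,
             showWarnings = FALSE)
  for (sid in names(cohort$slides)) {
    write_slide(cohort$slides[[sid]], file.path(dir, paste0(sid, ".png")))
    tr <- cohort$truth[[sid]]
    for (cls in c("tumor", "short_like", "long_like", "necrosis",
                  "artifact", "background")) {
      write_mask(class_mask(sid, cls, tr[[cls]]),
                 file.path(dir, "ground_truth", paste0(sid, "_", cls, ".png")))
    }
  }
  write_cohort_table(cohort$metadata, file.path(dir, "cohort.csv"))
  utils::write.csv(
    data.frame(slide_id = names(cohort$truth),
               short_frac = vapply(cohort$truth, `[[`, numeric(1),
                                   "short_frac"),
               row.names = NULL),
    file.path(dir, "truth.csv"), row.names = FALSE
  )
  invisible(dir)
}
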