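# Procedural texture palette for synthetic slides.
#
# Textures are band-limited value noise: a coarse Gaussian grid bilinearly
# upsampled to pixel resolution, with a class-specific correlation length
# (spatial frequency) and RGB profile, plus fine per-pixel noise. The
# outcome-associated classes are separated along two axes — spatial
# frequency (short_like is fine-grained, long_like coarse/solid) and hue
# (short_like shifts pink/eosinophilic, long_like purple/basophilic) — with
# the separation scaled by a single `contrast` parameter. At contrast 0 the
# short_like and long_like parameters collapse onto the neutral texture, so
# the two classes are drawn from the same distribution by construction.

# Smooth value noise with correlation length `scale` px; uses the current
# RNG stream. Approximately zero mean, unit sd.
smooth_noise <- function(h, w, scale) {
  scale <- max(1, scale)
  gh <- ceiling(h / scale) + 2L
  gw <- ceiling(w / scale) + 2L
  g <- matrix(stats::rnorm(gh * gw), gh, gw)
  ry <- (seq_len(h) - 1) / scale + 1
  rx <- (seq_len(w) - 1) / scale + 1
  y0 <- pmin(floor(ry), gh - 1L); x0 <- pmin(floor(rx), gw - 1L)
  fy <- ry - y0; fx <- rx - x0
  # separable bilinear interpolation: rows first, then columns
  m <- g[y0, , drop = FALSE] * (1 - fy) + g[y0 + 1L, , drop = FALSE] * fy
  v <- t(t(m[, x0, drop = FALSE]) * (1 - fx) +
           t(m[, x0 + 1L, drop = FALSE]) * fx)
  # bilinear interpolation shrinks the variance; restore unit scale
  v / sqrt(mean(c(1, 4 / 9, 1 / 4)))
}

texture_palette <- function() {
  c("neutral", "short_like", "long_like", "papillary_like", "solid_like",
    "necrosis", "background", "fold")
}

# Parameters of each texture at a given contrast. Tumor textures share the
# neutral amplitude so contrast 0 makes them literally identical in law.
texture_params <- function(name, contrast = 1, necrosis_margin = 0.15) {
  base_mean <- c(0.78, 0.52, 0.68)   # H&E-ish pink-purple
  base_amp <- 0.08
  base_scale <- 8
  p <- switch(name,
    neutral = list(scale = base_scale, mean = base_mean, amp = base_amp),
    short_like = list(scale = base_scale - 5 * contrast,
                      mean = base_mean + contrast * c(0.06, -0.05, -0.03),
                      amp = base_amp),
    long_like = list(scale = base_scale + 8 * contrast,
                     mean = base_mean + contrast * c(-0.06, -0.03, 0.05),
                     amp = base_amp),
    papillary_like = list(scale = base_scale - 4 * contrast,
                          mean = base_mean + contrast * c(0.04, -0.02, -0.04),
                          amp = base_amp),
    solid_like = list(scale = base_scale + 6 * contrast,
                      mean = base_mean + contrast * c(-0.04, -0.04, 0.02),
                      amp = base_amp),
    necrosis = {
      # luminance = max tumor luminance + margin, by construction
      tum_lum <- max(vapply(c("neutral", "short_like", "long_like"),
                            function(nm) mean(texture_params(nm, contrast)$mean),
                            numeric(1)))
      lum <- tum_lum + necrosis_margin
      list(scale = 20, mean = c(lum + 0.11, lum + 0.01, lum - 0.12),
           amp = 0.03)
    },
    background = list(scale = 16, mean = c(0.96, 0.96, 0.97), amp = 0.01),
    fold = list(scale = 6, mean = c(0.38, 0.28, 0.46), amp = 0.05),
    stop("unknown texture '", name, "'")
  )
  p$scale <- max(1.5, p$scale)
  p
}

#' Render a texture patch
#'
#' Draws an `h x w` RGB raster of one named texture from the procedural
#' palette, using the current RNG stream. Textures are stationary within a
#' region; `contrast` controls how far the outcome-associated textures
#' (`short_like`, `long_like`) sit from the shared neutral profile, with
#' contrast 0 collapsing them onto the same distribution.
#'
#' @param h,w Raster dimensions in pixels.
#' @param name Texture name; see `texture_palette()` in the sources for the
#'   full set (`neutral`, `short_like`, `long_like`, `papillary_like`,
#'   `solid_like`, `necrosis`, `background`, `fold`).
#' @param contrast Class-separation scale in `[0, 1]`.
#' @param necrosis_margin Luminance margin of necrosis over the brightest
#'   tumor texture.
#' @return `h x w x 3` numeric array in `[0, 1]`.
#' @export
render_textures <- function(h, w, name, contrast = 1, necrosis_margin = 0.15) {
  p <- texture_params(name, contrast, necrosis_margin)
  # one spatial field shared across channels (channels co-vary, as staining
  # intensity does), plus shared fine-grain pixel noise
  field <- p$amp * smooth_noise(h, w, p$scale) +
    stats::rnorm(h * w, sd = 0.015)
  out <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) out[, , ch] <- p$mean[ch] + field
  pmin(pmax(out, 0.01), 0.99)
}
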