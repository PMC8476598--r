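# Shared small trained pipeline, built once per test run.

.wsidbm_test_cache <- new.env(parent = emptyenv())

mini_spec <- function(...) {
  cohort_spec(n_short_patients = 3, n_long_patients = 3,
              slides_per_patient = c(2, 2), slide_size_px = c(320, 320),
              ...)
}

mini_config <- function() {
  pipeline_config(stage2 = stage2_config(stride_px = 64L))
}

mini_cohort <- function() {
  if (is.null(.wsidbm_test_cache$cohort)) {
    .wsidbm_test_cache$cohort <- generate_cohort(mini_spec(), seed = 11)
  }
  .wsidbm_test_cache$cohort
}

mini_pipeline <- function() {
  if (is.null(.wsidbm_test_cache$pipe)) {
    .wsidbm_test_cache$pipe <- train_pipeline(mini_cohort(),
                                              config = mini_config(),
                                              seed = 7)
  }
  .wsidbm_test_cache$pipe
}

# A slide that is pure background (no tumor planted).
background_slide <- function(seed = 5, h = 256, w = 256) {
  px <- wsidbm:::with_seed(seed, "bg_slide",
                           render_textures(h, w, "background"))
  slide_image("BG01-s01", "BG01", px, 2.0)
}
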