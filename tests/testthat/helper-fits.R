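## trained fixtures shared across test files; each is built once per run
.fit_cache <- new.env(parent = emptyenv())

cached_fit <- function(variant, seed = 101L) {
  key <- paste(variant, seed, sep = "_")
  if (is.null(.fit_cache[[key]])) {
    cfg <- pps_config(variant, scale = "reduced", seed = seed,
                      snapshot_epochs = 1L)
    .fit_cache[[key]] <- pps_train(cfg, quiet = TRUE)
  }
  .fit_cache[[key]]
}

## hand-vision fixture: slimmer than the reduced preset because the extra
## visual population doubles the lower layer; the RHI checks it supports
## are qualitative
cached_fit_handvision <- function(seed = 101L) {
  key <- paste("handvision_small", seed, sep = "_")
  if (is.null(.fit_cache[[key]])) {
    cfg <- pps_config("handvision", scale = "reduced", seed = seed,
                      visual_grid = c(30L, 30L), n_multi = 300L,
                      epochs = 12L)
    .fit_cache[[key]] <- pps_train(cfg, quiet = TRUE)
  }
  .fit_cache[[key]]
}
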