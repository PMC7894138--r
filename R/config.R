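.default_config <- function() {
  list(
    variant = "constrained",
    scale = "full",
    epochs = 100L,
    batches_per_epoch = 400L,
    batch_size = 100L,
    eta = 0.005,
    n_multi = 500L,
    visual_grid = c(50L, 50L),
    n_tactile = 30L,
    seed = 1L,
    snapshot_epochs = integer(0),
    use_mean_m = FALSE,
    p_touch = 0.05,
    test_gain = 10
  )
}

## reduced preset: same learning recipe, fewer and coarser units and far
## fewer batches, sized so a constrained run completes in a few minutes on
## one CPU. The 40x40 visual grid keeps the visual code fine enough for
## the multisensory layer to split into the full model's excitatory /
## inhibitory proportions; coarser grids bias the split.
.reduced_overrides <- list(
  epochs = 6L,
  batches_per_epoch = 100L,
  visual_grid = c(40L, 40L),
  n_multi = 500L
)

#' Build and validate a run configuration
#'
#' Defaults are the full-scale recipe: learning rate 0.005, 100 epochs of
#' 400 batches of 100 samples, 500 multisensory units, 50x50 visual grid.
#' `scale = "reduced"` swaps in a named fast preset (smaller visual grid
#' and multisensory layer, fewer batches) without touching any other
#' default; all settings remain individually overridable.
#'
#' @param variant training-statistics variant, see [pps_populations()].
#' @param scale `"full"` or `"reduced"`.
#' @param ... named overrides of individual fields.
#' @return A validated list of class `pps_config`.
#' @examples
#' cfg <- pps_config("constrained", scale = "reduced", seed = 7)
#' @export
pps_config <- function(variant = c("constrained", "unconstrained",
                                   "handvision", "joint", "gaze"),
                       scale = c("full", "reduced"), ...) {
  variant <- match.arg(variant)
  scale <- match.arg(scale)
  cfg <- .default_config()
  cfg$variant <- variant
  cfg$scale <- scale
  if (scale == "reduced") cfg[names(.reduced_overrides)] <- .reduced_overrides
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  .validate_config(cfg)
}

.validate_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$eta > 0, "eta must be positive")
  for (f in c("epochs", "batches_per_epoch", "batch_size", "n_multi",
              "n_tactile")) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] >= 1,
        sprintf("%s must be a positive count", f))
  }
  chk(length(cfg$visual_grid) == 2 && all(cfg$visual_grid >= 2),
      "visual_grid must be two sizes >= 2")
  chk(cfg$p_touch >= 0 && cfg$p_touch <= 1, "p_touch must be in [0, 1]")
  chk(cfg$variant %in% c("constrained", "unconstrained", "handvision",
                         "joint", "gaze"), "unknown variant")
  if (length(problems)) abort(c("invalid configuration", problems))
  structure(cfg, class = "pps_config")
}

#' Read / write configurations as YAML
#'
#' Missing keys take the full-scale defaults, so an empty file yields the
#' default configuration; unknown keys are rejected with the offending
#' names.
#'
#' @param path YAML file path.
#' @param cfg a [pps_config()].
#' @return `pps_config_read()` returns a validated `pps_config`;
#'   `pps_config_write()` returns `path` invisibly.
#' @export
pps_config_read <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  variant <- raw$variant %||% "constrained"
  scale <- raw$scale %||% "full"
  raw$variant <- NULL; raw$scale <- NULL
  if (!is.null(raw$visual_grid)) raw$visual_grid <- as.integer(raw$visual_grid)
  if (!is.null(raw$snapshot_epochs)) raw$snapshot_epochs <- as.integer(raw$snapshot_epochs)
  do.call(pps_config, c(list(variant = variant, scale = scale), raw))
}

#' @rdname pps_config_read
#' @export
pps_config_write <- function(cfg, path) {
  stopifnot(inherits(cfg, "pps_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_hash <- function(cfg) {
  ## stable short fingerprint for provenance metadata
  s <- paste(names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","),
                                character(1)), sep = "=", collapse = ";")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9
}
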