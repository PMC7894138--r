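#' Save / load a fitted network as a plain-text checkpoint
#'
#' A checkpoint directory holds the weight matrix and biases as TSV
#' files, the configuration as YAML, and the metrics table as CSV, so
#' checkpoints are diffable and portable. Snapshots, when present, are
#' stored in `epoch_NNN/` subdirectories.
#'
#' @param fit a [pps_train()] result.
#' @param dir checkpoint directory (created if needed).
#' @return `pps_save()` returns `dir` invisibly; `pps_load()` returns a
#'   `pps_fit`.
#' @export
pps_save <- function(fit, dir) {
  stopifnot(inherits(fit, "pps_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_params <- function(params, d) {
    dir.create(d, showWarnings = FALSE)
    utils::write.table(params$W, file.path(d, "W.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    writeLines(format(params$b_u, digits = 17), file.path(d, "b_u.txt"))
    writeLines(format(params$b_m, digits = 17), file.path(d, "b_m.txt"))
  }
  .write_params(fit$params, dir)
  pps_config_write(fit$config, file.path(dir, "config.yaml"))
  if (!is.null(fit$metrics)) {
    write.csv(fit$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  }
  for (nm in names(fit$snapshots)) {
    .write_params(fit$snapshots[[nm]], file.path(dir, nm))
  }
  invisible(dir)
}

#' @rdname pps_save
#' @export
pps_load <- function(dir) {
  cfg <- pps_config_read(file.path(dir, "config.yaml"))
  pops <- pps_populations(cfg$variant, visual_grid = cfg$visual_grid,
                          n_tactile = cfg$n_tactile)
  .read_params <- function(d) {
    W <- as.matrix(utils::read.table(file.path(d, "W.tsv"), sep = "\t"))
    dimnames(W) <- NULL
    list(W = W,
         b_u = as.numeric(readLines(file.path(d, "b_u.txt"))),
         b_m = as.numeric(readLines(file.path(d, "b_m.txt"))))
  }
  params <- .read_params(dir)
  net <- pps_rbm(pops, n_multi = nrow(params$W))
  net$W <- params$W; net$b_u <- params$b_u; net$b_m <- params$b_m
  metrics_path <- file.path(dir, "metrics.csv")
  metrics <- if (file.exists(metrics_path)) {
    m <- as_tibble(read.csv(metrics_path))
    m$overlap_index <- as.numeric(m$overlap_index)
    m
  } else NULL
  snaps <- list()
  for (d in list.dirs(dir, recursive = FALSE)) {
    if (grepl("^epoch_\\d+$", basename(d))) snaps[[basename(d)]] <- .read_params(d)
  }
  .as_fit(net, pops, cfg, metrics = metrics,
          snapshots = if (length(snaps)) snaps else NULL)
}

#' Reproduce a figure-style analysis bundle
#'
#' Named recipes chain training and the matching analyses and write their
#' tables (CSV) and figures (PDF) to `out_dir`, returning a manifest of
#' every artifact with its checksum, the seed and the runtime. Recipes:
#' `rf` (receptive-field profile, strength distribution, RF shift),
#' `evoked` (evoked tactile maps and distance profile), `training`
#' (metrics across epochs), `illusions` (IHI, plus RHI on the hand-vision
#' variant), `deep3` (three-layer RF-peak/hand-position tuning).
#'
#' @param recipe one of `"rf"`, `"evoked"`, `"training"`, `"illusions"`,
#'   `"deep3"`.
#' @param out_dir output directory.
#' @param scale `"reduced"` (default) or `"full"`.
#' @param seed integer seed for the whole bundle.
#' @param quiet suppress training progress.
#' @param ... configuration overrides forwarded to [pps_config()] (e.g.
#'   a smaller grid for a quick look).
#' @return A tibble manifest: `file`, `md5`, `seed`, `elapsed_s`.
#' @export
pps_reproduce <- function(recipe = c("rf", "evoked", "training",
                                     "illusions", "deep3"),
                          out_dir, scale = "reduced", seed = 1,
                          quiet = TRUE, ...) {
  recipe <- match.arg(recipe)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  save_tbl <- function(x, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    write.csv(x, path, row.names = FALSE)
    path
  }
  save_fig <- function(p, name) {
    path <- file.path(out_dir, paste0(name, ".pdf"))
    ggplot2::ggsave(path, p, width = 6, height = 4)
    path
  }
  variant <- if (recipe == "illusions") "handvision" else "constrained"
  cfg <- pps_config(variant, scale = scale, seed = as.integer(seed), ...)
  files <- character(0)
  if (recipe == "deep3") {
    fit3 <- pps_train_stagewise(cfg, quiet = quiet)
    rf3 <- rf_peak_hand_correlation(fit3, seed = seed)
    files <- c(files, save_tbl(rf3, "deep3_rf_peak_correlation"))
  } else {
    fit <- pps_train(cfg, quiet = quiet)
    if (recipe == "rf") {
      prof <- rf_profile(fit)
      shift <- population_rf_shift(fit)
      files <- c(files,
                 save_tbl(prof, "rf_profile"),
                 save_tbl(shift, "rf_shift"),
                 save_fig(plot_tactile_strength(prof), "tactile_strength"),
                 save_fig(plot_vp_overlap(prof), "vp_overlap"))
    } else if (recipe == "evoked") {
      map <- evoked_tactile_map(fit, seed = seed)
      files <- c(files,
                 save_tbl(map, "evoked_map"),
                 save_tbl(evoked_distance_profile(map), "evoked_profile"),
                 save_fig(plot_evoked_map(map), "evoked_map"))
    } else if (recipe == "training") {
      files <- c(files,
                 save_tbl(fit$metrics, "training_metrics"),
                 save_fig(plot_training(fit), "training_metrics"))
    } else if (recipe == "illusions") {
      ihi <- drift_experiment(fit, "ihi")
      rhi <- drift_experiment(fit, "rhi")
      files <- c(files,
                 save_tbl(ihi, "drift_ihi"), save_tbl(rhi, "drift_rhi"),
                 save_fig(plot_drift(ihi), "drift_ihi"),
                 save_fig(plot_drift(rhi), "drift_rhi"))
    }
  }
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest <- tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    seed = as.integer(seed),
    elapsed_s = round(elapsed, 1)
  )
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
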