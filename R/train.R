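.sample_variant <- function(cfg, n) {
  switch(cfg$variant,
    constrained   = sample_constrained(n),
    unconstrained = sample_unconstrained(n, p_touch = cfg$p_touch),
    handvision    = sample_handvision(n),
    joint         = sample_joint(n),
    gaze          = sample_gaze(n)
  )
}

#' Train the two-layer network
#'
#' Runs the contrastive-divergence training loop: every epoch draws fresh
#' world samples from the configured variant, encodes them as Poisson
#' population activity, and applies one CD-1 update per batch. Per-epoch
#' reconstruction error is recorded; at snapshot epochs the parameters are
#' stored and the visuo-proprioceptive overlap index is computed. Training
#' aborts with diagnostics if the reconstruction error increases by more
#' than 50% over five consecutive epochs.
#'
#' @param cfg a [pps_config()].
#' @param quiet suppress the per-epoch progress line.
#' @return An object of class `pps_fit`: `$params` ([pps_rbm()]), `$pops`,
#'   `$config`, `$metrics` (tibble: epoch, recon_error, overlap_index at
#'   snapshots), `$snapshots` (named list of parameter copies).
#' @export
pps_train <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pps_config"))
  set.seed(cfg$seed)
  pops <- pps_populations(cfg$variant, visual_grid = cfg$visual_grid,
                          n_tactile = cfg$n_tactile)
  net <- pps_rbm(pops, n_multi = cfg$n_multi)
  snaps <- cfg$snapshot_epochs
  metrics <- vector("list", cfg$epochs)
  snapshots <- list()
  err_hist <- numeric(0)
  for (e in seq_len(cfg$epochs)) {
    errs <- numeric(cfg$batches_per_epoch)
    for (b in seq_len(cfg$batches_per_epoch)) {
      w <- .sample_variant(cfg, cfg$batch_size)
      U0 <- encode_world(pops, w, sample = TRUE)
      net <- cd1_update(net, U0, eta = cfg$eta, use_mean_m = cfg$use_mean_m)
      errs[b] <- attr(net, "stats")$recon_error
    }
    err <- mean(errs)
    err_hist <- c(err_hist, err)
    ov <- NA_real_
    if (e %in% snaps || e == cfg$epochs) {
      snapshots[[sprintf("epoch_%03d", e)]] <- net[c("W", "b_u", "b_m")]
      ov <- overlap_index(rf_profile(.as_fit(net, pops, cfg)))
    }
    metrics[[e]] <- tibble(epoch = e, recon_error = err, overlap_index = ov)
    if (!quiet) {
      message(sprintf("[%s %s] epoch %d/%d  recon %.4f%s",
                      cfg$variant, cfg$scale, e, cfg$epochs, err,
                      if (is.na(ov)) "" else sprintf("  overlap %.3f", ov)))
    }
    if (length(err_hist) >= 6) {
      recent <- tail(err_hist, 6)
      if (all(diff(recent) > 0) && recent[6] > 1.5 * recent[1]) {
        abort(c("training diverged: reconstruction error rose >50% over 5 epochs",
                sprintf("errors: %s", paste(signif(recent, 4), collapse = ", "))))
      }
    }
  }
  .as_fit(net, pops, cfg, metrics = dplyr::bind_rows(metrics),
          snapshots = snapshots)
}

.as_fit <- function(net, pops, cfg, metrics = NULL, snapshots = NULL) {
  net$pops <- pops
  structure(
    list(params = net, pops = pops, config = cfg,
         metrics = metrics, snapshots = snapshots,
         hash = .config_hash(cfg)),
    class = "pps_fit"
  )
}

#' @export
print.pps_fit <- function(x, ...) {
  cat(sprintf("<pps_fit '%s' (%s)> %d multisensory units, %d lower-layer units\n",
              x$config$variant, x$config$scale,
              nrow(x$params$W), ncol(x$params$W)))
  if (!is.null(x$metrics) && nrow(x$metrics)) {
    cat(sprintf("  %d epochs, final reconstruction error %.4f\n",
                max(x$metrics$epoch), tail(x$metrics$recon_error, 1)))
  }
  invisible(x)
}

#' Two-stage training of the three-layer extension
#'
#' Stage 1 trains the ordinary two-layer network. Stage 2 freezes it and
#' trains a second machine whose visible layer concatenates the first
#' multisensory layer's activity (sampled up pass on freshly encoded
#' stimuli) with the raw tactile activity, using the same CD-1 rule. The
#' third layer can thereby learn the association between touch and the
#' first-layer units whose visual and proprioceptive fields overlap,
#' yielding individual neurons with hand-anchored visual fields.
#'
#' @param cfg a [pps_config()] for stage 1 (stage 2 reuses its schedule).
#' @param n_multi2 number of third-layer units.
#' @param stage1 optionally, an existing `pps_fit` to reuse as stage 1.
#' @param quiet suppress progress lines.
#' @return An object of class `pps_fit3` with `$stage1` (`pps_fit`),
#'   `$params2` (the stage-2 [pps_rbm()]), `$config`.
#' @export
pps_train_stagewise <- function(cfg, n_multi2 = 100, stage1 = NULL,
                                quiet = FALSE) {
  stopifnot(inherits(cfg, "pps_config"))
  if (is.null(stage1)) {
    stage1 <- pps_train(cfg, quiet = quiet)
  } else if (!inherits(stage1, "pps_fit")) {
    abort("stage 2 requested without a valid stage-1 fit")
  }
  set.seed(cfg$seed + 1L)
  pops <- stage1$pops
  net1 <- stage1$params
  n_vis2 <- nrow(net1$W) + pops$n_tactile
  net2 <- pps_rbm(n_vis2, n_multi = n_multi2)
  tact <- pops$slices$tactile
  for (e in seq_len(cfg$epochs)) {
    errs <- numeric(cfg$batches_per_epoch)
    for (b in seq_len(cfg$batches_per_epoch)) {
      w <- .sample_variant(cfg, cfg$batch_size)
      U0 <- encode_world(pops, w, sample = TRUE)
      m1 <- up_pass(net1, U0, sample = TRUE)$m
      V0 <- cbind(m1, U0[, tact, drop = FALSE])
      net2 <- cd1_update(net2, V0, eta = cfg$eta)
      errs[b] <- attr(net2, "stats")$recon_error
    }
    if (!quiet) {
      message(sprintf("[stage2] epoch %d/%d  recon %.4f", e, cfg$epochs,
                      mean(errs)))
    }
  }
  structure(list(stage1 = stage1, params2 = net2, config = cfg,
                 n_multi2 = n_multi2),
            class = "pps_fit3")
}

#' @export
print.pps_fit3 <- function(x, ...) {
  cat(sprintf("<pps_fit3> stage-1 %d units, stage-2 %d units over %d visible\n",
              nrow(x$stage1$params$W), nrow(x$params2$W), ncol(x$params2$W)))
  invisible(x)
}
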