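.fit_parts <- function(fit) {
  stopifnot(inherits(fit, "pps_fit"))
  pops <- fit$pops
  list(net = fit$params, pops = pops,
       vis = pops$layouts$visual, prop = pops$layouts$proprioceptive,
       i_vis = pops$slices$visual, i_prop = pops$slices$proprioceptive,
       i_tact = pops$slices$tactile)
}

## bilinear interpolation of a weight map defined on `layout` at query
## points (matrix qx, qy); queries outside the layout grid get NA
.interp_map <- function(layout, w, qx, qy) {
  Z <- matrix(w, layout$n[1], layout$n[2])
  ## pracma::interp2 takes x = columns, y = rows
  pracma::interp2(x = layout$axes[[2]], y = layout$axes[[1]], Z = Z,
                  xp = qy, yp = qx, method = "linear")
}

#' Receptive-field profile of the multisensory layer
#'
#' For each multisensory neuron: the tactile input strength (mean of its
#' 30 incoming tactile weights), the preferred visual distance (the
#' anterior-posterior preferred position of the visual neuron projecting
#' the strongest excitatory synapse; ties broken towards the lowest unit
#' index), and the visuo-proprioceptive overlap (Pearson correlation of
#' the visual weight map with the proprioceptive weight map, the latter
#' bilinearly interpolated onto a grid with the visual population's
#' spacing covering the proprioceptive sheet).
#'
#' @param fit a [pps_train()] result.
#' @return A tibble with one row per multisensory neuron: `neuron`,
#'   `tactile_strength`, `preferred_visual_distance`, `vp_overlap`,
#'   `sign_class` (`"excitatory"`/`"inhibitory"`). The result carries the
#'   configuration hash in `attr(, "provenance")`.
#' @export
rf_profile <- function(fit) {
  p <- .fit_parts(fit)
  W <- p$net$W
  tactile_strength <- rowMeans(W[, p$i_tact, drop = FALSE])
  if (max(abs(W)) < 0.01) {
    warn("weights are near initialization scale; overlap estimates are unreliable")
  }
  vis_grid <- layout_grid(p$vis)
  pref_idx <- max.col(W[, p$i_vis, drop = FALSE], ties.method = "first")
  preferred_visual_distance <- vis_grid$y[pref_idx]
  ## shared query grid: visual spacing, spanning the proprioceptive sheet
  qx_ax <- seq(p$prop$axes[[1]][1], tail(p$prop$axes[[1]], 1),
               by = p$vis$spacing[1])
  qy_ax <- seq(p$prop$axes[[2]][1], tail(p$prop$axes[[2]], 1),
               by = p$vis$spacing[2])
  qx <- rep(qx_ax, times = length(qy_ax))
  qy <- rep(qy_ax, each = length(qx_ax))
  vp_overlap <- vapply(seq_len(nrow(W)), function(j) {
    pw <- .interp_map(p$prop, W[j, p$i_prop], qx, qy)
    vw <- .interp_map(p$vis, W[j, p$i_vis], qx, qy)
    suppressWarnings(cor(pw, vw))
  }, numeric(1))
  out <- tibble(
    neuron = seq_len(nrow(W)),
    tactile_strength = tactile_strength,
    preferred_visual_distance = preferred_visual_distance,
    vp_overlap = vp_overlap,
    sign_class = ifelse(tactile_strength > 0, "excitatory", "inhibitory")
  )
  attr(out, "provenance") <- list(config_hash = fit$hash)
  out
}

#' Percentage of tactile-excitatory multisensory neurons
#'
#' @param profile an [rf_profile()] table.
#' @return Percentage of neurons with positive mean tactile weight.
#' @export
excitatory_fraction <- function(profile) {
  mean(profile$tactile_strength > 0) * 100
}

#' Visuo-proprioceptive overlap index
#'
#' Difference between the mean visuo-proprioceptive overlap of
#' tactile-excitatory and tactile-inhibitory neurons; near zero for an
#' untrained or geometry-blind (unconstrained) network, rising during
#' body-constrained training.
#'
#' @param profile an [rf_profile()] table.
#' @return Scalar index.
#' @export
overlap_index <- function(profile) {
  exc <- profile$vp_overlap[profile$sign_class == "excitatory"]
  inh <- profile$vp_overlap[profile$sign_class == "inhibitory"]
  if (!length(exc) || !length(inh)) return(NA_real_)
  mean(exc, na.rm = TRUE) - mean(inh, na.rm = TRUE)
}

#' Evoked tactile activity map
#'
#' Simulates the tactile-detection read-out: visual and proprioceptive
#' inputs are encoded while the tactile slice is zeroed, and the mean
#' reconstructed tactile rate after a mean-mode down pass is recorded as
#' the evoked tactile activity, per trial. Hand positions are sampled
#' uniformly in an inner region of the workspace and visual positions at
#' uniform hand-centred offsets, so the map can be read both in
#' trunk-centred and in hand-centred coordinates.
#'
#' @param fit a trained [pps_train()] result (Cartesian variants).
#' @param n_trials number of (hand, stimulus) pairs.
#' @param max_offset largest hand-centred offset per axis (m).
#' @param gain stimulus and proprioceptive test gain.
#' @param hand_inner margin kept between sampled hands and the workspace
#'   edge, so that offsets stay within the represented visual space.
#' @param sample_input encode inputs as Poisson draws instead of means.
#' @param seed optional seed for the protocol draws.
#' @return A tibble per trial: hand and stimulus positions, hand-centred
#'   offsets `dx`, `dy`, distance `dist`, and `evoked` (mean tactile
#'   rate); provenance in attributes. Trials whose stimulus would fall
#'   outside the delivered visual workspace are dropped (the read-out is
#'   only defined where stimuli occurred in training), so fewer than
#'   `n_trials` rows are returned.
#' @export
evoked_tactile_map <- function(fit, n_trials = 4000, max_offset = 0.4,
                               gain = 10, hand_inner = 0.15,
                               sample_input = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_trials < 1) abort("empty protocol grid")
  p <- .fit_parts(fit)
  hand <- cbind(
    runif(n_trials, .pps$hand_lo[1] + hand_inner, .pps$hand_hi[1] - hand_inner),
    runif(n_trials, .pps$hand_lo[2] + hand_inner, .pps$hand_hi[2] - hand_inner)
  )
  off <- cbind(runif(n_trials, -max_offset, max_offset),
               runif(n_trials, -max_offset, max_offset))
  vis <- hand + off
  ## keep probes inside the delivered visual workspace: the read-out is
  ## only defined where stimuli occurred during training, and margin
  ## units produce spurious evoked activity
  keep <- vis[, 1] >= .pps$vis_lo[1] & vis[, 1] <= .pps$vis_hi[1] &
          vis[, 2] >= .pps$vis_lo[2] & vis[, 2] <= .pps$vis_hi[2]
  hand <- hand[keep, , drop = FALSE]
  off <- off[keep, , drop = FALSE]
  vis <- vis[keep, , drop = FALSE]
  n_trials <- nrow(vis)
  U <- cbind(
    encode_position(p$vis, vis, gain, sample = sample_input),
    encode_position(p$prop, hand, gain, sample = sample_input),
    matrix(0, n_trials, p$pops$n_tactile)
  )
  U <- .pad_extra_slices(fit, U)
  lam <- reconstruct(fit$params, U, mask = "tactile")
  out <- tibble(
    hand_x = hand[, 1], hand_y = hand[, 2],
    vis_x = vis[, 1], vis_y = vis[, 2],
    dx = off[, 1], dy = off[, 2],
    dist = sqrt(off[, 1]^2 + off[, 2]^2),
    evoked = rowMeans(lam[, p$i_tact, drop = FALSE])
  )
  attr(out, "provenance") <- list(config_hash = fit$hash, gain = gain,
                                  n_trials = n_trials)
  out
}

## hand-vision variant: analyses that address only the core populations
## present the hand-visual slice as silent (occluded hand)
.pad_extra_slices <- function(fit, U) {
  n_low <- ncol(fit$params$W)
  if (ncol(U) == n_low) return(U)
  full <- matrix(0, nrow(U), n_low)
  sl <- fit$pops$slices
  full[, sl$visual] <- U[, seq_along(sl$visual)]
  full[, sl$proprioceptive] <- U[, length(sl$visual) + seq_along(sl$proprioceptive)]
  full[, sl$tactile] <- U[, ncol(U) - length(sl$tactile) + seq_along(sl$tactile)]
  full
}

#' Mean evoked activity versus hand-centred distance
#'
#' Bins an [evoked_tactile_map()] by hand-centred distance.
#'
#' @param map tibble from [evoked_tactile_map()].
#' @param breaks bin edges (m).
#' @return Tibble with `dist_mid`, `evoked_mean`, `n`.
#' @export
evoked_distance_profile <- function(map, breaks = seq(0, 0.4, by = 0.05)) {
  map |>
    dplyr::filter(.data$dist <= max(breaks)) |>
    dplyr::mutate(bin = cut(.data$dist, breaks, include.lowest = TRUE)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(evoked_mean = mean(.data$evoked), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(dist_mid = head(breaks, -1) [as.integer(.data$bin)] +
                    diff(breaks)[1] / 2) |>
    dplyr::select("dist_mid", "evoked_mean", "n")
}

#' Population receptive-field shift with hand position
#'
#' Mean activity of the tactile-excitatory multisensory neurons as a
#' function of the visual stimulus' lateral position, for two fixed hand
#' positions (default 25 cm left and right of the midline). The peak of
#' the population response tracks the hand.
#'
#' @param fit a trained [pps_train()] result.
#' @param hand_left,hand_right the two proprioceptive inputs (m).
#' @param vis_y anterior-posterior coordinate of the probe stimuli.
#' @param gain test gain.
#' @param n_x number of lateral probe positions.
#' @return Tibble: `hand` (`"left"`/`"right"`), `vis_x`, `response`.
#' @export
population_rf_shift <- function(fit, hand_left = c(-0.25, 0.3),
                                hand_right = c(0.25, 0.3), vis_y = 0.3,
                                gain = 10, n_x = 61) {
  p <- .fit_parts(fit)
  prof <- rf_profile(fit)
  exc <- prof$neuron[prof$sign_class == "excitatory"]
  xs <- seq(.pps$vis_lo[1], .pps$vis_hi[1], length.out = n_x)
  resp_for <- function(hand) {
    U <- cbind(
      encode_position(p$vis, cbind(xs, vis_y), gain, sample = FALSE),
      encode_position(p$prop, matrix(hand, n_x, 2, byrow = TRUE), gain,
                      sample = FALSE),
      matrix(0, n_x, p$pops$n_tactile)
    )
    U <- .pad_extra_slices(fit, U)
    mu <- up_pass(fit$params, U, sample = FALSE)$mu
    rowMeans(mu[, exc, drop = FALSE])
  }
  out <- dplyr::bind_rows(
    tibble(hand = "left", vis_x = xs, response = resp_for(hand_left)),
    tibble(hand = "right", vis_x = xs, response = resp_for(hand_right))
  )
  attr(out, "provenance") <- list(config_hash = fit$hash,
                                  hand_left = hand_left,
                                  hand_right = hand_right)
  out
}

#' Peak abscissa of a response curve
#'
#' Argmax after Gaussian smoothing (SD = one probe step by default);
#' `smooth_sd = 0` gives the raw argmax.
#'
#' @param x,response curve samples.
#' @param smooth_sd smoothing SD in units of the `x` step.
#' @return The `x` at the (smoothed) maximum.
#' @export
response_peak <- function(x, response, smooth_sd = 1) {
  if (smooth_sd > 0) {
    k <- stats::dnorm(seq(-3 * smooth_sd, 3 * smooth_sd), sd = smooth_sd)
    k <- k / sum(k)
    pad <- (length(k) - 1) / 2
    padded <- c(rep(response[1], pad), response, rep(tail(response, 1), pad))
    response <- stats::filter(padded, k, sides = 2)[pad + seq_along(x)]
  }
  x[which.max(response)]
}

#' Simulated proprioceptive-drift experiments
#'
#' Reproduces the invisible-hand (IHI) and rubber-hand (RHI) stimulation
#' patterns: the proprioceptive input is fixed at the midline while a
#' visual stimulus is presented at lateral offsets, with the tactile
#' drive off (asynchronous) or at several positive gains (synchronous).
#' The decoded proprioceptive position is the barycentre of the
#' proprioceptive slice after an up pass and a mean-mode down pass. In
#' the RHI protocol (hand-vision variant only) the hand-visual population
#' codes the stimulus location (the rubber hand); in the IHI protocol any
#' hand-visual population is silenced (hand out of view).
#'
#' @param fit a trained [pps_train()] result (Cartesian variants).
#' @param protocol `"ihi"` or `"rhi"`.
#' @param offsets lateral visual offsets from the hand (m).
#' @param touch_gains tactile intensities; 0 encodes touch OFF.
#' @param hand the fixed proprioceptive hand position (m).
#' @param gain visual and proprioceptive test gain.
#' @return Tibble: `offset`, `touch_gain`, `touch` (on/off), decoded
#'   `decoded_x`, `drift_m` (decoded minus true, m), `drift_pct` (as % of
#'   the visuo-proprioceptive disparity).
#' @export
drift_experiment <- function(fit, protocol = c("ihi", "rhi"),
                             offsets = seq(0.05, 0.4, by = 0.05),
                             touch_gains = c(0, 4, 7, 10),
                             hand = c(0, 0.3), gain = 10) {
  protocol <- match.arg(protocol)
  p <- .fit_parts(fit)
  has_hv <- "hand_visual" %in% names(fit$pops$slices)
  if (protocol == "rhi" && !has_hv) {
    abort("the RHI protocol needs a checkpoint with a hand-visual population")
  }
  grid <- tidyr::expand_grid(offset = offsets, touch_gain = touch_gains)
  B <- nrow(grid)
  vis <- cbind(hand[1] + grid$offset, hand[2])
  U_vis <- encode_position(p$vis, vis, gain, sample = FALSE)
  U_prop <- encode_position(p$prop, matrix(hand, B, 2, byrow = TRUE), gain,
                            sample = FALSE)
  U_tact <- matrix(grid$touch_gain, B, p$pops$n_tactile)
  parts <- list(visual = U_vis, proprioceptive = U_prop)
  if (has_hv) {
    parts$hand_visual <- if (protocol == "rhi") {
      ## the rubber hand sits where the brush strokes: at the stimulus
      encode_position(fit$pops$layouts$hand_visual, vis, gain, sample = FALSE)
    } else {
      matrix(0, B, prod(fit$pops$layouts$hand_visual$n))
    }
  }
  parts$tactile <- U_tact
  U <- do.call(cbind, parts[names(fit$pops$slices)])
  lam <- reconstruct(fit$params, U, mask = character())
  dec <- decode_barycentre(p$prop, lam[, p$i_prop, drop = FALSE])
  out <- grid |>
    dplyr::mutate(
      touch = ifelse(.data$touch_gain > 0, "on", "off"),
      decoded_x = dec$x,
      drift_m = dec$x - hand[1],
      drift_pct = 100 * (dec$x - hand[1]) / .data$offset
    )
  attr(out, "provenance") <- list(config_hash = fit$hash,
                                  protocol = protocol, hand = hand,
                                  gain = gain)
  out
}

#' Predicted visuotactile facilitation for the trajectory experiment
#'
#' Evoked tactile activity at the geometry of the tactile-detection
#' experiment: hand placed 25 cm left or right of the midline and 30 cm
#' in front of the trunk, with visual stimuli at the final approach
#' positions of three trajectories (towards the left target, the right
#' target, or receding along the midline). Trajectories are recoded as
#' congruent/incongruent with the stimulated hand.
#'
#' @param fit a trained [pps_train()] result.
#' @param ball_dists distances of the ball from the trajectory target at
#'   tactile-stimulation time (m).
#' @param gain test gain.
#' @return Tibble: `hand_side`, `trajectory`, `congruency`, `ball_dist`,
#'   ball position, `evoked`.
#' @export
congruency_prediction <- function(fit, ball_dists = c(0, 0.05, 0.10),
                                  gain = 10) {
  p <- .fit_parts(fit)
  fixation <- c(0, 0.65)
  targets <- list(left = c(-0.25, 0.3), right = c(0.25, 0.3),
                  receding = c(0, 0.95))
  cases <- tidyr::expand_grid(
    hand_side = c("left", "right"),
    trajectory = names(targets),
    ball_dist = ball_dists
  )
  pos <- t(vapply(seq_len(nrow(cases)), function(i) {
    tg <- targets[[cases$trajectory[i]]]
    dir <- tg - fixation
    tg - dir / sqrt(sum(dir^2)) * cases$ball_dist[i]
  }, numeric(2)))
  hand <- t(vapply(cases$hand_side, function(s) targets[[s]], numeric(2)))
  U <- cbind(
    encode_position(p$vis, pos, gain, sample = FALSE),
    encode_position(p$prop, hand, gain, sample = FALSE),
    matrix(0, nrow(cases), p$pops$n_tactile)
  )
  U <- .pad_extra_slices(fit, U)
  lam <- reconstruct(fit$params, U, mask = "tactile")
  cases |>
    dplyr::mutate(
      ball_x = pos[, 1], ball_y = pos[, 2],
      congruency = dplyr::case_when(
        trajectory == "receding" ~ "receding",
        trajectory == hand_side ~ "congruent",
        TRUE ~ "incongruent"
      ),
      evoked = rowMeans(lam[, p$i_tact, drop = FALSE])
    )
}

#' Hand-position tuning of third-layer receptive-field peaks
#'
#' For a stagewise-trained three-layer network: with tactile input
#' zeroed, maps each third-layer neuron's visual receptive-field peak for
#' `n_hand` random hand positions, and correlates peak coordinates with
#' hand coordinates (mean of the Pearson r along x and y). Neurons
#' receiving stronger unisensory tactile projections are expected to show
#' stronger hand tuning.
#'
#' @param fit3 a [pps_train_stagewise()] result.
#' @param n_hand number of probe hand positions.
#' @param vis_probe number of visual probe positions per axis.
#' @param gain test gain.
#' @param seed optional seed for the probe draws.
#' @return Tibble per third-layer neuron: `neuron`, `hand_correlation`,
#'   `tactile_input_strength`.
#' @export
rf_peak_hand_correlation <- function(fit3, n_hand = 100, vis_probe = 21,
                                     gain = 10, seed = NULL) {
  stopifnot(inherits(fit3, "pps_fit3"))
  if (!is.null(seed)) set.seed(seed)
  fit1 <- fit3$stage1
  p <- .fit_parts(fit1)
  net2 <- fit3$params2
  n_multi1 <- nrow(fit1$params$W)
  xs <- seq(.pps$vis_lo[1], .pps$vis_hi[1], length.out = vis_probe)
  ys <- seq(.pps$vis_lo[2], .pps$vis_hi[2], length.out = vis_probe)
  probe <- as.matrix(expand.grid(x = xs, y = ys))
  U_vis_probe <- encode_position(p$vis, probe, gain, sample = FALSE)
  hands <- cbind(runif(n_hand, .pps$hand_lo[1], .pps$hand_hi[1]),
                 runif(n_hand, .pps$hand_lo[2], .pps$hand_hi[2]))
  n_neuron <- nrow(net2$W)
  peaks <- array(NA_real_, c(n_hand, n_neuron, 2))
  for (h in seq_len(n_hand)) {
    U <- cbind(
      U_vis_probe,
      encode_position(p$prop, matrix(hands[h, ], nrow(probe), 2, byrow = TRUE),
                      gain, sample = FALSE),
      matrix(0, nrow(probe), p$pops$n_tactile)
    )
    mu1 <- up_pass(fit1$params, U, sample = FALSE)$mu
    V <- cbind(mu1, matrix(0, nrow(probe), p$pops$n_tactile))
    mu2 <- up_pass(net2, V, sample = FALSE)$mu
    best <- apply(mu2, 2, which.max)
    peaks[h, , 1] <- probe[best, 1]
    peaks[h, , 2] <- probe[best, 2]
  }
  hand_correlation <- vapply(seq_len(n_neuron), function(j) {
    ## a peak that never moves is hand-independent: correlation 0
    rx <- if (sd(peaks[, j, 1]) == 0) 0
          else cor(hands[, 1], peaks[, j, 1])
    ry <- if (sd(peaks[, j, 2]) == 0) 0
          else cor(hands[, 2], peaks[, j, 2])
    mean(c(rx, ry))
  }, numeric(1))
  tact_cols <- n_multi1 + seq_len(p$pops$n_tactile)
  tibble(
    neuron = seq_len(n_neuron),
    hand_correlation = hand_correlation,
    tactile_input_strength = rowMeans(net2$W[, tact_cols, drop = FALSE])
  )
}
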