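## hand-built fit around a small constrained architecture, so analysis
## definitions can be checked against crafted weights
crafted_fit <- function(W_fun, n_multi = 4, visual_grid = c(12, 12)) {
  cfg <- pps_config("constrained", visual_grid = as.integer(visual_grid),
                    n_multi = as.integer(n_multi))
  pops <- pps_populations("constrained", visual_grid = visual_grid)
  net <- pps_rbm(pops, n_multi = n_multi, init_sd = 0)
  net$W <- W_fun(pops, net$W)
  ppsnet:::.as_fit(net, pops, cfg)
}

## weight map over a layout shaped as a Gaussian bump at `centre`
bump <- function(layout, centre, height = 1, width = 0.2) {
  g <- layout_grid(layout)
  height * exp(-((g$x - centre[1])^2 + (g$y - centre[2])^2) / (2 * width^2))
}

test_that("rf_profile recovers crafted receptive-field structure", {
  fit <- crafted_fit(function(pops, W) {
    vis <- pops$layouts$visual; prop <- pops$layouts$proprioceptive
    # neuron 1: matching visual/proprioceptive bumps, excitatory tactile
    W[1, pops$slices$visual] <- bump(vis, c(0, 0.3))
    W[1, pops$slices$proprioceptive] <- bump(prop, c(0, 0.3))
    W[1, pops$slices$tactile] <- 0.5
    # neuron 2: same maps but proprioceptive negated, inhibitory tactile
    W[2, pops$slices$visual] <- bump(vis, c(0.2, 0.5))
    W[2, pops$slices$proprioceptive] <- -bump(prop, c(0.2, 0.5))
    W[2, pops$slices$tactile] <- -0.5
    # neurons 3-4: far visual peak, weak tactile
    W[3, pops$slices$visual] <- bump(vis, c(0, 1.0))
    W[3, pops$slices$tactile] <- 0.1
    W[4, pops$slices$tactile] <- -0.1
    W
  })
  prof <- rf_profile(fit)
  expect_equal(prof$tactile_strength, c(0.5, -0.5, 0.1, -0.1))
  expect_equal(prof$sign_class,
               c("excitatory", "inhibitory", "excitatory", "inhibitory"))
  # identical (interpolated) maps correlate at ~1, negated at ~-1
  expect_gt(prof$vp_overlap[1], 0.99)
  expect_lt(prof$vp_overlap[2], -0.99)
  # preferred visual distance = anterior-posterior position of the
  # strongest visual synapse
  expect_lt(abs(prof$preferred_visual_distance[1] - 0.3), 0.1)
  expect_lt(abs(prof$preferred_visual_distance[3] - 1.0), 0.1)
})

test_that("excitatory fraction and overlap index follow their definitions", {
  tbl <- tibble::tibble(
    tactile_strength = c(1, 2, -1, 3),
    vp_overlap = c(0.8, 0.6, -0.5, 0.4),
    sign_class = c("excitatory", "excitatory", "inhibitory", "excitatory")
  )
  expect_equal(excitatory_fraction(tbl), 75)
  expect_equal(overlap_index(tbl), mean(c(0.8, 0.6, 0.4)) - (-0.5))
  all_pos <- dplyr::mutate(tbl, tactile_strength = abs(tactile_strength),
                           sign_class = "excitatory")
  expect_equal(excitatory_fraction(all_pos), 100)
  expect_true(is.na(overlap_index(all_pos)))
})

test_that("an untrained network yields a flat evoked map and ~zero overlap index", {
  cfg <- pps_config("constrained", visual_grid = c(15L, 15L), n_multi = 40L)
  pops <- pps_populations("constrained", visual_grid = c(15, 15))
  set.seed(40)
  net <- pps_rbm(pops, n_multi = 40)
  fit <- ppsnet:::.as_fit(net, pops, cfg)
  map <- evoked_tactile_map(fit, n_trials = 600, seed = 1)
  cv <- sd(map$evoked) / mean(map$evoked)
  expect_lt(cv, 0.05)
  # hand-centred re-binning agrees with the per-trial offset computation
  expect_equal(map$dx, map$vis_x - map$hand_x)
  expect_equal(map$dist, sqrt(map$dx^2 + map$dy^2))
  expect_warning(prof <- rf_profile(fit), "initialization")
  expect_lt(abs(overlap_index(prof)), 0.05)
})

test_that("drift experiment is unbiased when reconstruction is perfect", {
  # identity-like network: strong autoencoding weights per proprio unit
  # are unnecessary -- check instead that identical hand inputs give
  # identical curves and that drift columns follow their definition
  fit <- crafted_fit(function(pops, W) W, n_multi = 6)
  dr <- drift_experiment(fit, "ihi", offsets = c(0.1, 0.2),
                         touch_gains = c(0, 5))
  expect_equal(nrow(dr), 4)
  expect_equal(dr$drift_pct, 100 * dr$drift_m / dr$offset)
  expect_equal(unique(dr$touch[dr$touch_gain == 0]), "off")
  # untrained weights: reconstruction driven by biases only, no drift
  expect_true(all(abs(dr$drift_m) < 1e-6))
  expect_error(drift_experiment(fit, "rhi"), "hand-visual")
})

test_that("population RF shift curves coincide for identical hand inputs", {
  fit <- crafted_fit(function(pops, W) {
    W[, pops$slices$tactile] <- 0.2   # all excitatory
    W[1, pops$slices$visual] <- bump(pops$layouts$visual, c(-0.2, 0.3))
    W
  })
  same <- population_rf_shift(fit, hand_left = c(0.1, 0.3),
                              hand_right = c(0.1, 0.3), n_x = 21)
  left <- same$response[same$hand == "left"]
  right <- same$response[same$hand == "right"]
  expect_equal(left, right)
})

test_that("response_peak finds smoothed and raw maxima", {
  x <- seq(0, 1, by = 0.05)
  y <- dnorm(x, 0.4, 0.15)
  expect_equal(response_peak(x, y, smooth_sd = 0), 0.4)
  y_noisy <- y + c(rep(0, 10), 1.0, rep(0, 10))  # single-bin spike at 0.5
  expect_equal(response_peak(x, y_noisy, smooth_sd = 0), 0.5)
  expect_equal(response_peak(x, y_noisy, smooth_sd = 2), 0.4, tolerance = 0.1)
})

test_that("congruency prediction covers the trajectory-experiment geometry", {
  fit <- crafted_fit(function(pops, W) W, n_multi = 5)
  cp <- congruency_prediction(fit)
  expect_equal(nrow(cp), 2 * 3 * 3)
  expect_setequal(unique(cp$congruency),
                  c("congruent", "incongruent", "receding"))
  # congruent cases probe the stimulated hand's own position
  cg <- cp[cp$congruency == "congruent" & cp$ball_dist == 0, ]
  expect_equal(cg$ball_x, ifelse(cg$hand_side == "left", -0.25, 0.25))
  expect_equal(cg$ball_y, rep(0.3, 2))
})

test_that("third-layer RF-peak correlation separates crafted tunings", {
  ## stage 1: conjunction units on a coarse shared grid, active only when
  ## the visual stimulus and the hand are both near the unit's centre;
  ## a third-layer neuron pooling them has an RF peak that tracks the
  ## hand, while a neuron ignoring them does not
  visual_grid <- c(12, 12)
  pops <- pps_populations("constrained", visual_grid = visual_grid)
  centres <- as.matrix(expand.grid(x = seq(-0.5, 0.5, by = 0.2),
                                   y = seq(0.1, 0.5, by = 0.2)))
  n1 <- nrow(centres)
  net1 <- pps_rbm(pops, n_multi = n1, init_sd = 0)
  for (k in seq_len(n1)) {
    net1$W[k, pops$slices$visual] <-
      4 * bump(pops$layouts$visual, centres[k, ], width = 0.12)
    net1$W[k, pops$slices$proprioceptive] <-
      4 * bump(pops$layouts$proprioceptive, centres[k, ], width = 0.12)
  }
  net1$b_m <- rep(-190, n1)  # require strong joint visual+proprio drive
  cfg <- pps_config("constrained", visual_grid = as.integer(visual_grid),
                    n_multi = as.integer(n1))
  fit1 <- ppsnet:::.as_fit(net1, pops, cfg)
  net2 <- pps_rbm(n1 + 30, n_multi = 2, init_sd = 0)
  net2$W[1, seq_len(n1)] <- 8          # pools all conjunction units
  net2$W[1, n1 + 1:30] <- 0.3          # touch-excited
  net2$W[2, ] <- 0                     # hand-blind control
  net2$W[2, n1 + 1:30] <- -0.1
  fit3 <- structure(list(stage1 = fit1, params2 = net2,
                         config = cfg, n_multi2 = 2), class = "pps_fit3")
  rf <- rf_peak_hand_correlation(fit3, n_hand = 40, vis_probe = 25, seed = 2)
  expect_gt(rf$hand_correlation[1], 0.8)
  expect_lt(abs(rf$hand_correlation[2]), 0.5)
  expect_gt(rf$tactile_input_strength[1], 0)
  expect_lt(rf$tactile_input_strength[2], 0)
})
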