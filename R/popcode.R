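#' Build a population-code layout
#'
#' A layout places Gaussian-tuned neurons on a regular grid of preferred
#' positions covering the stimulus workspace plus a safety margin on each
#' side (to avoid edge effects in decoding). Preferred positions include
#' the endpoints of the margin-extended range, so the grid spacing along
#' axis \eqn{k} is \eqn{(hi_k - lo_k + 2\,margin_k) / (n_k - 1)}. The
#' tuning-curve SD is expressed in grid spacings and converted to physical
#' units per axis.
#'
#' @param n integer vector of grid sizes, one per dimension (length 1 or 2).
#' @param lo,hi numeric vectors: physical span of delivered stimuli per
#'   dimension (metres or radians).
#' @param margin numeric vector, safety margin added on each side. The
#'   default 0.3 m corresponds to roughly three tuning-curve SDs for the
#'   standard visual and proprioceptive populations.
#' @param sigma_units tuning-curve SD in units of the grid spacing.
#' @param label optional population name.
#' @return An object of class `pps_layout`.
#' @examples
#' vis <- layout_visual()
#' vis$sigma      # ~0.11 m
#' @export
pps_layout <- function(n, lo, hi, margin = rep(0.3, length(n)),
                       sigma_units = 1, label = "pop") {
  d <- length(n)
  stopifnot(d %in% c(1L, 2L), length(lo) == d, length(hi) == d)
  if (any(n < 2)) abort("each grid dimension needs at least 2 neurons")
  if (sigma_units <= 0) abort("sigma_units must be positive")
  margin <- rep(margin, length.out = d)
  axes <- lapply(seq_len(d), function(k) {
    seq(lo[k] - margin[k], hi[k] + margin[k], length.out = n[k])
  })
  spacing <- vapply(axes, function(a) a[2] - a[1], numeric(1))
  sigma <- sigma_units * spacing
  if (any(sigma < spacing / 2)) {
    warn("tuning-curve SD below half the grid spacing: the code is sparse and decoding may be biased")
  }
  structure(
    list(n = as.integer(n), d = d, axes = axes, spacing = spacing,
         sigma = sigma, sigma_units = sigma_units,
         lo = lo, hi = hi, margin = margin, label = label),
    class = "pps_layout"
  )
}

#' @export
print.pps_layout <- function(x, ...) {
  cat(sprintf("<pps_layout '%s'> %s neurons, sigma = %s (physical), spacing = %s\n",
              x$label, paste(x$n, collapse = "x"),
              paste(signif(x$sigma, 3), collapse = "/"),
              paste(signif(x$spacing, 3), collapse = "/")))
  invisible(x)
}

#' Standard layouts
#'
#' Constructors for the populations used throughout: a visual layout
#' (default 50x50 over 1.2x1.2 m, tuning SD three grid spacings, ~11 cm),
#' a Cartesian proprioceptive layout (15x10 over 1.2x0.6 m, SD one
#' spacing, ~13 cm), a joint-angle proprioceptive layout (15x10 over the
#' shoulder/elbow ranges), and a 1D gaze layout (120 neurons over
#' \eqn{[-\pi/4, \pi/4]}, SD one spacing).
#'
#' @param n grid size (see individual defaults).
#' @name standard_layouts
NULL

#' @rdname standard_layouts
#' @export
layout_visual <- function(n = c(50, 50)) {
  pps_layout(n, .pps$vis_lo, .pps$vis_hi, .pps$margin, sigma_units = 3,
             label = "visual")
}

#' @rdname standard_layouts
#' @export
layout_proprioceptive <- function(n = c(15, 10)) {
  pps_layout(n, .pps$hand_lo, .pps$hand_hi, .pps$margin, sigma_units = 1,
             label = "proprioceptive")
}

#' @rdname standard_layouts
#' @export
layout_joint <- function(n = c(15, 10)) {
  lo <- c(.pps$theta1_range[1], .pps$theta2_range[1])
  hi <- c(.pps$theta1_range[2], .pps$theta2_range[2])
  ## margin scaled to the angular span: same 1/4-of-range proportion as the
  ## 0.3 m margin on the 1.2 m Cartesian span
  pps_layout(n, lo, hi, margin = (hi - lo) / 4, sigma_units = 1,
             label = "joint")
}

#' @rdname standard_layouts
#' @export
layout_gaze <- function(n = 120) {
  lo <- .pps$gaze_range[1]; hi <- .pps$gaze_range[2]
  pps_layout(n, lo, hi, margin = (hi - lo) / 4, sigma_units = 1,
             label = "gaze")
}

#' Preferred positions of a layout
#'
#' @param layout a [pps_layout()].
#' @return A tibble with one row per neuron: `unit`, and `x` (plus `y` for
#'   2D layouts). The first axis varies fastest, matching the column order
#'   of encoded activity matrices.
#' @export
layout_grid <- function(layout) {
  stopifnot(inherits(layout, "pps_layout"))
  if (layout$d == 1L) {
    tibble(unit = seq_len(layout$n[1]), x = layout$axes[[1]])
  } else {
    tibble(unit = seq_len(prod(layout$n)),
           x = rep(layout$axes[[1]], times = layout$n[2]),
           y = rep(layout$axes[[2]], each = layout$n[1]))
  }
}

## Tuning-curve means for a batch of positions: B x n_units matrix.
## Separable Gaussians are evaluated per axis and combined by an outer
## product in flattened form (first axis fastest).
.tuning_means <- function(layout, pos, gain) {
  pos <- .as_pos_matrix(pos, layout$d)
  B <- nrow(pos)
  gain <- rep(gain, length.out = B)
  G <- lapply(seq_len(layout$d), function(k) {
    exp(-outer(pos[, k], layout$axes[[k]], "-")^2 / (2 * layout$sigma[k]^2))
  })
  lam <- if (layout$d == 1L) {
    G[[1]]
  } else {
    nx <- layout$n[1]; ny <- layout$n[2]
    G[[1]][, rep(seq_len(nx), times = ny), drop = FALSE] *
      G[[2]][, rep(seq_len(ny), each = nx), drop = FALSE]
  }
  lam * gain
}

.as_pos_matrix <- function(pos, d) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = d)
  pos <- as.matrix(pos)
  if (ncol(pos) != d) abort(sprintf("positions must have %d column(s)", d))
  pos
}

#' Encode physical positions as Poisson population activity
#'
#' Each neuron fires with mean `gain * exp(-||pos - pref||^2 / (2 sigma^2))`
#' (distances taken per axis against the layout's per-axis tuning SD).
#' With `sample = FALSE` the deterministic means are returned; with
#' `sample = TRUE` independent Poisson counts are drawn.
#'
#' @param layout a [pps_layout()].
#' @param pos numeric vector (one position) or matrix/data frame with one
#'   row per stimulus. Positions may lie inside the safety margin.
#' @param gain nonnegative scalar or per-row vector of gains.
#' @param sample draw Poisson counts (`TRUE`) or return the means.
#' @return Numeric matrix, stimuli x neurons.
#' @examples
#' lay <- layout_proprioceptive()
#' lam <- encode_position(lay, c(0, 0.3), gain = 10, sample = FALSE)
#' max(lam)  # close to 10: a neuron sits near the encoded position
#' @export
encode_position <- function(layout, pos, gain, sample = TRUE) {
  stopifnot(inherits(layout, "pps_layout"))
  pos <- .as_pos_matrix(pos, layout$d)
  if (!all(is.finite(pos))) abort("positions must be finite")
  if (any(!is.finite(gain)) || any(gain < 0)) abort("gain must be finite and nonnegative")
  lam <- .tuning_means(layout, pos, gain)
  if (!sample) return(lam)
  matrix(rpois(length(lam), lam), nrow = nrow(lam))
}

#' Encode tactile stimulation
#'
#' The tactile population has no spatial tuning: all `n_units` neurons are
#' driven at the stimulation gain when touch is present and are silent
#' otherwise.
#'
#' @param touch logical vector, one entry per stimulus.
#' @param gain scalar or per-stimulus gain used when touch is present.
#' @param n_units number of tactile neurons.
#' @param sample draw Poisson counts or return the means.
#' @return Numeric matrix, stimuli x `n_units`.
#' @export
encode_tactile <- function(touch, gain, n_units = 30, sample = TRUE) {
  if (!is.logical(touch)) abort("touch must be logical")
  if (any(!is.finite(gain)) || any(gain < 0)) abort("gain must be finite and nonnegative")
  B <- length(touch)
  lam <- matrix(as.numeric(touch) * rep(gain, length.out = B), B, n_units)
  if (!sample) return(lam)
  matrix(rpois(length(lam), lam), nrow = B)
}

#' Decode a position as the activity barycentre
#'
#' The decoded position is the activity-weighted mean of the neurons'
#' preferred positions, the read-out used for all simulated experiments.
#'
#' @param layout a [pps_layout()].
#' @param activity nonnegative numeric vector (one pattern) or matrix with
#'   one pattern per row.
#' @return A tibble with one row per pattern: decoded `x` (and `y`), total
#'   `activity`, and `decodable` (`FALSE`, with `NA` coordinates, for
#'   all-zero patterns).
#' @export
decode_barycentre <- function(layout, activity) {
  stopifnot(inherits(layout, "pps_layout"))
  if (is.null(dim(activity))) activity <- matrix(activity, nrow = 1)
  n_units <- if (layout$d == 1L) layout$n[1] else prod(layout$n)
  if (ncol(activity) != n_units) {
    abort(sprintf("activity has %d columns; layout '%s' has %d neurons",
                  ncol(activity), layout$label, n_units))
  }
  if (any(activity < 0)) abort("activity must be nonnegative")
  tot <- rowSums(activity)
  bad <- tot <= 0
  if (any(bad)) warn(sprintf("%d all-zero pattern(s) are undecodable", sum(bad)))
  grid <- layout_grid(layout)
  out <- tibble(
    x = as.numeric(activity %*% grid$x) / tot,
    activity = tot,
    decodable = !bad
  )
  if (layout$d == 2L) {
    out$y <- as.numeric(activity %*% grid$y) / tot
    out <- out[, c("x", "y", "activity", "decodable")]
  }
  out$x[bad] <- NA_real_
  if (layout$d == 2L) out$y[bad] <- NA_real_
  out
}

#' Maximum-likelihood position decoding
#'
#' Grid-search maximum-likelihood decoder for Poisson activity under the
#' layout's Gaussian tuning curves, used as an independent cross-check of
#' the barycentre read-out and of [pps_precision()]. Candidate positions
#' refine the layout grid by `refine` per axis over a window around
#' `centre` (default: the whole represented range).
#'
#' @param layout a [pps_layout()].
#' @param activity count matrix, patterns x neurons.
#' @param refine candidate grid refinement factor.
#' @param centre,halfwidth optional search window (physical units).
#' @return Tibble of decoded positions, one row per pattern.
#' @export
decode_ml <- function(layout, activity, refine = 4, centre = NULL,
                      halfwidth = NULL) {
  stopifnot(inherits(layout, "pps_layout"))
  if (is.null(dim(activity))) activity <- matrix(activity, nrow = 1)
  cand_axes <- lapply(seq_len(layout$d), function(k) {
    a <- layout$axes[[k]]
    if (!is.null(centre)) {
      hw <- if (is.null(halfwidth)) 4 * layout$sigma[k] else halfwidth[k]
      a <- c(max(a[1], centre[k] - hw), min(tail(a, 1), centre[k] + hw))
    }
    seq(a[1], tail(a, 1), by = layout$spacing[k] / refine)
  })
  cand <- if (layout$d == 1L) {
    matrix(cand_axes[[1]], ncol = 1)
  } else {
    as.matrix(expand.grid(cand_axes[[1]], cand_axes[[2]]))
  }
  lam <- .tuning_means(layout, cand, gain = 1)   # gain shifts logL by a constant
  loglam <- log(lam)
  ## log L(x) = sum_i n_i log lam_i(x) - sum_i lam_i(x)
  LL <- activity %*% t(loglam) - matrix(rowSums(lam), nrow(activity),
                                        nrow(cand), byrow = TRUE)
  best <- max.col(LL, ties.method = "first")
  out <- tibble(x = cand[best, 1])
  if (layout$d == 2L) out$y <- cand[best, 2]
  out
}

#' Theoretical decoder precision of a population code
#'
#' Posterior SD of the stimulus position given one volley of Poisson
#' population activity, in the dense-grid regime: per axis
#' \eqn{\sigma_{post} = \sigma / \sqrt{N}}, where \eqn{N} is the expected
#' total spike count, \eqn{N = g\,\prod_k \sqrt{2\pi}\,\sigma_k/\Delta_k}
#' (one factor per dimension; \eqn{\Delta} is the grid spacing).
#'
#' @param layout a [pps_layout()].
#' @param gain stimulus gain (must be positive).
#' @return A tibble with per-axis posterior SDs (`sd_x`, and `sd_y` for 2D
#'   layouts), their mean `sd` (the scalar summary), and the expected
#'   total count `n_spikes`.
#' @examples
#' pps_precision(layout_visual(), gain = 10)$sd * 100          # ~0.46 cm
#' pps_precision(layout_proprioceptive(), gain = 10)$sd * 100  # ~1.65 cm
#' @export
pps_precision <- function(layout, gain) {
  stopifnot(inherits(layout, "pps_layout"))
  if (gain <= 0) abort("gain must be positive")
  per_axis <- sqrt(2 * pi) * layout$sigma / layout$spacing
  n_spikes <- gain * prod(per_axis)
  sds <- layout$sigma / sqrt(n_spikes)
  out <- tibble(sd = mean(sds), n_spikes = n_spikes, sd_x = sds[1])
  if (layout$d == 2L) out$sd_y <- sds[2]
  out
}
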