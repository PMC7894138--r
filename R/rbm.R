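#' Initialize the two-layer network parameters
#'
#' Symmetric weights between the lower (unisensory, Poisson) and upper
#' (multisensory, Bernoulli) layers. At initialization each weight is
#' drawn from a zero-mean Gaussian with SD 0.001 and all biases are zero.
#' The same matrix `W` serves the feedforward ("up") and, transposed, the
#' feedback ("down") pass.
#'
#' @param pops a [pps_populations()], or an integer lower-layer size.
#' @param n_multi number of multisensory units.
#' @param init_sd SD of the weight initialization.
#' @return An object of class `pps_rbm`: `$W` (`n_multi x n_low`), `$b_u`,
#'   `$b_m`, `$pops` (when given), `$n_multi`.
#' @export
pps_rbm <- function(pops, n_multi = 500, init_sd = 0.001) {
  n_low <- if (inherits(pops, "pps_populations")) pops$n_low else as.integer(pops)
  net <- list(
    W = matrix(rnorm(n_multi * n_low, 0, init_sd), n_multi, n_low),
    b_u = rep(0, n_low),
    b_m = rep(0, n_multi),
    n_multi = n_multi,
    pops = if (inherits(pops, "pps_populations")) pops else NULL
  )
  structure(net, class = "pps_rbm")
}

#' @export
print.pps_rbm <- function(x, ...) {
  cat(sprintf("<pps_rbm> %d multisensory x %d unisensory units\n",
              nrow(x$W), ncol(x$W)))
  invisible(x)
}

.check_u <- function(net, U) {
  if (is.null(dim(U))) U <- matrix(U, nrow = 1)
  if (ncol(U) != ncol(net$W)) {
    hint <- ""
    if (!is.null(net$pops)) {
      sizes <- lengths(net$pops$slices)
      hint <- sprintf(" (expected %s = %d)",
                      paste(sprintf("%s[%d]", names(sizes), sizes),
                            collapse = " + "), ncol(net$W))
    }
    abort(sprintf("lower-layer activity has %d columns, network expects %d%s",
                  ncol(U), ncol(net$W), hint))
  }
  if (!all(is.finite(U)) || any(U < 0)) abort("lower-layer activity must be finite and nonnegative")
  U
}

#' Stochastic up pass
#'
#' Upper-layer Bernoulli means are a logistic function of the weighted
#' lower-layer activity: `mu = logistic(W u + b_m)`. With `sample = TRUE`
#' binary states are drawn; otherwise the mean field `mu` is returned as
#' the state.
#'
#' @param net a [pps_rbm()].
#' @param U lower-layer activity, one pattern per row.
#' @param sample draw Bernoulli states.
#' @return List with `mu` (means) and `m` (states), both patterns x units.
#' @export
up_pass <- function(net, U, sample = TRUE) {
  U <- .check_u(net, U)
  A <- U %*% t(net$W)
  A <- sweep(A, 2, net$b_m, "+")
  mu <- 1 / (1 + exp(-A))
  m <- if (sample) {
    (matrix(runif(length(mu)), nrow(mu)) < mu) * 1
  } else mu
  list(mu = mu, m = m)
}

#' Stochastic down pass
#'
#' Lower-layer Poisson means are an exponential function of the weighted
#' upper-layer activity: `lam = exp(W' m + b_u)`, using the transpose of
#' the up-pass weights (feedforward and feedback synapses are symmetric).
#' Means are clipped at `exp(log_ceiling)` to avoid overflow; a warning is
#' raised whenever clipping occurs.
#'
#' @param net a [pps_rbm()].
#' @param M upper-layer states (binary, or means in `[0, 1]` for a
#'   mean-field pass), one pattern per row.
#' @param sample draw Poisson counts.
#' @param log_ceiling cap on `W' m + b_u`.
#' @return List with `lam` (means) and `u` (counts, or `lam` when not
#'   sampling).
#' @export
down_pass <- function(net, M, sample = TRUE, log_ceiling = 10) {
  if (is.null(dim(M))) M <- matrix(M, nrow = 1)
  if (ncol(M) != nrow(net$W)) {
    abort(sprintf("upper-layer activity has %d columns, network expects %d",
                  ncol(M), nrow(net$W)))
  }
  A <- M %*% net$W
  A <- sweep(A, 2, net$b_u, "+")
  if (any(A > log_ceiling)) {
    warn(sprintf("down-pass means clipped at exp(%g) for %d unit activations",
                 log_ceiling, sum(A > log_ceiling)))
    A <- pmin(A, log_ceiling)
  }
  lam <- exp(A)
  u <- if (sample) matrix(rpois(length(lam), lam), nrow(lam)) else lam
  list(lam = lam, u = u)
}

#' One-step contrastive divergence update
#'
#' For each pattern in the batch: sample the upper layer from the data
#' (`m0`), reconstruct the lower layer by a sampled down pass (`u1`, the
#' confabulation), and sample the upper layer again (`m1`). Weights change
#' by the difference of phase correlations averaged over the batch:
#' `dW = eta * (<m0' u0> - <m1' u1>)`, with matching bias updates. The
#' confabulation-phase statistics use sampled binary upper states by
#' default (`use_mean_m = TRUE` substitutes the Bernoulli means).
#'
#' @param net a [pps_rbm()].
#' @param U0 batch of encoded lower-layer activity, patterns x units.
#' @param eta learning rate.
#' @param use_mean_m use `mu` instead of sampled `m` in the update
#'   statistics.
#' @return The updated `pps_rbm`, with a one-row tibble of batch
#'   statistics (reconstruction error, mean absolute update) in
#'   `attr(, "stats")`.
#' @export
cd1_update <- function(net, U0, eta = 0.005, use_mean_m = FALSE) {
  U0 <- .check_u(net, U0)
  if (nrow(U0) == 0) abort("batch is empty")
  if (eta <= 0) abort("eta must be positive")
  B <- nrow(U0)
  up0 <- up_pass(net, U0, sample = TRUE)
  m0 <- if (use_mean_m) up0$mu else up0$m
  dn <- down_pass(net, up0$m, sample = TRUE)
  U1 <- dn$u
  up1 <- up_pass(net, U1, sample = TRUE)
  m1 <- if (use_mean_m) up1$mu else up1$m
  dW <- eta * (crossprod(m0, U0) - crossprod(m1, U1)) / B
  db_u <- eta * colMeans(U0 - U1)
  db_m <- eta * colMeans(m0 - m1)
  if (any(!is.finite(dW)) || any(!is.finite(db_u)) || any(!is.finite(db_m))) {
    abort(c("non-finite contrastive-divergence update",
            sprintf("max |W| = %g, max |b_u| = %g, max |b_m| = %g",
                    max(abs(net$W)), max(abs(net$b_u)), max(abs(net$b_m)))))
  }
  net$W <- net$W + dW
  net$b_u <- net$b_u + db_u
  net$b_m <- net$b_m + db_m
  attr(net, "stats") <- tibble(
    recon_error = mean((U0 - U1)^2),
    mean_abs_dw = mean(abs(dW))
  )
  net
}

.resolve_mask <- function(net, mask) {
  if (length(mask) == 0) return(integer(0))
  if (is.null(net$pops)) abort("masking requires a network built from pps_populations")
  bad <- setdiff(mask, names(net$pops$slices))
  if (length(bad)) {
    abort(sprintf("unknown population mask '%s'; available: %s",
                  paste(bad, collapse = ", "),
                  paste(names(net$pops$slices), collapse = ", ")))
  }
  unlist(net$pops$slices[mask], use.names = FALSE)
}

#' Reconstruct lower-layer activity through the multisensory layer
#'
#' One up pass followed by a mean-mode down pass: the read-out of the
#' integrated information held in the multisensory layer. Selected
#' population slices of the input can be zeroed (masked) before the up
#' pass, e.g. the tactile slice when measuring evoked tactile activity,
#' or the hand-visual slice when simulating an occluded hand.
#'
#' @param net a [pps_rbm()].
#' @param U lower-layer activity, patterns x units.
#' @param mask character vector of population names to zero out.
#' @param sample_up sample the upper layer (`TRUE`) or use the mean field.
#' @return Matrix of reconstructed Poisson means `lam`, patterns x units.
#' @export
reconstruct <- function(net, U, mask = character(), sample_up = FALSE) {
  U <- .check_u(net, U)
  idx <- .resolve_mask(net, mask)
  if (length(idx)) U[, idx] <- 0
  up <- up_pass(net, U, sample = sample_up)
  down_pass(net, up$m, sample = FALSE)$lam
}

#' Reconstruction error of a batch
#'
#' Mean squared difference between the original lower-layer activity and
#' its confabulation (sampled up pass, sampled down pass), averaged over
#' units and patterns; the quantity tracked across training epochs.
#'
#' @param net a [pps_rbm()].
#' @param U batch of lower-layer activity.
#' @return Nonnegative scalar.
#' @export
reconstruction_error <- function(net, U) {
  U <- .check_u(net, U)
  up <- up_pass(net, U, sample = TRUE)
  U1 <- down_pass(net, up$m, sample = TRUE)$u
  mean((U - U1)^2)
}
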