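toy_net <- function(n_multi, n_low, W = matrix(0, n_multi, n_low),
                    b_u = rep(0, n_low), b_m = rep(0, n_multi)) {
  net <- pps_rbm(n_low, n_multi = n_multi, init_sd = 0)
  net$W <- W; net$b_u <- b_u; net$b_m <- b_m
  net
}

test_that("up pass is the logistic of the weighted input", {
  net <- toy_net(3, 4)
  up <- up_pass(net, c(1, 2, 3, 4), sample = FALSE)
  expect_equal(up$mu, matrix(0.5, 1, 3))
  # scalar oracle
  net1 <- toy_net(1, 1, W = matrix(0.7, 1, 1))
  expect_equal(up_pass(net1, 3, sample = FALSE)$mu[1, 1],
               1 / (1 + exp(-0.7 * 3)))
  # saturation
  net2 <- toy_net(1, 1, b_m = -50)
  expect_lt(up_pass(net2, 0, sample = FALSE)$mu[1, 1], 1e-20)
  set.seed(1)
  s <- up_pass(net, matrix(1, 200, 4), sample = TRUE)
  expect_true(all(s$m %in% c(0, 1)))
})

test_that("down pass is the exponential of the transposed weights", {
  net <- toy_net(3, 4)
  dn <- down_pass(net, c(1, 0, 1), sample = FALSE)
  expect_equal(dn$lam, matrix(1, 1, 4))
  net2 <- toy_net(2, 2, b_u = log(c(3, 5)))
  expect_equal(down_pass(net2, c(0, 0), sample = FALSE)$lam[1, ], c(3, 5))
  net3 <- toy_net(1, 1, W = matrix(0.4, 1, 1), b_u = 0.2)
  expect_equal(down_pass(net3, 1, sample = FALSE)$lam[1, 1], exp(0.6))
  # feedback uses the transpose of the feedforward matrix
  net4 <- toy_net(2, 3, W = matrix(1:6, 2, 3) / 10)
  m <- c(1, 1)
  expect_equal(down_pass(net4, m, sample = FALSE)$lam[1, ],
               exp(as.numeric(t(net4$W) %*% m)))
  expect_warning(down_pass(toy_net(1, 1, b_u = 20), 0, sample = FALSE),
                 "clipped")
})

test_that("dimension mismatches name the expected populations", {
  pops <- pps_populations("constrained", visual_grid = c(10, 10))
  net <- pps_rbm(pops, n_multi = 5)
  expect_error(up_pass(net, rep(0, 7)), "visual\\[100\\]")
  expect_error(down_pass(net, rep(0, 7)), "expects 5")
  expect_error(reconstruct(net, rep(0, pops$n_low), mask = "auditory"),
               "unknown population mask")
})

test_that("a CD-1 step matches a hand-computed update on a saturated toy net", {
  # probabilities driven to 0/1 so every sampled quantity is deterministic:
  # mu0 = mu1 = 1 (huge bias), lam = exp(-50) so u1 = 0 almost surely
  eta <- 0.01
  net <- toy_net(2, 2, W = matrix(0, 2, 2), b_u = c(-50, -50),
                 b_m = c(50, 50))
  u0 <- matrix(c(3, 1), 1, 2)
  set.seed(99)
  upd <- cd1_update(net, u0, eta = eta)
  # m0 = (1,1), u1 = (0,0), m1 = (1,1):
  # dW = eta (m0' u0 - m1' u1) = eta * [3 1; 3 1]
  expect_equal(upd$W, eta * matrix(c(3, 3, 1, 1), 2, 2))
  expect_equal(upd$b_u, net$b_u + eta * c(3, 1))
  expect_equal(upd$b_m, net$b_m + c(0, 0))
  expect_equal(attr(upd, "stats")$recon_error, mean(c(9, 1)))
})

test_that("identical data and confabulation phases cancel exactly", {
  # with all-zero input and lam = exp(-50) ~ 0 the reconstruction equals
  # the data, whatever the sampled hidden states
  net <- toy_net(3, 2, W = matrix(0.1, 3, 2), b_u = c(-50, -50))
  set.seed(3)
  upd <- cd1_update(net, matrix(0, 5, 2), eta = 0.005)
  expect_equal(upd$b_u, net$b_u)
  expect_equal(attr(upd, "stats")$recon_error, 0)
})

test_that("mean-mode pipeline is deterministic", {
  pops <- pps_populations("constrained", visual_grid = c(8, 8))
  set.seed(10)
  net <- pps_rbm(pops, n_multi = 6)
  w <- sample_constrained(5, seed = 2)
  U <- encode_world(pops, w, sample = FALSE)
  r1 <- reconstruct(net, U, mask = "tactile")
  r2 <- reconstruct(net, U, mask = "tactile")
  expect_identical(r1, r2)
})

## exact log-likelihood of a tiny Poisson-Bernoulli RBM by enumeration:
## unnormalized log p(u, m) = b_u.u + b_m.m + m'Wu - sum(log u!)
toy_loglik <- function(net, patterns, K = 12) {
  ms <- as.matrix(expand.grid(rep(list(0:1), nrow(net$W))))
  us <- as.matrix(expand.grid(rep(list(0:K), ncol(net$W))))
  logw <- function(u, m) {
    sum(net$b_u * u) + sum(net$b_m * m) + as.numeric(m %*% net$W %*% u) -
      sum(lgamma(u + 1))
  }
  all_lw <- apply(us, 1, function(u) {
    vapply(seq_len(nrow(ms)), function(i) logw(u, ms[i, ]), numeric(1))
  })
  logZ <- log(sum(exp(all_lw - max(all_lw)))) + max(all_lw)
  sum(apply(patterns, 1, function(u) {
    lw <- vapply(seq_len(nrow(ms)), function(i) logw(u, ms[i, ]), numeric(1))
    log(sum(exp(lw - max(lw)))) + max(lw) - logZ
  }))
}

test_that("CD-1 training raises the exact likelihood of a toy dataset", {
  set.seed(42)
  net <- pps_rbm(3, n_multi = 2, init_sd = 0.001)
  patterns <- rbind(c(4, 0, 0), c(0, 0, 4))
  ll0 <- toy_loglik(net, patterns)
  batch <- patterns[rep(1:2, each = 10), ]
  for (i in 1:300) net <- cd1_update(net, batch, eta = 0.01)
  ll1 <- toy_loglik(net, patterns)
  expect_gt(ll1, ll0)
})

test_that("reconstruction error is nonnegative and zero for a perfect copy", {
  net <- toy_net(2, 3, b_u = c(-50, -50, -50))
  set.seed(6)
  expect_equal(reconstruction_error(net, matrix(0, 4, 3)), 0)
  pops <- pps_populations("constrained", visual_grid = c(8, 8))
  set.seed(7)
  net2 <- pps_rbm(pops, n_multi = 5)
  U <- encode_world(pops, sample_constrained(20, seed = 3))
  expect_gte(reconstruction_error(net2, U), 0)
})

test_that("masking zeroes the requested slice before the up pass", {
  pops <- pps_populations("constrained", visual_grid = c(8, 8))
  set.seed(8)
  net <- pps_rbm(pops, n_multi = 6, init_sd = 0.1)
  w <- sample_constrained(3, seed = 4)
  w$touch <- TRUE
  U <- encode_world(pops, w, sample = FALSE)
  U_masked <- U
  U_masked[, pops$slices$tactile] <- 0
  expect_equal(reconstruct(net, U, mask = "tactile"),
               reconstruct(net, U_masked, mask = character()))
})
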