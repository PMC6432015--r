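# Free and conditioned mode-space dynamics.

zero_noise <- function(N) matrix(0 + 0i, N, 3)

test_that("noise-free free step decays each mode by (1 - lambda dt)", {
  p <- params_small(N = 8, lP = 1)
  m <- to_modes(random_ring(8, seed = 1))
  lambda <- mode_relaxation_rate(0:7, p)
  dt <- 1e-3
  stepped <- step_free(m, p, dt, noise = zero_noise(8))
  expect_equal(unclass(stepped), unclass(m) * (1 - lambda * dt), tolerance = 1e-12)
  # p = 0 is pure diffusion: no drift at all
  expect_equal(stepped[1, ], m[1, ], tolerance = 1e-15)
})

test_that("small-rate limit of the bridge drift equals the Brownian-bridge pull", {
  # lambda -> 0: -l x + l/sinh(l tau) (f - x e^{-l tau}) -> (f - x)/tau
  tau <- 0.37
  x <- 1.3
  f <- -0.4
  coef <- knotbridge:::ou_pull_coef(c(0, 1e-12, 1e-6), tau)
  drift <- -c(0, 1e-12, 1e-6) * x + coef * (f - x * exp(-c(0, 1e-12, 1e-6) * tau))
  expect_equal(drift, rep((f - x) / tau, 3), tolerance = 1e-6)
  # and the coefficient is stable for huge arguments (no overflow, decays to 0)
  expect_equal(knotbridge:::ou_pull_coef(500, 2), 0, tolerance = 1e-200)
  expect_false(any(!is.finite(knotbridge:::ou_pull_coef(c(1e-30, 1, 1e4), 2))))
})

test_that("noise-free bridge follows the conditioned mean and reaches the target", {
  p <- params_small(N = 8, lP = 1)
  m0 <- to_modes(random_ring(8, seed = 2))
  mf <- to_modes(random_ring(8, seed = 3))
  tf <- 0.5
  dt <- 5e-4
  lambda <- mode_relaxation_rate(0:7, p)
  m <- m0
  M <- round(tf / dt)
  for (k in 0:(M - 2)) {
    m <- step_bridge(m, mf, k * dt, tf, p, dt, noise = zero_noise(8))
  }
  # closed-form conditioned mean at t = tf - dt, mode by mode
  t1 <- tf - dt
  for (pp in c(0, 1, 3, 4)) {
    mom <- ou_bridge_moments(Re(unclass(m0)[pp + 1, 1]), Re(unclass(mf)[pp + 1, 1]),
                             t1, tf, lambda[pp + 1], Dx = 1)
    expect_equal(Re(unclass(m)[pp + 1, 1]), mom$mean, tolerance = 2e-2)
  }
  # the final Euler step lands on the target up to O(dt)
  m_end <- step_bridge(m, mf, tf - dt, tf, p, dt, noise = zero_noise(8))
  expect_equal(unclass(m_end)[1, ], unclass(mf)[1, ], tolerance = 1e-12) # p=0 exact
  expect_lt(max(abs(unclass(m_end) - unclass(mf))), 5e-3)
})

test_that("deterministic bridge discretization error scales as O(dt)", {
  p <- params_small(N = 8, lP = 1)
  m0 <- to_modes(random_ring(8, seed = 2))
  mf <- to_modes(random_ring(8, seed = 3))
  tf <- 0.5
  lambda <- mode_relaxation_rate(0:7, p)
  err_at_half <- function(dt) {
    m <- m0
    for (k in 0:(round(tf / (2 * dt)) - 1)) {
      m <- step_bridge(m, mf, k * dt, tf, p, dt, noise = zero_noise(8))
    }
    mom <- ou_bridge_moments(Re(unclass(m0)[2, 1]), Re(unclass(mf)[2, 1]),
                             tf / 2, tf, lambda[2], Dx = 1)
    abs(Re(unclass(m)[2, 1]) - mom$mean)
  }
  e1 <- err_at_half(2e-3)
  e2 <- err_at_half(1e-3)
  expect_gt(e1 / e2, 1.5)
  expect_lt(e1 / e2, 3)
})

test_that("permutation weights match a first-principles density product (N = 8)", {
  p <- params_small(N = 8, lP = 1.5)
  ri <- random_ring(8, seed = 5)
  rf <- random_ring(8, seed = 6)
  t <- 0.3
  tf <- 0.6
  w <- permutation_weights(to_modes(ri), to_modes(rf), t, tf, p)
  w_ref <- naive_perm_weights(ri, rf, t, tf, p)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(as.numeric(w), as.numeric(w_ref), tolerance = 1e-8)
})

test_that("R and compiled weight/drift computations agree", {
  p <- params_small(N = 12, lP = 2)
  m <- to_modes(random_ring(12, seed = 8))
  mf <- to_modes(random_ring(12, seed = 9))
  t <- 0.1
  tf <- 0.4
  lambda <- mode_relaxation_rate(0:11, p)
  dbg <- knotbridge:::cpp_bridge_debug(unclass(m), unclass(mf), lambda, p$D,
                                       t, tf, 0:11)
  w_r <- permutation_weights(m, mf, t, tf, p)
  expect_equal(as.numeric(dbg$weights), as.numeric(w_r), tolerance = 1e-10)
  stepped <- step_bridge_permuted(m, mf, t, tf, p, 1e-3, noise = zero_noise(12))
  drift_r <- (unclass(stepped) - unclass(m)) / 1e-3
  expect_equal(unclass(dbg$drift), drift_r, tolerance = 1e-8)
})

test_that("weights concentrate on the matching permutation as t -> tf", {
  p <- params_small(N = 8, lP = 1.5)
  rf <- random_ring(8, seed = 10)
  current <- cyclic_shift(rf, 5)  # state equals permutation n0 = 5 exactly
  w <- permutation_weights(to_modes(current), to_modes(rf), 0.999, 1, p)
  expect_equal(which.max(w) - 1L, 5L)
  expect_gt(w[6], 1 - 1e-9)
  # identical targets (all permutations coincide) give exactly uniform weights
  rf0 <- ring(matrix(0.3, 8, 3))
  w0 <- permutation_weights(to_modes(random_ring(8, seed = 11)), to_modes(rf0),
                            0.2, 1, p)
  expect_equal(as.numeric(w0), rep(1 / 8, 8), tolerance = 1e-12)
})

test_that("single-permutation run is bit-identical to the plain bridge", {
  p <- params_small(N = 16, lP = 2)
  set.seed(12)
  ri <- sample_gaussian_equilibrium(p, 1)[[1]]
  rf <- sample_gaussian_equilibrium(p, 1)[[1]]
  tr1 <- run_bridge(ri, rf, p, dt = 1e-3, tf = 0.3, conditioning = "bridge",
                    seed = 77, frame_stride = 50)
  tr2 <- run_bridge(ri, rf, p, dt = 1e-3, tf = 0.3,
                    conditioning = "bridge_permuted", seed = 77,
                    frame_stride = 50, permutations = 0L)
  expect_identical(lapply(tr1$frames, unclass), lapply(tr2$frames, unclass))
})

test_that("conditioned runs pin the endpoints exactly; reversal is a valid bridge", {
  p <- params_small(N = 16, lP = 2)
  set.seed(13)
  ri <- sample_gaussian_equilibrium(p, 1)[[1]]
  rf <- sample_gaussian_equilibrium(p, 1)[[1]]
  tr <- run_bridge(ri, rf, p, dt = 1e-3, tf = 0.4, seed = 5)
  expect_equal(unclass(tr$frames[[1]]), unclass(ri), tolerance = 1e-14)
  expect_lt(max(abs(unclass(tr$frames[[length(tr$frames)]]) - unclass(rf))), 1e-9)
  # permuted: lands on some cyclic shift
  trp <- run_bridge(ri, rf, p, dt = 1e-3, tf = 0.4,
                    conditioning = "bridge_permuted", seed = 6)
  lf <- trp$frames[[length(trp$frames)]]
  devs <- vapply(0:15, function(n0)
    max(abs(unclass(lf) - unclass(cyclic_shift(rf, n0)))), numeric(1))
  expect_lt(min(devs), 1e-9)
  expect_identical(which.min(devs) - 1L, as.integer(trp$landed_perm))
  # the time-reversed problem is a legitimate bridge too
  trr <- run_bridge(rf, ri, p, dt = 1e-3, tf = 0.4, seed = 7)
  expect_lt(max(abs(unclass(trr$frames[[length(trr$frames)]]) - unclass(ri))), 1e-9)
})

test_that("trajectory bookkeeping: times grid, stride, strictly increasing", {
  p <- params_small(N = 16, lP = 1)
  set.seed(14)
  ri <- sample_gaussian_equilibrium(p, 1)[[1]]
  rf <- sample_gaussian_equilibrium(p, 1)[[1]]
  tr <- run_bridge(ri, rf, p, dt = 1e-4, tf = 2, seed = 8, frame_stride = 2000)
  expect_equal(tr$times, seq(0, 2, by = 0.2), tolerance = 1e-9)
  expect_true(all(diff(tr$times) > 0))
  expect_error(run_bridge(ri, rf, p, dt = 3e-4, tf = 1, seed = 1), "divide")
})

test_that("free centre-of-mass mode diffuses with variance 2 D t / N", {
  p <- params_small(N = 4, lP = 0.5)
  start <- ring(matrix(0, 4, 3) + 0)
  nrep <- 400
  finals <- vapply(seq_len(nrep), function(i) {
    tr <- run_bridge(start, NULL, p, dt = 1e-3, tf = 0.5, conditioning = "free",
                     seed = 1000 + i, frame_stride = 1e6)
    Re(unclass(to_modes(tr$frames[[length(tr$frames)]]))[1, 1])
  }, numeric(1))
  v_th <- 2 * p$D * 0.5 / 4
  expect_lt(abs(mean(finals)), 3 * sqrt(v_th / nrep))
  expect_lt(abs(var(finals) - v_th), 3 * v_th * sqrt(2 / (nrep - 1)))
})
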