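# Calibration of (a, K) and the chain potential.

# independent brute-force evaluation of the mean-square-bond mode sum
brute_S <- function(N, kappa) {
  s <- 0
  for (p in 1:(N - 1)) s <- s + 1 / (1 + 2 * kappa * (1 - cos(2 * pi * p / N)))
  s / N
}

test_that("flexible limit: lP = 0 gives kappa = 0, K = 0 and a = b/sqrt(S)", {
  for (N in c(6, 240)) {
    sol <- solve_chain_parameters(N, b = 2, lP = 0)
    expect_identical(sol$kappa, 0)
    expect_identical(sol$K, 0)
    # S excludes the centre-of-mass mode, so S = (N-1)/N in this limit
    expect_equal(sol$S, (N - 1) / N, tolerance = 1e-14)
    expect_equal(sol$a, 2 / sqrt((N - 1) / N), tolerance = 1e-12)
  }
})

test_that("calibration matches a literal brute-force mode sum (round trip 1e-10)", {
  for (case in list(list(N = 240, b = 1, lP = 5), list(N = 6, b = 2, lP = 1),
                    list(N = 51, b = 0.5, lP = 3.3))) {
    sol <- solve_chain_parameters(case$N, case$b, case$lP)
    S <- brute_S(case$N, sol$kappa)
    expect_equal(sol$a^2 * S, case$b^2, tolerance = 1e-10)
    expect_equal(sol$K, 3 * sol$kappa / sol$a^2, tolerance = 1e-12)
  }
})

test_that("stiffness inverts the exact bond-correlation decay relation", {
  # kappa solves cosh(b/lP) = 1 + 1/(2 kappa): decay length of the mode-sum
  # pole equals lP; large lP behaves as (lP/b)^2
  sol <- solve_chain_parameters(240, b = 1, lP = 5)
  expect_equal(acosh(1 + 1 / (2 * sol$kappa)), 1 / 5, tolerance = 1e-12)
  sol2 <- solve_chain_parameters(240, b = 1, lP = 50)
  expect_equal(sol2$kappa / 50^2, 1, tolerance = 1e-3)
})

test_that("inputs are validated", {
  expect_error(solve_chain_parameters(2, 1, 1))
  expect_error(solve_chain_parameters(10, -1, 1))
  expect_error(solve_chain_parameters(10, 1, -1))
  expect_error(chain_parameters(10, 1, 1, D = 0))
})

test_that("potential energy equals a term-by-term independent re-summation", {
  p <- params_small(N = 8, lP = 1.2)
  r <- random_ring(8, seed = 3)
  # literal double sum with periodic wrap, written independently
  u_ref <- 0
  x <- unclass(r)
  for (n in 1:8) {
    np <- if (n == 8) 1 else n + 1
    nm <- if (n == 1) 8 else n - 1
    u_ref <- u_ref + 3 / (2 * p$a^2) * sum((x[np, ] - x[n, ])^2) +
      p$K / 2 * sum((x[np, ] - 2 * x[n, ] + x[nm, ])^2)
  }
  expect_equal(potential_energy(r, p), u_ref, tolerance = 1e-12)
})

test_that("energy: zero for coincident beads, invariant under rigid motions", {
  p <- params_small(N = 12, lP = 1.5)
  r0 <- ring(matrix(1, 12, 3))
  expect_equal(potential_energy(r0, p), 0)
  r <- random_ring(12, seed = 7)
  u <- potential_energy(r, p)
  shifted <- ring(sweep(unclass(r), 2, c(3.2, -1.1, 0.7), `+`))
  expect_equal(potential_energy(shifted, p), u, tolerance = 1e-10)
  rot <- random_rotation(2)
  rotated <- ring(unclass(r) %*% rot)
  expect_equal(potential_energy(rotated, p), u, tolerance = 1e-10)
  expect_error(potential_energy(random_ring(10), p), "beads")
})

test_that("persistence length estimator recovers the calibrated lP", {
  p <- chain_parameters(N = 120, b = 1, lP = 3)
  set.seed(42)
  rings <- sample_gaussian_equilibrium(p, 800)
  est <- persistence_length_estimate(rings)
  expect_lt(abs(est$lP - 3), 3 * est$se)
  expect_gt(est$se, 0)
  # doubling lP doubles the estimate (two-point check)
  p2 <- chain_parameters(N = 120, b = 1, lP = 6)
  set.seed(43)
  est2 <- persistence_length_estimate(sample_gaussian_equilibrium(p2, 800))
  expect_lt(abs(est2$lP - 6), 3 * est2$se)
  expect_equal(est2$lP / est$lP, 2, tolerance = 0.1)
  expect_error(persistence_length_estimate(rings[1:10]), "at least 100")
})

test_that("flexible chains show no tangent correlation beyond s = 0", {
  p <- chain_parameters(N = 60, b = 1, lP = 0)
  set.seed(5)
  rings <- sample_gaussian_equilibrium(p, 400)
  u <- bond_vectors(rings[[1]])
  # direct check: neighbour bond correlation is zero within MC error
  cors <- vapply(rings, function(r) {
    u <- bond_vectors(r)
    mean(rowSums(u * u[c(2:60, 1), ]))
  }, numeric(1))
  expect_lt(abs(mean(cors)) / (sd(cors) / sqrt(length(cors))), 4)
})
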