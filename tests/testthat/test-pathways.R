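# RMSD, contour rescaling, per-frame reports and ensembles.

test_that("rmsd: zero for identical rings, |d| under translation, Kabsch bound", {
  r <- random_ring(20, seed = 1)
  expect_equal(rmsd(r, r), 0)
  d <- c(3, -4, 0) # |d| = 5
  rt <- ring(sweep(unclass(r), 2, d, `+`))
  expect_equal(rmsd(r, rt), 5, tolerance = 1e-12)
  expect_lt(rmsd(r, rt, superpose = TRUE), 1e-9)
  r2 <- random_ring(20, seed = 2)
  expect_lte(rmsd(r, r2, superpose = TRUE), rmsd(r, r2) + 1e-12)
  expect_error(rmsd(r, random_ring(10, seed = 1)), "bead counts")
})

test_that("contour rescaling: identity, proportional bonds, topology safe", {
  r <- parametric_knot("3_1", N = 100, verify = FALSE)
  L <- contour_length(r)
  expect_equal(unclass(rescale_contour(r, L)), unclass(r), tolerance = 1e-12)
  r2 <- rescale_contour(r, 2 * L)
  expect_equal(sqrt(rowSums(bond_vectors(r2)^2)),
               2 * sqrt(rowSums(bond_vectors(r)^2)), tolerance = 1e-10)
  set.seed(3)
  expect_identical(knot_type(r2)$label, "3_1")
  expect_error(rescale_contour(r, -1))
})

test_that("report on a short unknotted bridge is internally consistent", {
  p <- chain_parameters(N = 48, b = 1, lP = 2)
  set.seed(4)
  ri <- mc_equilibrate(parametric_knot("0_1", N = 48, verify = FALSE),
                       p, 50, verify_knot = FALSE)$ring
  rf <- mc_equilibrate(parametric_knot("0_1", N = 48, verify = FALSE),
                       p, 50, verify_knot = FALSE)$ring
  tr <- run_bridge(ri, rf, p, dt = 2e-4, tf = 0.2,
                   conditioning = "bridge_permuted", seed = 11, frame_stride = 100)
  set.seed(5)
  rep <- build_report(tr, stride = 1, n_proj = 120)
  tab <- rep$table
  expect_identical(nrow(tab), length(tr$frames))
  expect_equal(tab$rmsd_initial[1], 0)
  expect_equal(tab$rmsd_final[nrow(tab)], 0, tolerance = 1e-9)
  # bands partition [0, tf]
  expect_equal(rep$bands$t_start[1], 0)
  expect_equal(rep$bands$t_end[nrow(rep$bands)], tr$tf)
  # short unknot-to-unknot bridge stays trivial
  expect_true(all(tab$knot == "0_1"))
  expect_false(rep$summary$exceeds_endpoints)
  # projection observables present and sane: <nc> >= |<Wr>|
  expect_true(all(tab$acn >= abs(tab$writhe_proj) - 1e-9))
})

test_that("degenerate single-trajectory ensemble gives 0/1 fractions", {
  p <- chain_parameters(N = 48, b = 1, lP = 2)
  set.seed(6)
  ri <- mc_equilibrate(parametric_knot("0_1", N = 48, verify = FALSE),
                       p, 40, verify_knot = FALSE)$ring
  rf <- mc_equilibrate(parametric_knot("0_1", N = 48, verify = FALSE),
                       p, 40, verify_knot = FALSE)$ring
  ens <- ensemble_experiment(list(list(initial = ri, final = rf)), n_traj = 1,
                             params = p, dt = 2e-4, tf = 0.2, seed = 3,
                             frame_stride = 200, stride = 1)
  expect_true(all(ens$fraction_visiting %in% c(0, 1)))
  expect_true(ens$frac_complex %in% c(0, 1))
  # sum rule: complex intermediates are a subset of nontrivial intermediates
  expect_lte(ens$frac_complex, ens$frac_nontrivial_intermediate + 1e-12)
})

test_that("XYZ round trip preserves a trajectory's frames and times", {
  p <- chain_parameters(N = 16, b = 1, lP = 1)
  set.seed(7)
  ri <- sample_gaussian_equilibrium(p, 1)[[1]]
  rf <- sample_gaussian_equilibrium(p, 1)[[1]]
  tr <- run_bridge(ri, rf, p, dt = 1e-3, tf = 0.2, seed = 2, frame_stride = 50)
  f <- tempfile(fileext = ".xyz")
  write_xyz(tr$frames, f, times = tr$times)
  back <- read_xyz(f)
  expect_identical(length(back), length(tr$frames))
  expect_equal(attr(back, "times"), tr$times)
  expect_equal(unclass(back[[3]]), unclass(tr$frames[[3]]), tolerance = 1e-10)
  unlink(f)
})
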