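# Knot identification, Alexander determinants, writhe, crossing numbers.

test_that("planar circle: no crossings, unknot, zero writhe and ACN", {
  t <- 2 * pi * (0:39) / 40
  circ <- ring(cbind(cos(t), sin(t), 0))
  set.seed(1)
  dg <- project_diagram(circ)
  expect_identical(dg$n, 0L)
  expect_equal(alexander_determinants(dg), c(det1 = 1, det2 = 1))
  kt <- knot_type(circ)
  expect_identical(kt$label, "0_1")
  expect_equal(writhe(circ, "gauss"), 0, tolerance = 1e-9)
  expect_equal(as.numeric(writhe(circ, "projections", 50)), 0)
  expect_equal(as.numeric(average_crossing_number(circ, 50)), 0)
})

test_that("axis projection of the (2,3) torus curve has 3 same-sign crossings", {
  r <- parametric_knot("3_1", N = 90, verify = FALSE)
  dg <- project_diagram(r, direction = c(0, 0, 1))
  expect_identical(dg$n, 3L)
  expect_identical(length(unique(dg$crossings$sign)), 1L)
  expect_equal(alexander_determinants(dg), c(det1 = 3, det2 = 7))
})

test_that("determinant pairs of the parametric fixtures match the polynomial oracle", {
  # |Delta(-1)|, |Delta(-2)| evaluated from the tabulated Alexander polynomials
  oracle <- list("0_1" = c(1, 1), "3_1" = c(3, 7), "4_1" = c(5, 11),
                 "5_1" = c(5, 31), "5_2" = c(7, 16), "7_1" = c(7, 127))
  set.seed(2)
  for (lab in names(oracle)) {
    r <- parametric_knot(lab, N = 140, verify = FALSE)
    kt <- knot_type(r)
    expect_identical(kt$label, lab)
    expect_identical(c(kt$det1, kt$det2), oracle[[lab]])
  }
})

test_that("determinants are invariant across independent generic projections", {
  set.seed(3)
  r <- parametric_knot("5_2", N = 140, verify = FALSE)
  dets <- replicate(10, alexander_determinants(project_diagram(r)))
  expect_true(all(dets[1, ] == 7))
  expect_true(all(dets[2, ] == 16))
})

test_that("knot label is invariant under rigid motions, scaling, re-indexing", {
  set.seed(4)
  r <- parametric_knot("4_1", N = 120, verify = FALSE)
  rot <- random_rotation(5)
  variants <- list(
    ring(unclass(r) %*% rot),
    ring(sweep(unclass(r), 2, c(5, -3, 11), `+`)),
    ring(unclass(r) * 7.3),
    cyclic_shift(r, 41))
  for (v in variants) expect_identical(knot_type(v)$label, "4_1")
})

test_that("mirror image: same determinants, flipped crossing signs and writhe", {
  set.seed(6)
  r <- parametric_knot("3_1", N = 100, chirality = "left", verify = FALSE)
  m <- unclass(r)
  m[, 3] <- -m[, 3]
  rm <- ring(m)
  d <- c(0.3, -0.2, 0.93)
  dg <- project_diagram(r, d)
  dgm <- project_diagram(rm, d * c(1, 1, -1))
  expect_identical(dg$n, dgm$n)
  expect_equal(sum(dg$crossings$sign), -sum(dgm$crossings$sign))
  expect_equal(writhe(r, "gauss"), -writhe(rm, "gauss"), tolerance = 1e-9)
  expect_identical(knot_type(r)$label, knot_type(rm)$label)
  expect_identical(knot_type(r)$chirality, "left")
  expect_identical(knot_type(rm)$chirality, "right")
})

test_that("projection-averaged writhe agrees with the exact Gauss integral", {
  set.seed(7)
  r <- random_ring(30, seed = 12)
  wg <- writhe(r, "gauss")
  wp <- writhe(r, "projections", 1500)
  expect_lt(abs(wp - wg), 3 * attr(wp, "se"))
  # torus knot too
  r2 <- parametric_knot("3_1", N = 80, verify = FALSE)
  wp2 <- writhe(r2, "projections", 1000)
  expect_lt(abs(wp2 - writhe(r2, "gauss")), 3 * attr(wp2, "se"))
})

test_that("ACN bounds |writhe| when evaluated over the same directions", {
  set.seed(8)
  r <- random_ring(24, seed = 9)
  cnt <- knotbridge:::crossing_counts(r, 300)
  expect_true(all(cnt[, 1] + cnt[, 2] >= abs(cnt[, 1] - cnt[, 2])))
  acn <- mean(cnt[, 1] + cnt[, 2])
  expect_gte(acn, abs(mean(cnt[, 1] - cnt[, 2])))
})

test_that("ACN of the trefoil is stable between 1000 and 4000 projections", {
  set.seed(9)
  r <- parametric_knot("3_1", N = 80, verify = FALSE)
  e1 <- average_crossing_number(r, 1000)
  e2 <- average_crossing_number(r, 4000)
  # estimates agree within their Monte Carlo error, which is itself < 2%
  expect_lt(abs(e1 - e2), 3 * sqrt(attr(e1, "se")^2 + attr(e2, "se")^2))
  expect_lt(attr(e1, "se") / as.numeric(e2), 0.02)
})

test_that("determinant table is injective and labels encode crossing numbers", {
  tab <- knotbridge:::knot_det_table()
  expect_false(anyDuplicated(paste(tab$det1, tab$det2)) > 0)
  expect_identical(label_crossings(c("0_1", "3_1", "7_4")), c(0L, 3L, 7L))
  expect_true(is.na(label_crossings("unresolved")))
})

test_that("composite or unknown determinant pairs report 'unresolved'", {
  # granny knot (3_1 # 3_1): Delta = (t^2 - t + 1)^2 -> (9, 49), not in table
  set.seed(10)
  r3 <- parametric_knot("3_1", N = 100, verify = FALSE)
  a <- unclass(r3) / (2 * max(abs(unclass(r3)))) # shrink into a unit-ish ball
  rot <- random_rotation(55)
  b <- a %*% rot
  b[, 1] <- b[, 1] + 2.5 # disjoint rotated copy
  # connect-sum: open each copy at its extreme-x bead and join the strands
  a2 <- unclass(cyclic_shift(ring(a), which.max(a[, 1]) - 1L))
  b2 <- unclass(cyclic_shift(ring(b), which.min(b[, 1]) - 1L))
  comp <- ring(rbind(a2, b2[nrow(b2):1, ]))
  kt <- knot_type(comp)
  expect_identical(kt$label, "unresolved")
  expect_identical(c(kt$det1, kt$det2), c(9, 49))
})
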