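#' Parametric ring initializers of prescribed knot type
#'
#' Closed curves of known topology, discretized to N beads and rescaled to a
#' target contour length: the unknot (planar circle), the (2,q) torus knots
#' 3_1, 5_1, 7_1 (drawable without self-intersection on a torus), the
#' figure-eight knot 4_1 (achiral), and the twist knot 5_2 (three half-twists
#' closed by a clasp, built from a verified Fourier parametrization).
#' The returned polygon's knot type is verified with [knot_type()] unless
#' `verify = FALSE`; chirality is imposed by mirroring (z -> -z) when the
#' Gauss writhe sign disagrees with the request.
#'
#' @param label one of "0_1", "3_1", "4_1", "5_1", "5_2", "7_1".
#' @param N number of beads.
#' @param chirality "right" (positive writhe), "left", or NULL (as built);
#'   ignored for the achiral 0_1 and 4_1.
#' @param contour target contour length (default N, i.e. unit mean bond).
#' @param verify check the knot type of the discretized polygon.
#' @return a [ring()].
#' @export
parametric_knot <- function(label, N = 240L, chirality = NULL,
                            contour = N, verify = TRUE) {
  stopifnot(N >= 24)
  t <- 2 * pi * (0:(N - 1L)) / N
  pos <- switch(label,
    "0_1" = cbind(cos(t), sin(t), 0),
    "3_1" = torus_curve(t, 3L),
    "5_1" = torus_curve(t, 5L),
    "7_1" = torus_curve(t, 7L),
    "4_1" = cbind((2 + cos(2 * t)) * cos(3 * t),
                  (2 + cos(2 * t)) * sin(3 * t),
                  sin(4 * t)),
    "5_2" = fourier_curve(t, matrix(c(
      # trigonometric loop verified to close into a 5_2 twist knot for
      # N >= 120 (both mirror images); harmonics 1..4, cos then sin, per axis
      -0.07825, -0.37323, 0.43673, 0.99995, -0.87664, -0.63285,
       0.5869, -1.82072, -1.51855, -0.32619, 0.39526, -0.47169,
      -0.12472, -0.71339, 0.29644, 1.23773, 0.00793, 0.17557,
       0.4309, 0.57028, 1.76485, -1.21059, 0.08006, 1.60159), 3, 8)),
    stop("unknown or unsupported knot label: ", label)
  )
  r <- rescale_contour(ring(pos), contour)
  if (!is.null(chirality) && !(label %in% c("0_1", "4_1"))) {
    chirality <- match.arg(chirality, c("right", "left"))
    wr <- cpp_gauss_writhe(unclass(r))
    if ((chirality == "right") != (wr > 0)) {
      m <- unclass(r)
      m[, 3] <- -m[, 3]
      r <- ring(m)
    }
  }
  if (verify) {
    kt <- knot_type(r)
    if (kt$label != label)
      stop(sprintf("discretization changed the knot type: wanted %s, got %s (N too small?)",
                   label, kt$label))
  }
  r
}

# (2,q) torus knot: winds twice around the symmetry axis, q times around the tube
torus_curve <- function(t, q) {
  cbind((2 + cos(q * t)) * cos(2 * t),
        (2 + cos(q * t)) * sin(2 * t),
        sin(q * t))
}

# trigonometric loop from a 3 x 2K coefficient matrix (cos 1..K, sin 1..K)
fourier_curve <- function(t, co) {
  K <- ncol(co) / 2L
  pos <- vapply(1:3, function(ax) {
    v <- numeric(length(t))
    for (k in seq_len(K)) v <- v + co[ax, k] * cos(k * t) + co[ax, k + K] * sin(k * t)
    v
  }, numeric(length(t)))
  pos
}

#' Exact equilibrium samples of the phantom Gaussian ring
#'
#' Draws statistically independent ring conformations from the Boltzmann
#' distribution of the quadratic chain potential by equipartition in mode
#' space: each non-zero Fourier mode is Gaussian with per-component variance
#' 1/(4 N Omega_p) in its real and imaginary parts (the real Nyquist mode,
#' present for even N, carries 1/(2 N Omega_p)); the centre of mass (p = 0)
#' is fixed at the origin. Used to validate the chain calibration
#' (mean-square bond length, persistence length) without Monte Carlo error
#' from correlated samples. Uses the R RNG; seed with [set.seed()].
#'
#' @param params a [chain_parameters()].
#' @param n_samples number of independent rings.
#' @return a list of [ring()] objects.
#' @export
sample_gaussian_equilibrium <- function(params, n_samples) {
  stopifnot(n_samples >= 1)
  N <- params$N
  om <- mode_omega(1:(N - 1L), params)
  scale <- c(0, 1 / sqrt(2 * om))
  lapply(seq_len(n_samples), function(i) {
    g <- matrix(stats::rnorm(3L * N), N, 3L)
    rho <- (stats::mvfft(g) / N) * scale
    ring(Re(stats::mvfft(rho, inverse = TRUE)))
  })
}

#' Crankshaft Monte Carlo equilibration of a self-avoiding cylinder ring
#'
#' Metropolis Monte Carlo on the semiflexible ring potential with crankshaft
#' moves: a random sub-arc (length <= `max_arc` beads) is rotated rigidly by a
#' random angle about the chord through its end beads. Crankshaft moves
#' preserve every bond length exactly, so only the bending energy at the two
#' hinges enters the Metropolis ratio. The ring is treated as N cylinders of
#' diameter `sigma`; moves bringing two non-adjacent cylinders closer than
#' `sigma` (minimum segment-segment distance) are rejected, which keeps the
#' ring self-avoiding and, for moderate rotation angles, preserves its knot
#' type. The knot label is re-verified after the run and a mismatch is an
#' error. Uses the R RNG; seed with [set.seed()].
#'
#' @param r a self-avoiding [ring()] (checked).
#' @param params a [chain_parameters()] with matching N.
#' @param n_sweeps number of MC sweeps (N trial moves each).
#' @param sigma cylinder diameter (default b/4).
#' @param max_arc largest rotated sub-arc (default N/4).
#' @param max_angle largest rotation angle in radians; the effective per-move
#'   angle is further capped so no bead moves farther than `max_disp`.
#' @param max_disp per-move displacement cap (default `sigma`): strand
#'   passage requires a displacement beyond the cylinder diameter, so capping
#'   below it keeps the move set topology preserving.
#' @param verify_knot verify knot-type conservation (on by default).
#' @return a list with `ring`, `acceptance` rate, `energy_trace` (potential
#'   energy every 10 sweeps, kBT units), and `knot` (the verified [knot_type()]
#'   of the result when `verify_knot`, else NULL).
#' @export
mc_equilibrate <- function(r, params, n_sweeps, sigma = params$b / 4,
                           max_arc = max(2L, params$N %/% 4L),
                           max_angle = pi / 2, max_disp = sigma,
                           verify_knot = TRUE) {
  stopifnot(is_ring(r), nrow(r) == params$N, n_sweeps >= 0)
  if (sigma > 0 && cpp_check_overlap(unclass(r), sigma))
    stop("starting ring violates self-avoidance at sigma = ", sigma)
  knot0 <- if (verify_knot) knot_type(r)$label else NULL
  if (n_sweeps == 0) {
    return(list(ring = r, acceptance = NA_real_, energy_trace = numeric(),
                knot = if (verify_knot) knot_type(r) else NULL))
  }
  res <- cpp_mc_equilibrate(unclass(r), params$a, params$K, sigma,
                            as.integer(n_sweeps), as.integer(max_arc),
                            max_angle, max_disp)
  out <- ring(res$positions)
  knot <- NULL
  if (verify_knot) {
    knot <- knot_type(out)
    if (knot$label != knot0)
      stop(sprintf("Monte Carlo move set changed the knot type (%s -> %s); reduce max_angle",
                   knot0, knot$label))
  }
  list(ring = out, acceptance = res$acceptance,
       energy_trace = as.numeric(res$energy_trace), knot = knot)
}
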