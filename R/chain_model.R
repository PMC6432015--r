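#' Calibrate the bare parameters of the semiflexible Gaussian ring
#'
#' The chain is governed by the quadratic potential (in units of kBT)
#' \deqn{U = \sum_{n=1}^{N} \frac{3}{2a^2} (r_{n+1}-r_n)^2 +
#'           \frac{K}{2} (r_{n+1}-2 r_n+r_{n-1})^2}
#' with periodic indices (the chain is a ring). The bare parameters are the
#' Gaussian bond scale `a` and the bending rigidity `K`; the user-facing
#' parameters are the root-mean-square bond length `b` and the persistence
#' length `lP` (decay length of bond-direction correlations, in the same
#' length units as `b`).
#'
#' Calibration proceeds in two steps, both exact for this model:
#'
#' 1. Stiffness. In equilibrium the bond-vector correlation decays
#'    geometrically with bond separation s, \eqn{\langle u_n u_{n+s}\rangle
#'    \propto e^{-\mu s}} with \eqn{\cosh\mu = 1 + 1/(2\kappa)} where
#'    \eqn{\kappa = K a^2/3} is the dimensionless stiffness (pole of the
#'    discrete mode sum). Requiring decay length lP/b bonds gives
#'    \eqn{\kappa = 1/(2(\cosh(b/lP)-1))}, whose large-lP limit is
#'    \eqn{\kappa \approx (lP/b)^2}. The often-quoted mean-field
#'    identification \eqn{lP = \kappa b} does not reproduce the decay this
#'    model actually exhibits and is not used.
#' 2. Bond scale. The equilibrium mean-square bond length is
#'    \eqn{b^2 = \frac{a^2}{N}\sum_{p=1}^{N-1} [1+2\kappa(1-\cos\omega_p)]^{-1}}
#'    with \eqn{\omega_p = 2\pi p/N}; hence \eqn{a = b/\sqrt{S}} with S the
#'    bracketed average, and \eqn{K = 3\kappa/a^2}.
#'
#' @param N integer number of beads (>= 3).
#' @param b target root-mean-square bond length (length unit; default 1).
#' @param lP target persistence length, same units as `b`; `0` gives the fully
#'   flexible chain.
#' @return a list with elements `a`, `K`, `kappa`, `S`.
#' @seealso [chain_parameters()] for the full parameter object.
#' @export
solve_chain_parameters <- function(N, b = 1, lP = 0) {
  stopifnot(is.finite(N), N >= 3, is.finite(b), b > 0, is.finite(lP), lP >= 0)
  N <- as.integer(N)
  kappa <- if (lP == 0) 0 else 1 / (2 * (cosh(b / lP) - 1))
  S <- eq_bond_sum(N, kappa)
  a <- b / sqrt(S)
  list(a = a, K = 3 * kappa / a^2, kappa = kappa, S = S)
}

# S(kappa, N) = (1/N) sum_{p=1}^{N-1} [1 + 2 kappa (1 - cos(2 pi p / N))]^{-1}
# The p = 0 (centre-of-mass) mode carries no bond-length fluctuation and is
# excluded; including it would bias the calibrated b^2 by O(1/(N S)).
eq_bond_sum <- function(N, kappa) {
  p <- seq_len(N - 1L)
  w <- 2 * pi * p / N
  sum(1 / (1 + 2 * kappa * (1 - cos(w)))) / N
}

#' Chain parameter set
#'
#' Bundles chain length, calibrated bare parameters and the diffusion constant
#' into a validated parameter object used throughout the package. Internally
#' the bond length b is the length unit and b^2/D the time unit (D = 1, b = 1
#' by default).
#'
#' @inheritParams solve_chain_parameters
#' @param D diffusion coefficient of a bead (length^2/time); the friction is
#'   gamma = kBT/D (Einstein relation).
#' @return an object of class `"chain_parameters"`: a list with fields
#'   `N`, `b`, `lP`, `a`, `K`, `kappa`, `D`, `gamma` (in kBT units).
#' @examples
#' p <- chain_parameters(N = 240, b = 1, lP = 5)
#' p$kappa
#' @export
chain_parameters <- function(N, b = 1, lP = 0, D = 1) {
  stopifnot(is.finite(D), D > 0)
  sol <- solve_chain_parameters(N, b, lP)
  structure(
    list(N = as.integer(N), b = b, lP = lP, a = sol$a, K = sol$K,
         kappa = sol$kappa, S = sol$S, D = D, gamma = 1 / D),
    class = "chain_parameters"
  )
}

#' @export
print.chain_parameters <- function(x, ...) {
  cat(sprintf(
    "chain_parameters: N=%d  b=%.4g  lP=%.4g  (a=%.6g, K=%.6g, kappa=%.6g)  D=%.4g\n",
    x$N, x$b, x$lP, x$a, x$K, x$kappa, x$D))
  invisible(x)
}

#' Potential energy of a ring conformation
#'
#' Evaluates the quadratic semiflexible ring potential (see
#' [solve_chain_parameters()]) in units of kBT, with periodic wrap.
#'
#' @param r a [ring()] with `params$N` beads.
#' @param params a [chain_parameters()] object.
#' @return a non-negative number (kBT units).
#' @export
potential_energy <- function(r, params) {
  if (nrow(r) != params$N)
    stop("ring has ", nrow(r), " beads but params$N = ", params$N)
  u <- bond_vectors(r)                      # u_n = r_{n+1} - r_n
  d2 <- rbind(u[-1L, , drop = FALSE], u[1L, , drop = FALSE]) - u  # r_{n+2}-2r_{n+1}+r_n
  3 / (2 * params$a^2) * sum(u^2) + params$K / 2 * sum(d2^2)
}

#' Estimate the persistence length from equilibrium ring samples
#'
#' Computes the orientation-averaged bond-vector autocorrelation
#' \eqn{C(s) = \langle u_n \cdot u_{n+s} \rangle} over all beads and samples
#' and fits \eqn{C(s) = A e^{-s/\xi} + B} by nonlinear least squares.
#' The offset B is required on a ring: closure (\eqn{\sum_n u_n = 0}) makes
#' \eqn{\sum_s C(s) = 0} exactly, so the correlation is a geometric decay
#' shifted by a small negative constant; omitting B biases \eqn{\xi} by
#' several percent. Raw bond vectors (not unit tangents) are used because for
#' this Gaussian model their correlation is exactly exponential, while
#' normalization introduces a short-range multiplicative correction.
#'
#' The returned standard error comes from refitting on `n_batch` disjoint
#' batches of samples (errors of C(s) across s are strongly correlated, so
#' per-point fit SEs would be badly understated).
#'
#' @param rings a list of [ring()] objects (>= 100) drawn from equilibrium.
#' @param s_max largest bond separation used in the fit; default `N %/% 4`.
#' @param n_batch number of batches for the standard error (default 10).
#' @return a list with `lP` (in length units: xi multiplied by the measured
#'   rms bond length), `se`, `xi_bonds`, `b_rms`, and the fitted `A`, `B`.
#' @export
persistence_length_estimate <- function(rings, s_max = NULL, n_batch = 10) {
  if (length(rings) < 100) stop("need at least 100 equilibrium samples")
  N <- nrow(rings[[1]])
  if (is.null(s_max)) s_max <- N %/% 4L

  corr_rows <- vapply(rings, function(r) {
    u <- bond_vectors(r)
    uf <- stats::mvfft(u)
    cc <- Re(stats::mvfft(uf * Conj(uf), inverse = TRUE)) / N^2
    rowSums(cc)[seq_len(s_max + 1L)]
  }, numeric(s_max + 1L))                     # (s_max+1) x nsamples

  fit_xi <- function(cols) {
    cbar <- rowMeans(corr_rows[, cols, drop = FALSE])
    df <- data.frame(s = 0:s_max, C = cbar)
    fit <- minpack.lm::nlsLM(
      C ~ A * exp(-s / xi) + B, data = df,
      start = list(A = df$C[1], xi = max(1, -1 / log(max(0.1, df$C[2] / df$C[1]))), B = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    stats::coef(fit)
  }

  co <- fit_xi(seq_along(rings))
  batches <- split(seq_along(rings), cut(seq_along(rings), n_batch, labels = FALSE))
  xis <- vapply(batches, function(ix) fit_xi(ix)[["xi"]], numeric(1))

  b_rms <- sqrt(mean(vapply(rings, function(r) mean(rowSums(bond_vectors(r)^2)),
                            numeric(1))))
  xi <- co[["xi"]]
  list(lP = xi * b_rms, se = stats::sd(xis) / sqrt(length(xis)) * b_rms,
       xi_bonds = xi, b_rms = b_rms, A = co[["A"]], B = co[["B"]])
}
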