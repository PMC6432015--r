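#' Fourier (Rouse) mode representation of a ring
#'
#' The chain's quadratic potential is diagonal in the discrete Fourier modes
#' \deqn{\tilde\rho_p = \frac{1}{N}\sum_{n=1}^{N} e^{-i\omega_p n} r_n,
#'       \qquad \omega_p = 2\pi p/N,}
#' the full complex-exponential basis (cosine and sine pairs), which is
#' invertible for arbitrary rings; amplitudes satisfy the Hermitian symmetry
#' \eqn{\tilde\rho_{N-p} = \overline{\tilde\rho_p}} whenever the real-space
#' ring is real. Mode p = 0 is the centre of mass, and the pair (p, N-p)
#' shares one relaxation rate and is propagated as one complex degree of
#' freedom. With this normalization the potential is
#' \eqn{U/k_BT = N \sum_p \Omega_p |\tilde\rho_p|^2} (see [mode_omega()]) and
#' the mode noises have the moments listed in [noise_variances()].
#'
#' @param r a [ring()].
#' @return `to_modes`: an N x 3 complex matrix of class `"mode_state"`;
#'   `from_modes`: a [ring()].
#' @export
to_modes <- function(r) {
  stopifnot(is_ring(r))
  m <- stats::mvfft(unclass(r)) / nrow(r)
  structure(m, class = c("mode_state", "matrix", "array"))
}

#' @rdname to_modes
#' @param modes an N x 3 complex matrix of mode amplitudes (Hermitian
#'   symmetric, e.g. from [to_modes()]).
#' @param tol tolerance on the residual imaginary part of the reconstruction,
#'   relative to the coordinate scale.
#' @export
from_modes <- function(modes, tol = 1e-8) {
  x <- stats::mvfft(unclass(modes), inverse = TRUE)
  scale <- max(1, max(abs(Re(x))))
  if (max(abs(Im(x))) > tol * scale)
    stop("mode amplitudes violate Hermitian symmetry: reconstruction is not real")
  ring(Re(x))
}

#' Mode stiffness and relaxation rate
#'
#' `mode_omega` returns the per-mode stiffness
#' \deqn{\Omega_p = (3/a^2)(1-\cos\omega_p) + 2K(1-\cos\omega_p)^2,}
#' in terms of which the chain potential reads
#' \eqn{U/k_BT = N\sum_p \Omega_p|\tilde\rho_p|^2}. `mode_relaxation_rate`
#' returns the relaxation rate of the overdamped dynamics of mode p,
#' \eqn{\lambda_p = 2 D \Omega_p}: the factor 2D converts the stiffness of
#' \eqn{|\tilde\rho_p|^2} (which enters U twice per complex pair) into the
#' decay rate of the gradient flow under the Einstein relation. Both vanish
#' at p = 0 and are symmetric under p -> N - p.
#'
#' @param p integer mode index (vectorized), 0 <= p < N.
#' @param params a [chain_parameters()] object.
#' @return numeric vector of stiffnesses (1/length^2) or rates (1/time).
#' @export
mode_omega <- function(p, params) {
  stopifnot(all(p >= 0), all(p < params$N))
  w <- 2 * pi * p / params$N
  (3 / params$a^2) * (1 - cos(w)) + 2 * params$K * (1 - cos(w))^2
}

#' @rdname mode_omega
#' @export
mode_relaxation_rate <- function(p, params) {
  2 * params$D * mode_omega(p, params)
}

#' Per-mode Gaussian noise increment variances
#'
#' The real-space noise has \eqn{\langle\eta_n^{(\alpha)}(t)
#' \eta_{n'}^{(\alpha')}(t')\rangle = 2D\,\delta_{nn'}\delta_{\alpha\alpha'}
#' \delta(t-t')}. Under the mode normalization of [to_modes()] each mode
#' carries total complex variance 2D dt / N per Cartesian component over a
#' step dt: the real modes p = 0 (and p = N/2 for even N) put all of it in
#' their real part, every other mode splits it as D dt / N in the real and
#' D dt / N in the imaginary part. Summing over modes reproduces the 2D dt
#' per-bead-component real-space variance (Parseval).
#'
#' @param params a [chain_parameters()] object.
#' @param dt time step.
#' @return a list with `p0` (variance of each Cartesian component of the
#'   p = 0 increment), `part` (variance of each real/imaginary part for
#'   generic p != 0), and `nyquist` (variance of the real N/2 mode, present
#'   for even N).
#' @export
noise_variances <- function(params, dt) {
  stopifnot(dt > 0)
  base <- params$D * dt / params$N
  list(p0 = 2 * base, part = base,
       nyquist = if (params$N %% 2L == 0L) 2 * base else NULL)
}

# Draw one step's mode-space noise increments by transforming iid real-space
# Gaussian increments (variance 2 D dt per bead component). This realizes all
# the moments of noise_variances() and exact Hermitian symmetry at once, and
# consumes the R RNG stream in a representation-independent order.
draw_mode_noise <- function(params, dt) {
  g <- matrix(stats::rnorm(3L * params$N, sd = sqrt(2 * params$D * dt)),
              params$N, 3L)
  stats::mvfft(g) / params$N
}
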