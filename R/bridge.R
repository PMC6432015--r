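#' Run free or conditioned (bridge) Langevin dynamics of a Gaussian ring
#'
#' Integrates the overdamped Langevin dynamics of the semiflexible Gaussian
#' ring in Fourier-mode space with an Euler--Maruyama scheme. Three
#' conditionings are available:
#'
#' * `"free"`: unconditioned dynamics, each mode an independent
#'   Ornstein--Uhlenbeck process with rate \eqn{\lambda_p = 2D\Omega_p}
#'   (the centre-of-mass mode diffuses freely).
#' * `"bridge"`: trajectories conditioned to reach `final` exactly at `tf`.
#'   The p = 0 mode gets the Brownian-bridge drift
#'   \eqn{(\tilde\rho_0^{(f)}-\tilde\rho_0)/(t_f-t)}; every other mode the
#'   Ornstein--Uhlenbeck bridge drift
#'   \eqn{-\lambda_p\tilde\rho_p + \frac{\lambda_p}{\sinh\lambda_p(t_f-t)}
#'   (\tilde\rho_p^{(f)} - \tilde\rho_p e^{-\lambda_p (t_f-t)})}.
#'   The conditioned trajectories are statistically unbiased samples of the
#'   free dynamics pinned at both ends.
#' * `"bridge_permuted"`: the final state is the *set* of all N circular
#'   permutations of `final`; the drift pulls towards the weighted average of
#'   the permutation targets with weights \eqn{P_1(n_0)} computed in log space
#'   and normalized by log-sum-exp (monomers on two closed rings have no
#'   preferred one-to-one correspondence, so the bridge may land on any
#'   cyclic relabelling).
#'
#' Numerical notes: \eqn{\lambda_p(t_f-t)} spans many orders of magnitude, so
#' \eqn{\lambda/\sinh} and the \eqn{1-e^{-2\lambda\tau}} denominators are
#' evaluated with `expm1`-based forms. The \eqn{1/(t_f-t)} drift is formally
#' singular at the last step; the integrator instead places the final frame
#' exactly on the maximal-weight permutation target (error O(dt)).
#'
#' @param initial a [ring()]: the start conformation (frame at t = 0).
#' @param final a [ring()] or NULL (required unless `conditioning = "free"`).
#' @param params a [chain_parameters()] with `params$N` matching the rings.
#' @param dt time step (units b^2/D); must divide `tf` to within one step.
#' @param tf total bridge time.
#' @param conditioning one of `"free"`, `"bridge"`, `"bridge_permuted"`.
#' @param seed integer seed; every source of randomness in the run derives
#'   from it, so runs are exactly reproducible.
#' @param frame_stride store every `frame_stride`-th frame (first and last
#'   frames are always stored exactly).
#' @param permutations integer vector of cyclic shifts n0 to condition on
#'   (default: `0` for `"bridge"`, `0:(N-1)` for `"bridge_permuted"`).
#'   A `"bridge_permuted"` run with a single permutation is bit-identical to
#'   the plain bridge under the same seed.
#' @return an object of class `"bridge_trajectory"`: list with `frames` (list
#'   of rings), `times`, `dt`, `tf`, `seed`, `conditioning`, `top_weight`
#'   (per stored frame, the largest normalized permutation weight),
#'   `landed_perm` (the cyclic shift the run terminated on, NA if free).
#' @export
run_bridge <- function(initial, final = NULL, params, dt, tf,
                       conditioning = c("bridge", "bridge_permuted", "free"),
                       seed = 1L, frame_stride = 100L, permutations = NULL) {
  conditioning <- match.arg(conditioning)
  stopifnot(is_ring(initial), nrow(initial) == params$N, dt > 0, tf > dt / 2)
  N <- params$N
  if (conditioning == "free") {
    final <- initial # unused placeholder
    perms <- 0L
  } else {
    if (is.null(final)) stop("conditioned runs need a final conformation")
    stopifnot(is_ring(final), nrow(final) == N)
    perms <- if (!is.null(permutations)) as.integer(permutations)
             else if (conditioning == "bridge") 0L else 0:(N - 1L)
    stopifnot(all(perms >= 0), all(perms < N))
  }
  lambda <- mode_relaxation_rate(0:(N - 1L), params)
  set.seed(seed)
  res <- cpp_run_bridge(unclass(initial), unclass(final), lambda, params$D,
                        dt, tf, if (conditioning == "free") 0L else 1L,
                        perms, as.integer(frame_stride))
  frames <- lapply(seq_len(dim(res$frames)[3]), function(i) ring(res$frames[, , i]))
  structure(
    list(frames = frames, times = as.numeric(res$times), dt = dt, tf = tf,
         seed = seed, conditioning = conditioning,
         top_weight = as.numeric(res$top_weight),
         landed_perm = res$landed_perm, params = params),
    class = "bridge_trajectory")
}

#' @export
print.bridge_trajectory <- function(x, ...) {
  cat(sprintf(
    "bridge_trajectory: %d frames, N=%d, tf=%g, dt=%g, conditioning=%s%s\n",
    length(x$frames), nrow(x$frames[[1]]), x$tf, x$dt, x$conditioning,
    if (!is.na(x$landed_perm)) sprintf(", landed on permutation n0=%d", x$landed_perm) else ""))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Reference (plain R) single-step propagators. These mirror the compiled
# integrator and are the surface the unit/property tests exercise; run_bridge
# uses the compiled loop.

ou_pull_coef <- function(lambda, tau) {
  ifelse(lambda <= 0, 1 / tau,
         2 * lambda * exp(-lambda * tau) / (-expm1(-2 * lambda * tau)))
}

#' Single Euler--Maruyama steps of the mode-space dynamics
#'
#' `step_free` propagates the unconditioned dynamics, `step_bridge` the
#' single-endpoint bridge and `step_bridge_permuted` the circular-permutation
#' bridge, each by one step of size `dt` (see [run_bridge()] for the drifts).
#' These consume the R RNG stream (seed with [set.seed()]).
#'
#' @param modes,final N x 3 complex mode matrices (see [to_modes()]).
#' @param params a [chain_parameters()].
#' @param dt time step.
#' @param t current time; `tf` total time (requires `t + dt <= tf`).
#' @param noise optional precomputed N x 3 complex mode-noise increment (for
#'   deterministic tests); default draws from the model's noise law.
#' @param permutations integer vector of cyclic shifts conditioned on.
#' @return the updated mode matrix.
#' @export
step_free <- function(modes, params, dt, noise = NULL) {
  lambda <- mode_relaxation_rate(0:(params$N - 1L), params)
  if (is.null(noise)) noise <- draw_mode_noise(params, dt)
  modes - (lambda * modes) * dt + noise
}

#' @rdname step_free
#' @export
step_bridge <- function(modes, final, t, tf, params, dt, noise = NULL) {
  if (t >= tf) stop("bridge step requires t < tf")
  if (t + dt > tf + 1e-12) stop("bridge step would overshoot tf")
  N <- params$N
  lambda <- mode_relaxation_rate(0:(N - 1L), params)
  tau <- tf - t
  coef <- ou_pull_coef(lambda, tau)
  dec <- exp(-lambda * tau)
  if (is.null(noise)) noise <- draw_mode_noise(params, dt)
  drift <- -(lambda * modes) + coef * (final - modes * dec)
  modes + drift * dt + noise
}

#' @rdname step_free
#' @export
step_bridge_permuted <- function(modes, final, t, tf, params, dt,
                                 permutations = 0:(params$N - 1L), noise = NULL) {
  if (t >= tf) stop("bridge step requires t < tf")
  N <- params$N
  lambda <- mode_relaxation_rate(0:(N - 1L), params)
  tau <- tf - t
  lw <- permutation_log_weights(modes, final, t, tf, params, permutations)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  # weighted permutation target: rhof_p * sum_n0 w(n0) e^{i w_p n0}
  wfull <- numeric(N)
  wfull[permutations + 1L] <- w
  phi <- stats::fft(wfull, inverse = TRUE)
  tgt <- final * phi
  coef <- ou_pull_coef(lambda, tau)
  dec <- exp(-lambda * tau)
  if (is.null(noise)) noise <- draw_mode_noise(params, dt)
  drift <- -(lambda * modes) + coef * (tgt - modes * dec)
  modes + drift * dt + noise
}

#' Normalized circular-permutation weights of the conditioned bridge
#'
#' Computes, in log space, the probability that the bridge currently at
#' `modes` (time `t`) terminates on cyclic shift n0 of `final` at `tf`:
#' \deqn{\log P_1(n_0) = -\frac{N}{2D} \sum_{p\ge 1} \frac{\lambda_p
#'  \left|\tilde\rho_p^{(n_0)} - \tilde\rho_p(t) e^{-\lambda_p\tau}\right|^2}
#'  {1 - e^{-2\lambda_p \tau}}, \qquad \tau = t_f - t,}
#' where \eqn{\tilde\rho_p^{(n_0)} = e^{i\omega_p n_0}\tilde\rho_p^{(f)}}
#' (a cyclic shift only twists mode phases). The p = 0 term is permutation
#' independent and drops out of the normalized weights. Weights are returned
#' normalized via log-sum-exp; they are finite and sum to 1.
#'
#' @inheritParams step_free
#' @param normalized if FALSE, return the raw log-weights instead.
#' @return numeric vector over `permutations` (normalized weights, or raw
#'   log-weights when `normalized = FALSE`).
#' @export
permutation_weights <- function(modes, final, t, tf, params,
                                permutations = 0:(params$N - 1L),
                                normalized = TRUE) {
  lw <- permutation_log_weights(modes, final, t, tf, params, permutations)
  if (!normalized) return(lw)
  m <- max(lw)
  if (!is.finite(m)) stop("all permutation log-weights are -Inf")
  w <- exp(lw - m)
  w / sum(w)
}

permutation_log_weights <- function(modes, final, t, tf, params, permutations) {
  N <- params$N
  stopifnot(nrow(modes) == N, nrow(final) == N, t < tf)
  tau <- tf - t
  lambda <- mode_relaxation_rate(0:(N - 1L), params)
  cp <- ifelse(lambda > 0, lambda / (-expm1(-2 * lambda * tau)), 0.5 / tau)
  cp[1] <- 0 # p = 0 excluded: permutation independent
  s <- modes * exp(-lambda * tau)
  A <- sum(cp * (rowSums(abs(final)^2) + rowSums(abs(s)^2)))
  B <- cp * rowSums(final * Conj(s))
  ft <- stats::fft(B, inverse = TRUE) # sum_p B_p e^{i w_p n0}
  lw <- -(N / (2 * params$D)) * (A - 2 * Re(ft))
  lw[permutations + 1L]
}

#' Closed-form moments of a bridged Ornstein--Uhlenbeck mode
#'
#' For one real mode component with relaxation rate `lambda` and noise
#' variance rate `2 * Dx` (so the unconditioned variance after time t is
#' (Dx/lambda)(1 - e^{-2 lambda t})), conditioned on values `x0` at 0 and
#' `xf` at `tf`, returns the conditional mean and variance at times `t`.
#' The limit lambda -> 0 is the Brownian bridge (mean linear in t, variance
#' 2 Dx t (tf - t) / tf). Used as the analytic oracle for bridge statistics.
#'
#' @param x0,xf endpoint values.
#' @param t numeric vector of interior times.
#' @param tf total time.
#' @param lambda relaxation rate (>= 0).
#' @param Dx half the noise variance rate of this component.
#' @return a list with vectors `mean` and `var`.
#' @export
ou_bridge_moments <- function(x0, xf, t, tf, lambda, Dx) {
  if (lambda > 0) {
    mean <- (x0 * sinh(lambda * (tf - t)) + xf * sinh(lambda * t)) / sinh(lambda * tf)
    var <- (Dx / lambda) * (-expm1(-2 * lambda * t)) * (-expm1(-2 * lambda * (tf - t))) /
      (-expm1(-2 * lambda * tf))
    list(mean = mean, var = var)
  } else {
    list(mean = x0 + (xf - x0) * t / tf, var = 2 * Dx * t * (tf - t) / tf)
  }
}
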