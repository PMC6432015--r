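# Shared fixtures: small chains and deterministic random rings.

params_small <- function(N = 16, lP = 2, b = 1, D = 1) {
  chain_parameters(N = N, b = b, lP = lP, D = D)
}

random_ring <- function(N, seed = 1, scale = 1) {
  set.seed(seed)
  ring(matrix(stats::rnorm(3 * N, sd = scale), N, 3))
}

# random rotation matrix (Haar-ish via QR)
random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_out <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_out)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# naive first-principles permutation weights for small N: product of Gaussian
# transition densities over every independent real mode degree of freedom.
naive_perm_weights <- function(r_now, r_final, t, tf, params) {
  N <- params$N
  tau <- tf - t
  rho <- to_modes(r_now)
  lambda <- mode_relaxation_rate(0:(N - 1), params)
  logw <- numeric(N)
  for (n0 in 0:(N - 1)) {
    target <- to_modes(cyclic_shift(r_final, n0))
    lp <- 0
    for (p in 1:(N - 1)) {
      if (N %% 2 == 0 && p == N / 2) {
        if (p > N / 2) next
        Dx <- params$D / N          # real Nyquist mode
        v <- (Dx / lambda[p + 1]) * (-expm1(-2 * lambda[p + 1] * tau))
        dev <- Re(target[p + 1, ]) - Re(rho[p + 1, ]) * exp(-lambda[p + 1] * tau)
        lp <- lp - sum(dev^2) / (2 * v)
      } else if (p < N / 2) {       # complex pair (p, N-p): Re and Im dof
        Dx <- params$D / (2 * N)
        v <- (Dx / lambda[p + 1]) * (-expm1(-2 * lambda[p + 1] * tau))
        dd <- target[p + 1, ] - rho[p + 1, ] * exp(-lambda[p + 1] * tau)
        lp <- lp - sum(Re(dd)^2 + Im(dd)^2) / (2 * v)
      }
    }
    logw[n0 + 1] <- lp
  }
  w <- exp(logw - max(logw))
  w / sum(w)
}
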