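# Independent oracles used by unit and acceptance tests.  These deliberately
# avoid the code paths they check: the cylinder oracle is a random walk, the
# Gibbs oracle a naive truncated Fourier sum, the direction oracle a
# multi-start search.

# Monte-Carlo random walk in a reflecting cylinder cross-section; spins
# accumulate phase under the two rectangular gradient pulses (+G then -G on
# the in-plane x coordinate).  Returns the attenuation estimate and its
# standard error.
mc_cylinder_perp <- function(D, R, delta, Delta, G,
                             gamma = 2.6752219e8,
                             n_walkers = 2e4, seed = 1) {
  set.seed(seed)
  dt <- min((Delta + delta) / 900, R^2 / (288 * D))  # step sd <= R/12
  n_steps <- ceiling((Delta + delta) / dt)
  dt <- (Delta + delta) / n_steps
  sd_step <- sqrt(2 * D * dt)
  u <- sqrt(stats::runif(n_walkers)) * R
  th <- stats::runif(n_walkers) * 2 * pi
  x <- u * cos(th); y <- u * sin(th)
  phase <- numeric(n_walkers)
  for (s in seq_len(n_steps)) {
    t_mid <- (s - 0.5) * dt
    ge <- if (t_mid < delta) 1 else
      if (t_mid >= Delta && t_mid < Delta + delta) -1 else 0
    x <- x + stats::rnorm(n_walkers, sd = sd_step)
    y <- y + stats::rnorm(n_walkers, sd = sd_step)
    r <- sqrt(x^2 + y^2)
    out <- r > R
    if (any(out)) {      # specular reflection at the wall
      sc <- (2 * R - r[out]) / r[out]
      x[out] <- x[out] * sc
      y[out] <- y[out] * sc
    }
    if (ge != 0) phase <- phase + gamma * G * ge * x * dt
  }
  c(value = mean(cos(phase)), se = stats::sd(cos(phase)) / sqrt(n_walkers))
}

# Naive truncated discrete Fourier reconstruction (Dirichlet-kernel
# convolution written as an explicit O(N K) double sum, no FFT): the
# partial sum over the K lowest frequencies of `x`, evaluated at sample
# positions `pos` (1-based, on the fine grid; fractional positions allowed).
dirichlet_truncate <- function(x, K, pos = seq_along(x)) {
  N <- length(x)
  ms <- seq.int(-floor(K / 2), ceiling(K / 2) - 1)  # matches central crop
  cm <- vapply(ms, function(m)
    sum(x * exp(-2i * pi * m * (seq_len(N) - 1) / N)), complex(1))
  vapply(pos, function(p)
    Re(sum(cm * exp(2i * pi * ms * (p - 1) / N))) / N, 0)
}

# Multi-start random-restart oracle for the minimum antipodal electrostatic
# energy (used against generate_directions at small n).
dir_energy <- function(y) {
  E <- 0
  n <- nrow(y)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    E <- E + 1 / sqrt(sum((y[i, ] - y[j, ])^2)) +
      1 / sqrt(sum((y[i, ] + y[j, ])^2))
  }
  E
}

min_energy_oracle <- function(n, restarts = 100, seed = 99) {
  set.seed(seed)
  best <- Inf
  fn <- function(p) {
    y <- matrix(p, ncol = 3)
    y <- y / sqrt(rowSums(y^2))
    dir_energy(y)
  }
  for (r in seq_len(restarts)) {
    x0 <- matrix(stats::rnorm(3 * n), n, 3)
    fit <- stats::optim(as.vector(x0), fn, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# Exact Rician moments via scaled Bessel functions (for noise calibration
# checks at high SNR without overflow).
rician_mean <- function(nu, sigma) {
  a <- nu^2 / (2 * sigma^2)
  # Laguerre L_{1/2}(-a) with the e^{-a/2} absorbed by the scaled Bessels
  L <- (1 + a) * besselI(a / 2, 0, expon.scaled = TRUE) +
    a * besselI(a / 2, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * L
}

rician_sd <- function(nu, sigma) {
  sqrt(nu^2 + 2 * sigma^2 - rician_mean(nu, sigma)^2)
}
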