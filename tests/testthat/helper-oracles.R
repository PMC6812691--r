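# Shared independent oracles and small fixtures.

# closed-form equal-posterior threshold of a two-normal mixture: root of
# the quadratic obtained by equating the weighted log-densities
closed_form_threshold <- function(mu, sigma, lambda) {
  A <- 1 / sigma[1]^2 - 1 / sigma[2]^2
  B <- -2 * (mu[1] / sigma[1]^2 - mu[2] / sigma[2]^2)
  C <- mu[1]^2 / sigma[1]^2 - mu[2]^2 / sigma[2]^2 +
    2 * log(sigma[1] / sigma[2]) - 2 * log(lambda[1] / lambda[2])
  if (abs(A) < 1e-14) return(-C / B)
  r <- (-B + c(-1, 1) * sqrt(B^2 - 4 * A * C)) / (2 * A)
  r[r > mu[1] & r < mu[2]][1]
}

# brute-force ray-casting point-in-polygon on raw lon/lat coordinates
# (adequate oracle at sub-degree scales)
pip_oracle <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- !inside
    j <- i
  }
  inside
}

# random MA coefficients guaranteed invertible (via the package's own
# transform; invertibility is re-checked independently where it matters)
rand_invertible_theta <- function(q) raftr:::.ma_from_unconstrained(rnorm(q))

# a small-track simulation config used across tests
small_cfg <- function(...) sim_config(n_birds = 3, hours_per_bird = 6, ...)
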