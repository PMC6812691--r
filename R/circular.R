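# Circular statistics: circular mean, von Mises fitting, and the
# Jammalamadaka-Sarma circular correlation (the circular analogue of
# Pearson's product-moment correlation) used to test wind-direction
# effects on rafting direction.

#' Convert degrees to radians on [0, 2*pi)
#' @param deg Angles in degrees.
#' @return Radians in [0, 2*pi).
#' @export
deg_to_circ <- function(deg) (.deg2rad(deg)) %% (2 * pi)

#' Circular mean direction
#'
#' Direction of the resultant vector of unit vectors at the given angles.
#'
#' @param theta Angles in radians.
#' @return Mean direction in [0, 2*pi), with the mean resultant length in
#'   attribute `rbar`.
#' @export
circular_mean <- function(theta) {
  if (length(theta) < 1 || any(!is.finite(theta)))
    stop("circular_mean: need finite angles", call. = FALSE)
  S <- mean(sin(theta)); C <- mean(cos(theta))
  rbar <- sqrt(S^2 + C^2)
  if (rbar < 1e-12)
    stop("circular_mean: zero resultant, mean direction undefined",
         call. = FALSE)
  mu <- atan2(S, C) %% (2 * pi)
  attr(mu, "rbar") <- rbar
  mu
}

#' Fit a von Mises distribution
#'
#' Maximum-likelihood fit: mean direction is the circular mean; the
#' concentration kappa solves A(kappa) = Rbar, where A = I1/I0 is the ratio
#' of modified Bessel functions, by bracketed root-finding (tolerance
#' 1e-10). Nearly-degenerate samples (Rbar ~ 1) cap kappa at 1e6 with a
#' warning.
#'
#' @param theta Angles in radians, n >= 2.
#' @return List with `mu` (radians), `kappa`, `rbar`, `n`.
#' @export
fit_vonmises <- function(theta) {
  if (length(theta) < 2)
    stop("fit_vonmises: need n >= 2", call. = FALSE)
  mu <- circular_mean(theta)
  rbar <- attr(mu, "rbar")
  kappa_max <- 1e6
  if (rbar > 1 - 1e-10) {
    warning("fit_vonmises: all angles (nearly) identical; kappa capped")
    kappa <- kappa_max
  } else {
    A <- function(k) {
      # I1/I0 via exponentially scaled Bessel functions for stability
      besselI(k, 1, expon.scaled = TRUE) /
        besselI(k, 0, expon.scaled = TRUE)
    }
    f <- function(k) A(k) - rbar
    hi <- 1
    while (f(hi) < 0 && hi < kappa_max) hi <- hi * 2
    if (hi >= kappa_max) {
      warning("fit_vonmises: concentration at cap")
      kappa <- kappa_max
    } else {
      kappa <- stats::uniroot(f, c(0, hi), tol = 1e-10)$root
    }
  }
  list(mu = as.numeric(mu), kappa = kappa, rbar = rbar,
       n = length(theta))
}

#' Jammalamadaka-Sarma circular correlation
#'
#' Correlation coefficient for paired angular data:
#' r = sum sin(a - abar) sin(b - bbar) /
#'     sqrt(sum sin^2(a - abar) * sum sin^2(b - bbar)),
#' with abar, bbar the circular means. The test statistic is
#' z = sqrt(n * l20 * l02 / l22) * r, where ljk are the sample mixed
#' moments of the sines of deviations, referred to the standard normal
#' (two-sided). An optional seeded permutation p-value is available for
#' small samples.
#'
#' @param alpha,beta Paired angle vectors in radians, equal length n >= 3.
#' @param permutation_p If TRUE, also compute a permutation p-value.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Seed for the permutation test.
#' @return Object of class `circ_corr`: list with `r`, `z`, `p`, `n`, and
#'   `p_perm` if requested.
#' @export
circular_correlation_js <- function(alpha, beta, permutation_p = FALSE,
                                    n_perm = 9999L, seed = 1L) {
  n <- length(alpha)
  if (length(beta) != n)
    stop("circular_correlation_js: series lengths differ", call. = FALSE)
  if (n < 3)
    stop("circular_correlation_js: need n >= 3 pairs", call. = FALSE)
  sa <- sin(alpha - circular_mean(alpha))
  sb <- sin(beta - circular_mean(beta))
  da <- sum(sa^2); db <- sum(sb^2)
  if (da < 1e-12 || db < 1e-12)
    stop("circular_correlation_js: degenerate margin (all deviations zero)",
         call. = FALSE)
  r <- sum(sa * sb) / sqrt(da * db)
  l20 <- mean(sa^2); l02 <- mean(sb^2); l22 <- mean(sa^2 * sb^2)
  z <- sqrt(n * l20 * l02 / l22) * r
  p <- 2 * stats::pnorm(-abs(z))
  out <- list(r = r, z = z, p = p, n = n)
  if (permutation_p) {
    set.seed(seed)
    robs <- abs(r)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      sp <- sb[sample.int(n)]
      rp <- sum(sa * sp) / sqrt(da * db)
      if (abs(rp) >= robs) hits <- hits + 1L
    }
    out$p_perm <- (hits + 1) / (n_perm + 1)
  }
  class(out) <- "circ_corr"
  out
}

#' @export
print.circ_corr <- function(x, ...) {
  cat("Jammalamadaka-Sarma circular correlation\n")
  cat(sprintf("  r = %.4f, z = %.3f, p = %.4f (n = %d)\n",
              x$r, x$z, x$p, x$n))
  if (!is.null(x$p_perm))
    cat(sprintf("  permutation p = %.4f\n", x$p_perm))
  invisible(x)
}
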