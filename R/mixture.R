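# Two-component normal mixture of between-fix speeds, fitted by
# expectation-maximisation, and the equal-posterior speed threshold that
# separates rafting from flying.

#' Fit a two-component normal mixture by EM
#'
#' Fits lambda1 N(mu1, sigma1) + lambda2 N(mu2, sigma2) to a sample of
#' speeds. EM runs to a relative log-likelihood change below `tol` (default
#' 1e-8, max 1000 iterations). Initialisation is quantile-based (means at
#' the 25th/75th percentiles, pooled sd, equal weights) plus `n_starts - 1`
#' jittered restarts under the given seed; the best log-likelihood wins.
#' Components are returned ordered mu1 < mu2. Degenerate runs (a component
#' sd collapsing below 1e-6 of the sample sd) are discarded.
#'
#' @param speeds Numeric sample, finite and non-negative, length >= 50.
#' @param seed Integer seed for the jittered restarts.
#' @param n_starts Number of initialisations (default 5).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @return Object of class `speed_mixture`: list with `mu`, `sigma`,
#'   `lambda` (each length 2, component 1 the slower), `loglik`,
#'   `n_iterations`, `converged`, `threshold` (equal-posterior speed),
#'   `overlap` (misclassification overlap diagnostic), `poorly_separated`,
#'   `n`.
#' @export
fit_speed_mixture <- function(speeds, seed = 1L, n_starts = 5L,
                              tol = 1e-8, max_iter = 1000L) {
  speeds <- as.numeric(speeds)
  if (any(!is.finite(speeds)) || any(speeds < 0))
    stop("fit_speed_mixture: speeds must be finite and non-negative",
         call. = FALSE)
  if (length(speeds) < 50)
    stop("fit_speed_mixture: need at least 50 speeds", call. = FALSE)
  s <- stats::sd(speeds)
  if (s == 0)
    stop("fit_speed_mixture: zero variance sample", call. = FALSE)

  q <- stats::quantile(speeds, c(0.25, 0.75), names = FALSE)
  starts <- list(list(mu = q, sigma = c(s, s), lambda = c(0.5, 0.5)))
  if (n_starts > 1) {
    if (!is.null(seed)) set.seed(seed)
    for (k in seq_len(n_starts - 1)) {
      starts[[k + 1]] <- list(
        mu = q + stats::rnorm(2) * s / 2,
        sigma = pmax(c(s, s) * exp(stats::rnorm(2) * 0.3), 1e-3 * s),
        lambda = {p <- stats::runif(1, 0.2, 0.8); c(p, 1 - p)})
    }
  }

  best <- NULL
  for (st in starts) {
    fit <- .em_two_normal(speeds, st, tol, max_iter)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop("fit_speed_mixture: all starts degenerate", call. = FALSE)

  o <- order(best$mu)
  best$mu <- best$mu[o]; best$sigma <- best$sigma[o]
  best$lambda <- best$lambda[o]
  best$n <- length(speeds)
  # overlap diagnostic: total posterior mass assigned across the threshold
  best$overlap <- .mixture_overlap(best)
  best$poorly_separated <- (best$mu[2] - best$mu[1]) <
    (best$sigma[1] + best$sigma[2]) || best$overlap > 0.2
  if (best$poorly_separated)
    warning("fit_speed_mixture: components poorly separated; ",
            "threshold may be unstable")
  best$threshold <- tryCatch(classification_threshold(best),
                             error = function(e) NA_real_)
  class(best) <- "speed_mixture"
  best
}

# EM inner loop; returns NULL on degeneracy
.em_two_normal <- function(x, start, tol, max_iter) {
  mu <- start$mu; sigma <- start$sigma; lambda <- start$lambda
  n <- length(x)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  sd_floor <- 1e-6 * stats::sd(x)
  for (iter in seq_len(max_iter)) {
    d1 <- lambda[1] * stats::dnorm(x, mu[1], sigma[1])
    d2 <- lambda[2] * stats::dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
    ll <- sum(log(tot))
    # EM guarantees monotone log-likelihood; a real decrease is a bug
    if (is.finite(ll_old) && ll < ll_old - 1e-8 * (abs(ll_old) + 1))
      stop("EM log-likelihood decreased: internal error", call. = FALSE)
    ll_trace <- c(ll_trace, ll)
    g1 <- d1 / tot
    g2 <- 1 - g1
    n1 <- sum(g1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) return(NULL)
    mu <- c(sum(g1 * x) / n1, sum(g2 * x) / n2)
    sigma <- sqrt(c(sum(g1 * (x - mu[1])^2) / n1,
                    sum(g2 * (x - mu[2])^2) / n2))
    if (any(sigma < sd_floor)) return(NULL)
    lambda <- c(n1, n2) / n
    done <- is.finite(ll_old) &&
      abs(ll - ll_old) < tol * (abs(ll_old) + tol)
    ll_old <- ll
    if (done)
      return(list(mu = mu, sigma = sigma, lambda = lambda, loglik = ll,
                  n_iterations = iter, converged = TRUE,
                  loglik_trace = ll_trace))
  }
  list(mu = mu, sigma = sigma, lambda = lambda, loglik = ll_old,
       n_iterations = max_iter, converged = FALSE,
       loglik_trace = ll_trace)
}

.mixture_overlap <- function(m) {
  thr <- tryCatch(classification_threshold(m), error = function(e) NA)
  if (!is.finite(thr)) return(1)
  # mass of the slow component above the threshold + fast below it
  m$lambda[1] * stats::pnorm(thr, m$mu[1], m$sigma[1],
                             lower.tail = FALSE) +
    m$lambda[2] * stats::pnorm(thr, m$mu[2], m$sigma[2])
}

#' Equal-posterior classification threshold of a two-normal mixture
#'
#' The speed at which a datum switches from being more likely under the
#' slow (rafting) component to more likely under the fast (flying) one:
#' the root of lambda1 phi(s; mu1, sigma1) = lambda2 phi(s; mu2, sigma2)
#' inside (mu1, mu2), found by safeguarded bisection on the log-density
#' difference.
#'
#' @param m A `speed_mixture` or a list with `mu`, `sigma`, `lambda`.
#' @param tol Bisection tolerance on the speed (default 1e-10).
#' @return The threshold speed.
#' @export
classification_threshold <- function(m, tol = 1e-10) {
  mu <- m$mu; sigma <- m$sigma; lambda <- m$lambda
  if (!(mu[1] < mu[2]))
    stop("classification_threshold: components must be ordered mu1 < mu2",
         call. = FALSE)
  f <- function(s)
    (log(lambda[1]) + stats::dnorm(s, mu[1], sigma[1], log = TRUE)) -
    (log(lambda[2]) + stats::dnorm(s, mu[2], sigma[2], log = TRUE))
  lo <- mu[1]; hi <- mu[2]
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo <= 0 || fhi >= 0)
    stop("classification_threshold: no equal-posterior crossing in ",
         "(mu1, mu2); components overlap pathologically", call. = FALSE)
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' @export
print.speed_mixture <- function(x, ...) {
  cat("Two-component normal speed mixture (EM fit)\n")
  cat(sprintf("  component 1 (slow): mu = %.3f, sd = %.3f, weight = %.3f\n",
              x$mu[1], x$sigma[1], x$lambda[1]))
  cat(sprintf("  component 2 (fast): mu = %.3f, sd = %.3f, weight = %.3f\n",
              x$mu[2], x$sigma[2], x$lambda[2]))
  cat(sprintf("  logLik %.2f after %d iterations (%s)\n", x$loglik,
              x$n_iterations,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  equal-posterior threshold: %.3f m/s\n", x$threshold))
  if (isTRUE(x$poorly_separated))
    cat("  warning: components poorly separated\n")
  invisible(x)
}
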