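# Raft-size vs wind-speed regression: log(size) ~ wind speed by
# generalized least squares, with moving-average MA(q) residual
# correlation nested within Julian day. The error covariance is
# block-diagonal, one block per day, each block the Toeplitz correlation
# implied by the MA coefficients; beta is profiled out by weighted least
# squares and (theta, sigma^2) maximised numerically on the ML or REML
# criterion.

#' Theoretical autocorrelation of an MA(q) process
#'
#' rho(h) = (theta_h + sum_i theta_i theta_{i+h}) / (1 + sum theta_i^2)
#' for 1 <= h <= q and 0 beyond (with theta_0 = 1 implicit).
#'
#' @param theta MA coefficients theta_1..theta_q.
#' @param lag_max Largest lag to return.
#' @return Numeric vector rho(0..lag_max).
#' @export
ma_acf <- function(theta, lag_max) {
  q <- length(theta)
  th <- c(1, theta)
  denom <- sum(th^2)
  rho <- vapply(seq_len(lag_max), function(h) {
    if (h > q) return(0)
    sum(th[seq_len(q + 1 - h)] * th[seq_len(q + 1 - h) + h]) / denom
  }, numeric(1))
  c(1, rho)
}

#' MA(q) within-block correlation matrix
#'
#' Toeplitz correlation matrix of the MA process for a block of
#' consecutive within-day observations. Coefficients must lie in the
#' invertibility region (all roots of 1 + theta_1 z + ... + theta_q z^q
#' outside the unit circle).
#'
#' @param theta MA coefficients.
#' @param block_size Number of observations in the block (>= 1).
#' @return block_size x block_size correlation matrix.
#' @export
ma_correlation_matrix <- function(theta, block_size) {
  if (block_size < 1)
    stop("ma_correlation_matrix: block_size must be >= 1", call. = FALSE)
  if (!ma_invertible(theta))
    stop("ma_correlation_matrix: theta outside the invertibility region",
         call. = FALSE)
  rho <- ma_acf(theta, block_size - 1)
  stats::toeplitz(rho[seq_len(block_size)])
}

#' Check MA invertibility
#' @param theta MA coefficients.
#' @return TRUE if all roots of the MA polynomial lie outside the unit
#'   circle.
#' @export
ma_invertible <- function(theta) {
  if (all(theta == 0)) return(TRUE)
  all(Mod(polyroot(c(1, theta))) > 1)
}

# Monahan (1984) map from unconstrained reals to invertible MA
# coefficients, via partial coefficients tanh(x) and the Levinson-type
# recursion; bijective onto the invertibility region.
.ma_from_unconstrained <- function(x) {
  r <- tanh(x)
  q <- length(r)
  phi <- r
  if (q > 1) {
    for (j in 2:q) {
      new <- phi[seq_len(j - 1)] - r[j] * phi[rev(seq_len(j - 1))]
      phi[seq_len(j - 1)] <- new
    }
  }
  -phi  # MA poly 1 + theta z + ... invertible <=> AR(phi) stationary
}

.ma_to_unconstrained <- function(theta) {
  # inverse of .ma_from_unconstrained (reverse Levinson recursion)
  phi <- -theta
  q <- length(phi)
  r <- numeric(q)
  work <- phi
  for (j in q:1) {
    r[j] <- work[j]
    if (j > 1) {
      denom <- 1 - r[j]^2
      prev <- (work[seq_len(j - 1)] +
                 r[j] * work[rev(seq_len(j - 1))]) / denom
      work[seq_len(j - 1)] <- prev
    }
  }
  atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
}

# Profiled (RE)ML criterion for given theta. Returns the pieces needed by
# the fitter. blocks: list of index vectors; X, y full design/response.
.gls_profile <- function(theta, X, y, blocks, reml) {
  n <- length(y); p <- ncol(X)
  sizes <- lengths(blocks)
  chols <- new.env(parent = emptyenv())
  logdet <- 0
  Xw <- matrix(0, n, p); yw <- numeric(n)
  pos <- 0
  for (b in blocks) {
    m <- length(b)
    key <- as.character(m)
    U <- get0(key, envir = chols)
    if (is.null(U)) {
      R <- ma_correlation_matrix(theta, m)
      U <- chol(R)
      assign(key, U, envir = chols)
    }
    logdet <- logdet + 2 * sum(log(diag(U)))
    idx <- pos + seq_len(m)
    Xw[idx, ] <- backsolve(U, X[b, , drop = FALSE], transpose = TRUE)
    yw[idx] <- backsolve(U, y[b], transpose = TRUE)
    pos <- pos + m
  }
  XtX <- crossprod(Xw)
  Xty <- crossprod(Xw, yw)
  beta <- tryCatch(solve(XtX, Xty), error = function(e)
    stop("fit_gls_ma: singular design", call. = FALSE))
  res <- yw - Xw %*% beta
  rss <- sum(res^2)
  if (reml) {
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2) + logdet +
                    determinant(XtX, logarithm = TRUE)$modulus[1] +
                    (n - p))
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + logdet + n)
  }
  list(loglik = as.numeric(ll), beta = drop(beta), sigma2 = s2,
       XtX = XtX, rss = rss, resid_w = drop(res))
}

#' Fit the raft-size GLS model with MA(q) errors
#'
#' Regresses log(raft size) on wind speed with MA(q) error correlation
#' nested within Julian day. Records are ordered within each day by their
#' input order (observation time); the MA lag index runs over that order.
#' theta is optimised on the Monahan-transformed scale by Nelder-Mead from
#' several seeded starts; beta and sigma are profiled out analytically.
#'
#' @param data data.frame with columns `raft_size` (>= 1), `wind_speed`,
#'   `julian_day`; rows sorted by (day, within-day time).
#' @param q MA order (default 4); `q = 0` gives ordinary least squares.
#' @param method `"REML"` (default) or `"ML"`.
#' @param n_starts Optimiser restarts (default 5).
#' @param seed Seed for the jittered restarts.
#' @return Object of class `size_model_fit`: coefficients table
#'   (estimate, SE, t, p, 95% CI), `theta`, `sigma`, `loglik`, `AIC`,
#'   `BIC`, `n`, `df_residual`, `method`, standardized (whitened)
#'   residuals and their five-number summary.
#' @export
fit_gls_ma <- function(data, q = 4, method = c("REML", "ML"),
                       n_starts = 5L, seed = 1L) {
  method <- match.arg(method)
  reml <- method == "REML"
  need <- c("raft_size", "wind_speed", "julian_day")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("fit_gls_ma: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(data$raft_size < 1))
    stop("fit_gls_ma: raft sizes must be >= 1 (log-transformed response)",
         call. = FALSE)
  if (length(unique(data$wind_speed)) < 2)
    stop("fit_gls_ma: need at least 2 distinct wind speeds", call. = FALSE)
  y <- log(data$raft_size)
  X <- cbind(`(Intercept)` = 1, wind_speed = data$wind_speed)
  n <- length(y); p <- ncol(X)
  blocks <- split(seq_len(n), factor(data$julian_day,
                                     levels = unique(data$julian_day)))

  if (q == 0) {
    prof <- .gls_profile(numeric(0), X, y, blocks, reml)
    theta <- numeric(0); opt_ok <- TRUE
  } else {
    obj <- function(x) {
      th <- .ma_from_unconstrained(x)
      -.gls_profile(th, X, y, blocks, reml)$loglik
    }
    set.seed(seed)
    starts <- c(list(rep(0, q)),
                replicate(max(0, n_starts - 1),
                          stats::rnorm(q, sd = 0.3), simplify = FALSE))
    best <- NULL
    for (x0 in starts) {
      o <- tryCatch(
        stats::optim(x0, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-10)),
        error = function(e) NULL)
      if (is.null(o)) next
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best))
      stop("fit_gls_ma: optimiser failed from all starts", call. = FALSE)
    opt_ok <- best$convergence == 0
    if (!opt_ok)
      warning("fit_gls_ma: optimiser did not report convergence (code ",
              best$convergence, ")")
    theta <- .ma_from_unconstrained(best$par)
    prof <- .gls_profile(theta, X, y, blocks, reml)
  }

  sigma2 <- prof$sigma2
  vcov_beta <- solve(prof$XtX) * sigma2
  se <- sqrt(diag(vcov_beta))
  beta <- prof$beta
  df_res <- n - p
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df_res)
  tcrit <- stats::qt(0.975, df_res)
  coef_table <- data.frame(
    term = colnames(X), estimate = beta, std_error = se,
    t_value = tval, p_value = pval,
    ci_lower = beta - tcrit * se, ci_upper = beta + tcrit * se,
    row.names = NULL)

  k <- p + q + 1  # betas + thetas + sigma^2
  ll <- prof$loglik
  nn <- if (reml) n - p else n
  fit <- list(
    coefficients = coef_table, theta = theta, sigma = sqrt(sigma2),
    loglik = ll, AIC = 2 * k - 2 * ll, BIC = k * log(nn) - 2 * ll,
    n = n, df_residual = df_res, q = q, method = method,
    converged = opt_ok,
    residuals_std = prof$resid_w / sqrt(sigma2),
    vcov = vcov_beta, blocks = lengths(blocks))
  fit$residual_summary <- stats::quantile(
    fit$residuals_std, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  names(fit$residual_summary) <- c("min", "q1", "median", "q3", "max")
  class(fit) <- "size_model_fit"
  fit
}

#' Standardized (whitened) residuals of a size-model fit
#'
#' Residuals premultiplied by the Cholesky factor of the inverse error
#' covariance, scaled to unit variance under the model.
#'
#' @param fit A `size_model_fit`.
#' @return List with `residuals` and `summary` (min, Q1, median, Q3, max).
#' @export
standardized_residuals <- function(fit) {
  if (!inherits(fit, "size_model_fit"))
    stop("standardized_residuals: not a size_model_fit", call. = FALSE)
  list(residuals = fit$residuals_std, summary = fit$residual_summary)
}

#' @export
print.size_model_fit <- function(x, ...) {
  cat(sprintf("Generalized least squares: log(raft_size) ~ wind_speed\n"))
  cat(sprintf("Correlation structure: MA(%d) nested within day; %s\n",
              x$q, x$method))
  cat(sprintf("  AIC %.1f  BIC %.1f  logLik %.1f\n", x$AIC, x$BIC,
              x$loglik))
  if (x$q > 0)
    cat("  theta:", paste(sprintf("%.3f", x$theta), collapse = " "), "\n")
  ct <- x$coefficients
  for (i in seq_len(nrow(ct)))
    cat(sprintf("  %-12s %8.3f (SE %.3f)  t = %.3f  p = %.4f  CI [%.3f, %.3f]\n",
                ct$term[i], ct$estimate[i], ct$std_error[i], ct$t_value[i],
                ct$p_value[i], ct$ci_lower[i], ct$ci_upper[i]))
  cat(sprintf("  residual SD %.3f on %d residual df (n = %d)\n",
              x$sigma, x$df_residual, x$n))
  rs <- x$residual_summary
  cat(sprintf("  std. residuals: %.3f / %.3f / %.3f / %.3f / %.3f\n",
              rs[1], rs[2], rs[3], rs[4], rs[5]))
  invisible(x)
}
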