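#' The generalised extreme value distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the GEV distribution under the convention
#' \deqn{G(x) = \exp(-[1 + c (x - a)/b]^{-1/c})} on
#' \eqn{1 + c (x - a)/b > 0}, with the \eqn{c \to 0} Gumbel limit
#' \eqn{\exp(-\exp(-(x - a)/b))}. Positive shape `c` gives the heavy-tailed
#' (Frechet) domain, negative `c` a finite upper endpoint at `a - b/c`.
#' Below the lower support endpoint the cdf is 0; above a finite upper
#' endpoint it is 1.
#'
#' @param x,q,p Numeric vectors of quantiles / probabilities.
#' @param n Number of draws.
#' @param a,b,c Location, scale (> 0) and shape.
#' @param log,lower.tail As in the usual d/p/q functions.
#' @return `dgev` the density, `pgev` the cdf, `qgev` the quantile
#'   function, `rgev` random draws.
#' @name gev
NULL

.gev_tol <- 1e-8  # |c| below this uses the Gumbel limit

#' @rdname gev
#' @export
dgev <- function(x, a = 0, b = 1, c = 0, log = FALSE) {
  stopifnot(b > 0)
  z <- (x - a) / b
  if (abs(c) < .gev_tol) {
    ld <- -log(b) - z - exp(-z)
  } else {
    t <- 1 + c * z
    ld <- ifelse(t > 0,
                 -log(b) - (1 + 1 / c) * log(pmax(t, .Machine$double.xmin)) -
                   pmax(t, .Machine$double.xmin)^(-1 / c),
                 -Inf)
  }
  if (log) ld else exp(ld)
}

#' @rdname gev
#' @export
pgev <- function(q, a = 0, b = 1, c = 0, lower.tail = TRUE) {
  stopifnot(b > 0)
  z <- (q - a) / b
  if (abs(c) < .gev_tol) {
    p <- exp(-exp(-z))
  } else {
    t <- 1 + c * z
    p <- ifelse(t > 0, exp(-t^(-1 / c)), ifelse(c > 0, 0, 1))
  }
  if (lower.tail) p else 1 - p
}

#' @rdname gev
#' @export
qgev <- function(p, a = 0, b = 1, c = 0) {
  stopifnot(b > 0, all(p >= 0 & p <= 1))
  y <- -log(p)  # p = exp(-y)
  if (abs(c) < .gev_tol) {
    a - b * log(y)
  } else {
    a + b * (y^(-c) - 1) / c
  }
}

#' @rdname gev
#' @export
rgev <- function(n, a = 0, b = 1, c = 0) {
  qgev(runif(n), a, b, c)
}

# Negative log-likelihood on the natural scale, +Inf outside the support.
.gev_nll <- function(par, x) {
  a <- par[1]; b <- par[2]; c <- par[3]
  if (!is.finite(a) || !is.finite(b) || !is.finite(c) || b <= 0) return(Inf)
  z <- (x - a) / b
  n <- length(x)
  if (abs(c) < .gev_tol) {
    return(n * log(b) + sum(z) + sum(exp(-z)))
  }
  t <- 1 + c * z
  if (any(t <= 0)) return(Inf)
  n * log(b) + (1 + 1 / c) * sum(log(t)) + sum(t^(-1 / c))
}

# Probability-weighted-moments start (Hosking, Wallis & Wood). Hosking's
# shape kappa equals -c under this package's sign convention.
.gev_pwm_start <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  i <- seq_len(n)
  b0 <- mean(xs)
  b1 <- sum((i - 1) / (n - 1) * xs) / n
  b2 <- sum((i - 1) * (i - 2) / ((n - 1) * (n - 2)) * xs) / n
  z <- (2 * b1 - b0) / (3 * b2 - b0) - log(2) / log(3)
  kap <- 7.8590 * z + 2.9554 * z^2
  if (!is.finite(kap) || abs(kap) < 1e-6) kap <- 1e-6
  g <- gamma(1 + kap)
  alpha <- (2 * b1 - b0) * kap / (g * (1 - 2^(-kap)))
  xi <- b0 + alpha * (g - 1) / kap
  if (!is.finite(alpha) || alpha <= 0) return(NULL)
  c(a = xi, b = alpha, c = -kap)
}

# Gumbel method-of-moments start.
.gev_gumbel_start <- function(x) {
  b <- sd(x) * sqrt(6) / pi
  a <- mean(x) - 0.5772156649015329 * b
  c(a = a, b = max(b, .Machine$double.eps), c = 0)
}

#' Fit a GEV null distribution by maximum likelihood
#'
#' Fits location, scale and shape to a sample of null GPS statistics (or
#' any numeric sample) by maximising the GEV log-likelihood. Optimisation
#' uses Nelder-Mead with an infinite barrier outside the support
#' constraint, started from probability-weighted-moments and Gumbel
#' method-of-moments estimates, with up to 5 additional jittered restarts
#' before declaring non-convergence (relative log-likelihood tolerance
#' 1e-8). Standard errors come from the numerically inverted observed
#' information at the optimum.
#'
#' @param sample A numeric vector, or a `gps_null` object from
#'   [permutation_null()]. At least 100 observations, not all equal.
#' @param max_restarts Extra random restarts after the two deterministic
#'   starts.
#' @return An object of class `gev_fit`: list with `estimate` (named
#'   `a`, `b`, `c`), `std_errors`, `loglik`, `n_fit`, `converged`.
#'   `tidy()` gives a term/estimate/std.error tibble, `glance()` a one-row
#'   fit summary.
#' @examples
#' set.seed(1)
#' fit <- fit_gev(rgev(1000, a = 2, b = 0.5, c = 0.1))
#' tidy(fit)
#' @export
fit_gev <- function(sample, max_restarts = 5) {
  x <- if (inherits(sample, "gps_null")) sample$d_values else as.numeric(sample)
  if (length(x) < 100) {
    abort(sprintf("GEV fitting needs at least 100 observations (got %d)",
                  length(x)),
          class = "gpstest_input_error")
  }
  if (all(x == x[1])) {
    abort("GEV fitting needs a non-degenerate sample (all values equal)",
          class = "gpstest_input_error")
  }
  starts <- list(.gev_pwm_start(x), .gev_gumbel_start(x))
  starts <- Filter(function(s) !is.null(s) && is.finite(.gev_nll(s, x)),
                   starts)
  if (length(starts) == 0) starts <- list(.gev_gumbel_start(x))

  run_one <- function(start) {
    optim(start, .gev_nll, x = x, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-8))
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(run_one(s), error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  r <- 0
  while ((is.null(best) || best$convergence != 0) && r < max_restarts) {
    r <- r + 1
    s0 <- starts[[1 + (r %% length(starts))]]
    s <- s0 * (1 + 0.1 * rnorm(3))
    s[2] <- abs(s[2])
    fit <- tryCatch(run_one(s), error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    abort("GEV fit failed: no start produced a finite likelihood",
          class = "gpstest_fit_error")
  }
  est <- setNames(best$par, c("a", "b", "c"))
  se <- rep(NA_real_, 3)
  hess <- tryCatch(optimHess(best$par, .gev_nll, x = x),
                   error = function(e) NULL)
  if (!is.null(hess)) {
    cov <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(cov) && all(is.finite(diag(cov))) && all(diag(cov) > 0)) {
      se <- sqrt(diag(cov))
    }
  }
  structure(
    list(
      estimate = est,
      std_errors = setNames(se, c("a", "b", "c")),
      loglik = -best$value,
      n_fit = length(x),
      converged = best$convergence == 0
    ),
    class = "gev_fit"
  )
}

#' GEV cdf under a fitted null
#'
#' @param x Numeric vector of quantiles.
#' @param params A `gev_fit` object (or named list with `estimate`).
#' @return `G(x)` under the fitted parameters.
#' @export
gev_cdf <- function(x, params) {
  est <- params$estimate
  pgev(x, est[["a"]], est[["b"]], est[["c"]])
}

#' @export
print.gev_fit <- function(x, ...) {
  cat(sprintf(
    "GEV fit (n = %d, loglik = %.2f, %s)\n  a = %.4f (%.4f), b = %.4f (%.4f), c = %.4f (%.4f)\n",
    x$n_fit, x$loglik, if (x$converged) "converged" else "NOT converged",
    x$estimate[["a"]], x$std_errors[["a"]],
    x$estimate[["b"]], x$std_errors[["b"]],
    x$estimate[["c"]], x$std_errors[["c"]]))
  invisible(x)
}

#' @export
tidy.gev_fit <- function(x, ...) {
  tibble::tibble(
    term = c("location", "scale", "shape"),
    estimate = unname(x$estimate),
    std.error = unname(x$std_errors)
  )
}

#' @export
glance.gev_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    AIC = 2 * 3 - 2 * x$loglik,
    nobs = x$n_fit,
    converged = x$converged
  )
}
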