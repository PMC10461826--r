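#' Permutation null sample of the GPS statistic
#'
#' Generates null realisations of the GPS statistic by repeatedly drawing a
#' uniform random permutation of the second p-value vector and recomputing
#' the statistic on the permuted pairing. Permutation leaves the marginal
#' ecdfs unchanged as multisets, so the marginal ranks are computed once and
#' reused; only the joint counts are recomputed per replicate.
#'
#' @param pair A `gps_pair`.
#' @param n_perm Number of permutations; at least 100, with a warning below
#'   1,000. The default of 3,000 balances parameter-estimate accuracy
#'   against running time.
#' @param seed Integer seed; the same seed reproduces `d_values` exactly.
#'   `NULL` uses the current RNG state.
#' @param backend Bivariate-ecdf backend, see [bivariate_ecdf()].
#' @return An object of class `gps_null`: list with `d_values`, `n_perm`,
#'   `seed`, `n_variants`, `backend`.
#' @examples
#' pair <- simulate_independent_null(500, seed = 1)
#' null <- permutation_null(pair, n_perm = 200, seed = 2)
#' @export
permutation_null <- function(pair, n_perm = 3000, seed = NULL,
                             backend = c("tree", "dac", "naive")) {
  backend <- match.arg(backend)
  pair <- validate_gps_pair(pair)
  n_perm <- as.integer(n_perm)
  if (n_perm < 100) {
    abort("`n_perm` must be at least 100", class = "gpstest_input_error")
  }
  if (n_perm < 1000) {
    rlang::warn(sprintf(
      "n_perm = %d is low; GEV parameter estimates may be imprecise below 1,000 permutations",
      n_perm))
  }
  if (!is.null(seed)) set.seed(seed)
  d <- tryCatch(
    .gps_perm_null_cpp(pair$p_a, pair$p_b, n_perm, backend),
    error = function(e) {
      if (grepl("degenerate", conditionMessage(e))) {
        abort(conditionMessage(e), class = "gpstest_degenerate_error")
      }
      abort(conditionMessage(e), class = "gpstest_input_error")
    }
  )
  structure(
    list(d_values = d, n_perm = n_perm, seed = seed,
         n_variants = nrow(pair), backend = backend),
    class = "gps_null"
  )
}

#' @export
print.gps_null <- function(x, ...) {
  cat(sprintf(
    "GPS permutation null: %d realisations on %d variants (backend %s)\n",
    x$n_perm, x$n_variants, x$backend))
  print(summary(x$d_values))
  invisible(x)
}

#' GPS-GEV p-value
#'
#' Upper-tail p-value of an observed GPS statistic under a fitted GEV null:
#' `p = 1 - G(D)`. With negative fitted shape the GEV has a finite upper
#' endpoint `a - b/c`; an observed statistic beyond it gets p = 0 and the
#' flag `"p beyond fitted support"`. No pseudo-count floor is applied.
#'
#' @param D Observed GPS statistic, >= 0.
#' @param params A `gev_fit`.
#' @return A list with `p_value` and `flags` (character vector, possibly
#'   empty).
#' @export
gps_gev_pvalue <- function(D, params) {
  stopifnot(D >= 0)
  est <- params$estimate
  p <- pgev(D, est[["a"]], est[["b"]], est[["c"]], lower.tail = FALSE)
  flags <- character()
  if (est[["c"]] < 0 && D > est[["a"]] - est[["b"]] / est[["c"]]) {
    p <- 0
    flags <- "p beyond fitted support"
  }
  list(p_value = p, flags = flags)
}

#' GPS-Exp p-value
#'
#' The legacy calibration treats `1/D^2` as a standard exponential random
#' variable under the null. Large D corresponds to small `1/D^2`, so
#' `p = P(X <= 1/D^2) = 1 - exp(-1/D^2)`, monotone decreasing in D. `D = 0`
#' returns p = 1 by continuity, flagged.
#'
#' @param D Observed GPS statistic, >= 0.
#' @return A list with `p_value` and `flags`.
#' @examples
#' gps_exp_pvalue(1 / sqrt(log(2)))$p_value  # 0.5
#' @export
gps_exp_pvalue <- function(D) {
  stopifnot(D >= 0)
  if (D == 0) {
    return(list(p_value = 1, flags = "D = 0: p = 1 by continuity"))
  }
  list(p_value = 1 - exp(-1 / D^2), flags = character())
}

.new_test_report <- function(method, statistic, p_value, n_variants, n_perm,
                             gev_params = NULL, flags = character(),
                             extra = list(), metadata = list()) {
  structure(
    c(list(method = method, statistic = statistic, p_value = p_value,
           n_variants = n_variants, n_perm = n_perm,
           gev_params = gev_params, flags = flags, metadata = metadata),
      extra),
    class = "gps_test_report"
  )
}

#' Run the GPS test on a harmonized pair
#'
#' The full pipeline: compute the observed GPS statistic, generate the
#' permutation null, fit the GEV by maximum likelihood, and return
#' p-values under both the GPS-GEV null and the legacy GPS-Exp null for
#' the same statistic.
#'
#' @inheritParams permutation_null
#' @return A `gps_test_report` (method `"gps-gev"`) carrying `statistic`,
#'   `p_value` (GEV), `p_value_exp`, the fitted `gev_params`, `flags` and
#'   echoed pair metadata. `tidy()` gives a one-row tibble;
#'   [write_report()] serialises it as single-row TSV.
#' @examples
#' pair <- simulate_independent_null(1000, seed = 1)
#' rep <- gps_gev_test(pair, n_perm = 500, seed = 2)
#' tidy(rep)
#' @export
gps_gev_test <- function(pair, n_perm = 3000, seed = NULL,
                         backend = c("tree", "dac", "naive")) {
  backend <- match.arg(backend)
  pair <- validate_gps_pair(pair)
  obs <- gps_statistic(pair, backend)
  null <- permutation_null(pair, n_perm = n_perm, seed = seed,
                           backend = backend)
  fit <- fit_gev(null)
  pg <- gps_gev_pvalue(obs$D, fit)
  pe <- gps_exp_pvalue(obs$D)
  flags <- c(pg$flags, pe$flags)
  if (!fit$converged) flags <- c(flags, "GEV fit did not converge")
  .new_test_report(
    method = "gps-gev", statistic = obs$D, p_value = pg$p_value,
    n_variants = nrow(pair), n_perm = n_perm, gev_params = fit,
    flags = flags,
    extra = list(p_value_exp = pe$p_value, gps_result = obs,
                 null_sample = null, seed = seed),
    metadata = pair_metadata(pair)
  )
}

#' Run the GPS-Exp test (no permutations)
#'
#' @inheritParams gps_gev_test
#' @return A `gps_test_report` with method `"gps-exp"` and `n_perm = 0`.
#' @export
gps_exp_test <- function(pair, backend = c("tree", "dac", "naive")) {
  backend <- match.arg(backend)
  pair <- validate_gps_pair(pair)
  obs <- gps_statistic(pair, backend)
  pe <- gps_exp_pvalue(obs$D)
  .new_test_report(
    method = "gps-exp", statistic = obs$D, p_value = pe$p_value,
    n_variants = nrow(pair), n_perm = 0L, flags = pe$flags,
    extra = list(gps_result = obs), metadata = pair_metadata(pair)
  )
}

#' Test a harmonized pair for shared genetic architecture
#'
#' Dispatcher over the three implemented tests of bivariate independence of
#' the paired p-values: the permutation-calibrated `"gps-gev"` test
#' (recommended), the legacy `"gps-exp"` closed-form calibration, and
#' `"hoeffding"`, the classical comparator with a permutation p-value.
#'
#' @inheritParams gps_gev_test
#' @param method Which test to run.
#' @return A `gps_test_report`.
#' @export
gps_test <- function(pair, method = c("gps-gev", "gps-exp", "hoeffding"),
                     n_perm = 3000, seed = NULL,
                     backend = c("tree", "dac", "naive")) {
  method <- match.arg(method)
  switch(method,
    "gps-gev" = gps_gev_test(pair, n_perm = n_perm, seed = seed,
                             backend = backend),
    "gps-exp" = gps_exp_test(pair, backend = backend),
    "hoeffding" = hoeffding_test(pair, n_perm = n_perm, seed = seed)
  )
}

#' @export
print.gps_test_report <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4f, p = %.4g (n = %d variants",
              x$method, x$statistic, x$p_value, x$n_variants))
  if (x$n_perm > 0) cat(sprintf(", %d permutations", x$n_perm))
  cat(")\n")
  if (!is.null(x$p_value_exp)) {
    cat(sprintf("  GPS-Exp p-value for the same statistic: %.4g\n",
                x$p_value_exp))
  }
  if (!is.null(x$gev_params)) {
    e <- x$gev_params$estimate
    cat(sprintf("  fitted GEV null: a = %.4f, b = %.4f, c = %.4f\n",
                e[["a"]], e[["b"]], e[["c"]]))
  }
  if (length(x$flags) > 0) {
    cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
tidy.gps_test_report <- function(x, ...) {
  e <- if (is.null(x$gev_params)) c(a = NA_real_, b = NA_real_, c = NA_real_)
       else x$gev_params$estimate
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    p_value = x$p_value,
    p_value_exp = if (is.null(x$p_value_exp)) NA_real_ else x$p_value_exp,
    n_variants = x$n_variants,
    n_perm = x$n_perm,
    a = unname(e[["a"]]), b = unname(e[["b"]]), c = unname(e[["c"]]),
    flags = paste(x$flags, collapse = "; ")
  )
}

#' @export
glance.gps_test_report <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p_value = x$p_value, n_variants = x$n_variants,
                 n_perm = x$n_perm)
}

#' Serialise a test report as single-row TSV
#'
#' Columns: method, statistic, p_value, n_variants, n_perm, a, b, c, flags.
#'
#' @param report A `gps_test_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  readr::write_tsv(tidy(report)[, c("method", "statistic", "p_value",
                                    "n_variants", "n_perm", "a", "b", "c",
                                    "flags")],
                   path)
  invisible(path)
}
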