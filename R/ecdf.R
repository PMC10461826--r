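#' Marginal empirical distribution function values
#'
#' For each observation, the fraction of sample values less than or equal to
#' it. Ties receive the equal, maximal-rank value, matching the set
#' definition of the ecdf.
#'
#' @param values Numeric vector, finite, length >= 1.
#' @return Numeric vector: `out[i] = #\{j : values[j] <= values[i]\} / n`.
#' @examples
#' marginal_ecdf(c(0.1, 0.5, 0.9))  # 1/3, 2/3, 1
#' @export
marginal_ecdf <- function(values) {
  if (length(values) < 1) {
    abort("`values` must have length >= 1", class = "gpstest_input_error")
  }
  bad <- which(!is.finite(values))
  if (length(bad) > 0) {
    abort(sprintf("non-finite value at index %d", bad[1]),
          class = "gpstest_input_error")
  }
  rank(values, ties.method = "max") / length(values)
}

#' Bivariate empirical distribution function values
#'
#' For each index i, the fraction of index pairs j with `u[j] <= u[i]` and
#' `v[j] <= v[i]`. Three interchangeable backends produce identical output
#' (they are compared on exact integer counts): `"naive"` is the quadratic
#' two-nested-loop reference, `"tree"` sweeps the points in u-order while
#' querying an order-statistic (Fenwick) structure over v-ranks, and
#' `"dac"` is a divide-and-conquer dominance count. `"tree"` is the fastest
#' and the default throughout the package.
#'
#' @param u,v Numeric vectors of equal length.
#' @param backend One of `"tree"`, `"dac"`, `"naive"`.
#' @return Numeric vector of joint ecdf values, each a multiple of 1/n in
#'   \[1/n, 1\].
#' @examples
#' bivariate_ecdf(c(0.1, 0.2), c(0.2, 0.1))  # 1/2, 1/2
#' @export
bivariate_ecdf <- function(u, v, backend = c("tree", "dac", "naive")) {
  backend <- match.arg(backend)
  .joint_count_cpp(as.numeric(u), as.numeric(v), backend) / length(u)
}

#' Full ecdf profile of a harmonized pair
#'
#' Per-variant marginal and joint ecdf values, the raw material of the GPS
#' statistic. Every row satisfies the Frechet bounds
#' `max(0, F_u + F_v - 1) <= F_uv <= min(F_u, F_v)`.
#'
#' @param pair A `gps_pair` (or data frame with `p_a`, `p_b`).
#' @inheritParams bivariate_ecdf
#' @return A tibble with columns `variant_id`, `F_u`, `F_v`, `F_uv`,
#'   `backend_name`.
#' @export
ecdf_profile <- function(pair, backend = c("tree", "dac", "naive")) {
  backend <- match.arg(backend)
  pair <- validate_gps_pair(pair)
  tibble::tibble(
    variant_id = pair$variant_id,
    F_u = marginal_ecdf(pair$p_a),
    F_v = marginal_ecdf(pair$p_b),
    F_uv = bivariate_ecdf(pair$p_a, pair$p_b, backend),
    backend_name = backend
  )
}
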