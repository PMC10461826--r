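#' Hoeffding's statistic of bivariate independence
#'
#' The classical rank-based D statistic with the conventional x30 scaling.
#' With midranks \eqn{R_i, S_i} and
#' \eqn{c_i = \#\{j \ne i : u_j < u_i, v_j < v_i\}} (ties contributing 1/2
#' per tied coordinate, 1/4 when tied on both),
#' \deqn{D = 30 \frac{(n-2)(n-3) D_1 + D_2 - 2(n-2) D_3}
#'   {n(n-1)(n-2)(n-3)(n-4)}}
#' where \eqn{D_1 = \sum c_i (c_i - 1)},
#' \eqn{D_2 = \sum (R_i-1)(R_i-2)(S_i-1)(S_i-2)},
#' \eqn{D_3 = \sum (R_i-2)(S_i-2) c_i}. Under independence the expectation
#' is approximately zero; the statistic is invariant under strictly
#' increasing marginal transforms.
#'
#' @param u,v Numeric vectors of equal length n >= 5.
#' @return The scaled statistic (a single number).
#' @examples
#' hoeffding_statistic(1:20, (1:20)^2)  # perfectly dependent
#' @export
hoeffding_statistic <- function(u, v) {
  u <- as.numeric(u)
  v <- as.numeric(v)
  if (length(u) != length(v)) {
    abort("u and v must have equal length", class = "gpstest_input_error")
  }
  if (length(u) < 5) {
    abort("Hoeffding's statistic requires n >= 5 (the denominator vanishes below)",
          class = "gpstest_input_error")
  }
  .hoeffding_stat_cpp(u, v)
}

#' Hoeffding's test with a permutation p-value
#'
#' Permutes the second p-value vector exactly as the GPS permutation null
#' does and reports `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#' Hoeffding's test assumes independent observations; on LD-pruned SNP sets
#' retaining residual correlation (high pruning r-squared) it does not
#' control the type 1 error rate, which is what makes it an instructive
#' comparator for the GPS tests.
#'
#' @inheritParams gps_gev_test
#' @return A `gps_test_report` with method `"hoeffding"`.
#' @export
hoeffding_test <- function(pair, n_perm = 1000, seed = NULL) {
  pair <- validate_gps_pair(pair)
  n_perm <- as.integer(n_perm)
  if (n_perm < 100) {
    abort("`n_perm` must be at least 100", class = "gpstest_input_error")
  }
  obs <- hoeffding_statistic(pair$p_a, pair$p_b)
  if (!is.null(seed)) set.seed(seed)
  null <- .hoeffding_perm_null_cpp(pair$p_a, pair$p_b, n_perm)
  p <- (1 + sum(null >= obs)) / (n_perm + 1)
  .new_test_report(
    method = "hoeffding", statistic = obs, p_value = p,
    n_variants = nrow(pair), n_perm = n_perm,
    extra = list(null_statistics = null, seed = seed),
    metadata = pair_metadata(pair)
  )
}
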