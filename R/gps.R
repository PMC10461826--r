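#' The GPS statistic
#'
#' The genome-wide pairwise-association signal sharing (GPS) statistic is a
#' weighted supremum-norm distance between the joint empirical distribution
#' of two traits' p-values and the product of the marginals:
#' \deqn{D = \sup_i \sqrt{n/\ln n}\,
#'   \frac{|F_{UV}(u_i, v_i) - F_U(u_i) F_V(v_i)|}
#'        {\sqrt{F_U(u_i) F_V(v_i) - F_U(u_i)^2 F_V(v_i)^2}}}
#' The denominator upweights discrepancies where both p-values are small, so
#' the statistic is most sensitive to coincident strong association signals.
#' The supremum is evaluated at the n observed pairs (the objective is
#' piecewise constant between them). Points where
#' \eqn{F_U F_V = 1} make the ratio 0/0; they are excluded from the
#' maximum and reported in `n_excluded` rather than being defined as zero.
#' Arg-max ties resolve to the smallest index.
#'
#' D depends on the data only through ranks: it is invariant under strictly
#' increasing transforms of either margin, and symmetric in its arguments.
#'
#' @param pair A `gps_pair` with at least 5 variants.
#' @param backend Bivariate-ecdf backend, see [bivariate_ecdf()].
#' @return An object of class `gps_result`: a list with elements `D`,
#'   `argmax_index`, `argmax_variant`, `argmax_values` (the triple
#'   `F_u`, `F_v`, `F_uv` at the supremum), `n`, `n_used`, `n_excluded`,
#'   `backend`. `tidy()` turns it into a one-row tibble.
#' @examples
#' pair <- simulate_independent_null(100, seed = 1)
#' gps_statistic(pair)
#' @export
gps_statistic <- function(pair, backend = c("tree", "dac", "naive")) {
  backend <- match.arg(backend)
  pair <- validate_gps_pair(pair)
  res <- tryCatch(
    .gps_stat_cpp(pair$p_a, pair$p_b, backend),
    error = function(e) {
      if (grepl("degenerate", conditionMessage(e))) {
        abort(conditionMessage(e), class = "gpstest_degenerate_error")
      }
      abort(conditionMessage(e), class = "gpstest_input_error")
    }
  )
  structure(
    list(
      D = res$D,
      argmax_index = res$argmax_index,
      argmax_variant = pair$variant_id[res$argmax_index],
      argmax_values = c(F_u = res$F_u, F_v = res$F_v, F_uv = res$F_uv),
      n = nrow(pair),
      n_used = res$n_used,
      n_excluded = res$n_excluded,
      backend = backend
    ),
    class = "gps_result"
  )
}

#' @export
print.gps_result <- function(x, ...) {
  cat(sprintf("GPS statistic D = %.4f (n = %d, backend = %s)\n",
              x$D, x$n, x$backend))
  cat(sprintf("  supremum at variant %s (index %d): F_u = %.4g, F_v = %.4g, F_uv = %.4g\n",
              x$argmax_variant, x$argmax_index,
              x$argmax_values[["F_u"]], x$argmax_values[["F_v"]],
              x$argmax_values[["F_uv"]]))
  if (x$n_excluded > 0) {
    cat(sprintf("  %d degenerate point(s) excluded from the supremum\n",
                x$n_excluded))
  }
  invisible(x)
}

#' @export
tidy.gps_result <- function(x, ...) {
  tibble::tibble(
    D = x$D,
    argmax_index = x$argmax_index,
    argmax_variant = x$argmax_variant,
    F_u = x$argmax_values[["F_u"]],
    F_v = x$argmax_values[["F_v"]],
    F_uv = x$argmax_values[["F_uv"]],
    n = x$n,
    n_used = x$n_used,
    n_excluded = x$n_excluded,
    backend = x$backend
  )
}
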