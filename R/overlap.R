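#' Expected effect-estimate correlation induced by sample overlap
#'
#' Two case-control GWAS drawn from the same cohort share participants, and
#' sharing cases and/or controls induces correlation between the studies'
#' effect estimates even at null SNPs. Following Lin and Sullivan, the
#' expected correlation for studies k and l is
#' \deqn{\rho = \left[ n_0 \sqrt{\frac{n_{k1} n_{l1}}{n_{k0} n_{l0}}}
#'   + n_1 \sqrt{\frac{n_{k0} n_{l0}}{n_{k1} n_{l1}}} \right]
#'   \Big/ \sqrt{(n_{k0}+n_{k1})(n_{l0}+n_{l1})}}
#' where \eqn{n_0, n_1} are shared controls and cases, and
#' \eqn{n_{k0}, n_{k1}} (\eqn{n_{l0}, n_{l1}}) the controls and cases of
#' study k (l). The canonical subscript order used throughout the package
#' is study-then-status: `n_k0` = controls of study k. No overlap gives
#' \eqn{\rho = 0}; two identical studies give \eqn{\rho = 1}.
#'
#' `rho_overlap()` is data-frame-first: it takes a design table (one row
#' per study pair) and appends a `rho` column.
#'
#' @param design A data frame with columns `study_k`, `study_l`,
#'   `n0_shared_controls`, `n1_shared_cases`, `k_controls`, `k_cases`,
#'   `l_controls`, `l_cases` (the schema of [read_overlap_design()]).
#' @return The design as a tibble with a `rho` column appended, each value
#'   in \[0, 1\].
#' @examples
#' design <- tibble::tibble(
#'   study_k = "A", study_l = "B",
#'   n0_shared_controls = 9000, n1_shared_cases = 0,
#'   k_controls = 10000, k_cases = 1000,
#'   l_controls = 9500, l_cases = 2000
#' )
#' rho_overlap(design)
#' @export
rho_overlap <- function(design) {
  design <- .validate_overlap_design(design)
  rho <- .rho_formula(design$n0_shared_controls, design$n1_shared_cases,
                      design$k_controls, design$k_cases,
                      design$l_controls, design$l_cases)
  dplyr::mutate(tibble::as_tibble(design), rho = rho)
}

.rho_formula <- function(n0, n1, nk0, nk1, nl0, nl1) {
  # doubles throughout: count products overflow 32-bit integers
  n0 <- as.numeric(n0); n1 <- as.numeric(n1)
  nk0 <- as.numeric(nk0); nk1 <- as.numeric(nk1)
  nl0 <- as.numeric(nl0); nl1 <- as.numeric(nl1)
  (n0 * sqrt((nk1 * nl1) / (nk0 * nl0)) +
     n1 * sqrt((nk0 * nl0) / (nk1 * nl1))) /
    sqrt((nk0 + nk1) * (nl0 + nl1))
}

.overlap_cols <- c("study_k", "study_l", "n0_shared_controls",
                   "n1_shared_cases", "k_controls", "k_cases",
                   "l_controls", "l_cases")

.validate_overlap_design <- function(design) {
  missing <- setdiff(.overlap_cols, names(design))
  if (length(missing) > 0) {
    abort(paste0("overlap design is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "gpstest_input_error")
  }
  num <- .overlap_cols[-(1:2)]
  for (col in num) {
    x <- design[[col]]
    if (any(!is.finite(x)) || any(x < 0)) {
      abort(sprintf("overlap design column `%s` must be non-negative and finite", col),
            class = "gpstest_input_error")
    }
  }
  if (any(design$k_controls <= 0) || any(design$k_cases <= 0) ||
      any(design$l_controls <= 0) || any(design$l_cases <= 0)) {
    abort("per-study case and control counts must be positive",
          class = "gpstest_input_error")
  }
  bad0 <- design$n0_shared_controls > pmin(design$k_controls, design$l_controls)
  bad1 <- design$n1_shared_cases > pmin(design$k_cases, design$l_cases)
  if (any(bad0) || any(bad1)) {
    abort("shared counts cannot exceed the smaller study's counts",
          class = "gpstest_input_error")
  }
  design
}

#' Pairwise overlap correlations for a set of studies
#'
#' Applies [rho_overlap()] to every study pair in a design table, returning
#' the symmetric correlation matrix (unit diagonal by convention, the
#' consistent limit for a study paired with itself) and summary statistics
#' over the off-diagonal entries.
#'
#' @param designs Design table covering each unordered study pair at most
#'   once (schema as in [rho_overlap()]).
#' @return An object of class `rho_matrix`: list with `matrix` (symmetric,
#'   unit diagonal), `pairs` (the design with `rho` appended) and `summary`
#'   (tibble with `min`, `median`, `max`, `n_pairs`). `tidy()` returns the
#'   per-pair tibble.
#' @export
pairwise_rho <- function(designs) {
  designs <- .validate_overlap_design(designs)
  key <- purrr::map2_chr(designs$study_k, designs$study_l,
                         ~ paste(sort(c(.x, .y)), collapse = "\r"))
  if (anyDuplicated(key) > 0) {
    dup <- key[duplicated(key)][1]
    abort(sprintf("duplicate study pair in design table: %s",
                  gsub("\r", " - ", dup)),
          class = "gpstest_input_error")
  }
  pairs <- rho_overlap(designs)
  studies <- sort(unique(c(pairs$study_k, pairs$study_l)))
  m <- matrix(NA_real_, length(studies), length(studies),
              dimnames = list(studies, studies))
  diag(m) <- 1
  for (i in seq_len(nrow(pairs))) {
    m[pairs$study_k[i], pairs$study_l[i]] <- pairs$rho[i]
    m[pairs$study_l[i], pairs$study_k[i]] <- pairs$rho[i]
  }
  structure(
    list(
      matrix = m,
      pairs = pairs,
      summary = tibble::tibble(
        min = min(pairs$rho), median = stats::median(pairs$rho),
        max = max(pairs$rho), n_pairs = nrow(pairs)
      )
    ),
    class = "rho_matrix"
  )
}

#' @export
print.rho_matrix <- function(x, ...) {
  cat(sprintf(
    "Pairwise sample-overlap correlations: %d studies, %d pairs\n",
    nrow(x$matrix), nrow(x$pairs)))
  cat(sprintf("  rho: min %.3f, median %.3f, max %.3f\n",
              x$summary$min, x$summary$median, x$summary$max))
  invisible(x)
}

#' @export
tidy.rho_matrix <- function(x, ...) x$pairs

#' Read / write an overlap design table
#'
#' TSV with columns `study_k`, `study_l`, `n0_shared_controls`,
#' `n1_shared_cases`, `k_controls`, `k_cases`, `l_controls`, `l_cases`.
#'
#' @param path File path.
#' @return `read_overlap_design()` a validated tibble;
#'   `write_rho_pairs()` writes the per-pair rho table and returns `path`
#'   invisibly.
#' @export
read_overlap_design <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  .validate_overlap_design(df)
  tibble::as_tibble(df)
}

#' @rdname read_overlap_design
#' @param rho A `rho_matrix` from [pairwise_rho()] or a tibble from
#'   [rho_overlap()].
#' @export
write_rho_pairs <- function(rho, path) {
  df <- if (inherits(rho, "rho_matrix")) rho$pairs else tibble::as_tibble(rho)
  readr::write_tsv(df, path)
  invisible(path)
}
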