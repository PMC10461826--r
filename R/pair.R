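#' Construct a harmonized pair of GWAS p-value vectors
#'
#' A harmonized pair holds, for each variant tested in both studies, the
#' association p-values for trait 1 (`p_a`) and trait 2 (`p_b`). It is the
#' input of every test in the package. Pairs are usually produced by
#' [harmonize_pair()] from two summary-statistic tables, or by the
#' `simulate_*()` generators; this constructor builds one directly from
#' vectors.
#'
#' @param u,v Numeric vectors of p-values in (0, 1], equal length, one entry
#'   per variant. A p-value of exactly 1 is legal; zero or negative
#'   p-values must be filtered upstream (see [read_sumstats()]).
#' @param variant_ids Optional character vector of variant identifiers;
#'   defaults to `"snp_1" ... "snp_n"`.
#' @param chrom,pos Optional chromosome labels and base-pair positions.
#' @param metadata Named list of free-form provenance (source files, the
#'   upstream LD-pruning r-squared threshold, MHC-exclusion flag, ...).
#'
#' @return A tibble of class `gps_pair` with columns `variant_id`, `chrom`,
#'   `pos`, `p_a`, `p_b` and a `metadata` attribute.
#' @examples
#' pair <- gps_pair(u = runif(10), v = runif(10))
#' n_variants(pair)
#' @export
gps_pair <- function(u, v, variant_ids = NULL, chrom = NULL, pos = NULL,
                     metadata = list()) {
  u <- as.numeric(u)
  v <- as.numeric(v)
  n <- length(u)
  if (is.null(variant_ids)) variant_ids <- paste0("snp_", seq_len(n))
  df <- tibble::tibble(
    variant_id = as.character(variant_ids),
    chrom = if (is.null(chrom)) NA_character_ else as.character(chrom),
    pos = if (is.null(pos)) NA_real_ else as.numeric(pos),
    p_a = u,
    p_b = v
  )
  new_gps_pair(df, metadata)
}

new_gps_pair <- function(df, metadata = list()) {
  out <- tibble::new_tibble(df, metadata = metadata,
                            class = "gps_pair", nrow = nrow(df))
  validate_gps_pair(out)
}

#' Validate a harmonized pair
#'
#' Checks the invariants every test relies on: equal-length columns, all
#' p-values finite and in (0, 1], and at least 5 variants (below this no
#' implemented test is meaningful).
#'
#' @param pair A `gps_pair` or any data frame with `p_a` and `p_b` columns.
#' @return The validated pair, invisibly coerced to `gps_pair`.
#' @export
validate_gps_pair <- function(pair) {
  if (!is.data.frame(pair) || !all(c("p_a", "p_b") %in% names(pair))) {
    abort("`pair` must be a data frame with `p_a` and `p_b` columns",
          class = "gpstest_input_error")
  }
  n <- nrow(pair)
  if (n < 5) {
    abort(sprintf("a harmonized pair needs at least 5 variants (got %d)", n),
          class = "gpstest_input_error")
  }
  for (col in c("p_a", "p_b")) {
    p <- pair[[col]]
    bad <- which(!is.finite(p))
    if (length(bad) > 0) {
      abort(sprintf("non-finite p-value in `%s` at index %d", col, bad[1]),
            class = "gpstest_input_error")
    }
    oob <- which(p <= 0 | p > 1)
    if (length(oob) > 0) {
      abort(sprintf("p-value out of (0, 1] in `%s` at index %d (value %g)",
                    col, oob[1], p[oob[1]]),
            class = "gpstest_input_error")
    }
  }
  if (!inherits(pair, "gps_pair")) {
    pair <- tibble::new_tibble(pair, metadata = list(),
                               class = "gps_pair", nrow = n)
  }
  pair
}

#' Number of variants in a harmonized pair
#' @param pair A `gps_pair`.
#' @return Integer count of variants.
#' @export
n_variants <- function(pair) nrow(pair)

#' Provenance metadata of a harmonized pair
#' @param pair A `gps_pair`.
#' @return The named `metadata` list attached to the pair.
#' @export
pair_metadata <- function(pair) {
  md <- attr(pair, "metadata")
  if (is.null(md)) list() else md
}

#' Write / read a harmonized pair as TSV
#'
#' Plain-text round trip: `write_pair()` then `read_pair()` reproduces the
#' pair exactly (doubles are written with shortest round-tripping
#' representation).
#'
#' @param pair A `gps_pair`.
#' @param path File path (a `.gz` suffix writes gzip).
#' @return `write_pair()` returns `path` invisibly; `read_pair()` returns a
#'   `gps_pair`.
#' @export
write_pair <- function(pair, path) {
  readr::write_tsv(tibble::as_tibble(pair), path)
  invisible(path)
}

#' @rdname write_pair
#' @export
read_pair <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          variant_id = readr::col_character(),
                          chrom = readr::col_character(),
                          pos = readr::col_double(),
                          p_a = readr::col_double(),
                          p_b = readr::col_double()
                        ))
  new_gps_pair(df, metadata = list(source = path))
}

#' @export
print.gps_pair <- function(x, ...) {
  cat(sprintf("# A harmonized GWAS pair: %d variants\n", nrow(x)))
  NextMethod()
  md <- pair_metadata(x)
  if (length(md) > 0) {
    cat(sprintf("# metadata: %s\n", paste(names(md), collapse = ", ")))
  }
  invisible(x)
}
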