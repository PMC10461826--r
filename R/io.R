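#' Map input column names to the package's schema
#'
#' GWAS summary-statistic releases name their columns inconsistently; a
#' column map records which input columns hold the variant ID, chromosome,
#' position and p-value. Chromosome and position may be `NULL` when the
#' file has none (region filtering then becomes unavailable).
#'
#' @param variant_col,chrom_col,pos_col,pval_col Column names in the input
#'   file.
#' @return A `column_map` list.
#' @export
column_map <- function(variant_col = "SNP", chrom_col = "CHR",
                       pos_col = "BP", pval_col = "P") {
  cols <- c(variant_col, chrom_col, pos_col, pval_col)
  cols <- cols[!vapply(list(variant_col, chrom_col, pos_col, pval_col),
                       is.null, logical(1))]
  if (any(!nzchar(cols))) {
    abort("column names must be non-empty", class = "gpstest_input_error")
  }
  if (anyDuplicated(cols) > 0) {
    abort("column names must be distinct", class = "gpstest_input_error")
  }
  structure(list(variant_col = variant_col, chrom_col = chrom_col,
                 pos_col = pos_col, pval_col = pval_col),
            class = "column_map")
}

#' Read a GWAS summary-statistic table
#'
#' Reads a (optionally gzipped) TSV of per-variant summary statistics,
#' keeping variant ID, chromosome, position and p-value. Rows with missing
#' or non-finite p, p > 1, or p <= 0 are dropped and counted by reason
#' (p = 0 rows are dropped, not clamped: the GPS statistic is rank-based
#' and clamping would silently create massive ties at the minimum). The
#' drop log is attached as the `drop_log` attribute and is summarised by
#' [drop_log()].
#'
#' @param path File path (plain or `.gz` TSV).
#' @param colmap A [column_map()].
#' @return A tibble of class `gps_sumstats` with columns `variant_id`,
#'   `chrom`, `pos`, `p`.
#' @export
read_sumstats <- function(path, colmap = column_map()) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "gpstest_input_error")
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  needed <- c(colmap$variant_col, colmap$chrom_col, colmap$pos_col,
              colmap$pval_col)
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("column(s) not found in %s: %s", path,
                  paste(missing, collapse = ", ")),
          class = "gpstest_schema_error")
  }
  df <- tibble::tibble(
    variant_id = trimws(raw[[colmap$variant_col]]),
    chrom = if (is.null(colmap$chrom_col)) NA_character_
            else trimws(raw[[colmap$chrom_col]]),
    pos = if (is.null(colmap$pos_col)) NA_real_
          else suppressWarnings(as.numeric(raw[[colmap$pos_col]])),
    p = suppressWarnings(as.numeric(raw[[colmap$pval_col]]))
  )
  n_read <- nrow(df)
  nonfinite <- !is.finite(df$p)
  zero <- !nonfinite & df$p <= 0
  above1 <- !nonfinite & df$p > 1
  keep <- !(nonfinite | zero | above1)
  out <- df[keep, ]
  if (nrow(out) == 0) {
    abort(sprintf("no usable rows in %s after p-value filtering", path),
          class = "gpstest_empty_error")
  }
  log <- list(path = path, rows_read = n_read, rows_kept = nrow(out),
              dropped = c(nonfinite = sum(nonfinite), zero = sum(zero),
                          above_one = sum(above1)))
  tibble::new_tibble(out, drop_log = log, class = "gps_sumstats",
                     nrow = nrow(out))
}

#' Ingestion drop log of a summary-statistic table
#' @param x A `gps_sumstats` from [read_sumstats()].
#' @return The named drop-log list.
#' @export
drop_log <- function(x) attr(x, "drop_log")

#' A genomic region filter
#'
#' Coordinates are 1-based and inclusive at both ends, the GWAS
#' summary-statistic convention.
#'
#' @param chrom Chromosome label (matched as a string, so `"6"` and `"chr6"`
#'   are distinct).
#' @param start,end Base-pair bounds, `start <= end`.
#' @param label Human-readable label echoed into output metadata.
#' @return A `region_filter` list.
#' @export
region_filter <- function(chrom, start, end, label = "") {
  if (start > end) {
    abort("`start` must not exceed `end`", class = "gpstest_input_error")
  }
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 label = label),
            class = "region_filter")
}

#' The default MHC region filter
#'
#' The major histocompatibility complex: gene-dense, long-range LD, and
#' host to the strongest immune-disease association signals, which can
#' dominate the GPS supremum. Default bounds 6:25,000,000-35,000,000
#' (GRCh37); override for other builds.
#'
#' @param start,end Base-pair bounds.
#' @return A `region_filter` labelled `"MHC"`.
#' @export
mhc_region <- function(start = 25e6, end = 35e6) {
  region_filter("6", start, end, label = "MHC")
}

#' Harmonize two summary-statistic tables into a pair
#'
#' Inner-joins the two tables on variant ID (exact string match after
#' whitespace trimming), removes variants falling inside any region filter,
#' and orders the result by chromosome and position when available (by
#' variant ID otherwise). Variant IDs duplicated within a file are wholly
#' dropped (all copies) and logged rather than arbitrarily resolved.
#'
#' @param table_a,table_b `gps_sumstats` tables (trait 1 and trait 2).
#' @param region_filters A [region_filter()], a list of them, or `NULL`.
#' @param r2_label Optional free-text record of the upstream LD-pruning
#'   r-squared threshold (metadata only; pruning is upstream).
#' @return A `gps_pair`; `pair_metadata()` records sources, drop logs,
#'   applied filters and `r2_label`.
#' @export
harmonize_pair <- function(table_a, table_b, region_filters = NULL,
                           r2_label = NA_character_) {
  stopifnot(is.data.frame(table_a), is.data.frame(table_b))
  if (nrow(table_a) == 0 || nrow(table_b) == 0) {
    abort("input tables must be non-empty", class = "gpstest_empty_error")
  }
  if (inherits(region_filters, "region_filter")) {
    region_filters <- list(region_filters)
  }
  dedup <- function(df) {
    dup_ids <- unique(df$variant_id[duplicated(df$variant_id)])
    list(table = df[!(df$variant_id %in% dup_ids), ], dropped = dup_ids)
  }
  da <- dedup(table_a)
  db <- dedup(table_b)
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(da$table), "variant_id", "chrom",
                  "pos", p_a = "p"),
    dplyr::select(tibble::as_tibble(db$table), "variant_id", p_b = "p"),
    by = "variant_id"
  )
  n_filtered <- 0L
  if (!is.null(region_filters) && nrow(joined) > 0) {
    inside <- rep(FALSE, nrow(joined))
    for (f in region_filters) {
      inside <- inside | (!is.na(joined$chrom) & !is.na(joined$pos) &
                            joined$chrom == f$chrom &
                            joined$pos >= f$start & joined$pos <= f$end)
    }
    n_filtered <- sum(inside)
    joined <- joined[!inside, ]
  }
  if (nrow(joined) < 5) {
    abort(sprintf(
      "only %d variants shared between the two tables after filtering (need >= 5)",
      nrow(joined)), class = "gpstest_insufficient_overlap_error")
  }
  if (all(!is.na(joined$chrom)) && all(!is.na(joined$pos))) {
    joined <- dplyr::arrange(joined,
                             suppressWarnings(as.numeric(.data$chrom)),
                             .data$chrom, .data$pos)
  } else {
    joined <- dplyr::arrange(joined, .data$variant_id)
  }
  new_gps_pair(joined, metadata = list(
    source_a = drop_log(table_a)$path, source_b = drop_log(table_b)$path,
    drop_log_a = drop_log(table_a), drop_log_b = drop_log(table_b),
    duplicates_dropped_a = da$dropped, duplicates_dropped_b = db$dropped,
    region_filters = region_filters, n_region_filtered = n_filtered,
    r2_label = r2_label
  ))
}
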