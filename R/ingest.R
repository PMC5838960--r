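#' Read a delimited expression table
#'
#' Parses a miRNA x sample measurement matrix from delimited text (tab or
#' comma, auto-detected): first column miRNA identifiers, remaining columns
#' one per sample with ids matching the manifest. Values are nonnegative
#' read counts (`platform = "counts"`), nonnegative hybridization
#' intensities (`"intensity"`), or quantitation-cycle values (`"cq"`).
#'
#' @param path Path to the delimited file.
#' @param platform `"counts"`, `"intensity"` or `"cq"`.
#' @param manifest Manifest tibble; the table must contain every
#'   `sample_id` it lists and no unknown sample columns.
#' @return A tibble with first column `mirna` and one numeric column per
#'   manifest sample, carrying attributes `platform` and `provenance`.
#' @export
read_expression_table <- function(path, platform = c("counts", "intensity", "cq"),
                                  manifest) {
  platform <- match.arg(platform)
  header <- readLines(path, n = 1L)
  delim <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           show_col_types = FALSE, progress = FALSE)
  names(raw)[1L] <- "mirna"
  raw$mirna <- as.character(raw$mirna)
  as_expression_table(raw, platform = platform, manifest = manifest,
                      provenance = list(source = path, delim = delim))
}

#' Validate a data frame as an expression table
#'
#' @param x Data frame whose first column is `mirna` and remaining columns
#'   are samples.
#' @inheritParams read_expression_table
#' @param provenance Optional list recording the table's history.
#' @return A validated expression tibble (see [read_expression_table()]).
#' @export
as_expression_table <- function(x, platform = c("counts", "intensity", "cq"),
                                manifest, provenance = list()) {
  platform <- match.arg(platform)
  x <- tibble::as_tibble(x)
  if (names(x)[1L] != "mirna") names(x)[1L] <- "mirna"
  sample_cols <- setdiff(names(x), "mirna")
  missing <- setdiff(manifest$sample_id, sample_cols)
  if (length(missing))
    stop("expression table is missing manifest samples: ",
         paste(missing, collapse = ", "), call. = FALSE)
  unknown <- setdiff(sample_cols, manifest$sample_id)
  if (length(unknown))
    stop("expression table has columns not in the manifest: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  dup <- unique(x$mirna[duplicated(x$mirna)])
  if (length(dup))
    stop("duplicated miRNA ids: ", paste(head(dup, 5L), collapse = ", "),
         call. = FALSE)
  for (cn in sample_cols) {
    v <- x[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop("non-numeric value in column '", cn, "'",
           if (length(bad)) paste0(", row ", bad[1L], " ('", v[bad[1L]], "')"),
           call. = FALSE)
    }
    if (platform != "cq" && any(v < 0, na.rm = TRUE))
      stop("negative ", platform, " value in column '", cn, "'", call. = FALSE)
  }
  x <- dplyr::select(x, "mirna", dplyr::all_of(manifest$sample_id))
  attr(x, "platform") <- platform
  attr(x, "provenance") <- provenance
  x
}

#' Platform of an expression or log2 table
#' @param x An expression tibble.
#' @return `"counts"`, `"intensity"` or `"cq"`.
#' @export
table_platform <- function(x) attr(x, "platform") %||% "counts"

sample_columns <- function(x) setdiff(names(x), c("mirna", "class", "subtype"))

expr_matrix <- function(x) {
  m <- as.matrix(x[sample_columns(x)])
  rownames(m) <- x$mirna
  m
}

add_provenance <- function(x, ...) {
  attr(x, "provenance") <- c(attr(x, "provenance") %||% list(), list(...))
  x
}

#' Detection filter
#'
#' Retains exactly those miRNAs whose maximum measurement across all samples
#' reaches `threshold` — the "detected in at least one sample" rule, with the
#' default threshold of 1 count. Applies to counts and intensity tables;
#' idempotent. Retained/removed counts are recorded in provenance.
#'
#' @param table Expression tibble (counts or intensity).
#' @param threshold Nonnegative detection threshold (default 1).
#' @return The filtered expression tibble.
#' @export
detect_filter <- function(table, threshold = 1) {
  if (table_platform(table) == "cq")
    stop("detection filtering applies to counts/intensity tables", call. = FALSE)
  stopifnot(is.numeric(threshold), threshold >= 0)
  m <- expr_matrix(table)
  keep <- apply(m, 1L, max, na.rm = TRUE) >= threshold
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no miRNA passed the detection filter", call. = FALSE)
  attributes(out)[c("platform", "provenance")] <-
    attributes(table)[c("platform", "provenance")]
  add_provenance(out, detect_filter = list(
    threshold = threshold, retained = sum(keep), removed = sum(!keep)))
}

#' Median-total normalization
#'
#' Scales each sample so that its total signal equals the median total
#' across the samples of the processed set: column j is multiplied by
#' `median(totals) / total_j`. Applied after detection filtering, before the
#' log2 transform, jointly over all samples of one round's set.
#'
#' @param table Filtered expression tibble (counts or intensity).
#' @return The normalized expression tibble; scale factors in provenance.
#' @export
normalize_median_total <- function(table) {
  if (table_platform(table) == "cq")
    stop("median-total normalization applies to counts/intensity tables", call. = FALSE)
  m <- expr_matrix(table)
  totals <- colSums(m, na.rm = TRUE)
  if (any(totals == 0))
    stop("sample(s) with zero total signal: ",
         paste(names(totals)[totals == 0], collapse = ", "), call. = FALSE)
  scale <- median(totals) / totals
  out <- table
  for (j in seq_along(scale)) out[[names(scale)[j]]] <- table[[names(scale)[j]]] * scale[[j]]
  attributes(out)[c("platform", "provenance")] <-
    attributes(table)[c("platform", "provenance")]
  add_provenance(out, normalize_median_total = list(
    median_total = median(totals), scale_factors = as.list(scale)))
}

#' Log2 transform of a normalized table
#'
#' `values = log2(value + pseudocount)`. The default pseudocount of 1 maps a
#' zero count to a log2 signal of 0; detected miRNAs can still carry zeros in
#' individual samples, so a positive pseudocount keeps them finite.
#'
#' @param table Normalized expression tibble (counts or intensity).
#' @param pseudocount Nonnegative offset added before the log (default 1).
#' @return A log2 tibble (same layout; attribute `scale = "log2"`).
#' @export
to_log2 <- function(table, pseudocount = 1) {
  if (table_platform(table) == "cq")
    stop("use cq_to_log2() for Cq tables", call. = FALSE)
  stopifnot(is.numeric(pseudocount), pseudocount >= 0)
  m <- expr_matrix(table)
  if (any(m + pseudocount <= 0, na.rm = TRUE))
    stop("value + pseudocount must be positive for the log2 transform", call. = FALSE)
  out <- table
  for (cn in colnames(m)) out[[cn]] <- log2(table[[cn]] + pseudocount)
  attributes(out)[c("platform", "provenance")] <-
    attributes(table)[c("platform", "provenance")]
  attr(out, "scale") <- "log2"
  add_provenance(out, to_log2 = list(pseudocount = pseudocount))
}

#' Negate Cq values to a log2-comparable scale
#'
#' A difference of 1 quantitation cycle corresponds to a 2-fold abundance
#' difference, so `-Cq` serves directly as a log2-scale signal. No detection
#' filter or total normalization is applied to PCR data.
#'
#' @param table Expression tibble with `platform = "cq"`.
#' @return A log2 tibble of negated Cq values.
#' @export
cq_to_log2 <- function(table) {
  if (table_platform(table) != "cq")
    stop("cq_to_log2() expects a Cq table", call. = FALSE)
  out <- table
  for (cn in sample_columns(table)) out[[cn]] <- -table[[cn]]
  attributes(out)[c("platform", "provenance")] <-
    attributes(table)[c("platform", "provenance")]
  attr(out, "scale") <- "log2"
  add_provenance(out, cq_to_log2 = list(transform = "negation"))
}

#' Write an expression table with a provenance sidecar
#'
#' @param table Expression or log2 tibble.
#' @param path Output TSV path; provenance is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  prov <- list(platform = table_platform(table),
               scale = attr(table, "scale") %||% "linear",
               history = attr(table, "provenance") %||% list())
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
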