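#' Deviation of observed from predicted log2 ratios
#'
#' Joins predicted and observed ratio records on miRNA id and computes
#' D = M_obs - M_pred together with the average signal level
#' A_avg = (A_obs + A_pred) / 2, attaching the selectivity class. miRNAs
#' present on only one side are excluded and counted in provenance.
#'
#' @param predicted,observed Ratio-record tibbles ([predicted_ratios()],
#'   [observed_ratios()]).
#' @param classification Classification tibble ([classify_selectivity()]).
#' @return Tibble `mirna`, `D`, `A_avg`, `class`; attribute
#'   `provenance$excluded` counts the unmatched ids.
#' @export
deviation_table <- function(predicted, observed, classification = NULL) {
  joined <- dplyr::inner_join(
    dplyr::select(predicted, "mirna", M_pred = "M", A_pred = "A"),
    dplyr::select(observed, "mirna", M_obs = "M", A_obs = "A"),
    by = "mirna"
  )
  excluded <- nrow(predicted) + nrow(observed) - 2L * nrow(joined)
  if (nrow(joined) == 0L)
    warning("predicted and observed records share no miRNA ids", call. = FALSE)
  out <- tibble::tibble(
    mirna = joined$mirna,
    D = joined$M_obs - joined$M_pred,
    A_avg = (joined$A_obs + joined$A_pred) / 2
  )
  if (!is.null(classification)) {
    out <- dplyr::left_join(out, dplyr::select(classification, "mirna", "class"),
                            by = "mirna")
  } else {
    out$class <- NA_character_
  }
  attr(out, "provenance") <- list(excluded = excluded)
  out
}

#' Bias and precision of the deviation distribution
#'
#' The median deviation is the bias indicator and the inter-quartile range
#' the precision estimate, over all detected miRNAs and optionally per
#' selectivity class. Quantiles use the linear-interpolation rule
#' (`type = 7`).
#'
#' @param records Deviation tibble from [deviation_table()].
#' @param by_class Also compute per-class rows? (default `FALSE`)
#' @return Tibble `class` (`"all"` plus class names when `by_class`), `n`,
#'   `median`, `iqr`.
#' @export
bias_precision <- function(records, by_class = FALSE) {
  if (nrow(records) == 0L)
    stop("no deviation records to summarize", call. = FALSE)
  overall <- tibble::tibble(class = "all", n = nrow(records),
                            median = median(records$D),
                            iqr = stats::IQR(records$D, type = 7))
  if (!by_class) return(overall)
  per <- records |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = dplyr::n(), median = median(.data$D),
                     iqr = stats::IQR(.data$D, type = 7), .groups = "drop")
  dplyr::bind_rows(overall, per)
}

window_coverage <- function(D, coverage) {
  alpha <- (1 - coverage) / 2
  quantile(D, probs = c(alpha, 1 - alpha), type = 7, names = FALSE)
}

#' Reliable region of the dynamic range
#'
#' Models how the deviation distribution changes along the dynamic range
#' with an empirical sliding window: records are sorted by their average
#' log2 signal, and within each window of `window_size` consecutive records
#' the central `coverage` interval of D is computed by linear-interpolation
#' quantiles. The lower limit is the smallest window-center signal such that
#' that window *and every window at higher signal* keep their coverage
#' interval inside `±tolerance` — the lowest average log2 signal at which at
#' least 95% (by default) of the deviation distribution stays within half a
#' fold-change (±0.585 log2). The upper limit is the maximum signal among
#' records (typical for sequencing), or, with `assess_upper = TRUE`
#' (hybridization platforms that can saturate), the center of the highest
#' window in the contiguous compliant region.
#'
#' @param records Deviation tibble from [deviation_table()].
#' @param tolerance Deviation tolerance in log2 units (default
#'   `log2(1.5) ~ 0.585`, half a fold-change).
#' @param coverage Required central coverage (default 0.95).
#' @param window_size Records per window; default `max(50, 5%)` of records.
#' @param assess_upper Derive the upper limit from window compliance rather
#'   than the maximum detectable signal (default `FALSE`).
#' @return A `mixqc_range` object: `lower_limit`, `upper_limit`,
#'   `range_span`, `tolerance`, `coverage`, `window_size`, `nd` flag (and
#'   `nd_reason`), plus the per-window tibble `windows` (`center`, `lo`,
#'   `hi`, `compliant`).
#' @export
reliable_range <- function(records, tolerance = log2(1.5), coverage = 0.95,
                           window_size = NULL, assess_upper = FALSE) {
  n <- nrow(records)
  window_size <- window_size %||% max(50L, ceiling(0.05 * n))
  window_size <- as.integer(window_size)
  if (n < 2L * window_size) {
    return(new_range(NA_real_, NA_real_, tolerance, coverage, window_size,
                     nd = TRUE,
                     nd_reason = sprintf("insufficient records (%d) for window size %d",
                                         n, window_size)))
  }
  ord <- dplyr::arrange(records, .data$A_avg)
  starts <- seq_len(n - window_size + 1L)
  mid <- (window_size + 1L) / 2
  windows <- purrr::map_dfr(starts, function(s) {
    idx <- s:(s + window_size - 1L)
    q <- window_coverage(ord$D[idx], coverage)
    tibble::tibble(center = median(ord$A_avg[idx]), lo = q[1L], hi = q[2L])
  })
  windows$compliant <- windows$lo >= -tolerance & windows$hi <= tolerance
  if (!any(windows$compliant)) {
    rng <- new_range(NA_real_, NA_real_, tolerance, coverage, window_size,
                     nd = TRUE, nd_reason = "no compliant window")
    rng$windows <- windows
    return(rng)
  }
  if (assess_upper) {
    # platforms that can saturate: take the longest contiguous compliant
    # run of windows; its first and last centers are the limits
    runs <- rle(windows$compliant)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    ok_runs <- which(runs$values)
    pick <- ok_runs[which.max(runs$lengths[ok_runs])]
    lower <- windows$center[starts[pick]]
    upper <- windows$center[ends[pick]]
  } else {
    # lowest window whose entire higher-signal tail is compliant
    rev_ok <- rev(cumall(rev(windows$compliant)))
    if (!any(rev_ok)) {
      rng <- new_range(NA_real_, NA_real_, tolerance, coverage, window_size,
                       nd = TRUE, nd_reason = "no compliant upper tail")
      rng$windows <- windows
      return(rng)
    }
    lower <- windows$center[which(rev_ok)[1L]]
    upper <- max(ord$A_avg)
  }
  rng <- new_range(lower, upper, tolerance, coverage, window_size,
                   nd = FALSE, nd_reason = NULL)
  rng$windows <- windows
  rng
}

cumall <- function(x) cumsum(!x) == 0L

new_range <- function(lower, upper, tolerance, coverage, window_size, nd,
                      nd_reason) {
  structure(list(
    lower_limit = lower, upper_limit = upper,
    range_span = if (nd) NA_real_ else upper - lower,
    tolerance = tolerance, coverage = coverage, window_size = window_size,
    nd = nd, nd_reason = nd_reason, windows = NULL
  ), class = "mixqc_range")
}

#' @export
print.mixqc_range <- function(x, ...) {
  if (x$nd) {
    cat("<mixqc_range> ND (", x$nd_reason, ")\n", sep = "")
  } else {
    cat(sprintf("<mixqc_range> lower %.2f, upper %.2f, span %.2f (tol ±%.3f log2, %.0f%% coverage)\n",
                x$lower_limit, x$upper_limit, x$range_span, x$tolerance,
                100 * x$coverage))
  }
  invisible(x)
}

#' @method glance mixqc_range
#' @export
glance.mixqc_range <- function(x, ...) {
  tibble::tibble(lower_limit = x$lower_limit, upper_limit = x$upper_limit,
                 range_span = x$range_span, tolerance = x$tolerance,
                 coverage = x$coverage, nd = x$nd)
}
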