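#' Predict mixture signals under the linear mixing model
#'
#' Each mixture's signal for miRNA i is the fraction-weighted sum of its
#' pure-component mean signals:
#' `S[i, mix] = sum over components c of S[i, c] * phi[c, mix]`.
#' The prediction is a convex combination, so every predicted signal lies
#' between the miRNA's smallest and largest pure-component means.
#'
#' @param profile Pure-profile tibble ([pure_profile()]), linear scale.
#' @param design A `mixqc_design` whose components match the profile columns.
#' @return A tibble `mirna` plus one predicted-signal column per mixture.
#' @export
predict_mixture_signals <- function(profile, design) {
  m <- profile_matrix(profile)
  if (!setequal(colnames(m), design$components))
    stop("profile components do not match the design", call. = FALSE)
  pred <- m[, design$components, drop = FALSE] %*% design$phi
  tibble::as_tibble(cbind(tibble::tibble(mirna = profile$mirna),
                          as.data.frame(pred)))
}

#' Predicted log2 ratio records (MA coordinates)
#'
#' Logs the two predicted mixture signals (with the same pseudocount used on
#' the observed side, for scale comparability) and forms M = difference,
#' A = average. Under the default design predicted M is bounded by ±1.
#'
#' @param pred Predicted-signal tibble from [predict_mixture_signals()]
#'   (exactly 2 mixture columns).
#' @param pseudocount Offset added before the log (default 1).
#' @return Tibble `mirna`, `M`, `A`, `source = "predicted"`.
#' @export
predicted_ratios <- function(pred, pseudocount = 1) {
  mixes <- sample_columns(pred)
  if (length(mixes) != 2L)
    stop("predicted ratios require exactly 2 mixtures", call. = FALSE)
  l1 <- log2(pred[[mixes[1L]]] + pseudocount)
  l2 <- log2(pred[[mixes[2L]]] + pseudocount)
  tibble::tibble(mirna = pred$mirna, M = l1 - l2, A = (l1 + l2) / 2,
                 source = "predicted")
}

#' Observed log2 ratio records (MA coordinates)
#'
#' Per miRNA, M is the difference between the mean log2 signal of the Mix1
#' replicates and that of the Mix2 replicates; A is the average of the two
#' means.
#'
#' @param log2_table Log2 tibble containing the mixture replicate columns.
#' @param manifest Manifest tibble.
#' @param design A `mixqc_design` with 2 mixtures.
#' @return Tibble `mirna`, `M`, `A`, `source = "observed"`.
#' @export
observed_ratios <- function(log2_table, manifest, design = default_mix_design()) {
  if (length(design$mixtures) != 2L)
    stop("observed ratios require exactly 2 mixtures", call. = FALSE)
  means <- lapply(design$mixtures, function(mx) {
    ids <- manifest_mix_ids(manifest, mx)
    ids <- intersect(ids, names(log2_table))
    if (!length(ids))
      stop("no samples for mixture '", mx, "' in the manifest/table", call. = FALSE)
    rowMeans(as.matrix(log2_table[ids]))
  })
  tibble::tibble(mirna = log2_table$mirna,
                 M = means[[1L]] - means[[2L]],
                 A = (means[[1L]] + means[[2L]]) / 2,
                 source = "observed")
}

#' Loess trend of M against A with a pointwise 95% band
#'
#' Fits a locally weighted regression of the log2 ratio on the average log2
#' signal for one selectivity subset (placenta, brain or 1-to-1 in the MA
#' panels) and evaluates the fit with a normal-approximation pointwise 95%
#' confidence band on a grid spanning the subset's A range.
#'
#' @param records Ratio-record tibble (`M`, `A`; e.g. from
#'   [predicted_ratios()] or [observed_ratios()]), already subset to one
#'   class.
#' @param span Loess span (default 0.75).
#' @param degree Local polynomial degree (default 2).
#' @param n_grid Number of evaluation points (default 80).
#' @return Tibble `A`, `fit`, `lower`, `upper`; zero rows (with a warning)
#'   when fewer than 10 points are available.
#' @export
loess_band <- function(records, span = 0.75, degree = 2, n_grid = 80) {
  if (nrow(records) < 10L) {
    warning("fewer than 10 points; loess band omitted", call. = FALSE)
    return(tibble::tibble(A = double(), fit = double(),
                          lower = double(), upper = double()))
  }
  fit <- loess(M ~ A, data = records, span = span, degree = degree,
               family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  grid <- seq(min(records$A), max(records$A), length.out = n_grid)
  pr <- predict(fit, newdata = data.frame(A = grid), se = TRUE)
  z <- stats::qnorm(0.975)
  tibble::tibble(A = grid, fit = as.numeric(pr$fit),
                 lower = as.numeric(pr$fit - z * pr$se.fit),
                 upper = as.numeric(pr$fit + z * pr$se.fit))
}

#' Export predicted and observed ratio records as one TSV
#'
#' @param predicted,observed Ratio-record tibbles.
#' @param classification Classification tibble ([classify_selectivity()]).
#' @param path Output path.
#' @return The joined tibble
#'   (`mirna`, `class`, `M_pred`, `A_pred`, `M_obs`, `A_obs`), invisibly
#'   written to `path` when given.
#' @export
ratio_records_table <- function(predicted, observed, classification, path = NULL) {
  out <- dplyr::inner_join(
    dplyr::select(predicted, "mirna", M_pred = "M", A_pred = "A"),
    dplyr::select(observed, "mirna", M_obs = "M", A_obs = "A"),
    by = "mirna"
  ) |>
    dplyr::left_join(dplyr::select(classification, "mirna", "class"), by = "mirna") |>
    dplyr::select("mirna", "class", "M_pred", "A_pred", "M_obs", "A_obs")
  if (!is.null(path)) readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}
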