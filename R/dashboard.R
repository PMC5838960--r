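#' Run the full measurement-assurance pipeline
#'
#' Executes the whole dashboard analysis on one round's expression table:
#' preprocessing (detection filter, median-total normalization, log2 — or Cq
#' negation for PCR), pure-profile means and tissue-selectivity
#' classification, predicted and observed log2 ratios, deviation bias and
#' precision, the reliable region of the dynamic range, designed-truth
#' ROC/AUC (all miRNAs and within-range), and mixture-proportion
#' deconvolution with the target-plot length sum.
#'
#' Three analysis modes are supported:
#' * `"full"` — pure and mixture samples from the same round, paired t-test
#'   ranking over the replicates;
#' * `"baseline"` — predictions and truth labels come from a stored
#'   pure-tissue `baseline_profile` (normalized linear-scale means), so the
#'   current round need only contain the two mixtures (the reduced 6-sample
#'   set);
#' * `"single_replicate"` — only replicate 1 of each sample is used and the
#'   ROC ranking switches to ordered |log2 ratio| scores.
#'
#' @param table Expression tibble ([read_expression_table()] /
#'   [as_expression_table()]).
#' @param manifest Manifest tibble.
#' @param design A `mixqc_design`.
#' @param mode `"full"`, `"baseline"` or `"single_replicate"`.
#' @param baseline_profile Pure-profile tibble (required for
#'   `mode = "baseline"`).
#' @param pseudocount Offset for the log2 transform (default 1).
#' @param detection_threshold Detection filter threshold (default 1).
#' @param fold Selectivity fold threshold (default 10).
#' @param equality_tol_log2 Brain/placenta equality band (default 0.5 log2).
#' @param tolerance Deviation tolerance for the reliable range (default
#'   `log2(1.5)`).
#' @param coverage Required coverage for the reliable range (default 0.95).
#' @param window_size Reliable-range window size (default `max(50, 5%)`).
#' @param assess_upper Tolerance-based upper limit (default `TRUE` for
#'   intensity platforms, else `FALSE`).
#' @param n_boot Bootstrap draws for proportion ellipses (default 200; 0
#'   skips the bootstrap).
#' @param seed Seed for the bootstrap.
#' @return A `mixqc_dashboard` object: summary metrics (`counts`, `range`,
#'   `auc_all`, `auc_within`, `deviation_median`, `deviation_iqr`,
#'   `proportion_sum`), the intermediate tables (`ratios`, `deviations`,
#'   `roc_all`, `roc_within`, `geometry`, `uncertainty`, `classification`,
#'   `profile`), `mode` and `provenance`. Metrics whose inputs are
#'   unavailable are `NA` with a reason in `nd_reasons`.
#' @export
run_pipeline <- function(table, manifest, design = default_mix_design(),
                         mode = c("full", "baseline", "single_replicate"),
                         baseline_profile = NULL,
                         pseudocount = 1, detection_threshold = 1,
                         fold = 10, equality_tol_log2 = 0.5,
                         tolerance = log2(1.5), coverage = 0.95,
                         window_size = NULL, assess_upper = NULL,
                         n_boot = 200, seed = 1) {
  mode <- match.arg(mode)
  platform <- table_platform(table)
  nd_reasons <- list()

  if (mode == "single_replicate") {
    manifest <- manifest[manifest$replicate == 1L, ]
    table <- dplyr::select(table, "mirna", dplyr::all_of(manifest$sample_id))
    attr(table, "platform") <- platform
  }
  has_pures <- all(paste0("pure:", design$components) %in% manifest$role)
  if (mode %in% c("full", "single_replicate") && !has_pures) {
    missing <- setdiff(paste0("pure:", design$components), manifest$role)
    stop(mode, " mode requires pure samples; missing roles: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (mode == "baseline" && is.null(baseline_profile))
    stop("baseline mode requires `baseline_profile`", call. = FALSE)
  missing_mix <- setdiff(paste0("mix:", design$mixtures), manifest$role)
  if (length(missing_mix))
    stop("missing mixture roles: ", paste(missing_mix, collapse = ", "),
         call. = FALSE)

  # --- preprocessing ---------------------------------------------------
  if (platform == "cq") {
    linear <- NULL
    logtab <- cq_to_log2(table)
  } else {
    filtered <- detect_filter(table, detection_threshold)
    linear <- normalize_median_total(filtered)
    logtab <- to_log2(linear, pseudocount)
  }

  # --- truth labels and predictions ------------------------------------
  if (mode == "baseline" && !is.null(baseline_profile)) {
    profile <- baseline_profile
  } else if (has_pures && !is.null(linear)) {
    profile <- pure_profile(linear, manifest, design)
  } else if (has_pures && platform == "cq") {
    # linear-scale means from negated Cq values
    lin_cq <- logtab
    for (cn in sample_columns(lin_cq)) lin_cq[[cn]] <- 2^logtab[[cn]]
    profile <- pure_profile(lin_cq, manifest, design)
  } else {
    stop("no source of pure-tissue profiles for prediction", call. = FALSE)
  }
  classification <- classify_selectivity(profile, design, fold = fold,
                                         equality_tol_log2 = equality_tol_log2)
  counts <- class_counts(classification, design)

  pred_sig <- predict_mixture_signals(profile, design)
  predicted <- predicted_ratios(pred_sig, pseudocount = pseudocount)
  observed <- observed_ratios(logtab, manifest, design)
  devs <- deviation_table(predicted, observed, classification)
  stats_all <- bias_precision(devs)
  stats_class <- bias_precision(devs, by_class = TRUE)

  # --- reliable range (not assessed for PCR) ----------------------------
  if (platform == "cq") {
    range <- NULL
    nd_reasons$range <- "margins not assessed for PCR data"
  } else {
    assess_upper <- assess_upper %||% (platform == "intensity")
    range <- reliable_range(devs, tolerance = tolerance, coverage = coverage,
                            window_size = window_size,
                            assess_upper = assess_upper)
    if (range$nd) nd_reasons$range <- range$nd_reason
  }

  # --- discrimination ---------------------------------------------------
  n_rep_mix <- vapply(design$mixtures, function(m)
    sum(manifest$role == paste0("mix:", m)), integer(1))
  ranking <- if (mode == "single_replicate" || any(n_rep_mix < 2L)) {
    unreplicated_scores(observed)
  } else {
    paired_pvalues(logtab, manifest, design)
  }
  obs_A <- dplyr::select(observed, "mirna", "A")
  roc_all <- roc_auc(ranking, classification, design)
  if (roc_all$nd) nd_reasons$auc_all <- roc_all$nd_reason
  roc_within <- if (!is.null(range)) {
    roc_auc(ranking, classification, design, range = range, A = obs_A)
  } else {
    new_roc(NULL, NA_real_, 0L, 0L, TRUE, nd = TRUE,
            nd_reason = "no reliable range for this platform")
  }
  if (roc_within$nd) nd_reasons$auc_within <- roc_within$nd_reason

  # --- deconvolution (genome-scale platforms only) ----------------------
  if (platform == "cq") {
    estimate <- NULL; geometry <- NULL; uncertainty <- NULL
    proportion_sum <- NA_real_
    nd_reasons$proportion_sum <- "deconvolution not assessed for PCR data"
  } else {
    mixes <- mixture_means(linear, manifest, design)
    estimate <- estimate_proportions(profile, mixes, design)
    geometry <- target_geometry(design, estimate)
    proportion_sum <- proportion_length_sum(geometry)
    uncertainty <- if (n_boot > 0) {
      proportion_uncertainty(profile, mixes, design, n_boot = n_boot,
                             seed = seed)
    }
  }

  structure(list(
    counts = counts,
    n_detected = nrow(classification),
    lower_limit = if (is.null(range)) NA_real_ else range$lower_limit,
    upper_limit = if (is.null(range)) NA_real_ else range$upper_limit,
    range_span = if (is.null(range)) NA_real_ else range$range_span,
    auc_all = roc_all$auc, auc_within = roc_within$auc,
    deviation_median = stats_all$median, deviation_iqr = stats_all$iqr,
    proportion_sum = proportion_sum,
    mode = mode, platform = platform,
    nd_reasons = nd_reasons,
    classification = classification, profile = profile,
    ratios = ratio_records_table(predicted, observed, classification),
    predicted = predicted, observed = observed,
    deviations = devs, deviation_by_class = stats_class,
    range = range, roc_all = roc_all, roc_within = roc_within,
    estimate = estimate, geometry = geometry, uncertainty = uncertainty,
    provenance = list(
      pseudocount = pseudocount, detection_threshold = detection_threshold,
      fold = fold, equality_tol_log2 = equality_tol_log2,
      tolerance = tolerance, coverage = coverage,
      n_boot = n_boot, seed = seed,
      note_upper = "tolerance: at least 95% of deviations within ±0.585 log2 by default"
    )
  ), class = "mixqc_dashboard")
}

#' @export
print.mixqc_dashboard <- function(x, ...) {
  cat("<mixqc_dashboard> mode:", x$mode, "| platform:", x$platform, "\n")
  print(glance(x))
  invisible(x)
}

#' @method glance mixqc_dashboard
#' @export
glance.mixqc_dashboard <- function(x, ...) {
  cc <- x$counts
  tibble::tibble(
    mode = x$mode, platform = x$platform, detected = x$n_detected,
    non_selective = cc$non_selective, one_to_one = cc$one_to_one,
    brain_selective = cc[["brain_selective"]] %||% NA_integer_,
    placenta_selective = cc[["placenta_selective"]] %||% NA_integer_,
    lower_limit = x$lower_limit, upper_limit = x$upper_limit,
    range_span = x$range_span,
    auc_all = x$auc_all, auc_within = x$auc_within,
    deviation_median = x$deviation_median, deviation_iqr = x$deviation_iqr,
    proportion_sum = x$proportion_sum
  )
}

#' @method tidy mixqc_dashboard
#' @export
tidy.mixqc_dashboard <- function(x, ...) {
  g <- glance(x)
  num <- g[vapply(g, is.numeric, logical(1))]
  tidyr::pivot_longer(num, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' Assemble the Table-1-style metrics table for several results
#'
#' One row per analyzed dataset/round with the dashboard summary columns;
#' undetermined metrics are rendered literally as `"ND"` so the emitted
#' table is self-describing. Suitable for longitudinal tracking of a lab's
#' rounds.
#'
#' @param results List of `mixqc_dashboard` objects (optionally named; names
#'   become the `dataset` column).
#' @param path Optional TSV output path.
#' @param digits Significant digits for formatting (default 4).
#' @return A tibble of character-rendered metrics, one row per result.
#' @export
metrics_to_table <- function(results, path = NULL, digits = 4) {
  fmt <- function(v) {
    ifelse(is.na(v), "ND",
           vapply(v, function(x) format(x, digits = digits, trim = TRUE),
                  character(1)))
  }
  rows <- purrr::imap_dfr(results, function(res, nm) {
    g <- glance(res)
    tibble::tibble(
      dataset = if (is.character(nm) && nzchar(nm)) nm else paste0("dataset", nm),
      mode = g$mode, platform = g$platform,
      detected = as.character(g$detected),
      non_selective = as.character(g$non_selective),
      one_to_one = as.character(g$one_to_one),
      brain = fmt(as.numeric(g$brain_selective)),
      placenta = fmt(as.numeric(g$placenta_selective)),
      lower_limit = fmt(g$lower_limit), upper_limit = fmt(g$upper_limit),
      range = fmt(g$range_span),
      auc_all = fmt(g$auc_all), auc_within = fmt(g$auc_within),
      median = fmt(g$deviation_median), iqr = fmt(g$deviation_iqr),
      proportion_sum = fmt(g$proportion_sum)
    )
  })
  if (length(results) == 0L) {
    rows <- tibble::tibble(
      dataset = character(), mode = character(), platform = character(),
      detected = character(), non_selective = character(),
      one_to_one = character(), brain = character(), placenta = character(),
      lower_limit = character(), upper_limit = character(),
      range = character(), auc_all = character(), auc_within = character(),
      median = character(), iqr = character(), proportion_sum = character()
    )
  }
  if (!is.null(path)) readr::write_tsv(rows, path, progress = FALSE)
  rows
}
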