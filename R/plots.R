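class_palette <- function() {
  c(placenta_selective = "#d62728", brain_selective = "#1f77b4",
    one_to_one = "#e6c300", non_selective = "grey65")
}

class_labels <- function() {
  c(placenta_selective = "placenta", brain_selective = "brain",
    one_to_one = "1-to-1", non_selective = "NS")
}

ratio_plot_data <- function(ratios, which = c("pred", "obs")) {
  which <- match.arg(which)
  tibble::tibble(
    mirna = ratios$mirna,
    class = factor(ratios$class %||% "non_selective",
                   levels = names(class_palette())),
    M = ratios[[paste0("M_", which)]],
    A = ratios[[paste0("A_", which)]]
  )
}

ma_panel <- function(dat, title, bands = NULL, ylim_pad = 0.25) {
  p <- ggplot(dat, aes(x = .data$A, y = .data$M)) +
    geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey40") +
    geom_point(data = dat[dat$class == "non_selective", ],
               shape = 1, colour = "grey65", size = 0.8, alpha = 0.6) +
    geom_point(data = dat[dat$class != "non_selective", ],
               aes(colour = .data$class), size = 0.9, alpha = 0.8) +
    scale_colour_manual(values = class_palette(), labels = class_labels(),
                        drop = FALSE, name = NULL) +
    labs(title = title, x = "average log2 signal (A)", y = "log2 ratio (M)") +
    theme_bw(base_size = 9)
  if (!is.null(bands)) {
    for (nm in names(bands)) {
      b <- bands[[nm]]
      if (nrow(b) == 0L) next
      p <- p +
        geom_ribbon(data = b, aes(x = .data$A, ymin = .data$lower,
                                  ymax = .data$upper),
                    inherit.aes = FALSE, fill = class_palette()[[nm]],
                    alpha = 0.25) +
        geom_line(data = b, aes(x = .data$A, y = .data$fit),
                  inherit.aes = FALSE, linewidth = 0.4)
    }
  }
  p
}

ratio_bands <- function(dat, span = 0.75) {
  subsets <- c("placenta_selective", "one_to_one", "brain_selective")
  bands <- lapply(subsets, function(cl) {
    sub <- dat[dat$class == cl & is.finite(dat$M), ]
    if (nrow(sub) < 10L) {
      return(tibble::tibble(A = double(), fit = double(),
                            lower = double(), upper = double()))
    }
    suppressWarnings(loess_band(sub, span = span))
  })
  names(bands) <- subsets
  bands
}

#' MA panel of predicted or observed log2 ratios
#'
#' The Bland-Altman view of the mixture comparison: log2 ratio against
#' average log2 signal, coloured by selectivity class (red = placenta, blue
#' = brain, yellow = 1-to-1, open grey = non-selective), with loess trend
#' and 95% band for each selective subset.
#'
#' @param result A `mixqc_dashboard` from [run_pipeline()].
#' @param which `"pred"` (predicted ratios) or `"obs"` (observed).
#' @param bands Draw loess bands? (default `TRUE`)
#' @return A ggplot.
#' @export
plot_ma <- function(result, which = c("pred", "obs"), bands = TRUE) {
  which <- match.arg(which)
  dat <- ratio_plot_data(result$ratios, which)
  ttl <- if (which == "pred") "Predicted log2 ratios" else "Observed log2 ratios"
  ma_panel(dat, ttl, bands = if (bands) ratio_bands(dat) else NULL)
}

#' Deviation-vs-signal panel with reliable-range margins
#'
#' Observed minus predicted log2 ratio against average signal; horizontal
#' lines mark the overall median (solid) and IQR (dashed), and shaded
#' margins mark the region outside the reliable range when determined.
#'
#' @param result A `mixqc_dashboard`.
#' @return A ggplot.
#' @export
plot_deviation <- function(result) {
  devs <- result$deviations
  dat <- tibble::tibble(
    A = devs$A_avg, M = devs$D,
    class = factor(devs$class %||% "non_selective",
                   levels = names(class_palette()))
  )
  p <- ma_panel(dat, "Deviation from predicted ratios") +
    labs(y = "observed - predicted log2 ratio (D)") +
    geom_hline(yintercept = result$deviation_median, linewidth = 0.4) +
    geom_hline(yintercept = result$deviation_median +
                 c(-0.5, 0.5) * result$deviation_iqr,
               linetype = "dashed", linewidth = 0.3)
  rng <- result$range
  if (!is.null(rng) && !rng$nd) {
    p <- p +
      annotate("rect", xmin = -Inf, xmax = rng$lower_limit,
               ymin = -Inf, ymax = Inf, fill = "grey30", alpha = 0.15) +
      annotate("rect", xmin = rng$upper_limit, xmax = Inf,
               ymin = -Inf, ymax = Inf, fill = "grey30", alpha = 0.15)
  }
  p
}

#' Per-class box-and-whisker panel of deviations
#'
#' Bias and dispersion within each tissue-selective class: boxes span the
#' IQR, whiskers 1.5 IQR, with the overall median and IQR as horizontal
#' reference lines.
#'
#' @param result A `mixqc_dashboard`.
#' @return A ggplot.
#' @export
plot_class_boxes <- function(result) {
  devs <- result$deviations
  dat <- tibble::tibble(
    class = factor(devs$class %||% "non_selective",
                   levels = names(class_palette())),
    D = devs$D
  )
  ggplot(dat, aes(x = .data$class, y = .data$D, fill = .data$class)) +
    geom_boxplot(outlier.shape = 124, outlier.size = 1.5, linewidth = 0.3) +
    scale_fill_manual(values = class_palette(), guide = "none") +
    scale_x_discrete(labels = class_labels(), drop = FALSE) +
    geom_hline(yintercept = result$deviation_median, linewidth = 0.4) +
    geom_hline(yintercept = result$deviation_median +
                 c(-0.5, 0.5) * result$deviation_iqr,
               linetype = "dashed", linewidth = 0.3) +
    labs(title = "Deviation by selectivity class", x = NULL,
         y = "observed - predicted log2 ratio (D)") +
    theme_bw(base_size = 9)
}

#' ROC panel (full range and within the reliable region)
#'
#' @param result A `mixqc_dashboard`.
#' @return A ggplot; annotated "ND" when the curve is not determined.
#' @export
plot_roc <- function(result) {
  base <- ggplot() +
    geom_abline(slope = 1, intercept = 0, colour = "grey70",
                linewidth = 0.3) +
    coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(title = "Discrimination accuracy",
         x = "false-positive rate", y = "true-positive rate") +
    theme_bw(base_size = 9)
  ann <- character()
  if (!result$roc_all$nd) {
    base <- base + geom_path(data = result$roc_all$points,
                             aes(x = .data$fpr, y = .data$tpr), linewidth = 0.5)
    ann <- c(ann, sprintf("AUC all = %.3f", result$roc_all$auc))
  } else {
    ann <- c(ann, "AUC all: ND")
  }
  if (!result$roc_within$nd) {
    base <- base + geom_path(data = result$roc_within$points,
                             aes(x = .data$fpr, y = .data$tpr),
                             linetype = "dashed", linewidth = 0.5)
    ann <- c(ann, sprintf("within range = %.3f", result$roc_within$auc))
  } else {
    ann <- c(ann, "within range: ND")
  }
  base + annotate("text", x = 0.97, y = 0.08,
                  label = paste(ann, collapse = "\n"),
                  hjust = 1, size = 2.7)
}

#' Target panel of deconvolved mixture proportions
#'
#' Each component sits at its designed (fraction-in-Mix1, fraction-in-Mix2)
#' point (concentric target circles); a segment joins it to the deconvolved
#' estimate, and bootstrap 95% ellipses surround the estimates.
#'
#' @param result A `mixqc_dashboard`.
#' @return A ggplot; a placeholder panel when deconvolution was not run.
#' @export
plot_target <- function(result) {
  comp_palette <- function(components, roles) {
    cols <- stats::setNames(rep("#e6c300", length(components)), components)
    if (length(roles$variable) == 2L) {
      cols[roles$variable[1L]] <- "#1f77b4"
      cols[roles$variable[2L]] <- "#d62728"
    }
    cols
  }
  if (is.null(result$geometry)) {
    return(ggplot() +
             annotate("text", x = 0.5, y = 0.5,
                      label = "proportion deconvolution\nnot assessed") +
             labs(title = "Deconvolved mixture proportions") +
             theme_void(base_size = 9))
  }
  geom <- result$geometry
  roles <- design_component_roles(
    mix_design(geom$component, cbind(mix1 = geom$center_x, mix2 = geom$center_y)))
  pal <- comp_palette(geom$component, roles)
  rings <- tidyr::expand_grid(geom, r = c(0.02, 0.04, 0.06))
  p <- ggplot(geom, aes(colour = .data$component)) +
    ggplot2::geom_point(aes(x = .data$center_x, y = .data$center_y), size = 1) +
    lapply(split(rings, seq_len(nrow(rings))), function(rr) {
      annotate("path",
               x = rr$center_x + rr$r * cos(seq(0, 2 * pi, length.out = 60)),
               y = rr$center_y + rr$r * sin(seq(0, 2 * pi, length.out = 60)),
               colour = "grey60", linewidth = 0.2)
    }) +
    geom_segment(aes(x = .data$center_x, y = .data$center_y,
                     xend = .data$est_x, yend = .data$est_y),
                 linewidth = 0.5) +
    geom_point(aes(x = .data$est_x, y = .data$est_y), size = 1.5) +
    scale_colour_manual(values = pal, name = NULL) +
    labs(title = "Deconvolved mixture proportions",
         x = "fraction in Mix1", y = "fraction in Mix2") +
    coord_equal() +
    theme_bw(base_size = 9)
  if (!is.null(result$uncertainty)) {
    for (i in seq_len(nrow(result$uncertainty))) {
      ell <- result$uncertainty$ellipse[[i]]
      ell$component <- result$uncertainty$component[i]
      p <- p + geom_path(data = ell, aes(x = .data$x, y = .data$y),
                         linewidth = 0.3)
    }
  }
  p
}

#' Assemble the multi-panel dashboard figure
#'
#' Arranges the six panels — predicted MA, observed MA, deviation with
#' range margins, per-class boxes, ROC, and the proportion target plot —
#' into one patchwork figure, the standardized per-round dashboard view.
#'
#' @param object A `mixqc_dashboard`.
#' @param ... Unused.
#' @return A patchwork object.
#' @method autoplot mixqc_dashboard
#' @export
autoplot.mixqc_dashboard <- function(object, ...) {
  patchwork::wrap_plots(
    list(plot_ma(object, "pred"), plot_ma(object, "obs"),
         plot_deviation(object), plot_class_boxes(object),
         plot_roc(object), plot_target(object)),
    ncol = 2
  ) +
    patchwork::plot_annotation(
      subtitle = sprintf("mode: %s | platform: %s", object$mode,
                         object$platform))
}

#' Render the dashboard to files
#'
#' Writes the six-panel figure as PNG and PDF plus machine-readable metric
#' twins (TSV via [metrics_to_table()] and JSON).
#'
#' @param result A `mixqc_dashboard`.
#' @param dir Output directory (created if needed).
#' @param name Basename for the emitted files (default `"dashboard"`).
#' @param width,height Figure size in inches.
#' @return Character vector of the files written, invisibly.
#' @export
render_dashboard <- function(result, dir, name = "dashboard",
                             width = 10, height = 12) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fig <- autoplot.mixqc_dashboard(result)
  png_path <- file.path(dir, paste0(name, ".png"))
  pdf_path <- file.path(dir, paste0(name, ".pdf"))
  ggsave(png_path, fig, width = width, height = height, dpi = 150)
  ggsave(pdf_path, fig, width = width, height = height)
  tsv_path <- file.path(dir, paste0(name, "_metrics.tsv"))
  metrics_to_table(stats::setNames(list(result), name), path = tsv_path)
  json_path <- file.path(dir, paste0(name, "_metrics.json"))
  g <- as.list(glance(result))
  g$nd_reasons <- result$nd_reasons
  g$provenance <- result$provenance
  jsonlite::write_json(g, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(png_path, pdf_path, tsv_path, json_path))
}
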