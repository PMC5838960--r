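#' Paired t-test p-values for the Mix1 vs Mix2 comparison
#'
#' For each miRNA, pairs the log2 signals of the Mix1 and Mix2 replicates by
#' replicate index and computes a two-sided paired t-test. Replicated
#' designs use these p-values to rank miRNAs for the ROC analysis. Two
#' degenerate cases are handled explicitly: all paired differences exactly
#' zero gives p = 1 (the null holds exactly), and zero variance with a
#' nonzero mean difference gives the machine-minimum p with a flag.
#'
#' @param log2_table Log2 tibble containing the mixture replicate columns.
#' @param manifest Manifest tibble; Mix1 and Mix2 must have equal replicate
#'   counts n >= 2.
#' @param design A `mixqc_design` with 2 mixtures.
#' @return Tibble `mirna`, `p`, `flag` (`"ok"`, `"zero_variance"`).
#' @export
paired_pvalues <- function(log2_table, manifest, design = default_mix_design()) {
  mx <- design$mixtures
  ids <- lapply(mx, function(m) {
    sub <- manifest[manifest$role == paste0("mix:", m), ]
    sub <- sub[order(sub$replicate), ]
    sub$sample_id
  })
  n1 <- length(ids[[1L]]); n2 <- length(ids[[2L]])
  if (n1 != n2 || n1 < 2L)
    stop("paired t-test needs equal replicate counts >= 2 for both mixtures",
         call. = FALSE)
  x <- as.matrix(log2_table[ids[[1L]]])
  y <- as.matrix(log2_table[ids[[2L]]])
  d <- x - y
  mean_d <- rowMeans(d)
  sd_d <- apply(d, 1L, sd)
  n <- ncol(d)
  p <- rep(NA_real_, nrow(d))
  flag <- rep("ok", nrow(d))
  degen <- sd_d == 0
  p[degen & mean_d == 0] <- 1
  zv <- degen & mean_d != 0
  p[zv] <- .Machine$double.xmin
  flag[zv] <- "zero_variance"
  ok <- !degen
  tstat <- mean_d[ok] / (sd_d[ok] / sqrt(n))
  p[ok] <- 2 * pt(-abs(tstat), df = n - 1)
  tibble::tibble(mirna = log2_table$mirna, p = p, delta = mean_d, flag = flag)
}

#' Ranking scores for unreplicated designs
#'
#' Without technical replication no p-value can be formed, so miRNAs are
#' ranked by the magnitude of their observed log2 ratio: larger |M| is more
#' evidence of a real Mix1/Mix2 difference.
#'
#' @param observed Ratio-record tibble from [observed_ratios()].
#' @return Tibble `mirna`, `score = |M|`.
#' @export
unreplicated_scores <- function(observed) {
  tibble::tibble(mirna = observed$mirna, score = abs(observed$M))
}

#' Designed-truth ROC curve and AUC
#'
#' Builds the receiver-operating-characteristic curve for recovering the
#' designed mixture differences: true positives are the variable-component
#' selective miRNAs (brain- and placenta-selective under the default
#' design), true negatives the 1-to-1 class; non-selective miRNAs take no
#' part. The ranking comes either from paired t-test p-values (ascending)
#' or from unreplicated |ratio| scores (descending). Ties share a midrank
#' and draw diagonal ROC segments; the AUC is the trapezoid-rule area,
#' identical to the Mann-Whitney pairwise-win probability. Optionally the
#' comparison is restricted to miRNAs whose signal lies inside the reliable
#' region of the dynamic range — the restriction changes only which labels
#' enter, never a miRNA's score.
#'
#' @param ranking Tibble with `mirna` and either a `p` column (smaller =
#'   stronger evidence) or a `score` column (larger = stronger evidence).
#' @param classification Classification tibble ([classify_selectivity()]).
#' @param design A `mixqc_design`.
#' @param range Optional `mixqc_range`; with `A`, restricts to miRNAs whose
#'   signal is within `[lower_limit, upper_limit]`.
#' @param A Optional tibble `mirna`, `A` giving each miRNA's average log2
#'   signal (used only with `range`).
#' @return A `mixqc_roc` object: `points` tibble (`fpr`, `tpr`), `auc`,
#'   `n_true_pos`, `n_true_neg`, `restricted_to_range`, `nd` flag.
#' @export
roc_auc <- function(ranking, classification, design = default_mix_design(),
                    range = NULL, A = NULL) {
  roles <- design_component_roles(design)
  tp_classes <- paste0(roles$variable, "_selective")

  labeled <- dplyr::inner_join(ranking, classification, by = "mirna")
  restricted <- FALSE
  if (!is.null(range)) {
    if (is.null(A))
      stop("restricting to the reliable range requires per-miRNA `A` values",
           call. = FALSE)
    restricted <- TRUE
    if (isTRUE(range$nd)) {
      return(new_roc(NULL, NA_real_, 0L, 0L, restricted, nd = TRUE,
                     nd_reason = "reliable range not determined"))
    }
    labeled <- dplyr::inner_join(labeled, dplyr::select(A, "mirna", "A"),
                                 by = "mirna")
    labeled <- labeled[labeled$A >= range$lower_limit &
                         labeled$A <= range$upper_limit, ]
  }
  labeled <- labeled[labeled$class %in% c(tp_classes, "one_to_one"), ]
  is_pos <- labeled$class %in% tp_classes
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) {
    return(new_roc(NULL, NA_real_, n_pos, n_neg, restricted, nd = TRUE,
                   nd_reason = "insufficient true positives or true negatives"))
  }
  score <- if ("p" %in% names(labeled)) -labeled$p else labeled$score
  if (is.null(score))
    stop("`ranking` must contain a `p` or `score` column", call. = FALSE)
  # ties at identical p (only reachable when the t statistic underflows or
  # is exactly degenerate) are refined by the magnitude of the mean paired
  # difference; elsewhere tiebreak never changes the order
  tiebreak <- if ("delta" %in% names(labeled)) abs(labeled$delta) else rep(0, nrow(labeled))

  ord <- order(score, tiebreak, decreasing = TRUE)
  s <- score[ord]; tb <- tiebreak[ord]; pos <- is_pos[ord]
  # collapse tied (score, tiebreak) pairs into single threshold steps
  # (diagonal segments)
  new_grp <- c(TRUE, diff(s) != 0 | diff(tb) != 0)
  grp <- cumsum(new_grp)
  tp_step <- rowsum(as.integer(pos), grp)[, 1L]
  fp_step <- rowsum(as.integer(!pos), grp)[, 1L]
  tpr <- c(0, unname(cumsum(tp_step)) / n_pos)
  fpr <- c(0, unname(cumsum(fp_step)) / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
  new_roc(tibble::tibble(fpr = fpr, tpr = tpr), auc, n_pos, n_neg,
          restricted, nd = FALSE, nd_reason = NULL)
}

new_roc <- function(points, auc, n_pos, n_neg, restricted, nd, nd_reason) {
  structure(list(points = points, auc = auc, n_true_pos = n_pos,
                 n_true_neg = n_neg, restricted_to_range = restricted,
                 nd = nd, nd_reason = nd_reason),
            class = "mixqc_roc")
}

#' @export
print.mixqc_roc <- function(x, ...) {
  if (x$nd) {
    cat("<mixqc_roc> ND (", x$nd_reason, ")\n", sep = "")
  } else {
    cat(sprintf("<mixqc_roc> AUC %.3f (%d TP, %d TN%s)\n", x$auc,
                x$n_true_pos, x$n_true_neg,
                if (x$restricted_to_range) ", within reliable range" else ""))
  }
  invisible(x)
}

#' @method tidy mixqc_roc
#' @export
tidy.mixqc_roc <- function(x, ...) {
  if (x$nd) return(tibble::tibble(fpr = double(), tpr = double()))
  x$points
}

#' @method glance mixqc_roc
#' @export
glance.mixqc_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_true_pos = x$n_true_pos,
                 n_true_neg = x$n_true_neg,
                 restricted_to_range = x$restricted_to_range, nd = x$nd)
}
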