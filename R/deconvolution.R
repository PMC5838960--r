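#' Average mixture replicates on the linear scale
#'
#' @param table Normalized linear-scale expression tibble containing the
#'   mixture samples.
#' @param manifest Manifest tibble.
#' @param design A `mixqc_design`.
#' @return Tibble `mirna` plus one mean-signal column per mixture.
#' @export
mixture_means <- function(table, manifest, design) {
  cols <- lapply(design$mixtures, function(mx) {
    ids <- intersect(manifest_mix_ids(manifest, mx), names(table))
    if (!length(ids))
      stop("no samples for mixture '", mx, "'", call. = FALSE)
    rowMeans(as.matrix(table[ids]))
  })
  names(cols) <- design$mixtures
  tibble::as_tibble(c(list(mirna = table$mirna), cols))
}

# Exact solution of min ||y - X b||^2  s.t.  sum(b) = 1, b >= 0, by
# enumerating active (zeroed) sets and solving each KKT equality system.
# Exhaustive over 2^k - 1 free sets; exact for the small k (# components)
# used here.
simplex_lsq <- function(X, y) {
  k <- ncol(X)
  # common rescale of X and y leaves the solution unchanged but keeps the
  # KKT system (crossprod terms vs unit constraint rows) well conditioned
  s <- sqrt(mean(X^2))
  if (s > 0) {
    X <- X / s
    y <- y / s
  }
  best <- NULL
  best_rss <- Inf
  for (bits in seq_len(2^k - 1L)) {
    free <- which(bitwAnd(bits, 2^(seq_len(k) - 1L)) > 0)
    Xf <- X[, free, drop = FALSE]
    kf <- length(free)
    kkt <- rbind(cbind(2 * crossprod(Xf), rep(1, kf)),
                 c(rep(1, kf), 0))
    rhs <- c(2 * crossprod(Xf, y), 1)
    sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    b_free <- sol[seq_len(kf)]
    if (any(b_free < -1e-10)) next
    b <- numeric(k)
    b[free] <- pmax(b_free, 0)
    b <- b / sum(b)
    rss <- sum((y - X %*% b)^2)
    if (rss < best_rss - 1e-12) {
      best_rss <- rss
      best <- b
    }
  }
  if (is.null(best))
    stop("constrained least-squares solve failed", call. = FALSE)
  best
}

#' Deconvolve mixture proportions from measured signals
#'
#' Inverts the linear mixing model: given the pure-component mean profiles
#' and the measured (replicate-averaged, linear-scale) signal of each
#' mixture, solves for the fraction vector phi that best explains the
#' mixture by constrained least squares,
#' `min over phi of sum_i (S[i, mix] - sum_c S[i, c] * phi[c])^2`
#' subject to `phi >= 0` and `sum(phi) = 1`. The fit runs on the linear
#' scale, where the mixing model is linear, and by default uses all
#' detected miRNAs; `rows` can restrict the fit (e.g. to the reliable
#' range) and `weights` can down-weight high-signal rows.
#'
#' @param profile Pure-profile tibble ([pure_profile()]), linear scale.
#' @param mixtures Mixture-mean tibble ([mixture_means()]), linear scale.
#' @param design A `mixqc_design`.
#' @param rows Optional character vector of miRNA ids to fit on.
#' @param weights Optional nonnegative per-row weights (aligned with the
#'   fitted rows).
#' @return A `mixqc_proportions` object with `phi_hat` (component x mixture
#'   matrix of estimated fractions), `design_phi`, `n_mirna`, and the design.
#' @export
estimate_proportions <- function(profile, mixtures, design,
                                 rows = NULL, weights = NULL) {
  merged <- dplyr::inner_join(profile, mixtures, by = "mirna")
  if (!is.null(rows)) merged <- merged[merged$mirna %in% rows, ]
  X <- as.matrix(merged[design$components])
  if (nrow(X) < ncol(X))
    stop("need at least as many miRNAs as components", call. = FALSE)
  kap <- kappa(X, exact = TRUE)
  if (!is.finite(kap) || kap > 1e10)
    stop("pure-component profiles are collinear (condition number ",
         format(kap, digits = 3), "); proportions are not identifiable",
         call. = FALSE)
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(X), all(weights >= 0))
    w <- sqrt(weights)
    Xw <- X * w
  } else {
    w <- NULL
    Xw <- X
  }
  phi_hat <- vapply(design$mixtures, function(mx) {
    y <- merged[[mx]]
    if (!is.null(w)) y <- y * w
    simplex_lsq(Xw, y)
  }, numeric(length(design$components)))
  rownames(phi_hat) <- design$components
  structure(list(phi_hat = phi_hat, design_phi = design$phi,
                 n_mirna = nrow(X), design = design),
            class = "mixqc_proportions")
}

#' @export
print.mixqc_proportions <- function(x, ...) {
  cat("<mixqc_proportions> estimated from", x$n_mirna, "miRNAs\n")
  print(round(x$phi_hat, 4))
  invisible(x)
}

#' @method tidy mixqc_proportions
#' @export
tidy.mixqc_proportions <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$phi_hat,
                                        responseName = "estimate")) |>
    dplyr::rename(component = "Var1", mixture = "Var2") |>
    dplyr::mutate(component = as.character(.data$component),
                  mixture = as.character(.data$mixture),
                  design = as.vector(x$design_phi))
}

#' Target-plot geometry for deconvolved proportions
#'
#' Places each component in (fraction-in-Mix1, fraction-in-Mix2) space: the
#' target center is the designed proportion pair, the segment endpoint the
#' estimated pair, and the segment length their Euclidean distance. The sum
#' of all segment lengths is a single bias indicator for the measurement
#' process (0 = perfect recovery of the design).
#'
#' @param design A `mixqc_design` with 2 mixtures.
#' @param estimate A `mixqc_proportions` from [estimate_proportions()].
#' @return Tibble `component`, `center_x`, `center_y`, `est_x`, `est_y`,
#'   `segment_length`, with attribute `length_sum`; see also
#'   [proportion_length_sum()].
#' @export
target_geometry <- function(design, estimate) {
  stopifnot(ncol(design$phi) == 2L)
  out <- tibble::tibble(
    component = design$components,
    center_x = unname(design$phi[, 1L]), center_y = unname(design$phi[, 2L]),
    est_x = unname(estimate$phi_hat[, 1L]),
    est_y = unname(estimate$phi_hat[, 2L])
  )
  out$segment_length <- sqrt((out$est_x - out$center_x)^2 +
                               (out$est_y - out$center_y)^2)
  attr(out, "length_sum") <- sum(out$segment_length)
  out
}

#' @rdname target_geometry
#' @param geometry Tibble from [target_geometry()].
#' @export
proportion_length_sum <- function(geometry) sum(geometry$segment_length)

#' Bootstrap confidence ellipses for the proportion estimates
#'
#' Resamples miRNA rows with replacement and re-runs the constrained
#' deconvolution on each draw, giving an empirical 2D distribution of each
#' component's (Mix1, Mix2) fraction pair. The 95% ellipse is the
#' chi-square(2 df) contour of the empirical mean and covariance. Rows (not
#' replicates) are resampled: with three replicates per mixture there is too
#' little replicate-level information, while row resampling reflects both
#' dispersion and detection within each selectivity class.
#'
#' @inheritParams estimate_proportions
#' @param n_boot Number of bootstrap draws (default 1000; must be >= 10).
#' @param seed Integer seed for the resampling.
#' @param level Ellipse coverage level (default 0.95).
#' @return Tibble per component: `component`, `mean_x`, `mean_y`,
#'   `var_x`, `var_y`, `cov_xy`, `degenerate` flag, and list-column
#'   `ellipse` of (x, y) path tibbles.
#' @export
proportion_uncertainty <- function(profile, mixtures, design,
                                   n_boot = 1000, seed = 1, level = 0.95) {
  if (n_boot < 10)
    stop("`n_boot` must be at least 10 for a usable ellipse", call. = FALSE)
  merged <- dplyr::inner_join(profile, mixtures, by = "mirna")
  n <- nrow(merged)
  X_all <- as.matrix(merged[design$components])
  Y_all <- as.matrix(merged[design$mixtures])
  k <- length(design$components)
  draws <- withr::with_seed(seed, {
    replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X_all[idx, , drop = FALSE]
      tryCatch(
        vapply(seq_along(design$mixtures),
               function(j) simplex_lsq(Xb, Y_all[idx, j]), numeric(k)),
        error = function(e) matrix(NA_real_, k, length(design$mixtures)))
    }, simplify = "array")
  })
  purrr::map_dfr(seq_along(design$components), function(ci) {
    pts <- t(draws[ci, , ])  # n_boot x 2 (Mix1, Mix2)
    pts <- pts[stats::complete.cases(pts), , drop = FALSE]
    mu <- colMeans(pts)
    S <- stats::cov(pts)
    degen <- any(!is.finite(S)) || det(S) < 1e-24
    ell <- ellipse_path(mu, S, level = level)
    tibble::tibble(component = design$components[ci],
                   mean_x = mu[1L], mean_y = mu[2L],
                   var_x = S[1L, 1L], var_y = S[2L, 2L], cov_xy = S[1L, 2L],
                   degenerate = degen, ellipse = list(ell))
  })
}

ellipse_path <- function(mu, S, level = 0.95, n = 100) {
  r <- sqrt(qchisq(level, df = 2))
  theta <- seq(0, 2 * pi, length.out = n)
  circ <- rbind(cos(theta), sin(theta))
  eig <- eigen(S, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  pts <- eig$vectors %*% (sqrt(lam) * circ) * r
  tibble::tibble(x = mu[1L] + pts[1L, ], y = mu[2L] + pts[2L, ])
}

#' Export proportion results as JSON
#'
#' @param estimate A `mixqc_proportions`.
#' @param geometry Tibble from [target_geometry()].
#' @param uncertainty Optional tibble from [proportion_uncertainty()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(estimate, geometry, uncertainty = NULL, path) {
  out <- list(
    phi_hat = apply(estimate$phi_hat, 2L, as.list),
    design_phi = apply(estimate$design_phi, 2L, as.list),
    segment_lengths = stats::setNames(as.list(geometry$segment_length),
                                      geometry$component),
    length_sum = proportion_length_sum(geometry),
    n_mirna = estimate$n_mirna,
    ellipse_method = "bootstrap over miRNA rows, chi-square(2) 95% contour"
  )
  if (!is.null(uncertainty)) {
    out$uncertainty <- purrr::map(seq_len(nrow(uncertainty)), function(i) {
      list(component = uncertainty$component[i],
           mean = c(uncertainty$mean_x[i], uncertainty$mean_y[i]),
           cov = list(c(uncertainty$var_x[i], uncertainty$cov_xy[i]),
                      c(uncertainty$cov_xy[i], uncertainty$var_y[i])),
           degenerate = uncertainty$degenerate[i])
    })
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
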