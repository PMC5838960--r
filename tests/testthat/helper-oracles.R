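# Independent brute-force oracles used to check the package implementations.
# Each deliberately avoids the code path it verifies.

# AUC as the Mann-Whitney pairwise-win probability: wins + half-ties over
# all (positive, negative) score pairs. Higher score = more positive.
oracle_auc <- function(scores_pos, scores_neg) {
  wins <- 0
  for (sp in scores_pos) {
    wins <- wins + sum(sp > scores_neg) + 0.5 * sum(sp == scores_neg)
  }
  wins / (length(scores_pos) * length(scores_neg))
}

# Exhaustive simplex grid search for the sum-to-one nonnegative least
# squares fit, at the stated resolution.
oracle_simplex_grid <- function(X, y, resolution = 1e-3) {
  steps <- round(1 / resolution)
  best <- NULL
  best_rss <- Inf
  for (i in 0:steps) {
    for (j in 0:(steps - i)) {
      b <- c(i, j, steps - i - j) / steps
      rss <- sum((y - X %*% b)^2)
      if (rss < best_rss) {
        best_rss <- rss
        best <- b
      }
    }
  }
  best
}

# Naive rescan of the sliding-window reliable-range rule.
oracle_reliable_lower <- function(A, D, window_size, tolerance, coverage) {
  ord <- order(A)
  A <- A[ord]; D <- D[ord]
  n <- length(D)
  alpha <- (1 - coverage) / 2
  centers <- numeric(0)
  ok <- logical(0)
  for (s in seq_len(n - window_size + 1L)) {
    idx <- s:(s + window_size - 1L)
    q <- quantile(D[idx], c(alpha, 1 - alpha), type = 7, names = FALSE)
    centers <- c(centers, median(A[idx]))
    ok <- c(ok, q[1] >= -tolerance && q[2] <= tolerance)
  }
  good <- which(vapply(seq_along(ok), function(i) all(ok[i:length(ok)]),
                       logical(1)))
  if (!length(good)) return(NA_real_)
  centers[good[1]]
}

# Brute-force maximization of the predicted Mix1/Mix2 log2 ratio over a
# grid of nonnegative pure-component signal vectors.
oracle_design_bound <- function(phi, n_grid = 25) {
  k <- nrow(phi)
  levels <- c(0, 10^seq(-2, 2, length.out = n_grid - 1))
  grid <- as.matrix(expand.grid(rep(list(levels), k)))
  s1 <- grid %*% phi[, 1]
  s2 <- grid %*% phi[, 2]
  keep <- s1 > 0 & s2 > 0
  max(abs(log2(s1[keep] / s2[keep])))
}

# Tiny dataset builders ------------------------------------------------

toy_manifest <- function(design = default_mix_design(), n_rep = 3) {
  build_manifest(design, n_rep, "full")
}

# Expression table from an explicit matrix (rows named by miRNA).
toy_table <- function(values, manifest, platform = "counts") {
  tbl <- tibble::as_tibble(cbind(
    tibble::tibble(mirna = rownames(values)),
    as.data.frame(values)
  ))
  as_expression_table(tbl, platform = platform, manifest = manifest)
}

# Deterministic noise-free dataset built directly from a profile matrix:
# pure replicates repeat the profile, mixtures apply the design exactly.
exact_dataset <- function(profile_mat, design = default_mix_design(),
                          n_rep = 3, platform = "counts") {
  manifest <- build_manifest(design, n_rep, "full")
  mixes <- profile_mat %*% design$phi
  cols <- lapply(seq_len(nrow(manifest)), function(i) {
    role <- sub("^(pure|mix):", "", manifest$role[i])
    if (role %in% colnames(profile_mat)) profile_mat[, role] else mixes[, role]
  })
  values <- do.call(cbind, cols)
  colnames(values) <- manifest$sample_id
  rownames(values) <- rownames(profile_mat)
  list(table = toy_table(values, manifest, platform), manifest = manifest)
}
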