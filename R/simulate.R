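#' Configuration for the synthetic reference-sample generator
#'
#' Defines the ground-truth world the simulator emulates: three tissue
#' total-RNA profiles carrying tissue-selective subsets over a wide dynamic
#' range, combined into the two reciprocal mixtures, and measured with
#' platform-specific noise. Defaults mirror the composition of a deeply
#' sequenced participant dataset (about a thousand detectable miRNAs of
#' which roughly a tenth each are brain- and placenta-selective, a couple of
#' percent liver-selective, and a few percent with matched brain/placenta
#' signal).
#'
#' @param n_mirna Number of miRNAs.
#' @param frac_selective Named fractions of miRNAs made selective for each
#'   component (defaults `c(liver = 0.02, brain = 0.10, placenta = 0.10)`).
#' @param frac_equal Fraction with exactly equal brain/placenta abundance
#'   (default 0.03).
#' @param enrichment_fold Fold enrichment injected into selective miRNAs in
#'   their target tissue (default 20; must be >= the 10x selectivity rule).
#' @param abundance_mean_log2,abundance_sd_log2 Log-normal baseline
#'   abundance model on the log2 scale (defaults 7 and 3, spanning a wide
#'   dynamic range).
#' @param tissue_sd_log2 Per-tissue log2 jitter around the shared baseline
#'   for non-selective miRNAs (default 1).
#' @param platform `"ngs"` (multinomial read counts), `"hyb"` (intensities
#'   with additive background and multiplicative noise) or `"pcr"`
#'   (quantitation cycles).
#' @param depth Expected total counts per NGS sample (default 1e6).
#' @param background Additive intensity floor for `"hyb"` (default 50).
#' @param hyb_noise_sd_log2 Multiplicative log-normal noise sd for `"hyb"`
#'   (default 0.15).
#' @param cq_intercept,cq_noise_sd Cq model for `"pcr"`:
#'   `Cq = cq_intercept - log2(signal) + N(0, cq_noise_sd)` (defaults 36 and
#'   0.25 cycles).
#' @param mirna_fraction Optional named per-tissue scalar multiplying that
#'   tissue's whole profile, emulating differing miRNA content per mass of
#'   total RNA (default all 1, i.e. equal tissue totals).
#' @param noise Apply the platform noise model? With `FALSE` the emitted
#'   table carries the exact expected signals (the noise-free limit used
#'   for ground-truth recovery checks).
#' @param n_replicates Replicates per sample (default 3).
#' @param seed Integer seed.
#' @return A `mixqc_sim_config` list.
#' @export
simulation_config <- function(n_mirna = 1000L,
                              frac_selective = c(liver = 0.02, brain = 0.10,
                                                 placenta = 0.10),
                              frac_equal = 0.03,
                              enrichment_fold = 20,
                              abundance_mean_log2 = 7,
                              abundance_sd_log2 = 3,
                              tissue_sd_log2 = 1,
                              platform = c("ngs", "hyb", "pcr"),
                              depth = 1e6,
                              background = 50,
                              hyb_noise_sd_log2 = 0.15,
                              cq_intercept = 36,
                              cq_noise_sd = 0.25,
                              mirna_fraction = NULL,
                              noise = TRUE,
                              n_replicates = 3L,
                              seed = 1L) {
  platform <- match.arg(platform)
  stopifnot(n_mirna >= 1, enrichment_fold >= 1,
            all(frac_selective >= 0), frac_equal >= 0,
            sum(frac_selective) + frac_equal <= 1,
            abundance_sd_log2 >= 0, tissue_sd_log2 >= 0,
            depth > 0, background >= 0, hyb_noise_sd_log2 >= 0,
            cq_noise_sd >= 0, n_replicates >= 1)
  structure(list(
    n_mirna = as.integer(n_mirna), frac_selective = frac_selective,
    frac_equal = frac_equal, enrichment_fold = enrichment_fold,
    abundance_mean_log2 = abundance_mean_log2,
    abundance_sd_log2 = abundance_sd_log2, tissue_sd_log2 = tissue_sd_log2,
    platform = platform, depth = depth, background = background,
    hyb_noise_sd_log2 = hyb_noise_sd_log2, cq_intercept = cq_intercept,
    cq_noise_sd = cq_noise_sd, mirna_fraction = mirna_fraction,
    noise = isTRUE(noise),
    n_replicates = as.integer(n_replicates), seed = as.integer(seed)
  ), class = "mixqc_sim_config")
}

#' Simulate ground-truth pure tissue profiles
#'
#' Draws a log-normal baseline abundance per miRNA, then injects structure:
#' selective miRNAs share the baseline across tissues and have their target
#' tissue multiplied by `enrichment_fold` (so the fold rule holds exactly at
#' the noise-free level); the equal-subset miRNAs get identical brain and
#' placenta values; remaining miRNAs get independent per-tissue log2 jitter
#' around the baseline. Truth labels are obtained by running
#' [classify_selectivity()] on the noise-free profile, so labels and
#' classifier agree exactly by construction.
#'
#' @param config A `mixqc_sim_config`.
#' @param design A `mixqc_design` (component names must cover the names of
#'   `frac_selective`).
#' @return List with `profile` (tibble `mirna` + component columns, linear
#'   scale) and `truth` (classification tibble).
#' @export
simulate_pure_profiles <- function(config, design = default_mix_design()) {
  stopifnot(inherits(config, "mixqc_sim_config"))
  comps <- design$components
  roles <- design_component_roles(design)
  n <- config$n_mirna
  withr::with_seed(config$seed, {
    baseline <- 2^rnorm(n, config$abundance_mean_log2, config$abundance_sd_log2)
    n_sel <- round(config$frac_selective * n)
    n_sel <- n_sel[intersect(names(n_sel), comps)]
    n_eq <- round(config$frac_equal * n)
    idx <- seq_len(n)
    assign_sel <- list()
    pool <- idx
    for (comp in names(n_sel)) {
      take <- head(pool, n_sel[[comp]])
      assign_sel[[comp]] <- take
      pool <- setdiff(pool, take)
    }
    eq_idx <- head(pool, n_eq)
    rest <- setdiff(pool, eq_idx)

    prof <- matrix(0, n, length(comps), dimnames = list(NULL, comps))
    # rest: independent per-tissue jitter around the shared baseline
    for (comp in comps) {
      prof[, comp] <- baseline * 2^rnorm(n, 0, config$tissue_sd_log2)
    }
    # selective: shared baseline, target tissue enriched exactly fold-fold
    for (comp in names(assign_sel)) {
      i <- assign_sel[[comp]]
      if (!length(i)) next
      for (cc in comps) prof[i, cc] <- baseline[i]
      prof[i, comp] <- baseline[i] * config$enrichment_fold
    }
    # equal subset: identical variable-component signals, mild jitter on the
    # invariable component so it stays non-selective
    if (length(eq_idx) && length(roles$variable) == 2L) {
      v <- roles$variable
      prof[eq_idx, v[1L]] <- baseline[eq_idx]
      prof[eq_idx, v[2L]] <- baseline[eq_idx]
      for (cc in roles$invariable) {
        prof[eq_idx, cc] <- baseline[eq_idx] * 2^rnorm(length(eq_idx), 0, 0.25)
      }
    }
    # Equalize per-tissue totals so that, absent a deliberate
    # `mirna_fraction` imbalance, each pure sample carries the same total
    # miRNA signal per mass of total RNA. Only the unstructured `rest` rows
    # are rescaled, so injected fold enrichments stay exact; relative-
    # abundance measurements (sequencing) then preserve cross-tissue ratios.
    structured <- c(unlist(assign_sel), eq_idx)
    if (length(rest)) {
      t_fixed <- colSums(prof[structured, , drop = FALSE])
      t_rest <- colSums(prof[rest, , drop = FALSE])
      t_target <- max(t_fixed) + mean(t_rest)
      for (comp in comps) {
        prof[rest, comp] <- prof[rest, comp] *
          (t_target - t_fixed[[comp]]) / t_rest[[comp]]
      }
    }
    if (!is.null(config$mirna_fraction)) {
      for (comp in intersect(names(config$mirna_fraction), comps)) {
        prof[, comp] <- prof[, comp] * config$mirna_fraction[[comp]]
      }
    }
    profile <- tibble::as_tibble(cbind(
      tibble::tibble(mirna = sprintf("mir-%04d", idx)),
      as.data.frame(prof)
    ))
    truth <- classify_selectivity(profile, design)
    list(profile = profile, truth = truth)
  })
}

#' Simulate a full reference-sample dataset
#'
#' Builds the expected signal of every sample in the manifest — pure samples
#' carry their tissue profile, mixtures the fraction-weighted combination
#' under the linear mixing model — then applies platform noise per sample:
#'
#' * `ngs`: a multinomial draw of `depth` total reads over the miRNA
#'   proportions (fixed depth respects sequencing's compositional
#'   constraint, which the median-total normalization is designed for);
#' * `hyb`: `signal * 2^N(0, sd) + background` — additive background floors
#'   low signals and compresses their observed ratios;
#' * `pcr`: `Cq = cq_intercept - log2(signal) + N(0, sd)`.
#'
#' @param config A `mixqc_sim_config`.
#' @param design A `mixqc_design`.
#' @return List with `table` (ingest-compatible expression tibble),
#'   `manifest`, and `truth` (list: `profile`, `classification`, `phi`,
#'   `config`).
#' @export
simulate_dataset <- function(config, design = default_mix_design()) {
  pure <- simulate_pure_profiles(config, design)
  prof <- profile_matrix(pure$profile)
  expected_mix <- prof %*% design$phi
  manifest <- build_manifest(design, config$n_replicates, "full")
  expected <- cbind(prof[, rep(design$components,
                               each = config$n_replicates), drop = FALSE],
                    expected_mix[, rep(design$mixtures,
                                       each = config$n_replicates), drop = FALSE])
  ord <- vapply(manifest$sample_id, function(sid) {
    role <- sub("^(pure|mix):", "", manifest$role[manifest$sample_id == sid])
    rep_i <- manifest$replicate[manifest$sample_id == sid]
    role_cols <- which(colnames(expected) == role)
    role_cols[rep_i]
  }, integer(1))
  expected <- expected[, ord, drop = FALSE]
  colnames(expected) <- manifest$sample_id

  values <- if (!config$noise) {
    switch(config$platform,
      ngs = apply(expected, 2L, function(mu) mu / sum(mu) * config$depth),
      hyb = expected + config$background,
      pcr = config$cq_intercept - log2(pmax(expected, 1e-9))
    )
  } else {
    withr::with_seed(config$seed + 1L, {
      switch(config$platform,
        ngs = apply(expected, 2L, function(mu) {
          p <- mu / sum(mu)
          as.numeric(rmultinom(1L, size = config$depth, prob = p))
        }),
        hyb = apply(expected, 2L, function(mu) {
          mu * 2^rnorm(length(mu), 0, config$hyb_noise_sd_log2) + config$background
        }),
        pcr = apply(expected, 2L, function(mu) {
          config$cq_intercept - log2(pmax(mu, 1e-9)) +
            rnorm(length(mu), 0, config$cq_noise_sd)
        })
      )
    })
  }
  platform <- switch(config$platform, ngs = "counts", hyb = "intensity",
                     pcr = "cq")
  tbl <- tibble::as_tibble(cbind(tibble::tibble(mirna = pure$profile$mirna),
                                 as.data.frame(values)))
  tbl <- as_expression_table(tbl, platform = platform, manifest = manifest,
                             provenance = list(simulated = TRUE,
                                               seed = config$seed))
  list(table = tbl, manifest = manifest,
       truth = list(profile = pure$profile, classification = pure$truth,
                    phi = design$phi, config = config))
}

#' Write a simulated dataset to disk
#'
#' Emits the expression table as TSV (plus provenance sidecar), the manifest
#' as YAML, and the ground truth (labels, design fractions, parameters,
#' seed) as JSON.
#'
#' @param sim List from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(sim$table, file.path(dir, "expression.tsv"))
  write_manifest(sim$manifest, file.path(dir, "manifest.yaml"))
  truth <- list(
    classification = list(mirna = sim$truth$classification$mirna,
                          class = sim$truth$classification$class,
                          subtype = sim$truth$classification$subtype),
    phi = apply(sim$truth$phi, 2L, as.list),
    config = unclass(sim$truth$config)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
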