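design <- default_mix_design()

test_that("noise-free pipeline recovers the designed ground truth", {
  cfg <- simulation_config(n_mirna = 250, noise = FALSE, seed = 41)
  sim <- simulate_dataset(cfg)
  res <- run_pipeline(sim$table, sim$manifest, design, n_boot = 0)
  expect_lt(abs(res$deviation_median), 1e-7)
  expect_lt(res$deviation_iqr, 1e-7)
  expect_equal(res$auc_all, 1.0)
  expect_lt(res$proportion_sum, 1e-6)
  expect_equal(res$lower_limit, res$range$windows$center[1])
  expect_equal(res$n_detected, sum(unlist(res$counts)))
})

test_that("baseline mode with the round's own pures matches full mode", {
  cfg <- simulation_config(n_mirna = 200, depth = 1e5, seed = 42)
  sim <- simulate_dataset(cfg)
  full <- run_pipeline(sim$table, sim$manifest, design, n_boot = 0)
  base <- run_pipeline(sim$table, sim$manifest, design, mode = "baseline",
                       baseline_profile = full$profile, n_boot = 0)
  expect_equal(glance(base)[-1], glance(full)[-1])  # all but the mode column
})

test_that("baseline mode works from the reduced mixtures-only sample set", {
  cfg <- simulation_config(n_mirna = 200, depth = 1e5, seed = 43)
  sim <- simulate_dataset(cfg)
  full <- run_pipeline(sim$table, sim$manifest, design, n_boot = 0)
  mix_manifest <- sim$manifest[grepl("^mix:", sim$manifest$role), ]
  mix_table <- sim$table[c("mirna", mix_manifest$sample_id)]
  attr(mix_table, "platform") <- "counts"
  res <- run_pipeline(mix_table, mix_manifest, design, mode = "baseline",
                      baseline_profile = full$profile, n_boot = 0)
  expect_equal(nrow(res$classification), nrow(full$classification))
  expect_false(is.na(res$auc_all))
  expect_error(run_pipeline(mix_table, mix_manifest, design, mode = "full"),
               "pure")
})

test_that("single-replicate mode restricts to replicate 1 and ranks by ratio", {
  cfg <- simulation_config(n_mirna = 200, depth = 1e5, seed = 44)
  sim <- simulate_dataset(cfg)
  res <- run_pipeline(sim$table, sim$manifest, design,
                      mode = "single_replicate", n_boot = 0)
  expect_equal(res$mode, "single_replicate")
  # means over a single replicate equal that replicate's values
  m1 <- sim$manifest[sim$manifest$replicate == 1, ]
  expect_equal(nrow(m1), 5L)
  lone <- run_pipeline(sim$table[c("mirna", m1$sample_id)] |>
                         (\(x) {attr(x, "platform") <- "counts"; x})(),
                       m1, design, n_boot = 0)
  expect_equal(lone$auc_all, res$auc_all)
})

test_that("replication improves discrimination on average", {
  aucs <- vapply(1:10, function(s) {
    cfg <- simulation_config(n_mirna = 250, depth = 3e4, seed = 900 + s)
    sim <- simulate_dataset(cfg)
    full <- run_pipeline(sim$table, sim$manifest, design, n_boot = 0)
    single <- run_pipeline(sim$table, sim$manifest, design,
                           mode = "single_replicate", n_boot = 0)
    c(full$auc_all, single$auc_all)
  }, numeric(2))
  expect_gt(mean(aucs[1, ]), mean(aucs[2, ]))
})

test_that("PCR tables flow through with range and deconvolution marked ND", {
  cfg <- simulation_config(n_mirna = 32, platform = "pcr", seed = 45)
  sim <- simulate_dataset(cfg)
  res <- run_pipeline(sim$table, sim$manifest, design, n_boot = 0)
  expect_true(is.na(res$lower_limit))
  expect_true(is.na(res$proportion_sum))
  expect_match(res$nd_reasons$range, "PCR")
  expect_false(is.na(res$deviation_median))
})

test_that("metrics table renders ND literally and round-trips", {
  cfg <- simulation_config(n_mirna = 120, depth = 5e4, seed = 46)
  sim <- simulate_dataset(cfg)
  res <- run_pipeline(sim$table, sim$manifest, design, n_boot = 0)
  cfgp <- simulation_config(n_mirna = 32, platform = "pcr", seed = 47)
  simp <- simulate_dataset(cfgp)
  resp <- run_pipeline(simp$table, simp$manifest, design, n_boot = 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- metrics_to_table(list(ngs_round3 = res, pcr_round3 = resp),
                          path = path)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$lower_limit[2], "ND")
  back <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  empty <- metrics_to_table(list())
  expect_equal(nrow(empty), 0L)
  expect_true("auc_all" %in% names(empty))
})

test_that("dashboard panels build and render to files", {
  cfg <- simulation_config(n_mirna = 150, depth = 5e4, seed = 48)
  sim <- simulate_dataset(cfg)
  res <- run_pipeline(sim$table, sim$manifest, design, n_boot = 20)
  for (p in list(plot_ma(res, "pred"), plot_ma(res, "obs"),
                 plot_deviation(res), plot_class_boxes(res),
                 plot_roc(res), plot_target(res))) {
    expect_s3_class(p, "ggplot")
  }
  dir <- withr::local_tempdir()
  files <- render_dashboard(res, dir, name = "round3")
  expect_true(all(file.exists(files)))
  metrics <- jsonlite::read_json(file.path(dir, "round3_metrics.json"))
  expect_equal(metrics$detected, res$n_detected)
})

test_that("tidy and glance expose the dashboard metrics", {
  cfg <- simulation_config(n_mirna = 120, depth = 5e4, seed = 49)
  sim <- simulate_dataset(cfg)
  res <- run_pipeline(sim$table, sim$manifest, design, n_boot = 0)
  g <- glance(res)
  expect_equal(nrow(g), 1L)
  td <- tidy(res)
  expect_true(all(c("auc_all", "deviation_iqr", "proportion_sum")
                  %in% td$metric))
  expect_s3_class(tidy(res$roc_all), "tbl_df")
  expect_s3_class(tidy(res$estimate), "tbl_df")
})
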