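test_that("deviations are observed minus predicted with averaged signal", {
  pred <- tibble::tibble(mirna = c("a", "b"), M = c(1.0, 0.0), A = c(5, 8),
                         source = "predicted")
  obs <- tibble::tibble(mirna = c("a", "b"), M = c(0.8, 0.1), A = c(5.2, 7.8),
                        source = "observed")
  cls <- tibble::tibble(mirna = c("a", "b"),
                        class = c("placenta_selective", "one_to_one"),
                        subtype = "none")
  dt <- deviation_table(pred, obs, cls)
  expect_equal(dt$D, c(-0.2, 0.1))
  expect_equal(dt$A_avg, c(5.1, 7.9))
  expect_equal(dt$class, cls$class)
  # identical records give zero deviation
  same <- deviation_table(pred, dplyr::mutate(pred, source = "observed"), cls)
  expect_equal(same$D, c(0, 0))
  # disjoint sets warn and return nothing
  obs2 <- dplyr::mutate(obs, mirna = c("x", "y"))
  expect_warning(empty <- deviation_table(pred, obs2, cls), "no miRNA")
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "provenance")$excluded, 4L)
})

test_that("bias/precision are the median and IQR of the deviations", {
  dt <- tibble::tibble(mirna = c("a", "b", "c"), D = c(-1, 0, 1),
                       A_avg = 1:3, class = "non_selective")
  bp <- bias_precision(dt)
  expect_equal(bp$median, 0)
  expect_equal(bp$iqr, 1)
  # agree with a direct quantile computation under the same rule
  expect_equal(bp$iqr, diff(quantile(dt$D, c(0.25, 0.75), type = 7,
                                     names = FALSE)))
  const <- dplyr::mutate(dt, D = 0.37)
  bpc <- bias_precision(const)
  expect_equal(bpc$median, 0.37)
  expect_equal(bpc$iqr, 0)
  expect_error(bias_precision(dt[0, ]), "no deviation")
})

test_that("median bias vanishes for symmetric deviation noise", {
  meds <- vapply(1:10, function(s) {
    withr::with_seed(100 + s, {
      dt <- tibble::tibble(mirna = sprintf("m%04d", 1:2000),
                           D = rnorm(2000, 0, 0.4), A_avg = stats::runif(2000, 2, 14),
                           class = "non_selective")
      bias_precision(dt)$median
    })
  }, numeric(1))
  expect_true(all(abs(meds) < 3 * 0.4 * sqrt(pi / 2) / sqrt(2000)))
})

test_that("per-class summaries cover every class plus the overall row", {
  withr::with_seed(3, {
    dt <- tibble::tibble(mirna = sprintf("m%03d", 1:90),
                         D = rnorm(90), A_avg = stats::runif(90, 0, 10),
                         class = rep(c("one_to_one", "brain_selective",
                                       "non_selective"), each = 30))
    bp <- bias_precision(dt, by_class = TRUE)
    expect_setequal(bp$class, c("all", "one_to_one", "brain_selective",
                                "non_selective"))
    expect_equal(bp$n[bp$class == "all"], 90L)
  })
})

test_that("noise-free deviations make the whole range reliable", {
  dt <- tibble::tibble(mirna = sprintf("m%04d", 1:500), D = 0,
                       A_avg = seq(2, 16, length.out = 500),
                       class = "non_selective")
  rng <- reliable_range(dt, window_size = 50)
  expect_false(rng$nd)
  expect_equal(rng$lower_limit, rng$windows$center[1])
  expect_equal(rng$upper_limit, max(dt$A_avg))
  expect_equal(rng$range_span, rng$upper_limit - rng$lower_limit,
               tolerance = 1e-9)
})

test_that("a noise step in A localizes the lower limit near the step", {
  withr::with_seed(17, {
    n <- 2000
    A <- stats::runif(n, 2, 16)
    D <- rnorm(n, 0, ifelse(A < 8, 1.0, 0.05))
    dt <- tibble::tibble(mirna = sprintf("m%04d", 1:n), D = D, A_avg = A,
                         class = "non_selective")
    rng <- reliable_range(dt, window_size = 100)
    expect_false(rng$nd)
    window_width <- diff(range(A)) * 100 / n * 2  # generous window span
    expect_lt(abs(rng$lower_limit - 8), 1 + window_width)
    # brute-force rescan oracle agrees exactly
    expect_equal(rng$lower_limit,
                 oracle_reliable_lower(A, D, 100, log2(1.5), 0.95))
  })
})

test_that("window scan matches the rescan oracle on random data", {
  for (s in 1:5) {
    withr::with_seed(200 + s, {
      n <- 400
      A <- stats::runif(n, 0, 12)
      D <- rnorm(n, 0, 0.2 + 1.2 * exp(-A / 2))
      dt <- tibble::tibble(mirna = sprintf("m%03d", 1:n), D = D, A_avg = A,
                           class = "non_selective")
      rng <- reliable_range(dt, window_size = 60)
      lower <- oracle_reliable_lower(A, D, 60, log2(1.5), 0.95)
      if (is.na(lower)) {
        expect_true(rng$nd)
      } else {
        expect_equal(rng$lower_limit, lower)
      }
    })
  }
})

test_that("hopeless noise yields an undefined (ND) range", {
  withr::with_seed(4, {
    dt <- tibble::tibble(mirna = sprintf("m%03d", 1:300),
                         D = rnorm(300, 0, 5),
                         A_avg = stats::runif(300, 0, 10), class = "non_selective")
    rng <- reliable_range(dt, window_size = 50)
    expect_true(rng$nd)
    expect_true(is.na(rng$lower_limit))
    few <- reliable_range(dt[1:20, ], window_size = 50)
    expect_true(few$nd)
    expect_match(few$nd_reason, "insufficient")
  })
})

test_that("lower limit is monotone non-increasing in tolerance", {
  withr::with_seed(9, {
    n <- 1500
    A <- stats::runif(n, 0, 14)
    D <- rnorm(n, 0, 0.15 + exp(-A / 3))
    dt <- tibble::tibble(mirna = sprintf("m%04d", 1:n), D = D, A_avg = A,
                         class = "non_selective")
    tols <- c(0.4, 0.585, 0.8, 1.2)
    lowers <- vapply(tols, function(tol) {
      r <- reliable_range(dt, tolerance = tol, window_size = 100)
      if (r$nd) Inf else r$lower_limit
    }, numeric(1))
    expect_true(all(diff(lowers) <= 1e-12))
  })
})

test_that("window coverage half-width approaches 1.96 sd for Gaussian noise", {
  half_widths <- vapply(1:10, function(s) {
    withr::with_seed(300 + s, {
      n <- 800
      dt <- tibble::tibble(mirna = sprintf("m%04d", 1:n),
                           D = rnorm(n, 0, 0.3),
                           A_avg = stats::runif(n, 0, 10), class = "non_selective")
      rng <- reliable_range(dt, tolerance = 10, window_size = 200)
      mean((rng$windows$hi - rng$windows$lo) / 2)
    })
  }, numeric(1))
  expect_equal(mean(half_widths), 1.96 * 0.3, tolerance = 0.1)
})

test_that("assess_upper bounds the range by the last compliant window", {
  n <- 1000
  A <- seq(1, 15, length.out = n)
  D <- numeric(n)
  D[A > 13] <- rep(c(-2, 2), length.out = sum(A > 13))  # saturation zone
  dt <- tibble::tibble(mirna = sprintf("m%04d", 1:n), D = D, A_avg = A,
                       class = "non_selective")
  with_upper <- reliable_range(dt, window_size = 50, assess_upper = TRUE)
  without <- reliable_range(dt, window_size = 50, assess_upper = FALSE)
  expect_true(without$nd)  # non-compliant top windows leave no compliant tail
  expect_false(with_upper$nd)
  expect_lt(with_upper$upper_limit, 13.5)
})
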