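make_betas <- function(values, samples, markers) {
  tidyr::expand_grid(sample_id = samples, marker_id = markers) |>
    dplyr::mutate(beta = values)
}

test_that("replicate MAD pools absolute differences over pairs and markers", {
  markers <- c("m1", "m2")
  betas <- tibble::tibble(
    sample_id = rep(c("a1", "a2", "b1", "b2"), each = 2),
    marker_id = rep(markers, 4),
    beta = c(0.2, 0.5, 0.3, 0.5, 0.1, 0.9, 0.1, 0.9))
  pairing <- tibble::tibble(rep1 = c("a1", "b1"), rep2 = c("a2", "b2"))
  res <- replicate_mad(betas, pairing)
  expect_equal(res$mean_abs_diff, mean(c(0.1, 0, 0, 0)))
  expect_equal(res$n_cells, 4)

  ident <- replicate_mad(dplyr::mutate(betas, beta = 0.4), pairing)
  expect_equal(c(ident$mean_abs_diff, ident$sd_abs_diff), c(0, 0))

  # pairwise-complete: a missing cell drops only that (pair, marker)
  betas$beta[1] <- NA
  expect_equal(replicate_mad(betas, pairing)$n_cells, 3)
  expect_error(replicate_mad(dplyr::mutate(betas, beta = NA_real_), pairing),
               "no overlapping")
  expect_error(replicate_mad(betas, tibble::tibble(rep1 = c("a1", "a1"),
                                                   rep2 = c("a2", "b2"))),
               "more than one")
})

test_that("replicate MAD matches a double-loop oracle and is order-invariant", {
  withr::with_seed(71, {
    markers <- sprintf("m%02d", 1:15)
    samples <- c("p1", "p2", "q1", "q2", "r1", "r2")
    betas <- make_betas(runif(90), samples, markers)
    pairing <- tibble::tibble(rep1 = c("p1", "q1", "r1"),
                              rep2 = c("p2", "q2", "r2"))
    res <- replicate_mad(betas, pairing)
    diffs <- c()
    for (i in seq_len(nrow(pairing))) {
      for (m in markers) {
        b1 <- betas$beta[betas$sample_id == pairing$rep1[i] &
                           betas$marker_id == m]
        b2 <- betas$beta[betas$sample_id == pairing$rep2[i] &
                           betas$marker_id == m]
        diffs <- c(diffs, abs(b1 - b2))
      }
    }
    expect_equal(res$mean_abs_diff, mean(diffs))
    expect_equal(res$sd_abs_diff, sd(diffs))
    # invariant under marker reordering and pair relabeling
    shuffled <- betas[sample(nrow(betas)), ]
    expect_equal(replicate_mad(shuffled, pairing), res)
    swapped <- tibble::tibble(rep1 = pairing$rep2, rep2 = pairing$rep1)
    expect_equal(replicate_mad(betas, swapped)$mean_abs_diff, res$mean_abs_diff)
  })
})

test_that("accuracy against expected levels is the pooled absolute deviation", {
  betas <- tibble::tibble(sample_id = "s1", marker_id = c("m1", "m2"),
                          beta = c(0.20, 0.30))
  truth <- tibble::tibble(sample_id = "s1", expected_beta = 0.25)
  res <- accuracy_vs_expected(betas, truth)
  expect_equal(res$mean_abs_diff, 0.05)
  exact <- accuracy_vs_expected(dplyr::mutate(betas, beta = 0.25), truth)
  expect_equal(exact$mean_abs_diff, 0)
  expect_error(accuracy_vs_expected(betas,
                                    tibble::tibble(sample_id = "s9",
                                                   expected_beta = 0.1)),
               "missing expected_beta")
})

test_that("simulated standards reach binomial-regime accuracy", {
  p <- small_panel()
  cfg <- sim_config(seed = 72, conversion_rate = 1, inappropriate_conversion = 0,
                    coverage_mu = log(1e4), coverage_sigma = 0)
  sim <- simulate_standard_series(p, config = cfg)
  betas <- call_betas(sim$counts, p)
  truth <- dplyr::select(sim$samples, sample_id, expected_beta)
  res <- accuracy_vs_expected(betas, truth)
  # E|betahat - beta| <= sqrt(2/pi) * sqrt(beta(1-beta)/n) <= 0.004 at n = 1e4
  expect_lt(res$mean_abs_diff, 0.02)
})

test_that("sensitivity summary groups by input and level", {
  betas <- tibble::tibble(sample_id = c("a", "a", "b", "b"),
                          marker_id = rep(c("m1", "m2"), 2),
                          beta = c(0.2, 0.3, 0.6, 0.8))
  meta <- tibble::tibble(sample_id = c("a", "b"), input_ng = c(50, 25),
                         expected_beta = c(0.25, 0.75))
  res <- sensitivity_summary(betas, meta)
  expect_equal(nrow(res), 2)
  expect_equal(res$mean_beta[res$input_ng == 50], 0.25)
  expect_equal(res$mean_beta[res$input_ng == 25], 0.7)
  one <- sensitivity_summary(betas[1:2, ], meta[1, ])
  expect_equal(nrow(one), 1)
})

test_that("measurement SD does not grow with DNA input", {
  p <- small_panel()
  sds <- sapply(1:20, function(s) {
    sim <- simulate_sensitivity_series(p, levels = 0.25, inputs = c(50, 1),
                                       config = sim_config(seed = 8000 + s))
    res <- sensitivity_summary(call_betas(sim$counts, p, min_reads = 1),
                               sim$samples)
    res$sd_beta[order(-res$input_ng)]
  })
  # averaged over seeds, the 50 ng series is no noisier than the 1 ng series
  expect_lte(mean(sds[1, ]), mean(sds[2, ]))
})

test_that("method correlation uses mid-rank Spearman and pairwise cells", {
  withr::with_seed(73, {
    markers <- sprintf("m%02d", 1:12)
    a <- make_betas(runif(36), c("s1", "s2", "s3"), markers)
    ident <- method_correlation(list(A = a, B = a))
    expect_equal(ident$spearman["A", "B"], 1)
    expect_equal(ident$mean_abs_diff["A", "B"], 0)

    mono <- dplyr::mutate(a, beta = beta^3)           # monotone transform
    expect_equal(method_correlation(list(A = a, B = mono))$spearman["A", "B"], 1)

    b <- make_betas(round(runif(36), 1), c("s1", "s2", "s3"), markers)  # ties
    r <- method_correlation(list(A = a, B = b))$spearman["A", "B"]
    oracle <- cor(rank(a$beta), rank(b$beta))          # mid-rank product-moment
    expect_equal(r, oracle, tolerance = 1e-12)

    disjoint <- dplyr::mutate(a, sample_id = paste0("x", sample_id))
    expect_error(method_correlation(list(A = a, B = disjoint)), "shared")
  })
})

test_that("age MAE matches a direct oracle", {
  expect_equal(mae_age(c(40, 50), c(44, 44))$mae, 5)
  expect_equal(mae_age(1:5, 1:5)$mae, 0)
  withr::with_seed(74, {
    pred <- rnorm(30, 50, 10); age <- rnorm(30, 50, 10)
    res <- mae_age(pred, age)
    expect_equal(res$mae, sum(abs(pred - age)) / 30)
    expect_equal(res$sd_abs_error, sd(abs(pred - age)))
  })
  expect_error(mae_age(1:3, 1:4), "length")
})

test_that("clock cross-correlation handles self, anti and noisy cases", {
  out <- tibble::tibble(sample_id = rep(sprintf("s%d", 1:10), 2),
                        clock = rep(c("A", "B"), each = 10),
                        value = c(1:10, -(1:10)))
  suppressMessages({
    m <- clock_cross_correlation(out)
  })
  expect_equal(m["A", "A"], 1)
  expect_equal(m["A", "B"], -1)

  # correlation between two clocks sharing a latent age decays with noise
  withr::with_seed(75, {
    age <- runif(40, 5, 80)
    mean_r <- function(noise) {
      mean(sapply(1:20, function(i) {
        a <- age + rnorm(40, 0, noise); b <- age + rnorm(40, 0, noise)
        out <- tibble::tibble(sample_id = rep(sprintf("s%d", 1:40), 2),
                              clock = rep(c("A", "B"), each = 40),
                              value = c(a, b))
        clock_cross_correlation(out)["A", "B"]
      }))
    }
    rs <- sapply(c(1, 10, 40), mean_r)
    expect_true(all(diff(rs) < 0))
  })
})

test_that("variance across replicates peaks at intermediate methylation", {
  p <- small_panel()
  for (s in 1:3) {
    cfg <- sim_config(seed = 9000 + s)  # defaults: c = 0.998, f = 0.005
    sim <- simulate_standard_series(p, config = cfg)
    lv <- level_variability(call_betas(sim$counts, p), sim$samples)
    mid <- lv$sd_beta[lv$expected_beta %in% c(0.25, 0.5, 0.75)]
    ext <- lv$sd_beta[lv$expected_beta %in% c(0, 1)]
    expect_gt(max(mid), max(ext))
    expect_equal(which.min(lv$sd_beta[order(lv$expected_beta)]) %in% c(1, 7),
                 TRUE)
  }
})

test_that("end-to-end calibration improves test-split age MAE", {
  p <- small_panel()
  clk <- small_clock()
  bias <- meth_transform(c(0.1, 0.8), "array_bias")
  ages <- seq(8, 78, length.out = 24)
  improved <- 0
  for (s in 1:20) {
    cfg <- sim_config(seed = 500 + s, platform_bias = bias, n_replicates = 1,
                      coverage_mu = log(2000), coverage_sigma = 0.3)
    sim <- simulate_blood_cohort(p, ages = ages, clock = clk, noise_sd = 0.01,
                                 config = cfg)
    betas <- call_betas(sim$counts, p)
    out <- run_all_clocks(betas, list(AGE6 = clk)) |>
      dplyr::left_join(sim$samples[c("sample_id", "age")], by = "sample_id")
    train <- seq(1, 24, by = 2); test <- seq(2, 24, by = 2)
    fit <- fit_linear_transform(out$value[train], out$age[train])
    mae_raw <- mae_age(out$value[test], out$age[test])$mae
    mae_cal <- mae_age(apply_transform(out$value[test], fit), out$age[test])$mae
    if (mae_cal < mae_raw) improved <- improved + 1
  }
  expect_gte(improved, 18)
})
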