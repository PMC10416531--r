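test_that("strand merging sums counts and passes single strands through", {
  counts <- tibble::tibble(
    sample_id = "s1", marker_id = c("m1", "m1", "m2", "m3", "m3"),
    strand = c("W", "C", "W", "W", "C"),
    n_meth = c(10L, 15L, 12L, 0L, 0L), n_unmeth = c(40L, 35L, 8L, 0L, 0L))
  m <- merge_strands(counts)
  expect_equal(m$n_meth[m$marker_id == "m1"], 25)
  expect_equal(m$n_unmeth[m$marker_id == "m1"], 75)
  expect_equal(unlist(m[m$marker_id == "m2", c("n_meth", "n_unmeth")],
                      use.names = FALSE), c(12, 8))
  expect_equal(unlist(m[m$marker_id == "m3", c("n_meth", "n_unmeth")],
                      use.names = FALSE), c(0, 0))
  expect_error(merge_strands(dplyr::bind_rows(counts, counts[1, ])),
               "duplicated")
})

test_that("beta calling applies the at-least-min-reads rule", {
  x <- call_beta(c(25, 30, 50, 0), c(75, 19, 0, 0), min_reads = 50)
  expect_equal(x$beta, c(0.25, NA, 1, NA))
  expect_equal(x$passed_threshold, c(TRUE, FALSE, TRUE, FALSE))
  expect_true(all(is.na(x$beta) != x$passed_threshold))  # missing iff failed
  expect_error(call_beta(-1, 10), "negative")
})

test_that("thresholding is monotone in min_reads", {
  withr::with_seed(21, {
    n_meth <- rbinom(200, 100, 0.3)
    n_unmeth <- rbinom(200, 100, 0.6)
    passed <- vapply(c(1, 20, 50, 100, 150, 200),
                     function(t) sum(call_beta(n_meth, n_unmeth, t)$passed_threshold),
                     numeric(1))
    expect_true(all(diff(passed) <= 0))
  })
})

test_that("merge-then-call equals calling on pre-summed counts", {
  withr::with_seed(22, {
    for (i in 1:10) {
      w <- c(rbinom(1, 200, 0.4), rbinom(1, 200, 0.5))
      c_ <- c(rbinom(1, 200, 0.4), rbinom(1, 200, 0.5))
      counts <- tibble::tibble(sample_id = "s", marker_id = "m",
                               strand = c("W", "C"),
                               n_meth = c(w[1], c_[1]),
                               n_unmeth = c(w[2], c_[2]))
      merged <- merge_strands(counts)
      a <- call_beta(merged$n_meth, merged$n_unmeth)
      b <- call_beta(w[1] + c_[1], w[2] + c_[2])
      expect_equal(a$beta, b$beta)
    }
  })
})

test_that("beta is symmetric: beta(a, b) + beta(b, a) = 1 when defined", {
  withr::with_seed(23, {
    a <- rbinom(50, 500, 0.5); b <- rbinom(50, 500, 0.5)
    x <- call_beta(a, b)$beta
    y <- call_beta(b, a)$beta
    ok <- !is.na(x) & !is.na(y)
    expect_equal(x[ok] + y[ok], rep(1, sum(ok)))
  })
})

test_that("call_betas yields one call per panel marker and routes QC", {
  p <- small_panel()
  counts <- exact_counts(p, 0.25, 100)
  betas <- call_betas(counts, p)
  expect_equal(nrow(betas), 12)                 # lambda excluded
  expect_false("lambda_amp1" %in% betas$marker_id)
  expect_true(all(betas$beta == 0.25))
  # marker with no counts comes back missing, not absent
  betas2 <- call_betas(counts[-3, ], p)
  expect_equal(nrow(betas2), 12)
  expect_true(is.na(betas2$beta[betas2$marker_id == counts$marker_id[3]]))
  # off-panel rows are warned about and skipped
  expect_warning(call_betas(dplyr::mutate(counts[1, ], marker_id = "offtarget"),
                            p), "offtarget")
})

test_that("zero-read marker fraction matches the failed-probe arithmetic", {
  p <- example_panel()
  body <- panel_markers(p)
  # 43 of 161 markers with zero reads, as for a failed-probe protocol
  covered <- exact_counts(p, 0.5, 100)
  covered <- covered[!covered$marker_id %in% body$marker_id[1:43], ]
  betas <- call_betas(covered, p)
  frac <- 100 * sum(!betas$passed_threshold) / nrow(betas)
  expect_equal(round(frac, 1), 26.7)
})

test_that("lambda conversion rate pools counts across amplicons", {
  p <- example_panel()
  lam <- tibble::tibble(
    sample_id = "s1", marker_id = c("lambda_amp1", "lambda_amp2"),
    strand = "W", n_meth = c(1L, 1L), n_unmeth = c(499L, 499L))
  expect_equal(conversion_rate_lambda(lam, p)$conversion_rate_lambda, 99.8)
  # count-summing equals the per-amplicon average at equal depths
  per_amp <- 100 * lam$n_unmeth / (lam$n_meth + lam$n_unmeth)
  expect_equal(conversion_rate_lambda(lam, p)$conversion_rate_lambda,
               mean(per_amp))
  clean <- dplyr::mutate(lam, n_meth = 0L, n_unmeth = 1000L)
  expect_equal(conversion_rate_lambda(clean, p)$conversion_rate_lambda, 100)
})

test_that("non-CpG conversion rate is the pooled converted fraction", {
  expect_equal(conversion_rate_noncpg(983, 17), 98.3)
  expect_equal(conversion_rate_noncpg(rep(100, 5), rep(0, 5)), 100)
  expect_true(is.na(conversion_rate_noncpg(0, 0)))
  withr::with_seed(31, {
    for (i in 1:10) {
      conv <- rbinom(4, 1000, 0.98); unconv <- rbinom(4, 1000, 0.02)
      expect_equal(conversion_rate_noncpg(conv, unconv),
                   100 * sum(conv) / (sum(conv) + sum(unconv)))
    }
  })
})

test_that("coverage summary uses strict > and is non-increasing", {
  cs <- coverage_summary(c(0, 60, 250, 1500), c(50, 200, 1000))
  expect_equal(cs$fraction, c(0.75, 0.5, 0.25))
  expect_equal(attr(cs, "n_below_20"), 1)
  expect_equal(coverage_summary(rep(0, 5))$fraction, rep(0, 3))
  expect_error(coverage_summary(numeric(0)), "empty")
  withr::with_seed(32, {
    depths <- rpois(1e4, 300)
    th <- sort(sample(1:1000, 6))
    cs <- coverage_summary(depths, th)
    oracle <- vapply(th, function(t) sum(sort(depths) > t) / length(depths),
                     numeric(1))
    expect_equal(cs$fraction, oracle)
    expect_true(all(diff(cs$fraction) <= 0))
  })
})

test_that("normalized depth divides by total mapped reads", {
  expect_equal(normalized_depth(c(10, 10), 100), c(0.1, 0.1))
  m <- 20; d <- 500
  expect_equal(normalized_depth(rep(d, m), m * d), rep(1 / m, m))
  expect_error(normalized_depth(c(1, 2), 0), "positive")
  withr::with_seed(33, {
    v <- runif(50, 0, 1e4)
    expect_equal(normalized_depth(v, 1e6), v / 1e6)
  })
})

test_that("count TSV and Bismark coverage files round-trip", {
  p <- small_panel()
  sim <- simulate_standard_series(p, levels = 0.5,
                                  config = sim_config(seed = 41, n_replicates = 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(sim$counts, path)
  expect_equal(as.data.frame(read_counts_tsv(path)),
               as.data.frame(sim$counts))

  dir <- withr::local_tempdir()
  write_bismark_cov(sim$counts, p, dir)
  s <- unique(sim$counts$sample_id)[1]
  back <- read_bismark_cov(file.path(dir, paste0(s, ".cov")), p)
  merged <- merge_strands(sim$counts) |> dplyr::filter(sample_id == s)
  joined <- dplyr::inner_join(back, merged, by = "marker_id",
                              suffix = c("_cov", "_orig"))
  expect_equal(nrow(joined), nrow(merged))
  expect_equal(joined$n_meth_cov, joined$n_meth_orig)
  expect_equal(joined$n_unmeth_cov, joined$n_unmeth_orig)
})

test_that("beta matrix TSV round-trips with explicit missingness", {
  p <- small_panel()
  counts <- exact_counts(p, 0.3, 100)[-c(2, 5), ]
  betas <- call_betas(counts, p)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(betas, path)
  back <- read_beta_matrix(path)
  joined <- dplyr::left_join(betas, back, by = c("sample_id", "marker_id"),
                             suffix = c("", "_rt"))
  expect_equal(joined$beta_rt, joined$beta)
})

test_that("QC coverage fractions are non-increasing in the threshold", {
  p <- small_panel()
  sim <- simulate_standard_series(p, levels = 0.5,
                                  config = sim_config(seed = 42))
  qc <- qc_report(sim$counts, p)
  fr <- as.matrix(qc[, c("frac_gt_50", "frac_gt_200", "frac_gt_1000")])
  expect_true(all(fr[, 1] >= fr[, 2] & fr[, 2] >= fr[, 3]))
  expect_true(all(qc$conversion_rate_lambda > 99))
})
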