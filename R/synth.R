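#' Simulation configuration
#'
#' Bundles the parameters of the synthetic read-count generator. The error
#' model has two channels: `conversion_rate` (`c`) is the probability that
#' an unmethylated cytosine is successfully converted and read as T/A, so
#' `1 - c` is the conversion-failure rate measured on unmethylated lambda
#' DNA; `inappropriate_conversion` (`f`) is the probability that a
#' methylated cytosine is nevertheless converted and read as T/A. A read at
#' a site with true methylation `beta` is called methylated with probability
#' `p = beta * (1 - f) + (1 - beta) * (1 - c)`.
#'
#' Per-target depth is drawn log-normally (`coverage_mu`, `coverage_sigma`,
#' log scale); defaults give a heavy-tailed distribution with median ~3000
#' reads, the order of magnitude of a well-performing amplicon run. All
#' randomness uses R's default Mersenne-Twister stream seeded from `seed`,
#' so a fixed seed yields bit-identical outputs.
#'
#' @param seed Integer RNG seed.
#' @param coverage_mu,coverage_sigma Log-scale mean and SD of per-target depth.
#' @param conversion_rate Probability `c` in `[0, 1]`; default 0.998.
#' @param inappropriate_conversion Probability `f` in `[0, 1]`; default 0.005.
#' @param strand_split Fraction of reads assigned to the Watson strand for
#'   both-strand markers; strictly inside (0, 1).
#' @param platform_bias Optional [meth_transform()] applied (with clamping)
#'   to true betas before read sampling; `NULL` means unbiased.
#' @param n_replicates Technical replicates per biological sample.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       coverage_mu = log(3000),
                       coverage_sigma = 1,
                       conversion_rate = 0.998,
                       inappropriate_conversion = 0.005,
                       strand_split = 0.5,
                       platform_bias = NULL,
                       n_replicates = 2L) {
  stopifnot(conversion_rate >= 0, conversion_rate <= 1,
            inappropriate_conversion >= 0, inappropriate_conversion <= 1,
            strand_split > 0, strand_split < 1,
            coverage_sigma >= 0, n_replicates >= 1)
  if (!is.null(platform_bias) && !inherits(platform_bias, "meth_transform")) {
    stop_data("platform_bias must be NULL or a meth_transform")
  }
  structure(
    list(seed = as.integer(seed), coverage_mu = coverage_mu,
         coverage_sigma = coverage_sigma, conversion_rate = conversion_rate,
         inappropriate_conversion = inappropriate_conversion,
         strand_split = strand_split, platform_bias = platform_bias,
         n_replicates = as.integer(n_replicates)),
    class = "sim_config"
  )
}

#' Probability of a methylated call given true beta and the error channels
#' @noRd
meth_call_prob <- function(beta, config) {
  beta * (1 - config$inappropriate_conversion) +
    (1 - beta) * (1 - config$conversion_rate)
}

draw_depths <- function(n, config, scale = 1) {
  round(scale * rlnorm(n, config$coverage_mu, config$coverage_sigma))
}

#' Sample per-strand read counts for one site
#'
#' Reads are split binomially between Watson and Crick for both-strand
#' markers (single-strand markers put all reads on their strand), then each
#' strand's methylated count is drawn `Binomial(n_strand, p)` with
#' `p = beta*(1-f) + (1-beta)*(1-c)`. Uses the current RNG state; seed at a
#' higher level for reproducibility.
#'
#' @param true_beta True methylation level in `[0, 1]`.
#' @param depth Total read depth (>= 0; 0 yields zero counts).
#' @param config A [sim_config()].
#' @param strands `"both"`, `"W"` or `"C"`.
#' @return Tibble with columns `strand`, `n_meth`, `n_unmeth` (one row per
#'   available strand).
#' @export
simulate_site_counts <- function(true_beta, depth, config = sim_config(),
                                 strands = "both") {
  stopifnot(true_beta >= 0, true_beta <= 1, depth >= 0)
  p <- meth_call_prob(true_beta, config)
  if (strands == "both") {
    n_w <- rbinom(1, depth, config$strand_split)
    n_c <- depth - n_w
    m_w <- rbinom(1, n_w, p)
    m_c <- rbinom(1, n_c, p)
    tibble(strand = c("W", "C"),
           n_meth = c(m_w, m_c),
           n_unmeth = c(n_w - m_w, n_c - m_c))
  } else {
    m <- rbinom(1, depth, p)
    tibble(strand = strands, n_meth = m, n_unmeth = depth - m)
  }
}

# Vectorised count sampling over a (sample, marker) grid.
# grid: sample_id, marker_id, strands, sampling_beta; depth_scale optional.
sample_counts_grid <- function(grid, config) {
  n <- nrow(grid)
  scale <- grid$depth_scale %||% rep(1, n)
  depth <- draw_depths(n, config, scale)
  p <- meth_call_prob(grid$sampling_beta, config)
  both <- grid$strands == "both"
  n_w <- integer(n)
  n_w[both] <- rbinom(sum(both), depth[both], config$strand_split)
  n_w[grid$strands == "W"] <- depth[grid$strands == "W"]
  n_c <- depth - n_w
  m_w <- rbinom(n, n_w, p)
  m_c <- rbinom(n, n_c, p)
  w_rows <- tibble(sample_id = grid$sample_id, marker_id = grid$marker_id,
                   strand = "W", n_meth = m_w, n_unmeth = n_w - m_w,
                   present = grid$strands %in% c("both", "W"))
  c_rows <- tibble(sample_id = grid$sample_id, marker_id = grid$marker_id,
                   strand = "C", n_meth = m_c, n_unmeth = n_c - m_c,
                   present = grid$strands %in% c("both", "C"))
  bind_rows(w_rows, c_rows) |>
    filter(.data$present) |>
    select(-"present") |>
    arrange(.data$sample_id, .data$marker_id, .data$strand)
}

apply_bias_vec <- function(beta, bias) {
  if (is.null(bias)) beta else clamp(apply_transform(beta, bias))
}

#' Apply a platform-bias transform to a truth table
#'
#' Replaces each true beta by `clamp(bias(beta), 0, 1)`, keeping the
#' original value in `true_beta` and the biased value in `sampling_beta`.
#'
#' @param truth Tibble with a `true_beta` column.
#' @param bias A [meth_transform()] (identity leaves values unchanged).
#' @return `truth` with a `sampling_beta` column added/replaced.
#' @export
apply_platform_bias <- function(truth, bias) {
  stopifnot(inherits(bias, "meth_transform"), "true_beta" %in% names(truth))
  mutate(truth, sampling_beta = apply_bias_vec(.data$true_beta, bias))
}

#' Simulate a methylation-standard dilution series
#'
#' Emulates artificially methylated standards: for each beta level and
#' technical replicate, read counts are sampled at every panel marker with
#' true beta equal to the level, plus lambda spike-in counts at true beta 0.
#' The default seven levels in duplicate reproduce a 14-library
#' repeatability design.
#'
#' @param panel A panel tibble (lambda rows included for conversion QC).
#' @param levels Standard beta levels, each in `[0, 1]`.
#' @param config A [sim_config()]; `platform_bias`, if set, distorts the
#'   sampling betas (truth retains both).
#' @param input_ng Optional vector of DNA inputs (ng), one series per input,
#'   with per-target depth scaled proportionally to input mass; default a
#'   single input of 25 ng at full depth.
#' @return List with `counts` (sample_id, marker_id, strand, n_meth,
#'   n_unmeth), `truth` (per sample x marker true and sampling betas) and
#'   `samples` (metadata: sample_id, source_id, replicate, sample_type,
#'   expected_beta, input_ng, technology).
#' @export
simulate_standard_series <- function(panel,
                                     levels = c(0, 0.10, 0.25, 0.50, 0.75, 0.90, 1),
                                     config = sim_config(),
                                     input_ng = 25) {
  validate_panel(panel)
  if (any(levels < 0 | levels > 1)) {
    stop_data("standard level outside [0, 1]: %s",
              paste(levels[levels < 0 | levels > 1], collapse = ", "))
  }
  technology <- if (is.null(config$platform_bias)) "HTS" else "array"
  samples <- tidyr::expand_grid(
    input_ng = input_ng,
    expected_beta = levels,
    replicate = seq_len(config$n_replicates)
  ) |>
    mutate(
      source_id = sprintf("std_b%03d_in%g", round(100 * .data$expected_beta),
                          .data$input_ng),
      sample_id = sprintf("%s_r%d", .data$source_id, .data$replicate),
      sample_type = "standard",
      age = NA_real_,
      technology = technology
    )
  truth <- tidyr::expand_grid(sample_id = samples$sample_id,
                              marker_id = panel$marker_id) |>
    left_join(select(samples, "sample_id", "expected_beta", "input_ng"),
              by = "sample_id") |>
    left_join(select(panel, "marker_id", "chrom", "strands"), by = "marker_id") |>
    mutate(
      true_beta = ifelse(.data$chrom == "lambda", 0, .data$expected_beta),
      sampling_beta = ifelse(.data$chrom == "lambda", 0,
                             apply_bias_vec(.data$true_beta, config$platform_bias)),
      depth_scale = .data$input_ng / max(.data$input_ng)
    )
  counts <- withr::with_seed(config$seed, sample_counts_grid(truth, config))
  list(
    counts = counts,
    truth = select(truth, "sample_id", "marker_id", "true_beta", "sampling_beta"),
    samples = select(samples, "sample_id", "source_id", "replicate",
                     "sample_type", "expected_beta", "input_ng", "age",
                     "technology")
  )
}

#' Simulate a sensitivity dilution series
#'
#' Convenience preset: two methylation levels across a ladder of DNA inputs
#' in duplicate (default 4 inputs x 2 levels x 2 replicates = 16 libraries),
#' with read depth scaled proportionally to input mass so that lower inputs
#' show the higher measurement variability expected when template molecules
#' are limiting.
#'
#' @inheritParams simulate_standard_series
#' @param inputs DNA inputs in ng.
#' @export
simulate_sensitivity_series <- function(panel,
                                        levels = c(0.25, 0.75),
                                        inputs = c(50, 25, 10, 1),
                                        config = sim_config()) {
  simulate_standard_series(panel, levels = levels, config = config,
                           input_ng = inputs)
}

# Invert a linear clock: construct per-marker true betas so the clock
# evaluates exactly to each requested age.
invert_clock_betas <- function(clock, ages, reference_age) {
  w <- clock$weights
  mu <- clock$imputation_means[names(w)]
  ssq <- sum(w^2)
  if (ssq == 0) stop_data("generating clock has all-zero weights")
  v <- clock$intercept + sum(w * mu)
  m <- mu + w * (reference_age - v) / ssq   # clock(m) == reference_age
  k <- 1 / ssq
  betas <- outer(w * k, ages - reference_age) + m   # markers x ages
  dimnames(betas) <- list(names(w), as.character(seq_along(ages)))
  clamped <- clamp(betas, 0.01, 0.99)
  pred <- clock$intercept + colSums(clamped * w)
  off <- abs(pred - ages)
  if (any(off > 0.1)) {
    stop_data(paste0(
      "clock inversion infeasible: age %g requires betas outside [0.01, 0.99] ",
      "(round-trip error %.2f years); rescale the generating clock ",
      "(larger weights) or narrow the age range"),
      ages[which.max(off)], max(off))
  }
  clamped
}

#' Simulate an age-structured blood cohort
#'
#' True betas at the generating clock's markers are constructed by inverting
#' the clock (`beta_i = m_i + w_i * k * (age - a0)` with baselines `m_i`
#' chosen so the clock evaluates to the reference age at baseline and
#' `k = 1 / sum(w_i^2)`), so that applying the clock to noise-free betas
#' returns each donor's age exactly. Betas are clamped to `[0.01, 0.99]`;
#' construction fails if clamping breaks the round-trip by more than 0.1
#' years. Markers outside the generating clock get fixed per-marker baseline
#' betas. Gaussian noise (`noise_sd`, beta scale) is added per sample and
#' marker before binomial read sampling.
#'
#' @param panel A panel tibble.
#' @param ages Donor ages in years (default the five-donor design 7, 28, 46,
#'   61, 78; duplicated by `config$n_replicates`).
#' @param clock Generating [clock_model()] (at least one nonzero weight).
#' @param noise_sd Beta-scale SD of biological/technical noise; default 0.
#' @param config A [sim_config()].
#' @return List with `counts`, `truth` (incl. `true_beta`, `sampling_beta`)
#'   and `samples` (incl. `age`).
#' @export
simulate_blood_cohort <- function(panel, ages = c(7, 28, 46, 61, 78),
                                  clock, noise_sd = 0,
                                  config = sim_config()) {
  validate_panel(panel)
  stopifnot(inherits(clock, "clock_model"), noise_sd >= 0)
  reference_age <- mean(ages)
  clock_betas <- invert_clock_betas(clock, ages, reference_age)

  technology <- if (is.null(config$platform_bias)) "HTS" else "array"
  samples <- tidyr::expand_grid(
    donor = seq_along(ages),
    replicate = seq_len(config$n_replicates)
  ) |>
    mutate(
      age = ages[.data$donor],
      source_id = sprintf("blood_d%02d_a%g", .data$donor, .data$age),
      sample_id = sprintf("%s_r%d", .data$source_id, .data$replicate),
      sample_type = "blood",
      expected_beta = NA_real_,
      input_ng = 25,
      technology = technology
    )

  withr::with_seed(config$seed, {
    body <- panel_markers(panel)
    baseline <- setNames(runif(nrow(body), 0.2, 0.8), body$marker_id)
    clock_truth <- as_tibble(clock_betas, rownames = "marker_id") |>
      pivot_longer(-"marker_id", names_to = "donor", values_to = "clock_beta") |>
      mutate(donor = as.integer(.data$donor))
    truth <- tidyr::expand_grid(sample_id = samples$sample_id,
                                marker_id = panel$marker_id) |>
      left_join(select(samples, "sample_id", "donor", "age"), by = "sample_id") |>
      left_join(select(panel, "marker_id", "chrom", "strands"), by = "marker_id") |>
      left_join(clock_truth, by = c("marker_id", "donor")) |>
      mutate(
        true_beta = dplyr::case_when(
          .data$chrom == "lambda" ~ 0,
          !is.na(.data$clock_beta) ~ .data$clock_beta,
          TRUE ~ unname(baseline[.data$marker_id])
        )
      )
    if (noise_sd > 0) {
      noisy <- clamp(truth$true_beta + rnorm(nrow(truth), 0, noise_sd))
      truth$sampling_beta <- ifelse(truth$chrom == "lambda", 0, noisy)
    } else {
      truth$sampling_beta <- truth$true_beta
    }
    truth$sampling_beta <- ifelse(
      truth$chrom == "lambda", 0,
      apply_bias_vec(truth$sampling_beta, config$platform_bias))
    truth$depth_scale <- 1
    counts <- sample_counts_grid(truth, config)
    list(
      counts = counts,
      truth = select(truth, "sample_id", "marker_id", "true_beta",
                     "sampling_beta"),
      samples = select(samples, "sample_id", "source_id", "replicate",
                       "sample_type", "expected_beta", "input_ng", "age",
                       "technology")
    )
  })
}

#' Simulate lambda spike-in counts
#'
#' Unmethylated lambda DNA has true beta 0 at every lambda amplicon, so any
#' methylated call arises only from conversion failure (rate `1 - c`).
#'
#' @param depth Read depth per lambda amplicon (>= 0).
#' @param config A [sim_config()].
#' @param panel Panel whose lambda rows to use; default [example_panel()].
#' @param sample_id Sample label for the returned rows.
#' @return Count tibble at the panel's lambda markers.
#' @export
simulate_lambda_spikein <- function(depth, config = sim_config(),
                                    panel = example_panel(),
                                    sample_id = "sample1") {
  stopifnot(depth >= 0)
  lam <- panel_lambda(panel)
  if (nrow(lam) == 0) stop_data("panel has no lambda rows")
  withr::with_seed(config$seed, {
    grid <- tibble(sample_id = sample_id, marker_id = lam$marker_id,
                   strands = lam$strands, sampling_beta = 0,
                   depth_scale = depth / exp(config$coverage_mu))
    # fixed depth rather than lognormal draw: override after sampling shape
    n <- nrow(grid)
    p <- meth_call_prob(0, config)
    both <- grid$strands == "both"
    n_w <- integer(n)
    n_w[both] <- rbinom(sum(both), depth, config$strand_split)
    n_w[grid$strands == "W"] <- depth
    n_c <- depth - n_w
    m_w <- rbinom(n, n_w, p)
    m_c <- rbinom(n, n_c, p)
    bind_rows(
      tibble(sample_id = sample_id, marker_id = grid$marker_id, strand = "W",
             n_meth = m_w, n_unmeth = n_w - m_w,
             present = grid$strands %in% c("both", "W")),
      tibble(sample_id = sample_id, marker_id = grid$marker_id, strand = "C",
             n_meth = m_c, n_unmeth = n_c - m_c,
             present = grid$strands %in% c("both", "C"))
    ) |>
      filter(.data$present) |>
      select(-"present")
  })
}

#' Write a simulation run manifest
#'
#' Records every generation parameter, the seed and a hash of the
#' configuration, so a run can be reproduced bit-identically.
#'
#' @param config A [sim_config()].
#' @param path Output JSON path.
#' @param extra Optional named list of additional fields.
#' @export
write_manifest <- function(config, path, extra = list()) {
  cfg <- unclass(config)
  cfg$platform_bias <- if (is.null(cfg$platform_bias)) NULL else
    as.list(tidy(cfg$platform_bias) |> select("term", "estimate") |> tibble::deframe())
  manifest <- c(list(package = "methclocks",
                     rng = "Mersenne-Twister (R default)",
                     config_hash = config_hash(cfg)),
                cfg, extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
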