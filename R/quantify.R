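#' Strand-merged beta calling from site counts
#'
#' A counts table has one row per (sample, marker, strand) with methylated
#' (`n_meth`: C or G calls) and unmethylated (`n_unmeth`: T or A calls)
#' read tallies. Beta is the ratio of methylated reads to total reads after
#' summing both strands where available; sites under the read-depth
#' threshold are reported as missing rather than as unreliable values.
#'
#' @name quantify
NULL

counts_cols <- c("sample_id", "marker_id", "strand", "n_meth", "n_unmeth")

validate_counts <- function(counts, strand_required = TRUE) {
  need <- if (strand_required) counts_cols else setdiff(counts_cols, "strand")
  missing <- setdiff(need, names(counts))
  if (length(missing) > 0) {
    stop_data("counts table missing column(s): %s", paste(missing, collapse = ", "))
  }
  if (any(counts$n_meth < 0) || any(counts$n_unmeth < 0)) {
    stop_data("negative read counts")
  }
  if (strand_required) {
    if (!all(counts$strand %in% c("W", "C"))) {
      stop_data("strand must be 'W' or 'C'")
    }
    key <- paste(counts$sample_id, counts$marker_id, counts$strand)
    if (anyDuplicated(key)) {
      stop_data("duplicated (sample_id, marker_id, strand) row: %s",
                key[duplicated(key)][1])
    }
  }
  invisible(counts)
}

#' Sum methylated/unmethylated counts over strands
#'
#' The final methylation call is made after summing methylated and
#' unmethylated reads from both strands, if available; single-strand input
#' passes through unchanged.
#'
#' @param counts Count tibble (sample_id, marker_id, strand, n_meth,
#'   n_unmeth); a strand-collapsed table (no `strand` column) is returned
#'   as-is after validation.
#' @return Tibble with one row per (sample_id, marker_id) and summed counts.
#' @export
merge_strands <- function(counts) {
  if (!"strand" %in% names(counts)) {
    validate_counts(counts, strand_required = FALSE)
    return(as_tibble(counts[setdiff(counts_cols, "strand")]))
  }
  validate_counts(counts)
  counts |>
    summarise(n_meth = sum(.data$n_meth), n_unmeth = sum(.data$n_unmeth),
              .by = c("sample_id", "marker_id"))
}

#' Call beta values from merged counts with a read-depth threshold
#'
#' `beta = n_meth / (n_meth + n_unmeth)`. A site passes when the merged
#' total is at least `min_reads` (so total == `min_reads` passes: sites with
#' *fewer* than the threshold are treated as missing data).
#'
#' @param n_meth,n_unmeth Non-negative merged counts (vectorised).
#' @param min_reads Minimum total reads for a call (default 50).
#' @return Tibble with columns `n_meth`, `n_unmeth`, `total_reads`, `beta`
#'   (NA where sub-threshold) and `passed_threshold`.
#' @export
call_beta <- function(n_meth, n_unmeth, min_reads = 50) {
  if (any(n_meth < 0) || any(n_unmeth < 0)) stop_data("negative read counts")
  stopifnot(min_reads >= 1)
  total <- n_meth + n_unmeth
  passed <- total >= min_reads
  tibble(n_meth = n_meth, n_unmeth = n_unmeth, total_reads = total,
         beta = ifelse(passed, n_meth / total, NA_real_),
         passed_threshold = passed)
}

#' Quantify beta values for all samples over a panel
#'
#' Merges strands, applies the read-depth threshold, and returns exactly one
#' beta call per sample per non-lambda panel marker (missing where counts
#' are absent or sub-threshold). Lambda QC rows are excluded from the beta
#' table (see [conversion_rate_lambda()]); counts at markers not in the
#' panel are reported via a warning and skipped, tolerating off-target rows
#' in real coverage files.
#'
#' @param counts Count tibble (with or without a `strand` column).
#' @param panel Panel tibble.
#' @param min_reads Read-depth threshold (default 50).
#' @return Beta-call tibble: `sample_id`, `marker_id`, `beta`,
#'   `total_reads`, `passed_threshold`.
#' @export
call_betas <- function(counts, panel, min_reads = 50) {
  validate_panel(panel)
  merged <- merge_strands(counts)
  unknown <- setdiff(unique(merged$marker_id), panel$marker_id)
  if (length(unknown) > 0) {
    warn(sprintf("skipping %d marker(s) not in panel: %s", length(unknown),
                 paste(head(unknown, 5), collapse = ", ")))
    merged <- filter(merged, .data$marker_id %in% panel$marker_id)
  }
  body <- panel_markers(panel)
  grid <- tidyr::expand_grid(sample_id = unique(counts$sample_id),
                             marker_id = body$marker_id)
  full <- grid |>
    left_join(merged, by = c("sample_id", "marker_id")) |>
    mutate(n_meth = coalesce(.data$n_meth, 0L),
           n_unmeth = coalesce(.data$n_unmeth, 0L))
  bind_cols(
    select(full, "sample_id", "marker_id"),
    call_beta(full$n_meth, full$n_unmeth, min_reads) |>
      select("beta", "total_reads", "passed_threshold")
  )
}

#' Bisulfite conversion rate from lambda spike-in counts
#'
#' Pools counts over all lambda amplicons (count-summing, not per-amplicon
#' averaging) and reports `100 * n_unmeth / (n_meth + n_unmeth)` per sample:
#' on unmethylated lambda DNA every methylated call is a conversion failure.
#'
#' @param counts Count tibble including lambda markers.
#' @param panel Panel tibble with lambda rows.
#' @return Tibble `sample_id`, `conversion_rate_lambda` (percent; NA when
#'   no lambda reads).
#' @export
conversion_rate_lambda <- function(counts, panel) {
  lam_ids <- panel_lambda(panel)$marker_id
  merged <- merge_strands(counts) |>
    filter(.data$marker_id %in% lam_ids)
  tibble(sample_id = unique(counts$sample_id)) |>
    left_join(
      merged |>
        summarise(n_meth = sum(.data$n_meth), n_unmeth = sum(.data$n_unmeth),
                  .by = "sample_id"),
      by = "sample_id") |>
    mutate(
      total = coalesce(.data$n_meth, 0L) + coalesce(.data$n_unmeth, 0L),
      conversion_rate_lambda =
        ifelse(.data$total > 0, 100 * .data$n_unmeth / .data$total, NA_real_)
    ) |>
    select("sample_id", "conversion_rate_lambda")
}

#' Bisulfite conversion rate from non-CpG cytosines
#'
#' For hybridisation-capture data the conversion rate is estimated from
#' cytosines outside CpG context observed within targets: pooled
#' `100 * converted / (converted + unconverted)`.
#'
#' @param n_converted,n_unconverted Read tallies over non-CpG cytosines
#'   (vectors are pooled by summing).
#' @return Percentage, or `NA` when there are no reads.
#' @export
conversion_rate_noncpg <- function(n_converted, n_unconverted) {
  if (any(n_converted < 0) || any(n_unconverted < 0)) stop_data("negative counts")
  tot <- sum(n_converted) + sum(n_unconverted)
  if (tot == 0) return(NA_real_)
  100 * sum(n_converted) / tot
}

#' Fraction of markers exceeding coverage thresholds
#'
#' Uses a strict `>` comparison ("covered more than t reads"), deliberately
#' different from the beta-calling threshold's `>=`. Also reports the number
#' of markers with fewer than 20 reads via the `n_below_20` attribute.
#'
#' @param depths Per-marker merged depths (non-empty).
#' @param thresholds Positive thresholds (default 50, 200, 1000).
#' @return Tibble `threshold`, `fraction`, with attribute `n_below_20`.
#' @export
coverage_summary <- function(depths, thresholds = c(50, 200, 1000)) {
  if (length(depths) == 0) stop_data("empty depth vector")
  stopifnot(all(thresholds > 0))
  out <- tibble(threshold = thresholds,
                fraction = map_dbl(thresholds, function(t) mean(depths > t)))
  attr(out, "n_below_20") <- sum(depths < 20)
  out
}

#' Normalised per-marker read depth
#'
#' `depth_i / total`, comparable across runs of different size; under a
#' perfect distribution of reads between `m` targets each marker's
#' normalised depth is `1/m` of the on-target total.
#'
#' @param depths Per-marker depths.
#' @param total Total mapped reads (> 0).
#' @return Numeric vector of fractions.
#' @export
normalized_depth <- function(depths, total) {
  if (total <= 0) stop_data("total mapped reads must be positive")
  depths / total
}

#' Per-sample quantification QC report
#'
#' Combines lambda conversion rates, coverage-threshold fractions over
#' non-lambda panel markers, and missing-marker counts at the beta-calling
#' threshold.
#'
#' @param counts Count tibble.
#' @param panel Panel tibble.
#' @param min_reads Beta-calling threshold (default 50).
#' @param thresholds Coverage thresholds (default 50, 200, 1000).
#' @return Tibble with one row per sample: `sample_id`,
#'   `conversion_rate_lambda`, `n_missing_markers`, and one
#'   `frac_gt_<t>` column per threshold (fractions non-increasing in `t`).
#' @export
qc_report <- function(counts, panel, min_reads = 50,
                      thresholds = c(50, 200, 1000)) {
  betas <- suppressWarnings(call_betas(counts, panel, min_reads))
  cov <- betas |>
    summarise(
      n_missing_markers = sum(!.data$passed_threshold),
      n_below_20 = sum(.data$total_reads < 20),
      !!!setNames(
        map(thresholds, function(t) rlang::expr(mean(.data$total_reads > !!t))),
        sprintf("frac_gt_%g", thresholds)),
      .by = "sample_id")
  conv <- conversion_rate_lambda(counts, panel)
  left_join(conv, cov, by = "sample_id") |>
    relocate("sample_id", "conversion_rate_lambda", "n_missing_markers")
}

#' Write a QC report to JSON
#' @param qc Tibble from [qc_report()].
#' @param path Output path.
#' @export
write_qc_json <- function(qc, path) {
  jsonlite::write_json(qc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

# ---- count file formats -----------------------------------------------------

#' Read/write the internal count TSV
#'
#' Columns: sample_id, marker_id, strand, n_meth, n_unmeth.
#'
#' @param counts Count tibble.
#' @param path File path.
#' @name counts_tsv
#' @export
write_counts_tsv <- function(counts, path) {
  validate_counts(counts)
  readr::write_tsv(counts[counts_cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname counts_tsv
#' @export
read_counts_tsv <- function(path) {
  counts <- readr::read_tsv(path, col_types = "cccii", progress = FALSE)
  validate_counts(counts)
  counts
}

#' Write Bismark-style cytosine coverage files
#'
#' One file per sample, strand-collapsed: chromosome, start, end (both the
#' 1-based cytosine position), methylation percentage, count methylated,
#' count unmethylated.
#'
#' @param counts Count tibble.
#' @param panel Panel tibble (for genomic coordinates).
#' @param dir Output directory; files are named `<sample_id>.cov`.
#' @return Character vector of written paths.
#' @export
write_bismark_cov <- function(counts, panel, dir) {
  validate_panel(panel)
  merged <- merge_strands(counts) |>
    inner_join(select(panel, "marker_id", "chrom", "pos"), by = "marker_id") |>
    mutate(total = .data$n_meth + .data$n_unmeth,
           pct = ifelse(.data$total > 0, 100 * .data$n_meth / .data$total, 0))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- map_chr(unique(merged$sample_id), function(s) {
    path <- file.path(dir, paste0(s, ".cov"))
    merged |>
      filter(.data$sample_id == s) |>
      transmute(.data$chrom, start = .data$pos, end = .data$pos,
                pct = .data$pct, n_meth = .data$n_meth,
                n_unmeth = .data$n_unmeth) |>
      readr::write_tsv(path, col_names = FALSE, progress = FALSE)
    path
  })
  invisible(paths)
}

#' Read a Bismark-style cytosine coverage file
#'
#' Methylated/unmethylated counts are taken from columns 5-6; the percentage
#' column is ignored and recomputed downstream, guarding against
#' inconsistent inputs. Positions are matched to panel markers by
#' (chromosome, 1-based position); unmatched rows are kept with a synthetic
#' `chrom:pos` marker id (and will be skipped with a warning by
#' [call_betas()]).
#'
#' @param path Coverage file path.
#' @param panel Panel tibble.
#' @param sample_id Sample label (default the file name without extension).
#' @return Strand-collapsed count tibble (sample_id, marker_id, n_meth,
#'   n_unmeth).
#' @export
read_bismark_cov <- function(path, panel, sample_id = NULL) {
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  raw <- readr::read_tsv(path,
                         col_names = c("chrom", "start", "end", "pct",
                                       "n_meth", "n_unmeth"),
                         col_types = "ciidii", progress = FALSE)
  raw |>
    left_join(select(panel, "marker_id", "chrom", "pos"),
              by = c("chrom", "start" = "pos")) |>
    mutate(marker_id = coalesce(.data$marker_id,
                                sprintf("%s:%d", .data$chrom, .data$start)),
           sample_id = sample_id) |>
    select("sample_id", "marker_id", "n_meth", "n_unmeth")
}

#' Write/read a beta matrix TSV
#'
#' Rows are samples, columns are marker ids, empty cells are missing values.
#'
#' @param betas Long beta-call tibble from [call_betas()].
#' @param path File path.
#' @name beta_matrix_tsv
#' @export
write_beta_matrix <- function(betas, path) {
  wide <- betas |>
    select("sample_id", "marker_id", "beta") |>
    pivot_wider(names_from = "marker_id", values_from = "beta")
  readr::write_tsv(wide, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname beta_matrix_tsv
#' @export
read_beta_matrix <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(sample_id = "c",
                                                        .default = "d"),
                          na = c("", "NA"), progress = FALSE)
  wide |>
    pivot_longer(-"sample_id", names_to = "marker_id", values_to = "beta")
}
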