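#' Target cytosine panels
#'
#' A panel is a tibble with one row per target cytosine (CG or CA context)
#' carrying its genomic location, the strands on which it can be analysed,
#' and the epigenetic clocks it belongs to. QC markers (unmethylated lambda
#' spike-in amplicons) are ordinary rows on the reserved chromosome
#' `"lambda"` with no clock membership, so downstream quantification needs
#' no special case.
#'
#' Columns: `marker_id`, `chrom`, `pos` (1-based coordinate of the
#' cytosine), `context` (`"CG"`/`"CA"`), `strands` (`"W"`, `"C"` or
#' `"both"`), `region`, `clocks` (list-column of character vectors, possibly
#' empty). Extra columns are preserved.
#'
#' @name panel
NULL

panel_required_cols <- c("marker_id", "chrom", "pos", "context",
                         "strands", "region", "clocks")

#' Known clock identifiers
#' @export
clock_names <- function() c("HANNUM", "VISAGE", "POAM", "MRS")

#' Validate a target panel
#'
#' Checks the structural invariants of a panel tibble: required columns,
#' unique marker ids, positive 1-based positions, valid context and strand
#' labels.
#'
#' @param panel A panel tibble (see [panel]).
#' @return The validated panel, invisibly usable in a pipe.
#' @export
validate_panel <- function(panel) {
  missing <- setdiff(panel_required_cols, names(panel))
  if (length(missing) > 0) {
    stop_data("panel is missing required column(s): %s",
              paste(missing, collapse = ", "))
  }
  dup <- panel$marker_id[duplicated(panel$marker_id)]
  if (length(dup) > 0) {
    stop_data("duplicated marker_id in panel: %s",
              paste(unique(dup), collapse = ", "))
  }
  bad_pos <- which(!is.finite(panel$pos) | panel$pos < 1 |
                     panel$pos != floor(panel$pos))
  if (length(bad_pos) > 0) {
    stop_data("unparseable or non-positive pos at row %d (marker %s)",
              bad_pos[1], panel$marker_id[bad_pos[1]])
  }
  bad_ctx <- which(!panel$context %in% c("CG", "CA"))
  if (length(bad_ctx) > 0) {
    stop_data("context outside {CG, CA} at row %d (marker %s): '%s'",
              bad_ctx[1], panel$marker_id[bad_ctx[1]], panel$context[bad_ctx[1]])
  }
  bad_str <- which(!panel$strands %in% c("W", "C", "both"))
  if (length(bad_str) > 0) {
    stop_data("strands outside {W, C, both} at row %d (marker %s): '%s'",
              bad_str[1], panel$marker_id[bad_str[1]], panel$strands[bad_str[1]])
  }
  if (!is.list(panel$clocks)) {
    stop_data("clocks must be a list-column of character vectors")
  }
  invisible(panel)
}

#' Read a target panel from TSV
#'
#' Tab-separated, UTF-8, `#` comment lines ignored. The `clocks` column is
#' semicolon-separated clock names (empty for QC-only markers) and is parsed
#' into a list-column.
#'
#' @param path Path to a panel TSV file.
#' @return A validated panel tibble, row order preserved.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop_data("panel file not found: %s", path)
  raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(panel_required_cols, names(raw))
  if (length(missing) > 0) {
    stop_data("panel file %s is missing required column(s): %s",
              path, paste(missing, collapse = ", "))
  }
  pos_num <- suppressWarnings(as.numeric(raw$pos))
  if (anyNA(pos_num)) {
    bad <- which(is.na(pos_num))[1]
    stop_data("unparseable pos at row %d (marker %s): '%s'",
              bad, raw$marker_id[bad], raw$pos[bad])
  }
  panel <- raw |>
    mutate(
      pos = pos_num,
      clocks = map(.data$clocks, function(x) {
        if (is.na(x) || x == "") character(0)
        else strsplit(x, ";", fixed = TRUE)[[1]]
      })
    )
  if ("ampliseq" %in% names(panel)) {
    panel$ampliseq <- panel$ampliseq %in% c("TRUE", "true", "1")
  }
  validate_panel(panel)
  panel
}

#' Write a target panel to TSV
#'
#' Inverse of [load_panel()]; the `clocks` list-column is collapsed to
#' semicolon-separated names.
#'
#' @param panel A panel tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  out <- panel |>
    mutate(clocks = map_chr(.data$clocks, paste, collapse = ";"))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Drop QC (lambda) rows from a panel
#' @param panel A panel tibble.
#' @return Panel rows targeting the genome proper.
#' @export
panel_markers <- function(panel) filter(panel, .data$chrom != "lambda")

#' Lambda spike-in QC rows of a panel
#' @param panel A panel tibble.
#' @return Panel rows on the reserved `"lambda"` chromosome.
#' @export
panel_lambda <- function(panel) filter(panel, .data$chrom == "lambda")

#' Per-clock marker lists of a panel
#'
#' @param panel A panel tibble.
#' @return Named list: for each clock name occurring in the panel, the
#'   character vector of its marker ids in panel order.
#' @export
clock_panels <- function(panel) {
  validate_panel(panel)
  long <- panel |>
    select("marker_id", "clocks") |>
    unnest_longer("clocks", values_to = "clock")
  split(long$marker_id, long$clock)
}

#' Number of distinct markers across clock panels
#'
#' @param panels Named or unnamed list of marker-id character vectors (as
#'   returned by [clock_panels()]).
#' @return Integer count of the union of all markers.
#' @export
union_size <- function(panels) {
  if (!is.list(panels) || length(panels) == 0) {
    stop_data("panels must be a non-empty list of marker-id vectors")
  }
  for (p in panels) {
    if (length(p) == 0) stop_data("clock panel with no markers")
    if (anyDuplicated(p)) stop_data("duplicate markers within one clock panel")
  }
  length(unique(unlist(panels, use.names = FALSE)))
}

#' Tally markers by strand availability
#'
#' @param panel A panel tibble (typically [panel_markers()] of a
#'   platform-specific design).
#' @return Tibble with columns `strand_class` (`both`, `W_only`, `C_only`)
#'   and `n`; the three counts sum to `nrow(panel)`.
#' @export
strand_breakdown <- function(panel) {
  validate_panel(panel)
  tibble(
    strand_class = c("both", "W_only", "C_only"),
    n = c(sum(panel$strands == "both"),
          sum(panel$strands == "W"),
          sum(panel$strands == "C"))
  )
}

#' Synthetic example panel of 161 clock markers plus lambda controls
#'
#' Builds the package's fixture panel: 161 CG/CA target cytosines with the
#' published per-clock counts and overlap structure (71 HANNUM, 44 VISAGE
#' with 9 shared with HANNUM; 46 POAM, 10 MRS with 1 shared), plus two
#' unmethylated lambda control amplicons. Marker ids, chromosomes and
#' positions are synthetic placeholders (ids prefixed `cgs`), not the real
#' loci. The `ampliseq` column marks the 155 markers for which an
#' amplicon-based design succeeds (134 both-strand, 16 Watson-only, 5
#' Crick-only); the 6 failures are 1 HANNUM-only and 5 POAM-only markers.
#'
#' @param include_lambda Include the two lambda QC rows (default `TRUE`).
#' @return A validated panel tibble.
#' @export
example_panel <- function(include_lambda = TRUE) {
  n <- 161L
  ids <- sprintf("cgs%05d", seq_len(n))
  clocks <- vector("list", n)
  clocks[1:9]     <- list("HANNUM;VISAGE")
  clocks[10:71]   <- list("HANNUM")
  clocks[72:106]  <- list("VISAGE")
  clocks[107]     <- list("POAM;MRS")
  clocks[108:152] <- list("POAM")
  clocks[153:161] <- list("MRS")
  clocks <- map(clocks, function(x) strsplit(x, ";", fixed = TRUE)[[1]])

  # amplicon design failures: one HANNUM-only and five POAM-only markers
  ampliseq <- rep(TRUE, n)
  ampliseq[c(71L, 148:152)] <- FALSE

  # among the 155 designed markers: 134 both, 16 Watson-only, 5 Crick-only
  strands <- rep("both", n)
  designed <- which(ampliseq)
  strands[designed[135:150]] <- "W"
  strands[designed[151:155]] <- "C"

  context <- rep("CG", n)
  context[seq(20, 160, by = 20)] <- "CA"

  panel <- tibble(
    marker_id = ids,
    chrom = paste0("chr", rep_len(1:22, n)),
    pos = 1e6 + 1013 * seq_len(n),
    context = context,
    strands = strands,
    region = sprintf("locus_%03d", (seq_len(n) - 1L) %/% 2L + 1L),
    clocks = clocks,
    ampliseq = ampliseq
  )
  if (include_lambda) {
    lambda <- tibble(
      marker_id = c("lambda_amp1", "lambda_amp2"),
      chrom = "lambda",
      pos = c(4500, 17421),
      context = "CG",
      strands = "both",
      region = "lambda_control",
      clocks = list(character(0), character(0)),
      ampliseq = TRUE
    )
    panel <- bind_rows(panel, lambda)
  }
  validate_panel(panel)
  panel
}
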