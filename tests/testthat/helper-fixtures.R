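# Small in-code fixtures shared across tests.

# 12-marker panel (one 6-marker age clock, mixed strand availability) plus
# one lambda QC amplicon: big enough to exercise strand merging, clock
# membership and QC routing, small enough for Monte-Carlo loops.
small_panel <- function() {
  tibble::tibble(
    marker_id = c(sprintf("cgt%03d", 1:12), "lambda_amp1"),
    chrom = c(paste0("chr", rep(1:6, each = 2)), "lambda"),
    pos = c(1000 * (1:12), 4500),
    context = c(rep("CG", 10), "CA", "CG", "CG"),
    strands = c(rep("both", 8), "W", "W", "C", "both", "both"),
    region = c(sprintf("locus_%02d", 1:12), "lambda_control"),
    clocks = c(as.list(rep("AGE6", 6)), rep(list(character(0)), 7))
  )
}

# 6-marker linear age clock over small_panel(), scaled so inversion over
# ages 7-78 stays inside [0.01, 0.99].
small_clock <- function(name = "AGE6") {
  markers <- sprintf("cgt%03d", 1:6)
  w <- stats::setNames(seq(28, 38, length.out = 6) * c(1, -1, 1, -1, 1, -1),
                       markers)
  mu <- stats::setNames(seq(0.4, 0.6, length.out = 6), markers)
  clock_model(name, intercept = 44 - sum(w * mu), weights = w,
              imputation_means = mu, units = "years")
}

# Noiseless counts for a fixed beta at a fixed depth over a panel.
exact_counts <- function(panel, beta, depth, sample_id = "s1") {
  body <- panel_markers(panel)
  tibble::tibble(
    sample_id = sample_id,
    marker_id = body$marker_id,
    strand = ifelse(body$strands == "C", "C", "W"),
    n_meth = round(beta * depth),
    n_unmeth = depth - round(beta * depth)
  )
}
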