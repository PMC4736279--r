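#' Elevated interval of a breadth archetype
#'
#' Archetypes are defined in transcription-direction coordinates as the
#' interval over which fragment midpoints are elevated `signal_height` log2
#' units above background: narrow peak -250..+250, upstream extended
#' -500..+250, downstream extended -250..+650, broad symmetric -500..+650,
#' unmarked nowhere.
#'
#' @param pattern A label from [pattern_labels()] or `"unmarked"`.
#' @return `c(lo, hi)` in bp, or `NULL` for unmarked.
#' @export
archetype_interval <- function(pattern) {
  switch(as.character(pattern),
    narrow_peak = c(-250, 250),
    upstream_extended = c(-500, 250),
    downstream_extended = c(-250, 650),
    broad_symmetric = c(-500, 650),
    unmarked = NULL,
    stop("unknown pattern: ", pattern)
  )
}

# transcription-relative midpoint window (bin window widened by half a
# fragment so coverage is defined over the full bin grid)
midpoint_window <- function(config) {
  config$window + c(-1, 1) * config$fragment_length / 2
}

# spans over which per-gene region multipliers act: the bases spanned by the
# region's bins, widened by half a fragment so the *coverage* inside the
# region moves by the intended factor
region_delta_spans <- function(config, regions = region_defaults()) {
  half <- config$fragment_length / 2
  grid <- bin_grid(config$bin_width)
  lapply(regions, function(r) {
    idx <- region_bin_index(r, grid)
    c(min(grid$start[idx]) - half, max(grid$end[idx]) + half)
  })
}

#' Expected normalized profile of an archetype
#'
#' Analytic expectation of the binned log2-vs-background profile produced by
#' the generator for one archetype (box-kernel smoothing by the fragment
#' length included), optionally with per-region percent multipliers applied.
#'
#' @param pattern Archetype label.
#' @param config A [generator_config()].
#' @param pct Named percent changes for `upstream`, `tss`, `downstream`
#'   (0 = none).
#' @return Numeric vector of 41 expected log2-fold values.
#' @export
expected_profile <- function(pattern, config,
                             pct = c(upstream = 0, tss = 0, downstream = 0)) {
  mw <- midpoint_window(config)
  xs <- seq(mw[1], mw[2] - 1) + 0.5   # midpoint-rate grid, 1 bp
  f <- rep(1, length(xs))
  el <- archetype_interval(pattern)
  if (!is.null(el)) {
    f[xs > el[1] & xs < el[2]] <- 2^config$signal_height
  }
  spans <- region_delta_spans(config)
  for (r in names(spans)) {
    p <- if (r %in% names(pct)) pct[[r]] else 0
    if (p != 0) {
      s <- spans[[r]]
      f[xs > s[1] & xs < s[2]] <- f[xs > s[1] & xs < s[2]] * (1 + p / 100)
    }
  }
  # coverage fold at base x = mean of midpoint fold over x +/- fragment/2
  fl <- config$fragment_length
  cs <- cumsum(f)
  cov_at <- function(x) {
    i <- x - mw[1]              # index of base x in xs (1-based offset)
    lo <- pmax(i - fl / 2, 0)
    hi <- pmin(i + fl / 2, length(xs))
    (cs[hi] - ifelse(lo > 0, cs[lo], 0)) / (hi - lo)
  }
  grid <- bin_grid(config$bin_width)
  vapply(seq_len(nrow(grid)), function(j) {
    bases <- seq(grid$start[j], grid$end[j] - 1)
    log2(mean(cov_at(bases)))
  }, numeric(1))
}

# synthetic annotation: TSSs on one contig, 10 kb apart, alternating strand
synthetic_tss_annotation <- function(n) {
  data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    chrom = "chrS",
    tss_pos = 5000L + (seq_len(n) - 1L) * 10000L,
    strand = rep(c("+", "-"), length.out = n),
    stringsAsFactors = FALSE
  )
}

# simulate one BED track of raw (unextended) reads for all TSSs.
# deltas: NULL or data.frame with pct_change_{upstream,tss,downstream};
# patterns: NULL (input track: flat background) or per-TSS labels.
simulate_track <- function(tss, patterns, deltas, config, seed) {
  set.seed(seed)
  n <- nrow(tss)
  mw <- midpoint_window(config)
  spans <- region_delta_spans(config)
  arch_edges <- c(-500, -250, 250, 650)
  brk <- sort(unique(c(mw, arch_edges, unlist(spans))))
  seg_lo <- brk[-length(brk)]
  seg_hi <- brk[-1]
  seg_len <- seg_hi - seg_lo
  n_seg <- length(seg_lo)

  base_rate <- config$background_depth / config$fragment_length
  fold <- matrix(1, nrow = n, ncol = n_seg)
  if (!is.null(patterns)) {
    pat <- as.character(patterns)
    for (p in pattern_labels()) {
      el <- archetype_interval(p)
      inside <- seg_lo >= el[1] & seg_hi <= el[2]
      rows <- pat == p
      if (any(rows) && any(inside)) {
        fold[rows, inside] <- fold[rows, inside] * 2^config$signal_height
      }
    }
  }
  if (!is.null(deltas)) {
    dcol <- c(upstream = "pct_change_upstream", tss = "pct_change_tss",
              downstream = "pct_change_downstream")
    for (r in names(spans)) {
      s <- spans[[r]]
      inside <- seg_lo >= s[1] & seg_hi <= s[2]
      mult <- pmax(1 + deltas[[dcol[[r]]]] / 100, 0)
      fold[, inside] <- fold[, inside] * mult
    }
  }

  lambda <- sweep(fold, 2, seg_len * base_rate, `*`)
  counts <- stats::rpois(length(lambda), as.vector(lambda))
  if (sum(counts) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  tss_idx <- rep(rep(seq_len(n), n_seg), counts)
  seg_idx <- rep(rep(seq_len(n_seg), each = n), counts)
  m <- seg_lo[seg_idx] + stats::runif(length(seg_idx)) * seg_len[seg_idx]

  plus_gene <- tss$strand[tss_idx] == "+"
  gm <- ifelse(plus_gene, tss$tss_pos[tss_idx] + m, tss$tss_pos[tss_idx] - m)
  gm <- round(gm)
  half <- config$fragment_length / 2
  read_plus <- stats::runif(length(gm)) < 0.5
  start <- ifelse(read_plus, gm - half, gm + half - config$read_length)
  start <- pmax(as.integer(start), 0L)
  df <- data.frame(
    chrom = tss$chrom[tss_idx],
    start = start,
    end = start + config$read_length,
    name = ".",
    score = 0L,
    strand = ifelse(read_plus, "+", "-"),
    stringsAsFactors = FALSE
  )
  df[order(df$start), , drop = FALSE]
}

#' Simulate a TSS-anchored ChIP-seq cohort
#'
#' Generates, for each condition, per-sample BED-like read tables whose
#' expected binned coverage follows the breadth archetype of each TSS, plus
#' matched flat input-control tracks and the cohort ground truth. Disease
#' ChIP tracks carry the per-gene region-specific H3K4me3 changes (and
#' pattern switches) recorded in the truth table; read counts are Poisson
#' over a flat background of `background_depth` reads/bp.
#'
#' @param config A [generator_config()].
#' @param truth Optional pre-generated [generate_truth()] table.
#' @return List of class `"tss_simulation"` with elements `tss` (annotation),
#'   `truth`, `chip_control`, `chip_disease`, `input_control`,
#'   `input_disease` (each a list of read data.frames, one per sample), and
#'   `config`.
#' @export
simulate_chipseq <- function(config, truth = NULL) {
  if (is.null(truth)) truth <- generate_truth(config)
  n <- nrow(truth)
  tss <- synthetic_tss_annotation(n)
  S <- config$n_samples_per_group
  base <- config$seed + 10L
  chip_control <- lapply(seq_len(S), function(s) {
    simulate_track(tss, truth$pattern_control, NULL, config, base + s)
  })
  chip_disease <- lapply(seq_len(S), function(s) {
    simulate_track(tss, truth$pattern_disease, truth, config, base + 100L + s)
  })
  input_control <- lapply(seq_len(S), function(s) {
    simulate_track(tss, NULL, NULL, config, base + 200L + s)
  })
  input_disease <- lapply(seq_len(S), function(s) {
    simulate_track(tss, NULL, NULL, config, base + 300L + s)
  })
  names(chip_control) <- names(input_control) <- sprintf("ctrl%02d", seq_len(S))
  names(chip_disease) <- names(input_disease) <- sprintf("sle%02d", seq_len(S))
  structure(
    list(tss = tss, truth = truth,
         chip_control = chip_control, chip_disease = chip_disease,
         input_control = input_control, input_disease = input_disease,
         config = config),
    class = "tss_simulation"
  )
}

#' @export
print.tss_simulation <- function(x, ...) {
  nr <- sum(vapply(c(x$chip_control, x$chip_disease,
                     x$input_control, x$input_disease),
                   nrow, integer(1)))
  cat(sprintf(
    "Synthetic ChIP-seq cohort: %d TSSs, %d+%d ChIP samples, %d reads total\n",
    nrow(x$tss), length(x$chip_control), length(x$chip_disease), nr
  ))
  invisible(x)
}
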