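#' Pattern label universe
#'
#' The four confident breadth patterns, in canonical order. `all_labels()`
#' appends the two non-pattern states: `unclassified` (marked but not
#' confidently patterned -- a classifier outcome) and `unmarked` (no signal
#' above background).
#'
#' @return Character vector of labels.
#' @export
pattern_labels <- function() {
  c("narrow_peak", "upstream_extended", "downstream_extended", "broad_symmetric")
}

#' @rdname pattern_labels
#' @export
all_labels <- function() c(pattern_labels(), "unclassified", "unmarked")

#' Synthetic-cohort generator configuration
#'
#' Bundles every parameter of the synthetic data generator. The defaults
#' encode the study conditions the downstream analysis is designed around:
#' six samples per group, a 41 x 50 bp bin grid over -1025..+1025 bp,
#' classified-pattern proportions 0.10/0.36/0.33/0.21
#' (narrow/upstream/downstream/broad) within the 60 percent of TSSs that
#' carry a confident pattern, a dose-response coefficient of 1.5 percent
#' transcription change per 1 percent downstream H3K4me3 change,
#' region-increase probabilities (0.788, 0.550, 0.471) for
#' (downstream, TSS, upstream) among DE-up genes, a pattern persistence
#' probability of 0.948 between conditions, and a 2.51x expression
#' multiplier for the downstream-extended pattern.
#'
#' @param n_tss Number of TSSs (= genes; the synthetic annotation is 1:1).
#' @param n_samples_per_group ChIP-seq samples per condition.
#' @param bin_width Bin width in bp.
#' @param window TSS-relative window covered by the bin grid, bp pair.
#' @param pattern_proportions Named simplex over the four patterns plus
#'   `unmarked`; must sum to 1.
#' @param background_depth Expected per-base coverage of the flat background
#'   (and of the input-control track), reads/bp after fragment extension.
#' @param signal_height Elevation of marked archetypes over background, log2
#'   units (2 means four-fold background within the elevated interval).
#' @param de_prob_by_pattern Probability that a gene is transcriptionally
#'   up-regulated in the disease condition, per truth label.
#' @param de_down_prob Probability of down-regulation among non-up genes.
#' @param persist_prob Probability a non-narrow TSS keeps its pattern in the
#'   disease condition. Narrow-peak TSSs never switch; switchers move
#'   uniformly to one of the other two non-narrow patterns.
#' @param beta_down Percent transcription change per 1 percent downstream
#'   H3K4me3 change.
#' @param frac_increase_by_region Probability that a DE-up gene's H3K4me3
#'   change is positive, named for (downstream, tss, upstream).
#' @param expr_multiplier_by_pattern Linear expression factor per truth
#'   label, relative to the unmarked baseline (1.0).
#' @param region_change_sd Scale (percent) of the half-normal magnitude of
#'   per-gene region H3K4me3 changes.
#' @param tx_noise_sd Gaussian noise (percent) added to the transcription
#'   change implied by the downstream coupling.
#' @param expr_meanlog,expr_sdlog Log-normal baseline expression parameters.
#' @param sample_noise_sd Per-sample log-scale expression noise.
#' @param read_length Raw read length in bp (pre-extension).
#' @param fragment_length Fragment length the 3' extension targets, bp.
#' @param seed Integer seed; every generator draw derives from it.
#' @return A validated list of class `"generator_config"`.
#' @export
generator_config <- function(n_tss = 1000L,
                             n_samples_per_group = 6L,
                             bin_width = 50L,
                             window = c(-1025L, 1025L),
                             pattern_proportions = c(
                               narrow_peak = 0.060,
                               upstream_extended = 0.216,
                               downstream_extended = 0.198,
                               broad_symmetric = 0.126,
                               unmarked = 0.400
                             ),
                             background_depth = 5,
                             signal_height = 2,
                             de_prob_by_pattern = c(
                               narrow_peak = 0.026,
                               upstream_extended = 0.12,
                               downstream_extended = 0.225,
                               broad_symmetric = 0.13,
                               unmarked = 0.05
                             ),
                             de_down_prob = 0.09,
                             persist_prob = 0.948,
                             beta_down = 1.5,
                             frac_increase_by_region = c(
                               downstream = 0.788,
                               tss = 0.550,
                               upstream = 0.471
                             ),
                             expr_multiplier_by_pattern = c(
                               narrow_peak = 1.2,
                               upstream_extended = 1.5,
                               downstream_extended = 2.51,
                               broad_symmetric = 1.8,
                               unmarked = 1.0
                             ),
                             region_change_sd = 5,
                             tx_noise_sd = 5,
                             expr_meanlog = 3,
                             expr_sdlog = 0.8,
                             sample_noise_sd = 0.2,
                             read_length = 50L,
                             fragment_length = 200L,
                             seed = 1L) {
  cfg <- list(
    n_tss = as.integer(n_tss),
    n_samples_per_group = as.integer(n_samples_per_group),
    bin_width = as.integer(bin_width),
    window = as.integer(window),
    pattern_proportions = pattern_proportions,
    background_depth = background_depth,
    signal_height = signal_height,
    de_prob_by_pattern = de_prob_by_pattern,
    de_down_prob = de_down_prob,
    persist_prob = persist_prob,
    beta_down = beta_down,
    frac_increase_by_region = frac_increase_by_region,
    expr_multiplier_by_pattern = expr_multiplier_by_pattern,
    region_change_sd = region_change_sd,
    tx_noise_sd = tx_noise_sd,
    expr_meanlog = expr_meanlog,
    expr_sdlog = expr_sdlog,
    sample_noise_sd = sample_noise_sd,
    read_length = as.integer(read_length),
    fragment_length = as.integer(fragment_length),
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  lbl <- c(pattern_labels(), "unmarked")
  if (cfg$n_tss < 1L) stop("n_tss must be at least 1")
  if (cfg$n_samples_per_group < 1L) stop("need at least one sample per group")
  if (cfg$background_depth <= 0) stop("background_depth must be positive")
  if (cfg$signal_height < 0) stop("signal_height must be non-negative")
  p <- cfg$pattern_proportions
  if (!setequal(names(p), lbl)) {
    stop("pattern_proportions must be named over: ", paste(lbl, collapse = ", "))
  }
  cfg$pattern_proportions <- p[lbl]
  if (abs(sum(p) - 1) > 1e-9) stop("pattern_proportions must sum to 1")
  probs <- c(
    p, cfg$de_prob_by_pattern, cfg$de_down_prob, cfg$persist_prob,
    cfg$frac_increase_by_region
  )
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (!setequal(names(cfg$de_prob_by_pattern), lbl)) {
    stop("de_prob_by_pattern must be named over the pattern universe")
  }
  cfg$de_prob_by_pattern <- cfg$de_prob_by_pattern[lbl]
  if (!setequal(names(cfg$expr_multiplier_by_pattern), lbl)) {
    stop("expr_multiplier_by_pattern must be named over the pattern universe")
  }
  cfg$expr_multiplier_by_pattern <- cfg$expr_multiplier_by_pattern[lbl]
  if (!setequal(names(cfg$frac_increase_by_region),
                c("downstream", "tss", "upstream"))) {
    stop("frac_increase_by_region must name downstream, tss, upstream")
  }
  cfg$frac_increase_by_region <-
    cfg$frac_increase_by_region[c("downstream", "tss", "upstream")]
  n_bins <- diff(cfg$window) / cfg$bin_width
  if (n_bins != 41L) {
    stop("window/bin_width must yield exactly 41 bins, got ", n_bins)
  }
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic TSS cohort configuration\n")
  cat(sprintf("  %d TSSs, %d samples/group, seed %d\n",
              x$n_tss, x$n_samples_per_group, x$seed))
  cat(sprintf("  bins: %d bp over %d..%d bp\n",
              x$bin_width, x$window[1], x$window[2]))
  cat("  pattern proportions:\n")
  print(round(x$pattern_proportions, 3))
  invisible(x)
}

#' Pattern proportions conditional on carrying a confident pattern
#'
#' @param config A [generator_config()].
#' @return Named numeric over the four patterns, summing to 1.
#' @export
classified_proportions <- function(config) {
  p <- config$pattern_proportions[pattern_labels()]
  p / sum(p)
}
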