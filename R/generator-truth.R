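#' Draw breadth-pattern labels for a synthetic cohort
#'
#' @param n Number of TSSs to draw.
#' @param config A [generator_config()].
#' @param classified_only If `TRUE`, draw only from the four confident
#'   patterns (with proportions conditional on being classified).
#' @param seed Integer seed; defaults to the config seed.
#' @return Factor of labels with levels [pattern_labels()] plus `unmarked`.
#' @export
sample_pattern_labels <- function(n, config, classified_only = FALSE,
                                  seed = config$seed) {
  levels <- c(pattern_labels(), "unmarked")
  p <- if (classified_only) {
    c(classified_proportions(config), unmarked = 0)
  } else {
    config$pattern_proportions[levels]
  }
  set.seed(seed)
  factor(sample(levels, n, replace = TRUE, prob = p[levels]), levels = levels)
}

#' Re-draw labels for the disease condition under pattern persistence
#'
#' Narrow-peak TSSs never switch. Each other patterned TSS keeps its label
#' with probability `persist_prob`; a switcher moves uniformly to one of the
#' other two non-narrow patterns (never to narrow). Unmarked TSSs stay
#' unmarked.
#'
#' @param labels Factor from [sample_pattern_labels()].
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return Factor of disease-condition labels, same levels.
#' @export
disease_pattern_labels <- function(labels, config, seed = config$seed + 1L) {
  set.seed(seed)
  out <- as.character(labels)
  nonnarrow <- setdiff(pattern_labels(), "narrow_peak")
  movable <- out %in% nonnarrow
  switch_flag <- movable & stats::runif(length(out)) > config$persist_prob
  if (any(switch_flag)) {
    cur <- out[switch_flag]
    out[switch_flag] <- vapply(cur, function(lab) {
      sample(setdiff(nonnarrow, lab), 1L)
    }, character(1))
  }
  factor(out, levels = levels(labels))
}

#' Generate the ground truth of a synthetic cohort
#'
#' Draws, per TSS/gene: the control and disease breadth patterns, the
#' differential-transcription state, percent H3K4me3 changes at the three
#' analysis regions, and the percent transcription change implied by the
#' downstream coupling. Region-change magnitudes are half-normal with scale
#' `region_change_sd`; signs follow `frac_increase_by_region` for DE-up
#' genes (mirrored for DE-down genes) and are symmetric otherwise. The
#' transcription change is `beta_down` times the downstream change plus
#' Gaussian noise.
#'
#' @param config A [generator_config()].
#' @param n Cohort size (defaults to `config$n_tss`).
#' @param classified_only Restrict the truth labels to the four patterns.
#' @param seed Integer seed.
#' @return A data.frame of class `"synthetic_truth"` with one row per gene
#'   and the config stored in `attr(, "config")`.
#' @export
generate_truth <- function(config, n = config$n_tss, classified_only = FALSE,
                           seed = config$seed) {
  if (n < 1L) stop("n_tss must be at least 1")
  pattern_ctrl <- sample_pattern_labels(n, config, classified_only, seed = seed)
  pattern_dis <- disease_pattern_labels(pattern_ctrl, config, seed = seed + 1L)

  set.seed(seed + 2L)
  p_up <- config$de_prob_by_pattern[as.character(pattern_ctrl)]
  de_up <- stats::runif(n) < p_up
  de_down <- !de_up & stats::runif(n) < config$de_down_prob
  de <- factor(
    ifelse(de_up, "increased", ifelse(de_down, "decreased", "neither")),
    levels = c("increased", "decreased", "neither")
  )

  fri <- config$frac_increase_by_region
  draw_region <- function(p_plus) {
    mag <- abs(stats::rnorm(n, 0, config$region_change_sd))
    p <- rep(0.5, n)
    p[de_up] <- p_plus
    p[de_down] <- 1 - p_plus
    sign <- ifelse(stats::runif(n) < p, 1, -1)
    sign * mag
  }
  pct_down <- draw_region(fri[["downstream"]])
  pct_tss <- draw_region(fri[["tss"]])
  pct_up <- draw_region(fri[["upstream"]])
  pct_tx <- config$beta_down * pct_down + stats::rnorm(n, 0, config$tx_noise_sd)

  truth <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    pattern_control = pattern_ctrl,
    pattern_disease = pattern_dis,
    de = de,
    pct_change_upstream = pct_up,
    pct_change_tss = pct_tss,
    pct_change_downstream = pct_down,
    pct_change_tx = pct_tx,
    stringsAsFactors = FALSE
  )
  attr(truth, "config") <- config
  class(truth) <- c("synthetic_truth", "data.frame")
  truth
}

#' Convert truth labels to a pattern-call table
#'
#' Useful when the association statistics are to be run on the generative
#' labels themselves rather than on labels recovered by the classifier.
#'
#' @param truth A [generate_truth()] result.
#' @param condition `"control"` or `"disease"`.
#' @return A pattern-call data.frame (`gene_id`, `label`, unit posteriors).
#' @export
truth_calls <- function(truth, condition = c("control", "disease")) {
  condition <- match.arg(condition)
  lab <- if (condition == "control") truth$pattern_control else truth$pattern_disease
  data.frame(
    gene_id = truth$gene_id,
    label = factor(as.character(lab), levels = all_labels()),
    posterior_upstream_extended = 1,
    posterior_downstream_extended = 1,
    stringsAsFactors = FALSE
  )
}
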