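#' Simulate per-sample expression and a differential-transcription table
#'
#' Baseline per-gene expression is log-normal; the truth label's linear
#' multiplier (relative to the unmarked baseline) scales every sample of the
#' gene, and disease samples are additionally scaled by the gene's percent
#' transcription change. Per-sample log-scale noise is Gaussian. The
#' differential table carries the generative percent transcription change,
#' a p-value drawn consistently with the generative DE state (U(0, 0.01)
#' for DE genes, U(0.01, 1) otherwise) and the generative DE flag.
#'
#' @param truth A [generate_truth()] table.
#' @param config The [generator_config()] the truth was generated from.
#' @param seed Integer seed.
#' @return List with `expression_control` and `expression_disease` (gene x
#'   sample matrices, linear scale) and `differential` (data.frame:
#'   `gene_id`, `mean_control`, `mean_disease`, `pct_change`, `p_value`,
#'   `de`).
#' @export
generate_expression <- function(truth, config, seed = config$seed + 500L) {
  cfg_echo <- attr(truth, "config")
  if (!is.null(cfg_echo) && !identical(cfg_echo$seed, config$seed)) {
    stop("truth table was generated from a different config (seed mismatch)")
  }
  n <- nrow(truth)
  S <- config$n_samples_per_group
  set.seed(seed)
  baseline <- stats::rnorm(n, config$expr_meanlog, config$expr_sdlog)
  mult <- config$expr_multiplier_by_pattern[as.character(truth$pattern_control)]
  noise <- function() {
    matrix(stats::rnorm(n * S, 0, config$sample_noise_sd), n, S)
  }
  ctrl <- mult * exp(baseline + noise())
  dis <- mult * exp(baseline + noise()) * (1 + truth$pct_change_tx / 100)
  dimnames(ctrl) <- list(truth$gene_id, sprintf("ctrl%02d", seq_len(S)))
  dimnames(dis) <- list(truth$gene_id, sprintf("sle%02d", seq_len(S)))

  is_de <- truth$de != "neither"
  p <- numeric(n)
  p[is_de] <- stats::runif(sum(is_de), 0, 0.01)
  p[!is_de] <- stats::runif(sum(!is_de), 0.01, 1)
  differential <- data.frame(
    gene_id = truth$gene_id,
    mean_control = rowMeans(ctrl),
    mean_disease = rowMeans(dis),
    pct_change = truth$pct_change_tx,
    p_value = p,
    de = truth$de,
    stringsAsFactors = FALSE
  )
  list(expression_control = ctrl, expression_disease = dis,
       differential = differential)
}
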