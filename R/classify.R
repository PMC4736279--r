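#' Classify TSS breadth patterns from region summaries
#'
#' Two-component mixtures are fit to the upstream-minus-TSS and
#' downstream-minus-TSS differences over marked TSSs; on each axis the
#' upper-mean component (the small drop) is the "extended" state. A marked
#' TSS is called extended on an axis when the upper-component posterior is
#' at least `confidence`, not-extended when it is at most `1 - confidence`,
#' and is otherwise unclassified. The four joint states map to: narrow peak
#' (neither extended), upstream extended, downstream extended, and broad
#' symmetric (both). Unmarked TSSs never receive a pattern.
#'
#' @param summary Region summary from [summarize_regions()].
#' @param marked Logical vector of marked flags (same order), e.g. from
#'   [select_marked()].
#' @param confidence Per-axis posterior confidence threshold.
#' @param seed Seed passed to the mixture fits.
#' @return Data.frame of class `"pattern_calls"`: `gene_id`, `label`
#'   (factor over [all_labels()]), `posterior_upstream_extended`,
#'   `posterior_downstream_extended`; axis fits in `attr(, "fits")`.
#' @export
classify_patterns <- function(summary, marked, confidence = 0.8, seed = 1L) {
  stopifnot(length(marked) == nrow(summary), confidence > 0.5, confidence <= 1)
  fit_up <- fit_gmm2(summary$up_minus_tss[marked], seed = seed)
  fit_down <- fit_gmm2(summary$down_minus_tss[marked], seed = seed + 1L)

  post_up <- posterior_gmm2(fit_up, summary$up_minus_tss)
  post_down <- posterior_gmm2(fit_down, summary$down_minus_tss)
  axis_state <- function(post) {
    ifelse(post >= confidence, "ext", ifelse(post <= 1 - confidence, "not", NA))
  }
  up <- axis_state(post_up)
  down <- axis_state(post_down)
  label <- rep("unclassified", nrow(summary))
  label[which(up == "not" & down == "not")] <- "narrow_peak"
  label[which(up == "ext" & down == "not")] <- "upstream_extended"
  label[which(up == "not" & down == "ext")] <- "downstream_extended"
  label[which(up == "ext" & down == "ext")] <- "broad_symmetric"
  label[!marked] <- "unmarked"

  out <- data.frame(
    gene_id = summary$gene_id,
    label = factor(label, levels = all_labels()),
    posterior_upstream_extended = post_up,
    posterior_downstream_extended = post_down,
    stringsAsFactors = FALSE
  )
  attr(out, "fits") <- list(upstream = fit_up, downstream = fit_down)
  class(out) <- c("pattern_calls", "data.frame")
  out
}

#' Cohen's kappa for a square contingency table
#'
#' Chance-corrected agreement with the asymptotic one-sided test of
#' kappa > 0 (normal approximation with the null-variance estimate).
#'
#' @param tab Square contingency table of co-classifications.
#' @return List: `kappa`, `percent_agreement`, `p_value`, `n`.
#' @export
cohen_kappa <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == ncol(tab))
  n <- sum(tab)
  if (n == 0) stop("empty contingency table")
  p <- tab / n
  po <- sum(diag(p))
  rowm <- rowSums(p)
  colm <- colSums(p)
  pe <- sum(rowm * colm)
  kappa <- (po - pe) / (1 - pe)
  var0 <- (pe + pe^2 - sum(rowm * colm * (rowm + colm))) / (n * (1 - pe)^2)
  z <- kappa / sqrt(var0)
  list(
    kappa = kappa,
    percent_agreement = 100 * po,
    p_value = stats::pnorm(z, lower.tail = FALSE),
    n = n
  )
}

#' Agreement between two pattern classifications
#'
#' Restricted to TSSs that carry one of the four confident patterns in both
#' classifications; reports the 4x4 contingency table, percent agreement,
#' and Cohen's kappa with its p-value.
#'
#' @param calls_a,calls_b Pattern-call tables sharing gene ids.
#' @return List of class `"pattern_agreement"`: `table`,
#'   `percent_agreement`, `kappa`, `p_value`, `n`.
#' @export
agreement <- function(calls_a, calls_b) {
  m <- merge(calls_a[, c("gene_id", "label")],
             calls_b[, c("gene_id", "label")],
             by = "gene_id", suffixes = c("_a", "_b"))
  keep <- m$label_a %in% pattern_labels() & m$label_b %in% pattern_labels()
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) stop("no TSS carries a confident pattern in both classifications")
  tab <- table(
    factor(as.character(m$label_a), levels = pattern_labels()),
    factor(as.character(m$label_b), levels = pattern_labels())
  )
  k <- cohen_kappa(tab)
  structure(
    list(table = tab, percent_agreement = k$percent_agreement,
         kappa = k$kappa, p_value = k$p_value, n = k$n),
    class = "pattern_agreement"
  )
}

#' @export
print.pattern_agreement <- function(x, ...) {
  cat(sprintf(
    "Pattern agreement on %d TSSs: %.1f%% (kappa = %.3f, p = %.3g)\n",
    x$n, x$percent_agreement, x$kappa, x$p_value
  ))
  print(x$table)
  invisible(x)
}
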