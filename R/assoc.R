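#' Differential-transcription flags from p-values and change signs
#'
#' @param p_value Numeric vector of per-gene p-values.
#' @param pct_change Percent transcription change (sign gives direction).
#' @param alpha Unadjusted significance threshold.
#' @return Factor with levels `increased`, `decreased`, `neither`.
#' @export
de_flags <- function(p_value, pct_change, alpha = 0.01) {
  stopifnot(length(p_value) == length(pct_change))
  out <- ifelse(p_value < alpha & pct_change > 0, "increased",
                ifelse(p_value < alpha & pct_change < 0, "decreased", "neither"))
  factor(out, levels = c("increased", "decreased", "neither"))
}

# genes whose multiple TSSs disagree on the pattern are excluded from
# gene-level association analyses
drop_ambiguous_genes <- function(calls) {
  nlab <- tapply(as.character(calls$label), calls$gene_id,
                 function(x) length(unique(x)))
  bad <- names(nlab)[nlab > 1]
  if (length(bad)) {
    message(length(bad), " gene(s) with conflicting multi-TSS patterns excluded")
    calls <- calls[!calls$gene_id %in% bad, , drop = FALSE]
  }
  calls[!duplicated(calls$gene_id), , drop = FALSE]
}

#' Expression level by breadth pattern
#'
#' Mean expression (linear scale) of the genes in each confident pattern,
#' the percent difference relative to a baseline group, and a two-sided
#' Wilcoxon rank-sum p-value against that baseline.
#'
#' @param expr Gene x sample matrix of linear expression values (rownames =
#'   gene ids), or a data.frame with a `gene_id` column.
#' @param calls Pattern-call table.
#' @param baseline Label of the comparison group (`"unclassified"` for
#'   classifier output; `"unmarked"` when calls come from synthetic truth).
#' @return Data.frame: `label`, `n`, `mean_level`, `pct_diff`, `p_value`.
#' @export
expression_by_pattern <- function(expr, calls, baseline = "unclassified") {
  if (is.data.frame(expr)) {
    rn <- expr$gene_id
    expr <- as.matrix(expr[, setdiff(colnames(expr), "gene_id")])
    rownames(expr) <- rn
  }
  calls <- drop_ambiguous_genes(calls)
  calls <- calls[calls$gene_id %in% rownames(expr), , drop = FALSE]
  level <- rowMeans(expr)[calls$gene_id]
  base_vals <- level[calls$label == baseline]
  if (length(base_vals) == 0) {
    stop("baseline group '", baseline, "' is empty")
  }
  groups <- pattern_labels()
  rows <- lapply(groups, function(g) {
    v <- level[calls$label == g]
    if (length(v) == 0) {
      warning("pattern group '", g, "' is empty; omitted")
      return(NULL)
    }
    data.frame(
      label = g, n = length(v), mean_level = mean(v),
      pct_diff = 100 * (mean(v) / mean(base_vals) - 1),
      p_value = stats::wilcox.test(v, base_vals)$p.value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- c(label = baseline, n = length(base_vals),
                             mean_level = mean(base_vals))
  out
}

#' Detrended between-sample expression variance
#'
#' Removes the dependence of between-sample variance on expression level by
#' a loess fit of log variance on mean log expression; the residual is the
#' level-free variability of each gene.
#'
#' @param expr Gene x sample matrix of linear expression values.
#' @param span Loess span.
#' @return Data.frame: `gene_id`, `mean_log`, `log_var`, `residual`.
#' @export
detrended_variance <- function(expr, span = 0.5) {
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  if (nrow(expr) < 30L) stop("need at least 30 genes for a stable loess fit")
  lx <- log2(pmax(expr, .Machine$double.eps))
  m <- rowMeans(lx)
  v <- apply(lx, 1, stats::var)
  lv <- log2(pmax(v, .Machine$double.eps))
  fit <- stats::loess(lv ~ m, span = span, degree = 2,
                      family = "symmetric", surface = "direct")
  data.frame(
    gene_id = rownames(expr),
    mean_log = m,
    log_var = lv,
    residual = lv - stats::predict(fit, m),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# cross-product odds ratio with Haldane correction for zero cells
# (exact p is computed on the uncorrected table)
odds_ratio_2x2 <- function(a, b, c, d) {
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  list(
    or = (a * d) / (b * c),
    se_log_or = sqrt(1 / a + 1 / b + 1 / c + 1 / d),
    corrected = corrected
  )
}

#' Association between breadth patterns and differential transcription
#'
#' For each confident pattern and DE direction, the 2x2 table of pattern
#' membership against differential status over the classified cohort, the
#' cross-product odds ratio (Haldane-corrected only when a cell is zero),
#' the two-sided Fisher exact p-value, and the log-OR standard error.
#'
#' @param calls Pattern-call table; the universe is its four-pattern genes.
#' @param de Differential table with `gene_id` and `de` columns (or a
#'   factor from [de_flags()] named by gene).
#' @param directions DE directions to test.
#' @return Data.frame: `label`, `direction`, cells `a`..`d`, `or`,
#'   `se_log_or`, `p_value`.
#' @export
pattern_de_fisher <- function(calls, de,
                              directions = c("increased", "decreased")) {
  calls <- drop_ambiguous_genes(calls)
  calls <- calls[calls$label %in% pattern_labels(), , drop = FALSE]
  m <- merge(calls[, c("gene_id", "label")], de[, c("gene_id", "de")],
             by = "gene_id")
  if (nrow(m) == 0) stop("no classified gene has a differential flag")
  rows <- list()
  for (dir in directions) {
    hit <- m$de == dir
    for (g in pattern_labels()) {
      inp <- m$label == g
      a <- sum(inp & hit); b <- sum(inp & !hit)
      c_ <- sum(!inp & hit); d <- sum(!inp & !hit)
      or <- odds_ratio_2x2(a, b, c_, d)
      p <- stats::fisher.test(matrix(c(a, b, c_, d), 2))$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        label = g, direction = dir, a = a, b = b, c = c_, d = d,
        or = or$or, se_log_or = or$se_log_or, p_value = p,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Gene-set overrepresentation of a pattern's genes
#'
#' Upper-tail hypergeometric test of the overlap between a pattern's genes
#' and each gene set, on the background of all genes with detectable signal;
#' the odds ratio is the cross-product ratio of the background 2x2
#' partition, and FDR is Benjamini-Hochberg across the sets tested.
#'
#' @param pattern_genes Character vector of gene ids in the pattern.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param background Character vector: the test background.
#' @return Data.frame: `set`, `n_set`, `N`, `or`, `p_value`, `fdr`, sorted
#'   by p-value.
#' @export
overrepresentation <- function(pattern_genes, gene_sets, background) {
  background <- unique(background)
  if (length(background) == 0) stop("empty background")
  pattern_genes <- intersect(unique(pattern_genes), background)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), background)
    N <- length(intersect(set, pattern_genes))
    a <- N
    b <- length(pattern_genes) - N
    c_ <- length(set) - N
    d <- length(background) - length(pattern_genes) - length(set) + N
    p <- stats::phyper(N - 1, length(set), length(background) - length(set),
                       length(pattern_genes), lower.tail = FALSE)
    data.frame(
      set = nm, n_set = length(set), N = N,
      or = odds_ratio_2x2(a, b, c_, d)$or,
      p_value = p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), , drop = FALSE]
}

#' Read gene sets in GMT format
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
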