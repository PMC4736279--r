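#' Percent change from a log2-unit difference
#'
#' Normalized depth lives on the log2-vs-background scale, so a difference
#' of `d` log2 units is a linear-scale change of `100 * (2^d - 1)` percent:
#' +1 log2 unit is +100 percent, -1 is -50 percent.
#'
#' @param delta Difference in log2 units.
#' @return Percent change on the linear scale.
#' @export
pct_from_log2 <- function(delta) 100 * (2^delta - 1)

#' Per-gene region changes between conditions
#'
#' Joins control and case region summaries by gene, converts the log2
#' differences at the three regions to linear percent changes, and attaches
#' the percent transcription change from the differential table. Genes
#' missing from either side are dropped with a message.
#'
#' @param ctrl_summary,case_summary Region summaries from
#'   [summarize_regions()].
#' @param de Optional differential table (`gene_id`, `pct_change`).
#' @return Data.frame of class `"region_change_table"`: `gene_id`,
#'   `pct_change_upstream`, `pct_change_tss`, `pct_change_downstream`,
#'   and `pct_change_tx` when `de` is given.
#' @export
region_changes <- function(ctrl_summary, case_summary, de = NULL) {
  m <- merge(ctrl_summary, case_summary, by = "gene_id",
             suffixes = c("_ctrl", "_case"))
  dropped <- nrow(ctrl_summary) + nrow(case_summary) - 2 * nrow(m)
  if (dropped > 0) message(dropped, " unmatched gene record(s) dropped")
  out <- data.frame(
    gene_id = m$gene_id,
    pct_change_upstream = pct_from_log2(m$upstream_case - m$upstream_ctrl),
    pct_change_tss = pct_from_log2(m$tss_case - m$tss_ctrl),
    pct_change_downstream = pct_from_log2(m$downstream_case - m$downstream_ctrl),
    stringsAsFactors = FALSE
  )
  if (!is.null(de)) {
    pre <- nrow(out)
    out <- merge(out, de[, c("gene_id", "pct_change")], by = "gene_id")
    names(out)[names(out) == "pct_change"] <- "pct_change_tx"
    if (nrow(out) < pre) message(pre - nrow(out), " gene(s) without transcription data dropped")
  }
  class(out) <- c("region_change_table", "data.frame")
  out
}

#' Region-change table straight from synthetic truth
#'
#' The generator records per-gene percent region changes directly, so the
#' dose-response statistics can be run at the truth level without
#' simulating reads.
#'
#' @param truth A [generate_truth()] table.
#' @return A `"region_change_table"` data.frame incl. `pct_change_tx`.
#' @export
region_change_table <- function(truth) {
  out <- truth[, c("gene_id", "pct_change_upstream", "pct_change_tss",
                   "pct_change_downstream", "pct_change_tx")]
  class(out) <- c("region_change_table", "data.frame")
  out
}

region_cols <- c(
  upstream = "pct_change_upstream",
  tss = "pct_change_tss",
  downstream = "pct_change_downstream"
)

#' Remove the mutual dependence of the three region changes
#'
#' Each region's percent change is regressed (OLS) on the raw changes of
#' the other two regions; the residual plus the region's grand mean is
#' stored, so "increase" and "decrease" keep their sign meaning. If the two
#' covariates are collinear the fit falls back to a single regressor with a
#' warning.
#'
#' @param table A region-change table.
#' @return The table with `resid_upstream`, `resid_tss`,
#'   `resid_downstream` columns added.
#' @export
residualize <- function(table) {
  if (nrow(table) < 30L) stop("need at least 30 genes to residualize")
  for (r in names(region_cols)) {
    y <- table[[region_cols[[r]]]]
    others <- table[, region_cols[setdiff(names(region_cols), r)], drop = FALSE]
    X <- as.matrix(others)
    fit <- stats::lm(y ~ X)
    if (anyNA(stats::coef(fit))) {
      warning("collinear region changes; residualizing '", r,
              "' on a single regressor")
      fit <- stats::lm(y ~ X[, 1])
    }
    table[[paste0("resid_", r)]] <- stats::residuals(fit) + mean(y)
  }
  table
}

#' Binned dose-response of transcription on region H3K4me3 change
#'
#' Genes are binned by their percent H3K4me3 change at one region; per bin
#' the mean percent transcription change, its standard error over genes and
#' the gene count are reported, and a least-squares line is fit to the bin
#' means over the 1..10 percent range (empty bins omitted).
#'
#' @param table A region-change table with `pct_change_tx` (and residual
#'   columns when `residualized = TRUE`).
#' @param region `"upstream"`, `"tss"` or `"downstream"`.
#' @param residualized Bin by residualized changes?
#' @param bin_edges Bin edges in percent (defaults to unit bins centered on
#'   the integers -10..10).
#' @param slope_range Range of bin centers entering the slope fit.
#' @return List of class `"response_curve"`: `curve` (data.frame `center`,
#'   `mean_tx`, `se`, `n`), `slope`, `slope_se`, `region`.
#' @export
response_curve <- function(table, region = c("downstream", "tss", "upstream"),
                           residualized = TRUE,
                           bin_edges = seq(-10.5, 10.5, by = 1),
                           slope_range = c(1, 10)) {
  region <- match.arg(region)
  col <- if (residualized) paste0("resid_", region) else region_cols[[region]]
  if (is.null(table[[col]])) stop("missing column: ", col)
  x <- table[[col]]
  y <- table$pct_change_tx
  centers <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  idx <- findInterval(x, bin_edges, rightmost.closed = TRUE)
  keep <- idx >= 1 & idx <= length(centers)
  agg <- tapply(y[keep], factor(idx[keep], levels = seq_along(centers)),
                function(v) c(mean(v), stats::sd(v) / sqrt(length(v)), length(v)))
  curve <- data.frame(
    center = centers,
    mean_tx = vapply(agg, function(v) if (is.null(v)) NA_real_ else v[1], 1),
    se = vapply(agg, function(v) if (is.null(v)) NA_real_ else v[2], 1),
    n = vapply(agg, function(v) if (is.null(v)) 0 else v[3], 1),
    row.names = NULL
  )
  fitdat <- curve[curve$n > 0 & curve$center >= slope_range[1] &
                    curve$center <= slope_range[2], ]
  fit <- stats::lm(mean_tx ~ center, data = fitdat)
  structure(
    list(curve = curve,
         slope = unname(stats::coef(fit)[2]),
         slope_se = unname(sqrt(diag(stats::vcov(fit)))[2]),
         region = region),
    class = "response_curve"
  )
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf(
    "Dose-response at %s region: slope %.3f %%/%% (SE %.3f) over bins %g..%g\n",
    x$region, x$slope, x$slope_se,
    min(x$curve$center[x$curve$n > 0]), max(x$curve$center[x$curve$n > 0])
  ))
  invisible(x)
}

#' Fraction of genes with increased region H3K4me3
#'
#' For a gene list (typically the DE-up genes), the fraction with a
#' positive (residualized) change at each region, with binomial standard
#' errors.
#'
#' @param table A region-change table (residualized when
#'   `residualized = TRUE`).
#' @param genes Character vector of gene ids (must be in the table).
#' @param residualized Use residualized changes?
#' @return Data.frame: `region`, `n`, `fraction`, `se`.
#' @export
fraction_increased <- function(table, genes, residualized = TRUE) {
  genes <- intersect(genes, table$gene_id)
  if (length(genes) == 0) stop("empty gene list")
  sub <- table[table$gene_id %in% genes, , drop = FALSE]
  rows <- lapply(names(region_cols), function(r) {
    col <- if (residualized) paste0("resid_", r) else region_cols[[r]]
    if (is.null(sub[[col]])) stop("missing column: ", col)
    f <- mean(sub[[col]] > 0)
    data.frame(region = r, n = nrow(sub), fraction = f,
               se = sqrt(f * (1 - f) / nrow(sub)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Zero-centered region-change summaries for external gene lists
#'
#' Region changes are centered so the all-gene average is zero at each
#' region, then averaged within each list, with one-sample t standard
#' errors. This is the summary used to ask whether an externally defined
#' gene list (e.g. genes up-regulated in another disease) shows a
#' region-specific H3K4me3 shift.
#'
#' @param table A region-change table.
#' @param gene_lists Named list of character vectors.
#' @param residualized Use residualized changes?
#' @return Data.frame: `list`, `region`, `n`, `mean_change`, `se`.
#' @export
external_geneset_summary <- function(table, gene_lists, residualized = FALSE) {
  rows <- list()
  for (r in names(region_cols)) {
    col <- if (residualized) paste0("resid_", r) else region_cols[[r]]
    if (is.null(table[[col]])) stop("missing column: ", col)
    centered <- table[[col]] - mean(table[[col]])
    names(centered) <- table$gene_id
    for (nm in names(gene_lists)) {
      g <- intersect(gene_lists[[nm]], table$gene_id)
      if (length(g) < 5) {
        warning("gene list '", nm, "' overlaps fewer than 5 table genes")
      }
      if (length(g) == 0) next
      v <- centered[g]
      rows[[length(rows) + 1L]] <- data.frame(
        list = nm, region = r, n = length(v), mean_change = mean(v),
        se = stats::sd(v) / sqrt(length(v)),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
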