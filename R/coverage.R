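#' Extend reads to the expected fragment length
#'
#' Each read keeps its 5' start and is extended toward its 3' end to
#' `target_len` bp, the standard surrogate for the sequenced fragment in
#' single-end ChIP-seq. Records without a strand cannot be oriented and are
#' dropped with a warning.
#'
#' @param reads BED-like data.frame with `chrom`, `start`, `end` (0-based,
#'   half-open) and `strand`.
#' @param target_len Target fragment length in bp.
#' @return The extended intervals, same columns.
#' @export
extend_reads <- function(reads, target_len = 200L) {
  ok <- reads$strand %in% c("+", "-")
  if (!all(ok)) {
    warning(sum(!ok), " read(s) without strand dropped before extension")
    reads <- reads[ok, , drop = FALSE]
  }
  plus <- reads$strand == "+"
  reads$end[plus] <- reads$start[plus] + target_len
  reads$start[!plus] <- pmax(reads$end[!plus] - target_len, 0L)
  reads
}

#' Bin per-base coverage around TSSs
#'
#' Computes the mean per-base coverage of each of the 41 bins of the
#' TSS-relative grid (see [bin_grid()]), oriented in the direction of
#' transcription: for a minus-strand TSS the bin order is mirrored so the
#' last column is always downstream. Bin j of a plus-strand TSS at 0-based
#' position p covers genomic bases `[p + start_j, p + end_j)`; for a
#' minus-strand TSS it covers `[p - end_j, p - start_j)`, the exact mirror
#' image. Bins truncated by a contig edge are averaged over their in-range
#' bases and flagged.
#'
#' @param reads Extended intervals from [extend_reads()] (or any BED-like
#'   coverage intervals).
#' @param tss TSS annotation data.frame: `gene_id`, `chrom`, `tss_pos`
#'   (0-based), `strand`.
#' @param bin_width,n_bins Grid parameters.
#' @return Numeric matrix (TSS x bins), rownames = gene ids, with a logical
#'   `truncated` attribute per TSS.
#' @export
bin_depth <- function(reads, tss, bin_width = 50L, n_bins = 41L) {
  stopifnot(!anyDuplicated(tss$gene_id), all(tss$tss_pos >= 0))
  grid <- bin_grid(bin_width, n_bins)
  gr <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(reads$start + 1L, reads$end)
  )
  covs <- GenomicRanges::coverage(gr)

  mat <- matrix(0, nrow(tss), n_bins,
                dimnames = list(tss$gene_id, paste0("bin", seq_len(n_bins))))
  truncated <- logical(nrow(tss))
  for (ch in unique(tss$chrom)) {
    rows <- which(tss$chrom == ch)
    cov <- if (ch %in% names(covs)) covs[[ch]] else S4Vectors::Rle(0L, 0L)
    clen <- length(cov)
    p <- tss$tss_pos[rows]
    plus <- tss$strand[rows] == "+"
    # 1-based inclusive genomic bin bounds, TSS x bins
    lo <- outer(p, grid$start, function(pp, s) pp + s + 1L)
    hi <- outer(p, grid$end, function(pp, e) pp + e)
    if (any(!plus)) {
      lo[!plus, ] <- outer(p[!plus], grid$end, function(pp, e) pp - e + 1L)
      hi[!plus, ] <- outer(p[!plus], grid$start, function(pp, s) pp - s)
    }
    need <- max(hi)
    if (clen < need) {           # zero coverage beyond the last read
      cov <- c(cov, S4Vectors::Rle(0L, need - clen))
    }
    clo <- pmax(lo, 1L)          # truncation only at the contig start
    chi <- hi
    truncated[rows] <- rowSums(clo != lo) > 0
    keep <- chi >= clo
    vals <- numeric(length(clo))
    if (any(keep)) {
      v <- IRanges::Views(
        cov, IRanges::IRanges(as.vector(clo[keep]), as.vector(chi[keep]))
      )
      vals[keep] <- IRanges::viewSums(v)
    }
    mat[rows, ] <- matrix(vals / bin_width, nrow = length(rows))
  }
  attr(mat, "truncated") <- truncated
  mat
}

#' Normalize profile matrices between samples and against input background
#'
#' Each ChIP sample is scaled by its own background level, estimated from
#' the matched input-control matrix (the median bin value, a robust
#' library-size proxy), and expressed on the log2-vs-background scale: 0 is
#' background, +1.0 is exactly two-fold above background and -1.0 two-fold
#' below. Values are floored so zero-coverage bins stay finite. The group
#' matrix is the mean of the per-sample normalized matrices.
#'
#' @param sample_mats A matrix or list of matrices from [bin_depth()], one
#'   per ChIP sample.
#' @param input_mats Matching input-control matrix or list of matrices.
#' @param floor Lower bound for normalized values, log2 units.
#' @return The group-level normalized matrix (TSS x 41), log2 units, with
#'   the per-sample background estimates in `attr(, "background")`.
#' @export
normalize_and_subtract <- function(sample_mats, input_mats, floor = -3) {
  if (is.matrix(sample_mats)) sample_mats <- list(sample_mats)
  if (is.matrix(input_mats)) input_mats <- list(input_mats)
  if (length(sample_mats) != length(input_mats)) {
    stop("need one input-control matrix per sample")
  }
  if (length(sample_mats) < 1L) stop("need at least one sample")
  nm <- names(sample_mats)
  if (is.null(nm)) nm <- paste0("sample", seq_along(sample_mats))
  bg <- vapply(input_mats, function(m) stats::median(m), numeric(1))
  bad <- which(!is.finite(bg) | bg <= 0)
  if (length(bad)) {
    stop("zero or invalid background estimate for sample(s): ",
         paste(nm[bad], collapse = ", "))
  }
  norm <- mapply(function(m, b) {
    pmax(log2(pmax(m, 0) / b), floor)
  }, sample_mats, bg, SIMPLIFY = FALSE)
  out <- Reduce(`+`, norm) / length(norm)
  attr(out, "background") <- stats::setNames(bg, nm)
  attr(out, "truncated") <- attr(sample_mats[[1]], "truncated")
  out
}

#' Summarize the three analysis regions of a profile matrix
#'
#' Region means are averages over the bins whose centers fall inside the
#' region; the two breadth statistics are the upstream-minus-TSS and
#' downstream-minus-TSS differences.
#'
#' @param mat Normalized 41-column matrix (rownames = gene ids).
#' @param bin_width Bin width in bp.
#' @param regions Region list from [region_defaults()].
#' @return Data.frame: `gene_id`, `tss`, `upstream`, `downstream`,
#'   `up_minus_tss`, `down_minus_tss`.
#' @export
summarize_regions <- function(mat, bin_width = 50L,
                              regions = region_defaults()) {
  if (ncol(mat) != 41L) stop("expected a 41-column profile matrix")
  grid <- bin_grid(bin_width, ncol(mat))
  mean_over <- function(r) {
    rowMeans(mat[, region_bin_index(r, grid), drop = FALSE])
  }
  tssm <- mean_over(regions$tss)
  up <- mean_over(regions$upstream)
  down <- mean_over(regions$downstream)
  data.frame(
    gene_id = rownames(mat),
    tss = tssm, upstream = up, downstream = down,
    up_minus_tss = up - tssm,
    down_minus_tss = down - tssm,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
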