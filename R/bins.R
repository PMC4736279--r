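#' TSS-relative bin grid
#'
#' The profile matrix uses 41 bins of 50 bp spanning -1025..+1025 bp around
#' the TSS in the direction of transcription, with bin 21 centered on the TSS
#' itself. Offsets are 0-based and half-open: bin j covers transcription-
#' relative offsets `[50*(j - 21) - 25, 50*(j - 21) + 25)`.
#'
#' @param bin_width Bin width in bp.
#' @param n_bins Number of bins (odd, so one bin is TSS-centered).
#' @return A data.frame with columns `start`, `end` (half-open, 0-based,
#'   TSS-relative) and `center`.
#' @export
bin_grid <- function(bin_width = 50L, n_bins = 41L) {
  stopifnot(n_bins %% 2L == 1L, bin_width > 0L)
  mid <- (n_bins + 1L) / 2L
  center <- bin_width * (seq_len(n_bins) - mid)
  data.frame(
    start = center - bin_width / 2L,
    end = center + bin_width / 2L,
    center = center
  )
}

#' Analysis region boundaries
#'
#' The three regions summarized from each profile: the TSS region (-250..+250),
#' an upstream region and a downstream region (+600..+700). Two upstream
#' conventions are in circulation for this analysis (-500..-400 and
#' -400..-300); the first is the default, the second is selectable.
#'
#' @param upstream Either `"-500:-400"` (default) or `"-400:-300"`.
#' @return Named list of `c(lo, hi)` pairs in bp (bin centers inside the
#'   closed interval belong to the region).
#' @export
region_defaults <- function(upstream = c("-500:-400", "-400:-300")) {
  upstream <- match.arg(upstream)
  up <- if (upstream == "-500:-400") c(-500, -400) else c(-400, -300)
  list(tss = c(-250, 250), upstream = up, downstream = c(600, 700))
}

# indices of bins whose centers fall inside [lo, hi]
region_bin_index <- function(region, grid) {
  which(grid$center >= region[1] & grid$center <= region[2])
}
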