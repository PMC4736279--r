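#' Read and write BED6 read placements
#'
#' Thin wrappers over rtracklayer keeping the package-internal BED-like
#' data.frame convention (0-based half-open `start`/`end`).
#'
#' @param reads BED-like data.frame (`chrom`, `start`, `end`, `name`,
#'   `score`, `strand`).
#' @param path File path.
#' @return `read_bed()` returns a BED-like data.frame.
#' @export
write_bed <- function(reads, path) {
  gr <- GenomicRanges::GRanges(
    reads$chrom,
    IRanges::IRanges(reads$start + 1L, reads$end),
    strand = ifelse(reads$strand %in% c("+", "-"), reads$strand, "*")
  )
  S4Vectors::mcols(gr)$name <- if (is.null(reads$name)) "." else reads$name
  S4Vectors::mcols(gr)$score <- if (is.null(reads$score)) 0L else reads$score
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = if (!is.null(gr$name)) gr$name else ".",
    score = if (!is.null(gr$score)) gr$score else 0L,
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Read a TSS annotation from BED
#'
#' Expects single-base BED records whose start is the 0-based TSS position,
#' name the gene id and strand the direction of transcription.
#'
#' @param path BED file path.
#' @return TSS annotation data.frame (`gene_id`, `chrom`, `tss_pos`,
#'   `strand`).
#' @export
read_tss_bed <- function(path) {
  b <- read_bed(path)
  if (!all(b$strand %in% c("+", "-"))) stop("TSS records must be stranded")
  if (anyDuplicated(b$name)) stop("TSS gene ids must be unique")
  data.frame(gene_id = b$name, chrom = b$chrom, tss_pos = b$start,
             strand = b$strand, stringsAsFactors = FALSE)
}

#' Write a TSS annotation as BED
#' @param tss TSS annotation data.frame.
#' @param path Output path.
#' @export
write_tss_bed <- function(tss, path) {
  write_bed(data.frame(
    chrom = tss$chrom, start = tss$tss_pos, end = tss$tss_pos + 1L,
    name = tss$gene_id, score = 0L, strand = tss$strand,
    stringsAsFactors = FALSE
  ), path)
}

#' Read and write profile matrices as TSV
#'
#' @param mat Profile matrix (rownames = gene ids).
#' @param path File path.
#' @return `read_profile_matrix()` returns the matrix.
#' @export
write_profile_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a data.frame as TSV
#' @param x Data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' Read a TSV into a data.frame
#' @param path File path.
#' @export
read_tsv <- function(path) {
  data.table::fread(path, sep = "\t", data.table = FALSE)
}
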