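#' Built-in toy position weight matrices
#'
#' Three near-deterministic PWMs used as generator defaults: an SP1-like
#' GC-box, an AP-1-like heptamer and a palindromic MluI-site hexamer
#' (useful for strand-symmetry checks). Consensus bases carry probability
#' `1 - 3 * eps`.
#'
#' @param eps Off-consensus probability per base.
#' @return Named list of `pwm` objects.
#' @export
toy_pwms <- function(eps = 0.01) {
  make <- function(id, consensus) {
    L <- nchar(consensus)
    m <- matrix(eps, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    b <- strsplit(consensus, "")[[1]]
    for (i in seq_len(L)) m[i, b[i]] <- 1 - 3 * eps
    pwm(m, id)
  }
  list(
    SP1_like = make("SP1_like", "GGGCGGGG"),
    AP1_like = make("AP1_like", "TGACTCA"),
    PAL6 = make("PAL6", "ACGCGT")
  )
}

#' Simulate promoter sequences with planted motif occurrences
#'
#' Generates a uniform-random -1..+1 kb promoter window per TSS (the TSS at
#' the central base) and plants exact consensus occurrences of each motif at
#' Poisson rates that may differ by breadth pattern. Planted occurrences are
#' recorded as ground truth with TSS-relative positions (position of the
#' motif's first base on the forward/transcription strand; reverse-strand
#' plants insert the reverse complement but are recorded at the forward
#' coordinate).
#'
#' @param config A [generator_config()].
#' @param truth Optional [generate_truth()] table (for per-pattern rates).
#' @param pwms Named list of [pwm()] objects (default [toy_pwms()]).
#' @param plant_rate_by_pattern Expected planted occurrences per promoter
#'   per motif, named over the pattern universe. A single unnamed number is
#'   recycled to all labels.
#' @param flank Half-width of the promoter window in bp.
#' @param seed Integer seed.
#' @return List with `sequences` (a [Biostrings::DNAStringSet], names =
#'   gene ids), `pwms`, and `planted` (data.frame: `gene_id`, `motif`,
#'   `position` TSS-relative, `strand`).
#' @export
generate_motif_data <- function(config, truth = NULL, pwms = toy_pwms(),
                                plant_rate_by_pattern = c(
                                  narrow_peak = 1.0,
                                  upstream_extended = 0.6,
                                  downstream_extended = 0.6,
                                  broad_symmetric = 0.6,
                                  unmarked = 0.3
                                ),
                                flank = 1000L, seed = config$seed + 900L) {
  if (is.null(truth)) truth <- generate_truth(config)
  lbl <- c(pattern_labels(), "unmarked")
  if (is.null(names(plant_rate_by_pattern))) {
    plant_rate_by_pattern <- stats::setNames(
      rep_len(plant_rate_by_pattern, length(lbl)), lbl
    )
  }
  stopifnot(all(lbl %in% names(plant_rate_by_pattern)))
  L_win <- 2L * flank + 1L
  max_w <- max(vapply(pwms, function(p) nrow(p$prob), integer(1)))
  if (max_w > L_win) stop("motif longer than the promoter window")

  set.seed(seed)
  n <- nrow(truth)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), L_win, replace = TRUE), collapse = "")
  }, character(1))

  planted <- list()
  for (mo in names(pwms)) {
    cons <- pwm_consensus(pwms[[mo]])
    w <- nchar(cons)
    rate <- plant_rate_by_pattern[as.character(truth$pattern_control)]
    k <- stats::rpois(n, rate)
    for (i in which(k > 0)) {
      # forward-strand start positions, 1-based within the window
      pos <- sample.int(L_win - w + 1L, k[i], replace = FALSE)
      strand <- ifelse(stats::runif(k[i]) < 0.5, "+", "-")
      ins <- ifelse(strand == "+", cons,
                    as.character(Biostrings::reverseComplement(
                      Biostrings::DNAString(cons))))
      for (j in seq_along(pos)) {
        substr(seqs[i], pos[j], pos[j] + w - 1L) <- ins[j]
      }
      planted[[length(planted) + 1L]] <- data.frame(
        gene_id = truth$gene_id[i], motif = mo,
        position = pos - flank - 1L, strand = strand,
        stringsAsFactors = FALSE
      )
    }
  }
  planted <- if (length(planted)) {
    do.call(rbind, planted)
  } else {
    data.frame(gene_id = character(), motif = character(),
               position = integer(), strand = character(),
               stringsAsFactors = FALSE)
  }
  sequences <- Biostrings::DNAStringSet(seqs)
  names(sequences) <- truth$gene_id
  list(sequences = sequences, pwms = pwms, planted = planted)
}
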