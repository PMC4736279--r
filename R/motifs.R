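#' Position weight matrix
#'
#' @param prob L x 4 probability matrix, columns A, C, G, T; rows must sum
#'   to 1 (within 1e-6).
#' @param id Motif identifier.
#' @param background Background base composition (default uniform).
#' @return List of class `"pwm"`: `id`, `prob`, `background`.
#' @export
pwm <- function(prob, id, background = rep(0.25, 4)) {
  prob <- as.matrix(prob)
  if (ncol(prob) != 4) stop("PWM must have 4 columns (A, C, G, T)")
  if (is.null(colnames(prob))) colnames(prob) <- c("A", "C", "G", "T")
  if (nrow(prob) < 4) stop("PWM must be at least 4 positions long")
  if (any(abs(rowSums(prob) - 1) > 1e-6)) stop("PWM rows must sum to 1")
  if (any(prob < 0)) stop("PWM probabilities must be non-negative")
  structure(
    list(id = id, prob = prob,
         background = stats::setNames(background, c("A", "C", "G", "T"))),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%d bp), consensus %s\n",
              x$id, nrow(x$prob), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param x A [pwm()].
#' @return Character string of the per-position argmax bases.
#' @export
pwm_consensus <- function(x) {
  paste(colnames(x$prob)[apply(x$prob, 1, which.max)], collapse = "")
}

# 4 x L log2-odds score matrix (rows A, C, G, T) with pseudocount
pwm_score_matrix <- function(x, pseudocount = 1e-3) {
  p <- t(x$prob) + pseudocount
  p <- sweep(p, 2, colSums(p), `/`)
  log2(p / x$background)
}

rev_comp_matrix <- function(s) {
  # reverse positions, swap A<->T and C<->G
  out <- s[c("T", "G", "C", "A"), rev(seq_len(ncol(s))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

#' Read motifs in minimal MEME text format
#'
#' Parses the `MOTIF` / `letter-probability matrix` blocks of the MEME
#' minimal motif format (the de-facto interchange format for PWM
#' collections).
#'
#' @param path Path to a MEME-format text file.
#' @return Named list of [pwm()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) && bg_at[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    if (length(tok) >= 8) {
      v <- suppressWarnings(as.numeric(tok[c(2, 4, 6, 8)]))
      if (!anyNA(v)) bg <- v
    }
  }
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0) stop("no MOTIF record in ", path)
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- s + grep("^letter-probability matrix",
                    lines[(s + 1):length(lines)])[1]
    w <- sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr])
    w <- as.integer(w)
    rows <- lines[(hdr + 1):(hdr + w)]
    m <- do.call(rbind, lapply(rows, function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }))
    colnames(m) <- c("A", "C", "G", "T")
    out[[id]] <- pwm(m, id, background = bg)
  }
  out
}

#' Write motifs in minimal MEME text format
#'
#' @param pwms Named list of [pwm()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(p$prob)
    ), con)
    apply(p$prob, 1, function(r) {
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4]), con)
    })
    writeLines("", con)
  }
  invisible(path)
}

#' Scan promoter windows for PWM matches
#'
#' Log2-odds scanning of TSS-oriented promoter windows on both strands.
#' A position matches when its score reaches `threshold` times the maximal
#' achievable score of the motif; reverse-complement matches are reported
#' at their forward-strand coordinate, and forward/reverse hits at the same
#' position (palindromes) are counted once. Sequences with more than 10
#' percent N are skipped with a warning (remaining Ns score as A).
#'
#' @param sequences Named [Biostrings::DNAStringSet] (or character vector)
#'   of equal-length windows with the TSS at the central base.
#' @param pwm A [pwm()].
#' @param threshold Fraction of the maximal log-odds score required.
#' @param pseudocount Added to PWM probabilities before log-odds.
#' @return Data.frame: `gene_id`, `motif`, `position` (TSS-relative start
#'   of the forward-strand footprint), `strand`, `score`.
#' @export
scan_pwm <- function(sequences, pwm, threshold = 0.8, pseudocount = 1e-3) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq%05d", seq_along(sequences))
  }
  L <- unique(Biostrings::width(sequences))
  if (length(L) != 1) stop("promoter windows must have equal length")
  if (nrow(pwm$prob) > L) stop("motif longer than the promoter window")
  flank <- (L - 1L) / 2L

  S <- pwm_score_matrix(pwm, pseudocount)
  Src <- rev_comp_matrix(S)
  max_score <- sum(apply(S, 2, max))
  min_needed <- threshold * max_score

  n_frac <- Biostrings::letterFrequency(sequences, "N", as.prob = TRUE)[, 1]
  skip <- n_frac > 0.10
  if (any(skip)) {
    warning(sum(skip), " sequence(s) with >10% N skipped")
  }
  rows <- list()
  for (i in which(!skip)) {
    subject <- sequences[[i]]
    if (n_frac[i] > 0) {
      subject <- Biostrings::DNAString(
        gsub("N", "A", as.character(subject), fixed = TRUE)
      )
    }
    for (dir in c("+", "-")) {
      mat <- if (dir == "+") S else Src
      hits <- Biostrings::matchPWM(mat, subject, min.score = min_needed)
      if (length(hits) == 0) next
      at <- BiocGenerics::start(hits)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = names(sequences)[i],
        motif = pwm$id,
        position = at - flank - 1L,
        strand = dir,
        score = Biostrings::PWMscoreStartingAt(mat, subject, starting.at = at),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(), motif = character(),
                      position = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$position, out$strand), , drop = FALSE]
  dup <- duplicated(out[, c("gene_id", "position")])
  rownames(out) <- NULL
  out[!dup, , drop = FALSE]
}

#' Positional motif enrichment by breadth pattern
#'
#' Match densities (matches per TSS) in 50 bp position bins for each
#' pattern group, divided by the density of a background group, plus the
#' overall window-wide enrichment ratio and the >= 20 percent enrichment
#' flag.
#'
#' @param matches Match table from [scan_pwm()] (one or several motifs).
#' @param calls Pattern-call table covering the scanned TSSs.
#' @param background `"marked"` (all TSSs with H3K4me3, the default) or
#'   `"all"` (every TSS in `calls`).
#' @param bin_width Position bin width, bp.
#' @param flank Window half-width, bp.
#' @param min_ratio Overall ratio required for the enriched flag.
#' @param min_tss Groups with fewer TSSs are suppressed.
#' @return List of class `"motif_enrichment"`: `overall` (per motif x
#'   group: `n_tss`, `matches`, `per_tss`, `ratio`, `enriched`) and
#'   `profile` (per motif x group x bin: `center`, `density`, `ratio`).
#' @export
profile_enrichment <- function(matches, calls, background = c("marked", "all"),
                               bin_width = 50L, flank = 1000L,
                               min_ratio = 1.2, min_tss = 20L) {
  background <- match.arg(background)
  bg_genes <- if (background == "marked") {
    calls$gene_id[calls$label != "unmarked"]
  } else {
    calls$gene_id
  }
  if (length(bg_genes) == 0) stop("empty background group")
  groups <- c(pattern_labels())
  edges <- seq(-flank, flank, by = bin_width)
  centers <- (edges[-1] + edges[-length(edges)]) / 2

  density_of <- function(genes, motif) {
    mm <- matches[matches$gene_id %in% genes & matches$motif == motif, ]
    counts <- tabulate(
      findInterval(mm$position, edges, rightmost.closed = TRUE),
      nbins = length(centers)
    )
    list(per_bin = counts / length(genes),
         total = nrow(mm), per_tss = nrow(mm) / length(genes))
  }

  overall <- list()
  profile <- list()
  for (mo in unique(matches$motif)) {
    bg <- density_of(bg_genes, mo)
    for (g in groups) {
      genes <- calls$gene_id[calls$label == g]
      if (length(genes) < min_tss) {
        warning("group '", g, "' has fewer than ", min_tss,
                " TSSs; profile suppressed")
        next
      }
      d <- density_of(genes, mo)
      if (d$total == 0) {
        warning("zero '", mo, "' matches in group '", g,
                "'; ratio based on small counts")
      }
      ratio <- if (bg$per_tss > 0) d$per_tss / bg$per_tss else NA_real_
      overall[[length(overall) + 1L]] <- data.frame(
        motif = mo, label = g, n_tss = length(genes), matches = d$total,
        per_tss = d$per_tss, ratio = ratio,
        enriched = !is.na(ratio) && ratio >= min_ratio,
        stringsAsFactors = FALSE
      )
      profile[[length(profile) + 1L]] <- data.frame(
        motif = mo, label = g, center = centers,
        density = d$per_bin,
        ratio = ifelse(bg$per_bin > 0, d$per_bin / bg$per_bin, NA_real_),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(overall = do.call(rbind, overall), profile = do.call(rbind, profile)),
    class = "motif_enrichment"
  )
}
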