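# shared fixtures built once per test run

.fixtures <- new.env(parent = emptyenv())

# default-configuration simulation plus its profile-derived summaries,
# reused by the classifier, pipeline and acceptance tests
shared_default_run <- function(seed = 101L) {
  key <- paste0("run", seed)
  if (is.null(.fixtures[[key]])) {
    cfg <- generator_config(seed = seed)
    sim <- simulate_chipseq(cfg)
    summarize_group <- function(chip, input) {
      mats <- lapply(lapply(chip, extend_reads), bin_depth, tss = sim$tss)
      inps <- lapply(lapply(input, extend_reads), bin_depth, tss = sim$tss)
      summarize_regions(normalize_and_subtract(mats, inps))
    }
    sum_ctrl <- summarize_group(sim$chip_control, sim$input_control)
    fit <- fit_gmm2(sum_ctrl$tss, seed = seed)
    marked <- select_marked(fit, sum_ctrl$tss)
    calls <- classify_patterns(sum_ctrl, marked, seed = seed)
    .fixtures[[key]] <- list(cfg = cfg, sim = sim, sum_ctrl = sum_ctrl,
                             marked = marked, calls = calls)
  }
  .fixtures[[key]]
}

# tiny deterministic read table builder
make_reads <- function(chrom, start, end, strand) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = ".", score = 0L, strand = strand,
             stringsAsFactors = FALSE)
}

# brute-force per-base binned coverage for small cases
brute_force_bins <- function(reads, tss, bin_width = 50L, n_bins = 41L) {
  grid <- bin_grid(bin_width, n_bins)
  out <- matrix(0, nrow(tss), n_bins, dimnames = list(tss$gene_id, NULL))
  for (i in seq_len(nrow(tss))) {
    for (j in seq_len(n_bins)) {
      if (tss$strand[i] == "+") {
        bases <- tss$tss_pos[i] + seq(grid$start[j], grid$end[j] - 1)
      } else {
        bases <- tss$tss_pos[i] - seq(grid$start[j] + 1, grid$end[j])
      }
      cov <- vapply(bases, function(b) {
        sum(reads$chrom == tss$chrom[i] & reads$start <= b & reads$end > b)
      }, numeric(1))
      out[i, j] <- mean(cov)
    }
  }
  out
}
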