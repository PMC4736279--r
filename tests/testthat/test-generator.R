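test_that("configuration is validated", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(n_tss = 0), "n_tss")
  expect_error(generator_config(background_depth = 0), "positive")
  bad <- generator_config()
  bad$pattern_proportions["unmarked"] <- 0.5
  expect_error(validate_generator_config <- tssbreadth:::validate_generator_config(bad),
               "sum to 1")
  expect_error(generator_config(window = c(-1000, 1000)), "41 bins")
  expect_equal(nrow(bin_grid()), 41L)
})

test_that("the generator is deterministic given config and seed", {
  cfg <- generator_config(n_tss = 60, seed = 42)
  expect_identical(generate_truth(cfg), generate_truth(cfg))
  expect_identical(simulate_chipseq(cfg), simulate_chipseq(cfg))
  md1 <- generate_motif_data(cfg)
  md2 <- generate_motif_data(cfg)
  expect_identical(as.character(md1$sequences), as.character(md2$sequences))
  expect_identical(md1$planted, md2$planted)
})

test_that("classified-pattern counts follow the configured multinomial", {
  cfg <- generator_config(n_tss = 2000, seed = 5)
  lab <- sample_pattern_labels(2000, cfg, classified_only = TRUE, seed = 5)
  counts <- table(lab)[pattern_labels()]
  expected <- 2000 * classified_proportions(cfg)
  sds <- sqrt(expected * (1 - classified_proportions(cfg)))
  expect_true(all(abs(counts - expected) <= 3 * sds))
})

test_that("archetypes put signal where they should and nowhere else", {
  cfg <- generator_config(n_tss = 200, background_depth = 50, seed = 8,
                          pattern_proportions = c(
                            narrow_peak = 1, upstream_extended = 0,
                            downstream_extended = 0, broad_symmetric = 0,
                            unmarked = 0
                          ))
  grid <- bin_grid()
  # analytic expectation: narrow archetype is background at +600..+650
  ep <- expected_profile("narrow_peak", cfg)
  far_bin <- which(grid$center == 650)   # bin 625..675, past signal + blur
  expect_equal(ep[far_bin], 0, tolerance = 1e-8)
  expect_gt(ep[which(grid$center == 0)], 0.9 * cfg$signal_height)
  # realized, near the zero-noise limit (deep coverage)
  sim <- simulate_chipseq(cfg)
  mats <- lapply(lapply(sim$chip_control, extend_reads), bin_depth, tss = sim$tss)
  inps <- lapply(lapply(sim$input_control, extend_reads), bin_depth, tss = sim$tss)
  m <- normalize_and_subtract(mats, inps)
  expect_lt(abs(mean(m[, far_bin])), 0.05)
  expect_equal(mean(m[, which(grid$center == 0)]), cfg$signal_height,
               tolerance = 0.05)
})

test_that("disease labels follow the persistence rule", {
  cfg <- generator_config(seed = 9)
  lab <- sample_pattern_labels(20000, cfg, classified_only = TRUE, seed = 9)
  dis <- disease_pattern_labels(lab, cfg)
  # narrow never switches, in either direction
  expect_true(all(dis[lab == "narrow_peak"] == "narrow_peak"))
  expect_true(all(lab[dis == "narrow_peak"] == "narrow_peak"))
  nonnarrow <- lab != "narrow_peak"
  switch_rate <- mean(dis[nonnarrow] != lab[nonnarrow])
  se <- sqrt(0.052 * 0.948 / sum(nonnarrow))
  expect_lt(abs(switch_rate - (1 - cfg$persist_prob)), 4 * se)
})

test_that("expression couplings propagate the configured effects", {
  # zero coupling: transcription change independent of downstream change
  cfg0 <- generator_config(n_tss = 5000, beta_down = 0, seed = 13)
  tr0 <- generate_truth(cfg0)
  expect_lt(abs(cor(tr0$pct_change_tx, tr0$pct_change_downstream)), 0.04)
  # flat multipliers: per-pattern mean expression equal within sampling error
  cfg1 <- generator_config(
    n_tss = 4000, seed = 14,
    expr_multiplier_by_pattern = c(
      narrow_peak = 1, upstream_extended = 1, downstream_extended = 1,
      broad_symmetric = 1, unmarked = 1
    )
  )
  tr1 <- generate_truth(cfg1)
  ex1 <- generate_expression(tr1, cfg1)
  mean_by <- tapply(rowMeans(ex1$expression_control),
                    tr1$pattern_control, mean)
  expect_lt(max(mean_by) / min(mean_by), 1.25)
  # region-increase probability for DE-up genes
  cfg2 <- generator_config(n_tss = 8000, seed = 15)
  tr2 <- generate_truth(cfg2)
  up <- tr2$de == "increased"
  f <- mean(tr2$pct_change_downstream[up] > 0)
  se <- sqrt(0.788 * 0.212 / sum(up))
  expect_lt(abs(f - 0.788), 3 * se)
})

test_that("expression generation rejects a foreign truth table", {
  cfg <- generator_config(n_tss = 50, seed = 3)
  other <- generator_config(n_tss = 50, seed = 4)
  tr <- generate_truth(other)
  expect_error(generate_expression(tr, cfg), "different config")
})

test_that("motif planting obeys rates, positions and strands", {
  cfg <- generator_config(n_tss = 120, seed = 31)
  # rate zero plants nothing
  md0 <- generate_motif_data(cfg, plant_rate_by_pattern = 0)
  expect_equal(nrow(md0$planted), 0L)
  # planted occurrences are really in the sequence at the recorded spot
  md <- generate_motif_data(cfg)
  expect_gt(nrow(md$planted), 0)
  flank <- (unique(Biostrings::width(md$sequences)) - 1) / 2
  ok <- vapply(seq_len(nrow(md$planted)), function(k) {
    row <- md$planted[k, ]
    cons <- pwm_consensus(md$pwms[[row$motif]])
    if (row$strand == "-") {
      cons <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
    }
    s <- row$position + flank + 1
    substr(as.character(md$sequences[[row$gene_id]]),
           s, s + nchar(cons) - 1) == cons
  }, logical(1))
  # later plants may overwrite earlier overlapping ones; require near-all
  expect_gt(mean(ok), 0.97)
  # 2x planting rate realizes a ~2x match count
  cfgA <- generator_config(n_tss = 1000, seed = 32,
                           pattern_proportions = c(
                             narrow_peak = 0.5, upstream_extended = 0,
                             downstream_extended = 0.5, broad_symmetric = 0,
                             unmarked = 0
                           ))
  mdA <- generate_motif_data(
    cfgA,
    pwms = toy_pwms()["SP1_like"],
    plant_rate_by_pattern = c(
      narrow_peak = 2, upstream_extended = 1, downstream_extended = 1,
      broad_symmetric = 1, unmarked = 1
    )
  )
  trA <- generate_truth(cfgA)
  nA <- sum(mdA$planted$gene_id %in% trA$gene_id[trA$pattern_control == "narrow_peak"])
  nB <- nrow(mdA$planted) - nA
  ratio <- (nA / sum(trA$pattern_control == "narrow_peak")) /
    (nB / sum(trA$pattern_control == "downstream_extended"))
  se <- ratio * sqrt(1 / nA + 1 / nB)
  expect_lt(abs(ratio - 2), 3 * se)
})

test_that("motifs longer than the window are rejected", {
  cfg <- generator_config(n_tss = 10, seed = 2)
  long <- pwm(matrix(0.25, 30, 4), "long30")
  expect_error(generate_motif_data(cfg, pwms = list(long30 = long), flank = 10),
               "longer than the promoter window")
})
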