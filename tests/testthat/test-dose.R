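mk_summary <- function(ids, tss, up, down) {
  data.frame(gene_id = ids, tss = tss, upstream = up, downstream = down,
             up_minus_tss = up - tss, down_minus_tss = down - tss,
             stringsAsFactors = FALSE)
}

test_that("region changes follow the log2-to-percent scale", {
  expect_equal(pct_from_log2(c(0, 1, -1)), c(0, 100, -50))
  ids <- c("a", "b", "c")
  ctrl <- mk_summary(ids, c(2, 2, 2), c(1, 1, 1), c(1, 1, 1))
  case <- mk_summary(ids, c(2, 2, 2), c(1, 1, 1), c(1, 2, 0))
  tab <- region_changes(ctrl, case)
  expect_equal(tab$pct_change_downstream, c(0, 100, -50))
  expect_equal(tab$pct_change_upstream, c(0, 0, 0))
  # unmatched genes are dropped with a message
  expect_message(
    tab2 <- region_changes(ctrl, case[1:2, ]),
    "unmatched"
  )
  expect_equal(nrow(tab2), 2L)
})

test_that("residualization removes inter-region dependence", {
  set.seed(5)
  n <- 5000
  up <- rnorm(n, 0, 5); ts <- rnorm(n, 1, 5); dn <- rnorm(n, 2, 5)
  tab <- data.frame(gene_id = sprintf("g%05d", 1:n),
                    pct_change_upstream = up, pct_change_tss = ts,
                    pct_change_downstream = dn,
                    pct_change_tx = rnorm(n))
  r <- residualize(tab)
  # independent columns: residualized ~ original
  expect_gt(cor(r$resid_downstream, dn), 0.999)
  expect_equal(mean(r$resid_downstream), mean(dn))
  # orthogonality to the covariates, to machine precision
  expect_lt(abs(cor(r$resid_downstream - mean(dn), up)), 1e-8)
  expect_lt(abs(cor(r$resid_downstream - mean(dn), ts)), 1e-8)
  # perfect dependence: residual collapses to the grand mean
  tab2 <- tab; tab2$pct_change_downstream <- tab2$pct_change_upstream
  r2 <- residualize(tab2)
  expect_lt(sd(r2$resid_downstream), 1e-8)
  # known independent noise is recovered
  eps <- rnorm(n, 0, 2)
  tab3 <- tab; tab3$pct_change_downstream <- tab3$pct_change_upstream + eps
  r3 <- residualize(tab3)
  expect_gt(cor(r3$resid_downstream - mean(r3$resid_downstream), eps), 0.99)
  expect_error(residualize(tab[1:10, ]), "30 genes")
})

test_that("collinear covariates fall back to a single regressor", {
  set.seed(15)
  n <- 100
  up <- rnorm(n)
  tab <- data.frame(gene_id = sprintf("g%03d", 1:n),
                    pct_change_upstream = up, pct_change_tss = up,
                    pct_change_downstream = rnorm(n),
                    pct_change_tx = rnorm(n))
  expect_warning(residualize(tab), "collinear")
})

test_that("response curves aggregate bins and recover the slope", {
  # constant case: one bin holds the exact mean
  tab <- data.frame(gene_id = sprintf("g%03d", 1:50),
                    pct_change_upstream = 0, pct_change_tss = 0,
                    pct_change_downstream = 2, pct_change_tx = 3)
  rc <- response_curve(tab, "downstream", residualized = FALSE)
  expect_equal(rc$curve$mean_tx[rc$curve$center == 2], 3)
  expect_equal(sum(rc$curve$n), 50)
  # orthogonal transcription change: slope near zero
  set.seed(16)
  n <- 5000
  tab2 <- data.frame(gene_id = sprintf("g%05d", 1:n),
                     pct_change_upstream = rnorm(n, 0, 5),
                     pct_change_tss = rnorm(n, 0, 5),
                     pct_change_downstream = rnorm(n, 0, 5),
                     pct_change_tx = rnorm(n, 0, 5))
  rc2 <- response_curve(tab2, "downstream", residualized = FALSE)
  expect_lt(abs(rc2$slope), 3 * rc2$slope_se)
})

test_that("generator slopes are recovered across coupling strengths", {
  for (beta in c(0, 0.5, 1.5, 3)) {
    cfg <- generator_config(n_tss = 5000, beta_down = beta,
                            seed = 100 + round(10 * beta))
    tab <- residualize(region_change_table(generate_truth(cfg)))
    rc <- response_curve(tab, "downstream", residualized = TRUE)
    expect_lt(abs(rc$slope - beta), 2.5 * rc$slope_se)
  }
})

test_that("fraction increased reports per-region binomial summaries", {
  tab <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    pct_change_upstream = 1, pct_change_tss = 1,
                    pct_change_downstream = 1, pct_change_tx = 0)
  r <- fraction_increased(tab, tab$gene_id, residualized = FALSE)
  expect_equal(r$fraction, c(1, 1, 1))
  set.seed(17)
  tab2 <- data.frame(gene_id = sprintf("g%04d", 1:2000),
                     pct_change_upstream = rnorm(2000),
                     pct_change_tss = rnorm(2000),
                     pct_change_downstream = rnorm(2000),
                     pct_change_tx = 0)
  r2 <- fraction_increased(tab2, tab2$gene_id, residualized = FALSE)
  expect_true(all(abs(r2$fraction - 0.5) < 3 * r2$se))
  expect_error(fraction_increased(tab, "nope"), "empty gene list")
})

test_that("external gene-list summaries are zero-centered", {
  set.seed(18)
  n <- 1000
  tab <- data.frame(gene_id = sprintf("g%04d", 1:n),
                    pct_change_upstream = rnorm(n, 3, 4),
                    pct_change_tss = rnorm(n, -1, 4),
                    pct_change_downstream = rnorm(n, 2, 4),
                    pct_change_tx = 0)
  # the all-genes list is exactly zero at every region
  r_all <- external_geneset_summary(tab, list(all = tab$gene_id))
  expect_equal(r_all$mean_change, c(0, 0, 0), tolerance = 1e-12)
  # a random list is near zero
  r_rand <- external_geneset_summary(tab, list(rand = sample(tab$gene_id, 200)))
  expect_true(all(abs(r_rand$mean_change) < 3.5 * r_rand$se))
  # a constructed +5 downstream shift is recovered (minus its dilution
  # of the grand mean)
  sel <- sample(tab$gene_id, 100)
  tab2 <- tab
  tab2$pct_change_downstream[tab2$gene_id %in% sel] <-
    tab2$pct_change_downstream[tab2$gene_id %in% sel] + 5
  r_shift <- external_geneset_summary(tab2, list(shift = sel))
  dn <- r_shift[r_shift$region == "downstream", ]
  expect_lt(abs(dn$mean_change - 5 * (1 - 100 / n)), 4 * dn$se)
  others <- r_shift[r_shift$region != "downstream", ]
  expect_true(all(abs(others$mean_change) < 3.5 * others$se))
  expect_warning(external_geneset_summary(tab, list(tiny = tab$gene_id[1:2])),
                 "fewer than 5")
})
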