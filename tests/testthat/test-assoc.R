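mk_calls <- function(ids, labels) {
  data.frame(gene_id = ids, label = factor(labels, levels = all_labels()),
             stringsAsFactors = FALSE)
}

test_that("differential flags are consistent with p and sign", {
  p <- c(0.001, 0.005, 0.5, 0.009, 0.011)
  chg <- c(10, -5, 8, 0, 20)
  f <- de_flags(p, chg)
  expect_equal(as.character(f),
               c("increased", "decreased", "neither", "neither", "neither"))
  expect_true(all(f[p >= 0.01] == "neither"))
})

test_that("expression summaries report the right percent differences", {
  set.seed(3)
  base <- rexp(50, 1 / 10)
  # pattern group is elementwise exactly double the baseline group
  expr <- rbind(cbind(2 * base, 2 * base, 2 * base),
                cbind(base, base, base))
  rownames(expr) <- sprintf("g%03d", 1:100)
  labels <- rep(c("downstream_extended", "unclassified"), each = 50)
  res <- suppressWarnings(expression_by_pattern(expr, mk_calls(rownames(expr), labels)))
  row <- res[res$label == "downstream_extended", ]
  expect_equal(row$pct_diff, 100, tolerance = 1e-12)
  expect_lt(row$p_value, 0.05)
  # identical distributions: near-zero difference, non-tiny p
  set.seed(4)
  expr2 <- matrix(rexp(400 * 4, 1 / 10), 400, 4,
                  dimnames = list(sprintf("h%03d", 1:400), NULL))
  labels2 <- rep(c("narrow_peak", "unclassified"), each = 200)
  res2 <- suppressWarnings(
    expression_by_pattern(expr2, mk_calls(rownames(expr2), labels2))
  )
  expect_lt(abs(res2$pct_diff[res2$label == "narrow_peak"]), 20)
  expect_gt(res2$p_value[res2$label == "narrow_peak"], 0.001)
})

test_that("genes with conflicting multi-TSS patterns are excluded", {
  expr <- matrix(5, 3, 3, dimnames = list(c("a", "b", "c"), NULL))
  calls <- mk_calls(c("a", "a", "b", "c"),
                    c("narrow_peak", "broad_symmetric", "narrow_peak",
                      "unclassified"))
  expect_message(
    res <- suppressWarnings(expression_by_pattern(expr, calls)),
    "conflicting"
  )
  expect_equal(res$n[res$label == "narrow_peak"], 1L)
})

test_that("variance detrending removes the level dependence", {
  set.seed(9)
  n <- 500
  m <- runif(n, 2, 10)
  # variance an exact smooth function of the mean
  v <- (m / 3)^2
  expr <- t(vapply(seq_len(n), function(i) m[i] + sqrt(v[i]) * scale(rnorm(40))[, 1],
                   numeric(40)))
  expr <- 2^expr   # module works on linear-scale expression
  rownames(expr) <- sprintf("g%03d", 1:n)
  dv <- detrended_variance(expr)
  expect_lt(sd(dv$residual), 0.1)
  expect_lt(abs(mean(dv$residual)), 0.02)
  # a gene with 10x the trend variance shows up as ~log2(10)
  expr2 <- expr
  expr2[1, ] <- 2^(m[1] + sqrt(10 * v[1]) * scale(rnorm(40))[, 1])
  dv2 <- detrended_variance(expr2)
  expect_equal(dv2$residual[1], log2(10), tolerance = 0.35)
  expect_error(detrended_variance(expr[, 1:2]), "3 samples")
  expect_error(detrended_variance(expr[1:10, ]), "30 genes")
})

test_that("Fisher association reproduces hand-computed odds ratios", {
  # cross product of [[10,90],[20,80]] = 0.444...
  ids <- sprintf("g%04d", 1:200)
  labels <- rep(c("narrow_peak", "downstream_extended"), c(100, 100))
  de <- rep("neither", 200)
  de[1:10] <- "increased"          # narrow: 10 up / 90 not
  de[101:120] <- "increased"       # downstream: 20 up / 80 not
  res <- pattern_de_fisher(mk_calls(ids, labels),
                           data.frame(gene_id = ids, de = de),
                           directions = "increased")
  nr <- res[res$label == "narrow_peak", ]
  expect_equal(nr$or, (10 * 80) / (90 * 20), tolerance = 1e-12)
  expect_equal(nr$se_log_or, sqrt(1 / 10 + 1 / 90 + 1 / 20 + 1 / 80))
  expect_equal(nr$p_value,
               fisher.test(matrix(c(10, 90, 20, 80), 2))$p.value)
  # zero cell: Haldane correction keeps OR/SE finite, exact p unchanged
  de0 <- rep("neither", 200); de0[101:120] <- "increased"
  res0 <- pattern_de_fisher(mk_calls(ids, labels),
                            data.frame(gene_id = ids, de = de0),
                            directions = "increased")
  nr0 <- res0[res0$label == "narrow_peak", ]
  expect_true(is.finite(nr0$or) && nr0$or > 0)
  expect_equal(nr0$p_value,
               fisher.test(matrix(c(0, 100, 20, 80), 2))$p.value)
})

test_that("independent flags give odds ratios near one", {
  set.seed(12)
  n <- 10000
  ids <- sprintf("g%05d", 1:n)
  labels <- sample(pattern_labels(), n, replace = TRUE)
  de <- ifelse(runif(n) < 0.15, "increased", "neither")
  res <- pattern_de_fisher(mk_calls(ids, labels),
                           data.frame(gene_id = ids, de = de),
                           directions = "increased")
  expect_true(all(abs(log(res$or)) < 3 * res$se_log_or))
})

test_that("synthetic cohort reproduces the configured DE odds ratios", {
  cfg <- generator_config(seed = 44)
  tr <- generate_truth(cfg, n = 8399, classified_only = TRUE, seed = 44)
  res <- pattern_de_fisher(truth_calls(tr),
                           data.frame(gene_id = tr$gene_id, de = tr$de),
                           directions = "increased")
  dn <- res[res$label == "downstream_extended", ]
  nr <- res[res$label == "narrow_peak", ]
  expect_lt(abs(log(dn$or) - log(2.37)), 2 * dn$se_log_or)
  expect_lt(abs(log(nr$or) - log(0.14)), 2 * nr$se_log_or)
})

test_that("hypergeometric overrepresentation matches exact enumeration", {
  # worked example: background 20, set 5, pattern 8, overlap 4
  bg <- sprintf("g%02d", 1:20)
  set5 <- bg[1:5]
  pattern <- bg[c(1:4, 10:13)]
  res <- overrepresentation(pattern, list(s = set5), bg)
  expect_equal(res$N, 4L)
  expect_equal(res$p_value, 7280 / 125970)
  # brute-force oracle over random small configurations
  choose_p <- function(bgn, k, n, N) {
    sum(vapply(N:min(k, n), function(i) {
      choose(k, i) * choose(bgn - k, n - i)
    }, numeric(1))) / choose(bgn, n)
  }
  set.seed(6)
  for (rep in 1:25) {
    bgn <- sample(8:25, 1)
    bgx <- sprintf("x%02d", 1:bgn)
    k <- sample(2:(bgn - 2), 1)
    n <- sample(2:(bgn - 2), 1)
    set_g <- sample(bgx, k)
    pat_g <- sample(bgx, n)
    N <- length(intersect(set_g, pat_g))
    r <- overrepresentation(pat_g, list(s = set_g), bgx)
    expect_equal(r$p_value, choose_p(bgn, k, n, N), tolerance = 1e-12)
  }
  expect_error(overrepresentation(pattern, list(s = set5), character(0)),
               "empty background")
})

test_that("enrichment odds ratio and FDR behave", {
  set.seed(21)
  bg <- sprintf("g%04d", 1:2000)
  pattern <- sample(bg, 400)
  sets <- lapply(1:20, function(i) sample(bg, 100))
  names(sets) <- paste0("s", 1:20)
  res <- overrepresentation(pattern, sets, bg)
  # independence: overlap near expectation, OR near 1
  expect_lt(abs(mean(log(res$or))), 0.25)
  expect_true(all(res$fdr >= res$p_value - 1e-15))
  # BH is monotone in p after sorting
  expect_true(all(diff(res$fdr[order(res$p_value)]) >= -1e-12))
})

test_that("GMT round trip works", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tsource\tg1\tg2\tg3", "setB\tsource\tg2\tg4"), f)
  gs <- read_gmt(f)
  expect_equal(gs$setA, c("g1", "g2", "g3"))
  expect_equal(gs$setB, c("g2", "g4"))
})
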