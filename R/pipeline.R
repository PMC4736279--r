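#' Default end-to-end run configuration
#'
#' Every tunable threshold of the workflow in one list; any entry can be
#' overridden, and a YAML file with the same keys can be loaded with
#' [yaml::read_yaml()] and passed to [run_breadth_pipeline()].
#'
#' @param seed Integer seed (drives the synthetic cohort when simulating).
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return Named list of class `"run_config"`.
#' @export
default_run_config <- function(seed = 1L, out_dir = NULL) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = TRUE,
    n_tss = 1000L,
    marked_confidence = 0.95,
    pattern_confidence = 0.8,
    de_alpha = 0.01,
    loess_span = 0.5,
    motif_threshold = 0.8,
    log2_floor = -3,
    upstream_region = "-500:-400",
    run_motifs = FALSE
  ), class = "run_config")
}

group_matrix <- function(read_tables, input_tables, tss, floor) {
  ext <- lapply(read_tables, extend_reads)
  mats <- lapply(ext, bin_depth, tss = tss)
  inp <- lapply(lapply(input_tables, extend_reads), bin_depth, tss = tss)
  normalize_and_subtract(mats, inp, floor = floor)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the whole breadth analysis end to end
#'
#' Orchestrates profile building, pattern classification in both
#' conditions, the transcription associations, and the dose-response
#' analysis (plus motif enrichment when requested) over a synthetic cohort,
#' writing per-stage tables and a JSON report when `out_dir` is set. The
#' report records the seed and every threshold used.
#'
#' @param config A [default_run_config()] (or list overriding its keys), or
#'   a path to a YAML file of the same shape.
#' @param sim Optional pre-built [simulate_chipseq()] bundle (otherwise one
#'   is simulated from `config$seed`).
#' @return The report list, invisibly.
#' @export
run_breadth_pipeline <- function(config = default_run_config(), sim = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_run_config()
  config <- utils::modifyList(base, config[!vapply(config, is.null, TRUE)])

  gcfg <- generator_config(n_tss = config$n_tss, seed = config$seed)
  if (is.null(sim)) {
    run_stage("simulate", sim <- simulate_chipseq(gcfg))
  }
  truth <- sim$truth
  regions <- region_defaults(config$upstream_region)

  run_stage("profile", {
    mat_ctrl <- group_matrix(sim$chip_control, sim$input_control, sim$tss,
                             config$log2_floor)
    mat_dis <- group_matrix(sim$chip_disease, sim$input_disease, sim$tss,
                            config$log2_floor)
    sum_ctrl <- summarize_regions(mat_ctrl, regions = regions)
    sum_dis <- summarize_regions(mat_dis, regions = regions)
  })

  run_stage("classify", {
    fit_marked <- fit_gmm2(sum_ctrl$tss, seed = config$seed)
    marked <- select_marked(fit_marked, sum_ctrl$tss,
                            confidence = config$marked_confidence)
    calls_ctrl <- classify_patterns(sum_ctrl, marked,
                                    confidence = config$pattern_confidence,
                                    seed = config$seed)
    fit_marked_dis <- fit_gmm2(sum_dis$tss, seed = config$seed)
    marked_dis <- select_marked(fit_marked_dis, sum_dis$tss,
                                confidence = config$marked_confidence)
    calls_dis <- classify_patterns(sum_dis, marked_dis,
                                   confidence = config$pattern_confidence,
                                   seed = config$seed)
    agree <- agreement(calls_ctrl, calls_dis)
  })

  run_stage("associate", {
    ex <- generate_expression(truth, gcfg)
    # baseline needs a reasonably sized group; well-separated synthetic
    # archetypes leave almost nothing unclassified, so fall back to unmarked
    baseline <- if (sum(calls_ctrl$label == "unclassified") >= 30) {
      "unclassified"
    } else {
      "unmarked"
    }
    expr_sum <- expression_by_pattern(ex$expression_control, calls_ctrl,
                                      baseline = baseline)
    fisher <- pattern_de_fisher(calls_ctrl, ex$differential)
  })

  run_stage("dose_response", {
    chg <- region_changes(sum_ctrl, sum_dis, ex$differential)
    chg <- residualize(chg)
    curve <- response_curve(chg, "downstream", residualized = TRUE)
    de_up <- ex$differential$gene_id[ex$differential$de == "increased"]
    frac <- fraction_increased(chg, de_up)
  })

  motifs <- NULL
  if (isTRUE(config$run_motifs)) {
    run_stage("motifs", {
      md <- generate_motif_data(gcfg, truth)
      hits <- do.call(rbind, lapply(md$pwms, function(p) {
        scan_pwm(md$sequences, p, threshold = config$motif_threshold)
      }))
      motifs <- profile_enrichment(hits, calls_ctrl)
    })
  }

  report <- list(
    seed = config$seed,
    thresholds = config[c("marked_confidence", "pattern_confidence",
                          "de_alpha", "loess_span", "motif_threshold",
                          "log2_floor", "upstream_region")],
    n_tss = nrow(sim$tss),
    n_marked = sum(marked),
    pattern_counts = as.list(table(calls_ctrl$label)),
    agreement = list(percent = agree$percent_agreement, kappa = agree$kappa,
                     p_value = agree$p_value, n = agree$n),
    expression_premium_pct = stats::setNames(
      as.list(expr_sum$pct_diff), expr_sum$label
    ),
    fisher_or_increased = stats::setNames(
      as.list(fisher$or[fisher$direction == "increased"]),
      fisher$label[fisher$direction == "increased"]
    ),
    downstream_slope = curve$slope,
    fraction_increased = stats::setNames(as.list(frac$fraction), frac$region)
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    outp <- function(f) file.path(config$out_dir, f)
    write_profile_matrix(mat_ctrl, outp("matrix_control.tsv"))
    write_profile_matrix(mat_dis, outp("matrix_disease.tsv"))
    write_tsv(calls_ctrl, outp("patterns_control.tsv"))
    write_tsv(calls_dis, outp("patterns_disease.tsv"))
    write_tsv(fisher, outp("pattern_de_fisher.tsv"))
    write_tsv(chg, outp("region_changes.tsv"))
    write_tsv(curve$curve, outp("response_curve_downstream.tsv"))
    if (!is.null(motifs)) write_tsv(motifs$overall, outp("motif_enrichment.tsv"))
    jsonlite::write_json(report, outp("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(report)
}
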