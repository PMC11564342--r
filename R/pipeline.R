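#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates filter -> rescue -> burden -> evolution -> cohort ->
#' classify from a single config (a list or a YAML file path). Every
#' stage's report is written even when downstream stages fail; a failing
#' stage is recorded and its dependents are skipped. Reruns with identical
#' inputs and seed produce byte-identical reports (the log carries no
#' timestamps).
#'
#' Config fields: `out_dir`; `seed`; `inputs` (paths: `calls` MAF,
#' `counts` TSV, `segments` SEG TSV, `matrix` + `labels` TSV); optional
#' parameter blocks `filter`, `rescue`, `burden` (`panel_size_mb`,
#' `numerator`), `evolution` (`fmin`, `fmax`, `clonal_cutoff`),
#' `classify` (`n_trees`).
#'
#' @param config list or path to a YAML file.
#' @return (invisibly) list with per-stage `results` and a `status`
#'   data.frame; attribute `ok` is FALSE when any attempted stage failed.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$out_dir))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  yaml::write_yaml(config, file.path(out, "config_used.yaml"))
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  status <- data.frame(stage = character(0), status = character(0),
                       message = character(0), stringsAsFactors = FALSE)
  results <- list()
  run_stage <- function(name, available, fn) {
    if (!available) {
      note("stage ", name, ": skipped (missing input or failed dependency)")
      status <<- rbind(status, data.frame(stage = name, status = "skipped",
                                          message = "missing input or failed dependency"))
      return(NULL)
    }
    res <- tryCatch(fn(), error = function(e) {
      note("stage ", name, ": FAILED: ", conditionMessage(e))
      status <<- rbind(status, data.frame(stage = name, status = "failed",
                                          message = conditionMessage(e)))
      structure(list(), class = "stage_failure")
    })
    if (inherits(res, "stage_failure")) return(NULL)
    note("stage ", name, ": ok")
    status <<- rbind(status, data.frame(stage = name, status = "ok",
                                        message = ""))
    res
  }
  inp <- config$inputs
  has <- function(x) !is.null(inp[[x]]) && file.exists(inp[[x]])
  fcfg <- do.call(filter_config, if (is.null(config$filter)) list()
                                 else config$filter)

  results$filter <- run_stage("filter", has("calls"), function() {
    calls <- read_calls(inp$calls, "maf")
    calls <- normalize_calls(calls)
    flt <- apply_filters(calls, mode = "tissue", cfg = fcfg)
    write_maf(flt$variants, file.path(out, "kept.maf"))
    rep <- rbind(flt$consensus_report$removed, flt$quality_report$removed)
    utils::write.table(rep, file.path(out, "filter_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("  filter: ", flt$consensus_report$n_input, " merged variants, ",
         nrow(flt$variants), " kept")
    flt
  })

  results$rescue <- run_stage("rescue",
                              has("counts") && !is.null(results$filter),
                              function() {
    counts <- utils::read.delim(inp$counts, stringsAsFactors = FALSE)
    rcfg <- do.call(rescue_config, if (is.null(config$rescue)) list()
                                   else config$rescue)
    res <- rescue(results$filter$variants, counts, rcfg)
    utils::write.table(as.data.frame(res), file.path(out, "rescue.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("  rescue: ", sum(res$detected, na.rm = TRUE), " of ", nrow(res),
         " sites detected")
    res
  })

  results$burden <- run_stage("burden",
                              !is.null(results$filter) || has("segments"),
                              function() {
    bcfg <- config$burden
    panel <- if (is.null(bcfg$panel_size_mb)) 3.34 else bcfg$panel_size_mb
    numer <- if (is.null(bcfg$numerator)) "nonsynonymous" else bcfg$numerator
    segs <- if (has("segments")) read_segments(inp$segments) else NULL
    samples <- unique(c(
      if (!is.null(results$filter)) results$filter$variants$patient_id,
      if (!is.null(segs)) segs$sample))
    rows <- lapply(samples, function(s) {
      v <- if (!is.null(results$filter))
        results$filter$variants[results$filter$variants$patient_id == s, ,
                                drop = FALSE] else NULL
      sg <- if (!is.null(segs)) segs[segs$sample == s, , drop = FALSE] else NULL
      if (!is.null(sg) && nrow(sg) == 0) sg <- NULL
      cbind(data.frame(sample = s), sample_burden(v, sg, panel, numer))
    })
    burden <- do.call(rbind, rows)
    utils::write.table(burden, file.path(out, "burden.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    burden
  })

  results$evolution <- run_stage("evolution", !is.null(results$filter),
                                 function() {
    ecfg <- config$evolution
    fmin <- if (is.null(ecfg$fmin)) 0.1 else ecfg$fmin
    fmax <- if (is.null(ecfg$fmax)) 0.25 else ecfg$fmax
    v <- results$filter$variants
    rows <- lapply(unique(v$patient_id), function(s) {
      fit <- neutrality_test(v$vaf[v$patient_id == s & !is.na(v$vaf)],
                             fmin = fmin, fmax = fmax)
      data.frame(sample = s, n_subclonal = fit$n_subclonal,
                 r_squared = fit$r_squared, mu_per_beta = fit$mu_per_beta,
                 evaluable = fit$evaluable, is_neutral = fit$is_neutral)
    })
    evo <- do.call(rbind, rows)
    utils::write.table(evo, file.path(out, "evo.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    evo
  })

  results$cohort <- run_stage("cohort", has("matrix"), function() {
    gm <- read_gene_matrix(inp$matrix,
                           if (has("labels")) inp$labels else NULL)
    cohorts <- names(sort(table(gm$cohort), decreasing = TRUE))
    if (length(cohorts) >= 2) {
      cmp <- compare_frequencies(gm, cohorts[1], cohorts[2], adjust = "BH")
    } else {
      fr <- gene_frequencies(gm, cohorts[1])
      cmp <- data.frame(gene = names(fr), frac_a = fr)
    }
    utils::write.table(cmp, file.path(out, "cohort.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cmp
  })

  results$classify <- run_stage("classify",
                                has("matrix") && has("labels"),
                                function() {
    gm <- read_gene_matrix(inp$matrix, inp$labels)
    if (length(unique(gm$cohort)) != 2)
      stop("classification needs exactly two cohorts")
    ccfg <- config$classify
    n_trees <- if (is.null(ccfg$n_trees)) 1000L else as.integer(ccfg$n_trees)
    full <- fit_forest(gm, seed = seed, n_trees = n_trees)
    sel <- minimal_depth_select(full)
    red <- if (length(sel$selected))
      reduced_model(gm, sel$selected, seed = seed, n_trees = n_trees)
    else full
    ev <- evaluate(red)
    out_json <- list(n_trees = n_trees, seed = seed,
                     selected_genes = sel$selected,
                     depth_threshold = sel$threshold,
                     auc = ev$auc, aucpr = ev$aucpr,
                     oob_error = ev$oob_error)
    jsonlite::write_json(out_json, file.path(out, "classify.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out_json
  })

  writeLines(log_lines, file.path(out, "run.log"))
  utils::write.table(status, file.path(out, "status.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ok <- !any(status$status == "failed")
  invisible(structure(list(results = results, status = status), ok = ok))
}

#' Write a complete synthetic input set for the pipeline
#'
#' Generates multi-caller calls, plasma pileup counts, a segment plan, a
#' cohort matrix with labels, and a ground-truth JSON into `dir`, plus a
#' ready-to-run `run.yaml`.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory.
#' @param n_patients patients with per-sample call sets.
#' @return (invisibly) the path to the generated `run.yaml`.
#' @export
simulate_pipeline_inputs <- function(cfg = sim_config(), dir,
                                     n_patients = 3L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sets <- lapply(seq_len(n_patients), function(i) {
    ci <- cfg; ci$seed <- .stream_seed(cfg$seed, "pipeline") + i
    simulate_multicaller_calls(ci, n_true = 30L,
                               patient = sprintf("P%d", i),
                               sensitivities = stats::setNames(
                                 rep(1, length(cfg$caller_sensitivity)),
                                 names(cfg$caller_sensitivity)))
  })
  calls <- do.call(rbind, lapply(sets, `[[`, "calls"))
  write_maf(calls, file.path(dir, "calls.maf"))
  pc <- simulate_plasma_counts(cfg, patient = "P1")
  utils::write.table(pc$counts, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # one aberrant sample, one quiet, mirroring tissue-vs-plasma instability
  segs <- rbind(simulate_segments(0.35, sample = "P1"),
                simulate_segments(0.10, sample = "P2"))
  write_segments(cn_segments(segs), file.path(dir, "segments.seg"))
  sim <- simulate_cohort(cfg)
  write_gene_matrix(sim$gm, file.path(dir, "matrix.tsv"),
                    file.path(dir, "labels.tsv"))
  jsonlite::write_json(
    list(truth_keys = lapply(sets, `[[`, "truth_keys"),
         shed = pc$truth$key[pc$truth$shed],
         informative_genes = sim$truth$informative_genes),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  cfg_yaml <- list(out_dir = file.path(dir, "out"), seed = cfg$seed,
                   inputs = list(calls = file.path(dir, "calls.maf"),
                                 counts = file.path(dir, "counts.tsv"),
                                 segments = file.path(dir, "segments.seg"),
                                 matrix = file.path(dir, "matrix.tsv"),
                                 labels = file.path(dir, "labels.tsv")),
                   classify = list(n_trees = 200L))
  yaml::write_yaml(cfg_yaml, file.path(dir, "run.yaml"))
  invisible(file.path(dir, "run.yaml"))
}
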