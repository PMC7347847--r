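#' Pipeline configuration
#'
#' Collects every threshold of the discovery -> validation workflow. Exactly
#' one of `study` (with optional `validation_study`) or `sim_spec` (with
#' optional `validation_spec`) must be supplied; a simulation spec is
#' materialized with [simulate_study()] at run time.
#'
#' @param study,validation_study [expression_study()] objects, or `NULL`.
#' @param sim_spec,validation_spec [simulation_spec()] objects, or `NULL`.
#' @param top_k Number of probes kept by CUR-leverage selection.
#' @param pairs List of 2-vectors of group labels to compare.
#' @param alpha,fc_min Panel-selection thresholds.
#' @param moderated Use the moderated t (default `TRUE`).
#' @param k_range,n_restarts NMF consensus settings.
#' @param lda_mode `"transfer"` trains on the discovery cohort and
#'   classifies the validation cohort; `"refit"` trains and evaluates within
#'   the validation cohort.
#' @param seed Seed governing every stochastic stage.
#' @param out_dir Optional directory; when set, every stage artifact is
#'   written there as TSV.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(study = NULL, validation_study = NULL,
                            sim_spec = NULL, validation_spec = NULL,
                            top_k = 1000L,
                            pairs = list(c("DA", "GBM"), c("AA", "GBM"),
                                         c("DA", "AA")),
                            alpha = 0.05, fc_min = 4, moderated = TRUE,
                            k_range = 2:4, n_restarts = 30L,
                            lda_mode = c("transfer", "refit"),
                            seed = 1L, out_dir = NULL) {
  lda_mode <- match.arg(lda_mode)
  if (is.null(study) == is.null(sim_spec)) {
    stop("supply exactly one of `study` or `sim_spec`")
  }
  if (alpha <= 0 || alpha >= 1 || fc_min < 1 || top_k < 1) {
    stop("threshold out of range")
  }
  structure(
    list(study = study, validation_study = validation_study,
         sim_spec = sim_spec, validation_spec = validation_spec,
         top_k = as.integer(top_k), pairs = pairs, alpha = alpha,
         fc_min = fc_min, moderated = moderated, k_range = k_range,
         n_restarts = as.integer(n_restarts), lda_mode = lda_mode,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full panel-discovery workflow
#'
#' Executes, in order: batch adjustment (skipped with a note when the study
#' has a single batch), CUR-leverage probe selection, pairwise differential
#' expression with BH correction and fold-change filtering, panel collapse,
#' NMF consensus clustering of the panel submatrix, canonical biplot, and —
#' when a validation cohort is available — LDA classification. Every stage's
#' record counts, parameters and seeds are collected in a run manifest; a
#' stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list with the stage artifacts (`study`,
#'   `batch_model`, `leverage`, `records`, `panel`, `consensus`, `nmf`,
#'   `biplot`, `lda_report`) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(seed = config$seed,
                   parameters = config[c("top_k", "alpha", "fc_min",
                                         "moderated", "k_range",
                                         "n_restarts", "lda_mode")],
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  truth <- NULL
  study <- run_stage("input", {
    if (!is.null(config$sim_spec)) {
      sim <- simulate_study(config$sim_spec)
      truth <- sim$truth
      sim$study
    } else {
      config$study
    }
  })
  note("input", probes = nrow(study$matrix), samples = ncol(study$matrix),
       groups = as.list(table(study$group)))

  batch_model <- NULL
  study <- run_stage("batch_adjust", {
    if (nlevels(droplevels(study$batch)) >= 2L) {
      adj <- combat_adjust(study)
      batch_model <- adj$model
      note("batch_adjust", batches = nlevels(droplevels(study$batch)),
           applied = TRUE)
      adj$study
    } else {
      note("batch_adjust", applied = FALSE, reason = "single batch")
      study
    }
  })

  leverage <- run_stage("cur_select", svd_leverages(study))
  k_sel <- min(config$top_k, nrow(study$matrix))
  selected <- top_k(leverage, k_sel)
  study_sel <- subset_probes(study, selected)
  note("cur_select", rank_used = leverage$rank_used,
       probes_in = nrow(study$matrix), probes_out = k_sel)

  records <- run_stage("diff_expr", {
    do.call(rbind, lapply(config$pairs, function(pr) {
      pairwise_test(study_sel, pr[1L], pr[2L], moderated = config$moderated)
    }))
  })
  panel <- run_stage("select_panel",
                     select_panel(records, config$alpha, config$fc_min))
  note("diff_expr", records = nrow(records),
       significant = sum(records$p_adj < config$alpha),
       panel_genes = length(panel$genes))

  panel_probes <- unlist(panel$probes, use.names = FALSE)
  consensus <- NULL
  nmf_fit <- NULL
  biplot <- NULL
  if (length(panel_probes) >= 2L) {
    panel_study <- subset_probes(study_sel, panel_probes)
    consensus <- run_stage("nmf", {
      consensus_cluster(panel_study$matrix,
                        k_range = config$k_range,
                        n_restarts = config$n_restarts,
                        seed = config$seed)
    })
    nmf_fit <- run_stage("nmf", {
      nmf_factorize(panel_study$matrix, k = consensus$recommended_k,
                    seed = config$seed)
    })
    note("nmf", recommended_k = consensus$recommended_k,
         cophenetic = as.list(round(consensus$cophenetic, 4L)))
    biplot <- run_stage("biplot", fit_canonical_biplot(panel_study))
    note("biplot", n_axes = biplot$n_axes,
         eigenvalues = as.list(signif(biplot$eigenvalues, 6L)))
  } else {
    note("nmf", skipped = TRUE, reason = "panel has < 2 probes")
  }

  lda_report <- NULL
  validation <- run_stage("validation_input", {
    if (!is.null(config$validation_spec)) {
      simulate_study(config$validation_spec)$study
    } else {
      config$validation_study
    }
  })
  if (!is.null(validation) && length(panel_probes) >= 2L) {
    lda_report <- run_stage("lda", {
      common <- intersect(panel_probes, validation$probe_ids)
      train <- if (config$lda_mode == "transfer") {
        subset_probes(study_sel, common)
      } else {
        subset_probes(validation, common)
      }
      test <- subset_probes(validation, common)
      classify(fit_lda(train), test)
    })
    note("lda", mode = config$lda_mode, accuracy = lda_report$accuracy)
  }

  result <- structure(
    list(study = study, truth = truth, batch_model = batch_model,
         leverage = leverage, selected_probes = selected, records = records,
         panel = panel, consensus = consensus, nmf = nmf_fit,
         biplot = biplot, lda_report = lda_report, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  for (st in names(x$manifest$stages)) {
    info <- x$manifest$stages[[st]]
    cat(sprintf("  %-14s %s\n", st,
                paste(names(info), vapply(info, function(v) {
                  paste(unlist(v), collapse = "/")
                }, character(1L)), sep = "=", collapse = ", ")))
  }
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  w(data.frame(probe_id = names(result$leverage$leverages),
               leverage = unname(result$leverage$leverages)),
    "leverages.tsv")
  w(result$records, "records.tsv")
  if (length(result$panel$genes)) {
    write_panel(result$panel, file.path(out_dir, "panel.tsv"))
  }
  if (!is.null(result$consensus)) {
    w(data.frame(k = result$consensus$k_range,
                 cophenetic = unname(result$consensus$cophenetic)),
      "cophenetic.tsv")
  }
  if (!is.null(result$biplot)) {
    w(data.frame(variable = rownames(result$biplot$variable_coordinates),
                 result$biplot$variable_coordinates, check.names = FALSE),
      "biplot_variables.tsv")
  }
  if (!is.null(result$lda_report) && !is.null(result$lda_report$confusion)) {
    w(as.data.frame(result$lda_report$confusion), "confusion.tsv")
  }
  jsonish <- deparse(result$manifest)
  writeLines(jsonish, file.path(out_dir, "manifest.txt"))
  invisible(result)
}
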