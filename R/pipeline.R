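#' Default pipeline configuration
#'
#' One root seed feeds named sub-seeds for every stochastic stage. Stage
#' configurations are the corresponding constructor arguments; iteration
#' counts default to desk-scale values suitable for a laptop run and can be
#' raised to the study-scale 500/5000 iterations.
#'
#' @param seed integer root seed.
#' @param ... named overrides for the `simulation`, `selection`, `model`,
#'   `fusion` and `correlation` sections, plus `figures` (logical).
#' @return nested configuration list.
#' @export
pipelineConfig <- function(seed = 1L, ...) {
  seeds <- .substreams(seed, 6L)
  base <- list(
    seed = as.integer(seed),
    input = NULL,  # list(fecal, fecal_meta, breath, breath_meta) to skip simulation
    simulation = list(seed = seeds[1L], n_features_fecal = 16L,
                      n_features_breath = 10L, n_markers = 4L),
    selection = list(seed = seeds[2L], n_iterations = 60L, rf_trees = 200L),
    model = list(seed = seeds[3L], n_iterations = 60L, rf_trees = 300L),
    fusion = list(seed = seeds[4L], n_iterations = 40L, rf_trees = 200L),
    correlation = list(seed = seeds[5L], n_iterations = 60L,
                       n_permutations = 99L),
    figures = FALSE)
  utils::modifyList(base, list(...))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full two-platform analysis pipeline
#'
#' Executes, in order: cohort input (simulation, or reading the four
#' delimited-text files named in `config$input`), blank filtering of the
#' fecal platform, shadow-feature stability selection and feature-set
#' optimisation, final fecal and breath models, proximity-stacking fusion
#' with grid-searched weight, and the iterated cross-platform correlation on
#' the IBD and PSC populations. Writes all tables, a summary JSON and a
#' manifest (config, seeds, versions, file checksums) into `out_dir`;
#' identical configurations yield identical summaries.
#'
#' @param config a [pipelineConfig()] list, or the path of a YAML file whose
#'   top-level keys override [pipelineConfig()] defaults.
#' @param out_dir output directory (created if needed).
#' @return the summary list, invisibly; side effect: files in `out_dir`.
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    overrides <- yaml::read_yaml(config)
    config <- do.call(pipelineConfig,
                      c(list(seed = overrides$seed %||% 1L),
                        overrides[setdiff(names(overrides), "seed")]))
  }
  stopifnot(is.list(config))
  if (!is.null(config$input)) {
    paths <- unlist(config$input)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("missing input path(s): ", paste(missing, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- .stage("input", {
    if (is.null(config$input)) {
      sim <- do.call(simulationConfig, config$simulation)
      generateCohort(sim)
    } else {
      list(fecal = readFeatureTable(config$input$fecal,
                                    config$input$fecal_meta),
           breath = readFeatureTable(config$input$breath,
                                     config$input$breath_meta),
           truth = NULL)
    }
  })
  writeFeatureTable(cohort$fecal, file.path(out_dir, "fecal_table.csv"),
                    file.path(out_dir, "fecal_meta.csv"))
  writeFeatureTable(cohort$breath, file.path(out_dir, "breath_table.csv"),
                    file.path(out_dir, "breath_meta.csv"))

  bf <- .stage("blank_filter", blankFilter(cohort$fecal))
  utils::write.csv(filterReport(bf),
                   file.path(out_dir, "blank_filter_report.csv"),
                   row.names = FALSE)
  fecal <- subsetFeatures(subsetByRole(cohort$fecal), retainedFeatures(bf))
  labeling <- mergePscGroups(fecal)

  sel_cfg <- do.call(selectionConfig, config$selection)
  freq <- .stage("selection", importanceFrequency(fecal, labeling, sel_cfg))
  utils::write.csv(freqMatrix(freq),
                   file.path(out_dir, "importance_frequency.csv"))
  opt <- .stage("optimize", rankAndOptimize(freq, fecal, labeling, sel_cfg))

  mod_cfg <- do.call(selectionConfig, config$model)
  fecal_model <- .stage("fecal_model", {
    if (nrow(opt$selected_ratios) == 0L)
      stop("no ratios survived selection")
    fitEvaluate(fecal, labeling, opt$selected_ratios, mod_cfg)
  })
  breath_lab <- mergePscGroups(cohort$breath)
  breath_model <- .stage("breath_model",
    fitEvaluate(cohort$breath, breath_lab, compounds(cohort$breath),
                mod_cfg))

  fus_cfg <- do.call(fusionConfig, config$fusion)
  fused <- .stage("fusion", {
    al <- alignSamples(fecal_model, breath_model)
    optimizeWeight(al$P_fecal, al$P_breath, al$labels, fus_cfg)
  })

  cor_cfg <- do.call(correlationConfig, config$correlation)
  correlations <- .stage("correlation", {
    lapply(stats::setNames(c("IBD", "PSC"), c("IBD", "PSC")), function(cls) {
      samp <- labeling@sampleIds[labeling@labels == cls]
      pat <- labeling@patientIds[labeling@labels == cls]
      # patient grain: first fecal sample per patient against the breath sample
      first <- samp[!duplicated(pat)]
      pats <- pat[!duplicated(pat)]
      bs <- sampleData(cohort$breath)
      keep <- pats %in% bs$patient_id
      first <- first[keep]; pats <- pats[keep]
      b_rows <- bs$sample_id[match(pats, bs$patient_id)]
      Xs <- ratioSampler(fecal, opt$selected_ratios, samples = first)
      Yb <- log(intensities(cohort$breath)[b_rows, , drop = FALSE])
      scr <- permutationScreen(Xs, Yb, cor_cfg)
      if (length(scr$selected_x) && length(scr$selected_y))
        averagedCorrelations(Xs, Yb, scr$selected_x, scr$selected_y, cor_cfg)
      else
        averagedCorrelations(Xs, Yb, colnames(Xs(cor_cfg$seed)),
                             colnames(Yb), cor_cfg)
    })
  })

  summary <- list(
    n_samples = list(fecal = ncol(cohort$fecal),
                     breath = ncol(cohort$breath)),
    blank_filter = list(retained = length(retainedFeatures(bf)),
                        total = nrow(filterReport(bf))),
    selection = list(k = opt$k, features = opt$selected_features,
                     n_ratios = nrow(opt$selected_ratios),
                     shadow_max = shadowMax(freq)),
    fecal = list(auc = modelAUC(fecal_model),
                 sensitivity = fecal_model@sensitivity,
                 specificity = fecal_model@specificity),
    breath = list(auc = modelAUC(breath_model),
                  sensitivity = breath_model@sensitivity,
                  specificity = breath_model@specificity),
    fusion = list(weight = fused$w, auc = modelAUC(fused$result),
                  sensitivity = fused$result@sensitivity,
                  specificity = fused$result@specificity),
    correlation = lapply(correlations, function(cr) list(
      canonical_r = cr@canonicalR, mean_p = cr@meanP,
      frac_significant = cr@fracSignificant,
      selected_x = cr@selectedX, selected_y = cr@selectedY)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (isTRUE(config$figures)) .pipeline_figures(out_dir, fecal_model,
                                                breath_model, fused$result)

  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("vocfusion")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}

.pipeline_figures <- function(out_dir, fecal_model, breath_model, fused) {
  grDevices::png(file.path(out_dir, "roc_curves.png"), width = 700,
                 height = 700)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(1 - fecal_model@rocCurve$specificity,
                 fecal_model@rocCurve$sensitivity, type = "l", col = "red",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = "ROC: fecal (red), breath (yellow), fused (purple)")
  graphics::lines(1 - breath_model@rocCurve$specificity,
                  breath_model@rocCurve$sensitivity, col = "goldenrod")
  graphics::lines(1 - fused@rocCurve$specificity,
                  fused@rocCurve$sensitivity, col = "purple")
  graphics::abline(0, 1, lty = 2)
}
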