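#' @include AllClasses.R averaging.R permutation.R classification.R
NULL

.schemaVersion <- "1.0"

# ---- stage-report serializers (plain lists -> JSON) -----------------------

.testCurveAsList <- function(tc) {
  list(statistic = tc@statistic, df = tc@df, p = tc@p,
       p_adjusted = tc@pAdjusted, alpha = tc@alpha,
       correction = tc@correction, mask = tc@mask,
       replicate_unit = tc@replicateUnit,
       n_significant = sum(tc@mask))
}

.collapseAsList <- function(cr) {
  list(method = cr@method, replicate_unit = cr@replicateUnit,
       n_units = nrow(cr@yes),
       grand_mean_yes = cr@grandYes, grand_mean_no = cr@grandNo,
       sd_yes = apply(cr@yes, 2, stats::sd),
       sd_no = apply(cr@no, 2, stats::sd))
}

.avgstatsReport <- function(cmp) {
  list(schema_version = .schemaVersion, stage = "avgstats",
       alpha = cmp$alpha, correction = cmp$correction,
       time_axis_s = cmp$timeAxis,
       methods = list(
         "A-flawed" = c(.collapseAsList(cmp$collapseA),
                        list(test = .testCurveAsList(cmp$testA))),
         "B-correct" = c(.collapseAsList(cmp$collapseB),
                         list(test = .testCurveAsList(cmp$testB)))),
       n_significant = list("A-flawed" = cmp$nSigA, "B-correct" = cmp$nSigB))
}

.permcheckReport <- function(audits) {
  list(schema_version = .schemaVersion, stage = "permcheck",
       audits = lapply(audits, function(a)
         list(method = a$method, scope = a$scope,
              n_permutations = a$nPermutations,
              audit_alpha = a$auditAlpha, seed = a$seed,
              significant_counts = a$significantCounts,
              flagged = a$flagged, fraction_flagged = a$fractionFlagged)))
}

.classifyReport <- function(rep) {
  list(schema_version = .schemaVersion, stage = "classify",
       chance = rep$chance, alpha = rep$alpha, correction = rep$correction,
       feature_spec = unclass(rep$featureSpec),
       classifier = unclass(rep$config),
       mean_accuracy = rep$meanAccuracy,
       pooled_k = rep$pooledK, pooled_n = rep$pooledN,
       n_significant_days = rep$nSignificantDays,
       days = lapply(rep$days, function(e)
         list(day_id = e$dayId, k = e$k, n = e$n, accuracy = e$accuracy,
              fold_accuracy = e$cv$foldAccuracy,
              selected_C = e$cv$selectedC,
              p_value = e$pValue, p_adjusted = e$pAdjusted,
              significant = e$significant)))
}

.chanceReport <- function(tab, chance, alpha) {
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    ct <- accuracyBinomialTest(tab$k[i], tab$n[i], chance = chance,
                               alpha = alpha)
    list(label = as.character(tab$label[i]), k = ct@k, n = ct@n,
         accuracy = ct@k / ct@n, p_value = ct@pValue,
         ci_lower = ct@ci[1], ci_upper = ct@ci[2],
         significant = ct@significant)
  })
  list(schema_version = .schemaVersion, stage = "chance",
       chance = chance, alpha = alpha, assessments = rows)
}

#' Pipeline configuration
#'
#' Bundles an input source (a dataset directory written by
#' [writeDataset()], or a synthetic preset name plus seed), the stages to
#' run, per-stage parameters and an output directory.
#'
#' @param outDir output directory for reports and figures.
#' @param inputDir directory containing `manifest.json` (exclusive with
#'   `preset`).
#' @param preset synthetic preset name for [syntheticPreset()].
#' @param seed integer seed (synthetic generation and all seeded stages).
#' @param stages subset of `c("avgstats", "permcheck", "classify",
#'   "chance")`, at least one.
#' @param alpha significance level shared by the stages.
#' @param correction multiple-comparison correction for avgstats/classify.
#' @param nPerm,auditAlpha permutation-audit parameters.
#' @param chance chance level for classification significance.
#' @param chanceTable optional data.frame `(label, k, n)` for the batch
#'   chance stage; when omitted the classify stage's per-day counts are
#'   assessed.
#' @param featureSpec a [featureSpec()].
#' @param classifier a [classifierConfig()].
#' @param figures write the two-panel averaging-order figure.
#' @return object of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(outDir, inputDir = NULL, preset = NULL,
                           seed = 1L,
                           stages = c("avgstats", "permcheck", "classify"),
                           alpha = 0.05, correction = "none",
                           nPerm = 10L, auditAlpha = 5e-4, chance = 0.5,
                           chanceTable = NULL,
                           featureSpec = trialaudit::featureSpec(),
                           classifier = classifierConfig(seed = seed),
                           figures = TRUE) {
  stages <- match.arg(stages, c("avgstats", "permcheck", "classify", "chance"),
                      several.ok = TRUE)
  if (is.null(inputDir) == is.null(preset))
    stopf("give exactly one of inputDir or preset")
  structure(list(outDir = outDir, inputDir = inputDir, preset = preset,
                 seed = as.integer(seed), stages = stages, alpha = alpha,
                 correction = correction, nPerm = as.integer(nPerm),
                 auditAlpha = auditAlpha, chance = chance,
                 chanceTable = chanceTable, featureSpec = featureSpec,
                 classifier = classifier, figures = isTRUE(figures)),
            class = "pipelineConfig")
}

#' Run the full reanalysis pipeline
#'
#' Loads (or generates) the dataset, runs the requested stages, and
#' writes one JSON report per stage plus a run manifest recording every
#' seed, parameter and the package version, so a rerun with the same
#' manifest reproduces the reports byte-identically. Stage timings are
#' logged to stderr. A stage failure halts the run; reports of completed
#' stages remain on disk.
#'
#' @param config a [pipelineConfig()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the dataset, per-stage results and the
#'   report paths.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipelineConfig"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  if (!dir.exists(config$outDir) &&
      !dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory '%s'", config$outDir)
  t0 <- Sys.time()
  dataset <- if (!is.null(config$preset)) {
    say("generating synthetic preset '%s' (seed %d)", config$preset, config$seed)
    generateDataset(syntheticPreset(config$preset, seed = config$seed))
  } else {
    say("reading dataset from '%s'", config$inputDir)
    readDataset(file.path(config$inputDir, "manifest.json"))
  }
  say("dataset loaded in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))

  results <- list(dataset = dataset, paths = character())
  writeReport <- function(obj, name) {
    path <- file.path(config$outDir, paste0(name, ".json"))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    results$paths <<- c(results$paths, path)
    path
  }
  timed <- function(label, expr) {
    t1 <- Sys.time()
    out <- expr
    say("stage %s finished in %.1f s", label,
        as.numeric(Sys.time() - t1, units = "secs"))
    out
  }

  if ("avgstats" %in% config$stages) {
    cmp <- timed("avgstats",
                 compareMethods(dataset, alpha = config$alpha,
                                correction = config$correction))
    results$avgstats <- cmp
    writeReport(.avgstatsReport(cmp), "avgstats")
    if (config$figures) {
      fig <- file.path(config$outDir, "avgstats.png")
      renderMethodComparison(cmp, fig)
      results$paths <- c(results$paths, fig)
    }
  }
  if ("permcheck" %in% config$stages) {
    audits <- timed("permcheck", lapply(c("A-flawed", "B-correct"),
      function(m) permutationAudit(dataset, m, nPerm = config$nPerm,
                                   auditAlpha = config$auditAlpha,
                                   seed = config$seed)))
    results$permcheck <- audits
    writeReport(.permcheckReport(audits), "permcheck")
  }
  if ("classify" %in% config$stages) {
    rep <- timed("classify",
                 runOfflineReanalysis(dataset, spec = config$featureSpec,
                                      config = config$classifier,
                                      chance = config$chance,
                                      alpha = config$alpha))
    results$classify <- rep
    writeReport(.classifyReport(rep), "classify")
  }
  if ("chance" %in% config$stages) {
    tab <- config$chanceTable
    if (is.null(tab)) {
      if (is.null(results$classify))
        stopf("chance stage needs chanceTable or a classify stage in the same run")
      tab <- data.frame(
        label = vapply(results$classify$days, `[[`, character(1), "dayId"),
        k = vapply(results$classify$days, `[[`, integer(1), "k"),
        n = vapply(results$classify$days, `[[`, integer(1), "n"))
    }
    results$chance <- timed("chance",
                            .chanceReport(tab, config$chance, config$alpha))
    writeReport(results$chance, "chance")
  }

  manifest <- list(schema_version = .schemaVersion,
                   package_version = as.character(utils::packageVersion("trialaudit")),
                   seed = config$seed, stages = config$stages,
                   preset = config$preset, input_dir = config$inputDir,
                   alpha = config$alpha, correction = config$correction,
                   n_permutations = config$nPerm,
                   audit_alpha = config$auditAlpha, chance = config$chance,
                   feature_spec = unclass(config$featureSpec),
                   classifier = unclass(config$classifier))
  writeReport(manifest, "run-manifest")
  say("pipeline finished in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  invisible(results)
}

#' Two-panel figure comparing both averaging orders
#'
#' Renders, for each method, the per-condition grand-mean curve with a
#' +/- 1 SD ribbon (SD across the method's replicate units) and shades
#' the timepoints the method declares significant — the flawed order's
#' panel typically fills with shading on null data while the correct
#' order's panel stays clean.
#'
#' @param cmp a `"methodComparison"` from [compareMethods()].
#' @param file output image path (.png); written via [ggplot2::ggsave()].
#' @param width,height,dpi figure geometry.
#' @return the file path, invisibly.
#' @export
renderMethodComparison <- function(cmp, file, width = 9, height = 4,
                                   dpi = 110) {
  stopifnot(inherits(cmp, "methodComparison"))
  tax <- cmp$timeAxis
  panel <- function(cr, tc, label) {
    sdY <- apply(cr@yes, 2, stats::sd)
    sdN <- apply(cr@no, 2, stats::sd)
    data.frame(
      method = label, time = rep(tax, 2),
      condition = rep(c("yes", "no"), each = length(tax)),
      mean = c(cr@grandYes, cr@grandNo),
      sd = c(sdY, sdN),
      sig = rep(tc@mask, 2))
  }
  df <- rbind(
    panel(cmp$collapseA, cmp$testA,
          sprintf("A-flawed (channel variance): %d sig.", cmp$nSigA)),
    panel(cmp$collapseB, cmp$testB,
          sprintf("B-correct (session variance): %d sig.", cmp$nSigB)))
  shade <- df[df$sig & df$condition == "yes",
              c("method", "time")]
  step <- if (length(tax) > 1) diff(tax)[1] else 1
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean,
                                        colour = .data$condition,
                                        fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25, colour = NA)
  if (nrow(shade))
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$time - step / 2,
                   xmax = .data$time + step / 2),
      ymin = -Inf, ymax = Inf, fill = "grey60", alpha = 0.35,
      colour = NA, inherit.aes = FALSE)
  p <- p + ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "time relative to stimulus onset (s)",
                  y = "relative HbO change (a.u.)",
                  colour = "condition", fill = "condition") +
    ggplot2::theme_minimal(base_size = 10)
  ggplot2::ggsave(file, p, width = width, height = height, dpi = dpi)
  invisible(file)
}

#' Structural check of a stage report against the shipped schema
#'
#' Verifies that a report list (or JSON file) carries the schema version
#' and the required fields of its stage, as documented in the JSON schema
#' shipped at `system.file("schema", "report-schema.json", package =
#' "trialaudit")`.
#'
#' @param report a report list or path to a report JSON.
#' @return TRUE invisibly; errors describe the first missing field.
#' @export
validateReport <- function(report) {
  if (is.character(report))
    report <- jsonlite::fromJSON(report, simplifyVector = FALSE)
  if (is.null(report$schema_version))
    stopf("report lacks schema_version")
  required <- list(
    avgstats = c("alpha", "correction", "time_axis_s", "methods", "n_significant"),
    permcheck = "audits",
    classify = c("chance", "alpha", "mean_accuracy", "pooled_k", "pooled_n", "days"),
    chance = c("chance", "alpha", "assessments"))
  stage <- report[["stage"]]
  if (is.null(stage)) {   # run manifest
    need <- c("package_version", "seed", "stages")
  } else {
    if (!stage %in% names(required)) stopf("unknown stage '%s'", stage)
    need <- required[[stage]]
  }
  miss <- setdiff(need, names(report))
  if (length(miss))
    stopf("report%s is missing field(s): %s",
          if (is.null(stage)) " (run manifest)" else sprintf(" (stage %s)", stage),
          paste(miss, collapse = ", "))
  invisible(TRUE)
}
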