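#' @include AllClasses.R io.R simulate.R enrichment.R subtype.R integration.R
#' @include stats.R cga.R network.R survcurves.R
NULL

.defaultRunConfig <- function() list(
  seed = 1,
  outDir = "proteoSubtype_run",
  simulate = TRUE,
  inputDir = NULL,
  simulation = list(),
  purityThreshold = 0.4,
  alpha = 0.25,
  mode = "cascade",
  q = 0.75,
  tcellQ = NULL,
  cisAlpha1 = 0.05,
  cisAlpha2 = 0.01,
  cgaFoldMin = 100,
  cgaZMin = 3,
  cgaEps = 0.01,
  networkTopVar = 500,
  networkRMin = 0.5,
  kModules = 6,
  coreK = 4)

#' Load a pipeline run configuration
#'
#' Reads a YAML or JSON configuration (or accepts a list) and fills in the
#' documented defaults for every module parameter.
#'
#' @param config path to a .yaml/.yml/.json file, or a named list.
#' @return Named list with all parameters populated.
#' @export
runConfig <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  out <- .defaultRunConfig()
  unknown <- setdiff(names(config), names(out))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  out[names(config)] <- config
  out
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
}

.logStage <- function(name, msg, verbose) {
  if (verbose) message(sprintf("[%s] %s", name, msg))
}

#' Run the full subtyping pipeline
#'
#' Orchestrates simulate/load -> purity filter -> signature scoring ->
#' classification -> genomic integration -> CGA analysis -> protein network
#' -> survival, writing all tabular outputs plus a machine-readable run
#' summary (with an md5 manifest of every file) to \code{outDir}.  Given a
#' fixed seed the whole run, including the manifest hashes, is
#' deterministic.  Any stage error aborts with the stage name attached.
#'
#' @param config a [runConfig()] list, or a path accepted by it.
#' @param bundle optional pre-built [CohortBundle-class]; overrides the
#'   simulate/load stage (used for testing and programmatic runs).
#' @param verbose emit per-stage progress messages.
#' @return The run summary, invisibly (also written as
#'   \code{run_summary.json}).
#' @export
runPipeline <- function(config = list(), bundle = NULL, verbose = FALSE) {
  cfg <- runConfig(config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(name, writer) {
    p <- file.path(cfg$outDir, name)
    writer(p)
    paths[[name]] <<- p
    p
  }

  bundle <- .stage("simulate", {
    if (!is.null(bundle)) bundle
    else if (isTRUE(cfg$simulate)) {
      simCfg <- do.call(simulationConfig,
                        c(cfg$simulation,
                          if (is.null(cfg$simulation$seed))
                            list(seed = cfg$seed)))
      generateCohort(simCfg)
    } else {
      if (is.null(cfg$inputDir)) stop("simulate = FALSE needs inputDir")
      readCohort(cfg$inputDir)
    }
  })
  .logStage("simulate", sprintf("%d samples, %d genes",
                                nrow(bundle@clinical),
                                nrow(omicsValues(bundle@rna))), verbose)

  filt <- .stage("purity_filter", applyPurityFilter(bundle, cfg$purityThreshold))
  bundle <- filt$bundle
  samples <- sampleIds(bundle)
  .logStage("purity_filter", sprintf("kept %d, excluded %d", length(samples),
                                     length(filt$excluded)), verbose)

  scoring <- .stage("score", {
    sets <- geneSets(bundle)
    sigSets <- sets[setdiff(names(sets), "cga_candidates")]
    rnaEs <- ssgseaScore(bundle@rna, sigSets, alpha = cfg$alpha)
    protEs <- ssgseaScore(bundle@protein, sigSets, alpha = cfg$alpha)
    combined <- combineLayers(rnaEs, protEs)
    est <- if (all(c("immune_estimate", "stromal_estimate") %in% names(sets)))
      estimateScores(bundle@rna, sets$immune_estimate, sets$stromal_estimate,
                     alpha = cfg$alpha)
    else NULL
    list(rna = rnaEs, protein = protEs, combined = combined, estimate = est)
  })
  emit("enrichment.tsv", function(p)
    writeOmicsMatrix(omicsMatrix(omicsValues(scoring$combined), "rna", "log2"),
                     p, idColumn = "signature"))

  assignment <- .stage("classify", {
    if (identical(cfg$mode, "cascade"))
      classifyCascade(scoring$combined, q = cfg$q, tcellQ = cfg$tcellQ)
    else classifyPureHclust(scoring$combined, k = 4)
  })
  labels <- subtypeLabels(assignment)
  emit("labels.tsv", function(p)
    .writeTsv(data.frame(sample = names(labels), subtype = unname(labels)), p))

  integration <- .stage("integrate", {
    cis <- cisCorrelate(bundle@cna, bundle@rna, bundle@protein,
                        alpha1 = cfg$cisAlpha1, alpha2 = cfg$cisAlpha2)
    assoc <- mutationSubgroupAssociation(bundle@mutations, labels)
    burden <- tmb(bundle@mutations, samples)
    list(cis = cis, assoc = assoc, tmb = burden)
  })
  emit("cis_results.tsv", function(p) .writeTsv(integration$cis$results, p))
  emit("mutation_assoc.tsv", function(p) .writeTsv(integration$assoc, p))
  emit("tmb.tsv", function(p)
    .writeTsv(data.frame(sample = samples,
                         tmb = unname(integration$tmb[samples])), p))

  cga <- .stage("cga", {
    cgaGenes <- geneSets(bundle)$cga_candidates
    if (is.null(cgaGenes)) NULL
    else {
      det <- cgaDetect(toLinearFpkm(bundle@rna), cgaGenes,
                       foldMin = cfg$cgaFoldMin, zMin = cfg$cgaZMin,
                       eps = cfg$cgaEps)
      comp <- cgaComposition(det$positive, labels)
      list(detect = det, composition = comp)
    }
  })
  if (!is.null(cga)) {
    emit("cga_calls.tsv", function(p) .writeTsv(cga$detect$calls, p))
    emit("cga_composition.tsv", function(p)
      .writeTsv(cga$composition$composition, p))
  }

  network <- .stage("network", {
    selected <- selectProteins(bundle@protein, nTopVar = cfg$networkTopVar,
                               rMin = cfg$networkRMin)
    if (length(selected) < max(4, cfg$kModules)) NULL
    else {
      sub <- omicsValues(bundle@protein)[selected, , drop = FALSE]
      mods <- clusterModules(sub, kModules = cfg$kModules,
                             sets = geneSets(bundle))
      g <- kcoreFilter(proteinGraph(sub, cfg$networkRMin), k = cfg$coreK)
      list(selected = selected, modules = mods, graph = g)
    }
  })
  if (!is.null(network)) {
    emit("modules.tsv", function(p)
      .writeTsv(data.frame(protein = names(network$modules$modules),
                           module = unname(network$modules$modules)), p))
    if (!is.null(network$modules$enrichment))
      emit("module_enrichment.tsv", function(p)
        .writeTsv(network$modules$enrichment, p))
    emit("edges.tsv", function(p) .writeTsv(edgeTable(network$graph), p))
  }

  surv <- .stage("survive", {
    clin <- bundle@clinical
    km <- kmFit(clin$os_time_months, clin$os_event, labels[clin$sample])
    lr <- logrankTest(clin$os_time_months, clin$os_event, labels[clin$sample])
    cox <- coxphFit(clin, labels)
    list(km = km, logrank = lr, cox = cox)
  })
  emit("km_curves.tsv", function(p) .writeTsv(surv$km, p))
  emit("logrank.json", function(p)
    jsonlite::write_json(surv$logrank, p, auto_unbox = TRUE, digits = NA))
  emit("cox.tsv", function(p) .writeTsv(surv$cox$table, p))

  summary <- .stage("report", {
    sizes <- as.list(table(factor(labels, levels = .SUBTYPE_LEVELS)))
    coxTab <- surv$cox$table
    hrRow <- function(term) {
      i <- match(term, coxTab$term)
      if (is.na(i)) NA_real_ else coxTab$hr[i]
    }
    cgaCounts <- if (is.null(cga)) NULL else
      stats::setNames(as.list(cga$composition$composition$n_positive),
                      cga$composition$composition$subgroup)
    out <- list(
      seed = cfg$seed,
      n_samples = length(samples),
      excluded_samples = as.list(filt$excluded),
      subgroup_sizes = lapply(sizes, as.integer),
      cis_summary = integration$cis$summary,
      cga_positive_by_subgroup = cgaCounts,
      logrank_p = surv$logrank$p,
      cox_hr = list(P_vs_I = hrRow("subtypeP"), A_vs_I = hrRow("subtypeA"),
                    M_vs_I = hrRow("subtypeM")),
      manifest = lapply(paths, function(p)
        unname(tools::md5sum(p))))
    validateRunSummary(out)
    out
  })
  p <- file.path(cfg$outDir, "run_summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

#' Validate a run summary against the shipped schema
#'
#' Structural validation of the pipeline's machine-readable summary
#' against the JSON schema in \code{inst/schema/run_summary.schema.json}:
#' all required fields present with the expected types, and exactly the
#' four subgroup keys.
#'
#' @param summary the list produced by [runPipeline()].
#' @return \code{TRUE} invisibly; errors describe the first violation.
#' @export
validateRunSummary <- function(summary) {
  schema <- jsonlite::read_json(system.file("schema",
                                            "run_summary.schema.json",
                                            package = "proteoSubtype"))
  required <- unlist(schema$required)
  missing <- setdiff(required, names(summary))
  if (length(missing))
    stop("run summary is missing required field(s): ",
         paste(missing, collapse = ", "))
  if (!is.numeric(summary$n_samples) || !is.numeric(summary$logrank_p))
    stop("n_samples and logrank_p must be numeric")
  if (!setequal(names(summary$subgroup_sizes), .SUBTYPE_LEVELS))
    stop("subgroup_sizes must have exactly the keys P, I, A, M")
  if (!length(summary$manifest))
    stop("manifest must list at least one output file")
  invisible(TRUE)
}
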