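#' @include AllClasses.R io.R
NULL

# Evaluate expr under a fixed seed without leaking RNG state to the caller.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: 102 samples
#' of which 3 are planted below the 0.4 purity cutoff (99 analysable), 5000
#' genes, subgroup mix P 25\% / I 30\% / A 20\% / M 25\%, +1.5 log2
#' signature shifts, protein layer attenuated to r = 0.6 with 20\% of genes
#' absent, 300 cis genes at dosage slope beta = 0.8 with CNA ~ N(0, 0.5), a
#' TP53-like mutation at 48\% in P vs 10\% elsewhere, hazard ratios vs I of
#' P 2.9 / A 2.0 / M 1.4 with ~40\% exponential censoring, and 10
#' CGA-outlier-positive samples drawn only from P and M.
#'
#' @param nSamples total number of samples generated.
#' @param nLowPurity planted low-purity samples among them.
#' @param nGenes total genes (including the CGA candidate genes).
#' @param subgroupProportions named numeric (P, I, A, M), must sum to 1.
#' @param signatureEffectDelta log2 shift on own-subgroup signature genes.
#' @param proteinAttenuation target per-gene RNA-protein Pearson correlation.
#' @param proteinMissingFraction fraction of genes absent from the protein layer.
#' @param cisGeneCount number of planted CNA dosage genes.
#' @param cisBeta dosage slope: standardised RNA = beta * CNA + noise, with
#'   total unit variance, so the model correlation is
#'   \code{beta * 0.5 / 1}.
#' @param mutationEnrichmentOdds named numeric \code{c(inP=, elsewhere=)}
#'   mutation rates for the TP53-like gene.
#' @param hazardRatios named numeric hazard ratios versus I.
#' @param censoringRate target overall censoring fraction.
#' @param nCgaPositive number of CGA-positive samples (planted in P/M only).
#' @param nCgaGenes size of the CGA candidate list.
#' @param signatureSetSize genes per planted signature set.
#' @param signatureOverlap fraction of each signature set drawn from a shared
#'   pool (0 = disjoint sets, the default; disjointness keeps classifier
#'   recovery tests sharp).
#' @param seed integer; a fixed seed yields a byte-identical bundle.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(nSamples = 102, nLowPurity = 3, nGenes = 5000,
                             subgroupProportions = c(P = 0.25, I = 0.30,
                                                     A = 0.20, M = 0.25),
                             signatureEffectDelta = 1.5,
                             proteinAttenuation = 0.6,
                             proteinMissingFraction = 0.2,
                             cisGeneCount = 300, cisBeta = 0.8,
                             mutationEnrichmentOdds = c(inP = 0.48,
                                                        elsewhere = 0.10),
                             hazardRatios = c(P = 2.9, A = 2.0, M = 1.4),
                             censoringRate = 0.4, nCgaPositive = 10,
                             nCgaGenes = 226, signatureSetSize = 30,
                             signatureOverlap = 0, seed = 1) {
  cfg <- new("SimulationConfig", nSamples = nSamples, nLowPurity = nLowPurity,
             nGenes = nGenes, subgroupProportions = subgroupProportions,
             signatureEffectDelta = signatureEffectDelta,
             proteinAttenuation = proteinAttenuation,
             proteinMissingFraction = proteinMissingFraction,
             cisGeneCount = cisGeneCount, cisBeta = cisBeta,
             mutationEnrichmentOdds = mutationEnrichmentOdds,
             hazardRatios = hazardRatios, censoringRate = censoringRate,
             nCgaPositive = nCgaPositive, signatureSetSize = signatureSetSize,
             signatureOverlap = signatureOverlap, seed = seed)
  attr(cfg, "nCgaGenes") <- nCgaGenes
  cfg
}

# Signature families elevated per subgroup.  Mirrors the structure of real
# TME/malignant-cell collections, where most sets co-vary with one of the
# four transcriptional programs; the remaining sets up to 31 are neutral
# fillers carrying no subgroup signal (useful for null calibration).
.SUBGROUP_SETS <- list(
  P = c("proliferation", "cell_cycle", "dna_replication", "e2f_targets",
        "mitotic_spindle"),
  I = c("t_cell", "b_cell", "immune_estimate", "stromal_estimate",
        "immune_checkpoint", "nk_cell", "treg", "mhc_class2",
        "cytokine_signaling"),
  A = c("angiogenesis", "caf", "endothelial", "tgf_beta", "cell_migration",
        "mdsc"),
  M = c("metabolism", "oxphos", "lipid_metabolism", "glycolysis",
        "fatty_acid_synthesis", "cholesterol_homeostasis"))
.N_SIGNATURE_SETS <- 31L

# largest-remainder apportionment of n among proportions
.apportion <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  stats::setNames(as.integer(base), names(prop))
}

#' Generate a fully labelled synthetic cohort
#'
#' Builds a [CohortBundle-class] with the statistical structure the
#' downstream analysis assumes: RNA log2 values are baseline
#' \code{Normal(mu_g, 1)} with \code{+delta} on own-subgroup signature
#' genes; the protein layer is \code{a * rna_z + sqrt(1 - a^2) * noise} per
#' gene with a fraction of genes absent; planted cis genes follow
#' \code{rna_z = beta * cna + eps} with \code{cna ~ Normal(0, 0.5)} and unit
#' total variance; mutations include a TP53-like subgroup-enriched gene, an
#' STK11-like gene whose carriers get a +2 log2 shift on 20 target proteins,
#' and subgroup-dependent background burden; survival times are exponential
#' with the configured subgroup hazards under independent exponential
#' censoring; CGA outliers are planted on the linear-FPKM scale at 200x the
#' leave-one-out mean.  All planted structure is recorded in the
#' \code{truth} slot.
#'
#' @param config a [SimulationConfig-class].
#' @return A [CohortBundle-class] with \code{truth} attached.
#' @examples
#' cfg <- simulationConfig(nSamples = 30, nGenes = 600, cisGeneCount = 40,
#'                         nCgaPositive = 3, nCgaGenes = 60,
#'                         signatureSetSize = 10, seed = 7)
#' bundle <- generateCohort(cfg)
#' bundle
#' @export
generateCohort <- function(config) {
  validObject(config)
  .withSeed(config@seed, .generateCohortImpl(config))
}

.generateCohortImpl <- function(config) {
  n <- as.integer(config@nSamples)
  nCga <- min(attr(config, "nCgaGenes") %||% 226L, config@nGenes %/% 4L)
  nReg <- as.integer(config@nGenes) - nCga
  samples <- sprintf("S%03d", seq_len(n))
  genes <- c(sprintf("G%04d", seq_len(nReg)), sprintf("CGA%03d", seq_len(nCga)))
  regular <- genes[seq_len(nReg)]
  cgaGenes <- genes[nReg + seq_len(nCga)]

  counts <- .apportion(n, config@subgroupProportions[.SUBTYPE_LEVELS])
  labels <- sample(rep(.SUBTYPE_LEVELS, times = counts))
  names(labels) <- samples

  ## --- signature gene sets -------------------------------------------------
  setSize <- as.integer(config@signatureSetSize)
  need <- .N_SIGNATURE_SETS * setSize + (config@signatureOverlap > 0) * setSize +
    config@cisGeneCount + 30L
  if (nReg < need)
    stop("nGenes too small for ", .N_SIGNATURE_SETS, " signature sets of size ",
         setSize, " plus ", config@cisGeneCount,
         " cis genes; lower signatureSetSize or cisGeneCount")
  setNames_ <- c(unlist(.SUBGROUP_SETS, use.names = FALSE),
                 sprintf("signature_%02d",
                         seq_len(.N_SIGNATURE_SETS -
                                   length(unlist(.SUBGROUP_SETS)))))
  pool <- sample(regular)
  sets <- vector("list", length(setNames_))
  names(sets) <- setNames_
  idx <- 0L
  for (nm in setNames_) {
    sets[[nm]] <- pool[idx + seq_len(setSize)]
    idx <- idx + setSize
  }
  if (config@signatureOverlap > 0) {
    nShare <- round(config@signatureOverlap * setSize)
    shared <- pool[idx + seq_len(setSize)]
    for (nm in setNames_)
      sets[[nm]] <- unique(c(sample(shared, nShare),
                             sets[[nm]][seq_len(setSize - nShare)]))
    idx <- idx + setSize
  }
  signatureGenes <- unique(unlist(sets))
  gsc <- geneSetCollection(c(sets, list(cga_candidates = cgaGenes)),
                           provenance = "synthetic signature collection")

  ## --- cis genes and CNA layer --------------------------------------------
  cisPool <- setdiff(regular, signatureGenes)
  cisGenes <- sort(sample(cisPool, as.integer(config@cisGeneCount)))
  cna <- matrix(stats::rnorm(length(genes) * n, 0, 0.5), length(genes), n,
                dimnames = list(genes, samples))

  ## --- RNA layer (log2) ----------------------------------------------------
  mu <- c(stats::runif(nReg, 2, 8), stats::runif(nCga, -1, 1))
  names(mu) <- genes
  beta <- config@cisBeta
  epsSd <- sqrt(max(0, 1 - beta^2 * 0.25))
  z <- matrix(stats::rnorm(length(genes) * n), length(genes), n,
              dimnames = list(genes, samples))
  isCis <- genes %in% cisGenes
  z[isCis, ] <- beta * cna[isCis, ] + epsSd * z[isCis, ]
  rna <- mu + z
  delta <- config@signatureEffectDelta
  for (grp in .SUBTYPE_LEVELS) {
    gset <- unique(unlist(sets[.SUBGROUP_SETS[[grp]]]))
    rna[gset, labels == grp] <- rna[gset, labels == grp] + delta
  }

  ## --- protein layer (attenuated, partially missing) -----------------------
  a <- config@proteinAttenuation
  rnaZ <- (rna - rowMeans(rna)) / apply(rna, 1L, stats::sd)
  prot <- a * rnaZ + sqrt(1 - a^2) *
    matrix(stats::rnorm(length(genes) * n), length(genes), n)
  dimnames(prot) <- dimnames(rna)
  keepProt <- sort(sample(seq_along(genes),
                          round((1 - config@proteinMissingFraction) *
                                  length(genes))))
  prot <- prot[keepProt, , drop = FALSE]

  ## --- mutations -----------------------------------------------------------
  odds <- config@mutationEnrichmentOdds
  pMut <- ifelse(labels == "P", odds[["inP"]], odds[["elsewhere"]])
  tp53Carriers <- samples[stats::runif(n) < pMut]
  pStk <- ifelse(labels == "M", 0.45, 0.05)
  stkCarriers <- samples[stats::runif(n) < pStk]
  effectPool <- setdiff(rownames(prot), c(signatureGenes, cgaGenes))
  effectProteins <- sort(sample(effectPool, 20L))
  prot[effectProteins, stkCarriers] <- prot[effectProteins, stkCarriers] + 2

  lambdaBg <- c(P = 10, I = 4, A = 9, M = 10)[labels]
  bgGenes <- setdiff(regular, c(signatureGenes, cgaGenes, cisGenes))
  classes <- c("missense", "nonsense", "frameshift", "inframe_indel", "splice")
  classProb <- c(0.70, 0.10, 0.10, 0.05, 0.05)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    s <- samples[i]
    gs <- character()
    if (s %in% tp53Carriers) gs <- c(gs, "TP53")
    if (s %in% stkCarriers) gs <- c(gs, "STK11")
    nBg <- stats::rpois(1L, lambdaBg[i])
    gs <- c(gs, sample(bgGenes, nBg))
    nOther <- stats::rpois(1L, 2)
    cls <- c(sample(classes, length(gs), replace = TRUE, prob = classProb),
             rep("other", nOther))
    gs <- c(gs, sample(bgGenes, nOther))
    keep <- !duplicated(gs)
    if (!any(keep)) next
    recs[[i]] <- data.frame(sample = s, gene = gs[keep],
                            variant_class = cls[keep],
                            protein_change = sprintf("p.X%dY",
                                                     seq_len(sum(keep))),
                            stringsAsFactors = FALSE)
  }
  mutations <- do.call(rbind, recs)

  ## --- clinical + survival -------------------------------------------------
  sex <- ifelse(stats::runif(n) < 0.869, "F", "M")
  age <- pmin(85, pmax(40, round(stats::rnorm(n, 63, 10))))
  stage <- sample(c("I", "II", "III"), n, replace = TRUE,
                  prob = c(0.394, 0.333, 0.273))
  hr <- c(I = 1, config@hazardRatios)[labels]
  lambdaI <- log(2) / 60  # median OS of 60 months in the reference subgroup
  hazard <- lambdaI * hr
  eventT <- stats::rexp(n, hazard)
  meanHaz <- sum(config@subgroupProportions[.SUBTYPE_LEVELS] *
                   lambdaI * c(I = 1, config@hazardRatios)[.SUBTYPE_LEVELS])
  lambdaC <- config@censoringRate / max(1e-12, 1 - config@censoringRate) * meanHaz
  censT <- if (lambdaC > 0) stats::rexp(n, lambdaC) else rep(Inf, n)
  osTime <- round(pmin(eventT, censT), 2)
  osEvent <- as.integer(eventT <= censT)

  purity <- stats::runif(n, 0.5, 0.95)
  lowIdx <- sample(n, as.integer(config@nLowPurity))
  purity[lowIdx] <- stats::runif(length(lowIdx), 0.2, 0.39)
  clinical <- data.frame(sample = samples, sex = sex, age = age, stage = stage,
                         os_time_months = osTime, os_event = osEvent,
                         purity = round(purity, 3), stringsAsFactors = FALSE)

  ## --- planted CGA outliers (on the linear-FPKM scale) ---------------------
  pmPool <- samples[labels %in% c("P", "M") & purity >= 0.4]
  cgaSamples <- sample(pmPool, min(config@nCgaPositive, length(pmPool)))
  cgaHits <- sample(cgaGenes, length(cgaSamples))
  for (j in seq_along(cgaSamples)) {
    g <- cgaHits[j]; s <- cgaSamples[j]
    lin <- 2^rna[g, ]
    rna[g, s] <- log2(200 * mean(lin[samples != s]))
  }
  cgaCalls <- data.frame(gene = cgaHits, sample = cgaSamples,
                         stringsAsFactors = FALSE)

  truth <- list(labels = labels, cisGenes = cisGenes, cgaCalls = cgaCalls,
                subgroupSets = .SUBGROUP_SETS, mutationGene = "TP53",
                effectGene = "STK11", effectProteins = effectProteins,
                lowPurity = samples[lowIdx], seed = as.integer(config@seed))

  new("CohortBundle",
      rna = omicsMatrix(rna, "rna", "log2"),
      protein = omicsMatrix(prot, "protein", "log2"),
      cna = omicsMatrix(cna, "cna", "log2"),
      mutations = mutations, clinical = clinical, geneSets = gsc,
      truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a log2 expression matrix to the linear-FPKM view
#'
#' \code{2^x} elementwise (values are positive by construction, satisfying
#' the linear-FPKM non-negativity invariant).  Identity for matrices already
#' on the linear scale.
#'
#' @param x an [OmicsMatrix-class].
#' @return An [OmicsMatrix-class] on scale \code{"linear_fpkm"}.
#' @export
toLinearFpkm <- function(x) {
  if (x@scale == "linear_fpkm") return(x)
  omicsMatrix(2^omicsValues(x), x@layer, "linear_fpkm")
}
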