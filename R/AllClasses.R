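#' @import methods
NULL

.OMICS_LAYERS <- c("rna", "protein", "cna")
.OMICS_SCALES <- c("linear_fpkm", "log2")
.SUBTYPE_LEVELS <- c("P", "I", "A", "M")
.PROTEIN_ALTERING <- c("missense", "nonsense", "frameshift", "inframe_indel", "splice")
.VARIANT_CLASSES <- c(.PROTEIN_ALTERING, "other")

#' OmicsMatrix: a genes-by-samples numeric matrix with layer metadata
#'
#' The substrate of all scoring operations: one molecular layer (RNA
#' expression, TMT protein log-ratio abundance, or gene-level copy-number
#' log2 ratio) as a numeric matrix with genes in rows and samples in
#' columns.  Missing values are permitted only in the protein layer, where
#' TMT panels never cover every gene; linear-FPKM values must be
#' non-negative.
#'
#' @slot values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames).
#' @slot layer one of \code{"rna"}, \code{"protein"}, \code{"cna"}.
#' @slot scale one of \code{"linear_fpkm"}, \code{"log2"}.  The cna layer is
#'   always a log2 copy ratio centred near 0 and uses \code{"log2"}.
#'
#' @seealso [omicsMatrix()] for the user-facing constructor,
#'   [readOmicsMatrix()] for TSV input.
#' @export
setClass("OmicsMatrix",
  representation(values = "matrix", layer = "character", scale = "character"))

setValidity("OmicsMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (length(object@layer) != 1L || !object@layer %in% .OMICS_LAYERS)
    msgs <- c(msgs, sprintf("layer must be one of %s", paste(.OMICS_LAYERS, collapse = ", ")))
  if (length(object@scale) != 1L || !object@scale %in% .OMICS_SCALES)
    msgs <- c(msgs, sprintf("scale must be one of %s", paste(.OMICS_SCALES, collapse = ", ")))
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  if (nrow(v) && (is.null(rownames(v)) || anyDuplicated(rownames(v))))
    msgs <- c(msgs, "gene identifiers must be present and unique")
  if (ncol(v) && (is.null(colnames(v)) || anyDuplicated(colnames(v))))
    msgs <- c(msgs, "sample identifiers must be present and unique")
  if (length(msgs) == 0L) {
    if (anyNA(v) && !identical(object@layer, "protein"))
      msgs <- c(msgs, "missing values are allowed only in the protein layer")
    if (identical(object@scale, "linear_fpkm") && any(v < 0, na.rm = TRUE))
      msgs <- c(msgs, "linear_fpkm values must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' GeneSetCollection: named gene lists
#'
#' Holds named gene sets (e.g. the 31 tumour-microenvironment / malignant-cell
#' signatures used for subtyping, hallmark-style collections, or the
#' cancer-germline-antigen candidate list).  Set names are unique, every set
#' is non-empty and genes within a set are unique.
#'
#' @slot sets named list of character vectors.
#' @slot provenance free-text description of where the sets came from.
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", provenance = "character"))

setValidity("GeneSetCollection", function(object) {
  s <- object@sets
  msgs <- character()
  if (length(s)) {
    if (is.null(names(s)) || anyDuplicated(names(s)) || any(!nzchar(names(s))))
      msgs <- c(msgs, "set names must be present and unique")
    if (!all(vapply(s, is.character, logical(1))))
      msgs <- c(msgs, "each set must be a character vector of gene ids")
    else {
      if (any(vapply(s, length, integer(1)) == 0L))
        msgs <- c(msgs, "each set must be non-empty")
      if (any(vapply(s, anyDuplicated, integer(1)) > 0L))
        msgs <- c(msgs, "genes within a set must be unique")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' EnrichmentMatrix: signatures-by-samples enrichment scores
#'
#' Result of single-sample GSEA scoring: one row per gene set (optionally
#' suffixed by molecular layer after [combineLayers()]), one column per
#' sample.  Carries the rank-weight exponent used and whether global
#' (max - min) normalisation was applied.
#'
#' @slot scores numeric matrix of enrichment scores, finite, unique dimnames.
#' @slot alpha rank-weight exponent used for scoring.
#' @slot normalized logical, whether scores were divided by the global range.
#' @export
setClass("EnrichmentMatrix",
  representation(scores = "matrix", alpha = "numeric", normalized = "logical"))

setValidity("EnrichmentMatrix", function(object) {
  s <- object@scores
  msgs <- character()
  if (!is.numeric(s) || any(!is.finite(s)))
    msgs <- c(msgs, "scores must be finite numeric")
  if (nrow(s) && (is.null(rownames(s)) || anyDuplicated(rownames(s))))
    msgs <- c(msgs, "signature names must be present and unique")
  if (ncol(s) && (is.null(colnames(s)) || anyDuplicated(colnames(s))))
    msgs <- c(msgs, "sample names must be present and unique")
  if (length(object@alpha) != 1L || object@alpha < 0)
    msgs <- c(msgs, "alpha must be a single non-negative number")
  if (length(msgs)) msgs else TRUE
})

#' SubtypeAssignment: sample-to-subgroup labels with the decisions behind them
#'
#' @slot labels named character vector, sample -> one of P, I, A, M.
#' @slot prolifThreshold the Q3 proliferation-score cutoff actually used.
#' @slot tcellThreshold the T-cell-score cutoff actually used (minimum score
#'   of the immune-high group under the cluster rule).
#' @slot splitTree the \code{hclust} merge history of the final two-way
#'   angiogenesis/metabolism split (list-wrapped; empty for pure-hclust mode).
#' @slot mode \code{"cascade"} or \code{"pure_hclust"}.
#' @export
setClass("SubtypeAssignment",
  representation(labels = "character", prolifThreshold = "numeric",
                 tcellThreshold = "numeric", splitTree = "list",
                 mode = "character"))

setValidity("SubtypeAssignment", function(object) {
  msgs <- character()
  if (is.null(names(object@labels)) || anyDuplicated(names(object@labels)))
    msgs <- c(msgs, "labels must be named by unique sample ids")
  if (!all(object@labels %in% .SUBTYPE_LEVELS))
    msgs <- c(msgs, "labels must be one of P, I, A, M")
  if (!object@mode %in% c("cascade", "pure_hclust"))
    msgs <- c(msgs, "mode must be 'cascade' or 'pure_hclust'")
  if (length(msgs)) msgs else TRUE
})

#' SimulationConfig: parameters of the synthetic study generator
#'
#' Defaults mirror the study conditions: 99 analysable samples plus 3 planted
#' low-purity samples, four latent subgroups (P 25\%, I 30\%, A 20\%, M 25\%),
#' a +1.5 log2 shift on a subgroup's own signature genes, an attenuated
#' protein layer with target RNA-protein correlation 0.6, 300 cis dosage
#' genes at beta = 0.8, a TP53-like mutation at 48\% in P versus 10\%
#' elsewhere, subgroup hazard ratios versus I of P 2.9 / A 2.0 / M 1.4,
#' ~40\% censoring, and 10 CGA-outlier-positive samples drawn from P and M.
#'
#' @slot nSamples total samples generated (analysable + planted low-purity).
#' @slot nLowPurity number of planted samples with purity below 0.4.
#' @slot nGenes number of genes.
#' @slot subgroupProportions named numeric (P, I, A, M) summing to 1.
#' @slot signatureEffectDelta log2 shift on own-subgroup signature genes.
#' @slot proteinAttenuation target per-gene RNA-protein correlation.
#' @slot proteinMissingFraction fraction of genes absent from the protein layer.
#' @slot cisGeneCount number of genes with a planted CNA dosage effect.
#' @slot cisBeta dosage slope linking CNA to standardised RNA.
#' @slot mutationEnrichmentOdds named numeric: TP53-like mutation frequency
#'   inside P (\code{inP}) and elsewhere (\code{elsewhere}).
#' @slot hazardRatios named numeric hazard ratios versus the I subgroup.
#' @slot censoringRate target fraction of censored survival times.
#' @slot nCgaPositive number of CGA-outlier-positive samples (P and M only).
#' @slot signatureSetSize genes per planted signature set.
#' @slot signatureOverlap fraction of shared genes between signature sets
#'   (0 = disjoint, the default).
#' @slot seed integer seed; a fixed seed yields a byte-identical bundle.
#' @export
setClass("SimulationConfig",
  representation(nSamples = "numeric", nLowPurity = "numeric",
                 nGenes = "numeric", subgroupProportions = "numeric",
                 signatureEffectDelta = "numeric", proteinAttenuation = "numeric",
                 proteinMissingFraction = "numeric",
                 cisGeneCount = "numeric", cisBeta = "numeric",
                 mutationEnrichmentOdds = "numeric", hazardRatios = "numeric",
                 censoringRate = "numeric", nCgaPositive = "numeric",
                 signatureSetSize = "numeric", signatureOverlap = "numeric",
                 seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  p <- object@subgroupProportions
  if (!identical(sort(names(p)), sort(.SUBTYPE_LEVELS)))
    msgs <- c(msgs, "subgroupProportions must be named P, I, A, M")
  else if (abs(sum(p) - 1) > 1e-8)
    msgs <- c(msgs, "subgroupProportions must sum to 1")
  for (nm in c("censoringRate", "proteinMissingFraction", "proteinAttenuation",
               "signatureOverlap")) {
    val <- slot(object, nm)
    if (length(val) != 1L || val < 0 || val > 1)
      msgs <- c(msgs, sprintf("%s must be a single value in [0, 1]", nm))
  }
  if (any(object@mutationEnrichmentOdds < 0 | object@mutationEnrichmentOdds > 1))
    msgs <- c(msgs, "mutationEnrichmentOdds rates must be in [0, 1]")
  if (object@nSamples < object@nLowPurity + 4)
    msgs <- c(msgs, "nSamples must exceed nLowPurity + 4")
  if (length(msgs)) msgs else TRUE
})

#' CohortBundle: the full study object
#'
#' Everything one run of the pipeline consumes: the three omics layers, the
#' somatic mutation table, the clinical table, the gene-set collection used
#' for scoring, and -- for synthetic cohorts only -- the planted ground truth
#' (subgroup labels, cis genes, CGA calls, signature membership).
#'
#' @slot rna,protein,cna [OmicsMatrix-class] layers sharing a sample universe.
#' @slot mutations data.frame with columns sample, gene, variant_class,
#'   protein_change.
#' @slot clinical data.frame with columns sample, sex, age, stage,
#'   os_time_months, os_event, purity.
#' @slot geneSets [GeneSetCollection-class] used for signature scoring.
#' @slot truth list of planted ground truth; empty for real cohorts.
#' @export
setClass("CohortBundle",
  representation(rna = "OmicsMatrix", protein = "OmicsMatrix",
                 cna = "OmicsMatrix", mutations = "data.frame",
                 clinical = "data.frame", geneSets = "GeneSetCollection",
                 truth = "list"))

setValidity("CohortBundle", function(object) {
  msgs <- character()
  univ <- object@clinical$sample
  if (is.null(univ)) return("clinical table must have a 'sample' column")
  if (anyDuplicated(univ)) msgs <- c(msgs, "clinical table must have one row per sample")
  for (nm in c("rna", "protein", "cna")) {
    m <- slot(object, nm)
    if (ncol(m@values) && !setequal(colnames(m@values), univ))
      msgs <- c(msgs, sprintf("%s samples differ from the clinical sample universe", nm))
  }
  if (nrow(object@mutations) && !all(object@mutations$sample %in% univ))
    msgs <- c(msgs, "every mutation sample must appear in the cohort sample list")
  if (length(msgs)) msgs else TRUE
})
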