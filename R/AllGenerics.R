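#' @include AllClasses.R
NULL

#' Accessors for proteoSubtype classes
#'
#' Small accessor generics: \code{omicsValues} returns the numeric matrix of
#' an [OmicsMatrix-class] or the score matrix of an
#' [EnrichmentMatrix-class]; \code{omicsLayer} and \code{omicsScale} return
#' the layer/scale tags; \code{geneIds} and \code{sampleIds} the dimnames;
#' \code{geneSets} the named list of a [GeneSetCollection-class];
#' \code{subtypeLabels} the named label vector of a
#' [SubtypeAssignment-class].
#'
#' @param x an object of the matching class.
#' @return See each accessor's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("omicsValues", function(x) standardGeneric("omicsValues"))
#' @rdname accessors
#' @export
setGeneric("omicsLayer", function(x) standardGeneric("omicsLayer"))
#' @rdname accessors
#' @export
setGeneric("omicsScale", function(x) standardGeneric("omicsScale"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("subtypeLabels", function(x) standardGeneric("subtypeLabels"))

#' @rdname accessors
setMethod("omicsValues", "OmicsMatrix", function(x) x@values)
#' @rdname accessors
setMethod("omicsValues", "EnrichmentMatrix", function(x) x@scores)
#' @rdname accessors
setMethod("omicsLayer", "OmicsMatrix", function(x) x@layer)
#' @rdname accessors
setMethod("omicsScale", "OmicsMatrix", function(x) x@scale)
#' @rdname accessors
setMethod("geneIds", "OmicsMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("sampleIds", "OmicsMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("sampleIds", "EnrichmentMatrix", function(x) colnames(x@scores))
#' @rdname accessors
setMethod("sampleIds", "CohortBundle", function(x) x@clinical$sample)
#' @rdname accessors
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)
#' @rdname accessors
setMethod("geneSets", "CohortBundle", function(x) x@geneSets@sets)
#' @rdname accessors
setMethod("subtypeLabels", "SubtypeAssignment", function(x) x@labels)

#' @rdname accessors
setMethod("length", "GeneSetCollection", function(x) length(x@sets))
#' @rdname accessors
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

setMethod("show", "OmicsMatrix", function(object) {
  v <- object@values
  cat(sprintf("OmicsMatrix [%s, %s]: %d genes x %d samples", object@layer,
              object@scale, nrow(v), ncol(v)))
  if (anyNA(v)) cat(sprintf(" (%.1f%% NA)", 100 * mean(is.na(v))))
  cat("\n")
})

setMethod("show", "GeneSetCollection", function(object) {
  sizes <- vapply(object@sets, length, integer(1))
  cat(sprintf("GeneSetCollection: %d sets (sizes %s)", length(object@sets),
              if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "-"))
  if (length(object@provenance) && nzchar(object@provenance[1]))
    cat(" |", object@provenance[1])
  cat("\n")
})

setMethod("show", "EnrichmentMatrix", function(object) {
  cat(sprintf("EnrichmentMatrix: %d signatures x %d samples (alpha = %g, %s)\n",
              nrow(object@scores), ncol(object@scores), object@alpha,
              if (object@normalized) "normalized" else "unnormalized"))
})

setMethod("show", "SubtypeAssignment", function(object) {
  tab <- table(factor(object@labels, levels = .SUBTYPE_LEVELS))
  cat(sprintf("SubtypeAssignment [%s]: %s\n", object@mode,
              paste(names(tab), tab, sep = "=", collapse = " ")))
})

setMethod("show", "CohortBundle", function(object) {
  cat(sprintf("CohortBundle: %d samples | rna %d genes, protein %d, cna %d | %d mutations | %d gene sets%s\n",
              nrow(object@clinical), nrow(object@rna@values),
              nrow(object@protein@values), nrow(object@cna@values),
              nrow(object@mutations), length(object@geneSets@sets),
              if (length(object@truth)) " | synthetic (truth attached)" else ""))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d samples (%d low-purity), %d genes, delta = %g, seed = %d\n",
              object@nSamples, object@nLowPurity, object@nGenes,
              object@signatureEffectDelta, as.integer(object@seed)))
})
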