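#' @include AllClasses.R io.R
NULL

# Core running-sum for one sample.  `ord` = gene indices in descending
# expression order; weights = |rank statistic|^alpha with the rank statistic
# taken as the (reversed) rank position, so the top-ranked gene carries the
# largest weight.  For each set the score is the summed difference between
# the weighted in-set ECDF and the unweighted complement ECDF over all rank
# positions (running-sum *sum* variant, not max deviation).
.ssgseaSample <- function(xs, membership, alpha, variant) {
  keep <- which(!is.na(xs))
  nK <- length(keep)
  ord <- keep[order(xs[keep], decreasing = TRUE)]  # stable: ties by input order
  w <- (nK:1)^alpha
  out <- numeric(ncol(membership))
  for (k in seq_len(ncol(membership))) {
    ind <- membership[ord, k]
    wIn <- w * ind
    denomIn <- sum(wIn)
    nOut <- nK - sum(ind)
    if (denomIn == 0 || nOut == 0) { out[k] <- NA_real_; next }
    diffs <- cumsum(wIn) / denomIn - cumsum(!ind) / nOut
    out[k] <- if (variant == "sum") sum(diffs) else diffs[which.max(abs(diffs))]
  }
  out
}

#' Single-sample GSEA scores
#'
#' Scores every sample of an expression matrix against a gene-set
#' collection with the rank-weighted running-sum statistic: per sample,
#' genes are ranked by decreasing expression (ties broken stably by input
#' gene order, missing values excluded from the ranking); the enrichment
#' score of a set is the sum over all rank positions of the difference
#' between the weighted in-set ECDF (weights = rank position to the power
#' \code{alpha}) and the complement ECDF.  With \code{normalize = TRUE} the
#' whole score matrix is divided by its global (max - min) range.
#'
#' Sets reduced to fewer than \code{minSetSize} genes present in the matrix
#' are dropped with a warning; a set covering the entire gene universe has
#' an empty complement and is an error, as is a collection with no set
#' intersecting the matrix.
#'
#' @param x an [OmicsMatrix-class] or a plain genes-by-samples matrix.
#' @param sets a [GeneSetCollection-class] or a named list of gene vectors.
#' @param alpha rank-weight exponent (default 0.25).
#' @param normalize divide scores by the global (max - min) range.
#' @param variant \code{"sum"} (default) adds all running-sum increments;
#'   \code{"maxdev"} takes the maximum deviation instead.
#' @param minSetSize minimum number of set genes that must be present.
#' @return An [EnrichmentMatrix-class] (sets x samples).
#' @examples
#' m <- matrix(c(5, 4, 3, 2, 1), 5, 1,
#'             dimnames = list(paste0("g", 1:5), "s1"))
#' es <- ssgseaScore(m, list(top = c("g1", "g2")), alpha = 0,
#'                   normalize = FALSE)
#' omicsValues(es)  # 2.5
#' @export
ssgseaScore <- function(x, sets, alpha = 0.25, normalize = TRUE,
                        variant = c("sum", "maxdev"), minSetSize = 2) {
  variant <- match.arg(variant)
  v <- if (is(x, "OmicsMatrix")) omicsValues(x) else x
  setList <- if (is(sets, "GeneSetCollection")) sets@sets else sets
  genes <- rownames(v)
  present <- lapply(setList, intersect, y = genes)
  sizes <- vapply(present, length, integer(1))
  if (all(sizes == 0L))
    stop("no gene set intersects the expression matrix")
  drop <- sizes < minSetSize
  if (any(drop)) {
    warning("dropping ", sum(drop), " set(s) with fewer than ", minSetSize,
            " genes present: ", paste(names(present)[drop], collapse = ", "))
    present <- present[!drop]
  }
  full <- vapply(present, function(g) length(g) == length(genes), logical(1))
  if (any(full))
    stop("set(s) covering the whole gene universe have an empty complement: ",
         paste(names(present)[full], collapse = ", "))
  membership <- vapply(present, function(g) genes %in% g,
                       logical(length(genes)))
  membership <- matrix(membership, nrow = length(genes),
                       dimnames = list(genes, names(present)))
  scores <- vapply(seq_len(ncol(v)), function(j)
    .ssgseaSample(v[, j], membership, alpha, variant),
    numeric(ncol(membership)))
  scores <- matrix(scores, nrow = ncol(membership),
                   dimnames = list(names(present), colnames(v)))
  if (anyNA(scores)) {
    bad <- rownames(scores)[apply(is.na(scores), 1L, any)]
    warning("dropping set(s) unscorable in at least one sample: ",
            paste(bad, collapse = ", "))
    scores <- scores[setdiff(rownames(scores), bad), , drop = FALSE]
    if (!nrow(scores)) stop("no scorable gene set remains")
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  new("EnrichmentMatrix", scores = scores, alpha = alpha,
      normalized = normalize)
}

#' ESTIMATE-style immune and stromal scores
#'
#' Unnormalised single-sample GSEA scores of the dedicated immune and
#' stromal signatures, plus their sum as a combined score, as a per-sample
#' table.
#'
#' @param rna an [OmicsMatrix-class] (RNA layer) or matrix.
#' @param immuneSet,stromalSet character vectors of signature genes.
#' @param alpha rank-weight exponent.
#' @return data.frame with columns sample, immune, stromal, combined.
#' @export
estimateScores <- function(rna, immuneSet, stromalSet, alpha = 0.25) {
  es <- ssgseaScore(rna, list(immune = immuneSet, stromal = stromalSet),
                    alpha = alpha, normalize = FALSE)
  s <- omicsValues(es)
  data.frame(sample = colnames(s), immune = s["immune", ],
             stromal = s["stromal", ], combined = s["immune", ] + s["stromal", ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Combine RNA and protein enrichment matrices into one
#'
#' Each row is z-scored across samples within its layer (optional but
#' default), then the two matrices are stacked with layer-suffixed row
#' names (\code{<set>_rna}, \code{<set>_protein}).  The protein layer may
#' have dropped sets; the sample sets must be identical.
#'
#' @param rnaEs,proteinEs [EnrichmentMatrix-class] objects on the same
#'   samples.
#' @param zscore z-score rows within layer before stacking.
#' @return An [EnrichmentMatrix-class] with stacked, layer-suffixed rows.
#' @export
combineLayers <- function(rnaEs, proteinEs, zscore = TRUE) {
  a <- omicsValues(rnaEs)
  b <- omicsValues(proteinEs)
  if (nrow(a) == 0L || ncol(a) == 0L || nrow(b) == 0L || ncol(b) == 0L)
    stop("both layers must contain at least one signature and one sample")
  if (!setequal(colnames(a), colnames(b)))
    stop("RNA and protein enrichment matrices cover different samples")
  b <- b[, colnames(a), drop = FALSE]
  zrow <- function(m) {
    if (!zscore) return(m)
    sds <- apply(m, 1L, stats::sd)
    if (any(sds == 0)) stop("cannot z-score constant signature row(s): ",
                            paste(rownames(m)[sds == 0], collapse = ", "))
    (m - rowMeans(m)) / sds
  }
  a <- zrow(a); b <- zrow(b)
  rownames(a) <- paste0(rownames(a), "_rna")
  rownames(b) <- paste0(rownames(b), "_protein")
  new("EnrichmentMatrix", scores = rbind(a, b), alpha = rnaEs@alpha,
      normalized = rnaEs@normalized)
}
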