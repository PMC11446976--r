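#' @include AllClasses.R enrichment.R
NULL

#' Complete-linkage hierarchical clustering of coordinate rows
#'
#' Thin, deterministic wrapper around \code{stats::hclust} on Euclidean
#' distances with the complete method: clusters with the smallest maximum
#' pairwise distance are merged iteratively.  Ties resolve toward the lower
#' input index, so a duplicated point set yields the same partition
#' regardless of input order.
#'
#' @param points numeric matrix, one observation per row (a vector is
#'   treated as 1-D observations).
#' @return An object of class \code{hclust}.
#' @examples
#' tree <- hclustComplete(c(a = 0, b = 1, c = 10))
#' cutTree(tree, 2)  # a, b together; c alone
#' @export
hclustComplete <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1,
                                             dimnames = list(names(points)))
  if (nrow(points) < 2L) stop("need at least 2 points to cluster")
  stats::hclust(stats::dist(points, method = "euclidean"), method = "complete")
}

#' Cut a dendrogram into k groups
#'
#' @param tree an \code{hclust} object.
#' @param k number of groups; must not exceed the number of leaves.
#' @return Integer cluster labels named by observation.
#' @export
cutTree <- function(tree, k) {
  n <- length(tree$order)
  if (k > n) stop("k = ", k, " exceeds the number of observations (", n, ")")
  stats::cutree(tree, k = k)
}

# average the rna/protein variants of one signature row; error if absent
.keyRow <- function(scores, key) {
  hits <- rownames(scores)[rownames(scores) %in%
                             c(key, paste0(key, c("_rna", "_protein")))]
  if (!length(hits))
    stop("signature row '", key, "' not found in the enrichment matrix")
  colMeans(scores[hits, , drop = FALSE])
}

.defaultKeys <- c(prolif = "proliferation", tcell = "t_cell",
                  angio = "angiogenesis", metab = "metabolism")

#' Cascaded four-subgroup classifier
#'
#' The operative subtyping rule: (1) samples in the top quartile of the
#' proliferation signature (score >= the cohort's Q3, linear-interpolation
#' quantile) form the proliferation-high subgroup P; (2) among the
#' remainder, T-cell-signature-high samples form the immune-high subgroup I;
#' (3) the rest are split in two by complete-linkage clustering on their
#' full enrichment profiles, and the cluster with the higher mean
#' angiogenesis score is labelled A, the other M (ties toward A).
#'
#' The T-cell-high rule defaults to a deterministic two-group
#' complete-linkage split of the T-cell score among non-P samples (the
#' higher-mean group is I), which adapts to the actual size of the immune
#' subgroup; passing \code{tcellQ} switches to a fixed-quantile rule
#' symmetric with the Q3 proliferation step.
#'
#' Signature rows present in both layers (suffixed \code{_rna} /
#' \code{_protein}) are averaged before thresholding.
#'
#' @param es an [EnrichmentMatrix-class], typically from [combineLayers()].
#' @param keys named character vector mapping \code{prolif}, \code{tcell},
#'   \code{angio}, \code{metab} to signature row names.
#' @param q proliferation quantile (default 0.75, the Q3 rule).
#' @param tcellQ optional quantile in (0, 1) for the T-cell step; \code{NULL}
#'   (default) uses the two-group split rule.
#' @return A [SubtypeAssignment-class].
#' @export
classifyCascade <- function(es, keys = .defaultKeys, q = 0.75, tcellQ = NULL) {
  stopifnot(all(c("prolif", "tcell", "angio", "metab") %in% names(keys)))
  s <- omicsValues(es)
  samples <- colnames(s)
  if (length(samples) < 4L) stop("need at least 4 samples to classify")
  prolif <- .keyRow(s, keys[["prolif"]])
  if (stats::sd(prolif) == 0)
    stop("non-informative proliferation score: all samples tie at Q3")
  prolifThr <- stats::quantile(prolif, q, type = 7, names = FALSE)
  labels <- stats::setNames(rep(NA_character_, length(samples)), samples)
  labels[prolif >= prolifThr] <- "P"
  nonP <- samples[is.na(labels)]
  if (!length(nonP))
    stop("non-informative proliferation score: every sample exceeds Q3")

  tcell <- .keyRow(s, keys[["tcell"]])[nonP]
  if (!is.null(tcellQ)) {
    tThr <- stats::quantile(tcell, tcellQ, type = 7, names = FALSE)
    iSamples <- nonP[tcell >= tThr]
  } else if (stats::sd(tcell) == 0) {
    iSamples <- character()
    tThr <- Inf
  } else {
    grp <- cutTree(hclustComplete(tcell), 2L)
    hi <- which.max(tapply(tcell, grp, mean))
    iSamples <- nonP[grp == as.integer(names(hi))]
    tThr <- min(tcell[grp == as.integer(names(hi))])
  }
  labels[iSamples] <- "I"

  rest <- samples[is.na(labels)]
  angio <- .keyRow(s, keys[["angio"]])
  metab <- .keyRow(s, keys[["metab"]])
  tree <- NULL
  if (length(rest) == 1L) {
    labels[rest] <- if (angio[rest] >= metab[rest]) "A" else "M"
  } else if (length(rest) >= 2L) {
    tree <- hclustComplete(t(s[, rest, drop = FALSE]))
    grp <- cutTree(tree, 2L)
    m1 <- mean(angio[rest][grp == 1L])
    m2 <- mean(angio[rest][grp == 2L])
    aCluster <- if (m1 >= m2) 1L else 2L  # ties broken toward A
    labels[rest] <- ifelse(grp == aCluster, "A", "M")
  }
  new("SubtypeAssignment", labels = labels, prolifThreshold = prolifThr,
      tcellThreshold = tThr, splitTree = if (is.null(tree)) list() else
        list(tree), mode = "cascade")
}

#' Single-cut four-group hierarchical classifier
#'
#' The alternative subtyping mode: complete-linkage clustering of the sample
#' columns of the combined enrichment matrix, cut at \code{k}, with each
#' cluster annotated P/I/A/M by its maximal mean key-signature score.  Two
#' clusters claiming the same label is an annotation collision and an
#' error listing the cluster means.
#'
#' @inheritParams classifyCascade
#' @param k number of clusters (default 4).
#' @return A [SubtypeAssignment-class] with mode \code{"pure_hclust"}.
#' @export
classifyPureHclust <- function(es, k = 4, keys = .defaultKeys) {
  s <- omicsValues(es)
  samples <- colnames(s)
  if (length(samples) < k) stop("fewer samples than clusters requested")
  if (k < 2L)
    stop("annotation collision: a single cluster cannot be assigned ",
         "one of four subtype labels")
  keyScores <- rbind(P = .keyRow(s, keys[["prolif"]]),
                     I = .keyRow(s, keys[["tcell"]]),
                     A = .keyRow(s, keys[["angio"]]),
                     M = .keyRow(s, keys[["metab"]]))
  tree <- hclustComplete(t(s))
  grp <- cutTree(tree, k)
  clusterMeans <- vapply(sort(unique(grp)), function(g)
    rowMeans(keyScores[, grp == g, drop = FALSE]), numeric(4L))
  anno <- rownames(keyScores)[apply(clusterMeans, 2L, which.max)]
  if (anyDuplicated(anno)) {
    msg <- paste(apply(round(clusterMeans, 3), 2L, paste, collapse = "/"),
                 collapse = "; ")
    stop("annotation collision: clusters share a maximal key signature ",
         "(cluster means P/I/A/M: ", msg, ")")
  }
  labels <- stats::setNames(anno[grp], samples)
  new("SubtypeAssignment", labels = labels, prolifThreshold = NA_real_,
      tcellThreshold = NA_real_, splitTree = list(tree),
      mode = "pure_hclust")
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples
#' (1 = identical, ~0 = random agreement).  Used to compare recovered
#' subgroups with planted truth.
#'
#' @param a,b label vectors; if both are named they are aligned by name.
#' @return Numeric scalar.
#' @export
adjustedRand <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  stopifnot(length(a) == length(b), !anyNA(a), !anyNA(b))
  tab <- table(a, b)
  n <- sum(tab)
  sumIj <- sum(choose(tab, 2))
  sumI <- sum(choose(rowSums(tab), 2))
  sumJ <- sum(choose(colSums(tab), 2))
  expected <- sumI * sumJ / choose(n, 2)
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expected) return(1)
  (sumIj - expected) / (maxIdx - expected)
}
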