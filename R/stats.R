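#' @include AllClasses.R
NULL

#' Welch's two-sample t-test
#'
#' Two-sided Welch (unequal-variance) t-test via \code{stats::t.test}, with
#' the degenerate constant-data case resolved explicitly: identical
#' constant groups give t = 0, p = 1; constant groups with different means
#' give a floored p of 1e-300.
#'
#' @param x,y numeric vectors.
#' @return list with \code{t}, \code{df}, \code{p}, \code{delta}
#'   (\code{mean(x) - mean(y)}).
#' @export
welchT <- function(x, y) {
  delta <- mean(x) - mean(y)
  res <- tryCatch(stats::t.test(x, y, var.equal = FALSE),
                  error = function(e) NULL)
  if (is.null(res)) {
    if (delta == 0) return(list(t = 0, df = NA_real_, p = 1, delta = 0))
    return(list(t = sign(delta) * Inf, df = NA_real_, p = 1e-300,
                delta = delta))
  }
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, delta = delta)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney-Wilcoxon via \code{stats::wilcox.test}.
#'
#' @param x,y numeric vectors.
#' @return list with \code{U} (the rank-sum statistic) and \code{p}.
#' @export
wilcoxonRankSum <- function(x, y) {
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
  list(U = unname(res$statistic), p = res$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p numeric vector of raw p-values.
#' @return Step-up adjusted q-values (monotone, never below the raw p).
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")

# Row-wise Welch t between two column-groups of a matrix; NA-tolerant.
# Returns delta, t, df, p (p floored at 1e-300; NA when a side has < 2
# usable values or both variances vanish with equal means).
rowWelch <- function(a, b) {
  n1 <- rowSums(!is.na(a)); n2 <- rowSums(!is.na(b))
  m1 <- rowMeans(a, na.rm = TRUE); m2 <- rowMeans(b, na.rm = TRUE)
  v1 <- rowSums((a - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((b - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  delta <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  t <- delta / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zeroVar <- se2 == 0
  p[zeroVar & delta != 0] <- 1e-300
  t[zeroVar & delta != 0] <- sign(delta[zeroVar & delta != 0]) * Inf
  p[zeroVar & delta == 0] <- 1
  t[zeroVar & delta == 0] <- 0
  bad <- n1 < 2 | n2 < 2
  p[bad] <- NA_real_; t[bad] <- NA_real_
  p <- pmax(p, 1e-300)
  list(delta = delta, t = t, df = df, p = p)
}

#' Weighted-rank marker statistic per layer
#'
#' For each gene and layer, the magnitude of change multiplied by the
#' significance: \code{w = sign(delta) * |delta| * (-log10 p)}, where
#' \code{delta} is the group-vs-rest mean difference and \code{p} the
#' two-sided Welch p (floored at 1e-300, so \code{w} is finite and zero iff
#' \code{delta} is zero).  Genes missing from a layer are omitted from that
#' layer.
#'
#' @param rna an [OmicsMatrix-class] or matrix (RNA layer).
#' @param protein optional [OmicsMatrix-class] or matrix (protein layer).
#' @param labels named group labels covering the matrix samples.
#' @param group the group compared against the rest; needs >= 3 members and
#'   >= 3 non-members.
#' @param useQ use BH-adjusted q instead of raw p as the significance term.
#' @return data.frame: gene, layer, delta, p, w.
#' @export
weightedRank <- function(rna, protein = NULL, labels, group, useQ = FALSE) {
  layerScore <- function(mat, layer) {
    v <- if (is(mat, "OmicsMatrix")) omicsValues(mat) else mat
    v <- v[, colnames(v) %in% names(labels), drop = FALSE]
    inG <- colnames(v) %in% names(labels)[labels == group]
    if (sum(inG) < 3L || sum(!inG) < 3L)
      stop("group '", group, "' needs >= 3 members and >= 3 non-members")
    wt <- rowWelch(v[, inG, drop = FALSE], v[, !inG, drop = FALSE])
    keep <- !is.na(wt$p)
    sig <- if (useQ) stats::p.adjust(wt$p[keep], "BH") else wt$p[keep]
    sig <- pmax(sig, 1e-300)
    data.frame(gene = rownames(v)[keep], layer = layer,
               delta = wt$delta[keep], p = wt$p[keep],
               w = sign(wt$delta[keep]) * abs(wt$delta[keep]) * -log10(sig),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- layerScore(rna, "rna")
  if (!is.null(protein)) out <- rbind(out, layerScore(protein, "protein"))
  out
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric enrichment of a hit list in each
#' gene set, restricted to the given universe.  Sets that do not intersect
#' the universe are skipped with a warning.  With zero overlap the
#' upper-tail p is 1.
#'
#' @param hits character vector of hit genes (intersected with the
#'   universe).
#' @param universe character vector of background genes.
#' @param sets a [GeneSetCollection-class] or named list.
#' @return data.frame: set, overlap, set_size, n_hits, universe, p, q.
#' @export
hypergeomEnrich <- function(hits, universe, sets) {
  setList <- if (is(sets, "GeneSetCollection")) sets@sets else sets
  universe <- unique(universe)
  hits <- intersect(hits, universe)
  inUniv <- lapply(setList, intersect, y = universe)
  empty <- vapply(inUniv, length, integer(1)) == 0L
  if (any(empty)) {
    warning("skipping ", sum(empty), " set(s) not intersecting the universe: ",
            paste(names(setList)[empty], collapse = ", "))
    inUniv <- inUniv[!empty]
  }
  rows <- lapply(names(inUniv), function(nm) {
    m <- length(inUniv[[nm]])
    k <- length(intersect(hits, inUniv[[nm]]))
    p <- stats::phyper(k - 1, m, length(universe) - m, length(hits),
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = m, n_hits = length(hits),
               universe = length(universe), p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(data.frame(set = character(), overlap = integer(),
                                      set_size = integer(), n_hits = integer(),
                                      universe = integer(), p = numeric(),
                                      q = numeric(), stringsAsFactors = FALSE))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res[order(res$p), , drop = FALSE]
}

#' Correlation profile of feature rows against a score vector
#'
#' Per-feature Pearson correlation (and two-sided p) between each row of a
#' feature matrix and a per-sample score, e.g. immune-checkpoint gene
#' expression against the ESTIMATE immune score.
#'
#' @param featureRows matrix or [OmicsMatrix-class]; rows = features.
#' @param score named numeric per-sample score (aligned by name when
#'   named).
#' @param method correlation method.
#' @return data.frame: feature, r, p, n.
#' @export
correlationProfile <- function(featureRows, score,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  v <- if (is(featureRows, "OmicsMatrix")) omicsValues(featureRows) else featureRows
  if (!is.null(names(score))) {
    common <- intersect(colnames(v), names(score))
    v <- v[, common, drop = FALSE]
    score <- score[common]
  }
  out <- t(vapply(rownames(v), function(g) .corTestPair(v[g, ], score, method),
                  c(r = 0, p = 0, n = 0)))
  data.frame(feature = rownames(v), r = out[, "r"], p = out[, "p"],
             n = out[, "n"], row.names = NULL, stringsAsFactors = FALSE)
}

#' Frequency reproduction for printed cohort summary tables
#'
#' Given printed category counts and the cohort size, recomputes the
#' percentage column as \code{round(100 * count / n, 1)} -- the convention
#' used in clinical characteristics tables.  A copy of the study's printed
#' patient-characteristics counts (N = 99) ships with the package:
#' \code{system.file("extdata", "table1_counts.tsv", package =
#' "proteoSubtype")}.
#'
#' @param counts data.frame with columns \code{category}, \code{item},
#'   \code{count}, or a path to such a TSV.
#' @param n cohort size the percentages are taken over.
#' @return The input data.frame with a \code{pct} column appended.
#' @export
frequencyTable <- function(counts, n = 99) {
  if (is.character(counts))
    counts <- utils::read.delim(counts, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("category", "item", "count") %in% names(counts)))
  counts$pct <- round(100 * counts$count / n, 1)
  counts
}
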