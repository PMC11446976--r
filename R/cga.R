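#' @include AllClasses.R
NULL

#' Cancer-germline-antigen outlier detection
#'
#' Flags gene/sample pairs whose linear-FPKM expression is both at least
#' \code{foldMin}-fold above the cohort mean and more than \code{zMin}
#' standard deviations above it.  By default the mean and SD are computed
#' leaving the candidate sample out: with a cohort of n < 100 positive
#' values, \code{x >= 100 * mean-including-x} is algebraically impossible,
#' so the literal including-self reading (available as \code{mode =
#' "cohort"}) can never fire; the leave-one-out form preserves the intent of
#' the 100-fold rule and makes the stated thresholds attainable.  A small
#' pseudocount \code{eps} is added to the denominator mean to handle
#' all-zero genes.
#'
#' @param rnaLinear an [OmicsMatrix-class] on the \code{linear_fpkm} scale
#'   (log2 input is an error).
#' @param cgaGenes character vector of candidate CGA genes.
#' @param foldMin fold-change threshold (default 100).
#' @param zMin SD threshold (default 3).
#' @param eps pseudocount added to the denominator mean (FPKM units).
#' @param mode \code{"loo"} (leave-one-out, default) or \code{"cohort"}
#'   (literal including-self statistics).
#' @return list with \code{calls} (data.frame gene, sample, value, mean, sd,
#'   fold, z for every passing pair) and \code{positive} (named logical:
#'   sample has >= 1 passing call).
#' @export
cgaDetect <- function(rnaLinear, cgaGenes, foldMin = 100, zMin = 3,
                      eps = 0.01, mode = c("loo", "cohort")) {
  mode <- match.arg(mode)
  if (omicsScale(rnaLinear) != "linear_fpkm")
    stop("linear FPKM required: the fold and SD thresholds are defined on ",
         "the linear scale, not log2")
  v <- omicsValues(rnaLinear)
  genes <- intersect(cgaGenes, rownames(v))
  if (!length(genes)) stop("no candidate CGA gene present in the matrix")
  n <- ncol(v)
  if (n < 3L) stop("need at least 3 samples")
  calls <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    x <- v[genes[gi], ]
    if (mode == "loo") {
      s <- sum(x); ss <- sum(x^2)
      m <- (s - x) / (n - 1)
      varLoo <- pmax(0, (ss - x^2 - (n - 1) * m^2) / (n - 2))
      sdv <- sqrt(varLoo)
    } else {
      m <- rep(mean(x), n)
      sdv <- rep(stats::sd(x), n)
    }
    fold <- x / (m + eps)
    # zero spread among the reference samples: any deviation is infinitely
    # many SDs away
    z <- ifelse(sdv > 0, (x - m) / sdv, sign(x - m) * Inf)
    z[x == m] <- 0
    pass <- fold >= foldMin & z > zMin
    if (any(pass))
      calls[[gi]] <- data.frame(gene = genes[gi], sample = names(x)[pass],
                                value = x[pass], mean = m[pass],
                                sd = sdv[pass], fold = fold[pass],
                                z = z[pass], row.names = NULL,
                                stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  if (is.null(calls))
    calls <- data.frame(gene = character(), sample = character(),
                        value = numeric(), mean = numeric(), sd = numeric(),
                        fold = numeric(), z = numeric(),
                        stringsAsFactors = FALSE)
  positive <- stats::setNames(colnames(v) %in% calls$sample, colnames(v))
  list(calls = calls, positive = positive)
}

#' Subgroup composition of CGA-positive samples
#'
#' Per-subgroup CGA-positive proportions plus a Fisher exact test of the
#' positive-by-subgroup contingency table (exact for the 2 x k table), used
#' to ask whether CGA overexpression is depleted or enriched in particular
#' subgroups.
#'
#' @param positive named logical per-sample CGA-positive flags (the
#'   \code{positive} element of [cgaDetect()]).
#' @param labels named subgroup labels over the same samples.
#' @return list with \code{composition} (data.frame subgroup, n, n_positive,
#'   proportion) and \code{p} (Fisher).
#' @export
cgaComposition <- function(positive, labels) {
  common <- intersect(names(positive), names(labels))
  pos <- positive[common]; lab <- labels[common]
  groups <- sort(unique(lab))
  comp <- data.frame(subgroup = groups,
                     n = as.integer(table(factor(lab, groups))),
                     n_positive = vapply(groups, function(g)
                       sum(pos[lab == g]), integer(1)),
                     stringsAsFactors = FALSE, row.names = NULL)
  comp$proportion <- comp$n_positive / comp$n
  p <- if (sum(pos) == 0) 1 else
    stats::fisher.test(table(factor(pos, c(TRUE, FALSE)), lab))$p.value
  list(composition = comp, p = p)
}
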