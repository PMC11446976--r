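#' @include AllClasses.R
NULL

# Pearson/Spearman correlation with the classical t-based two-sided p,
# pairwise-complete observations.  Returns c(r, p, n).
.corTestPair <- function(x, y, method = "pearson") {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3L) return(c(r = NA_real_, p = NA_real_, n = n))
  if (method == "spearman") {
    x <- rank(x[ok]); y <- rank(y[ok])
  } else {
    x <- x[ok]; y <- y[ok]
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x, y)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(c(r = r, p = 0, n = n))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' Cis copy-number dosage correlations
#'
#' For every gene shared between the CNA layer and the RNA (and, when
#' given, protein) layer, correlates the gene's CNA row with its own
#' RNA/protein row across samples (pairwise-complete; genes with fewer than
#' \code{minPairs} complete pairs are skipped with a warning).  Genes are
#' tiered: \code{both_positive} requires positive correlation in both
#' layers with both p-values below \code{alpha2}; \code{rna_only} /
#' \code{prot_only} flag significance at \code{alpha1} in a single layer.
#' Raw-p tiers mirror the convention of reporting cis counts at P < 0.05
#' and P < 0.01; BH-adjusted q-values are attached for optional use.
#'
#' @param cna,rna,protein [OmicsMatrix-class] layers (protein may be
#'   \code{NULL}).
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param alpha1 per-layer significance tier (default 0.05).
#' @param alpha2 joint positive tier (default 0.01).
#' @param minPairs minimum pairwise-complete sample count per gene.
#' @return list with \code{results} (data.frame: gene, r_rna, p_rna,
#'   q_rna, r_prot, p_prot, q_prot, tier) and \code{summary} (universe and
#'   tier counts).
#' @export
cisCorrelate <- function(cna, rna, protein = NULL,
                         method = c("pearson", "spearman"),
                         alpha1 = 0.05, alpha2 = 0.01, minPairs = 10) {
  method <- match.arg(method)
  cnaV <- omicsValues(cna); rnaV <- omicsValues(rna)
  protV <- if (!is.null(protein)) omicsValues(protein) else NULL
  genes <- intersect(rownames(cnaV), rownames(rnaV))
  samples <- intersect(colnames(cnaV), colnames(rnaV))
  if (!is.null(protV)) samples <- intersect(samples, colnames(protV))
  res <- data.frame(gene = genes, r_rna = NA_real_, p_rna = NA_real_,
                    r_prot = NA_real_, p_prot = NA_real_,
                    stringsAsFactors = FALSE)
  skipped <- character()
  for (i in seq_along(genes)) {
    g <- genes[i]
    rr <- .corTestPair(cnaV[g, samples], rnaV[g, samples], method)
    if (rr[["n"]] < minPairs) { skipped <- c(skipped, g); next }
    res$r_rna[i] <- rr[["r"]]; res$p_rna[i] <- rr[["p"]]
    if (!is.null(protV) && g %in% rownames(protV)) {
      rp <- .corTestPair(cnaV[g, samples], protV[g, samples], method)
      if (rp[["n"]] >= minPairs) {
        res$r_prot[i] <- rp[["r"]]; res$p_prot[i] <- rp[["p"]]
      }
    }
  }
  if (length(skipped)) {
    warning("skipping ", length(skipped),
            " gene(s) with fewer than ", minPairs, " complete pairs")
    res <- res[!res$gene %in% skipped, , drop = FALSE]
  }
  res$q_rna <- stats::p.adjust(res$p_rna, method = "BH")
  res$q_prot <- stats::p.adjust(res$p_prot, method = "BH")
  bothPos <- !is.na(res$p_rna) & !is.na(res$p_prot) &
    res$r_rna > 0 & res$r_prot > 0 & res$p_rna < alpha2 & res$p_prot < alpha2
  sigRna <- !is.na(res$p_rna) & res$p_rna < alpha1
  sigProt <- !is.na(res$p_prot) & res$p_prot < alpha1
  res$tier <- ifelse(bothPos, "both_positive",
                     ifelse(sigRna & !sigProt, "rna_only",
                            ifelse(sigProt & !sigRna, "prot_only", "none")))
  list(results = res,
       summary = list(n_genes = nrow(res),
                      n_sig_rna = sum(sigRna),
                      n_sig_prot = sum(sigProt),
                      n_both_positive = sum(bothPos)))
}

#' Trans effects of one gene's copy number on the proteome
#'
#' Correlates the effector gene's CNA row against every protein row and
#' partitions significant targets into up- (positive r) and down-regulated
#' (negative r) sets at the given alpha.
#'
#' @param cna an [OmicsMatrix-class] CNA layer containing the effector.
#' @param effector gene identifier of the trans-acting CNA.
#' @param proteome an [OmicsMatrix-class] protein layer.
#' @param alpha significance threshold on the raw correlation p.
#' @param minPairs minimum pairwise-complete sample count per target.
#' @return list with \code{results} (data.frame target, r, p),
#'   \code{up_targets}, \code{down_targets}.
#' @export
transCorrelate <- function(cna, effector, proteome, alpha = 0.05,
                           minPairs = 10) {
  cnaV <- omicsValues(cna); protV <- omicsValues(proteome)
  if (!effector %in% rownames(cnaV))
    stop("effector gene '", effector, "' absent from the CNA matrix")
  samples <- intersect(colnames(cnaV), colnames(protV))
  eff <- cnaV[effector, samples]
  if (stats::sd(eff, na.rm = TRUE) == 0)
    stop("zero variance: effector CNA row is constant")
  out <- t(vapply(rownames(protV), function(g)
    .corTestPair(eff, protV[g, samples]), c(r = 0, p = 0, n = 0)))
  res <- data.frame(target = rownames(protV), r = out[, "r"], p = out[, "p"],
                    n = out[, "n"], row.names = NULL, stringsAsFactors = FALSE)
  res <- res[!is.na(res$p) & res$n >= minPairs, , drop = FALSE]
  list(results = res,
       up_targets = res$target[res$p < alpha & res$r > 0],
       down_targets = res$target[res$p < alpha & res$r < 0])
}

.mutatedMatrix <- function(mutations, samples,
                           proteinAlteringOnly = TRUE) {
  mut <- mutations
  if (proteinAlteringOnly)
    mut <- mut[mut$variant_class %in% .PROTEIN_ALTERING, , drop = FALSE]
  genes <- unique(mut$gene)
  m <- matrix(FALSE, length(genes), length(samples),
              dimnames = list(genes, samples))
  if (nrow(mut)) {
    mut <- mut[mut$sample %in% samples, , drop = FALSE]
    m[cbind(match(mut$gene, genes), match(mut$sample, samples))] <- TRUE
  }
  m
}

#' Mutation-subgroup association tests
#'
#' For every gene mutated (protein-altering) in at least \code{minCount}
#' samples, a two-sided 2x2 Fisher exact test of gene mutation against
#' membership in each subgroup (subgroup vs rest).
#'
#' @param mutations mutation data.frame (sample, gene, variant_class, ...).
#' @param labels named subgroup labels covering the mutation samples.
#' @param minCount minimum mutated-sample count for a gene to be tested.
#' @return data.frame: gene, subgroup, n_mut_in, n_in, n_mut_out, n_out,
#'   odds_ratio, p, q (BH across all tests).  Zero rows for an empty table.
#' @export
mutationSubgroupAssociation <- function(mutations, labels, minCount = 3) {
  samples <- names(labels)
  empty <- data.frame(gene = character(), subgroup = character(),
                      n_mut_in = integer(), n_in = integer(),
                      n_mut_out = integer(), n_out = integer(),
                      odds_ratio = numeric(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(mutations)) return(empty)
  m <- .mutatedMatrix(mutations, samples)
  m <- m[rowSums(m) >= minCount, , drop = FALSE]
  if (!nrow(m)) return(empty)
  rows <- list()
  for (g in rownames(m)) for (grp in sort(unique(labels))) {
    inGrp <- labels == grp
    tab <- table(factor(m[g, ], c(TRUE, FALSE)), factor(inGrp, c(TRUE, FALSE)))
    ft <- stats::fisher.test(tab)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, subgroup = grp,
      n_mut_in = sum(m[g, inGrp]), n_in = sum(inGrp),
      n_mut_out = sum(m[g, !inGrp]), n_out = sum(!inGrp),
      odds_ratio = unname(ft$estimate), p = ft$p.value,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Mutation co-occurrence test for a gene pair
#'
#' Two-sided Fisher exact test on the 2x2 table of carrier status of two
#' genes across the sample universe, with the direction read off the odds
#' ratio.
#'
#' @param mutations mutation data.frame.
#' @param geneA,geneB gene identifiers.
#' @param samples character vector: the cohort sample universe.
#' @return list with \code{p}, \code{odds_ratio}, \code{direction}
#'   (\code{"co-occurrence"}, \code{"mutual_exclusivity"} or \code{"none"}),
#'   and the 2x2 \code{table}.
#' @export
cooccurrence <- function(mutations, geneA, geneB, samples) {
  mut <- mutations[mutations$variant_class %in% .PROTEIN_ALTERING, ,
                   drop = FALSE]
  aCar <- samples %in% mut$sample[mut$gene == geneA]
  bCar <- samples %in% mut$sample[mut$gene == geneB]
  tab <- table(factor(aCar, c(TRUE, FALSE)), factor(bCar, c(TRUE, FALSE)),
               dnn = c(geneA, geneB))
  ft <- stats::fisher.test(tab)
  orHat <- unname(ft$estimate)
  direction <- if (sum(aCar) == 0 || sum(bCar) == 0 || orHat == 1) "none"
    else if (orHat > 1) "co-occurrence" else "mutual_exclusivity"
  list(p = ft$p.value, odds_ratio = orHat, direction = direction, table = tab)
}

#' Tumour mutational burden
#'
#' Per-sample count of protein-altering mutations (missense, nonsense,
#' frameshift, inframe indel, splice); \code{"other"} variants are not
#' counted.  Samples without mutations get zero.
#'
#' @param mutations mutation data.frame.
#' @param samples character vector: the cohort sample universe.
#' @return named integer vector over \code{samples}.
#' @export
tmb <- function(mutations, samples) {
  mut <- mutations[mutations$variant_class %in% .PROTEIN_ALTERING &
                     mutations$sample %in% samples, , drop = FALSE]
  counts <- table(factor(mut$sample, levels = samples))
  stats::setNames(as.integer(counts), samples)
}

#' Proteome-wide effect of carrying a mutation
#'
#' Welch two-sided t-test of each protein between carriers and
#' non-carriers of a given mutated gene, BH-adjusted.  Requires at least
#' \code{minGroup} samples on each side; otherwise the gene is skipped with
#' a warning and a zero-row table is returned.
#'
#' @param mutations mutation data.frame.
#' @param proteome an [OmicsMatrix-class] protein layer.
#' @param gene mutated gene defining the carrier group.
#' @param minGroup minimum group size on both sides (default 3).
#' @return data.frame: protein, delta (carrier mean - non-carrier mean), t,
#'   p, q.
#' @export
mutationProteinEffect <- function(mutations, proteome, gene, minGroup = 3) {
  protV <- omicsValues(proteome)
  mut <- mutations[mutations$variant_class %in% .PROTEIN_ALTERING, ,
                   drop = FALSE]
  carriers <- colnames(protV) %in% mut$sample[mut$gene == gene]
  if (sum(carriers) < minGroup || sum(!carriers) < minGroup) {
    warning("skipping '", gene, "': carrier group of ", sum(carriers),
            " vs ", sum(!carriers), " is below the minimum of ", minGroup)
    return(data.frame(protein = character(), delta = numeric(),
                      t = numeric(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  }
  wt <- rowWelch(protV[, carriers, drop = FALSE],
                 protV[, !carriers, drop = FALSE])
  res <- data.frame(protein = rownames(protV), delta = wt$delta, t = wt$t,
                    p = wt$p, row.names = NULL, stringsAsFactors = FALSE)
  res <- res[!is.na(res$p), , drop = FALSE]
  res$q <- stats::p.adjust(res$p, method = "BH")
  res[order(res$p), , drop = FALSE]
}
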