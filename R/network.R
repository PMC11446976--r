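#' @include AllClasses.R stats.R
NULL

#' Select proteins for co-expression network analysis
#'
#' Variance-then-correlation selection: proteins are ranked by variance
#' (NA-tolerant; zero-variance rows are never retained), the top
#' \code{nTopVar} kept, and of those only proteins with at least one
#' partner at Pearson \code{|r| > rMin} within the retained set survive
#' (\code{partnerRule = "any"}, the default; \code{"max"} instead
#' thresholds each protein's maximum absolute off-diagonal correlation,
#' which is the same criterion stated differently and kept for sensitivity
#' analysis).
#'
#' @param protein an [OmicsMatrix-class] or matrix.
#' @param nTopVar number of top-variance proteins to keep before the
#'   correlation filter.
#' @param rMin correlation threshold (default 0.5).
#' @param partnerRule \code{"any"} or \code{"max"} (equivalent criteria).
#' @return character vector of selected protein ids.
#' @export
selectProteins <- function(protein, nTopVar = 2000, rMin = 0.5,
                           partnerRule = c("any", "max")) {
  partnerRule <- match.arg(partnerRule)
  v <- if (is(protein, "OmicsMatrix")) omicsValues(protein) else protein
  if (ncol(v) < 2L) stop("need at least 2 samples")
  vars <- apply(v, 1L, stats::var, na.rm = TRUE)
  vars[is.na(vars)] <- 0
  keep <- names(sort(vars[vars > 0], decreasing = TRUE))
  keep <- utils::head(keep, nTopVar)
  if (length(keep) < 2L) return(keep)
  if (rMin <= 0) return(keep)
  cc <- stats::cor(t(v[keep, , drop = FALSE]), use = "pairwise.complete.obs")
  diag(cc) <- 0
  maxAbs <- apply(abs(cc), 1L, max, na.rm = TRUE)
  keep[maxAbs > rMin]
}

#' Correlation-based protein co-expression graph
#'
#' Undirected graph over proteins with an edge wherever the pairwise
#' Pearson correlation exceeds \code{rThreshold} in absolute value; edge
#' weights carry the signed correlation.  No self-edges.
#'
#' @param protein an [OmicsMatrix-class] or matrix (rows = proteins).
#' @param rThreshold absolute-correlation edge threshold (default 0.5).
#' @return An \code{igraph} graph with a \code{weight} edge attribute.
#' @export
proteinGraph <- function(protein, rThreshold = 0.5) {
  v <- if (is(protein, "OmicsMatrix")) omicsValues(protein) else protein
  cc <- stats::cor(t(v), use = "pairwise.complete.obs")
  cc[is.na(cc)] <- 0
  diag(cc) <- 0
  adj <- abs(cc) > rThreshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  ends <- igraph::as_edgelist(g)
  if (nrow(ends))
    igraph::E(g)$weight <- cc[cbind(ends[, 1], ends[, 2])]
  g
}

#' Cluster selected proteins into co-expression modules
#'
#' Complete-linkage hierarchical clustering on the correlation distance
#' \code{1 - r}, cut at \code{kModules}; each module is annotated by
#' hypergeometric enrichment against a hallmark-style gene-set collection
#' over the selected-protein universe.
#'
#' @param protein an [OmicsMatrix-class] or matrix restricted to the
#'   selected proteins.
#' @param kModules number of modules.
#' @param sets optional [GeneSetCollection-class] or named list for module
#'   annotation.
#' @return list with \code{modules} (named integer labels) and
#'   \code{enrichment} (data.frame with a \code{module} column; \code{NULL}
#'   without \code{sets}).
#' @export
clusterModules <- function(protein, kModules, sets = NULL) {
  v <- if (is(protein, "OmicsMatrix")) omicsValues(protein) else protein
  if (kModules > nrow(v)) stop("more modules requested than proteins")
  cc <- stats::cor(t(v), use = "pairwise.complete.obs")
  cc[is.na(cc)] <- 0
  tree <- stats::hclust(stats::as.dist(1 - cc), method = "complete")
  modules <- stats::cutree(tree, k = kModules)
  enrichment <- NULL
  if (!is.null(sets)) {
    pieces <- lapply(sort(unique(modules)), function(k) {
      e <- suppressWarnings(
        hypergeomEnrich(names(modules)[modules == k], rownames(v), sets))
      if (nrow(e)) cbind(module = k, e) else NULL
    })
    enrichment <- do.call(rbind, pieces)
  }
  list(modules = modules, enrichment = enrichment)
}

#' k-core filter of a protein graph
#'
#' Keeps the nodes whose core number is at least \code{k}, i.e. the maximal
#' subgraph in which every node has degree >= k.  The default k = 4
#' corresponds to the strict reading of a "K-core > 3" display filter.
#'
#' @param graph an \code{igraph} graph.
#' @param k minimum core number retained.
#' @return The induced \code{igraph} subgraph (idempotent under repeated
#'   application).
#' @export
kcoreFilter <- function(graph, k = 4) {
  core <- igraph::coreness(graph)
  igraph::induced_subgraph(graph, names(core)[core >= k] %||%
                             which(core >= k))
}

#' Export a protein graph as an edge-list table
#'
#' @param graph an \code{igraph} graph with a \code{weight} edge attribute.
#' @return data.frame: protein_a, protein_b, r.
#' @export
edgeTable <- function(graph) {
  ends <- igraph::as_edgelist(graph)
  w <- if ("weight" %in% igraph::edge_attr_names(graph))
    igraph::E(graph)$weight else rep(NA_real_, nrow(ends))
  data.frame(protein_a = ends[, 1], protein_b = ends[, 2], r = w,
             stringsAsFactors = FALSE)
}
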