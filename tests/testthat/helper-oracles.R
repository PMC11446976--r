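# Independent brute-force oracles used to cross-check the package
# implementations.  These deliberately share no code with R/.

# ssGSEA running-sum by explicit double loop over rank positions:
# at each position i, the weighted in-set ECDF minus the complement ECDF.
bruteSsgsea <- function(values, sets, alpha = 0.25, normalize = FALSE) {
  genes <- rownames(values)
  out <- matrix(NA_real_, length(sets), ncol(values),
                dimnames = list(names(sets), colnames(values)))
  for (s in seq_len(ncol(values))) {
    x <- values[, s]
    ord <- order(x, decreasing = TRUE)  # stable ties
    rankStat <- rev(seq_along(ord))     # N, N-1, ..., 1 down the ranking
    for (k in seq_along(sets)) {
      inSet <- genes[ord] %in% sets[[k]]
      nIn <- sum(inSet)
      nOut <- length(ord) - nIn
      if (nIn == 0 || nOut == 0) next
      es <- 0
      for (i in seq_along(ord)) {
        pin <- sum((abs(rankStat[seq_len(i)])^alpha)[inSet[seq_len(i)]]) /
          sum((abs(rankStat)^alpha)[inSet])
        pout <- sum(!inSet[seq_len(i)]) / nOut
        es <- es + (pin - pout)
      }
      out[k, s] <- es
    }
  }
  if (normalize) out <- out / (max(out) - min(out))
  out
}

# Upper-tail hypergeometric by explicit enumeration.
bruteHyperUpper <- function(overlap, setSize, universe, nHits) {
  kMax <- min(setSize, nHits)
  if (overlap > kMax) return(0)
  sum(vapply(overlap:kMax, function(k)
    choose(setSize, k) * choose(universe - setSize, nHits - k), numeric(1))) /
    choose(universe, nHits)
}

# Two-sided Fisher exact p for a 2x2 table by enumerating all tables with
# the same margins and summing probabilities <= that of the observed table.
bruteFisher2x2 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  prob <- function(x) choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  support <- max(0, c1 - r2):min(r1, c1)
  pObs <- prob(a)
  sum(vapply(support, prob, numeric(1))[
    vapply(support, prob, numeric(1)) <= pObs * (1 + 1e-7)])
}

# k-core by iterative minimal-degree peeling on an adjacency matrix.
bruteKcore <- function(adj, k) {
  nodes <- seq_len(nrow(adj))
  repeat {
    if (!length(nodes)) return(integer(0))
    deg <- rowSums(adj[nodes, nodes, drop = FALSE])
    drop <- deg < k
    if (!any(drop)) return(nodes)
    nodes <- nodes[!drop]
  }
}

# Cox partial log-likelihood for a single binary covariate, no ties.
coxPartialLogLik <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

randomAdjacency <- function(n, p) {
  adj <- matrix(0L, n, n, dimnames = list(paste0("n", 1:n), paste0("n", 1:n)))
  upper <- which(upper.tri(adj))
  on <- upper[stats::runif(length(upper)) < p]
  adj[on] <- 1L
  adj + t(adj)
}
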