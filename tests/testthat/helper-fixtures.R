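# Shared synthetic fixtures, generated once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

# Default-conditions cohort (102 samples incl. 3 low-purity, 5000 genes),
# purity-filtered to the 99 analysable samples.
cohortFixture <- function(seed = 1) {
  key <- paste0("cohort", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <-
      applyPurityFilter(generateCohort(simulationConfig(seed = seed)))$bundle
  .fixtureCache[[key]]
}

# Combined RNA+protein enrichment matrix of the default cohort.
scoredFixture <- function(seed = 1) {
  key <- paste0("scored", seed)
  if (is.null(.fixtureCache[[key]])) {
    b <- cohortFixture(seed)
    sets <- geneSets(b)
    sig <- sets[setdiff(names(sets), "cga_candidates")]
    .fixtureCache[[key]] <- combineLayers(ssgseaScore(b@rna, sig),
                                          ssgseaScore(b@protein, sig))
  }
  .fixtureCache[[key]]
}

# Small, fast cohort for IO/pipeline plumbing tests.
tinySimConfig <- function(seed = 5, ...) {
  simulationConfig(nSamples = 60, nLowPurity = 3, nGenes = 500,
                   signatureSetSize = 8, cisGeneCount = 60,
                   nCgaGenes = 60, nCgaPositive = 3, seed = seed, ...)
}

tinyCohortFixture <- function() {
  if (is.null(.fixtureCache$tiny))
    .fixtureCache$tiny <- generateCohort(tinySimConfig())
  .fixtureCache$tiny
}

# Enrichment matrix with the four key signature rows for classifier toys.
keyScoreMatrix <- function(prolif, tcell, angio, metab,
                           samples = paste0("s", seq_along(prolif))) {
  m <- rbind(proliferation = prolif, t_cell = tcell,
             angiogenesis = angio, metabolism = metab)
  colnames(m) <- samples
  new("EnrichmentMatrix", scores = m, alpha = 0.25, normalized = FALSE)
}
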