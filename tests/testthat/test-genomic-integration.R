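mkOmics <- function(v, layer = "rna") omicsMatrix(v, layer, "log2")

test_that("cis correlation is exact on a dosage-identical gene", {
  set.seed(17)
  n <- 30
  cna <- matrix(rnorm(2 * n, 0, 0.5), 2, n,
                dimnames = list(c("gA", "gB"), paste0("s", 1:n)))
  rna <- cna
  rna["gB", ] <- rnorm(n)  # gB independent
  res <- cisCorrelate(mkOmics(cna, "cna"), mkOmics(rna))$results
  expect_equal(res$r_rna[res$gene == "gA"], 1, tolerance = 1e-12)
  expect_lt(res$p_rna[res$gene == "gA"], 1e-20)
  # joint sample permutation leaves r unchanged
  perm <- sample(n)
  res2 <- cisCorrelate(mkOmics(cna[, perm], "cna"),
                       mkOmics(rna[, perm]))$results
  expect_equal(res2$r_rna, res$r_rna, tolerance = 1e-12)
})

test_that("genes with too few complete pairs are skipped with a warning", {
  n <- 8  # below the 10-pair minimum
  cna <- matrix(rnorm(n, 0, 0.5), 1, n,
                dimnames = list("gA", paste0("s", 1:n)))
  rna <- matrix(rnorm(n), 1, n, dimnames = dimnames(cna))
  expect_warning(out <- cisCorrelate(mkOmics(cna, "cna"), mkOmics(rna)),
                 "complete pairs")
  expect_equal(nrow(out$results), 0L)
})

test_that("cis detection is calibrated on nulls and powered on plants", {
  set.seed(7)
  n <- 99; g <- 500
  ids <- sprintf("n%03d", 1:g)
  cna <- matrix(rnorm(g * n, 0, 0.5), g, n,
                dimnames = list(ids, paste0("s", 1:n)))
  rna <- matrix(rnorm(g * n), g, n, dimnames = dimnames(cna))
  res <- cisCorrelate(mkOmics(cna, "cna"), mkOmics(rna))$results
  expect_gt(mean(res$p_rna < 0.05), 0.03)
  expect_lt(mean(res$p_rna < 0.05), 0.07)

  b <- cohortFixture(1)
  cis <- cisCorrelate(b@cna, b@rna, b@protein)
  sub <- cis$results[cis$results$gene %in% b@truth$cisGenes, ]
  expect_gte(mean(sub$p_rna < 0.05), 0.95)
  r <- cis$results
  shouldBeBoth <- !is.na(r$p_prot) & !is.na(r$p_rna) &
    r$r_rna > 0 & r$r_prot > 0 & r$p_rna < 0.01 & r$p_prot < 0.01
  expect_identical(r$tier == "both_positive", shouldBeBoth)
  expect_gt(sum(shouldBeBoth), 0)
  # BH is monotone and never below the raw p
  expect_true(all(cis$results$q_rna >= cis$results$p_rna, na.rm = TRUE))
})

test_that("trans correlation partitions constructed targets correctly", {
  set.seed(18)
  n <- 40
  eff <- rnorm(n, 0, 0.5)
  cna <- matrix(eff, 1, n, dimnames = list("EFF", paste0("s", 1:n)))
  prot <- rbind(up1 = eff, up2 = eff, down1 = -eff, down2 = -eff)
  colnames(prot) <- paste0("s", 1:n)
  tr <- transCorrelate(mkOmics(cna, "cna"), "EFF", mkOmics(prot, "protein"))
  expect_setequal(tr$up_targets, c("up1", "up2"))
  expect_setequal(tr$down_targets, c("down1", "down2"))
  expect_error(transCorrelate(mkOmics(cna, "cna"), "nope",
                              mkOmics(prot, "protein")), "absent")
  cnaC <- matrix(1, 1, n, dimnames = list("EFF", paste0("s", 1:n)))
  expect_error(transCorrelate(omicsMatrix(cnaC, "cna", "log2"), "EFF",
                              mkOmics(prot, "protein")), "zero variance")
  # null proteome: significant fraction near alpha
  nullProt <- matrix(rnorm(400 * n), 400, n,
                     dimnames = list(sprintf("p%03d", 1:400),
                                     paste0("s", 1:n)))
  trN <- transCorrelate(mkOmics(cna, "cna"), "EFF",
                        mkOmics(nullProt, "protein"))
  hits <- length(trN$up_targets) + length(trN$down_targets)
  expect_gt(hits, 4); expect_lt(hits, 45)
})

test_that("mutation-subgroup association flags strong enrichment only", {
  labels <- setNames(rep(c("P", "I", "A", "M"), times = c(25, 30, 20, 24)),
                     sprintf("s%02d", 1:99))
  mut <- data.frame(sample = c(names(labels)[labels == "P"][1:12],
                               names(labels)[labels != "P"][1:2]),
                    gene = "TP53", variant_class = "missense",
                    protein_change = "p.X1Y", stringsAsFactors = FALSE)
  res <- mutationSubgroupAssociation(mut, labels)
  pP <- res$p[res$gene == "TP53" & res$subgroup == "P"]
  expect_lt(pP, 0.001)
  # matches the enumeration oracle on the same 2x2 table
  expect_equal(pP, bruteFisher2x2(12, 2, 13, 72), tolerance = 1e-9)
  expect_equal(nrow(mutationSubgroupAssociation(mut[0, ], labels)), 0L)
  # uniformly mutated gene: no subgroup stands out in expectation
  set.seed(19)
  rates <- replicate(25, {
    m <- data.frame(sample = names(labels)[runif(99) < 0.2], gene = "G",
                    variant_class = "missense", protein_change = "p",
                    stringsAsFactors = FALSE)
    mean(mutationSubgroupAssociation(m, labels)$p < 0.05)
  })
  expect_lt(mean(rates), 0.15)
})

test_that("co-occurrence testing handles extremes and matches enumeration", {
  samples <- sprintf("s%02d", 1:99)
  co <- samples[1:10]
  mut <- rbind(data.frame(sample = co, gene = "A",
                          variant_class = "missense", protein_change = "p"),
               data.frame(sample = co, gene = "B",
                          variant_class = "missense", protein_change = "p"))
  res <- cooccurrence(mut, "A", "B", samples)
  expect_lt(res$p, 1e-6)
  expect_equal(res$direction, "co-occurrence")
  expect_equal(res$p, bruteFisher2x2(10, 0, 0, 89), tolerance = 1e-9)
  # gene B never mutated
  res2 <- cooccurrence(mut[mut$gene == "A", ], "A", "B", samples)
  expect_equal(res2$p, 1)
  expect_equal(res2$direction, "none")
  # independent plants: p roughly uniform
  set.seed(20)
  ps <- replicate(100, {
    m <- rbind(data.frame(sample = sample(samples, 15), gene = "A",
                          variant_class = "missense", protein_change = "p"),
               data.frame(sample = sample(samples, 15), gene = "B",
                          variant_class = "missense", protein_change = "p"))
    cooccurrence(m, "A", "B", samples)$p
  })
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("TMB counts protein-altering variants only", {
  samples <- c("s1", "s2", "s3")
  expect_equal(tmb(data.frame(sample = character(), gene = character(),
                              variant_class = character(),
                              protein_change = character()), samples),
               c(s1 = 0L, s2 = 0L, s3 = 0L))
  mut <- data.frame(sample = c("s1", "s1", "s1", "s1"),
                    gene = paste0("g", 1:4),
                    variant_class = c("missense", "missense", "missense",
                                      "other"),
                    protein_change = "p", stringsAsFactors = FALSE)
  expect_equal(tmb(mut, samples)[["s1"]], 3L)
  # planted burden difference: M above I
  b <- cohortFixture(1)
  lab <- b@truth$labels
  burden <- tmb(b@mutations, names(lab))
  w <- wilcoxonRankSum(burden[names(lab)[lab == "M"]],
                       burden[names(lab)[lab == "I"]])
  expect_lt(w$p, 0.05)
})

test_that("mutation-proteome effects recover planted shifts", {
  b <- cohortFixture(1)
  eff <- mutationProteinEffect(b@mutations, b@protein, "STK11")
  recovered <- sum(b@truth$effectProteins %in% eff$protein[eff$q < 0.05])
  expect_gte(recovered, 18)
  # null gene: no q anywhere near significance, deltas centred at zero
  set.seed(21)
  n <- 60
  prot <- matrix(rnorm(50 * n), 50, n,
                 dimnames = list(sprintf("p%02d", 1:50), sprintf("s%02d", 1:n)))
  mut <- data.frame(sample = sample(colnames(prot), 12), gene = "NULLG",
                    variant_class = "missense", protein_change = "p",
                    stringsAsFactors = FALSE)
  effN <- mutationProteinEffect(mut, omicsMatrix(prot, "protein", "log2"),
                                "NULLG")
  expect_gt(min(effN$q), 0.05)
  expect_lt(abs(mean(effN$delta)), 0.2)
  # single carrier is skipped with a warning
  mut1 <- mut[1, , drop = FALSE]
  expect_warning(out <- mutationProteinEffect(
    mut1, omicsMatrix(prot, "protein", "log2"), "NULLG"), "below the minimum")
  expect_equal(nrow(out), 0L)
})
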