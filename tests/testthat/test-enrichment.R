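test_that("the five-gene worked example scores +2.5 / -2.5 at alpha 0", {
  m <- matrix(c(5, 4, 3, 2, 1), 5, 1,
              dimnames = list(paste0("g", 1:5), "s1"))
  top <- ssgseaScore(m, list(S = c("g1", "g2")), alpha = 0, normalize = FALSE)
  expect_equal(unname(omicsValues(top)["S", 1]), 2.5, tolerance = 1e-12)
  bottom <- ssgseaScore(m, list(S = c("g4", "g5")), alpha = 0,
                        normalize = FALSE)
  expect_equal(unname(omicsValues(bottom)["S", 1]), -2.5, tolerance = 1e-12)
})

test_that("scores match the brute-force running-sum oracle", {
  set.seed(7)
  for (rep in 1:40) {
    v <- matrix(rnorm(24), 8, 3,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:3)))
    sets <- list(A = sample(rownames(v), 3), B = sample(rownames(v), 3))
    alpha <- sample(c(0, 0.25, 1), 1)
    got <- omicsValues(ssgseaScore(v, sets, alpha = alpha, normalize = FALSE))
    want <- bruteSsgsea(v, sets, alpha = alpha)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("scores are rank-based: monotone transforms change nothing", {
  set.seed(8)
  v <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  sets <- list(S = c("g1", "g4", "g7"))
  a <- omicsValues(ssgseaScore(v, sets, normalize = FALSE))
  b <- omicsValues(ssgseaScore(exp(v), sets, normalize = FALSE))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("degenerate set configurations are caught", {
  v <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_warning(es <- ssgseaScore(v, list(ok = c("g1", "g2"), tiny = "g3"),
                                   normalize = FALSE), "dropping")
  expect_equal(rownames(omicsValues(es)), "ok")
  expect_error(ssgseaScore(v, list(all = paste0("g", 1:5))),
               "empty complement")
  expect_error(ssgseaScore(v, list(S = c("x", "y"))), "no gene set")
  # missing values are excluded from a sample's ranking
  v2 <- v; v2[1, 1] <- NA
  es2 <- ssgseaScore(v2, list(S = c("g2", "g3")), normalize = FALSE)
  sub <- v2[-1, 1, drop = FALSE]
  expect_equal(omicsValues(es2)[1, 1],
               bruteSsgsea(sub, list(S = c("g2", "g3")))[1, 1],
               tolerance = 1e-9)
})

test_that("a gene absent from all sets shifts scores through the complement", {
  # at alpha = 0 the in-set numerator is untouched; appending a
  # bottom-ranked outside gene slows the complement ECDF, raising the score
  v <- matrix(c(5, 4, 3, 2), 4, 1,
              dimnames = list(paste0("g", 1:4), "s"))
  v2 <- rbind(v, g5 = 0.5)
  s1 <- omicsValues(ssgseaScore(v, list(S = c("g1", "g2")), alpha = 0,
                                normalize = FALSE))[1, 1]
  s2 <- omicsValues(ssgseaScore(v2, list(S = c("g1", "g2")), alpha = 0,
                                normalize = FALSE))[1, 1]
  expect_gt(s2, s1)
})

test_that("global normalization divides by the matrix-wide range", {
  set.seed(9)
  v <- matrix(rnorm(30), 6, 5,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:5)))
  sets <- list(A = c("g1", "g2"), B = c("g5", "g6"))
  raw <- omicsValues(ssgseaScore(v, sets, normalize = FALSE))
  norm <- omicsValues(ssgseaScore(v, sets, normalize = TRUE))
  expect_equal(norm, raw / (max(raw) - min(raw)), tolerance = 1e-12)
})

test_that("estimate scores are monotone and track planted immune structure", {
  set.seed(10)
  v <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  immune <- paste0("g", 1:4); stromal <- paste0("g", 5:8)
  v[immune, "s3"] <- v[immune, "s3"] + 50  # immune genes top-ranked in s3
  est <- estimateScores(v, immune, stromal)
  expect_equal(est$sample[which.max(est$immune)], "s3")
  expect_equal(est$combined, est$immune + est$stromal)
  # permuting samples permutes columns identically
  perm <- sample(colnames(v))
  est2 <- estimateScores(v[, perm], immune, stromal)
  expect_equal(est2$immune[match(est$sample, est2$sample)], est$immune)

  # planted joint elevation in subgroup I: immune and stromal co-vary
  b <- cohortFixture(1)
  sets <- geneSets(b)
  estB <- estimateScores(b@rna, sets$immune_estimate, sets$stromal_estimate)
  expect_gt(unname(coef(lm(estB$immune ~ estB$stromal))[2]), 0)
})

test_that("layer combination z-scores rows and stacks with suffixes", {
  set.seed(11)
  mk <- function(rows, n = 6)
    new("EnrichmentMatrix",
        scores = matrix(rnorm(rows * n), rows, n,
                        dimnames = list(paste0("sig", 1:rows),
                                        paste0("s", 1:n))),
        alpha = 0.25, normalized = TRUE)
  a <- mk(31); b <- mk(29)
  comb <- combineLayers(a, b)
  sc <- omicsValues(comb)
  expect_equal(nrow(sc), 60L)
  expect_equal(unname(rowMeans(sc)), rep(0, 60), tolerance = 1e-9)
  expect_equal(unname(apply(sc, 1, sd)), rep(1, 60), tolerance = 1e-9)
  expect_true(all(grepl("_rna$|_protein$", rownames(sc))))

  bBad <- mk(5)
  colnames(bBad@scores) <- paste0("x", 1:6)
  expect_error(combineLayers(a, bBad), "different samples")
  empty <- new("EnrichmentMatrix",
               scores = matrix(numeric(0), 0, 0,
                               dimnames = list(character(0), character(0))),
               alpha = 0.25, normalized = TRUE)
  expect_error(combineLayers(a, empty), "at least one")
})
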