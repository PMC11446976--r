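test_that("matrix TSV roundtrip is exact and enforces layer rules", {
  set.seed(42)
  v <- matrix(rnorm(12), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  m <- omicsMatrix(v, "rna", "log2")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeOmicsMatrix(m, path)
  back <- readOmicsMatrix(path, "rna", "log2")
  expect_identical(omicsValues(back), v)

  # protein layer may hold missing cells, written as empty fields
  v2 <- v; v2[2, 3] <- NA
  p <- omicsMatrix(v2, "protein", "log2")
  writeOmicsMatrix(p, path)
  backP <- readOmicsMatrix(path, "protein", "log2")
  expect_identical(omicsValues(backP), v2)
  expect_error(readOmicsMatrix(path, "rna", "log2"), "protein layer")
})

test_that("duplicate gene rows are averaged with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "gA\t2\t10", "gB\t5\t6", "gA\t4\t20"), path)
  expect_warning(m <- readOmicsMatrix(path, "rna", "log2"), "duplicated")
  expect_equal(omicsValues(m)["gA", ], c(s1 = 3, s2 = 15))
  expect_equal(nrow(omicsValues(m)), 2L)
})

test_that("malformed matrices are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts1", "gA\t1\t2"), path)
  expect_error(readOmicsMatrix(path, "rna", "log2"), "duplicate sample")
  writeLines(c("gene\ts1\ts2", "gA\t1\tnot_a_number"), path)
  expect_error(readOmicsMatrix(path, "rna", "log2"), "non-numeric")
  expect_error(omicsMatrix(matrix(-1, 1, 1, dimnames = list("g", "s")),
                           "rna", "linear_fpkm"), "linear_fpkm")
})

test_that("GMT parsing dedups genes and rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB", "S2\tdesc\tA\tA\tB"), path)
  gsc <- readGmt(path)
  expect_identical(geneSets(gsc), list(S1 = c("A", "B"), S2 = c("A", "B")))

  writeLines(c("S1\tdesc\tA", "S1\tonly_two"), path)
  expect_error(readGmt(path), "line 2")
  writeLines(c("S1\tdesc\tA", "S1\tdesc\tB"), path)
  expect_error(readGmt(path), "duplicate gene-set name")

  # roundtrip
  writeGmt(geneSetCollection(list(a = c("X", "Y"), b = "Z")), path)
  expect_identical(geneSets(readGmt(path)), list(a = c("X", "Y"), b = "Z"))
})

test_that("mutation and clinical readers validate their schemas", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tgene\tvariant_class\tprotein_change",
               "s1\tTP53\tmissense\tp.R175H",
               "s2\tKRAS\tweird_class\tp.G12V"), path)
  expect_warning(mut <- readMutations(path), "unknown variant class")
  expect_equal(nrow(mut), 2L)
  expect_equal(mut$variant_class[2], "other")
  writeLines(c("sample\tgene", "s1\tTP53"), path)
  expect_error(readMutations(path), "missing required column")

  clin <- data.frame(sample = c("s1", "s2"), sex = c("F", "M"),
                     age = c(60, 70), stage = c("I", "II"),
                     os_time_months = c(12, 30), os_event = c(1, 0),
                     purity = c(0.8, 0.6))
  write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(readClinical(path)$purity, c(0.8, 0.6))
  clin$stage[1] <- "IV"
  write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readClinical(path), "stage must be I, II or III")
  write.table(clin[, setdiff(names(clin), "purity")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(readClinical(path), "purity")
})

test_that("purity filter drops low-purity samples and is idempotent", {
  b <- tinyCohortFixture()
  expect_equal(nrow(b@clinical), 60L)
  f <- applyPurityFilter(b)
  expect_equal(length(f$excluded), 3L)
  expect_setequal(f$excluded, b@truth$lowPurity)
  expect_equal(nrow(f$bundle@clinical), 57L)
  expect_true(all(f$bundle@clinical$purity >= 0.4))
  # idempotent
  f2 <- applyPurityFilter(f$bundle)
  expect_identical(f2$bundle@clinical, f$bundle@clinical)
  expect_length(f2$excluded, 0L)
  # samples dropped from every member
  expect_false(any(f$excluded %in% colnames(omicsValues(f$bundle@rna))))
  expect_false(any(f$excluded %in% f$bundle@mutations$sample))
})

test_that("full cohort bundle roundtrips through a directory exactly", {
  b <- tinyCohortFixture()
  dir <- withr::local_tempdir()
  writeCohort(b, dir)
  back <- readCohort(dir)
  expect_identical(omicsValues(back@rna), omicsValues(b@rna))
  expect_identical(omicsValues(back@protein), omicsValues(b@protein))
  expect_identical(omicsValues(back@cna), omicsValues(b@cna))
  expect_identical(back@mutations, b@mutations)
  expect_equal(back@clinical, b@clinical)
  expect_identical(geneSets(back), geneSets(b))
  expect_identical(back@truth$labels, b@truth$labels)
})
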