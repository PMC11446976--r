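#' @include AllClasses.R
NULL

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique dimnames.
#' @param layer \code{"rna"}, \code{"protein"} or \code{"cna"}.
#' @param scale \code{"linear_fpkm"} or \code{"log2"}.
#' @return An [OmicsMatrix-class].
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' omicsMatrix(m, "rna", "log2")
#' @export
omicsMatrix <- function(values, layer = c("rna", "protein", "cna"),
                        scale = c("log2", "linear_fpkm")) {
  layer <- match.arg(layer)
  scale <- match.arg(scale)
  storage.mode(values) <- "double"
  new("OmicsMatrix", values = values, layer = layer, scale = scale)
}

#' Construct a GeneSetCollection
#'
#' @param sets named list of character gene vectors.
#' @param provenance free-text provenance note.
#' @return A [GeneSetCollection-class].
#' @export
geneSetCollection <- function(sets, provenance = "") {
  new("GeneSetCollection", sets = sets, provenance = provenance)
}

#' Read a genes-by-samples expression/CNA matrix from TSV
#'
#' The first column holds gene identifiers, the header row sample
#' identifiers.  Duplicate gene rows are averaged with a warning (redundant
#' gene entries are combined to their mean); duplicate sample columns are an
#' error.  Empty cells are read as missing values, which only the protein
#' layer may contain.
#'
#' @param path TSV file path.
#' @inheritParams omicsMatrix
#' @return An [OmicsMatrix-class].
#' @export
readOmicsMatrix <- function(path, layer = c("rna", "protein", "cna"),
                            scale = c("log2", "linear_fpkm")) {
  layer <- match.arg(layer)
  scale <- match.arg(scale)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = c("character", rep("character", length(samples))))
  genes <- raw[[1]]
  vals <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(ifelse(col == "", NA, col)),
           numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(NULL, samples))
  bad <- is.na(vals) & !(raw[-1] == "" | is.na(raw[-1]))
  if (any(bad))
    stop("non-numeric cell(s) in ", path)
  if (anyNA(vals) && layer != "protein")
    stop("missing values found in ", path, " but only the protein layer may contain them")
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("averaging ", length(dup), " duplicated gene row(s): ",
            paste(utils::head(dup, 5), collapse = ", "))
    vals <- rowsum(vals, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  rownames(vals) <- genes
  omicsMatrix(vals, layer, scale)
}

#' Write an OmicsMatrix to TSV
#'
#' Inverse of [readOmicsMatrix()]: gene ids in the first column, missing
#' values as empty cells.
#'
#' @param x an [OmicsMatrix-class].
#' @param path output file path.
#' @param idColumn name for the gene-id column.
#' @return \code{path}, invisibly.
#' @export
writeOmicsMatrix <- function(x, path, idColumn = "gene") {
  v <- omicsValues(x)
  # %.17g guarantees an exact decimal round trip for doubles
  chr <- matrix(ifelse(is.na(v), "", sprintf("%.17g", v)), nrow = nrow(v))
  lines <- c(paste(c(idColumn, colnames(v)), collapse = "\t"),
             paste(rownames(v), apply(chr, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  if (nrow(v) == 0L) lines <- lines[1]
  writeLines(lines, path)
  invisible(path)
}

.writeTsv <- function(df, path) {
  for (nm in names(df))
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated as name, description, then
#' genes.  The description is ignored; genes are de-duplicated preserving
#' order; duplicate set names or lines with fewer than 3 fields are errors.
#'
#' @param path GMT file path.
#' @return A [GeneSetCollection-class].
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 tab-separated fields")
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms))
    stop("duplicate gene-set name(s) in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  geneSetCollection(sets, provenance = path)
}

#' Write a GeneSetCollection to GMT
#'
#' @param x a [GeneSetCollection-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(x, path) {
  lines <- vapply(names(x@sets), function(nm)
    paste(c(nm, "na", x@sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a MAF-like somatic mutation table
#'
#' Requires columns sample, gene, variant_class, protein_change.  Variant
#' classes outside the five protein-altering classes (missense, nonsense,
#' frameshift, inframe_indel, splice) plus \code{"other"} are mapped to
#' \code{"other"} with a warning.
#'
#' @param path TSV file path.
#' @return data.frame with the four columns above.
#' @export
readMutations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("sample", "gene", "variant_class", "protein_change")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("mutation table is missing required column(s): ",
         paste(missing, collapse = ", "))
  unknown <- !df$variant_class %in% .VARIANT_CLASSES
  if (any(unknown)) {
    warning("mapping ", sum(unknown), " unknown variant class value(s) to 'other': ",
            paste(unique(df$variant_class[unknown]), collapse = ", "))
    df$variant_class[unknown] <- "other"
  }
  df[required]
}

#' Read a clinical table
#'
#' Requires columns sample, sex (F/M), age, stage (I/II/III),
#' os_time_months (finite, >= 0), os_event (0/1) and purity (in [0, 1],
#' present for every sample).  A stage outside I-III is an error: the cohort
#' the pipeline models is stage I-III.
#'
#' @param path TSV file path.
#' @return data.frame with typed columns.
#' @export
readClinical <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("sample", "sex", "age", "stage", "os_time_months", "os_event", "purity")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("clinical table is missing required column(s): ",
         paste(missing, collapse = ", "))
  df <- df[required]
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) stop("clinical table must have one row per sample")
  if (!all(df$sex %in% c("F", "M"))) stop("sex must be F or M")
  if (!all(df$stage %in% c("I", "II", "III")))
    stop("stage must be I, II or III: got ",
         paste(setdiff(unique(df$stage), c("I", "II", "III")), collapse = ", "))
  for (nm in c("age", "os_time_months", "os_event", "purity"))
    df[[nm]] <- as.numeric(df[[nm]])
  if (any(!is.finite(df$os_time_months)) || any(df$os_time_months < 0))
    stop("os_time_months must be finite and >= 0")
  if (!all(df$os_event %in% c(0, 1))) stop("os_event must be 0 or 1")
  df$os_event <- as.integer(df$os_event)
  if (anyNA(df$purity) || any(df$purity < 0 | df$purity > 1))
    stop("purity must be present for all samples and lie in [0, 1]")
  df
}

.restrictOmics <- function(x, keep) {
  v <- omicsValues(x)
  if (!ncol(v)) return(x)
  omicsMatrix(v[, intersect(colnames(v), keep), drop = FALSE], x@layer, x@scale)
}

#' Exclude low-purity samples from a cohort
#'
#' Restricts every matrix and table of the bundle to samples whose tumour
#' purity is at least \code{threshold} (default 0.4, the study's cutoff) and
#' reports the excluded samples.  Applying the filter twice equals applying
#' it once.
#'
#' @param bundle a [CohortBundle-class].
#' @param threshold minimum purity retained.
#' @return list with elements \code{bundle} (the filtered
#'   [CohortBundle-class]) and \code{excluded} (character vector of dropped
#'   sample ids).
#' @export
applyPurityFilter <- function(bundle, threshold = 0.4) {
  clin <- bundle@clinical
  keep <- clin$sample[clin$purity >= threshold]
  excluded <- setdiff(clin$sample, keep)
  truth <- bundle@truth
  if (length(truth) && !is.null(truth$labels))
    truth$labels <- truth$labels[names(truth$labels) %in% keep]
  out <- new("CohortBundle",
             rna = .restrictOmics(bundle@rna, keep),
             protein = .restrictOmics(bundle@protein, keep),
             cna = .restrictOmics(bundle@cna, keep),
             mutations = bundle@mutations[bundle@mutations$sample %in% keep, ,
                                          drop = FALSE],
             clinical = clin[clin$sample %in% keep, , drop = FALSE],
             geneSets = bundle@geneSets,
             truth = truth)
  list(bundle = out, excluded = excluded)
}

#' Write a full cohort bundle to a directory
#'
#' Emits rna.tsv, protein.tsv, cna.tsv, mutations.tsv, clinical.tsv,
#' signatures.gmt and (for synthetic cohorts) truth.json.
#'
#' @param bundle a [CohortBundle-class].
#' @param dir output directory, created if needed.
#' @return named character vector of written paths, invisibly.
#' @export
writeCohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(rna = file.path(dir, "rna.tsv"),
             protein = file.path(dir, "protein.tsv"),
             cna = file.path(dir, "cna.tsv"),
             mutations = file.path(dir, "mutations.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             geneSets = file.path(dir, "signatures.gmt"))
  writeOmicsMatrix(bundle@rna, paths["rna"])
  writeOmicsMatrix(bundle@protein, paths["protein"])
  writeOmicsMatrix(bundle@cna, paths["cna"])
  .writeTsv(bundle@mutations, paths["mutations"])
  .writeTsv(bundle@clinical, paths["clinical"])
  writeGmt(bundle@geneSets, paths["geneSets"])
  if (length(bundle@truth)) {
    paths["truth"] <- file.path(dir, "truth.json")
    tr <- bundle@truth
    if (!is.null(tr$labels)) tr$labels <- as.list(tr$labels)
    jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Read a cohort bundle written by [writeCohort()]
#'
#' @param dir directory containing the bundle files.
#' @return A [CohortBundle-class].
#' @export
readCohort <- function(dir) {
  truthPath <- file.path(dir, "truth.json")
  truth <- if (file.exists(truthPath)) {
    tr <- jsonlite::read_json(truthPath, simplifyVector = TRUE)
    if (!is.null(tr$labels)) tr$labels <- unlist(tr$labels)
    tr
  } else list()
  new("CohortBundle",
      rna = readOmicsMatrix(file.path(dir, "rna.tsv"), "rna", "log2"),
      protein = readOmicsMatrix(file.path(dir, "protein.tsv"), "protein", "log2"),
      cna = readOmicsMatrix(file.path(dir, "cna.tsv"), "cna", "log2"),
      mutations = readMutations(file.path(dir, "mutations.tsv")),
      clinical = readClinical(file.path(dir, "clinical.tsv")),
      geneSets = readGmt(file.path(dir, "signatures.gmt")),
      truth = truth)
}
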