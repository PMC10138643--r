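#' Run the full cuticular-protein annotation pipeline
#'
#' Chains classification, ortholog naming, tandem-array detection,
#' expression profiling and subfamily trees, writing every report to one
#' output directory: \code{calls.tsv}, \code{orthologs.tsv},
#' \code{arrays.tsv}, \code{family_tissue_table.tsv},
#' \code{heatmap_matrix.tsv}, \code{trees/*.nwk}, \code{config.yaml} (the
#' effective configuration) and \code{pipeline.log} (per-stage counts).
#' Deterministic for a fixed configuration and seed.
#'
#' @param proteome named \code{AAStringSet} or path to a proteome FASTA.
#' @param reference \code{\linkS4class{ReferenceCatalog}}, or NULL to skip
#'   homology-based rules and naming.
#' @param loci \code{GRanges} with \code{gene_id}, or path to a GFF3, or
#'   NULL to skip the layout stage.
#' @param expression \code{\linkS4class{CpExperiment}}, path to an FPKM TSV,
#'   or NULL to skip the expression stage.
#' @param outDir output directory (created).
#' @param config \code{\link{cpConfig}} list.
#' @param overrides optional manual-override data.frame (id, family,
#'   subfamily).
#' @param treeFamilies CPR subfamilies to build consensus-region NJ trees
#'   for (default RR-1 and RR-2); trees need >= 3 members.
#' @param bootstrap bootstrap replicates for the trees (0 = none).
#' @param seed seed for the bootstrap resampling.
#' @return \code{outDir}, invisibly; side effect: report files.
#' @export
runPipeline <- function(proteome, reference = NULL, loci = NULL,
                        expression = NULL, outDir, config = cpConfig(),
                        overrides = NULL, treeFamilies = c("RR-1", "RR-2"),
                        bootstrap = 100L, seed = 1L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(outDir, "pipeline.log")
  logLines <- character()
  note <- function(...) {
    line <- sprintf(...)
    logLines <<- c(logLines, line)
    message(line)
  }
  if (is.character(proteome)) {
    if (!file.exists(proteome)) stop("proteome FASTA not found: ", proteome)
    proteome <- readProteome(proteome)
  }
  if (is.character(loci)) {
    if (!file.exists(loci)) stop("GFF3 not found: ", loci)
    loci <- readGeneLoci(loci)
  }
  if (is.character(expression)) {
    if (!file.exists(expression))
      stop("expression TSV not found: ", expression)
    expression <- readExpression(expression)
  }
  tsv <- function(df, name) {
    write.table(df, file.path(outDir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  note("classify: %d proteins", length(proteome))
  calls <- classifyProteome(proteome, reference, config, overrides = overrides)
  for (f in setdiff(unique(calls$family), NULL))
    note("classify: %s = %d", f, sum(calls$family == f))

  orth <- NULL
  if (!is.null(reference)) {
    cpIds <- calls$id[calls$family != "not-CP"]
    note("orthologs: %d CP proteins vs %d references",
         length(cpIds), length(reference))
    orth <- reciprocalBestHits(proteome[cpIds], refSequences(reference),
                               minIdentity = config$minOrthologIdentity)
    note("orthologs: %d 1:1 pairs, %d co-ortholog edges",
         sum(orth$relation == "1:1"), sum(orth$relation != "1:1"))
    calls <- assignNames(calls, reference, orthologPairs(orth), loci,
                         prefix = config$namePrefix)
    tsv(orth, "orthologs.tsv")
  } else {
    calls <- assignNames(calls, loci = loci, prefix = config$namePrefix)
  }
  tsv(calls, "calls.tsv")

  if (!is.null(loci)) {
    arrays <- buildArrays(calls, loci, config$maxGapKb, config$maxIntervening)
    note("layout: %d tandem arrays covering %d genes",
         nrow(arrays), sum(arrays$size))
    tsv(arrays, "arrays.tsv")
    tsv(colocalizationReport(arrays), "chromosome_summary.tsv")
  }

  if (!is.null(expression)) {
    tab <- familyTissueTable(expression, calls, config$expressedThreshold)
    note("expression: %d genes x %d tissues, %s expressed per tissue",
         nrow(fpkm(expression)), ncol(fpkm(expression)),
         paste(tab$counts["Total", -1], collapse = "/"))
    cts <- cbind(stratum = rownames(tab$counts), tab$counts)
    pct <- cbind(stratum = rownames(tab$percent), tab$percent)
    tsv(cts, "family_tissue_table.tsv")
    tsv(pct, "family_tissue_percent.tsv")
    hm <- heatmapMatrix(expression, config$pseudocount)
    tsv(cbind(gene = rownames(hm$matrix), as.data.frame(hm$matrix)),
        "heatmap_matrix.tsv")
    tsv(tissueSpecificity(expression, config$dominance),
        "tissue_specificity.tsv")
  }

  motifs <- defaultMotifs()
  treeDir <- file.path(outDir, "trees")
  for (sf in treeFamilies) {
    ids <- calls$id[calls$family == "CPR" & !is.na(calls$subfamily) &
                      calls$subfamily == sf]
    if (length(ids) < 3L) {
      note("tree: %s skipped (%d members < 3)", sf, length(ids))
      next
    }
    motif <- if (sf == "RR-1") motifs$rr1 else motifs$rr2
    msa <- consensusRegion(proteome[ids], motif, config$consensusFlank)
    tr <- if (bootstrap > 0L) bootstrapTree(msa, bootstrap, seed)
          else njTree(poissonDist(msa))
    dir.create(treeDir, showWarnings = FALSE)
    writeNewickTree(tr, file.path(treeDir, paste0(sf, ".nwk")))
    note("tree: %s with %d tips written", sf, length(ids))
  }

  yaml::write_yaml(c(config, list(seed = seed, bootstrap = bootstrap)),
                   file.path(outDir, "config.yaml"))
  writeLines(logLines, logFile)
  invisible(outDir)
}

#' Run the bundled synthetic demonstration
#'
#' Generates the default synthetic fixture (60 planted proteins over the
#' twelve A. pernyi-relevant categories plus decoys, a tandem-array layout,
#' and an FPKM table spanning all six expression bins over six tissues) and
#' runs the full pipeline on it.
#'
#' @param outDir output directory.
#' @param seed RNG seed controlling generation and bootstrap.
#' @param mutationRate planted-diagnostic mutation rate.
#' @return invisibly, a list with the generator truth and the output
#'   directory, for downstream comparison.
#' @export
runDemo <- function(outDir = tempfile("cuticleR-demo"), seed = 7L,
                    mutationRate = 0.02) {
  sim <- simulateProteome(nDecoys = 10L, mutationRate = mutationRate,
                          seed = seed)
  n <- length(sim$proteome)
  ## layout: every planted gene placed; CP arrays for the two RR subfamilies
  spec <- data.frame(
    family = c("CPR", "CPR", "CPG", "not-CP"),
    subfamily = c("RR-1", "RR-2", NA, NA),
    size = c(5L, 8L, 3L, 4L),
    chromosome = c("chr18", "chr14", "chr5", "chr2"),
    spacing_kb = c(10, 12, 15, 20), stringsAsFactors = FALSE)
  lay <- simulateLayout(spec, seed = seed)
  ## expression: one bin column per tissue cycling through all six bins
  tissues <- c("Ep", "PG", "He", "Mg", "FA", "MA")
  set.seed(seed)
  bins <- matrix(sample(expressionBins(), n * length(tissues), replace = TRUE),
                 nrow = n, dimnames = list(names(sim$proteome), tissues))
  expr <- simulateExpression(bins, seed = seed)
  out <- runPipeline(sim$proteome, sim$reference, loci = NULL,
                     expression = expr$expression, outDir = outDir,
                     seed = seed)
  ## layout stage runs on its own planted fixture (ids differ from proteome)
  arrays <- buildArrays(lay$calls, lay$loci)
  write.table(arrays, file.path(outDir, "arrays.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(outDir = out, proteomeTruth = sim$truth,
                 layoutTruth = lay$truth, expressionTruth = expr$truth))
}
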