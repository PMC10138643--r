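## Synthetic fixtures with known ground truth: proteomes with planted family
## diagnostics, reference catalogs, chromosome layouts with tandem arrays,
## FPKM tables hitting requested bins, and clade-structured alignments.

.AA20 <- setdiff(.AA_ALPHABET, "X")

.randSeq <- function(n, freq = NULL) {
  paste(sample(.AA20, n, replace = TRUE, prob = freq), collapse = "")
}

## cysteine-free random sequence: used for homology-defined reference
## members so a chance C-X5-C pair can never pre-empt the homology rule
.randSeqNoC <- function(n) {
  paste(sample(setdiff(.AA20, "C"), n, replace = TRUE), collapse = "")
}

.mutate <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit))
    chars[hit] <- vapply(chars[hit], function(old)
      sample(setdiff(.AA20, old), 1L), character(1))
  paste(chars, collapse = "")
}

## sample() that never falls into the scalar-expansion trap
.resample <- function(x, n = 1L) x[sample.int(length(x), n)]

## instantiate a motif: fixed residues kept, alternatives/gaps sampled
.instantiateMotif <- function(motif) {
  paste(vapply(motif@elements, function(el) {
    switch(el$type,
      fixed = el$residues,
      alt = .resample(el$residues),
      gap = .randSeq(.resample(el$min:el$max)))
  }, character(1)), collapse = "")
}

.plant <- function(core, flank = c(15L, 40L)) {
  paste0(.randSeq(.resample(flank[1]:flank[2])), core,
         .randSeq(.resample(flank[1]:flank[2])))
}

#' Generate a synthetic reference catalog
#'
#' A verified-CP stand-in: per family a few synthetic members whose
#' sequences carry that family's diagnostic (or, for the purely
#' homology-defined families, a reproducible random sequence), named in the
#' style of a curated B. mori catalog (\code{BmorCPF1}, ...). Used as the
#' homology target for classification, RR-3 assignment and ortholog naming
#' on synthetic runs.
#'
#' @param seed RNG seed.
#' @param perFamily members per homology family.
#' @return a \code{\linkS4class{ReferenceCatalog}}.
#' @export
simulateReference <- function(seed = 1L, perFamily = 2L) {
  set.seed(seed)
  motifs <- defaultMotifs()
  seqs <- character(); fam <- character(); sub <- character(); nm <- character()
  add <- function(s, f, sb, name) {
    seqs <<- c(seqs, s); fam <<- c(fam, f); sub <<- c(sub, sb); nm <<- c(nm, name)
  }
  for (k in seq_len(perFamily)) {
    add(.plant(.instantiateMotif(motifs$rr1)), "CPR", "RR-1",
        sprintf("BmorCPR%d", k))
    add(.plant(.instantiateMotif(motifs$rr2)), "CPR", "RR-2",
        sprintf("BmorCPR%d", 50 + k))
  }
  for (k in seq_len(max(2L, perFamily)))   # RR-3 exemplars: homology-only
    add(.randSeqNoC(160L), "CPR", "RR-3", sprintf("BmorCPR%d", 90 + k))
  add(.plant(.instantiateMotif(motifs$cpap1)), "CPAP1", NA, "BmorCPAP1-A")
  add(.plant(paste0(.instantiateMotif(motifs$cpap3), .randSeq(10L),
                    .instantiateMotif(motifs$cpap3), .randSeq(10L),
                    .instantiateMotif(motifs$cpap3))), "CPAP3", NA,
      "BmorCPAP3-A1")
  for (k in seq_len(perFamily)) {
    add(.randSeqNoC(140L), "CPF", NA, sprintf("BmorCPF%d", k))
    add(.randSeqNoC(130L), "CPFL", NA, sprintf("BmorCPFL%d", k))
    add(.randSeqNoC(120L), "18aa", NA, sprintf("Bmor18aa%d", k))
    add(.randSeqNoC(125L), "CPLCA", NA, sprintf("BmorCPLCA%d", k))
    gly <- paste(rep("GGYGG", 6L), collapse = .randSeq(3L))
    add(.plant(gly, c(10L, 20L)), "CPG", NA, sprintf("BmorCPG%d", k))
    add(.randSeqNoC(110L), "CPH", NA, sprintf("BmorCPH%d", k))
  }
  ids <- sprintf("BMREF%03d", seq_along(seqs))
  ss <- AAStringSet(seqs); names(ss) <- ids
  ReferenceCatalog(ss, fam, sub, nm)
}

.PLANT_CATEGORIES <- c("RR-1", "RR-2", "RR-3", "CPAP1", "CPAP3", "CPF",
                       "CPFL", "CPT", "CPCFC", "CPLCP", "CPG", "CPH")

.plantOne <- function(category, motifs, reference) {
  pickRef <- function(f, sb = NULL) {
    sub <- refSubset(reference, f, sb)
    as.character(refSequences(sub))[[sample(length(sub), 1L)]]
  }
  switch(category,
    "RR-1" = .plant(.instantiateMotif(motifs$rr1)),
    "RR-2" = .plant(.instantiateMotif(motifs$rr2)),
    "RR-3" = .mutate(pickRef("CPR", "RR-3"), 0.05),
    "CPAP1" = .plant(.instantiateMotif(motifs$cpap1)),
    "CPAP3" = .plant(paste0(.instantiateMotif(motifs$cpap3), .randSeq(10L),
                            .instantiateMotif(motifs$cpap3), .randSeq(10L),
                            .instantiateMotif(motifs$cpap3))),
    "CPF" = .mutate(pickRef("CPF"), 0.05),
    "CPFL" = .mutate(pickRef("CPFL"), 0.05),
    "CPT" = paste0(.randSeq(10L), .instantiateMotif(motifs$tweedle1),
                   .randSeq(8L), .instantiateMotif(motifs$tweedle2),
                   .randSeq(8L), .instantiateMotif(motifs$tweedle3),
                   .randSeq(8L), .instantiateMotif(motifs$tweedle4),
                   .randSeq(10L)),
    "CPCFC" = paste0(.randSeq(12L), .instantiateMotif(motifs$cpcfc),
                     .randSeq(4L), .instantiateMotif(motifs$cpcfc),
                     .randSeq(4L), .instantiateMotif(motifs$cpcfc),
                     .randSeq(12L)),
    "CPLCP" = paste0(.randSeq(8L),
                     paste(sample(rep(c("PV", "PY"), 10L)), collapse = "A"),
                     .randSeq(8L)),
    "CPG" = .plant(paste0("GGYGG", .randSeq(3L), "GGAGG", .randSeq(3L),
                          "GGYGG"), c(8L, 15L)),
    "CPH" = .plant(paste(rep("AAPV", 5L), collapse = ""), c(20L, 40L)),
    stop("unknown planted category ", category))
}

.familyOf <- function(category) {
  ifelse(category %in% c("RR-1", "RR-2", "RR-3", "RR-NC"), "CPR", category)
}

#' Generate a synthetic proteome with planted family diagnostics
#'
#' Each planted protein is random flank sequence around an instantiated
#' family diagnostic (R&R consensus with wildcards randomized, one or three
#' ChtBD2 spacing instances, ordered Tweedle blocks, three C-X5-C repeats,
#' PV/PY-dense cores, GGxGG-rich glycine cores, AAP[AVL] repeats; RR-3 and
#' the homology families are mutated copies of reference members), then
#' mutated at a per-site substitution rate. Decoys are random sequences
#' rejection-sampled until the classifier calls them not-CP, so planted
#' truth labels are the only positives.
#'
#' @param nPerCategory named integer vector over the planted categories
#'   (default 5 each of RR-1, RR-2, RR-3, CPAP1, CPAP3, CPF, CPFL, CPT,
#'   CPCFC, CPLCP, CPG, CPH: 60 genes).
#' @param nDecoys decoy proteins appended (default 0).
#' @param mutationRate per-site substitution probability after planting.
#' @param seed RNG seed; regeneration with the same arguments is identical.
#' @param reference catalog used for homology-planted families; defaults to
#'   \code{simulateReference(seed)}.
#' @param maxTries rejection-sampling budget per decoy.
#' @return list with \code{proteome} (\code{AAStringSet}), \code{truth}
#'   (data.frame: id, category, family) and \code{reference}.
#' @export
simulateProteome <- function(nPerCategory = setNames(rep(5L, 12L), .PLANT_CATEGORIES),
                             nDecoys = 0L, mutationRate = 0,
                             seed = 7L, reference = NULL, maxTries = 50L) {
  if (is.null(reference)) reference <- simulateReference(seed)
  set.seed(seed + 1L)
  motifs <- defaultMotifs()
  stopifnot(all(names(nPerCategory) %in% .PLANT_CATEGORIES),
            mutationRate >= 0, mutationRate <= 1)
  seqs <- character(); cat <- character()
  for (cg in names(nPerCategory)) {
    for (k in seq_len(nPerCategory[[cg]])) {
      seqs <- c(seqs, .mutate(.plantOne(cg, motifs, reference), mutationRate))
      cat <- c(cat, cg)
    }
  }
  config <- cpConfig()
  for (k in seq_len(nDecoys)) {
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      s <- .randSeq(sample(80:200, 1L))
      cl <- classifyProteome(setNames(s, "d"), reference, config, motifs)
      if (cl$family == "not-CP") { ok <- TRUE; break }
    }
    if (!ok) stop("decoy rejection sampling exhausted after ", maxTries,
                  " tries; lower the composition bias")
    seqs <- c(seqs, s); cat <- c(cat, "decoy")
  }
  ids <- sprintf("SYNP%04d", seq_along(seqs))
  prot <- AAStringSet(seqs); names(prot) <- ids
  truth <- data.frame(id = ids, category = cat,
                      family = ifelse(cat == "decoy", "not-CP", .familyOf(cat)),
                      stringsAsFactors = FALSE)
  list(proteome = prot, truth = truth, reference = reference)
}

#' Generate a synthetic chromosome layout with tandem arrays
#'
#' Places requested same-family arrays at fixed start-to-start spacings with
#' decoy genes interleaved between arrays, and writes the truth of intended
#' array membership. RR-1 and RR-2 arrays are never co-planted.
#'
#' @param arraysSpec data.frame with columns \code{family}, \code{subfamily}
#'   (NA for non-CPR), \code{size}, \code{chromosome}, \code{spacing_kb}.
#' @param seed RNG seed.
#' @param geneKb span of each gene, kb.
#' @return list: \code{loci} (\code{GRanges} with gene_id), \code{calls}
#'   (family-call data.frame for the planted genes; decoys are not-CP) and
#'   \code{truth} (data.frame id, array id or NA).
#' @export
simulateLayout <- function(arraysSpec, seed = 1L, geneKb = 2) {
  set.seed(seed)
  stopifnot(all(c("family", "size", "chromosome", "spacing_kb") %in%
                colnames(arraysSpec)))
  if (!"subfamily" %in% colnames(arraysSpec))
    arraysSpec$subfamily <- NA_character_
  rows <- list(); idc <- 0L
  nextStart <- list()
  for (i in seq_len(nrow(arraysSpec))) {
    chr <- arraysSpec$chromosome[i]
    if (is.null(nextStart[[chr]])) nextStart[[chr]] <- 1e4
    pos <- nextStart[[chr]]
    for (g in seq_len(arraysSpec$size[i])) {
      idc <- idc + 1L
      rows[[idc]] <- data.frame(
        id = sprintf("SYNG%04d", idc), chromosome = chr,
        start = round(pos), end = round(pos + geneKb * 1000 - 1),
        family = arraysSpec$family[i], subfamily = arraysSpec$subfamily[i],
        array = if (arraysSpec$size[i] >= 2L) sprintf("truth%02d", i)
                else NA_character_,
        stringsAsFactors = FALSE)
      pos <- pos + arraysSpec$spacing_kb[i] * 1000
    }
    ## decoy spacer genes after each array, far enough not to chain
    pos <- pos + 1e6
    for (d in 1:2) {
      idc <- idc + 1L
      rows[[idc]] <- data.frame(
        id = sprintf("SYNG%04d", idc), chromosome = chr,
        start = round(pos), end = round(pos + geneKb * 1000 - 1),
        family = "not-CP", subfamily = NA_character_, array = NA_character_,
        stringsAsFactors = FALSE)
      pos <- pos + 5e5
    }
    nextStart[[chr]] <- pos
  }
  df <- do.call(rbind, rows)
  if (anyDuplicated(paste(df$chromosome, df$start)))
    stop("overlapping placements in layout spec")
  loci <- GRanges(df$chromosome, IRanges(df$start, df$end), strand = "+")
  loci$gene_id <- df$id
  calls <- data.frame(id = df$id, family = df$family, subfamily = df$subfamily,
                      evidence = "planted", stringsAsFactors = FALSE)
  list(loci = loci, calls = calls,
       truth = df[, c("id", "array")],
       gff3 = NULL)
}

#' Write synthetic loci to a GFF3 file
#' @param loci \code{GRanges} with \code{gene_id}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGff3 <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_along(loci)) {
    writeLines(sprintf("%s\tcuticleR\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       as.character(GenomicRanges::seqnames(loci))[i],
                       GenomicRanges::start(loci)[i],
                       GenomicRanges::end(loci)[i],
                       as.character(GenomicRanges::strand(loci))[i],
                       loci$gene_id[i]), con)
  }
  invisible(path)
}

#' Generate an FPKM table hitting requested expression bins
#'
#' Values are drawn log-uniformly within each target bin's interval (the
#' lowest bin draws uniformly on [0,1); very_high is capped at 1e5), so
#' binning the generated table reproduces the targets exactly.
#'
#' @param binTargets character matrix (genes x tissues) of bin labels from
#'   \code{\link{expressionBins}}.
#' @param seed RNG seed.
#' @return a \code{\linkS4class{CpExperiment}} plus the target matrix, as a
#'   list (\code{expression}, \code{truth}).
#' @export
simulateExpression <- function(binTargets, seed = 1L) {
  set.seed(seed)
  stopifnot(is.matrix(binTargets), all(binTargets %in% .BIN_LEVELS))
  lo <- setNames(.BIN_BREAKS[-length(.BIN_BREAKS)], .BIN_LEVELS)
  hi <- setNames(c(.BIN_BREAKS[2:6], 1e5), .BIN_LEVELS)
  vals <- matrix(0, nrow(binTargets), ncol(binTargets),
                 dimnames = dimnames(binTargets))
  for (i in seq_len(nrow(binTargets))) for (j in seq_len(ncol(binTargets))) {
    b <- binTargets[i, j]
    vals[i, j] <- if (b == "none_or_extremely_low") runif(1, 0, 1 - 1e-9)
                  else exp(runif(1, log(lo[[b]]), log(hi[[b]] - 1e-6)))
  }
  list(expression = CpExperiment(vals), truth = binTargets)
}

#' Generate a clade-structured alignment with known memberships
#'
#' Each clade ancestor is the root sequence mutated at
#' \code{betweenDivergence - withinDivergence} (the extra divergence
#' separating clades); leaves are their ancestor mutated at
#' \code{withinDivergence}. Setting within = between therefore erases the
#' clade signal, the documented negative control. Sequences are generated
#' ungapped, so the set is an alignment as-is.
#'
#' @param nClades,perClade clade count and leaves per clade.
#' @param withinDivergence,betweenDivergence per-site substitution
#'   probabilities, within < between.
#' @param length alignment length (columns).
#' @param seed RNG seed.
#' @return list: \code{msa} (named character vector) and \code{truth}
#'   (data.frame id, clade).
#' @export
simulateCladeMsa <- function(nClades = 2L, perClade = 4L,
                             withinDivergence = 0.05, betweenDivergence = 0.6,
                             length = 120L, seed = 1L) {
  stopifnot(withinDivergence >= 0, withinDivergence <= betweenDivergence,
            betweenDivergence <= 1)
  set.seed(seed)
  root <- .randSeq(length)
  msa <- character(); clade <- character()
  for (c in seq_len(nClades)) {
    anc <- .mutate(root, betweenDivergence - withinDivergence)
    for (l in seq_len(perClade)) {
      msa <- c(msa, .mutate(anc, withinDivergence))
      clade <- c(clade, sprintf("clade%d", c))
    }
  }
  ids <- sprintf("%s_t%d", clade, seq_along(msa))
  names(msa) <- ids
  list(msa = msa, truth = data.frame(id = ids, clade = clade,
                                     stringsAsFactors = FALSE))
}

#' Realize an FPKM matrix and calls from a printed count table
#'
#' Given a family-by-tissue table of genome counts and expressed counts
#' (the shape of a published CP census), constructs a minimal expression
#' matrix and call set whose \code{\link{familyTissueTable}} reproduces the
#' table: each stratum gets its genome count of genes, and in each tissue
#' the first k of them receive FPKM 10 (expressed) and the rest 0.
#'
#' @param counts data.frame/matrix: rows = family strata (rownames from the
#'   stratum vocabulary), columns = \code{Genome} then tissues; no totals
#'   row.
#' @param prefix gene-id prefix.
#' @return list: \code{expression} (\code{\linkS4class{CpExperiment}}) and
#'   \code{calls}.
#' @export
expressionFromCounts <- function(counts, prefix = "G") {
  counts <- as.matrix(counts)
  stopifnot("Genome" %in% colnames(counts),
            all(rownames(counts) %in% .famStrata()))
  tissues <- setdiff(colnames(counts), "Genome")
  ids <- character(); fam <- character(); sub <- character()
  for (s in rownames(counts)) {
    n <- counts[s, "Genome"]
    if (n == 0) next
    ids <- c(ids, sprintf("%s_%s_%03d", prefix, gsub("[^A-Za-z0-9]", "", s),
                          seq_len(n)))
    if (s %in% cpFamilies(TRUE)) {
      fam <- c(fam, rep("CPR", n)); sub <- c(sub, rep(s, n))
    } else {
      fam <- c(fam, rep(s, n)); sub <- c(sub, rep(NA_character_, n))
    }
  }
  m <- matrix(0, length(ids), length(tissues),
              dimnames = list(ids, tissues))
  strat <- ifelse(fam == "CPR", sub, fam)
  for (s in rownames(counts)) for (tis in tissues) {
    k <- counts[s, tis]
    if (k > counts[s, "Genome"])
      stop("expressed count exceeds genome count for ", s, " / ", tis)
    if (k > 0) m[which(strat == s)[seq_len(k)], tis] <- 10
  }
  calls <- data.frame(id = ids, family = fam, subfamily = sub,
                      evidence = "from-counts", stringsAsFactors = FALSE)
  list(expression = CpExperiment(m), calls = calls)
}
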