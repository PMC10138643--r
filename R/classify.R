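#' Default classifier configuration
#'
#' Every numeric threshold of the decision cascade in one place. The family
#' definitions are qualitative in the literature ("glycine-rich", "high
#' density of PV and PY", "sequence similarity"); the numbers here make them
#' operational and every report prints the configuration used.
#'
#' \describe{
#'   \item{cprScore}{minimal fraction of matched consensus positions for a
#'     CPR call (0.5).}
#'   \item{cprTieMargin}{RR-1/RR-2 score difference below which the
#'     subfamily is left as RR-NC (0.05).}
#'   \item{rr3Identity}{identity to a known RR-3 exemplar claiming the RR-3
#'     subfamily (0.5); must also exceed both consensus scores.}
#'   \item{cpapMaxMismatches}{substitutions tolerated across the six
#'     cysteines of a ChtBD2 spacing hit (1).}
#'   \item{tweedleMinBlocks}{Tweedle blocks (of four) required in order (3).}
#'   \item{familyIdentity}{identity to a verified CPF/CPFL/18aa/CPLCA
#'     reference member (0.40).}
#'   \item{cplcpDipeptideMin}{combined PV+PY occurrences for CPLCP (10).}
#'   \item{cplcpProline}{minimal proline fraction for CPLCP (0.10).}
#'   \item{cpgGlycine}{glycine fraction defining "glycine-rich" (0.20).}
#'   \item{cpgRepeatMin}{non-overlapping GGxGG repeats for CPG (2).}
#'   \item{cphIdentity}{identity to a CPG/CPH reference member for CPH
#'     (0.36, the floor reported for verified CPH/CPG homology).}
#'   \item{cphAapMin}{AAP[AVL] repeats for CPH (3).}
#'   \item{minOrthologIdentity}{identity floor for reciprocal best hits (0.3).}
#'   \item{namePrefix}{species prefix for newly named genes ("Ap").}
#'   \item{maxGapKb, maxIntervening}{tandem-array chaining rules (100 kb
#'     start-to-start, 1 intervening non-family gene).}
#'   \item{expressedThreshold}{FPKM at or above which a gene counts as
#'     expressed (1).}
#'   \item{pseudocount}{added to FPKM before log10 for heat maps (1).}
#'   \item{dominance}{max/total FPKM ratio flagging tissue-specificity (0.8).}
#'   \item{consensusFlank}{residues flanking the consensus window for
#'     subfamily trees (10).}
#' }
#'
#' @param ... overrides, e.g. \code{cpConfig(cprScore = 0.6)}.
#' @return named list.
#' @export
cpConfig <- function(...) {
  cfg <- list(
    cprScore = 0.5, cprTieMargin = 0.05, rr3Identity = 0.5,
    cpapMaxMismatches = 1L, tweedleMinBlocks = 3L,
    familyIdentity = 0.40, cplcpDipeptideMin = 10L, cplcpProline = 0.10,
    cpgGlycine = 0.20, cpgRepeatMin = 2L, cphIdentity = 0.36, cphAapMin = 3L,
    minOrthologIdentity = 0.3, namePrefix = "Ap",
    maxGapKb = 100, maxIntervening = 1L,
    expressedThreshold = 1, pseudocount = 1, dominance = 0.8,
    consensusFlank = 10L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config option(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

.call <- function(id, family, subfamily = NA_character_, evidence = "") {
  data.frame(id = id, family = family, subfamily = subfamily,
             evidence = evidence, stringsAsFactors = FALSE)
}

.bestIdentity <- function(seq, catalog, families, subfamilies = NULL,
                          scheme = defaultScheme()) {
  sub <- refSubset(catalog, families, subfamilies)
  if (length(sub) == 0L) return(list(identity = -Inf, id = NA_character_))
  ids <- .identityBatch(seq, as.character(refSequences(sub)), scheme)$identity
  k <- which.max(ids)
  list(identity = ids[[k]], id = names(refSequences(sub))[k])
}

#' Classify one protein as CPR (RR-1 / RR-2 / RR-3 / RR-NC) or not
#'
#' The CPR family carries the R&R chitin-binding consensus. A protein is
#' called CPR when its best positional score against the extended RR-1 or
#' RR-2 consensus reaches \code{cprScore}; the subfamily is the better of
#' the two unless the scores are within \code{cprTieMargin}, in which case
#' the protein stays RR-NC (CPR not classified). RR-3 is claimed by identity
#' to known RR-3 exemplars when that identity beats both consensus scores.
#'
#' @param id protein id.
#' @param seq amino-acid string.
#' @param motifs motif list from \code{\link{defaultMotifs}}.
#' @param reference \code{\linkS4class{ReferenceCatalog}} (RR-3 exemplars).
#' @param config \code{\link{cpConfig}} list.
#' @return one-row FamilyCall data.frame, or NULL when no rule fires.
#' @export
classifyCpr <- function(id, seq, motifs = defaultMotifs(), reference = NULL,
                        config = cpConfig()) {
  s1 <- consensusScore(seq, motifs$rr1)
  s2 <- consensusScore(seq, motifs$rr2)
  rr3 <- if (!is.null(reference))
    .bestIdentity(seq, reference, "CPR", "RR-3") else list(identity = -Inf)
  consBest <- max(s1$score, s2$score)
  if (rr3$identity >= config$rr3Identity && rr3$identity > consBest)
    return(.call(id, "CPR", "RR-3",
                 sprintf("rr3-identity=%.3f to %s", rr3$identity, rr3$id)))
  if (consBest < config$cprScore) return(NULL)
  ev <- sprintf("rr1-score=%.3f;rr2-score=%.3f", s1$score, s2$score)
  sub <- if (abs(s1$score - s2$score) < config$cprTieMargin) "RR-NC"
         else if (s1$score > s2$score) "RR-1" else "RR-2"
  .call(id, "CPR", sub, ev)
}

#' Classify one protein as CPAP1 or CPAP3 by ChtBD2 spacing
#'
#' CPAPs (cuticular proteins analogous to peritrophins) carry one (CPAP1) or
#' three (CPAP3) ChtBD2 chitin-binding domains, recognized as
#' cysteine-spacing motifs. Three or more non-overlapping CPAP3-spacing hits
#' call CPAP3; otherwise one CPAP1-spacing hit calls CPAP1.
#'
#' @inheritParams classifyCpr
#' @return one-row FamilyCall data.frame, or NULL.
#' @export
classifyCpap <- function(id, seq, motifs = defaultMotifs(), config = cpConfig()) {
  mm <- config$cpapMaxMismatches
  n3 <- countNonoverlapping(seq, motifs$cpap3, maxMismatches = mm)
  if (n3 >= 3L)
    return(.call(id, "CPAP3", evidence = sprintf("chtbd2-spacing-hits=%d", n3)))
  n1 <- countNonoverlapping(seq, motifs$cpap1, maxMismatches = mm)
  if (n1 >= 1L)
    return(.call(id, "CPAP1", evidence = sprintf("chtbd2-spacing-hits=%d", n1)))
  NULL
}

#' Classify one protein as Tweedle (CPT)
#'
#' The Tweedle motif comprises four conserved blocks (I: Kxx[YF],
#' II: Kx(4-5)FIKAP, III: TxxYVL, IV: KPEVYxF[VI]KY). A CPT call requires at
#' least \code{tweedleMinBlocks} of the four, appearing in order along the
#' protein.
#'
#' @inheritParams classifyCpr
#' @return one-row FamilyCall data.frame, or NULL.
#' @export
classifyTweedle <- function(id, seq, motifs = defaultMotifs(), config = cpConfig()) {
  blocks <- list(motifs$tweedle1, motifs$tweedle2, motifs$tweedle3, motifs$tweedle4)
  starts <- vapply(blocks, function(b) {
    h <- scanMotif(seq, b)
    if (nrow(h) == 0L) NA_integer_ else h$start[1]
  }, integer(1))
  present <- which(!is.na(starts))
  if (length(present) < config$tweedleMinBlocks) return(NULL)
  ## blocks found must occur in order I < II < III < IV by first hit
  ordered <- all(diff(starts[present]) > 0)
  if (!ordered) return(NULL)
  .call(id, "CPT", evidence = sprintf("tweedle-blocks=%s",
                                      paste(present, collapse = "+")))
}

#' Classify one protein into the low-complexity / homology-defined families
#'
#' Fixed rule order (first hit wins):
#' \enumerate{
#'   \item CPCFC: >= 2 non-overlapping C-X5-C repeats;
#'   \item CPF / CPFL / 18aa / CPLCA: identity to a verified member of that
#'     family >= \code{familyIdentity};
#'   \item CPLCP: PV+PY occurrences >= \code{cplcpDipeptideMin} and proline
#'     fraction >= \code{cplcpProline};
#'   \item CPG: glycine-rich and >= \code{cpgRepeatMin} GGxGG repeats;
#'   \item CPH: identity to a CPG/CPH member >= \code{cphIdentity}, or >=
#'     \code{cphAapMin} AAP[AVL] repeats.
#' }
#'
#' @inheritParams classifyCpr
#' @return one-row FamilyCall data.frame, or NULL.
#' @export
classifyLowComplexity <- function(id, seq, motifs = defaultMotifs(),
                                  reference = NULL, config = cpConfig()) {
  nCfc <- countNonoverlapping(seq, motifs$cpcfc)
  if (nCfc >= 2L)
    return(.call(id, "CPCFC", evidence = sprintf("cx5c-repeats=%d", nCfc)))
  if (!is.null(reference)) {
    for (fam in c("CPF", "CPFL", "18aa", "CPLCA")) {
      hit <- .bestIdentity(seq, reference, fam)
      if (hit$identity >= config$familyIdentity)
        return(.call(id, fam, evidence = sprintf("identity=%.3f to %s",
                                                 hit$identity, hit$id)))
    }
  }
  comp <- residueComposition(seq)
  pv <- countDipeptide(seq, "PV"); py <- countDipeptide(seq, "PY")
  pFrac <- if ("P" %in% names(comp)) comp[["P"]] else 0
  if (pv + py >= config$cplcpDipeptideMin && pFrac >= config$cplcpProline)
    return(.call(id, "CPLCP",
                 evidence = sprintf("pv=%d;py=%d;proline=%.2f", pv, py, pFrac)))
  gFrac <- if ("G" %in% names(comp)) comp[["G"]] else 0
  nGg <- countNonoverlapping(seq, motifs$cpg)
  if (gFrac >= config$cpgGlycine && nGg >= config$cpgRepeatMin)
    return(.call(id, "CPG",
                 evidence = sprintf("glycine=%.2f;ggxgg-repeats=%d", gFrac, nGg)))
  if (!is.null(reference)) {
    hit <- .bestIdentity(seq, reference, c("CPG", "CPH"))
    if (hit$identity >= config$cphIdentity)
      return(.call(id, "CPH", evidence = sprintf("identity=%.3f to %s",
                                                 hit$identity, hit$id)))
  }
  nAap <- countNonoverlapping(seq, motifs$cph)
  if (nAap >= config$cphAapMin)
    return(.call(id, "CPH", evidence = sprintf("aap-repeats=%d", nAap)))
  NULL
}

#' Classify a whole proteome through the family cascade
#'
#' Cascade: ChtBD2 spacing (CPAP, which takes precedence over CPR because a
#' ChtBD2-bearing protein is a CPAP by definition), then the R&R consensus
#' (CPR), then Tweedle, then the low-complexity / homology families;
#' anything left is not-CP. Exactly one call per protein; the run is a pure
#' function of (proteome, reference, config).
#'
#' @param proteome named \code{AAStringSet} or character vector.
#' @param reference \code{\linkS4class{ReferenceCatalog}} or NULL.
#' @param config \code{\link{cpConfig}} list.
#' @param motifs motif list, see \code{\link{defaultMotifs}}.
#' @param overrides optional data.frame (\code{id}, \code{family},
#'   \code{subfamily}) of manual curation decisions applied after the
#'   cascade; overridden calls are flagged.
#' @return data.frame with one row per protein: \code{id}, \code{family},
#'   \code{subfamily}, \code{evidence}, \code{override}.
#' @export
classifyProteome <- function(proteome, reference = NULL, config = cpConfig(),
                             motifs = defaultMotifs(), overrides = NULL) {
  ids <- names(proteome)
  seqs <- as.character(proteome)
  names(seqs) <- ids
  if (length(seqs) && (is.null(ids) || any(!nzchar(ids))))
    stop("proteome sequences must be named")
  rows <- lapply(seq_along(seqs), function(i) {
    id <- ids[i]; s <- seqs[[i]]
    res <- classifyCpap(id, s, motifs, config)
    if (is.null(res)) res <- classifyCpr(id, s, motifs, reference, config)
    if (is.null(res)) res <- classifyTweedle(id, s, motifs, config)
    if (is.null(res)) res <- classifyLowComplexity(id, s, motifs, reference, config)
    if (is.null(res)) res <- .call(id, "not-CP")
    res
  })
  calls <- if (length(rows)) do.call(rbind, rows)
           else data.frame(id = character(), family = character(),
                           subfamily = character(), evidence = character(),
                           stringsAsFactors = FALSE)
  calls$override <- logical(nrow(calls))
  if (!is.null(overrides) && nrow(overrides)) {
    stopifnot(all(c("id", "family") %in% colnames(overrides)))
    for (i in seq_len(nrow(overrides))) {
      k <- match(overrides$id[i], calls$id)
      if (is.na(k)) stop("override for unknown id ", overrides$id[i])
      calls$family[k] <- overrides$family[i]
      calls$subfamily[k] <- if ("subfamily" %in% colnames(overrides))
        overrides$subfamily[i] else NA_character_
      calls$override[k] <- TRUE
      calls$evidence[k] <- paste0(calls$evidence[k], ";manual-override")
    }
  }
  rownames(calls) <- NULL
  calls
}

#' Assign gene names from orthology and annotation order
#'
#' Proteins with a 1:1 reference ortholog inherit the reference name stem
#' (e.g. \code{BmorCPAP3-A1} -> \code{ApCPAP3-A1}); the rest are named
#' \code{<prefix><family><k>} with k increasing in genomic annotation order
#' within each family. Names are checked for uniqueness; a collision means a
#' reference name was inherited twice and is a hard error.
#'
#' @param calls output of \code{\link{classifyProteome}}.
#' @param reference \code{\linkS4class{ReferenceCatalog}}.
#' @param orthologs named vector query id -> reference id
#'   (\code{\link{orthologPairs}}).
#' @param loci optional \code{GRanges} with \code{gene_id}; defines the
#'   annotation order (chromosome, then start). Without loci, input order.
#' @param prefix species prefix for de-novo names.
#' @return \code{calls} with an \code{assigned_name} column.
#' @export
assignNames <- function(calls, reference = NULL, orthologs = NULL,
                        loci = NULL, prefix = "Ap") {
  calls$assigned_name <- NA_character_
  refNames <- if (!is.null(reference))
    setNames(as.character(refInfo(reference)$name), refInfo(reference)$id)
  if (!is.null(orthologs) && length(orthologs) && !is.null(reference)) {
    for (q in names(orthologs)) {
      k <- match(q, calls$id)
      if (is.na(k) || calls$family[k] == "not-CP") next
      stem <- refNames[[orthologs[[q]]]]
      stem <- sub("^[A-Z][a-z]+", "", stem)   # strip reference species prefix
      calls$assigned_name[k] <- paste0(prefix, stem)
    }
  }
  ## annotation order for the remainder
  ord <- seq_len(nrow(calls))
  if (!is.null(loci)) {
    pos <- match(calls$id, loci$gene_id)
    chr <- as.character(GenomicRanges::seqnames(loci))[pos]
    st <- GenomicRanges::start(loci)[pos]
    ord <- order(is.na(pos), chr, st, seq_len(nrow(calls)))
  }
  for (fam in setdiff(unique(calls$family), "not-CP")) {
    idx <- ord[calls$family[ord] == fam & is.na(calls$assigned_name[ord])]
    taken <- calls$assigned_name[!is.na(calls$assigned_name)]
    k <- 0L
    for (i in idx) {
      repeat {
        k <- k + 1L
        cand <- paste0(prefix, fam, k)
        if (!cand %in% taken) break
      }
      calls$assigned_name[i] <- cand
    }
  }
  named <- calls$assigned_name[!is.na(calls$assigned_name)]
  if (anyDuplicated(named))
    stop("name collision: ", paste(unique(named[duplicated(named)]),
                                   collapse = ", "),
         " (duplicated ortholog assignment?)")
  calls
}
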