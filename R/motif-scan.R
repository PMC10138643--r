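## Motif scanning against protein sequences.
## Proteins are plain uppercase AA strings (possibly containing X); 'X' in a
## protein never satisfies a fixed or alternative motif position.

.seqChars <- function(protein) {
  if (is(protein, "AAString") || is(protein, "AAStringSet"))
    protein <- as.character(protein)
  stopifnot(is.character(protein), length(protein) == 1L)
  strsplit(toupper(protein), "")[[1]]
}

## Attempt to match `elements[ei..]` at chars[pos..]; returns list of
## list(end, mismatches) for every distinct way the tail can match within
## budget. Gap widths are enumerated, so one start can yield several ends.
.matchFrom <- function(chars, pos, elements, ei, mis, budget) {
  if (ei > length(elements)) return(list(list(end = pos - 1L, mismatches = mis)))
  el <- elements[[ei]]
  out <- list()
  if (el$type == "gap") {
    for (w in el$min:el$max) {
      if (pos + w - 1L > length(chars) && w > 0L) break
      out <- c(out, .matchFrom(chars, pos + w, elements, ei + 1L, mis, budget))
    }
  } else {
    if (pos > length(chars)) return(out)
    ok <- chars[pos] %in% el$residues && chars[pos] != "X"
    mis2 <- mis + !ok
    if (mis2 <= budget)
      out <- c(out, .matchFrom(chars, pos + 1L, elements, ei + 1L, mis2, budget))
  }
  out
}

#' Scan a protein for all matches of a motif
#'
#' Reports every window of the protein that the motif can match, allowing up
#' to \code{maxMismatches} substitutions at fixed/alternative positions (gap
#' and wildcard positions never count as mismatches). Degenerate gap widths
#' can produce several hits sharing a start; all distinct (start, end)
#' windows are reported, each with the fewest mismatches achievable there.
#' Overlapping hits are all kept, sorted by start then end.
#'
#' @param protein an amino-acid string (or \code{AAString}).
#' @param motif a \code{\linkS4class{MotifSpec}}.
#' @param maxMismatches override for the spec's mismatch budget.
#' @return data.frame with columns \code{start}, \code{end} (1-based, closed),
#'   \code{mismatches}, \code{matched}; zero rows when there is no hit.
#' @examples
#' scanMotif("CAAAAACAAAAAC", parseMotif("Cx(5)C", "repeat"))
#' @export
scanMotif <- function(protein, motif, maxMismatches = motif@maxMismatches) {
  stopifnot(is(motif, "MotifSpec"))
  chars <- .seqChars(protein)
  n <- length(chars)
  w <- motifWidth(motif)
  hits <- list()
  if (n >= w[1]) {
    for (s in seq_len(n - w[1] + 1L)) {
      res <- .matchFrom(chars, s, motif@elements, 1L, 0L, as.integer(maxMismatches))
      if (length(res) == 0L) next
      ends <- vapply(res, `[[`, integer(1), "end")
      miss <- vapply(res, `[[`, integer(1), "mismatches")
      for (e in unique(ends)) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = s, end = e, mismatches = min(miss[ends == e]),
          matched = paste(chars[s:e], collapse = ""))
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      mismatches = integer(), matched = character()))
  out <- do.call(rbind, hits)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Count non-overlapping motif matches, greedily left to right
#'
#' Takes the leftmost hit (shortest window on ties), then the next hit
#' beginning at or after that hit's final residue, and so on. Allowing the
#' next repeat to begin on the previous one's last residue matches the
#' convention for cysteine-anchored repeats, where tandem C-X5-C units share
#' their boundary cysteine. Deterministic; used for repeat counting such as
#' the CPH AAP[AVL] micro-repeat or the CPCFC C-X5-C repeat.
#'
#' @inheritParams scanMotif
#' @return non-negative integer.
#' @examples
#' countNonoverlapping("AAPAAAPVAAPL", parseMotif("AAP[AVL]", "repeat"))  # 3
#' @export
countNonoverlapping <- function(protein, motif, maxMismatches = motif@maxMismatches) {
  hits <- scanMotif(protein, motif, maxMismatches)
  count <- 0L
  nextFree <- 1L
  i <- 1L
  while (i <= nrow(hits)) {
    if (hits$start[i] >= nextFree) {
      count <- count + 1L
      nextFree <- hits$end[i]   # next repeat may share this boundary residue
    }
    i <- i + 1L
  }
  count
}

#' Count (possibly overlapping) dipeptide occurrences
#'
#' Plain substring counting with overlaps allowed: \code{"PPP"} contains two
#' \code{"PP"}. This is the convention behind reported PV/PY densities in
#' low-complexity proline-rich cuticular proteins.
#'
#' @param protein amino-acid string.
#' @param dipeptide exactly two residues, e.g. \code{"PV"}.
#' @return non-negative integer.
#' @export
countDipeptide <- function(protein, dipeptide) {
  stopifnot(nchar(dipeptide) == 2L)
  s <- paste(.seqChars(protein), collapse = "")
  m <- gregexpr(paste0("(?=", dipeptide, ")"), s, perl = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Residue composition of a protein
#'
#' Fractions over informative residues; \code{X} positions are excluded from
#' both numerator and denominator.
#'
#' @param protein amino-acid string.
#' @return named numeric vector of fractions summing to 1.
#' @export
residueComposition <- function(protein) {
  chars <- .seqChars(protein)
  chars <- chars[chars != "X"]
  if (length(chars) == 0L)
    stop("no informative residues (sequence is entirely X)")
  tab <- table(chars)
  out <- as.numeric(tab) / length(chars)
  names(out) <- names(tab)
  out
}

#' Best alignment score of a consensus motif against a protein
#'
#' Slides the consensus over the protein with all gaps held at their minimal
#' width and returns the maximal fraction of fixed/alternative positions that
#' match, together with the window achieving it (smallest start on ties).
#' This positional scoring stands in for a profile-HMM search: a protein
#' carrying the printed R&R consensus verbatim scores 1.
#'
#' @param protein amino-acid string.
#' @param motif consensus-kind \code{\linkS4class{MotifSpec}}.
#' @return list with \code{score} (fraction in [0,1]) and \code{start},
#'   \code{end} (NA when the protein is shorter than the motif).
#' @export
consensusScore <- function(protein, motif) {
  stopifnot(is(motif, "MotifSpec"))
  if (motif@kind != "consensus")
    stop("consensusScore requires a consensus-kind motif")
  chars <- .seqChars(protein)
  ## lay the motif out at minimal gap widths: offsets of informative positions
  offs <- integer(); resl <- list(); pos <- 0L
  for (el in motif@elements) {
    if (el$type == "gap") pos <- pos + el$min
    else { offs <- c(offs, pos); resl[[length(resl) + 1L]] <- el$residues; pos <- pos + 1L }
  }
  width <- pos
  nInf <- length(offs)
  if (nInf == 0L) stop("consensus motif has no informative positions")
  n <- length(chars)
  if (n < width)
    return(list(score = 0, start = NA_integer_, end = NA_integer_))
  best <- -1; bestS <- NA_integer_
  for (s in seq_len(n - width + 1L)) {
    m <- 0L
    for (k in seq_len(nInf)) {
      ch <- chars[s + offs[k]]
      if (ch != "X" && ch %in% resl[[k]]) m <- m + 1L
    }
    sc <- m / nInf
    if (sc > best) { best <- sc; bestS <- s }
  }
  list(score = best, start = bestS, end = bestS + width - 1L)
}
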