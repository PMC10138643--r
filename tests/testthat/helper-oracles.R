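## Independent oracles used across the suite.

## Motif -> anchored regular expression (zero-mismatch semantics). X never
## matches a fixed/alternative element; gap and wildcard positions match any
## residue including X.
motifRegex <- function(motif) {
  parts <- vapply(motif@elements, function(el) {
    switch(el$type,
      fixed = el$residues,                     # X != residue, so X can't match
      alt = paste0("[", paste(el$residues, collapse = ""), "]"),
      gap = sprintf(".{%d,%d}", el$min, el$max))
  }, character(1))
  paste0("^", paste(parts, collapse = ""), "$")
}

## every window of `seq` matched against the anchored regex
bruteWindows <- function(seq, motif) {
  rx <- motifRegex(motif)
  n <- nchar(seq)
  out <- NULL
  for (s in seq_len(n)) for (e in s:n) {
    if (grepl(rx, substr(seq, s, e)))
      out <- rbind(out, data.frame(start = s, end = e))
  }
  if (is.null(out)) data.frame(start = integer(), end = integer()) else out
}

## memoized three-state (M / gap-in-a / gap-in-b) affine alignment score,
## written top-down as an independent check of the package's aligner
bruteAffineScore <- function(a, b, submat, gapOpen, gapExt) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == 0 && j == 0) {
      if (state == "M") 0 else -Inf
    } else if (state == "M") {
      if (i == 0 || j == 0) -Inf
      else submat[A[i], B[j]] +
        max(rec(i - 1, j - 1, "M"), rec(i - 1, j - 1, "X"),
            rec(i - 1, j - 1, "Y"))
    } else if (state == "X") {         # gap in a, consumes B[j]
      if (j == 0) -Inf
      else max(rec(i, j - 1, "M") - gapOpen - gapExt,
               rec(i, j - 1, "X") - gapExt,
               rec(i, j - 1, "Y") - gapOpen - gapExt)
    } else {                           # gap in b, consumes A[i]
      if (i == 0) -Inf
      else max(rec(i - 1, j, "M") - gapOpen - gapExt,
               rec(i - 1, j, "X") - gapOpen - gapExt,
               rec(i - 1, j, "Y") - gapExt)
    }
    memo[[key]] <- val
    val
  }
  max(rec(n, m, "M"), rec(n, m, "X"), rec(n, m, "Y"))
}

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

randomSeq <- function(n, alphabet = c("A", "C", "G")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## write a small FASTA fixture
writeFastaLines <- function(headers, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}

writeGffLines <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}

## instantiate a consensus with every wildcard set to one residue
fillConsensus <- function(text, fill) gsub("x", fill, text)

RR1_TEXT <- "GxFxYxxPDGxxxxVxYxADENGYQPxGAHLP"
RR2_TEXT <- "EYDAxPxYxFxYxDxHTGDxKSQxExRDGDVVxGxYSLxExDGxxRTVxYTADxxNGFNAVVxxE"
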