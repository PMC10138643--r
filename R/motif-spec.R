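#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' MotifSpec: a parsed degenerate sequence pattern
#'
#' Cuticular-protein families are diagnosed by degenerate patterns written in
#' the field's informal notation: fixed residues, \code{x} wildcards,
#' alternative sets (\code{[AVL]} or \code{Y/F}) and bounded gaps
#' (\code{x(14-16)}, \code{X5}). A \code{MotifSpec} is the parsed form of one
#' such pattern together with its match semantics.
#'
#' @slot name motif name, e.g. \code{"RR-1"}.
#' @slot kind one of \code{"consensus"}, \code{"spacing"}, \code{"repeat"},
#'   \code{"dipeptide"}. Kinds share the same matcher; \code{consensus}
#'   motifs are additionally scored position-wise by
#'   \code{\link{consensusScore}}.
#' @slot elements list of parsed elements; each element is a list with
#'   \code{type} (\code{"fixed"}, \code{"alt"}, \code{"gap"}) and either
#'   \code{residues} (character vector) or \code{min}/\code{max} gap widths.
#'   A wildcard \code{x} is a gap of width 1.
#' @slot maxMismatches substitutions tolerated at fixed/alternative positions.
#' @slot source the pattern text the spec was parsed from.
#' @export
setClass("MotifSpec",
  representation(name = "character", kind = "character", elements = "list",
                 maxMismatches = "integer", source = "character"))

setValidity("MotifSpec", function(object) {
  msg <- NULL
  if (!object@kind %in% c("consensus", "spacing", "repeat", "dipeptide"))
    msg <- c(msg, sprintf("unknown motif kind '%s'", object@kind))
  if (length(object@elements) == 0L)
    msg <- c(msg, "element list is empty")
  if (object@maxMismatches < 0L)
    msg <- c(msg, "maxMismatches must be >= 0")
  for (el in object@elements) {
    if (el$type == "gap" && (el$min < 0L || el$min > el$max))
      msg <- c(msg, sprintf("bad gap bounds (%d,%d)", el$min, el$max))
  }
  if (is.null(msg)) TRUE else msg
})

#' Parse a motif pattern written in consensus notation
#'
#' Accepted notation (case matters for residues): uppercase letters are fixed
#' residues; \code{x} (or a bare \code{X} followed by nothing numeric) is a
#' single-position wildcard; \code{x(5)}, \code{X5}, \code{X_5_} are exact
#' gaps; \code{x(14-16)}, \code{X_4-5_} are bounded gaps; \code{[AVL]} is an
#' alternative set; \code{A/B} makes the two flanking letters alternatives;
#' \code{-} outside parentheses is an ignorable separator.
#'
#' @param text pattern string, e.g. \code{"Cx(14-16)Cx(5)Cx(9-13)Cx(12)Cx(7-8)C"}.
#' @param kind motif kind (see \code{\linkS4class{MotifSpec}}).
#' @param name motif name; defaults to the pattern text.
#' @param maxMismatches substitutions tolerated at fixed/alternative positions
#'   when scanning (gaps and wildcards never count).
#' @return a \code{\linkS4class{MotifSpec}}.
#' @examples
#' m <- parseMotif("C-X5-C", "spacing")
#' motifWidth(m)  # c(7, 7)
#' @export
parseMotif <- function(text, kind = c("consensus", "spacing", "repeat", "dipeptide"),
                       name = text, maxMismatches = 0L) {
  kind <- match.arg(kind)
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  chars <- strsplit(text, "")[[1]]
  els <- list()
  i <- 1L
  n <- length(chars)
  push <- function(el) els[[length(els) + 1L]] <<- el

  readNumber <- function(j) {
    k <- j
    while (k <= n && grepl("[0-9]", chars[k])) k <- k + 1L
    if (k == j) stop("expected a number at position ", j, " of '", text, "'")
    list(value = as.integer(paste(chars[j:(k - 1L)], collapse = "")), nxt = k)
  }
  # reads "5", "14-16" after an opener; `close` is the closing char
  readRange <- function(j, close) {
    a <- readNumber(j); j <- a$nxt
    if (j <= n && chars[j] == "-") {
      b <- readNumber(j + 1L); j <- b$nxt
      rng <- c(a$value, b$value)
    } else rng <- c(a$value, a$value)
    if (j > n || chars[j] != close)
      stop("unterminated gap range in '", text, "'")
    if (rng[1] > rng[2])
      stop("malformed gap range ", rng[1], "-", rng[2], " in '", text, "'")
    list(min = rng[1], max = rng[2], nxt = j + 1L)
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "-" || ch == " ") { i <- i + 1L; next }
    if (ch == "[") {
      j <- i + 1L; set <- character()
      while (j <= n && chars[j] != "]") {
        if (!grepl("[A-WYZ]", chars[j]))
          stop("bad residue '", chars[j], "' in alternative set of '", text, "'")
        set <- c(set, chars[j]); j <- j + 1L
      }
      if (j > n) stop("unterminated [ ] in '", text, "'")
      if (length(set) == 0L) stop("empty alternative set in '", text, "'")
      push(list(type = "alt", residues = set))
      i <- j + 1L
      next
    }
    if (ch == "x" || ch == "X") {
      # gap: x, x(5), x(14-16), X5, X_5_, X_4-5_
      if (i < n && chars[i + 1L] == "(") {
        r <- readRange(i + 2L, ")")
        push(list(type = "gap", min = r$min, max = r$max)); i <- r$nxt
      } else if (i < n && chars[i + 1L] == "_") {
        r <- readRange(i + 2L, "_")
        push(list(type = "gap", min = r$min, max = r$max)); i <- r$nxt
      } else if (i < n && grepl("[0-9]", chars[i + 1L])) {
        a <- readNumber(i + 1L); j <- a$nxt
        if (j <= n && chars[j] == "-" && j < n && grepl("[0-9]", chars[j + 1L])) {
          b <- readNumber(j + 1L)
          if (a$value > b$value)
            stop("malformed gap range ", a$value, "-", b$value, " in '", text, "'")
          push(list(type = "gap", min = a$value, max = b$value)); i <- b$nxt
        } else {
          push(list(type = "gap", min = a$value, max = a$value)); i <- j
        }
      } else {
        push(list(type = "gap", min = 1L, max = 1L)); i <- i + 1L
      }
      next
    }
    if (grepl("[A-WYZ]", ch)) {
      if (i + 1L <= n && chars[i + 1L] == "/") {
        if (i + 2L > n || !grepl("[A-WYZ]", chars[i + 2L]))
          stop("dangling '/' in '", text, "'")
        push(list(type = "alt", residues = c(ch, chars[i + 2L])))
        i <- i + 3L
      } else {
        push(list(type = "fixed", residues = ch))
        i <- i + 1L
      }
      next
    }
    stop("unknown character '", ch, "' in motif '", text, "'")
  }
  new("MotifSpec", name = name, kind = kind, elements = els,
      maxMismatches = as.integer(maxMismatches), source = text)
}

#' Minimal and maximal match width of a motif
#' @param motif a \code{\linkS4class{MotifSpec}}.
#' @return integer vector \code{c(min, max)}.
#' @export
motifWidth <- function(motif) {
  stopifnot(is(motif, "MotifSpec"))
  lo <- hi <- 0L
  for (el in motif@elements) {
    if (el$type == "gap") { lo <- lo + el$min; hi <- hi + el$max }
    else { lo <- lo + 1L; hi <- hi + 1L }
  }
  c(min = lo, max = hi)
}

#' Render a motif back to pattern text
#'
#' Produces canonical text (\code{x}, \code{x(a-b)}, \code{[..]}) that
#' re-parses to an equivalent element list.
#' @param motif a \code{\linkS4class{MotifSpec}}.
#' @return character scalar.
#' @export
motifText <- function(motif) {
  stopifnot(is(motif, "MotifSpec"))
  paste(vapply(motif@elements, function(el) {
    switch(el$type,
      fixed = el$residues,
      alt = paste0("[", paste(el$residues, collapse = ""), "]"),
      gap = if (el$min == 1L && el$max == 1L) "x"
            else if (el$min == el$max) sprintf("x(%d)", el$min)
            else sprintf("x(%d-%d)", el$min, el$max))
  }, character(1)), collapse = "")
}

setMethod("show", "MotifSpec", function(object) {
  w <- motifWidth(object)
  cat(sprintf("MotifSpec '%s' (%s): %s [width %d-%d, maxMismatches %d]\n",
              object@name, object@kind, motifText(object), w[1], w[2],
              object@maxMismatches))
})

#' Default cuticular-protein family motifs
#'
#' The field's published diagnostic patterns: the extended R&R consensus
#' sequences discriminating the RR-1 and RR-2 subfamilies of CPR, the ChtBD2
#' cysteine-spacing patterns separating CPAP1 (one domain) from CPAP3 (three
#' domains), the four Tweedle blocks, the CPCFC C-X5-C repeat, the CPG
#' glycine repeat and the CPH AAP[AVL] micro-repeat.
#'
#' @return named list of \code{\linkS4class{MotifSpec}} objects.
#' @export
defaultMotifs <- function() {
  list(
    rr1 = parseMotif("GxFxYxxPDGxxxxVxYxADENGYQPxGAHLP", "consensus", name = "RR-1"),
    rr2 = parseMotif(
      "EYDAxPxYxFxYxDxHTGDxKSQxExRDGDVVxGxYSLxExDGxxRTVxYTADxxNGFNAVVxxE",
      "consensus", name = "RR-2"),
    cpap1 = parseMotif("Cx(14-16)Cx(5)Cx(9-13)Cx(12)Cx(7-8)C", "spacing",
                       name = "CPAP1-ChtBD2"),
    cpap3 = parseMotif("Cx(13-24)Cx(5)Cx(9-10)Cx(12-16)Cx(7-8)C", "spacing",
                       name = "CPAP3-ChtBD2"),
    tweedle1 = parseMotif("Kxx[YF]", "consensus", name = "Tweedle-I"),
    tweedle2 = parseMotif("Kx(4-5)FIKAP", "consensus", name = "Tweedle-II"),
    tweedle3 = parseMotif("TxxYVL", "consensus", name = "Tweedle-III"),
    tweedle4 = parseMotif("KPEVYxFV/IKY", "consensus", name = "Tweedle-IV"),
    cpcfc = parseMotif("Cx(5)C", "repeat", name = "C-X5-C"),
    cpg = parseMotif("GGxGG", "repeat", name = "GGxGG"),
    cph = parseMotif("AAP[AVL]", "repeat", name = "AAP[AVL]")
  )
}
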