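#' @importFrom Biostrings pairwiseAlignment alignedPattern alignedSubject
#' @importFrom Biostrings AAString
#' @importFrom Rcpp evalCpp
#' @useDynLib cuticleR, .registration = TRUE
NULL

## 26x26 substitution matrix indexed by A..Z, built once per scheme name
.schemeMatrixCache <- new.env(parent = emptyenv())
.schemeMatrix <- function(scheme) {
  if (is.matrix(scheme$matrix)) {
    src <- scheme$matrix
    key <- NULL
  } else {
    key <- scheme$matrix
    if (!is.null(.schemeMatrixCache[[key]])) return(.schemeMatrixCache[[key]])
    env <- new.env()
    utils::data(list = key, package = "Biostrings", envir = env)
    src <- env[[key]]
  }
  full <- matrix(0, 26, 26, dimnames = list(LETTERS, LETTERS))
  rows <- intersect(rownames(src), LETTERS)
  full[rows, intersect(colnames(src), LETTERS)] <-
    src[rows, intersect(colnames(src), LETTERS)]
  if (!is.null(key)) .schemeMatrixCache[[key]] <- full
  full
}

#' Default pairwise alignment scoring scheme
#'
#' Needleman-Wunsch global alignment with a BLOSUM62 substitution matrix and
#' affine gap penalties (open 10, extend 1), the conventions of a default
#' protein BLAST search.
#'
#' @return list with \code{matrix}, \code{gapOpening}, \code{gapExtension}.
#' @export
defaultScheme <- function() {
  list(matrix = "BLOSUM62", gapOpening = 10, gapExtension = 1)
}

#' Global alignment identity between two proteins
#'
#' Aligns the two sequences globally (Needleman-Wunsch, affine gaps) and
#' computes identity as matches / aligned columns, where columns inside
#' terminal gap runs of either sequence are excluded from both numerator and
#' denominator. Terminal-gap exclusion keeps identities between full-length
#' proteins of unequal length comparable.
#'
#' Traceback ties are broken deterministically (aligned pair over gap in
#' \code{a} over gap in \code{b}).
#'
#' @param a,b amino-acid strings or \code{AAString}s.
#' @param scheme scoring scheme, see \code{\link{defaultScheme}}.
#' @return list with \code{identity} (fraction in [0,1]), \code{score}
#'   (alignment score), \code{columns} (aligned columns counted) and the
#'   gapped \code{alignedA}/\code{alignedB} strings.
#' @examples
#' globalIdentity("MKV", "MKV")$identity  # 1
#' @export
globalIdentity <- function(a, b, scheme = defaultScheme()) {
  res <- .nwAlignC(as.character(a), as.character(b),
                   .schemeMatrix(scheme), scheme$gapOpening,
                   scheme$gapExtension)
  res[c("identity", "score", "columns", "alignedA", "alignedB")]
}

## one query against many subjects
.identityBatch <- function(query, subjects, scheme = defaultScheme()) {
  stopifnot(nzchar(query), all(nzchar(subjects)))
  sm <- .schemeMatrix(scheme)
  res <- lapply(subjects, function(s)
    .nwAlignC(query, s, sm, scheme$gapOpening, scheme$gapExtension))
  data.frame(identity = vapply(res, `[[`, numeric(1), "identity"),
             score = vapply(res, `[[`, numeric(1), "score"),
             columns = vapply(res, `[[`, integer(1), "columns"))
}

#' All-vs-all identity matrix between two protein sets
#'
#' @param queries,references named \code{AAStringSet}s (or named character
#'   vectors).
#' @param scheme scoring scheme.
#' @return numeric matrix, rows = queries, columns = references.
#' @export
identityMatrix <- function(queries, references, scheme = defaultScheme()) {
  qn <- names(queries); rn <- names(references)
  q <- as.character(queries); r <- as.character(references)
  out <- matrix(0, nrow = length(q), ncol = length(r),
                dimnames = list(qn, rn))
  for (i in seq_along(q))
    out[i, ] <- .identityBatch(q[[i]], r, scheme)$identity
  out
}

#' Reciprocal-best-hit orthology between a proteome and a reference set
#'
#' A query/reference pair is a 1:1 ortholog when each is the other's unique
#' best hit and their identity reaches \code{minIdentity}. Best-hit edges
#' that fail the reciprocity test are grouped into connected components of
#' the best-hit graph and reported as co-ortholog groups, the many-to-many
#' relationships typical of recently expanded tandem families.
#'
#' @param queries,references named \code{AAStringSet}s.
#' @param scheme scoring scheme.
#' @param minIdentity identity floor for any reported relation.
#' @return data.frame with columns \code{query}, \code{reference},
#'   \code{identity}, \code{relation} (\code{"1:1"} or
#'   \code{"co-ortholog-group k"}); one row per retained best-hit edge.
#' @export
reciprocalBestHits <- function(queries, references, scheme = defaultScheme(),
                               minIdentity = 0.3) {
  empty <- data.frame(query = character(), reference = character(),
                      identity = numeric(), relation = character())
  if (length(queries) == 0L || length(references) == 0L) return(empty)
  idm <- identityMatrix(queries, references, scheme)
  qn <- sort(rownames(idm)); rn <- sort(colnames(idm))
  idm <- idm[qn, rn, drop = FALSE]   # input-order invariance
  ## best hits (all ties kept), identity floor applied up front
  edges <- NULL
  for (q in qn) {
    v <- idm[q, ]
    if (max(v) < minIdentity) next
    for (r in rn[v == max(v)])
      edges <- rbind(edges, data.frame(query = q, reference = r,
                                       identity = v[[r]]))
  }
  for (r in rn) {
    v <- idm[, r]
    if (max(v) < minIdentity) next
    for (q in qn[v == max(v)])
      edges <- rbind(edges, data.frame(query = q, reference = r,
                                       identity = idm[q, r]))
  }
  if (is.null(edges)) return(empty)
  edges <- unique(edges)
  ## 1:1: unique mutual best
  qBest <- lapply(qn, function(q) rn[idm[q, ] == max(idm[q, ])])
  names(qBest) <- qn
  rBest <- lapply(rn, function(r) qn[idm[, r] == max(idm[, r])])
  names(rBest) <- rn
  one2one <- vapply(seq_len(nrow(edges)), function(i) {
    q <- edges$query[i]; r <- edges$reference[i]
    identical(qBest[[q]], r) && identical(rBest[[r]], q)
  }, logical(1))
  edges$relation <- NA_character_
  edges$relation[one2one] <- "1:1"
  ## remaining edges: connected components of the best-hit graph
  rest <- edges[!one2one, , drop = FALSE]
  if (nrow(rest)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = paste0("q|", rest$query),
                 to = paste0("r|", rest$reference)), directed = FALSE)
    comp <- igraph::components(g)$membership
    ## stable numbering: components ordered by smallest member name
    key <- vapply(split(names(comp), comp), function(v) min(v), character(1))
    renum <- match(names(sort(key)), names(key))
    lab <- setNames(match(seq_along(key), renum), names(key))
    edges$relation[!one2one] <- sprintf("co-ortholog-group %d",
                                        lab[as.character(comp[paste0("q|", rest$query)])])
  }
  rownames(edges) <- NULL
  edges
}

#' Extract the 1:1 ortholog pairs from an RBH table
#' @param rbh output of \code{\link{reciprocalBestHits}}.
#' @return named character vector: query id -> reference id.
#' @export
orthologPairs <- function(rbh) {
  p <- rbh[rbh$relation == "1:1", , drop = FALSE]
  setNames(p$reference, p$query)
}
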