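#' @importFrom stats setNames as.dist
NULL

.msaMatrix <- function(msa) {
  if (is.matrix(msa)) {
    m <- toupper(msa)
  } else {
    if (is(msa, "AAStringSet") || is(msa, "AAMultipleAlignment"))
      msa <- as.character(msa)
    stopifnot(is.character(msa))
    w <- nchar(msa)
    if (length(unique(w)) != 1L)
      stop("alignment rows have unequal length")
    m <- do.call(rbind, strsplit(toupper(msa), ""))
    rownames(m) <- names(msa)
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("alignment rows must carry unique ids")
  m
}

#' Poisson-corrected pairwise-deletion distance matrix
#'
#' For each sequence pair, only alignment columns where both rows are
#' ungapped (and not \code{X}) are used (pairwise deletion). With p the
#' proportion of differing residues over those columns, the multiple-hit
#' corrected distance is d = -ln(1 - p). Pairs with p = 1 get an infinite
#' distance and a warning; a pair with no shared column is an error.
#'
#' @param msa aligned sequences: named character vector, \code{AAStringSet}
#'   of equal widths, or character matrix. Gap character \code{"-"}.
#' @return symmetric numeric matrix with zero diagonal.
#' @examples
#' poissonDist(c(a = "AC-G", b = "AT-G"))["a", "b"]  # -log(2/3)
#' @export
poissonDist <- function(msa) {
  m <- .msaMatrix(msa)
  n <- nrow(m)
  ids <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  inf <- m != "-" & m != "X"
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    shared <- inf[i, ] & inf[j, ]
    if (!any(shared))
      stop("no shared ungapped columns for pair ", ids[i], " / ", ids[j])
    p <- mean(m[i, shared] != m[j, shared])
    dij <- if (p >= 1) {
      warning("saturated pair ", ids[i], " / ", ids[j],
              " (all shared columns differ); distance is infinite")
      Inf
    } else -log(1 - p)
    d[i, j] <- d[j, i] <- dij
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration; negative branch-length estimates are
#' clamped to zero (with a message), the convention most tree viewers apply.
#'
#' @param dm symmetric distance matrix with ids as dimnames.
#' @return an unrooted \code{ape::phylo} tree.
#' @export
njTree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) >= 3L)
  if (any(!is.finite(dm)))
    stop("distance matrix contains non-finite entries; ",
         "exclude saturated pairs before tree building")
  tr <- ape::nj(as.dist(dm))
  if (any(tr$edge.length < 0)) {
    message(sum(tr$edge.length < 0),
            " negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Poisson-distance NJ tree per replicate, and reports for each internal
#' edge of the full-data tree the percentage of replicates containing the
#' same bipartition. Deterministic for a fixed seed. An alignment whose
#' sequences are all identical yields no resolvable bipartition; the tree is
#' returned with a warning and zero supports.
#'
#' @param msa alignment as in \code{\link{poissonDist}}.
#' @param replicates bootstrap replicates (the field convention is 1000).
#' @param seed RNG seed.
#' @return \code{phylo} tree with \code{node.label} holding integer percent
#'   supports on internal nodes.
#' @export
bootstrapTree <- function(msa, replicates = 1000L, seed = 1L) {
  m <- .msaMatrix(msa)
  stopifnot(replicates >= 1L)
  dm <- poissonDist(m)
  if (all(dm[upper.tri(dm)] == 0))
    warning("all pairwise distances are zero; tree is unresolved")
  tr <- njTree(dm)
  set.seed(seed)
  bp <- ape::boot.phylo(tr, m,
                        FUN = function(x) suppressMessages(njTree(poissonDist(x))),
                        B = replicates, rooted = FALSE, quiet = TRUE,
                        trees = FALSE)
  support <- round(100 * bp / replicates)
  ## boot.phylo returns one value per internal node, first = root (NA-like)
  tr$node.label <- as.character(support)
  tr$node.label[1] <- ""   # root of the unrooted representation
  tr
}

#' Bootstrap support for a given bipartition
#'
#' Convenience accessor: the support attached to the smallest clade
#' containing exactly \code{tips}.
#'
#' @param tree output of \code{\link{bootstrapTree}}.
#' @param tips character vector of tip labels forming one side of the
#'   bipartition.
#' @return numeric percent support, or NA when the bipartition is absent.
#' @export
bipartitionSupport <- function(tree, tips) {
  one <- function(tt) {
    if (length(tt) < 2L) return(NA_real_)
    node <- tryCatch(ape::getMRCA(tree, tt), error = function(e) NULL)
    if (is.null(node)) return(NA_real_)
    desc <- ape::extract.clade(tree, node)$tip.label
    if (!setequal(desc, tt)) return(NA_real_)
    lab <- tree$node.label[node - ape::Ntip(tree)]
    if (is.null(lab) || !nzchar(lab)) NA_real_ else as.numeric(lab)
  }
  s <- one(tips)
  if (!is.na(s)) return(s)
  one(setdiff(tree$tip.label, tips))   # same split seen from the other side
}

#' Extract the extended consensus region from CPR proteins
#'
#' For subfamily phylogenies the comparable region is the window where the
#' R&R consensus aligns best, widened by a flank on each side. All windows
#' share the consensus's minimal-gap width, so the extracted regions are
#' columnwise comparable without re-alignment; positions falling outside the
#' protein are padded with gaps.
#'
#' @param proteome named \code{AAStringSet} or character vector.
#' @param motif consensus-kind \code{\linkS4class{MotifSpec}} (RR-1 or RR-2).
#' @param flank residues to include on each side (default 10).
#' @return named character vector of equal-width sequences (an MSA).
#' @export
consensusRegion <- function(proteome, motif, flank = 10L) {
  seqs <- as.character(proteome)
  out <- vapply(seqs, function(s) {
    hit <- consensusScore(s, motif)
    if (is.na(hit$start)) return(NA_character_)
    lo <- hit$start - flank; hi <- hit$end + flank
    chars <- strsplit(s, "")[[1]]
    idx <- lo:hi
    piece <- ifelse(idx >= 1L & idx <= length(chars), chars[pmax(idx, 1L)], "-")
    paste(piece, collapse = "")
  }, character(1))
  if (anyNA(out))
    stop("protein(s) shorter than the consensus: ",
         paste(names(seqs)[is.na(out)], collapse = ", "))
  setNames(out, names(seqs))
}

#' Write a tree to a Newick file
#' @param tree a \code{phylo} tree.
#' @param path output file; when NULL the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
writeNewickTree <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"), ape::Ntip(tree) >= 2L)
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}

#' Sequence-logo matrix: per-column frequencies and information content
#'
#' Per alignment column, residue frequencies over non-gap residues and the
#' information content R = log2(20) - H bits, H the Shannon entropy of the
#' column. No small-sample correction is applied unless \code{correct}.
#' All-gap columns get NA.
#'
#' @param msa alignment as in \code{\link{poissonDist}} (>= 2 rows).
#' @param correct apply the small-sample correction
#'   (e - 1)/(2 ln 2 n) subtracted from R, floored at 0.
#' @return list with \code{frequencies} (20 x L matrix) and
#'   \code{information} (length-L numeric, bits).
#' @export
logoMatrix <- function(msa, correct = FALSE) {
  m <- .msaMatrix(msa)
  if (nrow(m) < 2L) stop("need >= 2 aligned sequences")
  aa <- setdiff(.AA_ALPHABET, "X")
  L <- ncol(m)
  freq <- matrix(0, nrow = length(aa), ncol = L, dimnames = list(aa, NULL))
  info <- numeric(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    col <- col[col != "-" & col != "X"]
    if (length(col) == 0L) { info[j] <- NA_real_; freq[, j] <- NA_real_; next }
    f <- table(factor(col, levels = aa)) / length(col)
    freq[, j] <- as.numeric(f)
    nz <- f[f > 0]
    H <- -sum(nz * log2(nz))
    R <- log2(20) - H
    if (correct)
      R <- max(0, R - (length(aa) - 1) / (2 * log(2) * length(col)))
    info[j] <- R
  }
  list(frequencies = freq, information = info)
}
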