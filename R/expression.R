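#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom stats hclust dist
NULL

.BIN_LEVELS <- c("none_or_extremely_low", "very_low", "low", "moderate",
                 "high", "very_high")
.BIN_BREAKS <- c(0, 1, 10, 100, 1000, 10000, Inf)

#' CpExperiment: a gene-by-tissue FPKM container
#'
#' A thin \code{SummarizedExperiment} subclass holding one \code{fpkm}
#' assay; validity requires non-negative finite values.
#'
#' @export
setClass("CpExperiment", contains = "SummarizedExperiment")

setValidity("CpExperiment", function(object) {
  if (!"fpkm" %in% assayNames(object)) return("needs an 'fpkm' assay")
  v <- assay(object, "fpkm")
  if (any(!is.finite(v)) || any(v < 0)) return("FPKM values must be finite and >= 0")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    return("gene ids (rownames) must be present and unique")
  TRUE
})

#' Construct a CpExperiment from an FPKM matrix
#' @param fpkm numeric matrix, genes x tissues, dimnames set.
#' @return a \code{\linkS4class{CpExperiment}}.
#' @export
CpExperiment <- function(fpkm) {
  new("CpExperiment",
      SummarizedExperiment(assays = list(fpkm = as.matrix(fpkm))))
}

#' Read a gene-by-tissue FPKM table from TSV
#'
#' First column = gene id, remaining columns = tissues; header required.
#' @param path TSV file.
#' @return a \code{\linkS4class{CpExperiment}}.
#' @export
readExpression <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (any(is.na(suppressWarnings(m <- apply(m, 2, as.numeric)))))
    stop("non-numeric FPKM values in ", path)
  rownames(m) <- tab[[1]]
  CpExperiment(m)
}

#' Extract the FPKM matrix
#' @param x a \code{\linkS4class{CpExperiment}} or plain matrix.
#' @return numeric matrix.
#' @export
fpkm <- function(x) {
  if (is(x, "CpExperiment")) assay(x, "fpkm") else as.matrix(x)
}

#' Bin FPKM values into the six expression categories
#'
#' The bins partition [0, Inf): [0,1) none or extremely low, [1,10) very
#' low, [10,100) low, [100,1000) moderate, [1000,10000) high, and
#' >= 10000 very high. Intervals are left-closed (a value of exactly 10 is
#' "low", exactly 1000 is "high").
#'
#' @param value numeric vector of FPKM values (>= 0).
#' @return factor with the ordered bin levels.
#' @examples
#' binFpkm(c(0, 143.57, 10886))
#' @export
binFpkm <- function(value) {
  if (any(value < 0)) stop("negative FPKM value")
  cut(value, breaks = .BIN_BREAKS, labels = .BIN_LEVELS,
      right = FALSE, include.lowest = TRUE)
}

#' Expression-bin vocabulary
#' @return character vector of the six ordered bin labels.
#' @export
expressionBins <- function() .BIN_LEVELS

#' Is a gene expressed at this FPKM?
#'
#' A gene counts as expressed when its FPKM reaches the threshold; the
#' default of 1 treats the lowest bin ("no or extremely low expression")
#' as not expressed.
#'
#' @param value numeric FPKM vector (>= 0).
#' @param threshold FPKM cutoff (default 1).
#' @return logical vector.
#' @export
expressedCall <- function(value, threshold = 1) {
  if (any(value < 0)) stop("negative FPKM value")
  value >= threshold
}

#' Round half away from zero to a fixed number of decimals
#' @param x numeric.
#' @param digits decimals.
#' @return numeric.
#' @export
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.famStrata <- function() c("RR-1", "RR-2", "RR-3", "RR-NC",
                           "CPAP1", "CPAP3", "CPCFC", "CPLCP", "CPLCA",
                           "CPF", "CPFL", "CPT", "CPG", "CPH", "18aa")

.stratumOf <- function(calls) {
  ifelse(calls$family == "CPR", calls$subfamily, calls$family)
}

#' Family-by-tissue expressed-gene count table
#'
#' Rows are family strata (CPR split into its subfamilies), columns are the
#' genome count followed by one column per tissue holding the number of
#' family members with an expressed call in that tissue. A totals row is
#' appended, and a companion percent table gives each cell as a percentage
#' of the stratum's genome count (1 decimal, half away from zero).
#'
#' @param x \code{\linkS4class{CpExperiment}} or FPKM matrix. Genes absent
#'   from the matrix (annotated but not quantified) count as not expressed.
#' @param calls classifier output covering at least every gene in \code{x};
#'   a quantified gene without a call is an error.
#' @param threshold expressed-call FPKM cutoff.
#' @return list of class \code{cpFamilyTable}: \code{counts} and
#'   \code{percent} data.frames and the \code{threshold} used.
#' @export
familyTissueTable <- function(x, calls, threshold = 1) {
  m <- fpkm(x)
  missing <- setdiff(rownames(m), calls$id)
  if (length(missing))
    stop("gene(s) in the expression matrix without a family call: ",
         paste(missing, collapse = ", "))
  cp <- calls[calls$family != "not-CP", , drop = FALSE]
  strat <- .stratumOf(cp)
  strata <- .famStrata()
  tissues <- colnames(m)
  counts <- matrix(0L, nrow = length(strata), ncol = 1L + length(tissues),
                   dimnames = list(strata, c("Genome", tissues)))
  counts[, "Genome"] <- vapply(strata, function(s) sum(strat == s, na.rm = TRUE),
                               integer(1))
  for (tis in tissues) {
    expr <- rownames(m)[expressedCall(m[, tis], threshold)]
    counts[, tis] <- vapply(strata, function(s)
      sum(strat == s & cp$id %in% expr, na.rm = TRUE), integer(1))
  }
  counts <- rbind(counts, Total = colSums(counts))
  pct <- 100 * sweep(counts, 1, counts[, "Genome"], "/")
  pct[counts[, "Genome"] == 0, ] <- NA
  pct <- roundHalfUp(pct, 1)
  structure(list(counts = as.data.frame(counts),
                 percent = as.data.frame(pct),
                 threshold = threshold),
            class = "cpFamilyTable")
}

#' @export
print.cpFamilyTable <- function(x, ...) {
  cat("Family-by-tissue expressed-gene counts (expressed: FPKM >=",
      x$threshold, ")\n")
  print(x$counts)
  cat("\nPercent of genome count:\n")
  print(x$percent)
  invisible(x)
}

#' Number of family members not expressed in a tissue
#'
#' Genome count minus expressed count for one stratum, e.g. the RR-2 genes
#' silent in the larval epidermis.
#'
#' @param x \code{\linkS4class{CpExperiment}} or FPKM matrix.
#' @param calls classifier output.
#' @param family family label; use subfamily for CPR strata.
#' @param tissue tissue (column) name.
#' @param subfamily CPR subfamily, if family = "CPR".
#' @param threshold expressed-call FPKM cutoff.
#' @return integer.
#' @export
notExpressedCount <- function(x, calls, family, tissue, subfamily = NULL,
                              threshold = 1) {
  tab <- familyTissueTable(x, calls, threshold)$counts
  stratum <- if (family == "CPR") {
    if (is.null(subfamily)) stop("CPR requires a subfamily")
    subfamily
  } else family
  if (!stratum %in% rownames(tab)) stop("unknown family stratum ", stratum)
  if (!tissue %in% colnames(tab)) stop("unknown tissue ", tissue)
  as.integer(tab[stratum, "Genome"] - tab[stratum, tissue])
}

#' Log10 heat-map matrix with deterministic row ordering
#'
#' Cells are log10(FPKM + pseudocount); the transform is strictly monotone
#' so ordering between any two cells is preserved. Rows are ordered by
#' average-linkage hierarchical clustering of the transformed profiles
#' (Euclidean distance) or left in genomic/input order.
#'
#' @param x \code{\linkS4class{CpExperiment}} or FPKM matrix.
#' @param pseudocount added before log10 (default 1, so FPKM 0 maps to 0).
#' @param cluster cluster rows (TRUE) or keep input order.
#' @return list with \code{matrix} (transformed, rows reordered),
#'   \code{rowOrder} and \code{colOrder} index vectors.
#' @export
heatmapMatrix <- function(x, pseudocount = 1, cluster = TRUE) {
  m <- fpkm(x)
  if (any(m < 0)) stop("negative FPKM value")
  tm <- log10(m + pseudocount)
  rowOrder <- seq_len(nrow(tm))
  if (cluster && nrow(tm) > 2L)
    rowOrder <- hclust(dist(tm), method = "average")$order
  list(matrix = tm[rowOrder, , drop = FALSE], rowOrder = rowOrder,
       colOrder = seq_len(ncol(tm)))
}

#' Per-gene dominant tissue and specificity flag
#'
#' For each gene: the tissue with maximal FPKM, the dominance ratio
#' (max / total), and a tissue-specific flag when the ratio reaches the
#' threshold. All-zero genes are flagged silent with no dominant tissue.
#'
#' @param x \code{\linkS4class{CpExperiment}} or FPKM matrix (>= 2 tissues).
#' @param dominance ratio threshold (default 0.8).
#' @return data.frame: \code{gene}, \code{dominant_tissue}, \code{ratio},
#'   \code{specific}, \code{silent}.
#' @export
tissueSpecificity <- function(x, dominance = 0.8) {
  m <- fpkm(x)
  if (ncol(m) < 2L) stop("need >= 2 tissues")
  tot <- rowSums(m)
  silent <- tot == 0
  dom <- colnames(m)[max.col(m, ties.method = "first")]
  ratio <- ifelse(silent, NA_real_, apply(m, 1, max) / tot)
  data.frame(gene = rownames(m),
             dominant_tissue = ifelse(silent, NA_character_, dom),
             ratio = ratio,
             specific = !silent & ratio >= dominance,
             silent = silent,
             row.names = NULL, stringsAsFactors = FALSE)
}
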