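#' Detect tandem arrays of same-family cuticular-protein genes
#'
#' Cuticular-protein families expand by tandem duplication, leaving runs of
#' same-family genes on one chromosome. Within each chromosome, genes of one
#' family stratum (family, plus subfamily for CPR: RR-1 and RR-2 genes never
#' share an array) are chained into an array when consecutive members are at
#' most \code{maxGapKb} apart (start-to-start) and separated by at most
#' \code{maxIntervening} non-stratum genes. Singletons are dropped.
#'
#' @param calls classifier output (\code{\link{classifyProteome}}).
#' @param loci \code{GRanges} with a \code{gene_id} column covering every
#'   called id.
#' @param maxGapKb maximal start-to-start gap within an array, kb.
#' @param maxIntervening maximal number of intervening non-stratum genes.
#' @return data.frame with one row per array: \code{array_id},
#'   \code{chromosome}, \code{family}, \code{subfamily}, \code{size},
#'   \code{span_start}, \code{span_end}, \code{members}
#'   (comma-separated gene ids in start order).
#' @export
buildArrays <- function(calls, loci, maxGapKb = 100, maxIntervening = 1L) {
  cp <- calls[calls$family != "not-CP", , drop = FALSE]
  pos <- match(cp$id, loci$gene_id)
  if (anyNA(pos))
    stop("call id(s) without a locus: ",
         paste(cp$id[is.na(pos)], collapse = ", "))
  df <- data.frame(
    id = loci$gene_id,
    chromosome = as.character(GenomicRanges::seqnames(loci)),
    start = GenomicRanges::start(loci),
    end = GenomicRanges::end(loci),
    stringsAsFactors = FALSE)
  k <- match(df$id, cp$id)
  df$family <- cp$family[k]
  df$subfamily <- cp$subfamily[k]
  df <- df[order(df$chromosome, df$start, df$id), , drop = FALSE]
  df$stratum <- ifelse(is.na(df$family), NA_character_,
                       paste(df$family, ifelse(is.na(df$subfamily), "",
                                               df$subfamily)))
  arrays <- list()
  for (chr in unique(df$chromosome)) {
    sub <- df[df$chromosome == chr, , drop = FALSE]
    for (st in unique(sub$stratum[!is.na(sub$stratum)])) {
      idx <- which(sub$stratum == st)   # positions within chromosome order
      if (length(idx) < 2L) next
      chain <- list(idx[1])
      for (t in idx[-1]) {
        prev <- chain[[length(chain)]]
        p <- prev[length(prev)]
        gapKb <- (sub$start[t] - sub$start[p]) / 1000
        interv <- t - p - 1L   # consecutive stratum members: all between are non-stratum
        if (gapKb <= maxGapKb && interv <= maxIntervening)
          chain[[length(chain)]] <- c(prev, t)
        else chain[[length(chain) + 1L]] <- t
      }
      for (grp in chain) {
        if (length(grp) < 2L) next
        fam <- sub$family[grp[1]]
        arrays[[length(arrays) + 1L]] <- data.frame(
          chromosome = chr, family = fam, subfamily = sub$subfamily[grp[1]],
          size = length(grp),
          span_start = min(sub$start[grp]), span_end = max(sub$end[grp]),
          members = paste(sub$id[grp], collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(arrays) == 0L)
    return(data.frame(array_id = character(), chromosome = character(),
                      family = character(), subfamily = character(),
                      size = integer(), span_start = integer(),
                      span_end = integer(), members = character()))
  out <- do.call(rbind, arrays)
  out <- out[order(out$chromosome, out$span_start, out$family), , drop = FALSE]
  out <- cbind(array_id = sprintf("array%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Per-chromosome co-localization summary of tandem arrays
#'
#' @param arrays output of \code{\link{buildArrays}}.
#' @return data.frame, one row per chromosome: \code{chromosome},
#'   \code{n_arrays}, \code{n_genes}, \code{families}, \code{min_size},
#'   \code{max_size}, \code{mixed_rr} (TRUE if any array mixes RR-1 and
#'   RR-2 members; always FALSE by construction, reported as a check).
#' @export
colocalizationReport <- function(arrays) {
  if (nrow(arrays) == 0L)
    return(data.frame(chromosome = character(), n_arrays = integer(),
                      n_genes = integer(), families = character(),
                      min_size = integer(), max_size = integer(),
                      mixed_rr = logical()))
  do.call(rbind, lapply(split(arrays, arrays$chromosome), function(a) {
    ## arrays are chained per stratum, so a single array can never mix RR-1
    ## and RR-2; verified from the table rather than assumed
    mixed <- any(vapply(strsplit(a$subfamily[!is.na(a$subfamily)], ","),
                        function(s) all(c("RR-1", "RR-2") %in% s), logical(1)))
    strat <- ifelse(is.na(a$subfamily), a$family,
                    paste0(a$family, "/", a$subfamily))
    data.frame(chromosome = a$chromosome[1], n_arrays = nrow(a),
               n_genes = sum(a$size),
               families = paste(sort(unique(strat)), collapse = ";"),
               min_size = min(a$size), max_size = max(a$size),
               mixed_rr = mixed, stringsAsFactors = FALSE)
  }))
}
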