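#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges
#' @importFrom utils read.delim write.table
NULL

.AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                  "R","S","T","V","W","Y","X")

#' The closed cuticular-protein family vocabulary
#'
#' @param subfamilies if TRUE, return the CPR subfamily vocabulary instead.
#' @return character vector of permitted labels.
#' @export
cpFamilies <- function(subfamilies = FALSE) {
  if (subfamilies) c("RR-1", "RR-2", "RR-3", "RR-NC")
  else c("CPR", "CPAP1", "CPAP3", "CPF", "CPFL", "CPT", "CPCFC",
         "CPLCP", "CPLCA", "CPG", "CPH", "18aa")
}

#' Read a predicted proteome from FASTA
#'
#' Sequences are uppercased, trailing stop symbols (\code{*}) stripped, and
#' validated against the 20-letter amino-acid alphabet plus \code{X}.
#' Internal stops signal a broken gene model and are a hard error, as are
#' duplicate identifiers.
#'
#' @param path FASTA file.
#' @return an \code{AAStringSet}; names are the first whitespace-delimited
#'   token of each header, full headers kept in \code{metadata()$description}.
#' @export
readProteome <- function(path) {
  if (file.size(path) == 0L || length(readLines(path, n = 1L)) == 0L) {
    warning("empty FASTA file: ", path)
    return(AAStringSet())
  }
  raw <- withCallingHandlers(
    readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("non-amino-acid characters in ", path, call. = FALSE)
      invokeRestart("muffleWarning")
    })
  desc <- names(raw)
  ids <- sub("\\s.*$", "", desc)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate id ", paste(unique(dup), collapse = ", "), " in ", path)
  seqs <- toupper(as.character(raw))
  seqs <- sub("\\*+$", "", seqs)
  if (any(!nzchar(seqs)))
    stop("zero-length sequence for id ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  if (any(grepl("\\*", seqs, fixed = FALSE)))
    stop("internal stop codon (*) in ",
         paste(ids[grepl("\\*", seqs)], collapse = ", "))
  bad <- grepl(paste0("[^", paste(.AA_ALPHABET, collapse = ""), "]"), seqs)
  if (any(bad))
    stop("non-amino-acid characters in ", paste(ids[bad], collapse = ", "))
  out <- AAStringSet(seqs)
  names(out) <- ids
  metadata(out)$description <- desc
  out
}

#' Write a proteome to FASTA
#' @param proteome an \code{AAStringSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeProteome <- function(proteome, path) {
  writeXStringSet(proteome, path)
  invisible(path)
}

#' Read gene loci from GFF3
#'
#' Keeps features of type \code{gene} as a \code{GRanges} (1-based closed
#' coordinates, as written). Every gene must carry an \code{ID} attribute.
#'
#' @param path GFF3 file.
#' @return \code{GRanges} with a \code{gene_id} metadata column.
#' @export
readGeneLoci <- function(path) {
  emptyLoci <- function() { g <- GRanges(); g$gene_id <- character(); g }
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0L)
    return(emptyLoci())
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L)
    return(emptyLoci())
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    miss <- if (is.null(ids)) seq_along(gr) else which(is.na(ids) | !nzchar(ids))
    stop("gene feature(s) without an ID attribute (feature #",
         paste(miss, collapse = ", #"), " of type 'gene' in ", path, ")")
  }
  if (anyDuplicated(ids))
    stop("duplicate gene ID ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- gr[, character(0)]
  out$gene_id <- as.character(ids)
  out
}

#' ReferenceCatalog: verified cuticular proteins with family labels
#'
#' The homology arm of the classifier compares candidates against a catalog
#' of verified cuticular proteins (typically the curated B. mori set), each
#' carrying a family label from the closed vocabulary, an optional CPR
#' subfamily, and a reference name such as \code{"BmorCPG24"} used for
#' ortholog-based naming.
#'
#' @slot sequences \code{AAStringSet} of reference proteins.
#' @slot info \code{DataFrame} with columns \code{id}, \code{family},
#'   \code{subfamily} (NA unless family is CPR), \code{name}.
#' @export
setClass("ReferenceCatalog",
  representation(sequences = "AAStringSet", info = "DataFrame"))

setValidity("ReferenceCatalog", function(object) {
  msg <- NULL
  info <- object@info
  need <- c("id", "family", "subfamily", "name")
  if (!all(need %in% colnames(info)))
    return(paste("info must have columns", paste(need, collapse = ", ")))
  if (length(object@sequences) != nrow(info))
    msg <- c(msg, "sequence count differs from label count")
  if (!identical(names(object@sequences), as.character(info$id)))
    msg <- c(msg, "sequence names do not match info$id")
  badFam <- setdiff(unique(info$family), cpFamilies())
  if (length(badFam))
    msg <- c(msg, sprintf("unknown family label(s) %s; permitted: %s",
                          paste(badFam, collapse = ", "),
                          paste(cpFamilies(), collapse = ", ")))
  hasSub <- !is.na(info$subfamily)
  if (any(hasSub & info$family != "CPR"))
    msg <- c(msg, "subfamily is only allowed when family = CPR")
  badSub <- setdiff(unique(info$subfamily[hasSub]), cpFamilies(TRUE))
  if (length(badSub))
    msg <- c(msg, sprintf("unknown CPR subfamily %s", paste(badSub, collapse = ", ")))
  if (anyDuplicated(info$id))
    msg <- c(msg, "duplicate reference ids")
  if (is.null(msg)) TRUE else msg
})

#' Construct a ReferenceCatalog in memory
#' @param sequences \code{AAStringSet} (named).
#' @param family,subfamily,name parallel label vectors; \code{subfamily}
#'   must be NA except for CPR members.
#' @return a \code{\linkS4class{ReferenceCatalog}}.
#' @export
ReferenceCatalog <- function(sequences, family,
                             subfamily = rep(NA_character_, length(sequences)),
                             name = names(sequences)) {
  info <- DataFrame(id = names(sequences), family = as.character(family),
                    subfamily = as.character(subfamily),
                    name = as.character(name))
  new("ReferenceCatalog", sequences = sequences, info = info)
}

#' Read a reference catalog from FASTA plus a label TSV
#'
#' The TSV needs a header with columns \code{id}, \code{family},
#' \code{subfamily}, \code{name}; empty subfamily fields become NA. Labels
#' are validated against the closed family vocabulary and every labelled id
#' must be present in the FASTA.
#'
#' @param fasta FASTA of reference proteins.
#' @param labels TSV of labels.
#' @return a \code{\linkS4class{ReferenceCatalog}}.
#' @export
readReferenceCatalog <- function(fasta, labels) {
  seqs <- readProteome(fasta)
  lab <- read.delim(labels, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "family", "subfamily", "name")
  if (!all(need %in% colnames(lab)))
    stop("label TSV must have columns ", paste(need, collapse = ", "))
  missing <- setdiff(lab$id, names(seqs))
  if (length(missing))
    stop("labelled id(s) absent from FASTA: ", paste(missing, collapse = ", "))
  lab <- lab[match(names(seqs), lab$id), , drop = FALSE]
  if (anyNA(lab$id))
    stop("FASTA id(s) without a label row: ",
         paste(setdiff(names(seqs), lab$id), collapse = ", "))
  lab$subfamily[!nzchar(lab$subfamily) | is.na(lab$subfamily)] <- NA_character_
  ReferenceCatalog(seqs, lab$family, lab$subfamily, lab$name)
}

#' @describeIn ReferenceCatalog-class number of reference proteins
#' @param x a \code{ReferenceCatalog}.
#' @export
setMethod("length", "ReferenceCatalog", function(x) length(x@sequences))

#' Accessors for ReferenceCatalog
#' @param object a \code{\linkS4class{ReferenceCatalog}}.
#' @return \code{refSequences}: the \code{AAStringSet}; \code{refInfo}: the
#'   label \code{DataFrame}.
#' @export
refSequences <- function(object) object@sequences

#' @rdname refSequences
#' @export
refInfo <- function(object) object@info

setMethod("show", "ReferenceCatalog", function(object) {
  cat(sprintf("ReferenceCatalog with %d proteins across %d families\n",
              length(object), length(unique(object@info$family))))
  print(table(object@info$family))
})

#' Subset a reference catalog by family
#' @param object a \code{\linkS4class{ReferenceCatalog}}.
#' @param families family labels to keep.
#' @param subfamilies optional CPR subfamily filter.
#' @return a \code{\linkS4class{ReferenceCatalog}}.
#' @export
refSubset <- function(object, families, subfamilies = NULL) {
  keep <- object@info$family %in% families
  if (!is.null(subfamilies))
    keep <- keep & object@info$subfamily %in% subfamilies
  new("ReferenceCatalog", sequences = object@sequences[keep],
      info = object@info[keep, , drop = FALSE])
}
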