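# Haploid alignment container and FASTA I/O.

#' Construct a haploid alignment
#'
#' A `hap_alignment` stores equal-length haploid sequences over the alphabet
#' `{A, C, G, T, 0, 1, N}` as a character matrix (one row per sequence, one
#' column per site).  `N` marks missing data; `0`/`1` encode
#' ancestral/derived states for biallelic site grids.  Lowercase input is
#' normalised to uppercase.
#'
#' @param seqs character vector of sequences (strings) or a character matrix
#'   of single characters with one row per sequence.
#' @param ids unique sequence identifiers; defaults to names of `seqs` or
#'   rownames of the matrix.
#' @param populations optional population assignment per sequence.
#' @return an object of class `hap_alignment`.
#' @export
hap_alignment <- function(seqs, ids = NULL, populations = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
    ids <- ids %||% rownames(mat)
  } else {
    seqs <- toupper(as.character(seqs))
    ids <- ids %||% names(seqs)
    if (length(unique(nchar(seqs))) > 1L)
      stop_ypg("alignment is ragged: sequence lengths ",
               paste(unique(nchar(seqs)), collapse = ", "))
    mat <- if (length(seqs) && nchar(seqs[1]) > 0)
      do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    else matrix(character(0), nrow = length(seqs), ncol = 0)
  }
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(mat)))
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop_ypg("duplicate sequence ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- toupper(mat)
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "0", "1", "N"))
  if (length(bad))
    stop_ypg("invalid alignment symbols: ", paste(bad, collapse = ", "))
  rownames(mat) <- ids
  if (!is.null(populations)) {
    stopifnot(length(populations) == nrow(mat))
    populations <- as.character(populations)
  }
  structure(list(mat = mat, ids = ids, populations = populations),
            class = "hap_alignment")
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat("hap_alignment:", nrow(x$mat), "sequences x", ncol(x$mat), "sites\n")
  invisible(x)
}

#' Number of sequences / sites in an alignment
#' @param aln a [hap_alignment()].
#' @return integer count.
#' @export
n_sequences <- function(aln) nrow(aln$mat)

#' @rdname n_sequences
#' @export
n_sites <- function(aln) ncol(aln$mat)

#' Subset an alignment by sequence ids
#' @param aln a [hap_alignment()].
#' @param ids sequence identifiers to keep (order preserved).
#' @return a [hap_alignment()] restricted to `ids`.
#' @export
subset_alignment <- function(aln, ids) {
  missing <- setdiff(ids, aln$ids)
  if (length(missing))
    stop_ypg("ids absent from alignment: ", paste(missing, collapse = ", "))
  keep <- match(ids, aln$ids)
  hap_alignment(aln$mat[keep, , drop = FALSE], ids = aln$ids[keep],
                populations = aln$populations[keep])
}

#' Read a haploid alignment from FASTA
#'
#' All records must have equal length; ragged files are rejected.  Lowercase
#' bases are normalised to uppercase.
#'
#' @param path FASTA file with at least one record.
#' @return a [hap_alignment()].
#' @export
read_alignment <- function(path) {
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  if (!length(recs)) stop_ypg("no FASTA records in ", path)
  seqs <- vapply(recs, function(r) as.character(r)[1], character(1))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop_ypg("ragged FASTA: lengths ", paste(unique(lens), collapse = ", "))
  hap_alignment(seqs, ids = names(recs))
}

#' Write a haploid alignment to FASTA
#' @param aln a [hap_alignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  seqinr::write.fasta(as.list(seqs), names = aln$ids, file.out = path,
                      nbchar = 80)
  invisible(path)
}
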