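# Multiple-alignment container and FASTA I/O.

#' Construct a multiple sequence alignment object
#'
#' Lightweight container for an aligned set of homologous protein sequences
#' with a designated query row. Sequences are stored as a character matrix
#' (rows = sequences, columns = alignment columns) over the 20 amino acids
#' plus the gap character `-`.
#'
#' @param seqs Character vector of aligned sequences (equal lengths), or a
#'   character matrix of single characters.
#' @param ids Sequence identifiers; defaults to names of `seqs` or
#'   `seq_1 ...`.
#' @param query_index Row index of the query sequence (default 1).
#' @return An object of class `msa` with elements `mat` (character matrix),
#'   `ids`, and `query_index`.
#' @export
msa <- function(seqs, ids = NULL, query_index = 1L) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    seqs <- toupper(as.character(seqs))
    if (length(seqs) == 0L) stop("alignment must contain at least one sequence")
    n <- nchar(seqs)
    if (length(unique(n)) != 1L)
      stop("aligned sequences must have equal length")
    if (n[1] == 0L) stop("alignment must contain at least one column")
    mat <- do.call(rbind, strsplit(seqs, ""))
    if (is.null(ids)) ids <- names(seqs)
  }
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_len(nrow(mat)))
  query_index <- as.integer(query_index)
  if (query_index < 1L || query_index > nrow(mat))
    stop("query_index out of range")
  if (any(mat[query_index, ] %in% c("X", "B", "Z", "J", "U", "O", "*")))
    stop("query row contains ambiguous residue characters")
  structure(list(mat = mat, ids = as.character(ids),
                 query_index = query_index),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns (query: %s)\n",
              nrow(x$mat), ncol(x$mat), x$ids[x$query_index]))
  invisible(x)
}

#' @export
dim.msa <- function(x) dim(x$mat)

#' Ungapped query sequence of an alignment
#'
#' @param aln An [msa] object.
#' @return Single string: the query row with gaps removed.
#' @export
msa_query_sequence <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  q <- aln$mat[aln$query_index, ]
  paste(q[q != "-"], collapse = "")
}

#' Read an alignment (or sequence set) from FASTA
#'
#' @param path FASTA file. For alignments all records must share one length.
#' @param query_id Identifier of the query row; defaults to the first record.
#' @return An [msa] object.
#' @export
read_msa_fasta <- function(path, query_id = NULL) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(set))
  qi <- 1L
  if (!is.null(query_id)) {
    qi <- match(query_id, ids)
    if (is.na(qi)) stop("query id '", query_id, "' not found in ", path)
  }
  msa(as.character(set), ids = ids, query_index = qi)
}

#' Write an alignment to FASTA
#'
#' @param aln An [msa] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "msa"))
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Per-column residue frequencies of an alignment
#'
#' Gap-excluded relative frequencies of the 20 amino acids for each
#' alignment column, optionally restricted to columns where the query is
#' ungapped.
#'
#' @param aln An [msa] object.
#' @param query_columns If `TRUE` (default) report only columns at which the
#'   query row has a residue, indexed by ungapped query position.
#' @return Numeric matrix, 20 rows (amino acids) by columns.
#' @export
msa_column_frequencies <- function(aln, query_columns = TRUE) {
  stopifnot(inherits(aln, "msa"))
  cols <- seq_len(ncol(aln$mat))
  if (query_columns) cols <- which(aln$mat[aln$query_index, ] != "-")
  freq <- vapply(cols, function(j) {
    col <- aln$mat[, j]
    col <- col[col %in% AA_ALPHABET1]
    if (length(col) == 0L) return(stats::setNames(rep(0, 20), AA_ALPHABET1))
    tab <- table(factor(col, levels = AA_ALPHABET1))
    as.numeric(tab) / length(col)
  }, numeric(20))
  rownames(freq) <- AA_ALPHABET1
  colnames(freq) <- if (query_columns) seq_along(cols) else cols
  freq
}
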