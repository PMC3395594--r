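# Homolog filtering, per-column conservation scoring, percentile
# normalization, and mapping of scores onto structure residue numbering.

.pairwise_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  # matches over full alignment length (including gap columns)
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Filter homologous sequences before conservation analysis
#'
#' Applies the standard homolog-curation rules: drop candidates more than
#' `max_identity` identical to the query, drop candidates shorter than
#' `min_length_fraction` of the query length, then remove redundancy by
#' greedy longest-first clustering at `redundancy_identity`, keeping one
#' representative per cluster. Identity is matches over the global-alignment
#' length (affine gap penalties, BLOSUM62).
#'
#' @param query Query sequence (unaligned, single string).
#' @param candidates Character vector of candidate homolog sequences
#'   (unaligned), optionally named.
#' @param max_identity Maximum allowed identity to the query (default 0.95).
#' @param min_length_fraction Minimum length relative to the query
#'   (default 0.60).
#' @param redundancy_identity Pairwise identity above which two candidates
#'   are considered redundant (default 0.95).
#' @return Named character vector of retained sequences (possibly empty).
#' @export
filter_homologs <- function(query, candidates, max_identity = 0.95,
                            min_length_fraction = 0.60,
                            redundancy_identity = 0.95) {
  query <- gsub("-", "", toupper(query))
  if (nchar(query) == 0L) stop("query sequence must be non-empty")
  if (length(candidates) == 0L) return(character(0))
  if (is.null(names(candidates)))
    names(candidates) <- sprintf("cand_%d", seq_along(candidates))
  candidates <- vapply(candidates, function(s) gsub("-", "", toupper(s)), "")

  keep <- nchar(candidates) >= min_length_fraction * nchar(query)
  candidates <- candidates[keep]
  idq <- vapply(candidates, .pairwise_identity, 0, b = query)
  candidates <- candidates[idq <= max_identity]

  if (length(candidates) > 1L) {
    ord <- order(nchar(candidates), decreasing = TRUE)
    candidates <- candidates[ord]
    reps <- character(0)
    rep_names <- character(0)
    for (i in seq_along(candidates)) {
      red <- length(reps) > 0L &&
        any(vapply(reps, .pairwise_identity, 0,
                   b = candidates[[i]]) > redundancy_identity)
      if (!red) {
        reps <- c(reps, candidates[[i]])
        rep_names <- c(rep_names, names(candidates)[i])
      }
    }
    candidates <- stats::setNames(reps, rep_names)
  }
  if (length(candidates) == 0L)
    warning("all candidate sequences were filtered out")
  candidates
}

# Henikoff position-based sequence weights; gaps contribute nothing.
henikoff_weights <- function(mat) {
  n <- nrow(mat)
  w <- numeric(n)
  used <- 0L
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    ok <- col %in% AA_ALPHABET1
    if (!any(ok)) next
    used <- used + 1L
    tab <- table(col[ok])
    r <- length(tab)
    contrib <- numeric(n)
    contrib[ok] <- 1 / (r * as.numeric(tab[col[ok]]))
    w <- w + contrib
  }
  if (used == 0L || sum(w) == 0) return(rep(1 / n, n))
  w / sum(w)
}

.column_distribution <- function(col, weights) {
  ok <- col %in% AA_ALPHABET1
  if (!any(ok)) return(NULL)
  w <- weights[ok]
  p <- vapply(AA_ALPHABET1, function(a) sum(w[col[ok] == a]), 0)
  p / sum(p)
}

.jsd_score <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Score per-residue conservation from an alignment
#'
#' For every alignment column at which the query has a residue, computes a
#' raw conservation score: `method = "jsd"` is the Jensen-Shannon divergence
#' (base 2) between the weighted gap-excluded column distribution and a
#' fixed BLOSUM62-derived background; `method = "entropy"` is one minus the
#' normalized Shannon entropy of the column. Higher means more conserved.
#' Position-based (Henikoff) sequence weighting is applied by default.
#' Columns with more than `gap_flag_threshold` gaps are scored but flagged
#' low-confidence.
#'
#' @param aln An [msa] with at least two non-query rows.
#' @param method `"jsd"` (default) or `"entropy"`.
#' @param weighting `"henikoff"` (default) or `"none"`.
#' @param gap_flag_threshold Gap fraction above which a column is flagged.
#' @return Data frame with one row per ungapped query position:
#'   `query_position`, `residue`, `raw_score`, `n_nongap`, `gappy`.
#' @export
score_conservation <- function(aln, method = c("jsd", "entropy"),
                               weighting = c("henikoff", "none"),
                               gap_flag_threshold = 0.5) {
  stopifnot(inherits(aln, "msa"))
  method <- match.arg(method)
  weighting <- match.arg(weighting)
  mat <- aln$mat
  if (nrow(mat) - 1L < 2L)
    stop("insufficient homologs: need at least 2 non-query rows")
  w <- if (weighting == "henikoff") henikoff_weights(mat)
       else rep(1 / nrow(mat), nrow(mat))
  qcols <- which(mat[aln$query_index, ] != "-")
  res <- lapply(seq_along(qcols), function(k) {
    j <- qcols[k]
    col <- mat[, j]
    n_nongap <- sum(col != "-")
    p <- .column_distribution(col, w)
    score <- if (is.null(p)) NA_real_
    else if (method == "jsd") .jsd_score(p, .AA_BACKGROUND)
    else {
      nz <- p > 0
      1 - (-sum(p[nz] * log(p[nz]))) / log(20)
    }
    data.frame(query_position = k,
               residue = mat[aln$query_index, j],
               raw_score = score,
               n_nongap = n_nongap,
               gappy = mean(col == "-") > gap_flag_threshold)
  })
  do.call(rbind, res)
}

#' Percentile-normalize raw conservation scores
#'
#' Replaces raw scores by within-protein rank fractions,
#' `(rank - 1) / (N - 1)` with average ranks for ties, so the least
#' conserved position maps to 0, the most conserved to 1, and scores are
#' comparable across proteins.
#'
#' @param raw Numeric vector of raw scores (length >= 2).
#' @return Numeric vector in `[0, 1]`, same order as `raw`.
#' @export
percentile_normalize <- function(raw) {
  if (length(raw) < 2L)
    stop("degenerate input: need at least 2 positions to normalize")
  (rank(raw, ties.method = "average") - 1) / (length(raw) - 1)
}

#' Full conservation profile of the query sequence
#'
#' Convenience wrapper: [score_conservation] followed by
#' [percentile_normalize].
#'
#' @inheritParams score_conservation
#' @return Data frame: `query_position`, `residue`, `raw_score`,
#'   `normalized_score`, `n_nongap`, `gappy`.
#' @export
conservation_profile <- function(aln, method = c("jsd", "entropy"),
                                 weighting = c("henikoff", "none")) {
  prof <- score_conservation(aln, method = method, weighting = weighting)
  prof$normalized_score <- percentile_normalize(prof$raw_score)
  prof[c("query_position", "residue", "raw_score", "normalized_score",
         "n_nongap", "gappy")]
}

#' Map a conservation profile onto a structure chain sequence
#'
#' Globally aligns the profile's query sequence to the chain sequence
#' extracted from a structure and transfers per-position scores. Residues of
#' the chain without an aligned query position are flagged unmapped.
#'
#' @param profile Output of [conservation_profile].
#' @param chain_seq Chain sequence (single string) in structure order.
#' @param min_identity Minimum identity over the aligned (non-gap) region
#'   (default 0.90).
#' @return Data frame, one row per chain position: `structure_index`,
#'   `chain_residue`, `query_position`, `raw_score`, `normalized_score`,
#'   `unmapped`.
#' @export
map_to_structure <- function(profile, chain_seq, min_identity = 0.90) {
  qseq <- paste(profile$residue, collapse = "")
  chain_seq <- gsub("-", "", toupper(chain_seq))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qseq), Biostrings::AAString(chain_seq),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  both <- pa != "-" & sa != "-"
  ident <- sum(pa[both] == sa[both]) / max(sum(both), 1L)
  if (ident < min_identity)
    stop(sprintf(
      "mapping error: %.1f%% identity between query '%s...' and chain '%s...'",
      100 * ident, substr(qseq, 1, 10), substr(chain_seq, 1, 10)))
  qi <- 0L; si <- 0L
  out <- vector("list", nchar(chain_seq))
  for (k in seq_along(pa)) {
    if (pa[k] != "-") qi <- qi + 1L
    if (sa[k] != "-") {
      si <- si + 1L
      mapped <- pa[k] != "-"
      out[[si]] <- data.frame(
        structure_index = si,
        chain_residue = sa[k],
        query_position = if (mapped) qi else NA_integer_,
        raw_score = if (mapped) profile$raw_score[qi] else NA_real_,
        normalized_score = if (mapped) profile$normalized_score[qi]
                           else NA_real_,
        unmapped = !mapped)
    }
  }
  do.call(rbind, out)
}

#' Write a per-residue conservation score table
#'
#' @param profile A profile data frame ([conservation_profile] or
#'   [map_to_structure] output).
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
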