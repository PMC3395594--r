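# Three-rule mutation design for deregulating allosteric inhibition:
# (1) target evolutionarily variable allosteric-site residues,
# (2) prefer residues giving ligand selectivity through charge/H-bond or
#     large contact area,
# (3) substitute with similar-volume neutral/hydrophobic residues that
#     occur rarely in the alignment column.

#' Select allosteric-site candidate positions for mutation
#'
#' Returns allosteric-class residues whose percentile-normalized
#' conservation score is below the threshold (default 0.5, the
#' variable-position rule), sorted by ascending conservation.
#'
#' @param scores Data frame with columns `resno` and `normalized_score`
#'   (and optionally `wild_type`), e.g. a mapped conservation profile or a
#'   curated score table.
#' @param annotation Data frame with columns `resno` and `class`
#'   ([classify_sites] output or curated). Only rows with
#'   `class == "allosteric"` are eligible.
#' @param conservation_threshold Candidates must score strictly below this
#'   value (default 0.5).
#' @return Data frame of candidate positions sorted by ascending
#'   `normalized_score` (empty, with a warning, when there are no
#'   allosteric residues).
#' @export
select_candidates <- function(scores, annotation,
                              conservation_threshold = 0.5) {
  stopifnot("resno" %in% names(scores),
            "normalized_score" %in% names(scores),
            all(c("resno", "class") %in% names(annotation)))
  allo <- annotation[annotation$class == "allosteric", ]
  if (nrow(allo) == 0L) {
    warning("no allosteric residues in annotation")
    return(scores[0, ])
  }
  cand <- merge(scores, allo["resno"], by = "resno")
  cand <- cand[!is.na(cand$normalized_score) &
                 cand$normalized_score < conservation_threshold, ]
  cand <- cand[order(cand$normalized_score, cand$resno), ]
  rownames(cand) <- NULL
  cand
}

#' Propose deregulating substitutions for a candidate position
#'
#' Draws proposals from a similar-volume neutral/hydrophobic mapping table
#' for the wild-type residue, drops proposals occurring at or above
#' `frequency_threshold` in the alignment column (rarely-observed rule),
#' and ranks by absolute side-chain volume difference, then ascending
#' column frequency.
#'
#' @param wild_type One-letter wild-type residue.
#' @param resno Residue number (carried through to the output).
#' @param column_freqs Optional named length-20 frequency vector for the
#'   position's alignment column (e.g. one column of
#'   [msa_column_frequencies]); when absent, frequencies are treated as
#'   unobserved (0).
#' @param frequency_threshold Maximum allowed column frequency of a
#'   proposed residue (default 0.05).
#' @param conservation Optional normalized conservation score, carried
#'   through.
#' @param contact_area Optional residue-ligand contact area (Angstrom^2);
#'   areas of 40 or more set the large-contact rationale flag.
#' @param substitution_map Optional custom map (named list wild type ->
#'   ordered proposal vector); defaults to the built-in table.
#' @return Data frame of ranked `mutation_candidate` rows: `resno`,
#'   `wild_type`, `proposed`, `volume_diff`, `column_frequency`,
#'   `conservation`, `charged_wt`, `large_contact`, `flag`.
#' @export
propose_substitutions <- function(wild_type, resno = NA_integer_,
                                  column_freqs = NULL,
                                  frequency_threshold = 0.05,
                                  conservation = NA_real_,
                                  contact_area = NA_real_,
                                  substitution_map = NULL) {
  if (!wild_type %in% AA_ALPHABET1)
    stop("wild type must be a standard one-letter amino-acid code")
  map <- if (is.null(substitution_map)) .SUBSTITUTION_MAP
         else substitution_map
  props <- map[[wild_type]]
  empty <- data.frame(resno = integer(0), wild_type = character(0),
                      proposed = character(0), volume_diff = numeric(0),
                      column_frequency = numeric(0),
                      conservation = numeric(0), charged_wt = logical(0),
                      large_contact = logical(0), flag = character(0))
  if (is.null(props) || length(props) == 0L) {
    attr(empty, "flag") <- "no_mapped_alternatives"
    return(empty)
  }
  props <- setdiff(props, wild_type)
  freq <- if (is.null(column_freqs)) stats::setNames(rep(0, 20),
                                                     AA_ALPHABET1)
          else column_freqs
  f <- as.numeric(freq[props])
  keep <- f < frequency_threshold
  props <- props[keep]; f <- f[keep]
  if (length(props) == 0L) {
    attr(empty, "flag") <- "all_proposals_frequent"
    return(empty)
  }
  vd <- abs(.AA_VOLUME[props] - .AA_VOLUME[[wild_type]])
  ord <- order(vd, f, props)
  data.frame(resno = resno, wild_type = wild_type,
             proposed = props[ord], volume_diff = as.numeric(vd[ord]),
             column_frequency = f[ord], conservation = conservation,
             charged_wt = wild_type %in% aa_groups()$charged,
             large_contact = !is.na(contact_area) && contact_area >= 40,
             flag = "", stringsAsFactors = FALSE)
}

#' Read a mutation-outcome table
#'
#' Reads a TSV of previously attempted allosteric-site mutations with
#' conservation scores and outcomes (the format of the packaged FBPase
#' record: columns `residue`, `pocket`, `wild_type`, `resno`,
#' `conservation_score`, `substitutions` (comma-separated),
#' `enzyme_activity`, `allosteric_inhibition`).
#'
#' @param path TSV file; defaults to the packaged FBPase mutation record.
#' @return Data frame with one row per residue and a `n_substitutions`
#'   column.
#' @export
read_mutation_outcomes <- function(path = system.file(
  "extdata", "fbpase_mutation_outcomes.tsv", package = "allosite")) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  out$n_substitutions <- lengths(strsplit(out$substitutions, ","))
  out
}

#' Assemble a mutation-design report
#'
#' Combines candidate selection and substitution proposals with an optional
#' retrospective outcome analysis: attempted mutations are partitioned into
#' variable (`score < threshold`) and conserved positions, successes are
#' counted when per-mutation labels are available, and the resulting 2x2
#' table is tested with Fisher's exact test.
#'
#' @param scores,annotation As in [select_candidates]; `scores` should
#'   carry a `wild_type` column for proposals.
#' @param column_freqs Optional matrix from [msa_column_frequencies]
#'   (columns indexed by query position) used for the rare-substitution
#'   rule.
#' @param outcomes Optional outcome records ([read_mutation_outcomes]
#'   format); per-mutation success labels, when present, must be in a
#'   logical `success` column of an expanded one-row-per-substitution
#'   table.
#' @param conservation_threshold Variable/conserved partition threshold
#'   (default 0.5).
#' @param frequency_threshold Passed to [propose_substitutions].
#' @return Object of class `design_report`: list with `candidates`,
#'   `proposals`, and (when outcomes are supplied) `outcome_analysis` with
#'   counts and the Fisher test.
#' @export
design_report <- function(scores, annotation, column_freqs = NULL,
                          outcomes = NULL, conservation_threshold = 0.5,
                          frequency_threshold = 0.05) {
  cand <- select_candidates(scores, annotation, conservation_threshold)
  proposals <- NULL
  if (nrow(cand) > 0L && "wild_type" %in% names(cand)) {
    proposals <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
      cf <- NULL
      if (!is.null(column_freqs) && "query_position" %in% names(cand)) {
        qp <- as.character(cand$query_position[i])
        if (qp %in% colnames(column_freqs)) cf <- column_freqs[, qp]
      }
      propose_substitutions(cand$wild_type[i], cand$resno[i],
                            column_freqs = cf,
                            frequency_threshold = frequency_threshold,
                            conservation = cand$normalized_score[i])
    }))
  }
  report <- list(candidates = cand, proposals = proposals,
                 conservation_threshold = conservation_threshold)
  if (!is.null(outcomes)) {
    if (!"conservation_score" %in% names(outcomes))
      stop("outcomes must carry a conservation_score column")
    miss <- is.na(outcomes$conservation_score)
    if (any(miss)) {
      warning("excluding ", sum(miss), " outcome record(s) without scores")
      outcomes <- outcomes[!miss, ]
    }
    n_mut <- if ("n_substitutions" %in% names(outcomes))
      outcomes$n_substitutions
    else lengths(strsplit(outcomes$substitutions, ","))
    variable <- outcomes$conservation_score < conservation_threshold
    counts <- c(variable = sum(n_mut[variable]),
                conserved = sum(n_mut[!variable]))
    oa <- list(n_mutations = counts)
    if ("success" %in% names(outcomes)) {
      succ <- c(variable = sum(n_mut[variable & outcomes$success]),
                conserved = sum(n_mut[!variable & outcomes$success]))
      m <- rbind(conserved = c(succ[["conserved"]],
                               counts[["conserved"]] - succ[["conserved"]]),
                 variable = c(succ[["variable"]],
                              counts[["variable"]] - succ[["variable"]]))
      colnames(m) <- c("success", "failure")
      oa$n_success <- succ
      if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
        oa$fisher <- list(p = NA_real_, degenerate = TRUE)
      } else {
        oa$fisher <- list(p = stats::fisher.test(m)$p.value,
                          degenerate = FALSE)
      }
      oa$table <- m
    }
    report$outcome_analysis <- oa
  }
  structure(report, class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("design_report: %d candidate position(s) below %.2f\n",
              nrow(x$candidates), x$conservation_threshold))
  if (!is.null(x$outcome_analysis))
    cat(sprintf("  prior mutations: %d at variable, %d at conserved positions\n",
                x$outcome_analysis$n_mutations[["variable"]],
                x$outcome_analysis$n_mutations[["conserved"]]))
  invisible(x)
}
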