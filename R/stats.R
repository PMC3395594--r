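# Statistical comparisons between residue classes: rank-sum and
# variance-ratio tests on conservation scores, and amino-acid composition
# enrichment via Fisher's exact test. The tests themselves are the standard
# base-R implementations, wrapped to fix the conventions used here.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two score samples. Uses exact
#' enumeration when the combined sample size is at most 20 and there are no
#' ties, otherwise the normal approximation with tie and continuity
#' corrections.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return List with `U` (number of `(x, y)` pairs with `x > y`, counting
#'   ties as half), `p` (two-sided), `exact` (logical).
#' @export
mann_whitney <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L)
    stop("invalid input: both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 20L && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value, exact = exact)
}

#' Variance-ratio (F) test
#'
#' Two-sided F test of equality of variances, `F = s2_x / s2_y`, with the
#' p-value obtained by doubling the smaller tail of the F distribution.
#' Used to compare the spread of conservation scores between site classes.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @return List with `F`, `df`, and `p` (two-sided).
#' @export
variance_ratio_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("invalid input: need >= 2 values per sample")
  if (stats::var(y) == 0)
    stop("degenerate input: zero variance in denominator sample")
  ht <- stats::var.test(x, y)
  list(F = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Amino-acid composition table for two residue classes
#'
#' Counts each of the 20 amino acids within two residue classes of a site
#' annotation (by default catalytic versus allosteric), the comparison
#' underlying pocket-composition enrichment.
#'
#' @param annotation Data frame with columns `aa` and `class`
#'   (e.g. [classify_sites] output, or curated annotations).
#' @param classes Length-2 character vector naming the compared classes.
#' @return Object of class `composition_table`: list with `counts` (20 x 2
#'   integer matrix), `totals`, `classes`, and `groups` ([aa_groups]).
#' @export
composition_table <- function(annotation,
                              classes = c("catalytic", "allosteric")) {
  stopifnot(length(classes) == 2L,
            all(c("aa", "class") %in% names(annotation)))
  bad <- !(annotation$aa %in% AA_ALPHABET1) &
    annotation$class %in% classes
  if (any(bad)) {
    warning("excluding ", sum(bad), " residue(s) with non-standard codes: ",
            paste(unique(annotation$aa[bad]), collapse = ", "))
    annotation <- annotation[!bad, ]
  }
  counts <- sapply(classes, function(cl) {
    aa <- annotation$aa[annotation$class == cl]
    as.integer(table(factor(aa, levels = AA_ALPHABET1)))
  })
  rownames(counts) <- AA_ALPHABET1
  totals <- colSums(counts)
  if (any(totals == 0))
    warning("empty class: ",
            paste(classes[totals == 0], collapse = ", "))
  structure(list(counts = counts, totals = totals, classes = classes,
                 groups = aa_groups()),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat("composition_table:", paste(x$classes, x$totals, sep = " n=",
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Composition fractions per class
#'
#' @param table A [composition_table].
#' @return 20 x 2 matrix of within-class fractions (columns sum to 1).
#' @export
composition_fractions <- function(table) {
  stopifnot(inherits(table, "composition_table"))
  sweep(table$counts, 2, pmax(table$totals, 1L), "/")
}

#' Fisher's exact enrichment per amino acid or residue group
#'
#' For each amino acid (or physicochemical group), tests the 2x2 table of
#' (item vs rest) x (class A vs class B) under the null hypothesis that
#' both classes share the same composition. Two-sided p-values follow the
#' point-probability convention (sum of tables at most as probable as the
#' observed one). Odds ratios are the sample cross-product ratio with a
#' Haldane 0.5 correction when a cell is zero. Holm-adjusted p-values are
#' reported alongside the raw ones.
#'
#' @param table A [composition_table].
#' @param by `"aa"` (default, 20 tests) or `"group"` (charged /
#'   hydrophobic / other).
#' @return Data frame: `item`, `count_a`, `count_b`, `fraction_a`,
#'   `fraction_b`, `odds_ratio`, `p`, `p_holm`.
#' @export
fisher_enrichment <- function(table, by = c("aa", "group")) {
  stopifnot(inherits(table, "composition_table"))
  by <- match.arg(by)
  if (all(table$counts == 0L)) stop("invalid input: all-zero table")
  items <- if (by == "aa") as.list(stats::setNames(AA_ALPHABET1,
                                                   AA_ALPHABET1))
           else table$groups
  nA <- table$totals[1]; nB <- table$totals[2]
  rows <- lapply(names(items), function(nm) {
    a <- sum(table$counts[items[[nm]], 1])
    b <- sum(table$counts[items[[nm]], 2])
    m <- matrix(c(a, nA - a, b, nB - b), nrow = 2)
    p <- if (all(rowSums(m) > 0) && all(colSums(m) > 0))
      stats::fisher.test(m)$p.value else NA_real_
    orr <- (a * (nB - b)) / ((nA - a) * b)
    if (!is.finite(orr) || any(m == 0))
      orr <- ((a + 0.5) * (nB - b + 0.5)) / ((nA - a + 0.5) * (b + 0.5))
    data.frame(item = nm, count_a = a, count_b = b,
               fraction_a = a / max(nA, 1L), fraction_b = b / max(nB, 1L),
               odds_ratio = orr, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}

#' Compare conservation-score distributions between site classes
#'
#' Runs the rank-sum and variance-ratio comparisons between two residue
#' classes of an annotated conservation profile.
#'
#' @param scores Numeric conservation scores.
#' @param class Character class labels aligned with `scores`.
#' @param classes Length-2 vector of class names compared (first vs
#'   second).
#' @return Data frame of test results (one row per test).
#' @export
compare_site_conservation <- function(scores, class,
                                      classes = c("catalytic",
                                                  "allosteric")) {
  x <- scores[class == classes[1]]
  y <- scores[class == classes[2]]
  mw <- mann_whitney(x, y)
  vr <- if (length(x) >= 2L && length(y) >= 2L && stats::var(y) > 0)
    variance_ratio_test(x, y) else list(F = NA_real_, p = NA_real_)
  data.frame(test = c("mann_whitney", "variance_ratio"),
             class_a = classes[1], class_b = classes[2],
             n_a = length(x), n_b = length(y),
             mean_a = mean(x), mean_b = mean(y),
             statistic = c(mw$U, vr$F),
             p = c(mw$p, vr$p))
}
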