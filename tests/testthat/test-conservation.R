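test_that("homolog filtering applies identity, length, and redundancy rules", {
  query <- paste(rep(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"),
                     10), collapse = "")
  mutate_seq <- function(s, positions, to = "W") {
    v <- strsplit(s, "")[[1]]
    v[positions] <- to
    paste(v, collapse = "")
  }
  near_query <- mutate_seq(query, 1:4)            # 96% identical
  distant <- paste(rep(c("W", "Y", "V", "M", "N"), 20), collapse = "")
  distant2 <- mutate_seq(distant, 1)              # ~99% identical to distant
  short <- substr(query, 1, 55)                   # 0.55 of query length
  kept <- filter_homologs(query, c(a = near_query, b = distant,
                                   c = distant2, d = short))
  expect_false("a" %in% names(kept))
  expect_false("d" %in% names(kept))
  expect_length(intersect(c("b", "c"), names(kept)), 1L)

  expect_identical(filter_homologs(query, character(0)), character(0))
  expect_warning(filter_homologs(query, c(x = near_query)), "filtered out")
})

test_that("conservation scores agree with direct formula computation", {
  # 10 rows: column 1 = A x9 + V; column 2 = five residues twice each;
  # column 3 invariant
  rows <- cbind(c(rep("A", 9), "V"),
                rep(c("A", "C", "D", "E", "F"), each = 2),
                rep("K", 10))
  aln <- msa(rows)
  for (method in c("jsd", "entropy")) {
    prof <- score_conservation(aln, method = method, weighting = "none")
    # independent oracle: direct computation from column frequencies
    bg <- c(A = 0.078, R = 0.051, N = 0.041, D = 0.052, C = 0.024,
            Q = 0.034, E = 0.059, G = 0.083, H = 0.025, I = 0.062,
            L = 0.092, K = 0.056, M = 0.024, F = 0.044, P = 0.043,
            S = 0.059, T = 0.055, W = 0.014, Y = 0.034, V = 0.072)
    bg <- bg / sum(bg)
    col_p <- function(col) {
      tab <- table(factor(col, levels = names(bg)))
      as.numeric(tab) / length(col)
    }
    oracle <- function(col) {
      p <- col_p(col)
      if (method == "entropy") {
        nz <- p > 0
        1 - (-sum(p[nz] * log(p[nz]))) / log(20)
      } else {
        m <- (p + bg) / 2
        nzp <- p > 0
        0.5 * sum(p[nzp] * log2(p[nzp] / m[nzp])) +
          0.5 * sum(bg * log2(bg / m))
      }
    }
    expected <- apply(rows, 2, oracle)
    expect_equal(prof$raw_score, unname(expected), tolerance = 1e-12)
    expect_gt(prof$raw_score[1], prof$raw_score[2])
    expect_true(all(prof$raw_score[3] >= prof$raw_score))
  }
})

test_that("an equifrequent 20-residue column has zero entropy score", {
  rows <- cbind(AA_ALPHABET1, rep("A", 20))
  aln <- msa(rows)
  prof <- score_conservation(aln, method = "entropy", weighting = "none")
  expect_equal(prof$raw_score[1], 0, tolerance = 1e-12)
  expect_equal(prof$raw_score[2], 1, tolerance = 1e-12)
})

test_that("scoring requires at least two non-query rows", {
  expect_error(score_conservation(msa(c("ACD", "ACD"))), "insufficient")
})

test_that("percentile normalization follows the average-rank formula", {
  expect_equal(percentile_normalize(c(5, 1, 3)), c(1, 0, 0.5))
  expect_equal(percentile_normalize(rep(2, 4)), rep(0.5, 4))
  expect_equal(percentile_normalize(c(2, 2, 1, 3)), c(0.5, 0.5, 0, 1))
  expect_error(percentile_normalize(3), "degenerate")

  # order-preserving and idempotent on already-normalized ranks
  set.seed(1)
  raw <- rnorm(40)
  norm <- percentile_normalize(raw)
  expect_identical(order(norm), order(raw))
  expect_equal(percentile_normalize(norm), norm)
})

test_that("duplicating all rows leaves weighted entropy scores unchanged", {
  aln <- gen_msa(two_class_msa_spec(15, 10, seed = 4))
  dup <- msa(rbind(aln$mat, aln$mat))
  s1 <- score_conservation(aln, method = "entropy")$raw_score
  s2 <- score_conservation(dup, method = "entropy")$raw_score
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("profiles map onto structure chains through global alignment", {
  aln <- msa(c("ACDEFGHIKL", "ACDEFGHIKA", "ACDEFGYIKL", "ACWEFGHIKL"))
  prof <- conservation_profile(aln)

  same <- map_to_structure(prof, "ACDEFGHIKL")
  expect_equal(same$query_position, 1:10)
  expect_equal(same$normalized_score, prof$normalized_score)

  shifted <- map_to_structure(prof, "MACDEFGHIKL")
  expect_true(shifted$unmapped[1])
  expect_equal(shifted$query_position[-1], 1:10)
  expect_equal(shifted$normalized_score[-1], prof$normalized_score)

  deleted <- map_to_structure(prof, "ACDEFGHL")  # internal IK deletion
  expect_equal(sum(!deleted$unmapped), 8L)
  expect_equal(deleted$query_position[deleted$chain_residue == "L"], 10L)

  expect_error(map_to_structure(prof, "WWWWWWWWWW"), "mapping error")
})

test_that("synthetic rate classes separate in normalized conservation", {
  aln <- gen_msa(two_class_msa_spec(50, 50, seed = 8))
  prof <- conservation_profile(aln)
  cl <- attr(aln, "column_class")
  lo <- prof$normalized_score[cl == "conserved"]
  hi <- prof$normalized_score[cl == "variable"]
  expect_gt(mean(lo), mean(hi))
  expect_lt(mann_whitney(lo, hi)$p, 0.01)
})

test_that("rate-ordering of scores holds for nearly all column pairs", {
  frac_ok <- vapply(1:20, function(s) {
    aln <- gen_msa(two_class_msa_spec(30, 12, seed = 100 + s))
    raw <- score_conservation(aln)$raw_score
    cl <- attr(aln, "column_class")
    mean(outer(raw[cl == "conserved"], raw[cl == "variable"], ">="))
  }, 0)
  expect_gte(mean(frac_ok), 0.95)
})
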