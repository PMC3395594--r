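test_that("rank-sum test matches exact enumeration on small samples", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p, 0.1)
  expect_true(r$exact)

  expect_equal(mann_whitney(c(1, 2, 5, 5), c(5, 5, 1, 2))$p, 1,
               tolerance = 0.05)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")

  # property: agreement with full-enumeration oracle, tie-free samples
  set.seed(77)
  for (rep in 1:25) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    v <- sample(1:100, nx + ny)  # distinct values, no ties
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    expect_equal(mann_whitney(x, y)$p, mw_exact_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("variance-ratio test follows the doubled-tail convention", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7, 2.9)
  r <- variance_ratio_test(x, x)
  expect_equal(r$F, 1)
  expect_equal(r$p, 1)

  y <- 2 * (x - mean(x))
  expect_equal(variance_ratio_test(x, y)$F, 0.25, tolerance = 1e-12)
  expect_error(variance_ratio_test(x, rep(2, 5)), "degenerate")
  expect_error(variance_ratio_test(1, x), "2 values")

  # simulation: n = 50 per group, true variance ratio 4
  set.seed(31)
  fs <- replicate(500, variance_ratio_test(rnorm(50, sd = 2), rnorm(50))$F)
  expect_gt(median(fs), 3)
  expect_lt(median(fs), 5.3)
})

test_that("composition tables count classes and groups correctly", {
  ann <- data.frame(aa = c(strsplit("KKDD", "")[[1]],
                           strsplit("LLVV", "")[[1]]),
                    class = rep(c("catalytic", "allosteric"), each = 4))
  tab <- composition_table(ann)
  fr <- composition_fractions(tab)
  grp <- aa_groups()
  expect_equal(sum(fr[grp$charged, "catalytic"]), 1)
  expect_equal(sum(fr[grp$hydrophobic, "allosteric"]), 1)
  expect_equal(colSums(tab$counts), tab$totals)

  expect_warning(composition_table(data.frame(aa = "K",
                                              class = "catalytic")),
                 "empty class")
})

test_that("composition counts on a toy structure match the generator plan", {
  plan <- toy_residue_plan()
  model <- gen_toy_structure(toy_structure_spec(plan))
  ann <- classify_sites(model, n_points = 240)
  tab <- composition_table(ann)
  expect_equal(tab$counts["K", "catalytic"], 1L)
  expect_equal(sum(tab$counts[, "catalytic"]), 1L)
  expect_equal(sort(rownames(tab$counts)[tab$counts[, "allosteric"] > 0]),
               c("L", "R"))
})

test_that("Fisher enrichment agrees with hypergeometric enumeration", {
  # symmetric table: odds ratio 1, p 1
  ann <- data.frame(aa = rep(c("K", "L"), times = c(10, 10)),
                    class = rep(c("catalytic", "allosteric"), 10))
  tab <- composition_table(ann)
  fe <- fisher_enrichment(tab)
  expect_equal(fe$odds_ratio[fe$item == "K"], 1)
  expect_equal(fe$p[fe$item == "K"], 1)

  # disjoint composition: two extreme tables out of all arrangements
  ann2 <- data.frame(aa = rep(c("K", "L"), each = 10),
                     class = rep(c("catalytic", "allosteric"), each = 10))
  fe2 <- fisher_enrichment(composition_table(ann2))
  expect_equal(fe2$p[fe2$item == "K"], 2 / choose(20, 10),
               tolerance = 1e-9)

  # property: agreement with the enumeration oracle for margins <= 30
  set.seed(13)
  for (rep in 1:25) {
    nA <- sample(5:15, 1); nB <- sample(5:15, 1)
    kA <- rbinom(1, nA, 0.4); kB <- rbinom(1, nB, 0.4)
    ann3 <- data.frame(
      aa = c(rep("K", kA), rep("L", nA - kA),
             rep("K", kB), rep("L", nB - kB)),
      class = rep(c("catalytic", "allosteric"), times = c(nA, nB)))
    fe3 <- fisher_enrichment(composition_table(ann3))
    expect_equal(fe3$p[fe3$item == "K"],
                 fisher_exact_oracle(kA, kB, nA - kA, nB - kB),
                 tolerance = 1e-9)
  }

  empty_tab <- suppressWarnings(
    composition_table(data.frame(aa = character(0),
                                 class = character(0))))
  expect_error(fisher_enrichment(empty_tab), "all-zero")
})

test_that("group-level enrichment separates charged from hydrophobic pockets", {
  ann <- data.frame(
    aa = c(rep(c("K", "D", "E", "H"), 5), rep(c("L", "V", "F", "I"), 5)),
    class = rep(c("catalytic", "allosteric"), each = 20))
  fe <- fisher_enrichment(composition_table(ann), by = "group")
  expect_lt(fe$p[fe$item == "charged"], 0.005)
  expect_lt(fe$p[fe$item == "hydrophobic"], 0.005)
  expect_gt(fe$odds_ratio[fe$item == "charged"], 1)
  expect_lt(fe$odds_ratio[fe$item == "hydrophobic"], 1)
})

test_that("both tests hold their nominal size under the null", {
  set.seed(42)
  fisher_rej <- replicate(1000, {
    a <- rbinom(1, 150, 0.3); b <- rbinom(1, 150, 0.3)
    ann <- data.frame(
      aa = c(rep("K", a), rep("L", 150 - a), rep("K", b),
             rep("L", 150 - b)),
      class = rep(c("catalytic", "allosteric"), each = 150))
    fe <- fisher_enrichment(composition_table(ann))
    fe$p[fe$item == "K"] < 0.05
  })
  expect_gte(mean(fisher_rej), 0.03)
  expect_lte(mean(fisher_rej), 0.07)

  mw_rej <- replicate(1000, mann_whitney(rnorm(25), rnorm(25))$p < 0.05)
  expect_gte(mean(mw_rej), 0.03)
  expect_lte(mean(mw_rej), 0.07)
})

test_that("null p-values of the rank-sum test are uniform", {
  set.seed(5)
  ps <- replicate(1000, mann_whitney(rnorm(30), rnorm(30))$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
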