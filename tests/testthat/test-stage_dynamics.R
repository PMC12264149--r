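# Normalization, decay/ZGA classification, entropy, homologs, stat kernels.

mk_em <- function(values, stages = NULL) {
  # values: named list gene -> per-stage vector (single replicate)
  m <- do.call(rbind, values)
  if (is.null(stages)) stages <- paste0("S", seq_len(ncol(m)))
  colnames(m) <- paste0(stages, "_rep1")
  samples <- data.frame(sample = colnames(m), stage = stages, replicate = 1,
                        stringsAsFactors = FALSE)
  expression_matrix(m, samples)
}

test_that("median-of-ratios normalization matches hand computation", {
  m <- matrix(c(2, 10, 6, 4, 20, 12), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("A_rep1", "B_rep1")))
  em <- expression_matrix(m, data.frame(sample = colnames(m),
                                        stage = c("A", "B"), replicate = 1))
  norm <- normalize_expression(em)
  # B = 2A: factors (1/sqrt(2), sqrt(2))
  expect_equal(unname(norm$size_factors), c(1 / sqrt(2), sqrt(2)))
  expect_equal(norm$values[, 1], m[, 1] * sqrt(2))

  # single sample -> factor 1, unchanged
  em1 <- expression_matrix(m[, 1, drop = FALSE],
                           data.frame(sample = "A_rep1", stage = "A",
                                      replicate = 1))
  expect_equal(unname(normalize_expression(em1)$size_factors), 1)
  # identical samples -> all factors 1
  mm <- cbind(A_rep1 = m[, 1], B_rep1 = m[, 1])
  em2 <- expression_matrix(mm, data.frame(sample = colnames(mm),
                                          stage = c("A", "B"),
                                          replicate = 1))
  expect_equal(unname(normalize_expression(em2)$size_factors), c(1, 1))
  # no gene positive everywhere -> error
  m0 <- matrix(c(0, 1, 1, 0), 2,
               dimnames = list(c("g1", "g2"), c("A_rep1", "B_rep1")))
  em0 <- expression_matrix(m0, data.frame(sample = colnames(m0),
                                          stage = c("A", "B"),
                                          replicate = 1))
  expect_error(normalize_expression(em0), "positive")
})

test_that("decay/ZGA rules are evaluated literally", {
  stages <- c("GV", "MII", "1C", "8C")
  em <- mk_em(list(
    md   = c(40, 25, 12, 8),     # all five M-decay conditions hold
    zd   = c(20, 18, 24, 4),     # Z-decay example (1C/GV = 1.2 < 1.5)
    zga  = c(0.2, 0.4, 3, 30),
    lowgv = c(5, 4, 1, 1),       # fails condition (1) of both decay sets
    none = c(15, 14, 13, 12)
  ), stages)
  cls <- classify_maternal_zga(em)
  lab <- stats::setNames(cls$label, cls$gene_id)
  expect_equal(unname(lab[c("md", "zd", "zga", "lowgv")]),
               c("M-decay", "Z-decay", "ZGA", "none"))
  expect_true(cls$md[cls$gene_id == "zd"])
  # missing stage is an error naming it
  expect_error(classify_maternal_zga(mk_em(list(g = c(1, 2, 3)),
                                           c("GV", "MII", "1C"))),
               "8C")
})

test_that("zero-denominator fold changes follow the stated conventions", {
  stages <- c("GV", "MII", "1C", "8C")
  # GV/1C = 12/0 -> +Inf > 2: M-decay can fire on a zero zygote
  em <- mk_em(list(g = c(12, 10, 0, 0)), stages)
  expect_equal(classify_maternal_zga(em)$label, "M-decay")
  # ZGA: 8C > 1C with 1C = 0; GV = MII = 0
  em2 <- mk_em(list(g = c(0, 0, 0, 30)), stages)
  expect_equal(classify_maternal_zga(em2)$label, "ZGA")
})

test_that("replicates are averaged per stage before rule evaluation", {
  m <- matrix(c(8, 16, 9, 9, 4, 4, 2, 2), nrow = 1)  # GV mean 12 > 10
  dimnames(m) <- list("g", c("GV_rep1", "GV_rep2", "MII_rep1", "MII_rep2",
                             "1C_rep1", "1C_rep2", "8C_rep1", "8C_rep2"))
  samples <- data.frame(sample = colnames(m),
                        stage = rep(c("GV", "MII", "1C", "8C"), each = 2),
                        replicate = rep(1:2, 4))
  em <- expression_matrix(m, samples)
  expect_equal(classify_maternal_zga(em)$label, "M-decay")
})

test_that("entropy specificity matches hand values and invariances", {
  expect_equal(entropy_specificity(c(10, 10, 10, 10)), 0)
  expect_equal(entropy_specificity(c(12, 0, 0, 0)), 2)   # log2(4)
  expect_equal(entropy_specificity(c(30, 10)),
               0.75 * log2(1.5) + 0.25 * log2(0.5))
  # permutation and scale invariance
  set.seed(9)
  x <- runif(8, 0, 50)
  expect_equal(entropy_specificity(x), entropy_specificity(sample(x)))
  expect_equal(entropy_specificity(x), entropy_specificity(17 * x))
  expect_error(entropy_specificity(c(0, 0, 0)), "all-zero")
})

test_that("homolog expression categories follow the printed thresholds", {
  hs <- c("8C")
  mk2 <- function(v, genes) {
    m <- matrix(v, ncol = 1, dimnames = list(genes, "8C_rep1"))
    expression_matrix(m, data.frame(sample = "8C_rep1", stage = "8C",
                                    replicate = 1))
  }
  mk2m <- function(v, genes) {
    m <- matrix(v, ncol = 1, dimnames = list(genes, "2C_rep1"))
    expression_matrix(m, data.frame(sample = "2C_rep1", stage = "2C",
                                    replicate = 1))
  }
  hom <- data.frame(human_gene = c("h1", "h2", "h3", "h4"),
                    mouse_gene = c("m1", "m2", "m3", "m4"))
  human <- mk2(c(60, 60, 60, 5), hom$human_gene)
  mouse <- mk2m(c(55, 5, 30, 60), hom$mouse_gene)
  res <- classify_homolog_expression(human, mouse, hom, c("8C" = "2C"))
  expect_equal(res$category,
               c("co-expressed", "human-specific", "ambiguous",
                 "mouse-specific"))
  expect_error(classify_homolog_expression(human, mouse, hom,
                                           c("BLT" = "2C")),
               "unpaired")
})

test_that("homology loader drops many-to-one pairs", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("human_gene\tmouse_gene", "h1\tm1", "h2\tm2", "h3\tm2",
               "h4\tm4", "h4\tm5"), path)
  expect_message(tab <- read_homology_table(path), "4 removed")
  expect_equal(tab$human_gene, c("h1"))
})

test_that("one-sided Fisher equals hypergeometric enumeration (margins <= 15)", {
  for (r1 in c(0, 1, 3, 7, 15)) for (r2 in c(0, 2, 5, 15)) {
    for (a in 0:r1) for (c in 0:r2) {
      tab <- matrix(c(a, r1 - a, c, r2 - c), 2, byrow = TRUE)
      if (sum(tab) == 0) next
      expect_equal(fisher_one_sided(tab)$p_value, min(1, oracle_fisher(tab)),
                   tolerance = 1e-12)
    }
  }
  # the classic fully-separated table
  expect_equal(fisher_one_sided(matrix(c(10, 0, 0, 10), 2,
                                       byrow = TRUE))$p_value,
               1 / choose(20, 10), tolerance = 1e-12)
})

test_that("exact Wilcoxon equals full rank enumeration (n <= 8)", {
  set.seed(21)
  for (ns in list(c(2, 6), c(3, 5), c(4, 4), c(5, 3), c(8, 8))) {
    for (rep in 1:3) {
      x <- runif(ns[1]); y <- runif(ns[2])
      got <- wilcoxon_rank_sum(x, y)
      expect_true(got$exact)
      expect_equal(got$p_value, oracle_wilcoxon(x, y), tolerance = 1e-12)
    }
  }
  # identical groups -> p = 1 (ties force the corrected approximation)
  g <- rep(1:3, 2)
  expect_equal(wilcoxon_rank_sum(g, g)$p_value, 1)
  # agreement with the reference implementation in the tied/large regime
  set.seed(22)
  x <- round(rnorm(40), 1); y <- round(rnorm(35, 0.4), 1)
  ours <- wilcoxon_rank_sum(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("compare_groups carries the five-percentile summary", {
  res <- compare_groups(1:100, 1:100)
  expect_equal(res$p_value, 1)
  s <- res$summary
  expect_equal(s$median, c(50.5, 50.5))
  expect_equal(s$mean, c(50.5, 50.5))
  expect_equal(s$p5, c(5.95, 5.95))    # type-7 linear interpolation
  expect_true(all(diff(unlist(s[1, c("p5", "p25", "median", "p75",
                                     "p95")])) >= 0))
  expect_error(compare_groups(numeric(0), 1:3), "empty")
  fres <- compare_groups(test = "fisher_one_sided",
                         table = matrix(c(8, 2, 3, 7), 2, byrow = TRUE))
  expect_equal(fres$summary$proportion, c(0.8, 0.3))
})
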