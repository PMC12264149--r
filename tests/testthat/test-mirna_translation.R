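# miRNA RPM, targeting association, translation efficiency.

mk_mirna <- function(counts, stage = "GV") {
  samples <- data.frame(sample = colnames(counts), stage = stage,
                        replicate = seq_len(ncol(counts)),
                        stringsAsFactors = FALSE)
  mirna_rpm(counts, samples)
}

test_that("RPM normalization and stage averaging follow the definitions", {
  counts <- matrix(c(5, 999995, 10, 999990), ncol = 2,
                   dimnames = list(c("miR-a", "miR-b"), c("s1", "s2")))
  me <- mk_mirna(counts)
  expect_equal(unname(me$rpm["miR-a", ]), c(5, 10))
  expect_equal(unname(me$stage_rpm["miR-a", "GV"]), 7.5)
  # RPM conservation: each replicate sums to 1e6
  expect_equal(unname(colSums(me$rpm)), c(1e6, 1e6))
  # all-zero miRNA keeps RPM 0
  counts2 <- rbind(counts, `miR-z` = c(0, 0))
  expect_equal(unname(mk_mirna(counts2)$stage_rpm["miR-z", "GV"]), 0)
  # zero-total replicate is an error
  counts3 <- counts; counts3[, 2] <- 0
  expect_error(mk_mirna(counts3), "zero-total")
})

mk_targeting_fixture <- function(rpms) {
  # three miRNAs in distinct conserved families targeting gene gX
  counts <- matrix(round(rpms), ncol = 1,
                   dimnames = list(paste0("miR-", seq_along(rpms)), "s1"))
  counts <- rbind(counts, filler = 1e6 - sum(counts))
  samples <- data.frame(sample = "s1", stage = "GV", replicate = 1)
  fams <- data.frame(mirna = rownames(counts),
                     family = paste0("f", seq_len(nrow(counts))),
                     conserved = c(rep(TRUE, length(rpms)), FALSE))
  mirna_rpm(counts, samples, fams)
}

test_that("weighted miRNA counts are the sum of log10 RPM", {
  calls <- data.frame(gene_id = c("gX", "gY"), status = c("m6A+", "m6A-"),
                      stringsAsFactors = FALSE)
  map <- data.frame(family = c("f1", "f2"), gene_id = "gX")
  # miR-1 at RPM 100, miR-2 at RPM 1000 -> weighted 2 + 3 = 5
  me <- mk_targeting_fixture(c(100, 1000))
  res <- mirna_targeting(calls, map, me, "GV", coding_genes = c("gX", "gY"))
  gx <- res$genes[res$genes$gene_id == "gX", ]
  expect_true(gx$targeted)
  expect_equal(gx$n_mirnas, 2)
  expect_equal(gx$weighted, 5)
  # single miRNA at RPM 100 -> (targeted, 1, 2)
  res1 <- mirna_targeting(calls, map[1, , drop = FALSE],
                          mk_targeting_fixture(c(100, 1000)), "GV",
                          coding_genes = c("gX", "gY"))
  gx1 <- res1$genes[res1$genes$gene_id == "gX", ]
  expect_equal(c(gx1$n_mirnas, gx1$weighted), c(1, 2))
  # below the RPM floor -> not targeted; boundary RPM 10 counts (log10 = 1)
  me_low <- mk_targeting_fixture(c(9, 10))
  res2 <- suppressMessages(
    mirna_targeting(calls, map, me_low, "GV",
                    coding_genes = c("gX", "gY")))
  gx2 <- res2$genes[res2$genes$gene_id == "gX", ]
  expect_equal(c(gx2$n_mirnas, gx2$weighted), c(1, 1))
  expect_error(mirna_targeting(calls, map[0, ], me, "GV",
                               coding_genes = "gX"),
               "empty")
})

test_that("non-coding genes and non-conserved families are excluded", {
  calls <- data.frame(gene_id = c("gX", "gL"), status = c("m6A+", "m6A+"))
  me <- mk_targeting_fixture(c(100))
  map <- data.frame(family = c("f1", "f2"), gene_id = c("gX", "gX"))
  # f2 is the non-conserved filler family: does not count
  res <- mirna_targeting(calls, map, me, "GV", coding_genes = "gX")
  expect_equal(nrow(res$genes), 1)   # gL dropped (non-coding)
  expect_equal(res$genes$n_mirnas, 1)
})

test_that("translation efficiency applies the +1 ratio and FPKM floor", {
  mk_fpkm <- function(v, genes) {
    m <- matrix(rep(v, 2), ncol = 2,
                dimnames = list(genes, c("GV_rep1", "GV_rep2")))
    expression_matrix(m, data.frame(sample = colnames(m), stage = "GV",
                                    replicate = 1:2), unit = "FPKM")
  }
  genes <- c("g1", "g2", "g3")
  ribo <- mk_fpkm(c(19, 39, 5), genes)
  mrna <- mk_fpkm(c(19, 19, 9), genes)
  te <- translation_efficiency(ribo, mrna)
  expect_equal(te$te, c(1, 2, 0.6))
  expect_equal(te$included, c(TRUE, TRUE, FALSE))   # mRNA 9 < 10 excluded
  expect_error(translation_efficiency(ribo, mrna, stages = "BLT"),
               "missing stage")
  # replicate averaging: FPKM (10, 30) -> mean 20 -> TE (21ximately)/21
  m <- matrix(c(10, 30, 20, 20), nrow = 1,
              dimnames = list("g", c("GV_rep1", "GV_rep2", "x", "y")))
  ribo2 <- expression_matrix(m[, 1:2, drop = FALSE],
                             data.frame(sample = c("GV_rep1", "GV_rep2"),
                                        stage = "GV", replicate = 1:2),
                             unit = "FPKM")
  mrna2 <- expression_matrix(m[, 3:4, drop = FALSE] * 0 + 20,
                             data.frame(sample = c("x", "y"), stage = "GV",
                                        replicate = 1:2), unit = "FPKM")
  te2 <- translation_efficiency(ribo2, mrna2)
  expect_equal(te2$te, 21 / 21)
})

test_that("TE-by-region multi-membership convention", {
  te <- data.frame(gene_id = c("g1", "g2"), stage = "GV",
                   ribo_fpkm = c(30, 40), mrna_fpkm = c(20, 20),
                   te = c(31 / 21, 41 / 21), included = TRUE)
  asg <- rbind(
    data.frame(feature = "stop_codon", gene_id = "g1"),
    data.frame(feature = "CDS", gene_id = "g2"),
    data.frame(feature = "3UTR", gene_id = "g2"))
  res <- te_by_peak_region(te, "GV", asg, constant_m6a_genes = c("g1", "g2"))
  expect_equal(sort(res$membership$feature[res$membership$gene_id == "g2"]),
               c("3UTR", "CDS"))   # contributes to both regions
  expect_equal(res$membership$feature[res$membership$gene_id == "g1"],
               "stop_codon")
  expect_equal(nrow(res$summary), 3)
  expect_warning(te_by_peak_region(te, "GV", asg, character(0)), "no constant")
})
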