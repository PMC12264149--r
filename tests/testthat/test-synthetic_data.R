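# Generator contracts: determinism, config echo, planted-rule consistency,
# coverage conservation, condition limit cases.

test_that("identical config and seed give identical outputs", {
  cfg <- small_sim_config()
  s1 <- simulate_annotation(cfg, seed = 5)
  s2 <- simulate_annotation(cfg, seed = 5)
  expect_identical(s1$bundle$exons, s2$bundle$exons)
  expect_identical(as.character(s1$bundle$sequence),
                   as.character(s2$bundle$sequence))
  expect_identical(s1$repeats, s2$repeats)
  expect_identical(s1$truth$classes, s2$truth$classes)
  # byte-identical files
  f1 <- tempfile(); f2 <- tempfile()
  write_gene_models(s1$bundle, f1); write_gene_models(s2$bundle, f2)
  expect_identical(readLines(f1), readLines(f2))
  e1 <- simulate_stage_experiment(cfg, s1, seed = 9, tracks = FALSE)
  e2 <- simulate_stage_experiment(cfg, s2, seed = 9, tracks = FALSE)
  expect_identical(e1$expression$values, e2$expression$values)
})

test_that("config is echoed: gene counts, class counts, stages", {
  sm <- small_simulation()
  cfg <- sm$cfg
  expect_equal(nrow(sm$sim$bundle$genes), cfg$n_genes)
  expect_equal(as.integer(table(sm$sim$truth$classes$class)[
    c("m_decay", "z_decay", "zga", "constant")]),
    unname(cfg$class_counts))
  expect_equal(unique(sm$exp$expression$samples$stage), cfg$stages)
  expect_error(simulate_annotation(sim_config(n_genes = 5000,
                                              chrom_length = 1e6)),
               "too small")
})

test_that("planted classes satisfy exactly their printed rules on emitted matrices", {
  sm <- small_simulation()
  cls <- classify_maternal_zga(sm$exp$expression)
  truth <- sm$sim$truth$classes
  planted <- stats::setNames(truth$class, truth$gene_id)[cls$gene_id]
  map <- c(m_decay = "M-decay", z_decay = "Z-decay", zga = "ZGA")
  for (cl in names(map)) {
    expect_true(all(cls$label[planted == cl] == map[[cl]]),
                label = sprintf("recall for %s", cl))
    expect_true(all(planted[cls$label == map[[cl]]] == cl),
                label = sprintf("precision for %s", cl))
  }
  # constant genes pass the entropy + floor rule, background passes nothing
  expect_true(all(cls$constant[planted == "constant"]))
  expect_true(all(cls$label[planted == "background"] == "none"))
})

test_that("margin <= 1 is rejected", {
  cfg <- small_sim_config()
  cfg$margin <- 1
  sim <- simulate_annotation(cfg)
  expect_error(simulate_stage_experiment(cfg, sim), "margin")
})

test_that("ZGA plants satisfy the printed inequalities with margin", {
  sm <- small_simulation()
  sm_tpm <- sm$exp$stage_tpm
  zga <- sm$sim$truth$classes$gene_id[sm$sim$truth$classes$class == "zga"]
  expect_true(all(sm_tpm[zga, "GV"] < 1 & sm_tpm[zga, "MII"] < 1))
  expect_true(all(sm_tpm[zga, "8C"] > 10))
  expect_true(all(sm_tpm[zga, "8C"] > sm_tpm[zga, "1C"]))
})

test_that("coverage conservation: emitted fragments equal configured depth", {
  sm <- small_simulation()
  tr <- sm$exp$tracks$GV$rep1
  # total is carried through; RPKM sums recover the fragment count scale:
  # sum over bins of n_b = sum over fragments of (#bins overlapped)
  expect_equal(tr$input$total, sm$cfg$depth)
  counts <- sum(unlist(tr$input$values)) *
    (sm$cfg$bin_size / 1000) * (sm$cfg$depth / 1e6)
  mean_bins_per_frag <- counts / sm$cfg$depth
  expect_gte(mean_bins_per_frag, 1)   # every fragment hit >= 1 bin
  expect_lte(mean_bins_per_frag, 1 + (sm$cfg$frag_len + 4 * sm$cfg$frag_sd) /
               sm$cfg$bin_size)
})

test_that("null IP model: enrichment 1 gives near-zero signal", {
  cfg <- sim_config(n_genes = 40, chrom_length = 4e5, depth = 1e5,
                    class_counts = c(m_decay = 4, z_decay = 4, zga = 4,
                                     constant = 4),
                    enrichment = 1,
                    repeat_model = list(
                      list(subfamily = "AluY", class = "SINE",
                           family = "Alu", consensus = 300, n = 4)),
                    seed = 8)
  sim <- simulate_annotation(cfg, sequence = FALSE)
  exp <- simulate_stage_experiment(cfg, sim)
  s <- exp$tracks$GV$rep1$signal
  expect_lt(abs(mean(unlist(s$values))), 0.05)
})

test_that("replicate noise 0 gives identical replicate matrices", {
  cfg <- small_sim_config()
  cfg$replicate_cv <- 0
  sim <- simulate_annotation(cfg, sequence = FALSE)
  exp <- simulate_stage_experiment(cfg, sim, tracks = FALSE)
  v <- exp$expression$values
  expect_equal(v[, "GV_rep1"], v[, "GV_rep2"])
})

test_that("condition limit cases behave as stated", {
  cfg <- sim_config(n_genes = 40, chrom_length = 5e5, depth = 5e4,
                    class_counts = c(constant = 20),
                    repeat_model = list(
                      list(subfamily = "THE1C", class = "LTR",
                           family = "THE1", consensus = 350, n = 20,
                           type = "solo")),
                    inhibitor_reduction = 0, seed = 13)
  sim <- simulate_annotation(cfg, sequence = FALSE)
  cond <- simulate_condition_experiment(cfg, sim)
  # reduction 0: treated m6A signal <= 0 at every planted peak
  sig <- cond$tracks$treated$rep1$signal
  sites <- sim$truth$peak_sites
  sites <- sites[sites$gene_id %in% sim$truth$m6a_genes, ]
  for (i in seq_len(nrow(sites))) {
    b <- sites$summit[i] %/% cfg$bin_size + 1
    expect_lte(sig$values[[sites$chrom[i]]][b], 0)
  }
  # reduction 1: Ctrl and treated drawn from the same model
  cfg1 <- cfg; cfg1$inhibitor_reduction <- 1
  cond1 <- simulate_condition_experiment(cfg1, sim)
  m_ctrl <- mean(unlist(cond1$tracks$Ctrl$rep1$signal$values))
  m_trt <- mean(unlist(cond1$tracks$treated$rep1$signal$values))
  expect_lt(abs(m_ctrl - m_trt), 0.05)
})

test_that("incomplete repeat fraction is recovered by the completeness filter", {
  cfg <- sim_config(n_genes = 20, chrom_length = 1.2e6, depth = 1e4,
                    class_counts = c(constant = 5),
                    incomplete_frac = 0.3,
                    repeat_model = list(
                      list(subfamily = "THE1C", class = "LTR",
                           family = "THE1", consensus = 350, n = 400,
                           type = "solo")),
                    seed = 17)
  sim <- simulate_annotation(cfg, sequence = FALSE)
  loci <- suppressMessages(filter_repeat_loci(sim$repeats, sim$consensus,
                                              sim$bundle))
  frac_kept <- nrow(loci) / nrow(sim$repeats)
  # ~30% drawn below 0.9 completeness are removed
  expect_lt(abs(frac_kept - 0.7), 0.06)
})
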