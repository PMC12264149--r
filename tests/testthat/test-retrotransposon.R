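# Repeat locus filtering, scoring, summaries, profiles, condition compare.

mk_repeats <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(subfamily = r[[1]], class = r[[2]], family = r[[3]],
               chrom = r[[4]], start = as.integer(r[[5]]),
               end = as.integer(r[[6]]), strand = r[[7]], segment = r[[8]],
               stringsAsFactors = FALSE)
  }))
}

empty_bundle <- function(sizes = c(chrR = 1e5)) {
  g <- data.frame(gene_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0),
                  strand = character(0), biotype = character(0))
  t <- cbind(data.frame(transcript_id = character(0)), g)
  e <- data.frame(transcript_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0),
                  strand = character(0), rank = integer(0))
  annotation_bundle(g, t[, c("transcript_id", "gene_id", "chrom", "start",
                             "end", "strand", "biotype")], e,
                    chrom_sizes = sizes)
}

test_that("completeness filter is exact and closed at 0.9", {
  cons <- c(L1HS = 6000)
  b <- empty_bundle()
  reps <- mk_repeats(
    list("L1HS", "LINE", "L1", "chrR", 1000, 1000 + 5400, "+", "single"),
    list("L1HS", "LINE", "L1", "chrR", 10000, 10000 + 5399, "+", "single"),
    list("L1HS", "LINE", "L1", "chrR", 20000, 20000 + 6000, "-", "single"))
  loci <- suppressMessages(filter_repeat_loci(reps, cons, b))
  expect_equal(nrow(loci), 2)        # 5400/6000 = 0.90 kept, 5399 dropped
  expect_equal(loci$completeness, c(0.9, 1.0))
  expect_error(suppressMessages(
    filter_repeat_loci(mk_repeats(list("NEW", "SINE", "x", "chrR", 1, 300,
                                       "+", "single")), cons, b)),
    "NEW")
})

test_that("full-length ERV assembly requires LTR-internal-LTR runs", {
  cons <- c(LTR7 = 400, `HERVH-int` = 2000, HERVH = 2800)
  b <- empty_bundle()
  reps <- mk_repeats(
    # full-length: LTR + internal + LTR within the gap tolerance
    list("LTR7", "LTR", "HERVH", "chrR", 1000, 1400, "+", "LTR"),
    list("HERVH-int", "LTR", "HERVH", "chrR", 1450, 3400, "+", "internal"),
    list("LTR7", "LTR", "HERVH", "chrR", 3450, 3850, "+", "LTR"),
    # LTR pair without internal -> two solo candidates
    list("LTR7", "LTR", "HERVH", "chrR", 10000, 10400, "+", "LTR"),
    list("LTR7", "LTR", "HERVH", "chrR", 10450, 10850, "+", "LTR"),
    # triple split by a gap > tolerance -> no full-length
    list("LTR7", "LTR", "HERVH", "chrR", 20000, 20400, "+", "LTR"),
    list("HERVH-int", "LTR", "HERVH", "chrR", 21200, 23200, "+", "internal"),
    list("LTR7", "LTR", "HERVH", "chrR", 23250, 23650, "+", "LTR"),
    # opposite strand breaks the run
    list("LTR7", "LTR", "HERVH", "chrR", 30000, 30400, "+", "LTR"),
    list("HERVH-int", "LTR", "HERVH", "chrR", 30450, 32450, "-", "internal"),
    list("LTR7", "LTR", "HERVH", "chrR", 32500, 32900, "+", "LTR"))
  loci <- suppressMessages(filter_repeat_loci(reps, cons, b, gap_tol = 500))
  full <- loci[loci$architecture == "full_length_ERV", ]
  expect_equal(nrow(full), 1)
  expect_equal(c(full$start, full$end), c(1000, 3850))
  expect_equal(full$subfamily, "HERVH")
  # the split triple: internal+LTR run is not full-length; its LTRs are solo
  solo <- loci[loci$architecture == "solo", ]
  expect_equal(nrow(solo), 6)       # 2 (pair) + 2 (split) + 2 (strand break)
})

test_that("loci intersecting gene exons are excluded", {
  b <- tiny_bundle()
  cons <- c(AluY = 300)
  reps <- mk_repeats(
    list("AluY", "SINE", "Alu", "chrT", 390, 690, "+", "single"),  # hits exon
    list("AluY", "SINE", "Alu", "chrT", 7000, 7300, "+", "single"))
  loci <- suppressMessages(filter_repeat_loci(reps, cons, b))
  expect_equal(nrow(loci), 1)
  expect_equal(loci$start, 7000)
})

test_that("max-over-bins scoring equals the per-base oracle and averages replicates", {
  sizes <- c(chrR = 1000)
  set.seed(31)
  mk_tr <- function(kind) {
    v <- if (kind == "rpkm") stats::rexp(100) else stats::rnorm(100)
    binned_track(list(chrR = v), 10, sizes, kind = kind)
  }
  in1 <- mk_tr("rpkm"); in2 <- mk_tr("rpkm")
  s1 <- mk_tr("signal"); s2 <- mk_tr("signal")
  loci <- data.frame(locus_id = sprintf("L%02d", 1:30),
                     subfamily = "X", class = "LINE", family = "X",
                     chrom = "chrR",
                     start = sample.int(800, 30), strand = "+",
                     completeness = 1, architecture = "n/a")
  loci$end <- loci$start + sample(20:150, 30, replace = TRUE)
  sc <- score_repeat_loci(loci, list(in1, in2), list(s1, s2))
  for (i in seq_len(nrow(loci))) {
    expect_equal(sc$expression[i],
                 mean(c(oracle_locus_max(in1, "chrR", loci$start[i], loci$end[i]),
                        oracle_locus_max(in2, "chrR", loci$start[i], loci$end[i]))))
    expect_equal(sc$m6a_signal[i],
                 mean(c(oracle_locus_max(s1, "chrR", loci$start[i], loci$end[i]),
                        oracle_locus_max(s2, "chrR", loci$start[i], loci$end[i]))))
  }
  # monotonicity: shrinking a locus never increases max-based scores
  shrunk <- loci
  shrunk$start <- shrunk$start + 10
  shrunk$end <- pmax(shrunk$end - 10, shrunk$start + 5)
  sc2 <- score_repeat_loci(shrunk, list(in1, in2), list(s1, s2))
  expect_true(all(sc2$expression <= sc$expression + 1e-12))
  # out-of-bounds locus errors
  bad <- loci[1, ]; bad$end <- 2000
  expect_error(score_repeat_loci(bad, list(in1), list(s1)), "bounds")
})

test_that("subfamily summary counts expressed and modified loci", {
  sc <- data.frame(subfamily = rep(c("A", "B"), c(12, 4)),
                   expressed = c(rep(TRUE, 10), FALSE, FALSE, rep(FALSE, 4)),
                   modified = c(rep(TRUE, 5), rep(FALSE, 7), rep(FALSE, 4)))
  s <- subfamily_summary(sc)
  expect_equal(s$n_expressed, c(10, 0))
  expect_equal(s$percent_modified, c(50, NA_real_))
})

test_that("element profiles are strand-oriented 5' to 3'", {
  sizes <- c(chrR = 2000)
  ramp <- binned_track(list(chrR = seq(0, 1.99, by = 0.01)), 10, sizes,
                       kind = "signal")
  plus <- data.frame(subfamily = "S", chrom = "chrR", start = 500, end = 1500,
                     strand = "+")
  minus <- plus; minus$strand <- "-"
  p1 <- element_profile(plus, ramp, n_bins = 10)
  p2 <- element_profile(minus, ramp, n_bins = 10)
  expect_true(all(diff(p1$mean) > 0))      # rises along the genomic ramp
  expect_equal(p2$mean, rev(p1$mean))      # minus strand reversed
  expect_true(all(p1$sd == 0))             # single locus -> SD 0
  # constant signal -> mean constant, SD 0 across several loci
  flat <- binned_track(list(chrR = rep(1, 200)), 10, sizes, kind = "signal")
  many <- do.call(rbind, lapply(c(100, 600, 1200), function(s) {
    data.frame(subfamily = "S", chrom = "chrR", start = s, end = s + 300,
               strand = "+")
  }))
  pf <- element_profile(many, flat, n_bins = 20)
  expect_equal(pf$mean, rep(1, 20))
  expect_equal(pf$sd, rep(0, 20))
  expect_equal(pf$n_loci, 3)
})

test_that("condition peak comparison arithmetic", {
  loci <- data.frame(subfamily = "S", chrom = "chrR",
                     start = seq(0, 990, by = 10), strand = "+")
  loci$end <- loci$start + 8
  mk_pk <- function(n) {
    if (n == 0) return(peak_row("chrR", 5000, 5100)[0, ])
    do.call(rbind, lapply(seq_len(n), function(i) {
      peak_row("chrR", (i - 1) * 10, (i - 1) * 10 + 5)
    }))
  }
  res <- condition_peak_comparison(mk_pk(100), mk_pk(53), loci)
  expect_equal(res$reduction_percent, 47)
  res_same <- condition_peak_comparison(mk_pk(40), mk_pk(40), loci)
  expect_equal(res_same$reduction_percent, 0)
  far <- peak_row("chrR", 5000, 5100)
  res_none <- condition_peak_comparison(far, far, loci)
  expect_equal(res_none$n_ctrl, 0)
  expect_true(is.na(res_none$reduction_percent))
})
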