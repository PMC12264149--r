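# Feature hierarchy, enrichment, metagene arithmetic, gene calls, RRACH.

test_that("peak assignment follows the stop-codon-first hierarchy", {
  b <- tiny_bundle()
  # GA stop codon is [2200,2203); +/-200 window is [2000,2403)
  a <- assign_peak_features(peak_row("chrT", 2290, 2310), b)
  expect_equal(a$feature, "stop_codon")   # 100 bp downstream of the stop

  # past the window but inside the annotated 3'UTR
  a <- assign_peak_features(peak_row("chrT", 2480, 2560), b)
  expect_equal(a$feature, "3UTR")
  expect_equal(a$transcript_id, "GA.t1")

  a <- assign_peak_features(peak_row("chrT", 120, 180), b)
  expect_equal(a$feature, "5UTR")
  a <- assign_peak_features(peak_row("chrT", 1100, 1200), b)
  expect_equal(a$feature, "CDS")
  a <- assign_peak_features(peak_row("chrT", 600, 700), b)   # GA intron 1
  expect_equal(a$feature, "intron")
  a <- assign_peak_features(peak_row("chrT", 8000, 8100), b)
  expect_equal(a$feature, "intergenic")
  expect_true(is.na(a$transcript_id))

  # minus-strand gene: stop window [5097,5500); 3'UTR beyond it
  a <- assign_peak_features(peak_row("chrT", 5010, 5060), b)
  expect_equal(a$feature, "3UTR")
  expect_equal(a$gene_id, "GB")
})

test_that("hierarchy-masked lengths partition the genome", {
  b <- tiny_bundle()
  fm <- feature_masks(b)
  expect_equal(sum(fm$lengths), sum(b$chrom_sizes))
  expect_true(all(fm$lengths >= 0))
  # every peak gets exactly one label and counts sum to the total
  set.seed(3)
  n <- 200
  start <- sample.int(9900, n)
  pk <- do.call(rbind, lapply(start, function(s) peak_row("chrT", s, s + 50)))
  a <- assign_peak_features(pk, b)
  expect_equal(sum(table(a$feature)), n)
})

test_that("feature enrichment follows log2(observed/expected)", {
  b <- tiny_bundle()
  pk <- do.call(rbind, lapply(c(2290, 2300, 2310, 2320), function(s) {
    peak_row("chrT", s, s + 10)
  }))
  fe <- feature_enrichment(pk, b)
  expect_s3_class(fe, "EnrichmentTable")
  expect_equal(sum(fe$expected), nrow(pk), tolerance = 1e-12)
  stop_row <- fe[fe$feature == "stop_codon", ]
  expect_equal(stop_row$observed, 4)
  expect_equal(stop_row$enrichment, log2(4 / stop_row$expected))
  expect_true(is.na(fe$enrichment[fe$observed == 0][1]))
  expect_error(feature_enrichment(pk[0, ], b), "empty")
})

test_that("metagene coordinates follow transcript-space arithmetic", {
  b <- tiny_bundle()
  # GA: u5 = 200, cds = 900, tail = 400 (stop + 3'UTR)
  cases <- list(
    list(summit = 100, expect = 0),           # first 5'UTR base
    list(summit = 2200, expect = 2),          # first stop-codon base
    list(summit = 1350, expect = 1.5),        # CDS midpoint (tx 650 = u5+450)
    list(summit = 200, expect = 0.5),         # 5'UTR midpoint (tx 100)
    list(summit = 2400, expect = 2.5)         # tail midpoint (tx 1300)
  )
  for (cs in cases) {
    mg <- metagene_profile(peak_row("chrT", cs$summit, cs$summit + 1,
                                    summit = cs$summit), b)
    expect_equal(mg$coords$coord, cs$expect, tolerance = 1e-9)
  }
  # minus strand: GB first stop base (genomic 5299, tx 700) -> 2.0
  mg <- metagene_profile(peak_row("chrT", 5299, 5300, summit = 5299), b)
  expect_equal(mg$coords$coord, 2)
  # intronic summit is skipped with a log line
  expect_message(
    mg0 <- metagene_profile(peak_row("chrT", 600, 601, summit = 600), b),
    "skipped")
  expect_equal(mg0$n_used, 0)
  # density sums to one
  mg2 <- metagene_profile(do.call(rbind, lapply(c(2200, 1350), function(s) {
    peak_row("chrT", s, s + 1, summit = s)
  })), b)
  expect_equal(sum(mg2$density$density), 1)
})

test_that("representative transcript picks highest expression then length", {
  sm <- small_simulation()
  b <- sm$sim$bundle
  two_iso <- names(which(table(b$transcripts$gene_id) == 2))
  expect_gt(length(two_iso), 0)
  g <- two_iso[1]
  txs <- b$transcripts$transcript_id[b$transcripts$gene_id == g]
  e <- stats::setNames(c(1, 5), txs)
  expect_equal(unname(representative_transcripts(b, e)[g]), txs[2])
  # tie -> longer transcript (isoform 1 here, its 3'UTR is untruncated)
  e2 <- stats::setNames(c(3, 3), txs)
  expect_equal(unname(representative_transcripts(b, e2)[g]), txs[1])
})

test_that("gene-level m6A calls use exon intersection and replicate union", {
  b <- tiny_bundle()
  exonic <- peak_row("chrT", 1100, 1200)       # GA exon 2
  intronic <- peak_row("chrT", 600, 700)       # GA intron
  calls <- call_m6a_genes(list(rep1 = exonic, rep2 = NULL), b)
  expect_equal(calls$status[calls$gene_id == "GA"], "m6A+")  # union rule
  expect_equal(calls$status[calls$gene_id == "GB"], "m6A-")
  # wholly intronic peak is m6A- in exon mode, m6A+ in span mode
  calls_i <- call_m6a_genes(list(rep1 = intronic), b)
  expect_equal(calls_i$status[calls_i$gene_id == "GA"], "m6A-")
  calls_s <- call_m6a_genes(list(rep1 = intronic), b, mode = "span")
  expect_equal(calls_s$status[calls_s$gene_id == "GA"], "m6A+")
  # expression floor
  calls_e <- call_m6a_genes(list(rep1 = exonic), b,
                            expr = c(GA = 0.5, GB = 2))
  expect_equal(calls_e$status, c("not_expressed", "m6A-"))
})

test_that("gene calls equal the all-pairs brute-force oracle", {
  sm <- small_simulation()
  b <- sm$sim$bundle
  set.seed(11)
  mk_peaks <- function(n) {
    chrom <- sample(names(b$chrom_sizes), n, replace = TRUE)
    start <- floor(runif(n, 0, b$chrom_sizes[chrom] - 300))
    do.call(rbind, lapply(seq_len(n), function(i) {
      peak_row(chrom[i], start[i], start[i] + sample(50:300, 1))
    }))
  }
  pbr <- list(rep1 = mk_peaks(120), rep2 = mk_peaks(120))
  calls <- call_m6a_genes(pbr, b)
  orc <- oracle_gene_calls(pbr, b)
  expect_equal(calls$status == "m6A+", unname(orc[calls$gene_id]))
})

test_that("RRACH counting matches a sliding-window oracle", {
  # single-exon plus-strand gene with a fully controlled sequence
  mk_seq_bundle <- function(seqstr) {
    L <- nchar(seqstr)
    genes <- data.frame(gene_id = "G", chrom = "chrS", start = 0L, end = L,
                        strand = "+", biotype = "protein_coding")
    txs <- data.frame(transcript_id = "G.t", gene_id = "G", chrom = "chrS",
                      start = 0L, end = L, strand = "+",
                      biotype = "protein_coding")
    ex <- data.frame(transcript_id = "G.t", chrom = "chrS", start = 0L,
                     end = L, strand = "+", rank = 1L)
    seqs <- Biostrings::DNAStringSet(seqstr); names(seqs) <- "chrS"
    annotation_bundle(genes, txs, ex, sequence = seqs,
                      chrom_sizes = c(chrS = L))
  }
  expect_equal(count_rrach(mk_seq_bundle("GGACT"))$count, 1)
  expect_equal(count_rrach(mk_seq_bundle("CCCCCCC"))$count, 0)
  expect_equal(count_rrach(mk_seq_bundle("GGACTAAACA"))$count, 2)
  set.seed(5)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
    res <- count_rrach(mk_seq_bundle(s))
    expect_identical(res$count, oracle_rrach(s))
    expect_equal(res$density_per_kb, res$count / 1)
  }
  expect_error(count_rrach(tiny_bundle()), "no sequence")
})

test_that("RRACH counting is strand-aware on the simulated genome", {
  sm <- small_simulation()
  b <- sm$sim$bundle
  minus_genes <- b$genes$gene_id[b$genes$strand == "-" &
                                   b$genes$biotype == "protein_coding"]
  res <- count_rrach(b, gene_ids = minus_genes[1:5])
  # independent check: reverse-complement concatenated exons, scan
  for (i in 1:5) {
    tx <- res$transcript_id[i]
    ex <- b$exons[b$exons$transcript_id == tx, ]
    ex <- ex[order(ex$start), ]
    pieces <- vapply(seq_len(nrow(ex)), function(j) {
      as.character(Biostrings::subseq(b$sequence[[ex$chrom[1]]],
                                      ex$start[j] + 1, ex$end[j]))
    }, character(1))
    sense <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(paste(pieces, collapse = ""))))
    expect_identical(res$count[i], oracle_rrach(sense))
  }
})
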