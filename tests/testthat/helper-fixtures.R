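# Fixtures built in code and brute-force oracles shared by the suite.

# Hand-constructed two-gene bundle on one 10-kb chromosome with known
# architecture; used wherever exact transcript-coordinate arithmetic is
# asserted.
#
#  GA (+): exons [100,400) [1000,1600) [2000,2600); 5'UTR 200, CDS 900
#          (tx [200,1100)), stop tx [1100,1103) = genomic [2200,2203),
#          3'UTR tx [1103,1500) = genomic [2203,2600).
#  GB (-): exons [5000,5500) [6000,6500); 5'UTR 100 (tx [0,100) =
#          genomic [6400,6500)), CDS 600 (tx [100,700)), stop genomic
#          [5297,5300), 3'UTR genomic [5000,5297).
tiny_bundle <- function(sequence = NULL) {
  genes <- data.frame(
    gene_id = c("GA", "GB"), chrom = "chrT",
    start = c(100L, 5000L), end = c(2600L, 6500L),
    strand = c("+", "-"), biotype = "protein_coding",
    stringsAsFactors = FALSE)
  transcripts <- data.frame(
    transcript_id = c("GA.t1", "GB.t1"), gene_id = c("GA", "GB"),
    chrom = "chrT", start = c(100L, 5000L), end = c(2600L, 6500L),
    strand = c("+", "-"), biotype = "protein_coding",
    stringsAsFactors = FALSE)
  exons <- data.frame(
    transcript_id = c("GA.t1", "GA.t1", "GA.t1", "GB.t1", "GB.t1"),
    chrom = "chrT",
    start = c(100L, 1000L, 2000L, 6000L, 5000L),
    end = c(400L, 1600L, 2600L, 6500L, 5500L),
    strand = c("+", "+", "+", "-", "-"),
    rank = c(1L, 2L, 3L, 1L, 2L), stringsAsFactors = FALSE)
  cds <- data.frame(
    transcript_id = c("GA.t1", "GA.t1", "GA.t1", "GB.t1", "GB.t1"),
    chrom = "chrT",
    start = c(300L, 1000L, 2000L, 6000L, 5300L),
    end = c(400L, 1600L, 2200L, 6400L, 5500L),
    strand = c("+", "+", "+", "-", "-"), stringsAsFactors = FALSE)
  stops <- data.frame(
    transcript_id = c("GA.t1", "GB.t1"), chrom = "chrT",
    start = c(2200L, 5297L), end = c(2203L, 5300L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  annotation_bundle(genes, transcripts, exons, cds, stops,
                    sequence = sequence, chrom_sizes = c(chrT = 10000))
}

# one-row peak data.frame helper
peak_row <- function(chrom, start, end, summit = NULL) {
  data.frame(chrom = chrom, start = start, end = end,
             name = "p", score = 0, strand = ".", signal = NA_real_,
             pvalue = NA_real_, qvalue = NA_real_,
             summit = summit %||% (start + (end - start) %/% 2),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# scaled-down repeat model reused by simulation-backed tests
small_repeat_model <- function() {
  list(
    list(subfamily = "L1HS", class = "LINE", family = "L1",
         consensus = 3000, n = 6),
    list(subfamily = "AluY", class = "SINE", family = "Alu",
         consensus = 300, n = 10),
    list(subfamily = "THE1C", class = "LTR", family = "THE1",
         consensus = 350, n = 10, type = "solo"),
    list(family = "HERVH", class = "LTR", type = "erv", n = 6,
         ltr_subfamily = "LTR7", int_subfamily = "HERVH-int",
         consensus_ltr = 400, consensus_int = 2000,
         full_frac = 0.6, no_int_frac = 0.2))
}

small_sim_config <- function(...) {
  sim_config(n_genes = 80, chrom_length = 7e5, depth = 3e4,
             class_counts = c(m_decay = 8, z_decay = 8, zga = 8,
                              constant = 8),
             repeat_model = small_repeat_model(), seed = 42, ...)
}

# cached small simulation + experiment (built once per test run)
.sim_cache <- new.env(parent = emptyenv())
small_simulation <- function() {
  if (is.null(.sim_cache$sim)) {
    cfg <- small_sim_config()
    .sim_cache$cfg <- cfg
    .sim_cache$sim <- simulate_annotation(cfg)
    .sim_cache$exp <- simulate_stage_experiment(cfg, .sim_cache$sim)
  }
  list(cfg = .sim_cache$cfg, sim = .sim_cache$sim, exp = .sim_cache$exp)
}

## ------------------------------------------------------------------
## independent brute-force oracles

# per-bin fragment overlap count, position by position
oracle_rpkm <- function(fragments, chrom_sizes, bin_size, total) {
  out <- lapply(names(chrom_sizes), function(chrom) {
    nb <- ceiling(chrom_sizes[[chrom]] / bin_size)
    v <- numeric(nb)
    d <- fragments[fragments$chrom == chrom, , drop = FALSE]
    for (b in seq_len(nb)) {
      lo <- (b - 1) * bin_size; hi <- b * bin_size
      if (nrow(d)) {
        v[b] <- sum(d$start < hi & d$end > lo)   # overlap >= 1 bp
      }
    }
    v / ((bin_size / 1000) * (total / 1e6))
  })
  names(out) <- names(chrom_sizes)
  out
}

# sliding-window RRACH scan on a character string
oracle_rrach <- function(seq) {
  n <- nchar(seq)
  if (n < 5) return(0L)
  hits <- 0L
  for (i in seq_len(n - 4L)) {
    w <- substr(seq, i, i + 4L)
    if (grepl("^[GA][GA]AC[ACT]$", w)) hits <- hits + 1L
  }
  hits
}

# one-sided (greater) Fisher p by exhaustive hypergeometric enumeration
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  sum(probs[xs >= a])
}

# exact two-sided Wilcoxon p by full enumeration of rank assignments
oracle_wilcoxon <- function(x, y) {
  nx <- length(x); ny <- length(y)
  rk <- rank(c(x, y))
  u_obs <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(ix) sum(seq_len(nx + ny)[ix]) -
                nx * (nx + 1) / 2)
  if (u_obs > nx * ny / 2) {
    p <- 2 * mean(us >= u_obs)
  } else {
    p <- 2 * mean(us <= u_obs)
  }
  min(1, p)
}

# per-base maximum over a locus, against the binned track
oracle_locus_max <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  per_base <- v[(start:(end - 1)) %/% track$bin_size + 1L]
  max(per_base)
}

# all-pairs gene/peak exon-overlap union call
oracle_gene_calls <- function(peaks_by_rep, bundle) {
  genes <- bundle$genes$gene_id
  tx2g <- stats::setNames(bundle$transcripts$gene_id,
                          bundle$transcripts$transcript_id)
  ex <- bundle$exons
  ex$gene_id <- tx2g[ex$transcript_id]
  pos <- character(0)
  for (pk in peaks_by_rep) {
    if (is.null(pk)) next
    for (i in seq_len(nrow(pk))) {
      for (j in seq_len(nrow(ex))) {
        if (pk$chrom[i] == ex$chrom[j] && pk$start[i] < ex$end[j] &&
            pk$end[i] > ex$start[j]) {
          pos <- c(pos, ex$gene_id[j])
        }
      }
    }
  }
  stats::setNames(genes %in% pos, genes)
}
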