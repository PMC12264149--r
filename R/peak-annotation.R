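# Peak-to-feature assignment with the stop-codon-first hierarchy, feature
# enrichment scores, metagene profiling of peak summits, gene-level m6A
# calls, and RRACH motif counting.

FEATURE_ORDER <- c("stop_codon", "3UTR", "5UTR", "CDS", "exon", "intron",
                   "intergenic")

.reduce0 <- function(df_list) {
  # list of 0-based dfs -> reduced unstranded GRanges
  df <- do.call(rbind, df_list)
  if (is.null(df) || !nrow(df)) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(.gr0(df$chrom, df$start, df$end))
}

# Per-transcript genomic projections of each feature, with transcript ids.
.feature_tx_intervals <- function(bundle, stop_flank = 200) {
  reg <- .tx_regions(bundle)
  coding <- reg[reg$coding, , drop = FALSE]
  u5 <- list(); u3 <- list()
  for (i in seq_len(nrow(coding))) {
    tx <- coding$transcript_id[i]
    ex <- .tx_exons(bundle, tx)
    if (coding$u5[i] > 0) {
      d <- .tx_to_genomic(0, coding$u5[i], ex)
      d$transcript_id <- tx
      u5[[length(u5) + 1L]] <- d
    }
    tail_start <- coding$u5[i] + coding$cds[i] + 3L   # after the stop codon
    if (tail_start < coding$tx_len[i]) {
      d <- .tx_to_genomic(tail_start, coding$tx_len[i], ex)
      d$transcript_id <- tx
      u3[[length(u3) + 1L]] <- d
    }
  }
  sc <- bundle$stop_codons
  stop_win <- if (nrow(sc)) {
    data.frame(chrom = sc$chrom,
               start = pmax(0, sc$start - stop_flank),
               end = pmin(bundle$chrom_sizes[sc$chrom], sc$end + stop_flank),
               strand = sc$strand, transcript_id = sc$transcript_id,
               stringsAsFactors = FALSE)
  } else NULL
  ex_all <- bundle$exons
  spans <- bundle$transcripts
  list(
    stop_codon = stop_win,
    `3UTR` = if (length(u3)) do.call(rbind, u3) else NULL,
    `5UTR` = if (length(u5)) do.call(rbind, u5) else NULL,
    CDS = if (nrow(bundle$cds)) bundle$cds else NULL,
    exon = if (nrow(ex_all)) ex_all else NULL,
    intron = if (nrow(spans)) spans else NULL   # attribution by span
  )
}

#' Hierarchy-masked genomic feature partition
#'
#' Projects every transcript's features onto the genome and subtracts
#' higher-priority features (stop codon > 3'UTR > 5'UTR > CDS > exon >
#' intron > intergenic) so the seven feature classes partition the genome
#' exactly.  The stop-codon feature is the annotated 3-nt stop codon
#' extended `stop_flank` bp on both sides in genomic space.
#'
#' @param bundle An `AnnotationBundle`.
#' @param stop_flank Flank around the stop codon in bp (default 200).
#' @return List with `lengths` (named, sums to genome length), `masked`
#'   (GRangesList-like list of disjoint regions) and `unions` (unmasked
#'   per-feature unions).
#' @export
feature_masks <- function(bundle, stop_flank = 200) {
  fx <- .feature_tx_intervals(bundle, stop_flank)
  unions <- list(
    stop_codon = .reduce0(list(fx$stop_codon)),
    `3UTR` = .reduce0(list(fx$`3UTR`)),
    `5UTR` = .reduce0(list(fx$`5UTR`)),
    CDS = .reduce0(list(fx$CDS)),
    exon = .reduce0(list(fx$exon)),
    span = .reduce0(list(fx$intron))
  )
  genome <- .gr0(names(bundle$chrom_sizes),
                 rep(0, length(bundle$chrom_sizes)),
                 unname(bundle$chrom_sizes))
  masked <- list()
  covered <- GenomicRanges::GRanges()
  for (f in c("stop_codon", "3UTR", "5UTR", "CDS", "exon")) {
    m <- GenomicRanges::setdiff(unions[[f]], covered)
    masked[[f]] <- m
    covered <- GenomicRanges::reduce(c(covered, m))
  }
  masked$intron <- GenomicRanges::setdiff(unions$span, covered)
  covered <- GenomicRanges::reduce(c(covered, masked$intron))
  masked$intergenic <- GenomicRanges::setdiff(genome, covered)
  lengths <- vapply(masked, function(g) sum(as.numeric(GenomicRanges::width(g))),
                    numeric(1))
  .assert(abs(sum(lengths) - sum(bundle$chrom_sizes)) < 1e-9,
          "masked feature lengths do not partition the genome")
  list(lengths = lengths[FEATURE_ORDER], masked = masked[FEATURE_ORDER],
       unions = unions)
}

#' Assign peaks to genomic features
#'
#' Each peak receives exactly one label: the first feature in the priority
#' order stop_codon > 3'UTR > 5'UTR > CDS > exon > intron > intergenic whose
#' genomic projection (over all transcripts) the peak interval overlaps by
#' at least 1 bp.  The assigned transcript is the lexicographically smallest
#' transcript contributing the matched feature.
#'
#' @param peaks Peak data.frame (see [read_peaks()]).
#' @param bundle An `AnnotationBundle`.
#' @param stop_flank Flank around the stop codon in bp (default 200).
#' @param by One of `"interval"` (default: test the peak interval) or
#'   `"summit"` (test the 1-bp summit).
#' @return `peaks` with added columns `feature`, `transcript_id`, `gene_id`.
#' @export
assign_peak_features <- function(peaks, bundle, stop_flank = 200,
                                 by = c("interval", "summit")) {
  by <- match.arg(by)
  n <- nrow(peaks)
  feature <- rep("intergenic", n)
  tx_assigned <- rep(NA_character_, n)
  if (n == 0) {
    peaks$feature <- character(0); peaks$transcript_id <- character(0)
    peaks$gene_id <- character(0)
    return(peaks)
  }
  pk_gr <- if (by == "summit") {
    .gr0(peaks$chrom, peaks$summit, peaks$summit + 1L)
  } else {
    .gr0(peaks$chrom, peaks$start, peaks$end)
  }
  fx <- .feature_tx_intervals(bundle, stop_flank)
  names(fx)[names(fx) == "intron"] <- "intron"
  unassigned <- rep(TRUE, n)
  for (f in c("stop_codon", "3UTR", "5UTR", "CDS", "exon", "intron")) {
    d <- fx[[f]]
    if (is.null(d) || !nrow(d)) next
    f_gr <- .gr0(d$chrom, d$start, d$end)
    hits <- GenomicRanges::findOverlaps(pk_gr, f_gr)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    keep <- unassigned[qh]
    qh <- qh[keep]; sh <- sh[keep]
    if (!length(qh)) next
    txs <- d$transcript_id[sh]
    first <- tapply(txs, qh, function(v) sort(v)[1])
    idx <- as.integer(names(first))
    feature[idx] <- f
    tx_assigned[idx] <- as.character(first)
    unassigned[idx] <- FALSE
  }
  tx2g <- stats::setNames(bundle$transcripts$gene_id,
                          bundle$transcripts$transcript_id)
  peaks$feature <- feature
  peaks$transcript_id <- tx_assigned
  peaks$gene_id <- unname(tx2g[tx_assigned])
  peaks
}

#' Feature enrichment scores for a peak set
#'
#' For each feature class f, `expected_f = total_peaks * L_f / L_genome`
#' where `L_f` is the hierarchy-masked genomic length of the feature, and the
#' enrichment score is `E_f = log2(observed_f / expected_f)` (missing when no
#' peak was observed in the class).  Expected counts sum to the total number
#' of peaks because the masked lengths partition the genome.
#'
#' @param peaks Peak data.frame; may already carry a `feature` column from
#'   [assign_peak_features()], otherwise assignment is run first.
#' @param bundle An `AnnotationBundle`.
#' @param stop_flank Flank around the stop codon in bp (default 200).
#' @param by Assignment mode, see [assign_peak_features()].
#' @return data.frame of class `EnrichmentTable` with `feature`, `observed`,
#'   `expected`, `enrichment`.
#' @export
feature_enrichment <- function(peaks, bundle, stop_flank = 200,
                               by = "interval") {
  .assert(nrow(peaks) > 0, "empty peak list")
  if (is.null(peaks$feature)) {
    peaks <- assign_peak_features(peaks, bundle, stop_flank, by = by)
  }
  fm <- feature_masks(bundle, stop_flank)
  total <- nrow(peaks)
  observed <- vapply(FEATURE_ORDER, function(f) sum(peaks$feature == f),
                     numeric(1))
  expected <- total * fm$lengths / sum(bundle$chrom_sizes)
  enrichment <- ifelse(observed > 0, log2(observed / expected), NA_real_)
  out <- data.frame(feature = FEATURE_ORDER, observed = unname(observed),
                    expected = unname(expected),
                    enrichment = unname(enrichment), row.names = NULL)
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}

#' Metagene profile of peak summits
#'
#' Maps each summit onto the concatenated exons of the representative
#' (highest-expression) transcript of its gene, scales the position within
#' its region to unit length, and offsets the regions so that 5'UTR spans
#' [0,1), CDS [1,2) and stop codon + 3'UTR [2,3).  Summits on non-coding or
#' UTR-less transcripts are skipped and counted.
#'
#' @param peaks Peak data.frame with a `summit` column, or a data.frame with
#'   `chrom` and `summit`.
#' @param bundle An `AnnotationBundle`.
#' @param tx_expr Named transcript expression vector used to pick the
#'   representative isoform (see [representative_transcripts()]).
#' @param n_bins Number of density bins over [0,3) (default 90).
#' @return An object of class `MetageneProfile`: `coords` (per-summit
#'   metagene coordinates), `density` (sums to 1), `n_used`, `n_skipped`.
#' @export
metagene_profile <- function(peaks, bundle, tx_expr = NULL, n_bins = 90) {
  rep_tx <- representative_transcripts(bundle, tx_expr)
  reg <- .tx_regions(bundle)
  reg <- reg[match(unname(rep_tx), reg$transcript_id), , drop = FALSE]
  reg <- reg[reg$coding & reg$u5 > 0 & reg$tail > 3, , drop = FALSE]

  # exon intervals of eligible representative transcripts
  ex <- bundle$exons[bundle$exons$transcript_id %in% reg$transcript_id, ,
                     drop = FALSE]
  ex_gr <- .gr0(ex$chrom, ex$start, ex$end)
  s_gr <- .gr0(peaks$chrom, peaks$summit, peaks$summit + 1L)
  hits <- GenomicRanges::findOverlaps(s_gr, ex_gr)
  qh <- S4Vectors::queryHits(hits)
  tx_hit <- ex$transcript_id[S4Vectors::subjectHits(hits)]
  pick <- tapply(tx_hit, qh, function(v) sort(v)[1])

  coords <- data.frame(peak = as.integer(names(pick)),
                       transcript_id = as.character(pick),
                       coord = rep(NA_real_, length(pick)),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(coords))) {
    tx <- coords$transcript_id[i]
    exi <- .tx_exons(bundle, tx)
    t <- .genomic_to_tx(peaks$summit[coords$peak[i]], exi)
    r <- reg[reg$transcript_id == tx, ]
    u5 <- r$u5; cds <- r$cds; tail <- r$tail
    coords$coord[i] <-
      if (t < u5) t / u5
      else if (t < u5 + cds) 1 + (t - u5) / cds
      else 2 + (t - u5 - cds) / tail
  }
  coords <- coords[!is.na(coords$coord), , drop = FALSE]
  n_skipped <- nrow(peaks) - nrow(coords)
  if (n_skipped > 0) {
    .log_msg("metagene_profile: %d summit(s) skipped (non-coding, UTR-less or non-exonic)",
             n_skipped)
  }
  breaks <- seq(0, 3, length.out = n_bins + 1)
  cnt <- if (nrow(coords)) {
    graphics::hist(coords$coord, breaks = breaks, plot = FALSE)$counts
  } else rep(0L, n_bins)
  dens <- if (sum(cnt) > 0) cnt / sum(cnt) else rep(0, n_bins)
  structure(list(coords = coords,
                 density = data.frame(
                   mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                   density = dens),
                 n_used = nrow(coords), n_skipped = n_skipped),
            class = "MetageneProfile")
}

#' @export
print.MetageneProfile <- function(x, ...) {
  cat(sprintf("MetageneProfile: %d summits used, %d skipped\n",
              x$n_used, x$n_skipped))
  invisible(x)
}

#' Gene-level m6A calls
#'
#' A gene is m6A+ in one replicate when any of its transcripts' exonic
#' intervals (or full genomic spans with `mode = "span"`) overlap any peak
#' by at least 1 bp; the stage-level call is the union over replicates.
#' Genes below the expression floor are flagged `not_expressed`.
#'
#' @param peaks_by_replicate Named list of peak data.frames, one per IP
#'   replicate.
#' @param bundle An `AnnotationBundle`.
#' @param expr Optional named vector of per-gene stage expression (TPM).
#' @param tpm_floor Expression floor below which genes are `not_expressed`
#'   (default 1).
#' @param mode `"exon"` (default) or `"span"` peak-transcript intersection.
#' @return data.frame of class `GeneM6ACall`: `gene_id`, `status`
#'   (`"m6A+"`, `"m6A-"`, `"not_expressed"`), `n_replicates`, `replicates`.
#' @export
call_m6a_genes <- function(peaks_by_replicate, bundle, expr = NULL,
                           tpm_floor = 1, mode = c("exon", "span")) {
  mode <- match.arg(mode)
  .assert(length(peaks_by_replicate) >= 1, "need at least one replicate")
  if (is.null(names(peaks_by_replicate))) {
    names(peaks_by_replicate) <- paste0("rep", seq_along(peaks_by_replicate))
  }
  tx2g <- stats::setNames(bundle$transcripts$gene_id,
                          bundle$transcripts$transcript_id)
  if (mode == "exon") {
    feat <- bundle$exons
    feat$gene_id <- unname(tx2g[feat$transcript_id])
  } else {
    feat <- bundle$transcripts
    feat$gene_id <- feat$gene_id
  }
  f_gr <- .gr0(feat$chrom, feat$start, feat$end)

  hit_genes <- lapply(peaks_by_replicate, function(pk) {
    if (is.null(pk) || !nrow(pk)) return(character(0))
    p_gr <- .gr0(pk$chrom, pk$start, pk$end)
    hits <- GenomicRanges::findOverlaps(p_gr, f_gr)
    unique(feat$gene_id[S4Vectors::subjectHits(hits)])
  })
  genes <- bundle$genes$gene_id
  support <- sapply(names(hit_genes), function(r) genes %in% hit_genes[[r]])
  if (is.null(dim(support))) support <- matrix(support, nrow = length(genes))
  n_rep <- rowSums(support)
  status <- ifelse(n_rep > 0, "m6A+", "m6A-")
  if (!is.null(expr)) {
    e <- unname(expr[genes])
    status[is.na(e) | e < tpm_floor] <- "not_expressed"
  }
  reps <- apply(support, 1, function(z) {
    paste(names(peaks_by_replicate)[z], collapse = ",")
  })
  out <- data.frame(gene_id = genes, status = status,
                    n_replicates = n_rep,
                    replicates = ifelse(nzchar(reps), reps, NA_character_),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("GeneM6ACall", "data.frame")
  out
}

#' Count RRACH motifs on representative transcripts
#'
#' Counts occurrences of the m6A consensus 5-mer (default `RRACH`; R = G/A,
#' H = A/C/T on the DNA sense strand, U in RNA display) on the concatenated
#' exonic sense-strand sequence of each gene's representative transcript.
#' Overlapping matches are counted.
#'
#' @param bundle An `AnnotationBundle` carrying `sequence`.
#' @param gene_ids Genes to count (default: all).
#' @param tx_expr Named transcript expression vector for representative
#'   isoform selection.
#' @param motif IUPAC DNA pattern (default `"RRACH"`).
#' @return data.frame with `gene_id`, `transcript_id`, `count`,
#'   `exonic_length`, `density_per_kb`.
#' @export
count_rrach <- function(bundle, gene_ids = NULL, tx_expr = NULL,
                        motif = "RRACH") {
  .assert(!is.null(bundle$sequence), "bundle carries no sequence")
  rep_tx <- representative_transcripts(bundle, tx_expr)
  if (is.null(gene_ids)) gene_ids <- names(rep_tx)
  out <- data.frame(gene_id = gene_ids,
                    transcript_id = unname(rep_tx[gene_ids]),
                    count = NA_integer_, exonic_length = NA_integer_,
                    density_per_kb = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(gene_ids)) {
    tx <- out$transcript_id[i]
    .assert(!is.na(tx), "gene %s has no transcript", gene_ids[i])
    ex <- .tx_exons(bundle, tx)
    .assert(ex$chrom[1] %in% names(bundle$sequence),
            "missing sequence for gene %s (chromosome %s)",
            gene_ids[i], ex$chrom[1])
    chrom_seq <- bundle$sequence[[ex$chrom[1]]]
    exg <- ex[order(ex$start), ]
    pieces <- vapply(seq_len(nrow(exg)), function(j) {
      as.character(Biostrings::subseq(chrom_seq, exg$start[j] + 1L,
                                      exg$end[j]))
    }, character(1))
    s <- Biostrings::DNAString(paste(pieces, collapse = ""))
    if (ex$strand[1] == "-") s <- Biostrings::reverseComplement(s)
    cnt <- Biostrings::countPattern(motif, s, fixed = FALSE)
    len <- length(s)
    out$count[i] <- cnt
    out$exonic_length[i] <- len
    out$density_per_kb[i] <- cnt / (len / 1000)
  }
  out
}
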