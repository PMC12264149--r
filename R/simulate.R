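# Synthetic-data generator: emits every input shape the pipeline consumes
# (gene models + sequence, stage-structured expression with planted
# M-decay/Z-decay/ZGA/constant classes, paired IP/Input coverage with peaks
# planted at stop codons, miRNA counts and target maps, Ribo/mRNA FPKM,
# RepeatMasker-style repeat annotations, Ctrl-vs-inhibitor condition pairs)
# with a ground-truth record for every planted feature.
#
# The IP model: IP fragment density follows the Input density scaled by a
# position-wise enrichment field - `enrichment` inside planted peak windows
# and across m6A-modified repeat loci, 1 elsewhere, and 0 across expressed
# but unmodified repeat loci (an idealized fully-selective antibody; with
# enrichment = 1 the field is flat and IP coincides with Input in
# distribution).

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator with defaults that
#' state the emulated world: six developmental stages with two replicates,
#' planted gene classes with a 1.5x fold-change margin beyond each printed
#' threshold, peak summits Normal(stop codon, 50 bp), and a desk-scale
#' genome.
#'
#' @param n_chromosomes,chrom_length Genome shape (default 2 x 2.5 Mb).
#' @param n_genes Number of genes (default 300).
#' @param lnc_frac Fraction of non-coding (lncRNA) genes.
#' @param second_isoform_frac Fraction of coding genes with a second,
#'   3'UTR-truncated isoform.
#' @param stages,replicates Stage labels and replicates per stage.
#' @param class_counts Named counts of planted M-decay, Z-decay, ZGA and
#'   constant genes.
#' @param margin Multiplicative margin by which every planted class
#'   satisfies its defining inequalities (> 1).
#' @param background_tpm TPM range of unplanted genes (kept clear of every
#'   rule threshold).
#' @param replicate_cv Log-normal replicate noise (sdlog).
#' @param frac_m6a Fraction of coding genes carrying an m6A site; sampling
#'   is length-biased (probability proportional to exonic length).
#' @param enrichment IP enrichment factor inside planted peaks (>= 1).
#' @param depth Fragments per coverage sample.
#' @param frag_len,frag_sd Fragment length model (bp).
#' @param summit_sd SD of the planted summit around the stop codon (bp).
#' @param peak_halfwidth Half-width of planted peak windows (bp).
#' @param peak_dropout Probability that a planted peak is absent from one
#'   replicate's peak file.
#' @param repeat_model List of repeat subfamily specifications.
#' @param incomplete_frac Fraction of simple/solo repeat loci drawn below
#'   90% completeness.
#' @param repeat_expressed_frac,repeat_m6a_frac Per-stage probability that
#'   a repeat locus is expressed, and modified given expressed.
#' @param repeat_level_meanlog,repeat_level_sdlog Log-normal expression
#'   level of expressed repeat loci (per-bp weight, on the TPM scale of
#'   the gene model).  Keep total repeat mass a minor library fraction:
#'   when repeat fragments dominate the library, per-sample RPKM
#'   renormalization absorbs IP enrichment differences (composition bias).
#' @param inhibitor_reduction Factor in [0, 1] scaling the IP enrichment
#'   under inhibitor treatment.
#' @param n_mirnas,mirna_conserved_frac,mirna_depth,mirna_replicates,mirna_stages
#'   miRNA model.
#' @param target_p_m6a,target_p_other Per conserved family, probability of
#'   targeting an m6A+ (resp. other) coding gene.
#' @param te_multiplier,te_sd,te_stages Translation model: TE multiplier
#'   for m6A+ genes, log-normal TE spread, stages with translatome data.
#' @param homolog_one2one_frac,homolog_missing_frac Homology-table shape
#'   (the remainder is emitted as deliberately many-to-one rows).
#' @param bin_size Track bin width (bp).
#' @param seed Default seed.
#' @return An object of class `SimConfig`.
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_length = 2.5e6,
                       n_genes = 300,
                       lnc_frac = 0.1,
                       second_isoform_frac = 0.2,
                       stages = c("GV", "MII", "1C", "2C", "8C", "BLT"),
                       replicates = 2,
                       class_counts = c(m_decay = 40, z_decay = 40,
                                        zga = 40, constant = 40),
                       margin = 1.5,
                       background_tpm = c(1.2, 8),
                       replicate_cv = 0.1,
                       frac_m6a = 0.4,
                       enrichment = 6,
                       depth = 1e5,
                       frag_len = 180, frag_sd = 30,
                       summit_sd = 50,
                       peak_halfwidth = 100,
                       peak_dropout = 0.1,
                       repeat_model = NULL,
                       incomplete_frac = 0.3,
                       repeat_expressed_frac = 0.7,
                       repeat_m6a_frac = 0.5,
                       repeat_level_meanlog = log(20),
                       repeat_level_sdlog = 0.5,
                       inhibitor_reduction = 0.5,
                       n_mirnas = 100,
                       mirna_conserved_frac = 0.6,
                       mirna_depth = 5e5,
                       mirna_replicates = 3,
                       mirna_stages = c("GV", "MII", "1C", "8C"),
                       target_p_m6a = 0.05,
                       target_p_other = 1 / 60,
                       te_multiplier = 1.5,
                       te_sd = 0.25,
                       te_stages = c("GV", "MII", "1C", "8C"),
                       homolog_one2one_frac = 0.85,
                       homolog_missing_frac = 0.05,
                       bin_size = 10,
                       seed = 1) {
  if (is.null(repeat_model)) {
    repeat_model <- list(
      list(subfamily = "L1HS", class = "LINE", family = "L1",
           consensus = 3000, n = 40),
      list(subfamily = "AluY", class = "SINE", family = "Alu",
           consensus = 300, n = 60),
      list(subfamily = "SVA_D", class = "SVA", family = "SVA",
           consensus = 1300, n = 30),
      list(subfamily = "THE1C", class = "LTR", family = "THE1",
           consensus = 350, n = 40, type = "solo"),
      list(family = "HERVH", class = "LTR", type = "erv", n = 30,
           ltr_subfamily = "LTR7", int_subfamily = "HERVH-int",
           consensus_ltr = 400, consensus_int = 2000,
           full_frac = 0.6, no_int_frac = 0.2)
    )
  }
  cfg <- as.list(environment())
  .assert(sum(class_counts) <= n_genes,
          "class counts exceed the number of genes")
  fracs <- c(lnc_frac, second_isoform_frac, frac_m6a, incomplete_frac,
             repeat_expressed_frac, repeat_m6a_frac, peak_dropout,
             mirna_conserved_frac, target_p_m6a, target_p_other,
             homolog_one2one_frac, homolog_missing_frac)
  .assert(all(fracs >= 0 & fracs <= 1), "fractions must lie in [0, 1]")
  .assert(enrichment >= 1, "IP enrichment factor must be >= 1")
  .assert(inhibitor_reduction >= 0 && inhibitor_reduction <= 1,
          "inhibitor_reduction must lie in [0, 1]")
  structure(cfg, class = "SimConfig")
}

# ---------------------------------------------------------------------------
# annotation + genome + repeats + homology + miRNA map

#' Simulate an annotated genome with ground truth
#'
#' Generates gene models (multi-exon coding genes with 5'UTR/CDS/3'UTR and
#' optional second isoforms, a fraction of lncRNAs), random chromosome
#' sequence with GGACT planted at the future peak summits, a
#' RepeatMasker-style repeat annotation (fragmented copies, full-length
#' ERVs as 5'LTR + internal + 3'LTR fragment runs, solo LTRs), a two-species
#' homology table (one-to-one, missing, and deliberately many-to-one rows),
#' a conserved-family miRNA target map, and a `TruthSet` recording every
#' planted feature.
#'
#' @param config A `SimConfig`.
#' @param seed Random seed (default `config$seed`).
#' @param sequence Set `FALSE` to skip chromosome-sequence generation
#'   (classification-only studies that never touch motifs).
#' @return An object of class `M6ASimulation`.
#' @export
simulate_annotation <- function(config, seed = config$seed,
                                sequence = TRUE) {
  set.seed(seed)
  n_chrom <- config$n_chromosomes
  chrom_sizes <- stats::setNames(rep(config$chrom_length, n_chrom),
                                 paste0("chr", seq_len(n_chrom)))
  gene_region_end <- floor(0.72 * config$chrom_length)

  genes <- list(); transcripts <- list(); exons <- list()
  cds <- list(); stops <- list()
  gene_meta <- list()   # per-gene architecture bookkeeping
  cursor <- stats::setNames(rep(1000, n_chrom), names(chrom_sizes))

  biotypes <- ifelse(stats::runif(config$n_genes) < config$lnc_frac,
                     "lncRNA", "protein_coding")
  # planted classes and m6A status must sit on coding genes: force enough
  .assert(sum(biotypes == "protein_coding") >= sum(config$class_counts),
          "too few coding genes for the requested class counts")

  for (i in seq_len(config$n_genes)) {
    gid <- sprintf("G%04d", i)
    coding <- biotypes[i] == "protein_coding"
    if (coding) {
      # realistic spread: CDS 0.9-6 kb, 3'UTR 0.8-3 kb; the lower bounds
      # keep planted summits (sd 50 bp) inside the stop-codon metagene
      # window, the upper bounds give the length variation that makes
      # length-biased m6A deposition detectable
      u5 <- round(stats::runif(1, 100, 300))
      cds_len <- 3L * sample(300:2000, 1)
      u3 <- round(stats::runif(1, 800, 3000))
      exonic <- u5 + cds_len + 3L + u3
    } else {
      u5 <- cds_len <- u3 <- 0L
      exonic <- round(stats::runif(1, 500, 2000))
    }
    k <- sample(3:6, 1)
    if (!coding) k <- max(2L, min(k, exonic %/% 150L))
    lens <- .split_len(exonic, k, 100L)
    if (coding) {
      # keep the stop codon inside one exon
      cum <- cumsum(lens)
      s0 <- u5 + cds_len          # tx start of the stop codon
      j <- findInterval(s0, c(0, cum), rightmost.closed = FALSE)
      if (j < k && s0 + 3L > cum[j]) {
        shift <- cum[j] - s0      # move boundary down to s0
        if (lens[j] - shift >= 50) {
          lens[j] <- lens[j] - shift; lens[j + 1L] <- lens[j + 1L] + shift
        } else {
          lens[j] <- lens[j] + (3L - shift)
          lens[j + 1L] <- lens[j + 1L] - (3L - shift)
        }
      }
    }
    introns <- round(stats::runif(k - 1L, 200, 800))
    span <- sum(lens) + sum(introns)

    placed <- FALSE
    ord <- order(cursor)
    for (ci in ord) {
      gap <- round(stats::runif(1, 500, 2500))
      if (cursor[ci] + gap + span < gene_region_end) {
        chrom <- names(chrom_sizes)[ci]
        gstart <- cursor[ci] + gap
        cursor[ci] <- gstart + span
        placed <- TRUE
        break
      }
    }
    .assert(placed,
            "genome too small for %d genes: need roughly %d bp of gene space per chromosome",
            config$n_genes,
            ceiling((config$n_genes * (span + 1500)) / n_chrom / 0.72))

    strand <- sample(c("+", "-"), 1)
    # genomic exon layout: transcription order reversed for minus strand
    lens_gen <- if (strand == "-") rev(lens) else lens
    introns_gen <- if (strand == "-") rev(introns) else introns
    ex_start <- gstart + cumsum(c(0, head(lens_gen, -1) + introns_gen))
    ex_end <- ex_start + lens_gen
    ranks <- if (strand == "-") rev(seq_len(k)) else seq_len(k)
    tx1 <- paste0(gid, ".t1")
    ex_tab <- data.frame(transcript_id = tx1, chrom = chrom,
                         start = ex_start, end = ex_end, strand = strand,
                         rank = ranks, stringsAsFactors = FALSE)
    ex_tx <- ex_tab[order(ex_tab$rank), ]
    exons[[length(exons) + 1L]] <- ex_tab
    transcripts[[length(transcripts) + 1L]] <- data.frame(
      transcript_id = tx1, gene_id = gid, chrom = chrom, start = gstart,
      end = gstart + span, strand = strand, biotype = biotypes[i],
      stringsAsFactors = FALSE)
    if (coding) {
      cds_g <- .tx_to_genomic(u5, u5 + cds_len, ex_tx)
      cds_g$transcript_id <- tx1
      cds[[length(cds) + 1L]] <- cds_g[, c("transcript_id", "chrom", "start",
                                           "end", "strand")]
      st_g <- .tx_to_genomic(u5 + cds_len, u5 + cds_len + 3L, ex_tx)
      st_g$transcript_id <- tx1
      stops[[length(stops) + 1L]] <- st_g[, c("transcript_id", "chrom",
                                              "start", "end", "strand")]
      if (stats::runif(1) < config$second_isoform_frac) {
        # second isoform: 3'UTR shortened by truncating the last exon
        last <- which(ex_tx$rank == k)
        trunc <- min(ex_tx$end[last] - ex_tx$start[last] - 20L,
                     floor(u3 / 2))
        if (trunc >= 50) {
          ex2 <- ex_tab
          tx2 <- paste0(gid, ".t2")
          ex2$transcript_id <- tx2
          gi <- which(ex2$rank == k)
          if (strand == "-") ex2$start[gi] <- ex2$start[gi] + trunc
          else ex2$end[gi] <- ex2$end[gi] - trunc
          exons[[length(exons) + 1L]] <- ex2
          transcripts[[length(transcripts) + 1L]] <- data.frame(
            transcript_id = tx2, gene_id = gid, chrom = chrom,
            start = min(ex2$start), end = max(ex2$end), strand = strand,
            biotype = biotypes[i], stringsAsFactors = FALSE)
          cds2 <- cds[[length(cds)]]; cds2$transcript_id <- tx2
          cds[[length(cds) + 1L]] <- cds2
          st2 <- stops[[length(stops)]]; st2$transcript_id <- tx2
          stops[[length(stops) + 1L]] <- st2
        }
      }
    }
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = gid, chrom = chrom, start = gstart, end = gstart + span,
      strand = strand, biotype = biotypes[i], stringsAsFactors = FALSE)
    gene_meta[[gid]] <- list(u5 = u5, cds = cds_len, u3 = u3,
                             tx_len = exonic, primary_tx = tx1,
                             exons_tx = ex_tx)
  }

  genes <- do.call(rbind, genes)
  transcripts <- do.call(rbind, transcripts)
  exons <- do.call(rbind, exons)
  cds <- do.call(rbind, cds)
  stops <- do.call(rbind, stops)

  coding_genes <- genes$gene_id[genes$biotype == "protein_coding"]
  exonic_len <- vapply(coding_genes,
                       function(g) gene_meta[[g]]$tx_len, numeric(1))

  ## planted m6A gene set: length-biased sampling
  n_m6a <- round(config$frac_m6a * length(coding_genes))
  m6a_genes <- sample(coding_genes, n_m6a, prob = exonic_len)

  ## planted classes (disjoint, on coding genes)
  cls_pool <- sample(coding_genes)
  cc <- config$class_counts
  class_tab <- data.frame(gene_id = genes$gene_id, class = "background",
                          stringsAsFactors = FALSE)
  off <- 0L
  for (cl in names(cc)) {
    ids <- cls_pool[(off + 1L):(off + cc[[cl]])]
    class_tab$class[match(ids, class_tab$gene_id)] <- cl
    off <- off + cc[[cl]]
  }

  ## peak sites: summit ~ Normal(stop codon, summit_sd) in transcript space
  sites <- do.call(rbind, lapply(coding_genes, function(g) {
    gm <- gene_meta[[g]]
    ts <- gm$u5 + gm$cds + round(stats::rnorm(1, 0, config$summit_sd))
    ts <- max(5L, min(gm$tx_len - 5L, ts))
    gpos <- .tx_to_genomic(ts, ts + 1L, gm$exons_tx)
    data.frame(gene_id = g, transcript_id = gm$primary_tx,
               tx_summit = ts, chrom = gpos$chrom[1], summit = gpos$start[1],
               strand = gm$exons_tx$strand[1], stringsAsFactors = FALSE)
  }))

  ## chromosome sequence with GGACT planted at summits
  seqs <- NULL
  if (sequence) {
    seq_chr <- lapply(names(chrom_sizes), function(chrom) {
      sample(c("A", "C", "G", "T"), chrom_sizes[[chrom]], replace = TRUE,
             prob = c(0.3, 0.2, 0.2, 0.3))
    })
    names(seq_chr) <- names(chrom_sizes)
    motif_plus <- c("G", "G", "A", "C", "T")
    motif_minus <- c("A", "G", "T", "C", "C")  # revcomp, sense reads GGACT
    for (i in seq_len(nrow(sites))) {
      s <- sites$summit[i]
      if (s < 3 || s > chrom_sizes[[sites$chrom[i]]] - 3) next
      mot <- if (sites$strand[i] == "-") motif_minus else motif_plus
      seq_chr[[sites$chrom[i]]][(s - 1):(s + 3)] <- mot
    }
    seqs <- Biostrings::DNAStringSet(
      vapply(seq_chr, paste, character(1), collapse = ""))
    names(seqs) <- names(chrom_sizes)
  }

  ## repeats in the tail region of each chromosome
  rep_res <- .sim_repeats(config, chrom_sizes, gene_region_end)

  ## homology table
  hom <- .sim_homology(config, coding_genes)

  ## miRNA families and conserved-target map
  mir <- .sim_mirna_map(config, coding_genes, m6a_genes)

  bundle <- annotation_bundle(genes, transcripts, exons, cds, stops,
                              sequence = seqs,
                              chrom_sizes = chrom_sizes)
  truth <- structure(list(
    classes = class_tab,
    m6a_genes = sort(m6a_genes),
    peak_sites = sites,
    gene_meta = gene_meta,
    repeat_elements = rep_res$elements,
    te_multiplier = stats::setNames(
      exp(stats::rnorm(length(coding_genes), 0, config$te_sd)) *
        ifelse(coding_genes %in% m6a_genes, config$te_multiplier, 1),
      coding_genes),
    target_map = mir$map
  ), class = "TruthSet")

  structure(list(bundle = bundle, repeats = rep_res$fragments,
                 consensus = rep_res$consensus, homology = hom,
                 mirna_families = mir$families, target_map = mir$map,
                 truth = truth, config = config),
            class = "M6ASimulation")
}

#' @export
print.M6ASimulation <- function(x, ...) {
  cat(sprintf("M6ASimulation: %d genes (%d m6A+), %d repeat fragments, %d-chromosome genome\n",
              nrow(x$bundle$genes), length(x$truth$m6a_genes),
              nrow(x$repeats), length(x$bundle$chrom_sizes)))
  invisible(x)
}

.sim_repeats <- function(config, chrom_sizes, gene_region_end) {
  frags <- list(); elements <- list()
  consensus <- c()
  cursor <- stats::setNames(rep(gene_region_end + 2000, length(chrom_sizes)),
                            names(chrom_sizes))
  eid <- 0L
  draw_comp <- function(n) {
    ifelse(stats::runif(n) < config$incomplete_frac,
           stats::runif(n, 0.5, 0.89), stats::runif(n, 0.9, 1.0))
  }
  place <- function(total_len) {
    ord <- order(cursor)
    for (ci in ord) {
      gap <- round(stats::runif(1, 600, 1500))
      if (cursor[ci] + gap + total_len < chrom_sizes[ci] - 100) {
        chrom <- names(chrom_sizes)[ci]
        start <- unname(cursor[ci] + gap)
        cursor[ci] <<- start + total_len
        return(list(chrom = chrom, start = start))
      }
    }
    stop("genome too small for the repeat model; enlarge chrom_length",
         call. = FALSE)
  }
  for (spec in config$repeat_model) {
    type <- spec$type %||% "single"
    if (type == "erv") {
      consensus[spec$ltr_subfamily] <- spec$consensus_ltr
      consensus[spec$int_subfamily] <- spec$consensus_int
      consensus[spec$family] <- 2 * spec$consensus_ltr + spec$consensus_int
      for (j in seq_len(spec$n)) {
        eid <- eid + 1L
        u <- stats::runif(1)
        arch <- if (u < spec$full_frac) "full"
                else if (u < spec$full_frac + spec$no_int_frac) "pair" else "solo"
        strand <- sample(c("+", "-"), 1)
        if (arch == "full") {
          lens <- round(c(stats::runif(1, 0.9, 1) * spec$consensus_ltr,
                          stats::runif(1, 0.9, 1) * spec$consensus_int,
                          stats::runif(1, 0.9, 1) * spec$consensus_ltr))
          segs <- c("LTR", "internal", "LTR")
          subf <- c(spec$ltr_subfamily, spec$int_subfamily,
                    spec$ltr_subfamily)
        } else if (arch == "pair") {
          lens <- round(stats::runif(2, 0.9, 1) * spec$consensus_ltr)
          segs <- c("LTR", "LTR"); subf <- rep(spec$ltr_subfamily, 2)
        } else {
          lens <- round(draw_comp(1) * spec$consensus_ltr)
          segs <- "LTR"; subf <- spec$ltr_subfamily
        }
        gaps <- if (length(lens) > 1) round(stats::runif(length(lens) - 1, 10, 150)) else integer(0)
        pos <- place(sum(lens) + sum(gaps))
        starts <- pos$start + cumsum(c(0, head(lens, -1) + gaps))
        frags[[length(frags) + 1L]] <- data.frame(
          element_id = sprintf("E%04d", eid), subfamily = subf,
          class = "LTR", family = spec$family, chrom = pos$chrom,
          start = starts, end = starts + lens, strand = strand,
          segment = segs, stringsAsFactors = FALSE)
        elements[[length(elements) + 1L]] <- data.frame(
          element_id = sprintf("E%04d", eid), family = spec$family,
          subfamily = if (arch == "full") spec$family else spec$ltr_subfamily,
          architecture = arch, chrom = pos$chrom, start = pos$start,
          end = max(starts + lens), strand = strand,
          stringsAsFactors = FALSE)
      }
    } else {
      consensus[spec$subfamily] <- spec$consensus
      comp <- draw_comp(spec$n)
      for (j in seq_len(spec$n)) {
        eid <- eid + 1L
        len <- max(50L, round(comp[j] * spec$consensus))
        strand <- sample(c("+", "-"), 1)
        pos <- place(len)
        seg <- if (spec$class == "LTR") "LTR" else "single"
        frags[[length(frags) + 1L]] <- data.frame(
          element_id = sprintf("E%04d", eid), subfamily = spec$subfamily,
          class = spec$class, family = spec$family, chrom = pos$chrom,
          start = pos$start, end = pos$start + len, strand = strand,
          segment = seg, stringsAsFactors = FALSE)
        elements[[length(elements) + 1L]] <- data.frame(
          element_id = sprintf("E%04d", eid), family = spec$family,
          subfamily = spec$subfamily, architecture = "single",
          chrom = pos$chrom, start = pos$start, end = pos$start + len,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  list(fragments = do.call(rbind, frags),
       elements = do.call(rbind, elements),
       consensus = consensus)
}

.sim_homology <- function(config, coding_genes) {
  u <- stats::runif(length(coding_genes))
  one2one <- u < config$homolog_one2one_frac
  missing <- !one2one &
    u < config$homolog_one2one_frac + config$homolog_missing_frac
  many <- !(one2one | missing)
  rows <- data.frame(human_gene = coding_genes[one2one],
                     mouse_gene = paste0("mm_", coding_genes[one2one]),
                     stringsAsFactors = FALSE)
  many_g <- coding_genes[many]
  if (length(many_g) >= 2) {
    # pairs of human genes sharing one mouse counterpart (to be omitted)
    n_pair <- length(many_g) %/% 2
    shared <- rep(sprintf("mm_shared_%03d", seq_len(n_pair)), each = 2)
    rows <- rbind(rows, data.frame(human_gene = many_g[seq_len(2 * n_pair)],
                                   mouse_gene = shared,
                                   stringsAsFactors = FALSE))
  }
  rows[order(rows$human_gene), ]
}

.sim_mirna_map <- function(config, coding_genes, m6a_genes) {
  n <- config$n_mirnas
  mirna <- sprintf("miR-%03d", seq_len(n))
  family <- sprintf("fam%03d", ceiling(seq_len(n) / 2))
  fam_ids <- unique(family)
  conserved_fam <- stats::setNames(
    stats::runif(length(fam_ids)) < config$mirna_conserved_frac, fam_ids)
  families <- data.frame(mirna = mirna, family = family,
                         conserved = unname(conserved_fam[family]),
                         stringsAsFactors = FALSE)
  cons <- fam_ids[conserved_fam]
  p <- ifelse(coding_genes %in% m6a_genes, config$target_p_m6a,
              config$target_p_other)
  map <- do.call(rbind, lapply(cons, function(f) {
    hit <- stats::runif(length(coding_genes)) < p
    if (!any(hit)) return(NULL)
    data.frame(family = f, gene_id = coding_genes[hit],
               stringsAsFactors = FALSE)
  }))
  if (is.null(map)) map <- data.frame(family = character(0),
                                      gene_id = character(0))
  list(families = families, map = map)
}
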