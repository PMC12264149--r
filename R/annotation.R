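# Gene-model container and GTF input/output.
#
# An AnnotationBundle holds GENCODE-style gene models as plain data.frames in
# 0-based half-open coordinates, together with optional chromosome sequence
# and mandatory chromosome sizes.  CDS intervals exclude the stop codon,
# which is carried as a separate 3-nt record per coding transcript (the
# GENCODE convention).

#' Build an annotation bundle
#'
#' Assembles gene models into the container used by every annotation-aware
#' operation in the package.  All coordinates are 0-based half-open.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`.
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `biotype`.
#' @param exons data.frame with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`, `rank` (1 = 5'-most exon in transcription order).
#' @param cds Optional data.frame like `exons` (no rank) with coding
#'   intervals, stop codon excluded.
#' @param stop_codons Optional data.frame with one 3-nt interval per coding
#'   transcript.
#' @param sequence Optional [Biostrings::DNAStringSet] of chromosome
#'   sequences.
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @return An object of class `AnnotationBundle`.
#' @export
annotation_bundle <- function(genes, transcripts, exons, cds = NULL,
                              stop_codons = NULL, sequence = NULL,
                              chrom_sizes) {
  .assert(!is.null(names(chrom_sizes)) && all(chrom_sizes > 0),
          "chrom_sizes must be a named vector of positive lengths")
  empty_tab <- function(cols) {
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  }
  if (is.null(cds)) {
    cds <- data.frame(transcript_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0))
  }
  if (is.null(stop_codons)) {
    stop_codons <- cds[0, ]
  }
  # normalize ordering so that identical inputs give identical bundles
  if (nrow(genes)) genes <- genes[order(genes$chrom, genes$start, genes$gene_id), ]
  if (nrow(transcripts)) {
    transcripts <- transcripts[order(transcripts$chrom, transcripts$start,
                                     transcripts$transcript_id), ]
  }
  if (nrow(exons)) exons <- exons[order(exons$transcript_id, exons$rank), ]
  if (nrow(cds)) cds <- cds[order(cds$transcript_id, cds$start), ]
  if (nrow(stop_codons)) {
    stop_codons <- stop_codons[order(stop_codons$transcript_id), ]
  }
  rownames(genes) <- rownames(transcripts) <- rownames(exons) <- NULL
  rownames(cds) <- rownames(stop_codons) <- NULL

  b <- structure(list(genes = genes, transcripts = transcripts, exons = exons,
                      cds = cds, stop_codons = stop_codons,
                      sequence = sequence, chrom_sizes = chrom_sizes),
                 class = "AnnotationBundle")
  validate_bundle(b)
  b
}

#' @export
print.AnnotationBundle <- function(x, ...) {
  cat(sprintf(
    "AnnotationBundle: %d genes, %d transcripts, %d exons on %d chromosomes%s\n",
    nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
    length(x$chrom_sizes),
    if (is.null(x$sequence)) "" else " (with sequence)"))
  invisible(x)
}

validate_bundle <- function(b) {
  .assert(all(b$transcripts$gene_id %in% b$genes$gene_id),
          "transcript references a missing gene")
  within_sizes <- function(tab) {
    if (!nrow(tab)) return(TRUE)
    sz <- b$chrom_sizes[tab$chrom]
    all(!is.na(sz)) && all(tab$start >= 0) && all(tab$end <= sz) &&
      all(tab$start < tab$end)
  }
  for (nm in c("genes", "transcripts", "exons", "cds", "stop_codons")) {
    .assert(within_sizes(b[[nm]]),
            "%s intervals outside chrom_sizes (no silent clipping)", nm)
  }
  # exons of a transcript must be non-overlapping and strand-ordered
  if (nrow(b$exons)) {
    by_tx <- split(b$exons, b$exons$transcript_id)
    for (ex in by_tx) {
      ex <- ex[order(ex$rank), ]
      gen_order <- if (ex$strand[1] == "-") order(-ex$start) else order(ex$start)
      .assert(identical(gen_order, seq_len(nrow(ex))),
              "exons of %s are not strand-ordered", ex$transcript_id[1])
      exo <- ex[order(ex$start), ]
      .assert(all(exo$start[-1] >= exo$end[-nrow(exo)]),
              "exons of %s overlap", ex$transcript_id[1])
    }
  }
  invisible(b)
}

# ---------------------------------------------------------------------------
# transcript-coordinate machinery

# exons of one transcript in transcription order
.tx_exons <- function(bundle, tx_id) {
  ex <- bundle$exons[bundle$exons$transcript_id == tx_id, , drop = FALSE]
  .assert(nrow(ex) > 0, "transcript %s has no exons", tx_id)
  ex[order(ex$rank), , drop = FALSE]
}

.tx_length <- function(ex) sum(ex$end - ex$start)

# genomic base (0-based) -> transcript coordinate (0-based); NA if intronic
.genomic_to_tx <- function(pos, ex) {
  len <- ex$end - ex$start
  before <- cumsum(c(0L, len))[seq_len(nrow(ex))]
  hit <- which(pos >= ex$start & pos < ex$end)
  if (!length(hit)) return(NA_integer_)
  i <- hit[1]
  if (ex$strand[1] == "-") {
    before[i] + (ex$end[i] - 1L - pos)
  } else {
    before[i] + (pos - ex$start[i])
  }
}

# transcript interval [t0, t1) -> genomic intervals (0-based half-open)
.tx_to_genomic <- function(t0, t1, ex) {
  len <- ex$end - ex$start
  before <- cumsum(c(0L, len))
  out <- list()
  for (i in seq_len(nrow(ex))) {
    a <- max(t0, before[i]); b <- min(t1, before[i + 1])
    if (a >= b) next
    if (ex$strand[1] == "-") {
      gs <- ex$end[i] - (b - before[i])
      ge <- ex$end[i] - (a - before[i])
    } else {
      gs <- ex$start[i] + (a - before[i])
      ge <- ex$start[i] + (b - before[i])
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom = ex$chrom[i], start = gs, end = ge, strand = ex$strand[i],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# per-transcript region lengths: 5'UTR, CDS (stop excluded), tail
# (stop codon + 3'UTR); coding flag
.tx_regions <- function(bundle) {
  txs <- bundle$transcripts
  out <- data.frame(transcript_id = txs$transcript_id,
                    gene_id = txs$gene_id,
                    tx_len = NA_integer_, u5 = NA_integer_,
                    cds = NA_integer_, tail = NA_integer_,
                    coding = FALSE, stringsAsFactors = FALSE)
  cds_by_tx <- split(bundle$cds, bundle$cds$transcript_id)
  for (i in seq_len(nrow(txs))) {
    tx <- txs$transcript_id[i]
    ex <- .tx_exons(bundle, tx)
    tl <- .tx_length(ex)
    out$tx_len[i] <- tl
    cc <- cds_by_tx[[tx]]
    if (is.null(cc) || !nrow(cc)) next
    cds_len <- sum(cc$end - cc$start)
    # 5'-most coding base in transcript coordinates
    first_base <- if (ex$strand[1] == "-") max(cc$end) - 1L else min(cc$start)
    u5 <- .genomic_to_tx(first_base, ex)
    out$u5[i] <- u5
    out$cds[i] <- cds_len
    out$tail[i] <- tl - u5 - cds_len
    out$coding[i] <- TRUE
  }
  out
}

# Representative transcript per gene: highest expression, ties broken by
# longer exonic length, then lexicographic id.
#' Select the representative transcript of each gene
#'
#' The representative isoform is the one with the highest expression value in
#' the matching Input sample; ties go to the longer transcript, then to the
#' lexicographically smaller identifier.
#'
#' @param bundle An `AnnotationBundle`.
#' @param tx_expr Named numeric vector of transcript-level expression (TPM).
#'   Transcripts absent from the vector count as zero.
#' @return Named character vector mapping `gene_id` to `transcript_id`.
#' @export
representative_transcripts <- function(bundle, tx_expr = NULL) {
  txs <- bundle$transcripts
  expr <- if (is.null(tx_expr)) stats::setNames(numeric(0), character(0)) else tx_expr
  e <- unname(expr[txs$transcript_id])
  e[is.na(e)] <- 0
  len <- vapply(txs$transcript_id,
                function(tx) as.numeric(.tx_length(.tx_exons(bundle, tx))),
                numeric(1))
  ord <- order(txs$gene_id, -e, -len, txs$transcript_id)
  txo <- txs[ord, ]
  keep <- !duplicated(txo$gene_id)
  stats::setNames(txo$transcript_id[keep], txo$gene_id[keep])
}

# ---------------------------------------------------------------------------
# GTF reading / writing

#' Read gene models from a GTF file
#'
#' Parses a GENCODE-style GTF (1-based closed coordinates) into an
#' `AnnotationBundle` (0-based half-open).  `gene` and `transcript` records
#' are derived from exons when absent; a `transcript` record without exons is
#' rejected.  If no `stop_codon` records are present the stop codon is carved
#' out of the last 3 coding bases.
#'
#' @param path GTF file.
#' @param chrom_sizes Named vector of chromosome lengths, or a path to a
#'   two-column `chrom<TAB>size` file.  When `NULL`, sizes are inferred from
#'   the annotation with a warning.
#' @param sequence Optional FASTA path or [Biostrings::DNAStringSet].
#' @return An `AnnotationBundle`.
#' @export
read_gene_models <- function(path, chrom_sizes = NULL, sequence = NULL) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) {
    warning("empty GTF: returning empty bundle")
    sz <- .resolve_chrom_sizes(chrom_sizes, NULL)
    if (is.null(sz)) sz <- c(chrEmpty = 1)
    gtab <- data.frame(gene_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), biotype = character(0))
    ttab <- cbind(data.frame(transcript_id = character(0)), gtab)
    etab <- data.frame(transcript_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), rank = integer(0))
    return(annotation_bundle(gtab, ttab[, c("transcript_id", "gene_id",
                                            "chrom", "start", "end", "strand",
                                            "biotype")],
                             etab, chrom_sizes = sz))
  }
  nfield <- lengths(strsplit(body, "\t", fixed = TRUE))
  bad <- which(nfield < 9L)
  if (length(bad)) {
    all_idx <- which(!grepl("^#", lines) & nzchar(lines))
    stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields",
                 all_idx[bad[1]]), call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df$chrom <- as.character(df$seqnames)
  df$start0 <- df$start - 1L
  df$strand <- as.character(df$strand)
  if (is.null(df$gene_biotype)) df$gene_biotype <- NA_character_
  biotype <- function(d) ifelse(is.na(d$gene_biotype), "protein_coding",
                                d$gene_biotype)

  ex <- df[df$type == "exon", , drop = FALSE]
  txr <- df[df$type == "transcript", , drop = FALSE]
  no_ex <- setdiff(txr$transcript_id, ex$transcript_id)
  .assert(length(no_ex) == 0, "transcript without exons: %s",
          paste(no_ex, collapse = ","))
  .assert(nrow(ex) > 0, "GTF contains no exon records")

  exons <- data.frame(transcript_id = ex$transcript_id, chrom = ex$chrom,
                      start = ex$start0, end = ex$end, strand = ex$strand,
                      stringsAsFactors = FALSE)
  # transcription-order rank
  exons <- exons[order(exons$transcript_id,
                       ifelse(exons$strand == "-", -1, 1) * exons$start), ]
  exons$rank <- stats::ave(seq_len(nrow(exons)), exons$transcript_id,
                           FUN = seq_along)

  tx_from_ex <- do.call(rbind, lapply(split(ex, ex$transcript_id), function(d) {
    data.frame(transcript_id = d$transcript_id[1],
               gene_id = d$gene_id[1], chrom = d$chrom[1],
               start = min(d$start0), end = max(d$end),
               strand = d$strand[1], biotype = biotype(d)[1],
               stringsAsFactors = FALSE)
  }))
  if (nrow(txr)) {
    transcripts <- data.frame(transcript_id = txr$transcript_id,
                              gene_id = txr$gene_id, chrom = txr$chrom,
                              start = txr$start0, end = txr$end,
                              strand = txr$strand, biotype = biotype(txr),
                              stringsAsFactors = FALSE)
    extra <- tx_from_ex[!(tx_from_ex$transcript_id %in%
                            transcripts$transcript_id), , drop = FALSE]
    transcripts <- rbind(transcripts, extra)
  } else {
    transcripts <- tx_from_ex
  }

  gn <- df[df$type == "gene", , drop = FALSE]
  if (nrow(gn)) {
    genes <- data.frame(gene_id = gn$gene_id, chrom = gn$chrom,
                        start = gn$start0, end = gn$end, strand = gn$strand,
                        biotype = biotype(gn), stringsAsFactors = FALSE)
  } else {
    genes <- do.call(rbind, lapply(split(transcripts, transcripts$gene_id),
      function(d) data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
                             start = min(d$start), end = max(d$end),
                             strand = d$strand[1], biotype = d$biotype[1],
                             stringsAsFactors = FALSE)))
  }

  cd <- df[df$type == "CDS", , drop = FALSE]
  cds <- if (nrow(cd)) {
    data.frame(transcript_id = cd$transcript_id, chrom = cd$chrom,
               start = cd$start0, end = cd$end, strand = cd$strand,
               stringsAsFactors = FALSE)
  } else NULL
  sc <- df[df$type == "stop_codon", , drop = FALSE]
  stop_codons <- if (nrow(sc)) {
    data.frame(transcript_id = sc$transcript_id, chrom = sc$chrom,
               start = sc$start0, end = sc$end, strand = sc$strand,
               stringsAsFactors = FALSE)
  } else NULL

  # derive stop codons from the CDS tail when the GTF lacks them
  if (is.null(stop_codons) && !is.null(cds)) {
    parts <- lapply(split(cds, cds$transcript_id), function(d) {
      minus <- d$strand[1] == "-"
      d <- d[order(d$start), ]
      if (minus) {
        st <- data.frame(transcript_id = d$transcript_id[1],
                         chrom = d$chrom[1], start = d$start[1],
                         end = d$start[1] + 3L, strand = d$strand[1])
        d$start[1] <- d$start[1] + 3L
      } else {
        n <- nrow(d)
        st <- data.frame(transcript_id = d$transcript_id[1],
                         chrom = d$chrom[1], start = d$end[n] - 3L,
                         end = d$end[n], strand = d$strand[1])
        d$end[n] <- d$end[n] - 3L
      }
      list(cds = d[d$end > d$start, , drop = FALSE], stop = st)
    })
    cds <- do.call(rbind, lapply(parts, `[[`, "cds"))
    stop_codons <- do.call(rbind, lapply(parts, `[[`, "stop"))
  }

  sz <- .resolve_chrom_sizes(chrom_sizes, NULL)
  if (is.null(sz)) {
    warning("chrom_sizes not supplied: inferring from annotation extent")
    mx <- tapply(c(genes$end, transcripts$end), c(genes$chrom, transcripts$chrom), max)
    sz <- stats::setNames(as.numeric(mx), names(mx))
  }
  seqs <- sequence
  if (is.character(seqs)) seqs <- Biostrings::readDNAStringSet(seqs)

  annotation_bundle(genes, transcripts, exons, cds, stop_codons,
                    sequence = seqs, chrom_sizes = sz)
}

.resolve_chrom_sizes <- function(chrom_sizes, default) {
  if (is.null(chrom_sizes)) return(default)
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1 &&
      file.exists(chrom_sizes)) {
    tab <- .read_tsv(chrom_sizes, header = FALSE)
    return(stats::setNames(as.numeric(tab[[2]]), tab[[1]]))
  }
  chrom_sizes
}

#' Write gene models to a GTF file
#'
#' Inverse of [read_gene_models()]: internal 0-based half-open intervals are
#' converted back to 1-based closed GTF records (`gene`, `transcript`,
#' `exon`, `CDS`, `stop_codon`).
#'
#' @param bundle An `AnnotationBundle`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(bundle, path) {
  fmt <- function(chrom, src, type, start, end, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, src, type, as.integer(start) + 1L, as.integer(end),
            strand, attrs)
  }
  lines <- character(0)
  g <- bundle$genes
  if (nrow(g)) {
    lines <- c(lines, fmt(g$chrom, "oetm6a", "gene", g$start, g$end, g$strand,
                          sprintf('gene_id "%s"; gene_biotype "%s";',
                                  g$gene_id, g$biotype)))
  }
  t <- bundle$transcripts
  if (nrow(t)) {
    lines <- c(lines, fmt(t$chrom, "oetm6a", "transcript", t$start, t$end,
                          t$strand,
                          sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                                  t$gene_id, t$transcript_id, t$biotype)))
  }
  tx2g <- stats::setNames(t$gene_id, t$transcript_id)
  e <- bundle$exons
  if (nrow(e)) {
    lines <- c(lines, fmt(e$chrom, "oetm6a", "exon", e$start, e$end, e$strand,
                          sprintf('gene_id "%s"; transcript_id "%s"; exon_number "%d";',
                                  tx2g[e$transcript_id], e$transcript_id,
                                  e$rank)))
  }
  for (nm in c("cds", "stop_codons")) {
    d <- bundle[[nm]]
    if (!nrow(d)) next
    type <- if (nm == "cds") "CDS" else "stop_codon"
    lines <- c(lines, fmt(d$chrom, "oetm6a", type, d$start, d$end, d$strand,
                          sprintf('gene_id "%s"; transcript_id "%s";',
                                  tx2g[d$transcript_id], d$transcript_id)))
  }
  writeLines(lines, path)
  invisible(path)
}
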