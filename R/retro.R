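# Locus-level retrotransposon analysis: filtering of RepeatMasker-style
# annotations to analyzable loci (completeness, full-length ERV
# architecture, exon exclusion), max-over-bins expression and m6A scoring,
# subfamily summaries, element-scaled profiles, and Ctrl-vs-inhibitor
# comparisons.

#' Read a RepeatMasker-style repeat annotation
#'
#' Tab-separated with header: `subfamily`, `class` (LINE/SINE/LTR/SVA),
#' `family`, `chrom`, `start`, `end` (0-based half-open), `strand`,
#' `segment` (`LTR`, `internal` or `single`).
#'
#' @param path TSV file.
#' @return data.frame of raw repeat fragments.
#' @export
read_repeat_annotation <- function(path) {
  tab <- .read_tsv(path, header = TRUE)
  need <- c("subfamily", "class", "family", "chrom", "start", "end",
            "strand", "segment")
  .assert(all(need %in% names(tab)), "repeat annotation must have columns %s",
          paste(need, collapse = ","))
  tab
}

#' Read a consensus-length table
#'
#' Two columns: `subfamily`, `length` (bp of the full-length reference
#' element).  For ERV families an additional `<family>` row gives the
#' full-length element size.
#'
#' @param path TSV file.
#' @return Named numeric vector.
#' @export
read_consensus_lengths <- function(path) {
  tab <- .read_tsv(path, header = TRUE)
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

#' Filter repeat annotations to analyzable loci
#'
#' Applies, in order: (1) for LINE/SINE/SVA and solo LTR loci a completeness
#' threshold (annotated length / consensus full length >= `min_completeness`,
#' boundary closed); (2) assembly of full-length ERVs as same-strand,
#' same-family runs of 5'LTR + internal(+) + 3'LTR fragments within
#' `gap_tol` bp — kept on architecture alone; LTR fragments not part of such
#' a run are solo-LTR candidates, internal fragments without both flanks are
#' dropped; (3) removal of any locus overlapping an annotated gene exon by
#' >= 1 bp.  Removal counts are logged per rule.
#'
#' @param repeats Raw fragment table from [read_repeat_annotation()].
#' @param consensus Named consensus lengths from [read_consensus_lengths()].
#' @param bundle An `AnnotationBundle` providing the exons to exclude.
#' @param min_completeness Completeness threshold (default 0.9).
#' @param gap_tol Maximum gap between fragments of one element (default 500).
#' @return data.frame of class `RepeatLocus`: `locus_id`, `subfamily`,
#'   `class`, `family`, `chrom`, `start`, `end`, `strand`, `completeness`,
#'   `architecture` (`"solo"`, `"full_length_ERV"`, `"n/a"`).
#' @export
filter_repeat_loci <- function(repeats, consensus, bundle,
                               min_completeness = 0.9, gap_tol = 500) {
  .need_consensus <- function(subfam) {
    miss <- setdiff(unique(subfam), names(consensus))
    .assert(length(miss) == 0, "no consensus length for subfamily: %s",
            paste(miss, collapse = ","))
  }
  loci <- list()

  ## LINE / SINE / SVA: one fragment = one candidate locus
  simple <- repeats[repeats$class != "LTR", , drop = FALSE]
  if (nrow(simple)) {
    .need_consensus(simple$subfamily)
    comp <- (simple$end - simple$start) / consensus[simple$subfamily]
    keep <- comp >= min_completeness
    .log_counts("filter_repeat_loci: LINE/SINE/SVA completeness",
                nrow(simple), sum(keep))
    if (any(keep)) {
      loci[[length(loci) + 1L]] <- data.frame(
        subfamily = simple$subfamily[keep], class = simple$class[keep],
        family = simple$family[keep], chrom = simple$chrom[keep],
        start = simple$start[keep], end = simple$end[keep],
        strand = simple$strand[keep], completeness = unname(comp[keep]),
        architecture = "n/a", stringsAsFactors = FALSE)
    }
  }

  ## LTR class: assemble full-length ERVs, keep leftover solo LTRs
  ltr <- repeats[repeats$class == "LTR", , drop = FALSE]
  if (nrow(ltr)) {
    ltr <- ltr[order(ltr$chrom, ltr$start), ]
    grp_key <- paste(ltr$chrom, ltr$strand, ltr$family)
    n_full <- 0L; n_solo_cand <- 0L; n_int_dropped <- 0L
    solo_rows <- list()
    for (key in unique(grp_key)) {
      d <- ltr[grp_key == key, , drop = FALSE]
      gap <- c(Inf, d$start[-1] - d$end[-nrow(d)])
      run_id <- cumsum(gap > gap_tol)
      for (rid in unique(run_id)) {
        r <- d[run_id == rid, , drop = FALSE]
        seg <- r$segment
        is_full <- nrow(r) >= 3 && seg[1] == "LTR" &&
          seg[nrow(r)] == "LTR" && any(seg == "internal")
        if (is_full) {
          n_full <- n_full + 1L
          full_name <- r$family[1]
          comp <- if (full_name %in% names(consensus)) {
            sum(r$end - r$start) / consensus[[full_name]]
          } else NA_real_
          loci[[length(loci) + 1L]] <- data.frame(
            subfamily = full_name, class = "LTR", family = full_name,
            chrom = r$chrom[1], start = min(r$start), end = max(r$end),
            strand = r$strand[1], completeness = comp,
            architecture = "full_length_ERV", stringsAsFactors = FALSE)
        } else {
          solo_rows[[length(solo_rows) + 1L]] <- r[r$segment == "LTR", ,
                                                   drop = FALSE]
          n_int_dropped <- n_int_dropped + sum(r$segment == "internal")
        }
      }
    }
    solo <- do.call(rbind, solo_rows)
    if (!is.null(solo) && nrow(solo)) {
      .need_consensus(solo$subfamily)
      comp <- (solo$end - solo$start) / consensus[solo$subfamily]
      keep <- comp >= min_completeness
      .log_counts("filter_repeat_loci: solo-LTR completeness", nrow(solo),
                  sum(keep))
      if (any(keep)) {
        loci[[length(loci) + 1L]] <- data.frame(
          subfamily = solo$subfamily[keep], class = "LTR",
          family = solo$family[keep], chrom = solo$chrom[keep],
          start = solo$start[keep], end = solo$end[keep],
          strand = solo$strand[keep], completeness = unname(comp[keep]),
          architecture = "solo", stringsAsFactors = FALSE)
      }
    }
    .log_msg("filter_repeat_loci: %d full-length ERV(s); %d orphan internal fragment(s) dropped",
             n_full, n_int_dropped)
  }

  out <- do.call(rbind, loci)
  if (is.null(out)) {
    out <- data.frame(subfamily = character(0), class = character(0),
                      family = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), completeness = numeric(0),
                      architecture = character(0))
  }

  ## exclude loci intersecting gene exons
  if (nrow(out) && nrow(bundle$exons)) {
    ex_gr <- .reduce0(list(bundle$exons))
    lo_gr <- .gr0(out$chrom, out$start, out$end)
    hit <- GenomicRanges::countOverlaps(lo_gr, ex_gr) > 0
    .log_counts("filter_repeat_loci: exon-overlap exclusion", nrow(out),
                sum(!hit))
    out <- out[!hit, , drop = FALSE]
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out)) out$locus_id <- sprintf("RL%05d", seq_len(nrow(out)))
  class(out) <- c("RepeatLocus", "data.frame")
  out
}

#' Score repeat loci from binned tracks
#'
#' Per replicate, a locus' expression is the maximum Input RPKM over all
#' bins overlapping the locus and its m6A value is the maximum m6A signal
#' over the same bins; the stage value is the mean across replicates.  A
#' locus is expressed when its expression value is > 0 and m6A-modified
#' when its m6A value is > 0 (strict).
#'
#' @param loci `RepeatLocus` data.frame.
#' @param input_tracks Named list of Input RPKM `BinnedTrack`s (replicates).
#' @param signal_tracks Named list of m6A signal `BinnedTrack`s, matching
#'   `input_tracks`.
#' @return `loci` with added columns `expression`, `m6a_signal`,
#'   `expressed`, `modified`.
#' @export
score_repeat_loci <- function(loci, input_tracks, signal_tracks) {
  .assert(length(input_tracks) == length(signal_tracks),
          "replicate lists differ in length")
  n_rep <- length(input_tracks)
  max_over_bins <- function(track, chrom, start, end) {
    .assert(chrom %in% names(track$values) &&
              end <= track$chrom_sizes[[chrom]],
            "locus outside track bounds on %s", chrom)
    sp <- .bin_span(start, end, track$bin_size)
    max(track$values[[chrom]][(sp$first + 1L):(sp$last + 1L)])
  }
  expr <- matrix(NA_real_, nrow(loci), n_rep)
  sig <- matrix(NA_real_, nrow(loci), n_rep)
  for (r in seq_len(n_rep)) {
    for (i in seq_len(nrow(loci))) {
      expr[i, r] <- max_over_bins(input_tracks[[r]], loci$chrom[i],
                                  loci$start[i], loci$end[i])
      sig[i, r] <- max_over_bins(signal_tracks[[r]], loci$chrom[i],
                                 loci$start[i], loci$end[i])
    }
  }
  loci$expression <- rowMeans(expr)
  loci$m6a_signal <- rowMeans(sig)
  loci$expressed <- loci$expression > 0
  loci$modified <- loci$m6a_signal > 0
  loci
}

#' Per-subfamily summary of expressed and m6A-modified loci
#'
#' @param scored Output of [score_repeat_loci()].
#' @return data.frame of class `RepeatSubfamilySummary`: `subfamily`,
#'   `n_loci`, `n_expressed`, `n_modified` (among expressed),
#'   `percent_modified` (missing when nothing is expressed).
#' @export
subfamily_summary <- function(scored) {
  out <- do.call(rbind, lapply(split(scored, scored$subfamily), function(d) {
    ne <- sum(d$expressed)
    nm <- sum(d$expressed & d$modified)
    data.frame(subfamily = d$subfamily[1], n_loci = nrow(d),
               n_expressed = ne, n_modified = nm,
               percent_modified = if (ne > 0) 100 * nm / ne else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("RepeatSubfamilySummary", "data.frame")
  out
}

#' Element-scaled m6A signal profile
#'
#' Divides each locus into `n_bins` equal relative-position segments
#' oriented 5' to 3' (minus-strand loci reversed); a segment's value is the
#' mean of the 10-bp signal bins it overlaps, and the profile is the
#' per-segment mean and standard deviation across loci.
#'
#' @param loci `RepeatLocus` rows of one subfamily (typically the expressed
#'   ones).
#' @param signal A `BinnedTrack` of m6A signal.
#' @param n_bins Number of relative-position segments (default 100).
#' @return An object of class `ElementProfile`: `subfamily`, `mean`, `sd`
#'   (length `n_bins`), `n_loci`.
#' @export
element_profile <- function(loci, signal, n_bins = 100) {
  .assert(nrow(loci) >= 1, "need at least one locus")
  bs <- signal$bin_size
  prof <- matrix(NA_real_, nrow(loci), n_bins)
  for (i in seq_len(nrow(loci))) {
    v <- signal$values[[loci$chrom[i]]]
    bounds <- loci$start[i] + (loci$end[i] - loci$start[i]) *
      (0:n_bins) / n_bins
    for (k in seq_len(n_bins)) {
      lo <- bounds[k]; hi <- bounds[k + 1]
      b0 <- floor(lo / bs); b1 <- floor((ceiling(hi) - 1) / bs)
      prof[i, k] <- mean(v[(b0 + 1):(b1 + 1)])
    }
    if (loci$strand[i] == "-") prof[i, ] <- rev(prof[i, ])
  }
  col_sd <- apply(prof, 2, function(z) {
    if (length(z) < 2) 0 else stats::sd(z)
  })
  structure(list(subfamily = loci$subfamily[1],
                 mean = colMeans(prof),
                 sd = col_sd,
                 n_loci = nrow(loci)),
            class = "ElementProfile")
}

#' @export
print.ElementProfile <- function(x, ...) {
  cat(sprintf("ElementProfile %s: %d loci, %d segments, mean signal %.3f\n",
              x$subfamily, x$n_loci, length(x$mean), mean(x$mean)))
  invisible(x)
}

#' Compare retrotransposon m6A between conditions
#'
#' Counts peaks overlapping any retained repeat locus by >= 1 bp in each
#' condition and reports the percent reduction; per-subfamily locus m6A
#' signal is compared between conditions by a two-sided Wilcoxon rank-sum
#' test.
#'
#' @param peaks_ctrl,peaks_treated Peak data.frames per condition.
#' @param loci `RepeatLocus` data.frame (same locus set for both
#'   conditions).
#' @param scored_ctrl,scored_treated Optional outputs of
#'   [score_repeat_loci()] per condition for the per-subfamily signal
#'   comparison.
#' @return List with `n_ctrl`, `n_treated`, `reduction_percent` (`NA` when
#'   no control peak is repeat-associated), and `subfamily_tests`.
#' @export
condition_peak_comparison <- function(peaks_ctrl, peaks_treated, loci,
                                      scored_ctrl = NULL,
                                      scored_treated = NULL) {
  count_assoc <- function(pk) {
    if (is.null(pk) || !nrow(pk) || !nrow(loci)) return(0L)
    p_gr <- .gr0(pk$chrom, pk$start, pk$end)
    l_gr <- .gr0(loci$chrom, loci$start, loci$end)
    sum(GenomicRanges::countOverlaps(p_gr, l_gr) > 0)
  }
  n_ctrl <- count_assoc(peaks_ctrl)
  n_trt <- count_assoc(peaks_treated)
  reduction <- if (n_ctrl > 0) 100 * (1 - n_trt / n_ctrl) else NA_real_
  tests <- NULL
  if (!is.null(scored_ctrl) && !is.null(scored_treated)) {
    subfams <- intersect(unique(scored_ctrl$subfamily),
                         unique(scored_treated$subfamily))
    tests <- do.call(rbind, lapply(subfams, function(sf) {
      a <- scored_ctrl$m6a_signal[scored_ctrl$subfamily == sf &
                                    scored_ctrl$expressed]
      b <- scored_treated$m6a_signal[scored_treated$subfamily == sf &
                                       scored_treated$expressed]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      w <- wilcoxon_rank_sum(a, b)
      data.frame(subfamily = sf, n_ctrl = length(a), n_treated = length(b),
                 median_ctrl = stats::median(a),
                 median_treated = stats::median(b),
                 p_value = w$p_value, stringsAsFactors = FALSE)
    }))
  }
  list(n_ctrl = n_ctrl, n_treated = n_trt, reduction_percent = reduction,
       subfamily_tests = tests)
}
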