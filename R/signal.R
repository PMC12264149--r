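# Binned RPKM coverage, the m6A signal statistic, sample similarity, and a
# naive threshold peak caller used on synthetic data (the production peaks
# are an upstream input).

#' Binned RPKM coverage from fragment intervals
#'
#' Each fragment (read pair) is counted once in every bin it overlaps by at
#' least 1 bp; bin counts are scaled to reads per kilobase per million:
#' `n_b / ((bin_size/1000) * (total/1e6))`.
#'
#' @param fragments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open fragment intervals).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param bin_size Bin width in bp (default 10).
#' @param total Total mapped fragments used for scaling (defaults to
#'   `nrow(fragments)`); must be positive.
#' @param sample Sample label.
#' @return A `BinnedTrack` of kind `"rpkm"`.
#' @export
compute_binned_rpkm <- function(fragments, chrom_sizes, bin_size = 10,
                                total = nrow(fragments), sample = "") {
  .assert(total > 0, "total mapped fragments must be positive")
  if (nrow(fragments)) {
    .assert(all(fragments$chrom %in% names(chrom_sizes)) &&
              all(fragments$start >= 0) &&
              all(fragments$end <= chrom_sizes[fragments$chrom]),
            "fragments outside chrom_sizes")
    .assert(all(fragments$end > fragments$start), "empty fragment interval")
  }
  scale <- (bin_size / 1000) * (total / 1e6)
  values <- lapply(names(chrom_sizes), function(chrom) {
    nb <- ceiling(chrom_sizes[[chrom]] / bin_size)
    d <- fragments[fragments$chrom == chrom, , drop = FALSE]
    if (!nrow(d)) return(numeric(nb))
    first <- d$start %/% bin_size
    last <- (d$end - 1L) %/% bin_size
    k <- last - first + 1L
    idx <- rep(first, k) + sequence(k) - 1L
    tabulate(idx + 1L, nbins = nb) / scale
  })
  names(values) <- names(chrom_sizes)
  binned_track(values, bin_size, chrom_sizes, sample = sample, total = total,
               kind = "rpkm")
}

#' Per-bin m6A signal
#'
#' The m6A signal of a bin is `log2((RPKM_IP + 1) / (RPKM_Input + 1))`; the
#' pseudocount keeps every bin finite.
#'
#' @param ip,input `BinnedTrack`s of RPKM values on the same bin grid.
#' @return A `BinnedTrack` of kind `"signal"`.
#' @export
compute_m6a_signal <- function(ip, input) {
  .assert(.same_grid(ip, input), "IP and Input tracks on different bin grids")
  values <- mapply(function(a, b) log2((a + 1) / (b + 1)),
                   ip$values, input$values, SIMPLIFY = FALSE)
  binned_track(values, ip$bin_size, ip$chrom_sizes,
               sample = paste0(ip$sample, ".m6A"), total = ip$total,
               kind = "signal")
}

#' Sample similarity: Pearson correlation, PCA and hierarchical clustering
#'
#' Tracks are re-aggregated (mean) to window-sized bins; Pearson `r` is
#' computed over all windows, the dissimilarity between samples is `1 - r`,
#' clustering uses average linkage, and PCA runs on the feature-centered
#' window x sample matrix (no scaling).  A track with zero variance gets
#' missing `r` entries and is excluded from clustering and PCA with a
#' warning.
#'
#' @param tracks List of `BinnedTrack`s on one genome.
#' @param window Aggregation window in bp (default 1000); must be a multiple
#'   of the bin size.
#' @return An object of class `SimilarityResult` with elements `r`, `dist`,
#'   `pca` (a `prcomp`), `hclust`, and the aggregated `matrix`.
#' @export
sample_similarity <- function(tracks, window = 1000) {
  .assert(length(tracks) >= 2, "need at least two tracks")
  bs <- tracks[[1]]$bin_size
  .assert(window %% bs == 0, "window must be a multiple of bin_size")
  for (t in tracks[-1]) {
    .assert(.same_grid(tracks[[1]], t), "tracks on different genomes")
  }
  k <- window %/% bs
  agg_one <- function(track) {
    unlist(lapply(track$values, function(v) {
      grp <- (seq_along(v) - 1L) %/% k
      as.numeric(tapply(v, grp, mean))
    }), use.names = FALSE)
  }
  mat <- sapply(tracks, agg_one)
  colnames(mat) <- vapply(seq_along(tracks), function(i) {
    s <- tracks[[i]]$sample
    if (nzchar(s)) s else paste0("sample_", i)
  }, character(1))

  ok <- apply(mat, 2, stats::sd) > 0
  if (!all(ok)) {
    warning(sprintf("zero-variance track(s) excluded from clustering: %s",
                    paste(colnames(mat)[!ok], collapse = ",")))
  }
  r <- matrix(NA_real_, ncol(mat), ncol(mat),
              dimnames = list(colnames(mat), colnames(mat)))
  r[ok, ok] <- stats::cor(mat[, ok, drop = FALSE])
  diag(r)[ok[colnames(r)]] <- 1
  d <- 1 - r
  hc <- if (sum(ok) >= 2) {
    stats::hclust(stats::as.dist(d[ok, ok, drop = FALSE]), method = "average")
  } else NULL
  pca <- if (sum(ok) >= 2) {
    stats::prcomp(t(mat[, ok, drop = FALSE]), center = TRUE, scale. = FALSE)
  } else NULL
  structure(list(r = r, dist = d, pca = pca, hclust = hc, matrix = mat),
            class = "SimilarityResult")
}

#' @export
print.SimilarityResult <- function(x, ...) {
  cat(sprintf("SimilarityResult: %d samples, %d windows\n",
              ncol(x$matrix), nrow(x$matrix)))
  print(round(x$r, 3))
  invisible(x)
}

#' Naive threshold peak caller
#'
#' Stand-in for the model-based caller used upstream on real data; intended
#' for synthetic end-to-end runs.  Maximal runs of bins with signal at or
#' above `threshold` are kept (gaps of up to `merge_gap` bins bridged) when
#' at least `min_bins` long.  The summit is the center of the leftmost
#' maximal-signal bin.
#'
#' @param signal A `BinnedTrack` of kind `"signal"`.
#' @param threshold Minimum per-bin signal (log2 units, > 0).
#' @param min_bins Minimum run length in bins.
#' @param merge_gap Maximum sub-threshold gap (bins) bridged within a run.
#' @return Peak data.frame (see [read_peaks()] for columns).
#' @export
call_peaks_naive <- function(signal, threshold, min_bins = 3, merge_gap = 1) {
  .assert(threshold > 0, "threshold must be positive")
  bs <- signal$bin_size
  rows <- list()
  for (chrom in names(signal$values)) {
    v <- signal$values[[chrom]]
    above <- v >= threshold
    if (!any(above)) next
    idx <- which(above)
    gap_after <- diff(idx) - 1L
    new_run <- c(TRUE, gap_after > merge_gap)
    run_id <- cumsum(new_run)
    for (rid in unique(run_id)) {
      b <- idx[run_id == rid]
      first <- b[1]; last <- b[length(b)]
      if (last - first + 1L < min_bins) next
      seg <- v[first:last]
      max_bin <- first + which.max(seg) - 1L   # leftmost max (which.max)
      start <- (first - 1L) * bs
      end <- min(last * bs, signal$chrom_sizes[[chrom]])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = start, end = end,
        name = NA_character_, score = max(seg), strand = ".",
        signal = max(seg), pvalue = NA_real_, qvalue = NA_real_,
        summit = (max_bin - 1L) * bs + bs %/% 2L,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), score = numeric(0), strand = character(0),
               signal = numeric(0), pvalue = numeric(0), qvalue = numeric(0),
               summit = integer(0))
  if (nrow(out)) out$name <- paste0("naive_peak_", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}
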