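# Binned genome tracks and peak file I/O.

#' Construct a binned genome track
#'
#' A BinnedTrack stores one value per fixed-width genomic bin (default width
#' 10 bp), per chromosome.  RPKM tracks are non-negative; m6A signal tracks
#' are log2 ratios and may be negative.
#'
#' @param values Named list of numeric vectors, one per chromosome, each of
#'   length `ceiling(chrom_size / bin_size)`.
#' @param bin_size Bin width in bp.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param sample Sample label.
#' @param total Total mapped fragments behind the track (`NA` if unknown).
#' @param kind One of `"rpkm"`, `"signal"`, `"raw"`.
#' @return An object of class `BinnedTrack`.
#' @export
binned_track <- function(values, bin_size, chrom_sizes, sample = "",
                         total = NA_real_, kind = "rpkm") {
  .assert(bin_size >= 1, "bin_size must be positive")
  .assert(setequal(names(values), names(chrom_sizes)),
          "value chromosomes must match chrom_sizes")
  for (chrom in names(values)) {
    want <- ceiling(chrom_sizes[[chrom]] / bin_size)
    .assert(length(values[[chrom]]) == want,
            "chromosome %s: expected %d bins, got %d", chrom, want,
            length(values[[chrom]]))
    .assert(all(is.finite(values[[chrom]])), "non-finite values on %s", chrom)
    if (kind == "rpkm") {
      .assert(all(values[[chrom]] >= 0), "negative RPKM on %s", chrom)
    }
  }
  structure(list(values = values[names(chrom_sizes)], bin_size = bin_size,
                 chrom_sizes = chrom_sizes, sample = sample, total = total,
                 kind = kind),
            class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  cat(sprintf("BinnedTrack [%s] '%s': %d chromosomes, bin %d bp, total %s\n",
              x$kind, x$sample, length(x$values), x$bin_size,
              format(x$total)))
  invisible(x)
}

.same_grid <- function(a, b) {
  a$bin_size == b$bin_size && identical(names(a$values), names(b$values)) &&
    all(lengths(a$values) == lengths(b$values))
}

#' Read peaks from a narrowPeak or BED file
#'
#' narrowPeak column 10 is the summit offset from `start`; an offset of -1
#' (and any plain BED file) falls back to the interval midpoint (floored).
#' Records with `start >= end` are rejected and counted.
#'
#' @param path narrowPeak (10 columns) or BED (>= 3 columns) file.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `signal`, `pvalue`, `qvalue`, `summit` (absolute 0-based
#'   position).
#' @export
read_peaks <- function(path) {
  tab <- .read_tsv(path, header = FALSE)
  if (!nrow(tab)) {
    warning("empty peak file")
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      signal = numeric(0), pvalue = numeric(0),
                      qvalue = numeric(0), summit = integer(0)))
  }
  .assert(ncol(tab) >= 3, "peak file needs at least 3 BED columns")
  out <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]),
                    end = as.integer(tab[[3]]),
                    stringsAsFactors = FALSE)
  out$name <- if (ncol(tab) >= 4) as.character(tab[[4]]) else
    paste0("peak_", seq_len(nrow(out)))
  out$score <- if (ncol(tab) >= 5) as.numeric(tab[[5]]) else 0
  out$strand <- if (ncol(tab) >= 6) as.character(tab[[6]]) else "."
  out$signal <- if (ncol(tab) >= 7) as.numeric(tab[[7]]) else NA_real_
  out$pvalue <- if (ncol(tab) >= 8) as.numeric(tab[[8]]) else NA_real_
  out$qvalue <- if (ncol(tab) >= 9) as.numeric(tab[[9]]) else NA_real_
  offset <- if (ncol(tab) >= 10) as.integer(tab[[10]]) else rep(-1L, nrow(out))

  bad <- out$start >= out$end
  if (any(bad)) {
    .log_counts("read_peaks: rejecting start >= end records",
                nrow(out), sum(!bad))
    out <- out[!bad, , drop = FALSE]
    offset <- offset[!bad]
  }
  midpoint <- out$start + (out$end - out$start) %/% 2L
  out$summit <- ifelse(offset >= 0L, out$start + offset, midpoint)
  rownames(out) <- NULL
  out
}

#' Write peaks as narrowPeak
#'
#' @param peaks data.frame as returned by [read_peaks()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  n <- nrow(peaks)
  tab <- data.frame(
    peaks$chrom, peaks$start, peaks$end,
    peaks$name %||% paste0("peak_", seq_len(n)),
    peaks$score %||% rep(0, n),
    peaks$strand %||% rep(".", n),
    if (is.null(peaks$signal)) rep(0, n) else ifelse(is.na(peaks$signal), 0, peaks$signal),
    if (is.null(peaks$pvalue)) rep(-1, n) else ifelse(is.na(peaks$pvalue), -1, peaks$pvalue),
    if (is.null(peaks$qvalue)) rep(-1, n) else ifelse(is.na(peaks$qvalue), -1, peaks$qvalue),
    peaks$summit - peaks$start)
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a coverage track from bedGraph or bigWig
#'
#' Interval values are resampled onto the configured fixed bins; a bin
#' covered by several intervals takes their length-weighted mean, and
#' uncovered bins are 0.
#'
#' @param path bedGraph (`.bedgraph`/`.bg`) or bigWig (`.bw`/`.bigwig`) file.
#' @param chrom_sizes Named vector of chromosome lengths (or a path).
#' @param bin_size Bin width in bp (default 10).
#' @param sample Sample label; defaults to the file name.
#' @param kind Track kind, see [binned_track()].
#' @return A `BinnedTrack`.
#' @export
read_signal_track <- function(path, chrom_sizes, bin_size = 10,
                              sample = basename(path), kind = "rpkm") {
  chrom_sizes <- .resolve_chrom_sizes(chrom_sizes, NULL)
  .assert(!is.null(chrom_sizes), "chrom_sizes required")
  fmt <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE))
    "BigWig" else "bedGraph"
  if (fmt == "bedGraph" && !length(readLines(path, n = 1))) {
    warning("empty track file: returning an all-zero track")
    values <- lapply(chrom_sizes,
                     function(sz) numeric(ceiling(sz / bin_size)))
    return(binned_track(values, bin_size, chrom_sizes, sample = sample,
                        kind = kind))
  }
  gr <- rtracklayer::import(path, format = fmt)
  iv <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   value = as.numeric(gr$score))
  bad_chrom <- setdiff(unique(iv$chrom), names(chrom_sizes))
  .assert(length(bad_chrom) == 0, "interval on unknown chromosome %s",
          paste(bad_chrom, collapse = ","))
  beyond <- iv$end > chrom_sizes[iv$chrom]
  .assert(!any(beyond), "interval beyond chromosome end on %s",
          paste(unique(iv$chrom[beyond]), collapse = ","))

  values <- lapply(names(chrom_sizes), function(chrom) {
    nb <- ceiling(chrom_sizes[[chrom]] / bin_size)
    num <- numeric(nb)   # sum of value * covered-bp per bin
    cov <- numeric(nb)   # covered bp per bin
    d <- iv[iv$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      sp <- .bin_span(d$start[i], d$end[i], bin_size)
      bins <- sp$first:sp$last
      lo <- pmax(d$start[i], bins * bin_size)
      hi <- pmin(d$end[i], (bins + 1) * bin_size)
      w <- hi - lo
      num[bins + 1L] <- num[bins + 1L] + d$value[i] * w
      cov[bins + 1L] <- cov[bins + 1L] + w
    }
    out <- numeric(nb)
    nz <- cov > 0
    out[nz] <- num[nz] / cov[nz]   # length-weighted mean over covered bp
    out
  })
  names(values) <- names(chrom_sizes)
  binned_track(values, bin_size, chrom_sizes, sample = sample, kind = kind)
}

#' Write a binned track as bedGraph
#'
#' Adjacent equal-valued bins are merged into one interval; zero bins are
#' omitted (bedGraph default semantics).
#'
#' @param track A `BinnedTrack`.
#' @param path Output file.
#' @param keep_zero Keep zero-valued intervals (default drop).
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, keep_zero = FALSE) {
  rows <- lapply(names(track$values), function(chrom) {
    v <- track$values[[chrom]]
    if (!length(v)) return(NULL)
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    start <- starts_bin * track$bin_size
    end <- pmin(ends_bin * track$bin_size, track$chrom_sizes[[chrom]])
    keep <- if (keep_zero) rep(TRUE, length(r$values)) else r$values != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = chrom, start = start[keep], end = end[keep],
               value = r$values[keep])
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(chrom = character(0), start = integer(0),
                                      end = integer(0), value = numeric(0))
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE, col.names = FALSE,
                     scipen = 50)
  invisible(path)
}
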