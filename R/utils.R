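# Internal helpers shared across modules.
#
# Coordinate convention: every interval held in a plain data.frame inside this
# package is 0-based half-open ([start, end)), the BED convention.  GTF input
# (1-based closed) is converted on read and back on write.  When a Bioconductor
# range container is needed for overlap machinery, .gr0() converts on the fly.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
.gr0 <- function(chrom, start, end, strand = NULL) {
  # 0-based half-open -> GRanges (1-based closed)
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    strand = if (is.null(strand)) "*" else strand
  )
}

.df0 <- function(gr) {
  # GRanges -> 0-based half-open data.frame
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

# Audit log: every filter reports input/output record counts.
.log_counts <- function(step, n_in, n_out) {
  message(sprintf("[oetm6a] %s: %d in -> %d out (%d removed)",
                  step, n_in, n_out, n_in - n_out))
  invisible(NULL)
}

.log_msg <- function(...) {
  message(sprintf("[oetm6a] %s", sprintf(...)))
  invisible(NULL)
}

# Bins overlapped by a 0-based half-open interval, as 0-based bin indices.
.bin_span <- function(start, end, bin_size) {
  .assert(all(end > start), "interval end must exceed start")
  first <- start %/% bin_size
  last <- (end - 1L) %/% bin_size
  list(first = first, last = last)
}

# Split `total` into `k` integer parts, each >= min_part (used by the
# simulator for exon length composition).
.split_len <- function(total, k, min_part) {
  .assert(total >= k * min_part, "cannot split %d into %d parts >= %d",
          total, k, min_part)
  free <- total - k * min_part
  if (k == 1L) return(total)
  w <- stats::runif(k)
  extra <- floor(free * w / sum(w))
  extra[1L] <- extra[1L] + (free - sum(extra))
  as.integer(min_part + extra)
}

# Five-number summary used by all boxplot-style outputs: 5th/25th/50th/75th/
# 95th percentiles (linear interpolation, quantile type 7) plus the mean.
.five_num <- function(x) {
  q <- stats::quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7,
                       names = FALSE)
  c(p5 = q[1], p25 = q[2], median = q[3], p75 = q[4], p95 = q[5],
    mean = mean(x))
}

.write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = ".")
  invisible(path)
}

.read_tsv <- function(path, ...) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = ".", ...))
}
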