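# Gene x sample abundance container (TPM/FPKM/RPM) with stage/replicate
# metadata, plus the median-of-ratios between-sample normalization.

#' Construct an expression matrix
#'
#' @param values Numeric matrix, genes x samples, with dimnames.
#' @param samples data.frame with one row per column of `values`:
#'   `sample`, `stage`, `replicate` (and optionally `species`).
#' @param unit Abundance unit label ("TPM", "FPKM", "RPM").
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, samples, unit = "TPM") {
  .assert(is.matrix(values) && !is.null(rownames(values)) &&
            !is.null(colnames(values)), "values must be a named matrix")
  .assert(all(values >= 0), "abundances must be non-negative")
  .assert(nrow(samples) == ncol(values) &&
            identical(samples$sample, colnames(values)),
          "sample metadata must match matrix columns")
  structure(list(values = values, samples = samples, unit = unit,
                 size_factors = NULL),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d samples (%d stages)%s\n",
              x$unit, nrow(x$values), ncol(x$values),
              length(unique(x$samples$stage)),
              if (is.null(x$size_factors)) "" else ", normalized"))
  invisible(x)
}

#' Per-stage mean abundance
#'
#' Averages replicate columns (arithmetic mean) within each stage.
#'
#' @param em An `ExpressionMatrix`.
#' @return Numeric matrix, genes x stages.
#' @export
stage_means <- function(em) {
  stages <- unique(em$samples$stage)
  out <- sapply(stages, function(s) {
    cols <- em$samples$sample[em$samples$stage == s]
    rowMeans(em$values[, cols, drop = FALSE])
  })
  if (is.null(dim(out))) out <- matrix(out, ncol = length(stages),
                                       dimnames = list(rownames(em$values),
                                                       stages))
  colnames(out) <- stages
  out
}

#' Median-of-ratios between-sample normalization
#'
#' DESeq-style size factors: the reference is the per-gene geometric mean
#' over samples (genes with a zero in any sample are excluded); each sample's
#' factor is the median over genes of sample / reference, and abundances are
#' divided by it.
#'
#' @param em An `ExpressionMatrix`.
#' @return The normalized `ExpressionMatrix`, with `size_factors` stored.
#' @export
normalize_expression <- function(em) {
  x <- em$values
  pos <- rowSums(x > 0) == ncol(x)
  .assert(any(pos), "no gene positive in all samples")
  lx <- log(x[pos, , drop = FALSE])
  ref <- exp(rowMeans(lx))
  factors <- apply(x[pos, , drop = FALSE] / ref, 2, stats::median)
  em$values <- sweep(x, 2, factors, "/")
  em$size_factors <- factors
  em
}

#' Read an expression matrix from TSV
#'
#' Expects a header row `gene_id` followed by sample names; sample metadata
#' is parsed from names of the form `<stage>_rep<k>` unless supplied.
#'
#' @param path TSV file.
#' @param samples Optional sample metadata data.frame.
#' @param unit Abundance unit label.
#' @return An `ExpressionMatrix`.
#' @export
read_expression <- function(path, samples = NULL, unit = "TPM") {
  tab <- .read_tsv(path, header = TRUE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  if (is.null(samples)) {
    nm <- colnames(values)
    samples <- data.frame(sample = nm,
                          stage = sub("_rep[0-9]+$", "", nm),
                          replicate = sub("^.*_rep", "", nm),
                          stringsAsFactors = FALSE)
  }
  expression_matrix(values, samples, unit = unit)
}

#' Write an expression matrix to TSV
#'
#' @param em An `ExpressionMatrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  tab <- data.frame(gene_id = rownames(em$values), em$values,
                    check.names = FALSE)
  .write_tsv(tab, path)
}
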