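# miRNA expression normalization, m6A-miRNA targeting association, and
# translation-efficiency computation with m6A association.

#' Normalize miRNA counts to reads per million
#'
#' RPM = count / replicate total * 1e6 within each sample; the stage value
#' of a miRNA is the mean RPM over all replicates of the stage.
#'
#' @param counts Integer matrix, miRNA x samples, with dimnames.
#' @param samples data.frame with `sample`, `stage`, `replicate` matching
#'   the columns of `counts`.
#' @param families Optional data.frame with `mirna`, `family`, `conserved`
#'   (logical) covering the rows of `counts`.
#' @return An object of class `MiRNAExpression` with `rpm` (per replicate),
#'   `stage_rpm` (miRNA x stage means) and `families`.
#' @export
mirna_rpm <- function(counts, samples, families = NULL) {
  .assert(is.matrix(counts) && !is.null(rownames(counts)),
          "counts must be a named matrix")
  totals <- colSums(counts)
  zero <- samples$sample[totals == 0]
  .assert(length(zero) == 0, "zero-total replicate: %s",
          paste(zero, collapse = ","))
  rpm <- sweep(counts, 2, totals, "/") * 1e6
  stages <- unique(samples$stage)
  stage_rpm <- sapply(stages, function(s) {
    cols <- samples$sample[samples$stage == s]
    rowMeans(rpm[, cols, drop = FALSE])
  })
  if (is.null(dim(stage_rpm))) {
    stage_rpm <- matrix(stage_rpm, ncol = length(stages),
                        dimnames = list(rownames(counts), stages))
  }
  colnames(stage_rpm) <- stages
  if (is.null(families)) {
    families <- data.frame(mirna = rownames(counts),
                           family = rownames(counts), conserved = TRUE,
                           stringsAsFactors = FALSE)
  }
  structure(list(rpm = rpm, stage_rpm = stage_rpm, samples = samples,
                 families = families),
            class = "MiRNAExpression")
}

#' @export
print.MiRNAExpression <- function(x, ...) {
  cat(sprintf("MiRNAExpression: %d miRNAs x %d samples (%d stages)\n",
              nrow(x$rpm), ncol(x$rpm), ncol(x$stage_rpm)))
  invisible(x)
}

#' m6A-miRNA targeting association
#'
#' Restricts to conserved miRNA families whose member miRNAs are highly
#' expressed at the stage (mean RPM >= `rpm_min`), and to protein-coding
#' genes.  A gene is miRNA-targeted when at least one such miRNA's family
#' targets it; per gene the number of targeting miRNAs and their weighted
#' count (sum of log10 RPM) are recorded.  The proportion of targeted genes
#' in the m6A+ versus m6A- group is compared by a one-sided Fisher's exact
#' test, and the per-gene counts and weighted counts by two-sided Wilcoxon
#' rank-sum tests.
#'
#' @param calls `GeneM6ACall` data.frame for one stage.
#' @param target_map data.frame with `family`, `gene_id` (conserved targets
#'   of conserved families).
#' @param mirna A `MiRNAExpression`.
#' @param stage Stage label present in `mirna$stage_rpm`.
#' @param rpm_min Expression floor for a miRNA to count (default 10,
#'   boundary included).
#' @param coding_genes Character vector of protein-coding gene ids.
#' @return List with `genes` (per-gene table), `fisher`, `wilcoxon_count`,
#'   `wilcoxon_weighted`.
#' @export
mirna_targeting <- function(calls, target_map, mirna, stage, rpm_min = 10,
                            coding_genes) {
  .assert(nrow(target_map) > 0, "empty target map")
  .assert(stage %in% colnames(mirna$stage_rpm), "stage %s has no miRNA data",
          stage)
  fam <- mirna$families
  rpm <- mirna$stage_rpm[, stage]
  eligible <- fam[fam$conserved & rpm[fam$mirna] >= rpm_min, , drop = FALSE]
  .log_counts(sprintf("mirna_targeting[%s]: conserved+expressed miRNAs", stage),
              nrow(fam), nrow(eligible))
  genes <- calls$gene_id[calls$gene_id %in% coding_genes &
                           calls$status != "not_expressed"]
  status <- calls$status[match(genes, calls$gene_id)]

  # per gene: miRNAs whose family targets it
  map <- target_map[target_map$gene_id %in% genes, , drop = FALSE]
  merged <- merge(map, eligible, by = "family")
  n_mirnas <- table(factor(merged$gene_id, levels = genes))
  weighted <- tapply(log10(rpm[merged$mirna]),
                     factor(merged$gene_id, levels = genes),
                     sum, default = 0)
  gene_tab <- data.frame(gene_id = genes, status = status,
                         targeted = as.integer(n_mirnas) > 0,
                         n_mirnas = as.integer(n_mirnas),
                         weighted = as.numeric(weighted),
                         row.names = NULL, stringsAsFactors = FALSE)
  pos <- gene_tab[gene_tab$status == "m6A+", ]
  neg <- gene_tab[gene_tab$status == "m6A-", ]
  tab <- matrix(c(sum(pos$targeted), sum(!pos$targeted),
                  sum(neg$targeted), sum(!neg$targeted)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("m6A+", "m6A-"),
                                c("targeted", "untargeted")))
  wx <- function(a, b) {
    if (length(a) < 2 || length(b) < 2) return(NULL)
    compare_groups(a, b, test = "wilcoxon_two_sided",
                   labels = c("m6A+", "m6A-"))
  }
  list(genes = gene_tab,
       fisher = compare_groups(test = "fisher_one_sided", table = tab,
                               labels = c("m6A+", "m6A-")),
       wilcoxon_count = wx(pos$n_mirnas, neg$n_mirnas),
       wilcoxon_weighted = wx(pos$weighted, neg$weighted))
}

#' Translation efficiency from Ribo and mRNA abundance
#'
#' Per stage, FPKM values are averaged over replicates and translation
#' efficiency is `(Ribo FPKM + 1) / (mRNA FPKM + 1)`, restricted to highly
#' expressed protein-coding genes (mean mRNA FPKM >= `fpkm_min` in that
#' stage).
#'
#' @param ribo,mrna `ExpressionMatrix` objects (FPKM) sharing stages.
#' @param stages Stages to evaluate (default: stages common to both).
#' @param fpkm_min mRNA abundance floor (default 10).
#' @param coding_genes Character vector of protein-coding gene ids.
#' @return data.frame of class `TranslationTable` with `gene_id`, `stage`,
#'   `ribo_fpkm`, `mrna_fpkm`, `te`, `included`.
#' @export
translation_efficiency <- function(ribo, mrna, stages = NULL, fpkm_min = 10,
                                   coding_genes = NULL) {
  sm_r <- stage_means(ribo)
  sm_m <- stage_means(mrna)
  if (is.null(stages)) stages <- intersect(colnames(sm_r), colnames(sm_m))
  miss <- setdiff(stages, intersect(colnames(sm_r), colnames(sm_m)))
  .assert(length(miss) == 0, "missing stage pairing: %s",
          paste(miss, collapse = ","))
  genes <- intersect(rownames(sm_r), rownames(sm_m))
  if (!is.null(coding_genes)) genes <- intersect(genes, coding_genes)
  out <- do.call(rbind, lapply(stages, function(s) {
    data.frame(gene_id = genes, stage = s,
               ribo_fpkm = unname(sm_r[genes, s]),
               mrna_fpkm = unname(sm_m[genes, s]),
               te = (sm_r[genes, s] + 1) / (sm_m[genes, s] + 1),
               included = unname(sm_m[genes, s] >= fpkm_min),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  class(out) <- c("TranslationTable", "data.frame")
  out
}

#' Translation efficiency by m6A peak region
#'
#' Groups constantly expressed m6A+ genes by the genomic feature of their
#' peak summits (5'UTR, CDS, stop codon, 3'UTR); a gene with summits in
#' several regions contributes to each of those groups.  Returns the
#' five-percentile summary of TE per region.
#'
#' @param te_table `TranslationTable` restricted (or restrictable) to one
#'   stage.
#' @param stage Stage to summarize.
#' @param assignments Peaks annotated by [assign_peak_features()] with
#'   `by = "summit"` semantics (the `feature` and `gene_id` columns are
#'   used).
#' @param constant_m6a_genes Character vector of constantly expressed m6A+
#'   gene ids.
#' @return List with `membership` (gene x region rows) and `summary`
#'   (per-region five-number summary of TE); empty with a warning when no
#'   gene qualifies.
#' @export
te_by_peak_region <- function(te_table, stage, assignments,
                              constant_m6a_genes) {
  regions <- c("5UTR", "CDS", "stop_codon", "3UTR")
  te <- te_table[te_table$stage == stage & te_table$included, , drop = FALSE]
  pk <- assignments[!is.na(assignments$gene_id) &
                      assignments$gene_id %in% constant_m6a_genes &
                      assignments$feature %in% regions, , drop = FALSE]
  memb <- unique(pk[, c("gene_id", "feature")])
  memb <- memb[memb$gene_id %in% te$gene_id, , drop = FALSE]
  if (!nrow(memb)) {
    warning("no constant m6A+ genes with regional peaks and TE data")
    return(list(membership = memb, summary = NULL))
  }
  memb$te <- te$te[match(memb$gene_id, te$gene_id)]
  summ <- do.call(rbind, lapply(regions, function(r) {
    v <- memb$te[memb$feature == r]
    if (!length(v)) return(NULL)
    data.frame(region = r, n = length(v), t(.five_num(v)), row.names = NULL)
  }))
  rownames(memb) <- NULL
  list(membership = memb, summary = summ)
}
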