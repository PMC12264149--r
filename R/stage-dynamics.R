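# Maternal-decay / ZGA / constant gene classification and human-mouse
# homolog expression categories.
#
# Fold change of A versus B is read literally as TPM_A / TPM_B; a zero
# denominator with a positive numerator gives +Inf, and 0/0 makes the
# condition false.

.fc <- function(a, b) {
  out <- a / b
  out[b == 0 & a > 0] <- Inf
  out[b == 0 & a == 0] <- NaN   # any comparison with NaN is false
  out
}

.cmp <- function(x) !is.na(x) & !is.nan(x) & x   # NaN-safe condition

#' Classify maternal-decay, ZGA and constantly expressed genes
#'
#' Evaluates the published rule sets on per-stage mean TPM (replicates are
#' averaged first):
#'
#' * M-decay: TPM > 10 in GV; GV > MII; GV/8C > 2; GV/zygote > 2;
#'   GV/MII < 2.
#' * Z-decay: TPM > 10 in GV; zygote/GV < 1.5; GV/8C > 2; GV/zygote < 2;
#'   zygote/8C > 2.
#' * ZGA: TPM < 1 in both GV and MII; TPM > 10 at 8C; 8C > zygote.
#' * Constant: entropy specificity < 0.5 and TPM >= 10 in every sample.
#'
#' MD genes are the union of M-decay and Z-decay.  A gene satisfying both
#' decay rule sets is labeled M-decay (evaluated first) and flagged.
#'
#' @param em An `ExpressionMatrix` whose stages include the four stages
#'   named in `stage_map`.
#' @param stage_map Named character vector mapping the roles `gv`, `mii`,
#'   `zygote`, `eight_cell` to stage labels of `em`.
#' @return data.frame of class `StageClassification` with per-gene `label`
#'   (`"M-decay"`, `"Z-decay"`, `"ZGA"`, `"constant"`, `"none"`), the
#'   individual rule outcomes, the entropy specificity score, and the
#'   `both_decay` flag.
#' @export
classify_maternal_zga <- function(em,
                                  stage_map = c(gv = "GV", mii = "MII",
                                                zygote = "1C",
                                                eight_cell = "8C")) {
  sm <- stage_means(em)
  missing_stage <- setdiff(unname(stage_map), colnames(sm))
  .assert(length(missing_stage) == 0, "missing stage: %s",
          paste(missing_stage, collapse = ","))
  gv <- sm[, stage_map[["gv"]]]
  mii <- sm[, stage_map[["mii"]]]
  zy <- sm[, stage_map[["zygote"]]]
  e8 <- sm[, stage_map[["eight_cell"]]]

  m_decay <- .cmp(gv > 10) & .cmp(gv > mii) & .cmp(.fc(gv, e8) > 2) &
    .cmp(.fc(gv, zy) > 2) & .cmp(.fc(gv, mii) < 2)
  z_decay <- .cmp(gv > 10) & .cmp(.fc(zy, gv) < 1.5) &
    .cmp(.fc(gv, e8) > 2) & .cmp(.fc(gv, zy) < 2) & .cmp(.fc(zy, e8) > 2)
  zga <- .cmp(gv < 1) & .cmp(mii < 1) & .cmp(e8 > 10) & .cmp(e8 > zy)

  entropy <- apply(em$values, 1, function(x) {
    if (sum(x) == 0) NA_real_ else entropy_specificity(x)
  })
  constant <- !is.na(entropy) & entropy < 0.5 &
    apply(em$values >= 10, 1, all)

  label <- rep("none", nrow(sm))
  label[constant] <- "constant"
  label[zga] <- "ZGA"
  label[z_decay] <- "Z-decay"
  label[m_decay] <- "M-decay"
  both <- m_decay & z_decay
  if (any(both)) {
    .log_msg("classify_maternal_zga: %d gene(s) satisfy both decay rule sets; labeled M-decay",
             sum(both))
  }
  out <- data.frame(gene_id = rownames(sm), label = label,
                    m_decay = unname(m_decay), z_decay = unname(z_decay),
                    zga = unname(zga), constant = unname(constant),
                    md = unname(m_decay | z_decay),
                    both_decay = unname(both),
                    entropy = unname(entropy), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("StageClassification", "data.frame")
  out
}

#' Read a human-mouse homology table
#'
#' Two-column TSV (`human_gene`, `mouse_gene`).  Any gene appearing in more
#' than one pair on either side is omitted, leaving strictly one-to-one
#' pairs.
#'
#' @param path TSV file (header optional when columns are unambiguous).
#' @return data.frame with `human_gene`, `mouse_gene`.
#' @export
read_homology_table <- function(path) {
  tab <- .read_tsv(path, header = TRUE)
  .assert(ncol(tab) >= 2, "homology table needs two columns")
  out <- data.frame(human_gene = as.character(tab[[1]]),
                    mouse_gene = as.character(tab[[2]]),
                    stringsAsFactors = FALSE)
  n0 <- nrow(out)
  multi_h <- names(which(table(out$human_gene) > 1))
  multi_m <- names(which(table(out$mouse_gene) > 1))
  out <- out[!(out$human_gene %in% multi_h) & !(out$mouse_gene %in% multi_m), ,
             drop = FALSE]
  .log_counts("read_homology_table: dropping many-to-one homologs", n0,
              nrow(out))
  rownames(out) <- NULL
  out
}

#' Classify homolog expression between species
#'
#' Within each paired stage, a one-to-one homolog pair is co-expressed when
#' TPM >= 50 in both species, human-specific when human TPM >= 50 and mouse
#' TPM <= 10, mouse-specific in the mirrored case, and ambiguous otherwise.
#'
#' @param human,mouse `ExpressionMatrix` objects (TPM).
#' @param homology One-to-one homology table from [read_homology_table()].
#' @param stage_pairs Named character vector: human stage -> mouse stage
#'   (e.g. `c("8C" = "2C")`).
#' @return data.frame with one row per homolog pair and paired stage:
#'   `human_gene`, `mouse_gene`, `stage_human`, `stage_mouse`, `tpm_human`,
#'   `tpm_mouse`, `category`.
#' @export
classify_homolog_expression <- function(human, mouse, homology, stage_pairs) {
  sm_h <- stage_means(human)
  sm_m <- stage_means(mouse)
  miss_h <- setdiff(names(stage_pairs), colnames(sm_h))
  miss_m <- setdiff(unname(stage_pairs), colnames(sm_m))
  .assert(length(miss_h) == 0 && length(miss_m) == 0,
          "unpaired stage: %s", paste(c(miss_h, miss_m), collapse = ","))
  pairs <- homology[homology$human_gene %in% rownames(sm_h) &
                      homology$mouse_gene %in% rownames(sm_m), , drop = FALSE]
  out <- list()
  for (hs in names(stage_pairs)) {
    ms <- stage_pairs[[hs]]
    th <- sm_h[pairs$human_gene, hs]
    tm <- sm_m[pairs$mouse_gene, ms]
    category <- rep("ambiguous", nrow(pairs))
    category[th >= 50 & tm >= 50] <- "co-expressed"
    category[th >= 50 & tm <= 10] <- "human-specific"
    category[tm >= 50 & th <= 10] <- "mouse-specific"
    out[[hs]] <- data.frame(human_gene = pairs$human_gene,
                            mouse_gene = pairs$mouse_gene,
                            stage_human = hs, stage_mouse = ms,
                            tpm_human = unname(th), tpm_mouse = unname(tm),
                            category = category, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
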