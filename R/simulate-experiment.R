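# Stage- and condition-level experiment simulation on top of a simulated
# annotation: expression matrices with planted classes, paired IP/Input
# coverage tracks, per-replicate peak files, miRNA counts, Ribo/mRNA FPKM
# tables, and a pseudo-mouse expression matrix for homolog comparisons.

# literal printed rule sets, re-stated here (deliberately independent of the
# classifier module) so the generator can enforce its planted-class contract
.rules_satisfied <- function(gv, mii, zy, e8) {
  fc <- function(a, b) if (b == 0) (if (a > 0) Inf else NaN) else a / b
  ok <- function(x) !is.na(x) && !is.nan(x) && x
  c(m_decay = ok(gv > 10) && ok(gv > mii) && ok(fc(gv, e8) > 2) &&
      ok(fc(gv, zy) > 2) && ok(fc(gv, mii) < 2),
    z_decay = ok(gv > 10) && ok(fc(zy, gv) < 1.5) && ok(fc(gv, e8) > 2) &&
      ok(fc(gv, zy) < 2) && ok(fc(zy, e8) > 2),
    zga = ok(gv < 1) && ok(mii < 1) && ok(e8 > 10) && ok(e8 > zy))
}

# stage-mean TPM profile for one gene of a given class, margin mu > 1
.class_profile <- function(class, stages, mu, background_tpm) {
  v <- stats::setNames(numeric(length(stages)), stages)
  if (class == "m_decay") {
    gv <- stats::runif(1, 10 * mu, 100)
    r1 <- stats::runif(1, 1.05, max(1.06, 2 / mu))
    v["GV"] <- gv
    v["MII"] <- gv / r1
    v["1C"] <- gv / (2 * mu * exp(stats::runif(1, 0, 0.7)))
    v["8C"] <- gv / (2 * mu * exp(stats::runif(1, 0, 0.7)))
    v["2C"] <- v["8C"] * exp(stats::runif(1, -0.3, 0.3))
    v["BLT"] <- v["8C"] * exp(stats::runif(1, -0.3, 0.3))
  } else if (class == "z_decay") {
    gv <- stats::runif(1, 10 * mu, 100)
    v["GV"] <- gv
    v["MII"] <- gv * exp(stats::runif(1, -0.1, 0.1))
    v["1C"] <- gv * exp(stats::runif(1, -0.15, 0))
    v["8C"] <- v["1C"] / (2 * mu * exp(stats::runif(1, 0, 0.7)))
    v["2C"] <- stats::runif(1, v["8C"], v["1C"])
    v["BLT"] <- v["8C"] * exp(stats::runif(1, -0.3, 0.3))
  } else if (class == "zga") {
    v["GV"] <- stats::runif(1, 0.05, 1 / mu)
    v["MII"] <- stats::runif(1, 0.05, 1 / mu)
    e8 <- stats::runif(1, 10 * mu, 100)
    v["8C"] <- e8
    v["1C"] <- stats::runif(1, 0.5, e8 / (2 * mu))
    v["2C"] <- stats::runif(1, v["1C"], e8)
    v["BLT"] <- e8 * exp(stats::runif(1, -0.3, 0.3))
  } else if (class == "constant") {
    base <- stats::runif(1, 10 * mu, 100)
    v[] <- base * exp(stats::rnorm(length(stages), 0, 0.05))
  } else {
    v[] <- stats::runif(length(stages), background_tpm[1], background_tpm[2])
  }
  v[stages]
}

#' Simulate a full stage-structured experiment
#'
#' Emits, for each developmental stage and replicate: TPM expression (gene
#' and transcript level), Input and IP coverage tracks with the m6A signal,
#' and per-replicate peak files; plus miRNA count tables, Ribo/mRNA FPKM
#' tables, and a pseudo-mouse TPM matrix for homolog comparisons.  Every
#' planted class member is guaranteed (by redrawing replicate noise) to
#' satisfy its defining inequalities, and only those, on the emitted stage
#' means; background genes are guaranteed to satisfy none.
#'
#' @param config A `SimConfig` (margin must exceed 1).
#' @param sim An `M6ASimulation` from [simulate_annotation()].
#' @param seed Random seed (default `config$seed + 1`).
#' @param tracks Set `FALSE` to skip coverage simulation (classification-
#'   only studies).
#' @return An object of class `StageExperiment`.
#' @export
simulate_stage_experiment <- function(config, sim, seed = config$seed + 1,
                                      tracks = TRUE) {
  .assert(config$margin > 1,
          "margin must exceed 1 (planted classes would be ambiguous)")
  set.seed(seed)
  stages <- config$stages
  genes <- sim$bundle$genes$gene_id
  classes <- stats::setNames(sim$truth$classes$class,
                             sim$truth$classes$gene_id)[genes]

  ## stage-mean profiles
  mt <- vapply(genes, function(g) {
    .class_profile(classes[[g]], stages, config$margin,
                   config$background_tpm)
  }, numeric(length(stages)))
  mean_tpm <- if (is.matrix(mt)) t(mt) else matrix(mt, ncol = 1)
  dimnames(mean_tpm) <- list(genes, stages)

  ## replicate matrices with planted-rule enforcement on realized means
  n_rep <- config$replicates
  sample_names <- as.vector(outer(stages, seq_len(n_rep),
                                  function(s, r) paste0(s, "_rep", r)))
  samples <- data.frame(sample = sample_names,
                        stage = rep(stages, n_rep),
                        replicate = rep(seq_len(n_rep), each = length(stages)),
                        stringsAsFactors = FALSE)
  samples <- samples[order(match(samples$stage, stages), samples$replicate), ]
  samples$sample <- paste0(samples$stage, "_rep", samples$replicate)
  rownames(samples) <- NULL

  draw_reps <- function(mu_row) {
    noise <- exp(stats::rnorm(length(mu_row) * n_rep, 0, config$replicate_cv))
    matrix(rep(mu_row, each = n_rep) * noise, nrow = n_rep)
  }
  # planted-rule enforcement needs the four rule stages
  enforce <- all(c("GV", "MII", "1C", "8C") %in% stages)
  tpm <- matrix(0, length(genes), nrow(samples),
                dimnames = list(genes, samples$sample))
  for (gi in seq_along(genes)) {
    cl <- classes[[gi]]
    target <- c(m_decay = cl == "m_decay", z_decay = cl == "z_decay",
                zga = cl == "zga")
    for (try in 1:50) {
      reps <- draw_reps(mean_tpm[gi, ])   # n_rep x stages
      if (!enforce) break
      sm <- colMeans(reps)
      names(sm) <- stages
      got <- .rules_satisfied(sm[["GV"]], sm[["MII"]], sm[["1C"]],
                              sm[["8C"]])
      if (identical(unname(got), unname(target))) break
      if (try == 50) reps <- matrix(rep(mean_tpm[gi, ], each = n_rep),
                                    nrow = n_rep)
    }
    for (r in seq_len(n_rep)) {
      cols <- paste0(stages, "_rep", r)
      tpm[gi, cols] <- reps[r, ]
    }
  }
  expression <- expression_matrix(tpm, samples, unit = "TPM")

  ## transcript-level TPM: dominant isoform 80%
  txs <- sim$bundle$transcripts
  second <- grepl("\\.t2$", txs$transcript_id)
  share <- ifelse(second, 0.2, 1)
  has2 <- txs$gene_id %in% txs$gene_id[second]
  share[!second & has2] <- 0.8
  tx_tpm <- tpm[txs$gene_id, , drop = FALSE] * share
  rownames(tx_tpm) <- txs$transcript_id

  ## per-stage realized means (for peaks and downstream truth)
  stage_tpm <- stage_means(expression)

  ## peak files per stage x replicate
  sites <- sim$truth$peak_sites
  peaks <- list()
  for (s in stages) {
    expressed <- rownames(stage_tpm)[stage_tpm[, s] >= 1]
    m6a_here <- intersect(sim$truth$m6a_genes, expressed)
    idx <- match(m6a_here, sites$gene_id)
    peaks[[s]] <- list()
    for (r in seq_len(n_rep)) {
      keep <- stats::runif(length(idx)) >= config$peak_dropout
      d <- sites[idx[keep], , drop = FALSE]
      if (nrow(d)) {
        tx_span <- txs[match(d$transcript_id, txs$transcript_id), ]
        start <- pmax(d$summit - config$peak_halfwidth, tx_span$start)
        end <- pmin(d$summit + config$peak_halfwidth, tx_span$end)
        pk <- data.frame(chrom = d$chrom, start = start, end = end,
                         name = paste0(d$gene_id, "_", s, "_rep", r),
                         score = round(stats::runif(nrow(d), 100, 1000)),
                         strand = ".",
                         signal = stats::runif(nrow(d), 2, 8),
                         pvalue = stats::runif(nrow(d), 5, 40),
                         qvalue = stats::runif(nrow(d), 2, 30),
                         summit = d$summit, stringsAsFactors = FALSE)
      } else pk <- NULL
      peaks[[s]][[paste0("rep", r)]] <- pk
    }
  }

  ## repeat locus truth per stage
  elements <- sim$truth$repeat_elements
  rep_truth <- list()
  for (s in stages) {
    expressed <- stats::runif(nrow(elements)) < config$repeat_expressed_frac
    modified <- expressed &
      stats::runif(nrow(elements)) < config$repeat_m6a_frac
    level <- exp(stats::rnorm(nrow(elements), config$repeat_level_meanlog,
                              config$repeat_level_sdlog))
    rep_truth[[s]] <- data.frame(element_id = elements$element_id,
                                 expressed = expressed, modified = modified,
                                 level = ifelse(expressed, level, 0),
                                 stringsAsFactors = FALSE)
  }

  ## coverage tracks
  track_list <- NULL
  if (tracks) {
    track_list <- list()
    for (s in stages) {
      track_list[[s]] <- list()
      for (r in seq_len(n_rep)) {
        col <- paste0(s, "_rep", r)
        tr <- .sim_coverage_pair(config, sim, tpm[, col], rep_truth[[s]],
                                 enrichment = config$enrichment,
                                 label = col)
        track_list[[s]][[paste0("rep", r)]] <- tr
      }
    }
  }

  ## miRNA counts
  mir_stages <- intersect(config$mirna_stages, stages)
  counts <- NULL; mir_samples <- NULL
  if (length(mir_stages)) {
    n_mir <- config$n_mirnas
    base_ab <- stats::rlnorm(n_mir, log(100), 1.5)
    mir_samples <- expand.grid(stage = mir_stages,
                               replicate = seq_len(config$mirna_replicates),
                               stringsAsFactors = FALSE)
    mir_samples$sample <- paste0("miR_", mir_samples$stage, "_rep",
                                 mir_samples$replicate)
    counts <- sapply(seq_len(nrow(mir_samples)), function(i) {
      ab <- base_ab * exp(stats::rnorm(n_mir, 0, 0.3))
      stats::rmultinom(1, config$mirna_depth, ab)[, 1]
    })
    rownames(counts) <- sim$mirna_families$mirna
    colnames(counts) <- mir_samples$sample
  }

  ## Ribo / mRNA FPKM tables (protein-coding genes, planted TE multiplier)
  te_stages <- intersect(config$te_stages, stages)
  mrna <- ribo <- NULL
  coding <- names(sim$truth$te_multiplier)
  if (length(te_stages)) {
  mk_cols <- function(vals_fun) {
    cols <- list()
    for (s in te_stages) for (r in 1:2) {
      cols[[paste0(s, "_rep", r)]] <- vals_fun(s)
    }
    m <- do.call(cbind, cols)
    rownames(m) <- coding
    m
  }
  mrna_fpkm <- mk_cols(function(s) {
    stage_tpm[coding, s] * exp(stats::rnorm(length(coding), 0, 0.1))
  })
  ribo_fpkm <- mk_cols(function(s) {
    stage_tpm[coding, s] * sim$truth$te_multiplier *
      exp(stats::rnorm(length(coding), 0, 0.1))
  })
  te_samples <- function(prefix) {
    nm <- colnames(mrna_fpkm)
    data.frame(sample = nm, stage = sub("_rep[0-9]+$", "", nm),
               replicate = sub("^.*_rep", "", nm), stringsAsFactors = FALSE)
  }
  mrna <- expression_matrix(mrna_fpkm, te_samples(), unit = "FPKM")
  ribo <- expression_matrix(ribo_fpkm, te_samples(), unit = "FPKM")
  }

  ## pseudo-mouse matrix for homolog comparison (mouse major ZGA at 2C)
  mouse_stages <- c("GV", "MII", "1C", "2C", "BLT")
  stage_src0 <- c(GV = "GV", MII = "MII", `1C` = "1C", `2C` = "8C",
                  BLT = "BLT")
  mouse <- NULL
  if (all(stage_src0 %in% stages)) {
  hom <- sim$homology
  mm_genes <- unique(hom$mouse_gene)
  h_of_m <- hom$human_gene[match(mm_genes, hom$mouse_gene)]
  mm_cols <- list()
  stage_src <- c(GV = "GV", MII = "MII", `1C` = "1C", `2C` = "8C",
                 BLT = "BLT")
  hs_pick <- stats::runif(length(mm_genes))
  for (s in mouse_stages) {
    src <- stage_src[[s]]
    base <- stage_tpm[h_of_m, src] * exp(stats::rnorm(length(mm_genes), 0, 0.2))
    if (s == "2C") {
      # plant species-specific expression at the ZGA-comparable stage
      base[hs_pick < 0.1 & stage_tpm[h_of_m, src] >= 50] <-
        stats::runif(sum(hs_pick < 0.1 & stage_tpm[h_of_m, src] >= 50), 0, 5)
      low <- hs_pick >= 0.9 & stage_tpm[h_of_m, src] <= 10
      base[low] <- stats::runif(sum(low), 60, 200)
    }
    for (r in 1:2) {
      mm_cols[[paste0(s, "_rep", r)]] <-
        base * exp(stats::rnorm(length(mm_genes), 0, config$replicate_cv))
    }
  }
  mm_mat <- do.call(cbind, mm_cols)
  rownames(mm_mat) <- mm_genes
  nm <- colnames(mm_mat)
  mouse <- expression_matrix(mm_mat,
                             data.frame(sample = nm,
                                        stage = sub("_rep[0-9]+$", "", nm),
                                        replicate = sub("^.*_rep", "", nm),
                                        stringsAsFactors = FALSE),
                             unit = "TPM")
  }

  structure(list(expression = expression, tx_expression = tx_tpm,
                 stage_tpm = stage_tpm, peaks = peaks, tracks = track_list,
                 repeat_truth = rep_truth,
                 mirna = list(counts = counts, samples = mir_samples,
                              families = sim$mirna_families),
                 ribo = ribo, mrna = mrna, mouse = mouse,
                 config = config),
            class = "StageExperiment")
}

# one IP/Input/signal track triple for one sample
.sim_coverage_pair <- function(config, sim, gene_tpm, rep_truth_stage,
                               enrichment, label) {
  bundle <- sim$bundle
  bs <- config$bin_size
  sizes <- bundle$chrom_sizes
  gm <- sim$truth$gene_meta
  sites <- sim$truth$peak_sites
  m6a <- sim$truth$m6a_genes

  segs <- list()
  for (g in names(gm)) {
    ex <- gm[[g]]$exons_tx
    w <- gene_tpm[[g]]
    if (is.na(w) || w <= 0) next
    if (g %in% m6a) {
      i <- match(g, sites$gene_id)
      win_s <- sites$summit[i] - config$peak_halfwidth
      win_e <- sites$summit[i] + config$peak_halfwidth
      for (j in seq_len(nrow(ex))) {
        pieces <- rbind(
          c(ex$start[j], min(ex$end[j], max(ex$start[j], win_s)), 1),
          c(max(ex$start[j], win_s), min(ex$end[j], win_e), enrichment),
          c(min(ex$end[j], max(ex$start[j], win_e)), ex$end[j], 1))
        for (p in seq_len(nrow(pieces))) {
          if (pieces[p, 2] > pieces[p, 1]) {
            segs[[length(segs) + 1L]] <- data.frame(
              chrom = ex$chrom[j], start = pieces[p, 1], end = pieces[p, 2],
              w = w, mult = pieces[p, 3])
          }
        }
      }
    } else {
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ex$chrom, start = ex$start, end = ex$end, w = w, mult = 1)
    }
  }
  ## repeat loci
  elements <- sim$truth$repeat_elements
  rt <- rep_truth_stage
  nonmod_mult <- if (config$enrichment > 1) 0 else 1
  for (i in seq_len(nrow(elements))) {
    if (!rt$expressed[i]) next
    mult <- if (rt$modified[i]) enrichment else nonmod_mult
    segs[[length(segs) + 1L]] <- data.frame(
      chrom = elements$chrom[i], start = elements$start[i],
      end = elements$end[i], w = rt$level[i], mult = mult)
  }
  segs <- do.call(rbind, segs)
  segs$len <- segs$end - segs$start
  w_input <- segs$w * segs$len
  w_ip <- w_input * segs$mult

  draw_frags <- function(w) {
    n_seg <- stats::rmultinom(1, config$depth, w)[, 1]
    keep <- n_seg > 0
    d <- segs[keep, , drop = FALSE]; n <- n_seg[keep]
    start <- floor(stats::runif(sum(n), rep(d$start, n), rep(d$end, n)))
    flen <- pmax(30, round(stats::rnorm(sum(n), config$frag_len,
                                        config$frag_sd)))
    end <- pmin(start + flen, rep(d$end, n))
    end <- pmax(end, start + 1)
    data.frame(chrom = rep(d$chrom, n), start = start, end = end)
  }
  input_fr <- draw_frags(w_input)
  ip_fr <- draw_frags(w_ip)
  input <- compute_binned_rpkm(input_fr, sizes, bs, total = config$depth,
                               sample = paste0(label, "_Input"))
  ip <- compute_binned_rpkm(ip_fr, sizes, bs, total = config$depth,
                            sample = paste0(label, "_IP"))
  list(input = input, ip = ip, signal = compute_m6a_signal(ip, input))
}

#' Simulate a Ctrl-versus-inhibitor condition experiment
#'
#' Two conditions on one cell state (hESC-like) with shared ground truth:
#' the treated condition's IP enrichment is scaled globally by
#' `config$inhibitor_reduction` (1 leaves the IP model unchanged; 0 removes
#' all IP fragments from planted peaks so their m6A signal cannot exceed
#' zero).
#'
#' @param config A `SimConfig`.
#' @param sim An `M6ASimulation`.
#' @param seed Random seed (default `config$seed + 2`).
#' @return An object of class `ConditionExperiment` with `tracks` (per
#'   condition and replicate), the shared `gene_tpm`, and `repeat_truth`.
#' @export
simulate_condition_experiment <- function(config, sim,
                                          seed = config$seed + 2) {
  set.seed(seed)
  genes <- sim$bundle$genes$gene_id
  gene_tpm <- stats::setNames(stats::rlnorm(length(genes), log(8), 1), genes)
  elements <- sim$truth$repeat_elements
  expressed <- stats::runif(nrow(elements)) < config$repeat_expressed_frac
  modified <- expressed & stats::runif(nrow(elements)) < config$repeat_m6a_frac
  level <- ifelse(expressed,
                  exp(stats::rnorm(nrow(elements),
                                   config$repeat_level_meanlog,
                                   config$repeat_level_sdlog)), 0)
  rt <- data.frame(element_id = elements$element_id, expressed = expressed,
                   modified = modified, level = level,
                   stringsAsFactors = FALSE)
  gammas <- c(Ctrl = config$enrichment,
              treated = config$enrichment * config$inhibitor_reduction)
  tracks <- list()
  for (cond in names(gammas)) {
    tracks[[cond]] <- list()
    for (r in seq_len(config$replicates)) {
      tracks[[cond]][[paste0("rep", r)]] <-
        .sim_coverage_pair(config, sim, gene_tpm, rt,
                           enrichment = gammas[[cond]],
                           label = paste0(cond, "_rep", r))
    }
  }
  structure(list(tracks = tracks, gene_tpm = gene_tpm, repeat_truth = rt,
                 config = config),
            class = "ConditionExperiment")
}
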