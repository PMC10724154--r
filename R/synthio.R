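#' Configuration for the synthetic allotetraploid generator
#'
#' Builds the parameter set that drives [simulate_tetraploid()] and the other
#' `simulate_*()` generators. The defaults describe a compact allotetraploid
#' with maternal (subM) dominance: the paternal subgenome loses more genes,
#' maternally biased expression is more frequent, and a handful of
#' subgenome-diagnostic repeat families separate the two chromosome sets.
#'
#' @param seed master seed; every generator derives its own RNG stream from it,
#'   so the seed fully determines all outputs.
#' @param n_pairs number of homoeologous chromosome pairs (>= 1).
#' @param chrom_len chromosome length in bp.
#' @param n_genes_per_chrom genes per reference chromosome.
#' @param gene_len fixed gene footprint in bp.
#' @param n_diag_families number of subgenome-diagnostic repeat families;
#'   families alternate the subgenome they are enriched in.
#' @param diag_ratio planted per-subgenome copy-rate ratio (enriched : other).
#' @param diag_copies copies of an enriched family per chromosome.
#' @param diag_unit_len repeat-unit length in bp.
#' @param homoeolog_divergence per-site substitution rate applied independently
#'   to each subgenome copy of the ancestral chromosome.
#' @param loss_rate_P,loss_rate_M per-gene deletion probability on subP / subM.
#' @param bias_fraction_M,bias_fraction_P fractions of complete ohnolog pairs
#'   with planted expression bias toward subM / subP.
#' @param fc_magnitude planted log2 fold change for biased pairs.
#' @param noise_sd log2-scale SD of multiplicative replicate noise.
#' @param fate_fractions named probabilities over planted ohnolog fates
#'   (`dosage`, `nonfunctionalized`, `subfunctionalized`, `neofunctionalized`).
#' @param cns_sub_rate_P,cns_sub_rate_M per-site substitution rates for CNSs.
#' @param cns_indel_rate per-site indel rate for CNSs.
#' @param neutral_sub_rate_P,neutral_sub_rate_M per-site substitution rates for
#'   the neutral (fourfold-degenerate) control pools; must be >= the CNS rates
#'   (constraint means CNSs evolve more slowly than neutral sequence).
#' @param cns_len_range CNS length range; must lie within the 8-100 nt filter.
#' @param compartment_block_len compartment block length in bins.
#' @param hic_within_mean,hic_between_mean mean contact counts within/between
#'   compartments.
#' @param hic_noise_sd SD of symmetric Gaussian noise added to contact counts.
#' @param methyl_baseline genome-wide CG weighted methylation level.
#' @param methyl_dip_depth depth of the planted dip upstream of TSSs.
#' @param methyl_dip_span dip extent upstream of the TSS in bp.
#' @param methyl_ch_level CH-context methylation level (kept below 0.5%).
#' @param methyl_coverage mean read coverage per cytosine.
#' @param methyl_site_spacing mean spacing between simulated cytosines in bp.
#'
#' @return an object of class `subdom_sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_pairs = 2L,
                       chrom_len = 1e6,
                       n_genes_per_chrom = 250L,
                       gene_len = 1000L,
                       n_diag_families = 6L,
                       diag_ratio = 10,
                       diag_copies = 120L,
                       diag_unit_len = 400L,
                       homoeolog_divergence = 0.02,
                       loss_rate_P = 0.15,
                       loss_rate_M = 0.05,
                       bias_fraction_M = 0.2,
                       bias_fraction_P = 0.1,
                       fc_magnitude = 3,
                       noise_sd = 0.2,
                       fate_fractions = c(dosage = 0.90,
                                          nonfunctionalized = 0.04,
                                          subfunctionalized = 0.02,
                                          neofunctionalized = 0.04),
                       cns_sub_rate_P = 0.05,
                       cns_sub_rate_M = 0.03,
                       cns_indel_rate = 0.01,
                       neutral_sub_rate_P = 0.12,
                       neutral_sub_rate_M = 0.10,
                       cns_len_range = c(8L, 100L),
                       compartment_block_len = 10L,
                       hic_within_mean = 10,
                       hic_between_mean = 2,
                       hic_noise_sd = 0,
                       methyl_baseline = 0.8,
                       methyl_dip_depth = 0.4,
                       methyl_dip_span = 1500L,
                       methyl_ch_level = 0.002,
                       methyl_coverage = 30,
                       methyl_site_spacing = 25L) {
  cfg <- as.list(environment())
  if (!is.numeric(seed) || length(seed) != 1L) stopf("'seed' must be a single integer")
  if (n_pairs < 1L) stopf("'n_pairs' must be >= 1")
  for (nm in c("loss_rate_P", "loss_rate_M", "bias_fraction_M", "bias_fraction_P",
               "homoeolog_divergence", "cns_sub_rate_P", "cns_sub_rate_M",
               "cns_indel_rate", "neutral_sub_rate_P", "neutral_sub_rate_M",
               "methyl_baseline", "methyl_dip_depth", "methyl_ch_level"))
    assert_prob(cfg[[nm]], nm)
  if (abs(sum(fate_fractions) - 1) > 1e-8) stopf("'fate_fractions' must sum to 1")
  if (bias_fraction_M + bias_fraction_P > fate_fractions[["dosage"]])
    stopf("bias fractions exceed the planted dosage-retained fraction")
  if (cns_len_range[1] < 8L || cns_len_range[2] > 100L)
    stopf("'cns_len_range' must lie within the 8-100 nt CNS length filter")
  if (neutral_sub_rate_P < cns_sub_rate_P || neutral_sub_rate_M < cns_sub_rate_M)
    stopf("neutral substitution rates must be >= CNS rates (CNSs are constrained)")
  if (methyl_baseline - methyl_dip_depth < 0)
    stopf("'methyl_dip_depth' cannot exceed 'methyl_baseline'")
  ## sizing: every gene needs its own slot with room to spare
  slot <- chrom_len / n_genes_per_chrom
  if (slot < 2 * gene_len)
    stopf(paste0("chrom_len too small to place genes: need chrom_len >= ",
                 "2 * gene_len * n_genes_per_chrom (= %d), got %d"),
          as.integer(2 * gene_len * n_genes_per_chrom), as.integer(chrom_len))
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "subdom_sim_config")
}

#' @export
print.subdom_sim_config <- function(x, ...) {
  cat("subdom synthetic-data configuration\n")
  cat(sprintf("  seed %d | %d pairs x %s bp | %d genes/chrom\n",
              x$seed, x$n_pairs, format(x$chrom_len, big.mark = ","),
              x$n_genes_per_chrom))
  cat(sprintf("  diag repeats: %d families at %g:1 | loss P/M: %.2f/%.2f\n",
              x$n_diag_families, x$diag_ratio, x$loss_rate_P, x$loss_rate_M))
  invisible(x)
}

gene_ids <- function(pair, idx) sprintf("g%02d_%04d", pair, idx)

#' Simulate an allotetraploid genome with known subgenome structure
#'
#' Generates `2 * n_pairs` chromosomes. Each homoeologous pair descends from a
#' common ancestral sequence carrying a shared gene complement; the two copies
#' then diverge by point substitution, subgenome-diagnostic repeat families are
#' inserted at the configured copy-rate ratio, and genes are deleted
#' independently per subgenome at the configured loss rates. All planted
#' structure is recorded in a ground-truth manifest.
#'
#' @param config a [sim_config()].
#' @return an object of class `subdom_sim` with elements `sequences` (a named
#'   [Biostrings::DNAStringSet]), `genes` and `tes` (annotation data.frames,
#'   1-based closed coordinates), `map` (homoeologous pair table),
#'   `ref_genes` (reference gene order) and `manifest` (ground truth).
#' @export
simulate_tetraploid <- function(config) {
  stopifnot(inherits(config, "subdom_sim_config"))
  cfg <- config
  with_seed(stream_seed(cfg$seed, "genome"), {
    n <- cfg$n_genes_per_chrom
    slot <- floor(cfg$chrom_len / n)
    fam_names <- sprintf("DIAG%02d", seq_len(cfg$n_diag_families))
    fam_enriched <- rep(c("subP", "subM"), length.out = cfg$n_diag_families)
    fam_consensus <- lapply(seq_len(cfg$n_diag_families),
                            function(i) random_dna_vec(cfg$diag_unit_len))
    n_lo <- max(1L, round(cfg$diag_copies / cfg$diag_ratio))

    seqs <- list(); genes <- list(); tes <- list()
    deleted <- list(subP = character(), subM = character())
    ref_genes <- list()

    for (p in seq_len(cfg$n_pairs)) {
      ids <- gene_ids(p, seq_len(n))
      jit <- sample.int(max(1L, slot - cfg$gene_len - 1L), n, replace = TRUE) - 1L
      gstart <- (seq_len(n) - 1L) * slot + 1L + jit
      gend <- gstart + cfg$gene_len - 1L
      strand <- rep(c("+", "-"), length.out = n)
      ref_genes[[p]] <- data.frame(ref_gene = ids, ref_chrom = sprintf("ref%02d", p),
                                   ref_rank = seq_len(n), stringsAsFactors = FALSE)
      anc <- random_dna_vec(cfg$chrom_len)
      for (sg in c("P", "M")) {
        chrom <- sprintf("chr%02d%s", p, sg)
        sub_lab <- paste0("sub", sg)
        s <- mutate_bases(anc, cfg$homoeolog_divergence)
        ## insert repeat copies into intergenic space
        te_rows <- list()
        for (f in seq_len(cfg$n_diag_families)) {
          ncopy <- if (fam_enriched[f] == sub_lab) cfg$diag_copies else n_lo
          for (cc in seq_len(ncopy)) {
            unit <- mutate_bases(fam_consensus[[f]], 0.02)
            L <- length(unit)
            for (try in seq_len(200L)) {
              pos <- sample.int(cfg$chrom_len - L, 1L)
              if (!any(gstart <= pos + L - 1L & gend >= pos)) break
              pos <- NA_integer_
            }
            if (is.na(pos)) next
            s[pos:(pos + L - 1L)] <- unit
            te_rows[[length(te_rows) + 1L]] <-
              data.frame(chrom = chrom, start = pos, end = pos + L - 1L,
                         strand = "+", family = fam_names[f],
                         stringsAsFactors = FALSE)
          }
        }
        loss_rate <- if (sg == "P") cfg$loss_rate_P else cfg$loss_rate_M
        lost <- runif(n) < loss_rate
        deleted[[sub_lab]] <- c(deleted[[sub_lab]], ids[lost])
        genes[[chrom]] <- data.frame(
          gene_id = paste0(ids[!lost], "_", sg), ref_gene = ids[!lost],
          chrom = chrom, start = gstart[!lost], end = gend[!lost],
          strand = strand[!lost], subgenome = sub_lab, pair = p,
          rank = seq_len(sum(!lost)), stringsAsFactors = FALSE)
        tes[[chrom]] <- if (length(te_rows)) do.call(rbind, te_rows) else
          data.frame(chrom = character(), start = integer(), end = integer(),
                     strand = character(), family = character())
        tes[[chrom]]$te_id <- if (nrow(tes[[chrom]]))
          sprintf("%s_te%04d", chrom, seq_len(nrow(tes[[chrom]]))) else character()
        seqs[[chrom]] <- paste(s, collapse = "")
      }
    }
    genes <- do.call(rbind, genes); rownames(genes) <- NULL
    tes <- do.call(rbind, tes); rownames(tes) <- NULL
    ref_genes <- do.call(rbind, ref_genes)
    map <- data.frame(pair = seq_len(cfg$n_pairs),
                      chrom_a = sprintf("chr%02dP", seq_len(cfg$n_pairs)),
                      chrom_b = sprintf("chr%02dM", seq_len(cfg$n_pairs)),
                      stringsAsFactors = FALSE)
    subgenome <- c(stats::setNames(rep("subP", cfg$n_pairs), map$chrom_a),
                   stats::setNames(rep("subM", cfg$n_pairs), map$chrom_b))
    manifest <- list(
      config = list(seed = cfg$seed, n_pairs = cfg$n_pairs,
                    chrom_len = cfg$chrom_len,
                    n_genes_per_chrom = cfg$n_genes_per_chrom,
                    loss_rate_P = cfg$loss_rate_P, loss_rate_M = cfg$loss_rate_M),
      subgenome = as.list(subgenome),
      diag_families = data.frame(family = fam_names, enriched = fam_enriched,
                                 ratio = cfg$diag_ratio,
                                 copies_enriched = cfg$diag_copies * cfg$n_pairs,
                                 copies_other = n_lo * cfg$n_pairs,
                                 stringsAsFactors = FALSE),
      deleted_P = deleted$subP, deleted_M = deleted$subM,
      n_ref_genes = nrow(ref_genes))
    structure(list(config = cfg,
                   sequences = Biostrings::DNAStringSet(unlist(seqs)),
                   genes = genes, tes = tes, map = map, ref_genes = ref_genes,
                   manifest = manifest),
              class = "subdom_sim")
  })
}

#' @export
print.subdom_sim <- function(x, ...) {
  cat(sprintf("subdom synthetic allotetraploid: %d chromosomes, %d genes, %d TE copies\n",
              length(x$sequences), nrow(x$genes), nrow(x$tes)))
  invisible(x)
}

#' Syntelog table of a simulated genome
#'
#' One row per reference gene, linking it to its (possibly deleted) subP and
#' subM copies; the table that drives fractionation, expression-bias and
#' fate analyses.
#'
#' @param sim a `subdom_sim` from [simulate_tetraploid()].
#' @return data.frame with columns `ref_gene`, `ref_chrom`, `ref_rank`,
#'   `gene_P`, `gene_M` (NA where the copy was deleted).
#' @export
syntelog_table <- function(sim) {
  stopifnot(inherits(sim, "subdom_sim"))
  st <- sim$ref_genes
  st$gene_P <- ifelse(st$ref_gene %in% sim$manifest$deleted_P, NA_character_,
                      paste0(st$ref_gene, "_P"))
  st$gene_M <- ifelse(st$ref_gene %in% sim$manifest$deleted_M, NA_character_,
                      paste0(st$ref_gene, "_M"))
  st
}

#' Simulate expression for the ancestor and both tetraploid copies
#'
#' TPM values over tissues and replicates for every reference (ancestor) gene
#' and every retained subgenome copy. Complete ohnolog pairs receive a planted
#' fate (dosage-retained / nonfunctionalized / subfunctionalized /
#' neofunctionalized); a planted log2 fold change of `fc_magnitude` is applied
#' to the biased fraction of dosage-retained pairs. Replicate noise is
#' log-normal and multiplicative, so `noise_sd = 0` gives the exact planted
#' means.
#'
#' @param sim a `subdom_sim`.
#' @param tissues number of tissues (>= 2).
#' @param replicates replicates per tissue (>= 2; downstream tests need them).
#' @return class `subdom_expr_sim`: list with `tpm` (matrix, genes x
#'   tissue.replicate), `tissues`, `replicates`, `trios` (ref/ohnolog id table)
#'   and `truth` (planted fate and bias per pair).
#' @export
simulate_expression <- function(sim, tissues = 6L, replicates = 3L) {
  stopifnot(inherits(sim, "subdom_sim"))
  cfg <- sim$config
  if (replicates < 2L) stopf("'replicates' must be >= 2 (downstream t-tests need them)")
  if (tissues < 2L) stopf("'tissues' must be >= 2")
  with_seed(stream_seed(cfg$seed, "expression"), {
    tiss <- c("brain", "eye", "gill", "heart", "liver", "muscle",
              sprintf("tissue%02d", seq_len(max(0L, tissues - 6L))))[seq_len(tissues)]
    st <- syntelog_table(sim)
    complete <- !is.na(st$gene_P) & !is.na(st$gene_M)
    ncmp <- sum(complete)

    fate <- rep(NA_character_, nrow(st))
    fate[complete] <- sample(names(cfg$fate_fractions), ncmp, replace = TRUE,
                             prob = cfg$fate_fractions)
    bias <- rep("none", nrow(st))
    dosage_idx <- which(complete & fate == "dosage")
    n_bm <- round(cfg$bias_fraction_M * ncmp)
    n_bp <- round(cfg$bias_fraction_P * ncmp)
    if (n_bm + n_bp > length(dosage_idx))
      stopf("not enough dosage-retained pairs to plant the requested bias fractions")
    pick <- sample(dosage_idx, n_bm + n_bp)
    bias[pick[seq_len(n_bm)]] <- "M"
    if (n_bp > 0) bias[pick[n_bm + seq_len(n_bp)]] <- "P"

    nT <- tissues
    O <- matrix(2 ^ runif(nrow(st) * nT, 2, 8), nrow(st), nT,
                dimnames = list(st$ref_gene, tiss))
    P <- O; M <- O
    nf_off <- rep(NA_character_, nrow(st))  # which copy is silenced / novel
    neo_copy <- rep(NA_character_, nrow(st))
    half <- seq_len(ceiling(nT / 2))
    for (i in which(complete)) {
      switch(fate[i],
        dosage = {
          if (bias[i] == "M") M[i, ] <- M[i, ] * 2 ^ cfg$fc_magnitude
          if (bias[i] == "P") P[i, ] <- P[i, ] * 2 ^ cfg$fc_magnitude
        },
        nonfunctionalized = {
          off <- sample(c("P", "M"), 1L)
          nf_off[i] <- off
          if (off == "P") P[i, ] <- 0.1 else M[i, ] <- 0.1
        },
        subfunctionalized = {
          on <- pmax(2, O[i, ])
          P[i, ] <- 0.1; M[i, ] <- 0.1
          P[i, half] <- on[half]
          M[i, -half] <- on[-half]
        },
        neofunctionalized = {
          winner <- sample(c("P", "M"), 1L)
          neo_copy[i] <- winner
          O[i, 1L] <- 0.1
          P[i, 1L] <- 0.1; M[i, 1L] <- 0.1
          if (winner == "P") P[i, 1L] <- 5 else M[i, 1L] <- 5
          if (winner == "P") P[i, -1L] <- O[i, -1L] else M[i, -1L] <- O[i, -1L]
        })
    }

    expand <- function(tm, ids, keep) {
      tm <- tm[keep, , drop = FALSE]
      out <- tm[, rep(seq_len(nT), each = replicates), drop = FALSE]
      if (cfg$noise_sd > 0)
        out <- out * 2 ^ matrix(rnorm(length(out), 0, cfg$noise_sd), nrow(out))
      rownames(out) <- ids[keep]
      colnames(out) <- paste0(rep(tiss, each = replicates), ".", seq_len(replicates))
      out
    }
    tpm <- rbind(expand(O, st$ref_gene, rep(TRUE, nrow(st))),
                 expand(P, st$gene_P, !is.na(st$gene_P)),
                 expand(M, st$gene_M, !is.na(st$gene_M)))
    truth <- data.frame(ref_gene = st$ref_gene, complete = complete,
                        fate = fate, bias = bias, nonf_off = nf_off,
                        neo_copy = neo_copy, stringsAsFactors = FALSE)
    structure(list(tpm = tpm, tissues = tiss, replicates = replicates,
                   trios = st, truth = truth),
              class = "subdom_expr_sim")
  })
}

## substitutions + indels on one sequence string
mutate_seq_str <- function(s, sub_rate, indel_rate) {
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  x <- mutate_bases(x, sub_rate)
  if (indel_rate > 0) {
    n <- length(x)
    ev <- runif(n) < indel_rate
    if (any(ev)) {
      kind <- sample(c("del", "ins"), sum(ev), replace = TRUE)
      out <- as.list(x)
      idx <- which(ev)
      for (j in seq_along(idx)) {
        if (kind[j] == "del") out[[idx[j]]] <- character(0)
        else out[[idx[j]]] <- c(x[idx[j]], sample(DNA_BASES, 1L))
      }
      x <- unlist(out)
    }
  }
  paste(x, collapse = "")
}

#' Simulate CNS records and a neutral fourfold-degenerate control pool
#'
#' Each record carries a reference sequence plus lifted subP and subM copies
#' diverged at the configured per-subgenome substitution and indel rates.
#' The neutral pool uses the (faster) neutral rates, emulating shuffled 4D-site
#' sequence pairs.
#'
#' @param sim a `subdom_sim`.
#' @param n_cns number of CNS records (the neutral pool has the same size).
#' @param len_range optional override of the CNS length range; must stay
#'   within the 8-100 nt filter.
#' @return class `subdom_cns_sim`: list with data.frames `cns` and `neutral`
#'   (columns `id`, `chrom`, `ref_seq`, `subP_seq`, `subM_seq`) and `truth`.
#' @export
simulate_cns_set <- function(sim, n_cns = 400L, len_range = NULL) {
  stopifnot(inherits(sim, "subdom_sim"))
  cfg <- sim$config
  lr <- as.integer(len_range %||% cfg$cns_len_range)
  if (lr[1] < 8L || lr[2] > 100L)
    stopf("requested CNS length range [%d, %d] outside the 8-100 nt filter", lr[1], lr[2])
  with_seed(stream_seed(cfg$seed, "cns"), {
    make_pool <- function(prefix, rate_P, rate_M, indel) {
      len <- sample(lr[1]:lr[2], n_cns, replace = TRUE)
      chrom <- sprintf("ref%02d", sample.int(cfg$n_pairs, n_cns, replace = TRUE))
      ref <- vapply(len, function(L) paste(random_dna_vec(L), collapse = ""), "")
      data.frame(id = sprintf("%s%05d", prefix, seq_len(n_cns)), chrom = chrom,
                 ref_seq = ref,
                 subP_seq = vapply(ref, mutate_seq_str, "", rate_P, indel,
                                   USE.NAMES = FALSE),
                 subM_seq = vapply(ref, mutate_seq_str, "", rate_M, indel,
                                   USE.NAMES = FALSE),
                 stringsAsFactors = FALSE)
    }
    cns <- make_pool("cns", cfg$cns_sub_rate_P, cfg$cns_sub_rate_M, cfg$cns_indel_rate)
    neutral <- make_pool("neu", cfg$neutral_sub_rate_P, cfg$neutral_sub_rate_M,
                         cfg$cns_indel_rate)
    structure(list(cns = cns, neutral = neutral,
                   truth = list(cns_sub_rate_P = cfg$cns_sub_rate_P,
                                cns_sub_rate_M = cfg$cns_sub_rate_M,
                                neutral_sub_rate_P = cfg$neutral_sub_rate_P,
                                neutral_sub_rate_M = cfg$neutral_sub_rate_M,
                                indel_rate = cfg$cns_indel_rate)),
              class = "subdom_cns_sim")
  })
}

#' Simulate Hi-C contact matrices, compartments and TAD sets
#'
#' Per tetraploid chromosome: a symmetric non-negative contact matrix with a
#' planted alternating A/B checkerboard (within-compartment contacts stronger
#' than between), a per-bin gene-density track (A bins denser, used for PC1
#' orientation), and per-pair TAD interval sets for both subgenomes in which a
#' known subset of TADs is conserved (their collinear genes map into a single
#' partner TAD) while the remainder have partners scattered across
#' non-conserved TADs.
#'
#' @param sim a `subdom_sim`.
#' @param n_bins bins per chromosome (>= 2 x `compartment_block_len`).
#' @param bin_size bin size in bp (default 100 kb, the compartment resolution).
#' @param n_tads TADs per subgenome chromosome.
#' @param n_conserved planted conserved TADs per chromosome pair.
#' @param genes_per_tad collinear genes placed in each TAD.
#' @return class `subdom_hic_sim`: list with `matrices` (named list of dense
#'   matrices), `bin_size`, `compartments`, `gene_density`, `tads_P`, `tads_M`,
#'   `genes_P`, `genes_M`, `syntelogs` and `truth`.
#' @export
simulate_hic <- function(sim, n_bins = 60L, bin_size = 1e5, n_tads = 20L,
                         n_conserved = 10L, genes_per_tad = 8L) {
  stopifnot(inherits(sim, "subdom_sim"))
  cfg <- sim$config
  bl <- cfg$compartment_block_len
  if (n_bins < 2L * bl)
    stopf("n_bins (%d) must be >= 2 x compartment_block_len (%d)", n_bins, 2L * bl)
  if (n_conserved > n_tads) stopf("'n_conserved' cannot exceed 'n_tads'")
  with_seed(stream_seed(cfg$seed, "hic"), {
    chroms <- names(sim$sequences)
    labels <- rep(rep(c("A", "B"), each = bl), length.out = n_bins)
    mats <- list(); comp <- list(); gd <- list()
    for (ch in chroms) {
      same <- outer(labels, labels, "==")
      M <- ifelse(same, cfg$hic_within_mean, cfg$hic_between_mean)
      if (cfg$hic_noise_sd > 0) {
        E <- matrix(rnorm(n_bins^2, 0, cfg$hic_noise_sd), n_bins)
        M <- pmax(M + (E + t(E)) / 2, 0)
      }
      diag(M) <- cfg$hic_within_mean * 2
      mats[[ch]] <- M
      comp[[ch]] <- data.frame(chrom = ch, bin = seq_len(n_bins), label = labels,
                               stringsAsFactors = FALSE)
      gd[[ch]] <- data.frame(chrom = ch, bin = seq_len(n_bins),
                             genes = rpois(n_bins, ifelse(labels == "A", 8, 2)),
                             stringsAsFactors = FALSE)
    }
    ## TADs + collinear genes, per homoeologous pair
    tadL <- floor(cfg$chrom_len / n_tads)
    tads_P <- list(); tads_M <- list(); genes_P <- list(); genes_M <- list()
    pairs <- list(); truth <- list()
    for (p in seq_len(nrow(sim$map))) {
      chP <- sim$map$chrom_a[p]; chM <- sim$map$chrom_b[p]
      tid_P <- sprintf("%s_tad%02d", chP, seq_len(n_tads))
      tid_M <- sprintf("%s_tad%02d", chM, seq_len(n_tads))
      tstart <- (seq_len(n_tads) - 1L) * tadL + 1L
      tads_P[[p]] <- data.frame(tad_id = tid_P, chrom = chP, start = tstart,
                                end = tstart + tadL - 1L, stringsAsFactors = FALSE)
      tads_M[[p]] <- data.frame(tad_id = tid_M, chrom = chM, start = tstart,
                                end = tstart + tadL - 1L, stringsAsFactors = FALSE)
      conserved <- seq_len(n_conserved)
      noncons <- setdiff(seq_len(n_tads), conserved)
      gp <- list(); gm <- list(); scatter <- 0L
      for (ti in seq_len(n_tads)) {
        gid_P <- sprintf("h%02d_t%02d_g%02d_P", p, ti, seq_len(genes_per_tad))
        gid_M <- sub("_P$", "_M", gid_P)
        pos_P <- tstart[ti] + round(seq(0.1, 0.9, length.out = genes_per_tad) * tadL)
        gp[[ti]] <- data.frame(gene = gid_P, chrom = chP, pos = pos_P,
                               stringsAsFactors = FALSE)
        if (ti %in% conserved) {
          gm[[ti]] <- data.frame(gene = gid_M, chrom = chM, pos = pos_P,
                                 stringsAsFactors = FALSE)
        } else {
          ## scatter partners round-robin across the non-conserved M TADs
          tgt <- noncons[(scatter + seq_len(genes_per_tad) - 1L) %% length(noncons) + 1L]
          scatter <- scatter + genes_per_tad
          off <- round(runif(genes_per_tad, 0.05, 0.95) * tadL)
          gm[[ti]] <- data.frame(gene = gid_M, chrom = chM,
                                 pos = tstart[tgt] + off, stringsAsFactors = FALSE)
        }
        pairs[[length(pairs) + 1L]] <- data.frame(gene_P = gid_P, gene_M = gid_M,
                                                  stringsAsFactors = FALSE)
      }
      genes_P[[p]] <- do.call(rbind, gp)
      genes_M[[p]] <- do.call(rbind, gm)
      truth[[p]] <- data.frame(pair = p, tad_P = tid_P, tad_M = tid_M,
                               conserved = seq_len(n_tads) %in% conserved,
                               stringsAsFactors = FALSE)
    }
    structure(list(matrices = mats, bin_size = bin_size,
                   compartments = do.call(rbind, comp),
                   gene_density = do.call(rbind, gd),
                   tads_P = do.call(rbind, tads_P), tads_M = do.call(rbind, tads_M),
                   genes_P = do.call(rbind, genes_P), genes_M = do.call(rbind, genes_M),
                   syntelogs = do.call(rbind, pairs),
                   truth = do.call(rbind, truth)),
              class = "subdom_hic_sim")
  })
}

#' Simulate per-cytosine methylation calls
#'
#' Cytosines are placed at roughly regular spacing along every tetraploid
#' chromosome with CG / CHG / CHH contexts. CG sites are methylated at the
#' configured baseline, with a planted dip of `methyl_dip_depth` in the
#' `methyl_dip_span` bp upstream (strand-aware) of the TSS of `dip_genes`;
#' CH-context sites stay at `methyl_ch_level` (< 0.5%).
#'
#' @param sim a `subdom_sim`.
#' @param dip_genes gene ids receiving the upstream dip; default all genes.
#' @param coverage mean read coverage (>= 1).
#' @return a data.frame of calls (`chrom`, `pos` 1-based, `strand`, `context`,
#'   `mc_reads`, `total_reads`) with the planted parameters in
#'   `attr(, "truth")`.
#' @export
simulate_methylome <- function(sim, dip_genes = NULL,
                               coverage = sim$config$methyl_coverage) {
  stopifnot(inherits(sim, "subdom_sim"))
  cfg <- sim$config
  if (coverage < 1) stopf("'coverage' must be >= 1")
  dip_genes <- dip_genes %||% sim$genes$gene_id
  with_seed(stream_seed(cfg$seed, "methylome"), {
    gsub_ <- sim$genes[sim$genes$gene_id %in% dip_genes, , drop = FALSE]
    out <- list()
    for (ch in names(sim$sequences)) {
      len <- Biostrings::width(sim$sequences[ch])
      pos <- seq(1L, len, by = cfg$methyl_site_spacing) +
        sample.int(cfg$methyl_site_spacing - 1L,
                    length(seq(1L, len, by = cfg$methyl_site_spacing)),
                    replace = TRUE) - 1L
      pos <- pos[pos <= len]
      nS <- length(pos)
      context <- sample(c("CG", "CHG", "CHH"), nS, replace = TRUE,
                        prob = c(0.25, 0.25, 0.5))
      strand <- sample(c("+", "-"), nS, replace = TRUE)
      p <- ifelse(context == "CG", cfg$methyl_baseline, cfg$methyl_ch_level)
      ## planted upstream dip for CG sites near dip-set TSSs on this chromosome
      g <- gsub_[gsub_$chrom == ch, , drop = FALSE]
      if (nrow(g) && cfg$methyl_dip_depth > 0) {
        ds <- ifelse(g$strand == "+", pmax(1L, g$start - cfg$methyl_dip_span), g$end + 1L)
        de <- ifelse(g$strand == "+", g$start - 1L, g$end + cfg$methyl_dip_span)
        keep <- ds <= de
        if (any(keep)) {
          ir <- IRanges::IRanges(ds[keep], de[keep])
          hit <- IRanges::overlapsAny(IRanges::IRanges(pos, pos), ir)
          p[hit & context == "CG"] <- cfg$methyl_baseline - cfg$methyl_dip_depth
        }
      }
      total <- rpois(nS, coverage) + 1L
      mc <- rbinom(nS, total, p)
      out[[ch]] <- data.frame(chrom = ch, pos = pos, strand = strand,
                              context = context, mc_reads = mc,
                              total_reads = total, stringsAsFactors = FALSE)
    }
    calls <- do.call(rbind, out); rownames(calls) <- NULL
    attr(calls, "truth") <- list(baseline = cfg$methyl_baseline,
                                 dip_depth = cfg$methyl_dip_depth,
                                 dip_span = cfg$methyl_dip_span,
                                 dip_genes = dip_genes,
                                 ch_level = cfg$methyl_ch_level)
    calls
  })
}

#' Simulate a complete dataset and assemble the ground-truth manifest
#'
#' Convenience wrapper running every generator and merging their truth blocks
#' into one manifest (serializable with [write_manifest()]).
#'
#' @param config a [sim_config()].
#' @param tissues,replicates passed to [simulate_expression()].
#' @param n_cns passed to [simulate_cns_set()].
#' @param n_bins,n_tads,n_conserved passed to [simulate_hic()].
#' @return list with elements `genome`, `expression`, `cns`, `hic`,
#'   `methylome` and `manifest`.
#' @export
simulate_dataset <- function(config, tissues = 6L, replicates = 3L,
                             n_cns = 400L, n_bins = 60L, n_tads = 20L,
                             n_conserved = 10L) {
  genome <- simulate_tetraploid(config)
  expr <- simulate_expression(genome, tissues, replicates)
  cns <- simulate_cns_set(genome, n_cns)
  hic <- simulate_hic(genome, n_bins = n_bins, n_tads = n_tads,
                      n_conserved = n_conserved)
  meth <- simulate_methylome(genome)
  manifest <- genome$manifest
  manifest$expression <- list(
    bias_M = expr$truth$ref_gene[expr$truth$bias == "M"],
    bias_P = expr$truth$ref_gene[expr$truth$bias == "P"],
    fates = expr$truth[expr$truth$complete,
                       c("ref_gene", "fate", "nonf_off", "neo_copy")])
  manifest$cns <- cns$truth
  manifest$hic <- list(block_len = config$compartment_block_len,
                       conserved_tads = hic$truth[hic$truth$conserved, c("tad_P", "tad_M")],
                       n_tads = n_tads, n_conserved = n_conserved)
  manifest$methylome <- attr(meth, "truth")[c("baseline", "dip_depth", "dip_span",
                                              "ch_level")]
  list(genome = genome, expression = expr, cns = cns, hic = hic,
       methylome = meth, manifest = manifest)
}

#' Write / read a ground-truth manifest as JSON
#'
#' @param manifest manifest list (from a `subdom_sim` or [simulate_dataset()]).
#' @param path output path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` the
#'   manifest list.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in intersect(c("deleted_P", "deleted_M"), names(m)))
    m[[nm]] <- as.character(m[[nm]])
  m
}
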