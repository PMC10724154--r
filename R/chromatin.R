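#' Call A/B compartments from a contact matrix
#'
#' The PCA-based compartment call: Pearson correlation matrix of the
#' (ICE-corrected) contact matrix, first principal component of that
#' correlation matrix, bins split by PC1 sign. The sign is oriented so that
#' the mean gene density of positive bins is at least that of negative bins
#' (A = open, gene-dense); without a gene track the track is returned
#' unoriented with a warning. Bins with zero total contacts are masked (NA).
#'
#' @param m square symmetric non-negative contact matrix (one chromosome,
#'   typically 100 kb bins).
#' @param gene_density optional numeric vector of genes per bin used to
#'   orient PC1.
#' @param min_bins minimum usable bins (default 10).
#' @param min_var minimum fraction of variance PC1 must explain (default
#'   0.05); below it a "no compartment signal" error is raised.
#' @return data.frame of class `compartment_track`: `bin`, `pc1`, `label`
#'   ("A", "B" or NA for masked/zero bins), with `attr(, "oriented")`.
#' @export
call_compartments <- function(m, gene_density = NULL, min_bins = 10L,
                              min_var = 0.05) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stopf("'m' must be a square matrix")
  if (max(abs(m - t(m))) > 1e-6 * max(1, max(abs(m)))) stopf("'m' must be symmetric")
  n <- nrow(m)
  usable <- rowSums(m) > 0
  if (sum(usable) < min_bins) stopf("fewer than %d usable bins", min_bins)
  mm <- m[usable, usable, drop = FALSE]
  if (max(mm) == min(mm))
    stop(errorCondition("no compartment signal: constant contact matrix",
                        class = c("no_compartment_signal", "error")))
  cc <- suppressWarnings(stats::cor(mm))
  cc[is.na(cc)] <- 0
  pca <- stats::prcomp(cc, center = TRUE, scale. = FALSE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  if (!is.finite(ve[1]) || ve[1] < min_var)
    stop(errorCondition(sprintf(
      "no compartment signal: PC1 explains %.1f%% of variance", 100 * ve[1]),
      class = c("no_compartment_signal", "error")))
  pc1 <- rep(NA_real_, n)
  pc1[usable] <- pca$x[, 1]
  oriented <- FALSE
  if (!is.null(gene_density)) {
    if (length(gene_density) != n) stopf("gene_density length != number of bins")
    pos <- mean(gene_density[!is.na(pc1) & pc1 > 0])
    neg <- mean(gene_density[!is.na(pc1) & pc1 < 0])
    if (!is.nan(pos) && !is.nan(neg) && pos < neg) pc1 <- -pc1
    oriented <- TRUE
  } else {
    warning("no gene track given; compartment orientation (A vs B) is arbitrary")
  }
  label <- ifelse(is.na(pc1) | pc1 == 0, NA_character_,
                  ifelse(pc1 > 0, "A", "B"))
  res <- data.frame(bin = seq_len(n), pc1 = pc1, label = label,
                    stringsAsFactors = FALSE)
  attr(res, "oriented") <- oriented
  attr(res, "pc1_var") <- ve[1]
  class(res) <- c("compartment_track", "data.frame")
  res
}

#' Compartment content summary
#'
#' A%/B% of labeled bins, gene counts per compartment (genes assigned to the
#' bin of their midpoint), TE bp fraction per compartment, and a Welch
#' two-sample t-test of gene expression (A vs B).
#'
#' @param track a [call_compartments()] result for one chromosome.
#' @param bin_size bin size in bp.
#' @param genes optional data.frame `gene_id`, `start`, `end` (this
#'   chromosome only).
#' @param tes optional data.frame `start`, `end`.
#' @param expression optional named vector of per-gene expression (e.g. mean
#'   TPM in one tissue).
#' @return list `bins` (`percent_A`, `percent_B`), `genes` (counts; NULL if
#'   no genes), `te_fraction`, `expression_test` (`t`, `p`, means).
#' @export
compartment_content <- function(track, bin_size, genes = NULL, tes = NULL,
                                expression = NULL) {
  lab <- track$label
  nl <- sum(!is.na(lab))
  out <- list(bins = list(percent_A = 100 * sum(lab == "A", na.rm = TRUE) / nl,
                          percent_B = 100 * sum(lab == "B", na.rm = TRUE) / nl))
  bin_of <- function(pos) pmin(length(lab), pmax(1L, ceiling(pos / bin_size)))
  if (!is.null(genes)) {
    mid <- (genes$start + genes$end) / 2
    gl <- lab[bin_of(mid)]
    outside <- mid > length(lab) * bin_size | mid < 1
    if (any(outside)) message(sprintf("%d genes outside binned range excluded",
                                      sum(outside)))
    gl[outside] <- NA
    out$genes <- list(n_A = sum(gl == "A", na.rm = TRUE),
                      n_B = sum(gl == "B", na.rm = TRUE),
                      assignment = data.frame(gene_id = genes$gene_id,
                                              compartment = gl,
                                              stringsAsFactors = FALSE))
    if (!is.null(expression)) {
      eA <- expression[genes$gene_id[!is.na(gl) & gl == "A"]]
      eB <- expression[genes$gene_id[!is.na(gl) & gl == "B"]]
      eA <- eA[!is.na(eA)]; eB <- eB[!is.na(eB)]
      if (length(eA) >= 2 && length(eB) >= 2) {
        tt <- stats::t.test(eA, eB)
        out$expression_test <- list(t = unname(tt$statistic), p = tt$p.value,
                                    mean_A = mean(eA), mean_B = mean(eB))
      }
    }
  }
  if (!is.null(tes)) {
    bp <- function(l) {
      bins <- which(lab == l)
      if (!length(bins)) return(0)
      rr <- IRanges::IRanges((bins - 1L) * bin_size + 1L, bins * bin_size)
      sum(IRanges::width(IRanges::intersect(
        IRanges::reduce(IRanges::IRanges(tes$start, tes$end)), rr)))
    }
    a_bp <- bp("A"); b_bp <- bp("B")
    out$te_fraction <- list(A = a_bp / (sum(lab == "A", na.rm = TRUE) * bin_size),
                            B = b_bp / (sum(lab == "B", na.rm = TRUE) * bin_size))
  }
  out
}

## assign genes (by position) to the TAD interval containing them
tad_of <- function(genes, tads) {
  hit <- rep(NA_character_, nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    tt <- tads[tads$chrom == ch, , drop = FALSE]
    if (!nrow(tt)) next
    ov <- IRanges::findOverlaps(IRanges::IRanges(genes$pos[gi], genes$pos[gi]),
                                IRanges::IRanges(tt$start, tt$end),
                                select = "first")
    hit[gi] <- tt$tad_id[ov]
  }
  hit
}

#' Classify conserved TADs between subgenomes
#'
#' A TAD is conserved when, of its collinear genes (those with a syntelog
#' partner), the fraction landing in a single partner-subgenome TAD exceeds
#' `min_frac` and the TAD holds at least `min_genes` collinear genes.
#' Evaluated in both directions; the reciprocal flag marks TAD pairs
#' conserved from both sides.
#'
#' @param tads_P,tads_M data.frames `tad_id`, `chrom`, `start`, `end`.
#' @param genes_P,genes_M data.frames `gene`, `chrom`, `pos`.
#' @param syntelogs data.frame `gene_P`, `gene_M`.
#' @param min_frac overlap fraction threshold (default 0.7, strict >).
#' @param min_genes minimum collinear genes (default 5, >=).
#' @return list of class `conserved_tads`: `per_tad` (both directions:
#'   `tad_id`, `direction`, `n_collinear`, `best_partner`, `best_fraction`,
#'   `conserved`, `evaluable`), `counts` (per direction + reciprocal).
#' @export
conserved_tads <- function(tads_P, tads_M, genes_P, genes_M, syntelogs,
                           min_frac = 0.7, min_genes = 5L) {
  gp <- genes_P; gp$tad <- tad_of(gp, tads_P)
  gm <- genes_M; gm$tad <- tad_of(gm, tads_M)
  partner_P <- stats::setNames(syntelogs$gene_M, syntelogs$gene_P)
  partner_M <- stats::setNames(syntelogs$gene_P, syntelogs$gene_M)
  tad_lookup_P <- stats::setNames(gp$tad, gp$gene)
  tad_lookup_M <- stats::setNames(gm$tad, gm$gene)
  eval_dir <- function(tads, gene_tab, partner, partner_tad, direction) {
    rows <- lapply(tads$tad_id, function(tid) {
      members <- gene_tab$gene[!is.na(gene_tab$tad) & gene_tab$tad == tid]
      coll <- members[members %in% names(partner)]
      ptads <- partner_tad[partner[coll]]
      ptads <- ptads[!is.na(ptads)]
      if (!length(coll))
        return(data.frame(tad_id = tid, direction = direction, n_collinear = 0L,
                          best_partner = NA_character_, best_fraction = NA_real_,
                          conserved = FALSE, evaluable = FALSE,
                          stringsAsFactors = FALSE))
      tab <- sort(table(ptads), decreasing = TRUE)
      best <- if (length(tab)) names(tab)[1] else NA_character_
      frac <- if (length(tab)) as.numeric(tab[1]) / length(coll) else 0
      data.frame(tad_id = tid, direction = direction, n_collinear = length(coll),
                 best_partner = best, best_fraction = frac,
                 conserved = frac > min_frac && length(coll) >= min_genes,
                 evaluable = TRUE, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  pm <- eval_dir(tads_P, gp, partner_P, tad_lookup_M, "P->M")
  mp <- eval_dir(tads_M, gm, partner_M, tad_lookup_P, "M->P")
  per_tad <- rbind(pm, mp)
  ## reciprocal: P TAD t conserved toward M TAD t' and t' conserved toward t
  mp_best <- stats::setNames(mp$best_partner, mp$tad_id)
  mp_cons <- stats::setNames(mp$conserved, mp$tad_id)
  recip <- pm$conserved & !is.na(pm$best_partner) &
    mp_cons[pm$best_partner] & mp_best[pm$best_partner] == pm$tad_id
  res <- list(per_tad = per_tad,
              counts = list(P_to_M = sum(pm$conserved),
                            M_to_P = sum(mp$conserved),
                            reciprocal = sum(recip, na.rm = TRUE)),
              reciprocal_pairs = data.frame(
                tad_P = pm$tad_id[which(recip)],
                tad_M = pm$best_partner[which(recip)],
                stringsAsFactors = FALSE))
  class(res) <- "conserved_tads"
  res
}

#' @export
print.conserved_tads <- function(x, ...) {
  cat(sprintf("conserved TADs: %d (P->M), %d (M->P), %d reciprocal\n",
              x$counts$P_to_M, x$counts$M_to_P, x$counts$reciprocal))
  invisible(x)
}
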