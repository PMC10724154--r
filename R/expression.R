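## tissue of a "tissue.replicate" column name
col_tissue <- function(x) sub("\\.[0-9]+$", "", x)

#' Mean TPM per gene and tissue
#'
#' Arithmetic mean over replicates, per tissue (the 3-5 replicate average
#' used throughout the expression analyses). Missing values are averaged
#' over the available replicates.
#'
#' @param tpm matrix of TPM values, genes x columns named `tissue.replicate`
#'   (e.g. `brain.1`), or a `subdom_expr_sim`.
#' @return matrix genes x tissues of mean TPM, with replicate counts in
#'   `attr(, "n_replicates")`.
#' @export
aggregate_tpm <- function(tpm) {
  if (inherits(tpm, "subdom_expr_sim")) tpm <- tpm$tpm
  if (any(tpm < 0, na.rm = TRUE)) stopf("TPM values must be >= 0")
  tis <- col_tissue(colnames(tpm))
  ut <- unique(tis)
  out <- vapply(ut, function(t)
    rowMeans(tpm[, tis == t, drop = FALSE], na.rm = TRUE),
    numeric(nrow(tpm)))
  if (!is.matrix(out)) out <- matrix(out, nrow = 1, dimnames = list(rownames(tpm), ut))
  attr(out, "n_replicates") <- vapply(ut, function(t) sum(tis == t), integer(1))
  out
}

#' Call homoeolog expression bias (HEB)
#'
#' Per ohnolog pair and tissue: `log2FC = log2((TPM_M + eps) / (TPM_P + eps))`
#' on mean TPM. A pair is evaluated in a tissue only when
#' `max(TPM_M, TPM_P) >= min_expr`; it is labelled M-biased or P-biased when
#' `|log2FC| > fc_thresh` (default 2, the standard homoeolog-bias cutoff) and
#' unbiased otherwise. Pairs missing one copy are excluded (that is a
#' retention event, not expression bias). Per-tissue biased counts are tested
#' for departure from 1:1 with [balance_chisq()].
#'
#' @param pairs data.frame with `gene_P` and `gene_M` columns (NAs dropped).
#' @param means gene x tissue matrix from [aggregate_tpm()].
#' @param eps pseudocount (> 0; default 0.5).
#' @param fc_thresh absolute log2FC threshold (default 2).
#' @param min_expr minimum mean TPM of the higher copy (default 1).
#' @return list of class `heb_result`: `calls` (long data.frame: `gene_P`,
#'   `gene_M`, `tissue`, `tpm_P`, `tpm_M`, `log2fc`, `label`), `counts`
#'   (per-tissue label counts with chi-square test), `total` (genome-wide
#'   M vs P counts and test).
#' @export
call_heb <- function(pairs, means, eps = 0.5, fc_thresh = 2, min_expr = 1) {
  if (eps <= 0) stopf("'eps' must be > 0")
  p <- pairs[!is.na(pairs$gene_P) & !is.na(pairs$gene_M), , drop = FALSE]
  miss <- setdiff(c(p$gene_P, p$gene_M), rownames(means))
  if (length(miss)) stopf("genes missing from the mean-TPM matrix: %s",
                          paste(head(miss, 3), collapse = ", "))
  tis <- colnames(means)
  mP <- means[p$gene_P, , drop = FALSE]
  mM <- means[p$gene_M, , drop = FALSE]
  lfc <- log2((mM + eps) / (mP + eps))
  expressed <- pmax(mP, mM) >= min_expr
  lab <- matrix("not-expressed", nrow(p), length(tis))
  lab[expressed] <- "unbiased"
  lab[expressed & lfc > fc_thresh] <- "M-biased"
  lab[expressed & lfc < -fc_thresh] <- "P-biased"
  calls <- data.frame(gene_P = rep(p$gene_P, times = length(tis)),
                      gene_M = rep(p$gene_M, times = length(tis)),
                      tissue = rep(tis, each = nrow(p)),
                      tpm_P = as.vector(mP), tpm_M = as.vector(mM),
                      log2fc = as.vector(lfc), label = as.vector(lab),
                      stringsAsFactors = FALSE)
  per_t <- do.call(rbind, lapply(tis, function(t) {
    l <- lab[, match(t, tis)]
    nM <- sum(l == "M-biased"); nP <- sum(l == "P-biased")
    ct <- if (nM + nP > 0) balance_chisq(nM, nP) else list(chisq = NA_real_, p = NA_real_)
    data.frame(tissue = t, n_M_biased = nM, n_P_biased = nP,
               n_unbiased = sum(l == "unbiased"),
               n_not_expressed = sum(l == "not-expressed"),
               chisq = ct$chisq, p = ct$p, stringsAsFactors = FALSE)
  }))
  nM <- sum(lab == "M-biased"); nP <- sum(lab == "P-biased")
  tot <- if (nM + nP > 0) balance_chisq(nM, nP) else list(chisq = NA_real_, p = NA_real_)
  res <- list(calls = calls, counts = per_t,
              total = list(n_M_biased = nM, n_P_biased = nP,
                           chisq = tot$chisq, p = tot$p))
  class(res) <- "heb_result"
  res
}

#' @export
print.heb_result <- function(x, ...) {
  cat(sprintf("HEB: %d M-biased vs %d P-biased pair-tissues (chi-square p = %.3g)\n",
              x$total$n_M_biased, x$total$n_P_biased, x$total$p))
  invisible(x)
}

#' Expression correlation with the diploid ancestor
#'
#' Pearson correlation of `log2(TPM + 1)` tissue profiles, with the two-sided
#' correlation test.
#'
#' @param x,y numeric vectors of per-tissue mean TPM (>= 3 tissues).
#' @return list `r`, `p`, `flag` ("ok" or "zero-variance"; r is NA when
#'   either profile is constant).
#' @export
correlation_with_ancestor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stopf("need two equal-length profiles over >= 3 tissues")
  lx <- log2(x + 1); ly <- log2(y + 1)
  if (sd(lx) == 0 || sd(ly) == 0)
    return(list(r = NA_real_, p = NA_real_, flag = "zero-variance"))
  ct <- stats::cor.test(lx, ly)
  list(r = unname(ct$estimate), p = ct$p.value, flag = "ok")
}

#' Classify the evolutionary fate of an ohnolog pair
#'
#' Applies an ordered on/off decision table to the tissue expression profiles
#' of a diploid ancestor gene O and the two tetraploid copies X and Y
#' ("on" relative to a partner means TPM >= `on` while the partner is
#' < `off`; "expressed" means TPM >= `expr` in at least one tissue):
#'
#' 1. all three silent -> `not-expressed` (dropped from proportions);
#' 2. exactly one copy below `off` in every tissue while O and the other copy
#'    are expressed -> `nonfunctionalized`;
#' 3. some tissue has X on / Y off and another has Y on / X off, with O
#'    expressed in both -> `subfunctionalized`;
#' 4. some tissue has one copy >= `on` while O and the other copy are below
#'    `off` -> `neofunctionalized`;
#' 5. both copies highly correlated with O (r > `r_thresh`, test p <
#'    `p_thresh`; r > `r_relaxed` when `relaxed`) -> `dosage` (retention
#'    under dosage selection);
#' 6. otherwise `unclassified`.
#'
#' @param O,X,Y numeric per-tissue mean TPM vectors (same tissues, >= 2).
#' @param on,off on/off thresholds (defaults 2 and 1).
#' @param expr expressed threshold (default 1).
#' @param r_thresh,p_thresh correlation gate for dosage retention (defaults
#'   0.75 and 0.1).
#' @param relaxed use the relaxed correlation tier `r_relaxed` (no p gate).
#' @param r_relaxed relaxed correlation threshold (default 0.6).
#' @return list of class `fate_call`: `category` plus an `evidence` list
#'   (per-tissue on/off states, correlations with test p, t-test p on
#'   log2(TPM+1) between X and Y — attached as evidence, not a trigger).
#' @export
classify_fate <- function(O, X, Y, on = 2, off = 1, expr = 1,
                          r_thresh = 0.75, p_thresh = 0.1,
                          relaxed = FALSE, r_relaxed = 0.6) {
  nT <- length(O)
  if (length(X) != nT || length(Y) != nT || nT < 2L)
    stopf("O, X, Y must share >= 2 tissues")
  expressed <- function(v) any(v >= expr)
  x_on_y_off <- X >= on & Y < off
  y_on_x_off <- Y >= on & X < off
  x_silent <- all(X < off); y_silent <- all(Y < off)
  neo_x <- X >= on & O < off & Y < off
  neo_y <- Y >= on & O < off & X < off
  cw <- function(f) tryCatch(f, error = function(e) list(r = NA_real_, p = NA_real_))
  rX <- cw(correlation_with_ancestor(O, X))
  rY <- cw(correlation_with_ancestor(O, Y))
  tXY <- tryCatch(stats::t.test(log2(X + 1), log2(Y + 1))$p.value,
                  error = function(e) NA_real_)
  corr_ok <- function(r) if (relaxed) !is.na(r$r) && r$r > r_relaxed else
    !is.na(r$r) && r$r > r_thresh && !is.na(r$p) && r$p < p_thresh
  sub_trig <- any(x_on_y_off & O >= expr) && any(y_on_x_off & O >= expr)
  neo_trig <- any(neo_x) || any(neo_y)
  category <-
    if (!expressed(O) && !expressed(X) && !expressed(Y)) "not-expressed"
    else if (x_silent && expressed(O) && expressed(Y)) "nonfunctionalized"
    else if (y_silent && expressed(O) && expressed(X)) "nonfunctionalized"
    else if (sub_trig) "subfunctionalized"
    else if (neo_trig) "neofunctionalized"
    else if (corr_ok(rX) && corr_ok(rY)) "dosage"
    else "unclassified"
  conflict <- sum(c(x_silent || y_silent, sub_trig, neo_trig)) > 1
  res <- list(category = category,
              evidence = list(x_on_y_off = x_on_y_off, y_on_x_off = y_on_x_off,
                              silenced = if (x_silent) "X" else if (y_silent) "Y" else NA,
                              neo_copy = if (any(neo_x)) "X" else if (any(neo_y)) "Y" else NA,
                              r_XO = rX$r, p_XO = rX$p, r_YO = rY$r, p_YO = rY$p,
                              t_p_XY = tXY, conflict = conflict))
  class(res) <- "fate_call"
  res
}

#' Classify fates for a table of ohnolog trios
#'
#' @param trios data.frame with `ref_gene`, `gene_P`, `gene_M`; rows with a
#'   missing copy are skipped (incomplete trios have no pair fate).
#' @param means gene x tissue matrix from [aggregate_tpm()] containing the
#'   ancestor and both copies.
#' @param ... passed to [classify_fate()].
#' @return data.frame: `ref_gene`, `category`, `r_PO`, `r_MO`, `conflict`.
#' @export
classify_fates <- function(trios, means, ...) {
  tr <- trios[!is.na(trios$gene_P) & !is.na(trios$gene_M), , drop = FALSE]
  rows <- lapply(seq_len(nrow(tr)), function(i) {
    fc <- classify_fate(means[tr$ref_gene[i], ], means[tr$gene_P[i], ],
                        means[tr$gene_M[i], ], ...)
    data.frame(ref_gene = tr$ref_gene[i], category = fc$category,
               r_PO = fc$evidence$r_XO %||% NA_real_,
               r_MO = fc$evidence$r_YO %||% NA_real_,
               conflict = fc$evidence$conflict, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fate category counts and percentages
#'
#' Percentages use the evaluated pairs (trios with some expression) as the
#' denominator.
#'
#' @param categories character vector of fate categories (e.g. the `category`
#'   column of [classify_fates()]).
#' @return data.frame `category`, `n`, `percent`.
#' @export
summarize_fates <- function(categories) {
  keep <- categories[categories != "not-expressed"]
  lev <- c("dosage", "nonfunctionalized", "subfunctionalized",
           "neofunctionalized", "unclassified")
  n <- table(factor(keep, levels = lev))
  data.frame(category = lev, n = as.vector(n),
             percent = 100 * as.vector(n) / length(keep))
}
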