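#' Count TE copies per family and homoeologous chromosome pair
#'
#' Produces the `N_iA` (subP member) / `N_iB` (subM member) copy counts that
#' feed the subgenome biased index. Families absent from a pair get zeros.
#'
#' @param tes data.frame of TE records with columns `chrom` and a family
#'   column (`family_field`).
#' @param assignment a `subgenome_assignment` (or any data.frame with `chrom`
#'   and `subgenome` columns) covering every TE chromosome.
#' @param map a [homoeolog_map()].
#' @param family_field name of the family column (default "family").
#' @return data.frame of class `te_count_table`: `family`, `pair`, `N_A`
#'   (subP member count), `N_B` (subM member count).
#' @export
count_te_by_homoeolog <- function(tes, assignment, map, family_field = "family") {
  if (!family_field %in% names(tes)) stopf("no '%s' column in TE table", family_field)
  sg <- stats::setNames(assignment$subgenome, assignment$chrom)
  if (nrow(tes)) {
    unknown <- setdiff(unique(tes$chrom), names(sg))
    if (length(unknown))
      stopf("TE chromosomes without subgenome assignment: %s",
            paste(unknown, collapse = ", "))
  }
  pair_of <- integer(0); side <- character(0)
  for (i in seq_len(nrow(map))) {
    a <- map$chrom_a[i]; b <- map$chrom_b[i]
    ## orient each pair by the assignment: A = subP member, B = subM member
    if (sg[[a]] == "subP") { pA <- a; pB <- b } else { pA <- b; pB <- a }
    pair_of[c(pA, pB)] <- i
    side[c(pA, pB)] <- c("A", "B")
  }
  fams <- sort(unique(tes[[family_field]]))
  out <- expand.grid(family = fams, pair = seq_len(nrow(map)),
                     stringsAsFactors = FALSE)
  cnt <- function(s) {
    sub <- tes[side[tes$chrom] == s, , drop = FALSE]
    tab <- table(factor(sub[[family_field]], levels = fams),
                 factor(pair_of[sub$chrom], levels = seq_len(nrow(map))))
    as.vector(tab)
  }
  if (length(fams)) { out$N_A <- cnt("A"); out$N_B <- cnt("B") }
  else { out$N_A <- integer(0); out$N_B <- integer(0) }
  class(out) <- c("te_count_table", "data.frame")
  out
}

#' Subgenome biased index (SBI) per TE family
#'
#' `SBI(f) = |sum_i N_iA - sum_i N_iB| / sum_i (N_iA + N_iB)`, ranging from 0
#' (perfectly balanced) to 1 (all copies in one subgenome). An alternative
#' per-pair-absolute form `sum_i |N_iA - N_iB| / sum_i (N_iA + N_iB)` is
#' available via `per_pair = TRUE`. Families with zero total copies are
#' excluded. The specificity flag marks families with `SBI >= sbi_threshold`
#' and at least `min_copies` total copies.
#'
#' @param t a `te_count_table`.
#' @param sbi_threshold flag threshold (default 0.5).
#' @param min_copies minimum total copies for the flag (default 30).
#' @param per_pair use the per-pair-absolute variant.
#' @return data.frame of class `sbi_result`: `family`, `sbi`, `total`,
#'   `biased_subgenome` ("subP"/"subM"/"none"), `specific`.
#' @export
compute_sbi <- function(t, sbi_threshold = 0.5, min_copies = 30L,
                        per_pair = FALSE) {
  if (nrow(t) == 0L) stopf("empty TE count table")
  dt <- data.table::as.data.table(t)
  agg <- dt[, list(sum_A = sum(N_A), sum_B = sum(N_B),
                   sum_absdiff = sum(abs(N_A - N_B))), by = "family"]
  agg[, "total" := agg$sum_A + agg$sum_B]
  dropped <- agg$family[agg$total == 0]
  if (length(dropped))
    message(sprintf("compute_sbi: excluding %d all-zero families", length(dropped)))
  agg <- agg[agg$total > 0, ]
  sbi <- if (per_pair) agg$sum_absdiff / agg$total else
    abs(agg$sum_A - agg$sum_B) / agg$total
  res <- data.frame(family = agg$family, sbi = sbi, total = agg$total,
                    biased_subgenome = ifelse(agg$sum_A > agg$sum_B, "subP",
                                       ifelse(agg$sum_B > agg$sum_A, "subM", "none")),
                    specific = sbi >= sbi_threshold & agg$total >= min_copies,
                    stringsAsFactors = FALSE)
  class(res) <- c("sbi_result", "data.frame")
  res
}

## union (overlap-merged) TE bp within [lo, hi] on one chromosome
union_bp <- function(te_start, te_end, lo, hi) {
  if (lo > hi || length(te_start) == 0L) return(0L)
  r <- IRanges::restrict(IRanges::IRanges(te_start, te_end), lo, hi)
  sum(IRanges::width(IRanges::reduce(r)))
}

#' TE density in gene-flanking windows
#'
#' Per gene: the fraction of TE-occupied bp (union coverage, overlap-merged)
#' in a strand-oriented window upstream of the TSS, within the gene body, and
#' downstream of the TTS. Windows truncated at a chromosome end use the
#' truncated length as denominator; a window fully truncated away yields NA.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param tes data.frame with `chrom`, `start`, `end` (any family mix; filter
#'   beforehand for per-order profiles).
#' @param window flank window length in bp (default 10000).
#' @param chrom_lengths optional named vector of chromosome lengths used for
#'   truncation at the right end.
#' @return data.frame of class `te_density_profile`: `gene_id`, `chrom`,
#'   `upstream`, `intragenic`, `downstream` densities in [0, 1].
#' @export
te_density_windows <- function(genes, tes, window = 10000L, chrom_lengths = NULL) {
  if (window <= 0) stopf("'window' must be > 0")
  res <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    upstream = NA_real_, intragenic = NA_real_,
                    downstream = NA_real_, stringsAsFactors = FALSE)
  te_by_chr <- split(tes[, c("start", "end")], tes$chrom)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    te <- te_by_chr[[g$chrom]]
    ts <- te$start %||% integer(0); te_e <- te$end %||% integer(0)
    cl <- if (!is.null(chrom_lengths)) chrom_lengths[[g$chrom]] else Inf
    up <- if (g$strand == "-") c(g$end + 1L, g$end + window) else
      c(g$start - window, g$start - 1L)
    dn <- if (g$strand == "-") c(g$start - window, g$start - 1L) else
      c(g$end + 1L, g$end + window)
    clampit <- function(w) c(max(w[1], 1), min(w[2], cl))
    up <- clampit(up); dn <- clampit(dn)
    den <- function(w) {
      len <- w[2] - w[1] + 1
      if (len <= 0) return(NA_real_)
      union_bp(ts, te_e, w[1], w[2]) / len
    }
    res$upstream[i] <- den(up)
    res$downstream[i] <- den(dn)
    res$intragenic[i] <- den(c(g$start, g$end))
  }
  class(res) <- c("te_density_profile", "data.frame")
  res
}

#' Syntelog TE density differences and two-sample test
#'
#' Joins a density profile over a syntelog table and returns the per-pair
#' difference subP - subM (positive = subP denser) for the requested window,
#' together with a Welch two-sample t-test between the subP and subM density
#' vectors.
#'
#' @param profile a [te_density_windows()] result covering both subgenomes.
#' @param syntelogs data.frame with `gene_P` and `gene_M` columns; rows with
#'   either copy missing are dropped.
#' @param which window to compare: "upstream", "intragenic" or "downstream".
#' @return list with `differences` (data.frame `ref_gene`?, `gene_P`,
#'   `gene_M`, `density_P`, `density_M`, `diff`), `t` and `p`.
#' @export
density_difference_test <- function(profile, syntelogs, which = "upstream") {
  which <- match.arg(which, c("upstream", "intragenic", "downstream"))
  st <- syntelogs[!is.na(syntelogs$gene_P) & !is.na(syntelogs$gene_M), , drop = FALSE]
  dens <- stats::setNames(profile[[which]], profile$gene_id)
  dP <- dens[st$gene_P]; dM <- dens[st$gene_M]
  ok <- !is.na(dP) & !is.na(dM)
  if (sum(ok) < 2L) stopf("need >= 2 syntelog pairs with densities on both copies")
  d <- data.frame(gene_P = st$gene_P[ok], gene_M = st$gene_M[ok],
                  density_P = unname(dP[ok]), density_M = unname(dM[ok]),
                  diff = unname(dP[ok] - dM[ok]), stringsAsFactors = FALSE)
  tt <- if (stats::sd(d$density_P) == 0 && stats::sd(d$density_M) == 0 &&
            all(d$diff == 0)) list(statistic = c(t = 0), p.value = 1)
  else stats::t.test(d$density_P, d$density_M)
  list(differences = d, t = unname(tt$statistic), p = tt$p.value)
}
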