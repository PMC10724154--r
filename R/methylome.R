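#' Weighted methylation level of a region
#'
#' `wML = sum(mc_reads) / sum(total_reads)` over the covered cytosines of the
#' requested context inside the region — read-weighted, not site-averaged, so
#' deeply covered sites count more. Returns NA when no covered cytosine
#' falls in the region (never 0).
#'
#' @param calls data.frame of per-cytosine calls: `chrom`, `pos` (1-based),
#'   `strand`, `context` ("CG"/"CHG"/"CHH"), `mc_reads`, `total_reads`.
#' @param chrom,start,end region (1-based closed).
#' @param context context filter; "CH" matches CHG + CHH.
#' @return weighted methylation level in [0, 1], or NA.
#' @export
weighted_methylation <- function(calls, chrom, start, end, context = "CG") {
  ctx <- if (context == "CH") calls$context %in% c("CHG", "CHH") else
    calls$context == context
  sel <- ctx & calls$chrom == chrom & calls$pos >= start & calls$pos <= end &
    calls$total_reads > 0
  if (!any(sel)) return(NA_real_)
  sum(calls$mc_reads[sel]) / sum(calls$total_reads[sel])
}

## bin index (1..n_bins) of relative position u in [0, 1]
rel_bin <- function(u, n_bins) pmin(n_bins, pmax(1L, ceiling(u * n_bins)))

#' Methylation metaplot over features and 2 kb flanks
#'
#' Feature bodies are divided into `body_bins` equal bins and each flank into
#' `flank_bins` fixed-width bins (2 kb / 20 = 100 bp by default), all
#' orientation-corrected by strand so upstream is always 5'. Per bin the
#' weighted methylation level pools reads across features; the per-feature
#' bin matrix is kept for between-set comparisons. Features shorter than
#' `body_bins` bp are skipped.
#'
#' @param features data.frame `feature_id`, `chrom`, `start`, `end`,
#'   `strand`; optionally `exon_start`/`exon_end` list-columns when
#'   `exonic_only`.
#' @param calls per-cytosine calls as in [weighted_methylation()].
#' @param context context filter ("CG" by default; bodies of the metaplots).
#' @param flank flank length in bp (default 2000).
#' @param body_bins,flank_bins bin counts (default 20 each).
#' @param exonic_only restrict body cytosines to exons (needs the exon
#'   list-columns).
#' @param per_feature method for the aggregated track: pool reads across
#'   features (FALSE, default — the weighted level) or average per-feature
#'   levels (TRUE).
#' @return object of class `metaplot`: list with `track` (data.frame `bin`,
#'   `region` = upstream/body/downstream, `position`, `wml`),
#'   `feature_matrix` (features x bins of per-feature wML), `n_features`.
#' @export
metaplot <- function(features, calls, context = "CG", flank = 2000L,
                     body_bins = 20L, flank_bins = 20L, exonic_only = FALSE,
                     per_feature = FALSE) {
  dt <- data.table::as.data.table(calls)
  ctx <- if (context == "CH") dt$context %in% c("CHG", "CHH") else dt$context == context
  dt <- dt[ctx & dt$total_reads > 0, ]
  by_chrom <- split(dt, dt$chrom)
  nb <- 2L * flank_bins + body_bins
  fw <- flank / flank_bins
  mc_mat <- matrix(0, nrow(features), nb)
  tot_mat <- matrix(0, nrow(features), nb)
  skipped <- 0L
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    len <- f$end - f$start + 1L
    if (len < body_bins) { skipped <- skipped + 1L; next }
    cdt <- by_chrom[[f$chrom]]
    if (is.null(cdt)) next
    sub <- cdt[cdt$pos >= f$start - flank & cdt$pos <= f$end + flank, ]
    if (!nrow(sub)) next
    pos <- sub$pos
    minus <- identical(f$strand, "-")
    in_body <- pos >= f$start & pos <= f$end
    if (exonic_only && !is.null(f$exon_start)) {
      es <- f$exon_start[[1]]; ee <- f$exon_end[[1]]
      in_exon <- IRanges::overlapsAny(IRanges::IRanges(pos, pos),
                                      IRanges::IRanges(es, ee))
      in_body <- in_body & in_exon
    }
    u <- (pos - f$start + 0.5) / len            # body relative coordinate
    if (minus) u <- 1 - u
    bin <- rep(NA_integer_, length(pos))
    bin[in_body] <- flank_bins + rel_bin(u[in_body], body_bins)
    left <- pos < f$start     # left of feature in genome coordinates
    right <- pos > f$end
    ## genomic-left flank is upstream for + features, downstream for -
    lb <- rel_bin((pos - (f$start - flank) + 0.5) / flank, flank_bins)
    rb <- rel_bin((pos - f$end - 0.5) / flank, flank_bins)
    if (!minus) {
      bin[left] <- lb[left]
      bin[right] <- flank_bins + body_bins + rb[right]
    } else {
      bin[left] <- flank_bins + body_bins + (flank_bins + 1L - lb[left])
      bin[right] <- flank_bins + 1L - rb[right]
    }
    ok <- !is.na(bin)
    if (!any(ok)) next
    mc_mat[i, ] <- mc_mat[i, ] + tapply2(sub$mc_reads[ok], bin[ok], nb)
    tot_mat[i, ] <- tot_mat[i, ] + tapply2(sub$total_reads[ok], bin[ok], nb)
  }
  if (skipped) message(sprintf("metaplot: skipped %d features shorter than %d bp",
                               skipped, body_bins))
  fm <- mc_mat / ifelse(tot_mat > 0, tot_mat, NA)
  rownames(fm) <- features$feature_id
  wml <- if (per_feature) colMeans(fm, na.rm = TRUE) else {
    tot <- colSums(tot_mat)
    ifelse(tot > 0, colSums(mc_mat) / tot, NA_real_)
  }
  region <- rep(c("upstream", "body", "downstream"),
                c(flank_bins, body_bins, flank_bins))
  track <- data.frame(bin = seq_len(nb), region = region,
                      position = c(-rev(seq_len(flank_bins)) * fw + fw / 2,
                                   seq_len(body_bins) - 0.5,
                                   seq_len(flank_bins) * fw - fw / 2),
                      wml = wml, stringsAsFactors = FALSE)
  res <- list(track = track, feature_matrix = fm, n_features = nrow(features),
              flank = flank, flank_bins = flank_bins, body_bins = body_bins)
  class(res) <- "metaplot"
  res
}

## sum values into 1..n bins
tapply2 <- function(v, bin, n) {
  out <- numeric(n)
  s <- tapply(v, factor(bin, levels = seq_len(n)), sum)
  out[!is.na(s)] <- s[!is.na(s)]
  out
}

#' @export
print.metaplot <- function(x, ...) {
  cat(sprintf("metaplot over %d features: mean body wML %.3f, upstream %.3f\n",
              x$n_features,
              mean(x$track$wml[x$track$region == "body"], na.rm = TRUE),
              mean(x$track$wml[x$track$region == "upstream"], na.rm = TRUE)))
  invisible(x)
}

#' Compare two metaplots bin by bin
#'
#' Per-bin difference of the pooled tracks (A - B) and a Welch two-sample
#' t-test on the per-feature bin values, plus a summary statistic over the
#' upstream window from -`upstream_window` bp to the TSS (the region where
#' biased-gene methylation differences concentrate).
#'
#' @param mp_a,mp_b [metaplot()] results with identical binning.
#' @param upstream_window bp upstream of the TSS summarized (default 1500).
#' @return list `per_bin` (data.frame `bin`, `region`, `diff`, `p`),
#'   `upstream_mean_diff`.
#' @export
compare_bias_sets <- function(mp_a, mp_b, upstream_window = 1500L) {
  if (!identical(dim(mp_a$feature_matrix)[2], dim(mp_b$feature_matrix)[2]) ||
      mp_a$flank_bins != mp_b$flank_bins || mp_a$body_bins != mp_b$body_bins)
    stopf("metaplots have mismatched binning schemes")
  tr_a <- mp_a$track; tr_b <- mp_b$track
  d <- tr_a$wml - tr_b$wml
  p <- vapply(seq_len(nrow(tr_a)), function(b) {
    va <- mp_a$feature_matrix[, b]; vb <- mp_b$feature_matrix[, b]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (length(va) < 2 || length(vb) < 2) return(NA_real_)
    if (sd(va) == 0 && sd(vb) == 0)
      return(if (isTRUE(all.equal(mean(va), mean(vb)))) 1 else 0)
    stats::t.test(va, vb)$p.value
  }, numeric(1))
  up <- tr_a$region == "upstream" & tr_a$position >= -upstream_window
  list(per_bin = data.frame(bin = tr_a$bin, region = tr_a$region, diff = d,
                            p = p, stringsAsFactors = FALSE),
       upstream_mean_diff = mean(d[up], na.rm = TRUE))
}

#' Genes with an intersecting TE within a distance
#'
#' Feature filter used for TE-proximity methylation comparisons.
#'
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end`.
#' @param tes data.frame `chrom`, `start`, `end`.
#' @param dist maximum gap in bp (default 1000).
#' @return logical vector along `genes`.
#' @export
genes_near_te <- function(genes, tes, dist = 1000L) {
  out <- logical(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    tt <- tes[tes$chrom == ch, , drop = FALSE]
    if (!nrow(tt)) next
    gr <- IRanges::IRanges(pmax(1L, genes$start[gi] - dist), genes$end[gi] + dist)
    out[gi] <- IRanges::overlapsAny(gr, IRanges::IRanges(tt$start, tt$end))
  }
  out
}
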