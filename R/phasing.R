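#' Count canonical k-mers per chromosome
#'
#' Counts every k-mer occurrence in each sequence; in canonical mode a k-mer
#' and its reverse complement are merged under their lexicographic minimum
#' (odd k makes the canonical form unique; palindromes are their own canonical
#' form and counted once per occurrence). Windows containing N are skipped.
#'
#' @param sequences a named [Biostrings::DNAStringSet] or named character
#'   vector of chromosome sequences.
#' @param k k-mer size; odd, >= 3 (default 15, the standard phasing choice).
#' @param canonical merge reverse complements (default TRUE).
#' @return object of class `kmer_matrix`: a list with `counts` (data.table
#'   `kmer`/`chrom`/`count`), `lengths` (named bp per chromosome) and `k`.
#' @export
count_kmers <- function(sequences, k = 15L, canonical = TRUE) {
  if (length(sequences) == 0L) stopf("'sequences' is empty")
  if (k < 3L || k %% 2L == 0L) stopf("'k' must be odd and >= 3")
  if (inherits(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  if (is.null(names(sequences))) stopf("'sequences' must be named")
  counts <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    s <- toupper(sequences[[i]])
    bad <- regexpr("[^ACGTN]", s)
    if (bad > 0L)
      stopf("non-ACGTN character '%s' in sequence '%s' at position %d",
            substr(s, bad, bad), names(sequences)[i], bad)
    n <- nchar(s)
    if (n < k) { counts[[i]] <- data.table::data.table(kmer = character(),
                                                       count = integer()); next }
    nw <- n - k + 1L
    fwd <- substring(s, seq_len(nw), seq_len(nw) + k - 1L)
    if (canonical) {
      rc <- chartr("ACGTN", "TGCAN",
                   paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
      ## window j of the reverse complement is the revcomp of forward window
      ## nw - j + 1, so reversing aligns the two.
      rev_al <- rev(substring(rc, seq_len(nw), seq_len(nw) + k - 1L))
      fwd <- pmin(fwd, rev_al)
    }
    fwd <- fwd[!grepl("N", fwd, fixed = TRUE)]
    dt <- data.table::data.table(kmer = fwd)
    counts[[i]] <- dt[, list(count = .N), by = "kmer"]
    counts[[i]][, "chrom" := names(sequences)[i]]
  }
  tab <- data.table::rbindlist(counts)
  lens <- stats::setNames(nchar(sequences), names(sequences))
  structure(list(counts = tab, lengths = lens, k = as.integer(k),
                 canonical = canonical),
            class = "kmer_matrix")
}

#' @export
print.kmer_matrix <- function(x, ...) {
  cat(sprintf("kmer_matrix: k=%d, %d chromosomes, %d distinct k-mers\n",
              x$k, length(x$lengths),
              data.table::uniqueN(x$counts, by = "kmer")))
  invisible(x)
}

#' Homoeologous pair table
#'
#' @param chrom_a,chrom_b character vectors naming the two members of each
#'   homoeologous chromosome pair (unordered until phasing).
#' @return data.frame of class `homoeolog_map`.
#' @export
homoeolog_map <- function(chrom_a, chrom_b) {
  if (length(chrom_a) != length(chrom_b)) stopf("member vectors differ in length")
  all_chr <- c(chrom_a, chrom_b)
  if (anyDuplicated(all_chr)) stopf("a chromosome appears in more than one pair")
  structure(data.frame(pair = seq_along(chrom_a), chrom_a = chrom_a,
                       chrom_b = chrom_b, stringsAsFactors = FALSE),
            class = c("homoeolog_map", "data.frame"))
}

## length-normalized counts (copies per Mb) as a chromosomes x kmers matrix
kmer_norm_matrix <- function(km, kmers = NULL) {
  tab <- km$counts
  if (!is.null(kmers)) tab <- tab[tab$kmer %in% kmers, ]
  wide <- data.table::dcast(tab, chrom ~ kmer, value.var = "count", fill = 0L)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$chrom
  ## chromosomes with no retained k-mer still need a row
  missing <- setdiff(names(km$lengths), rownames(m))
  if (length(missing)) {
    m <- rbind(m, matrix(0, length(missing), ncol(m),
                         dimnames = list(missing, colnames(m))))
  }
  m / (km$lengths[rownames(m)] / 1e6)
}

#' Select subgenome-differential k-mers
#'
#' Retains k-mers whose length-normalized count differs by at least
#' `min_fold` between the two members of at least `min_pairs` homoeologous
#' pairs and whose summed raw count is at least `min_count`. A zero
#' denominator counts as maximal fold change.
#'
#' @param km a [count_kmers()] result.
#' @param map a [homoeolog_map()] covering the counted chromosomes.
#' @param min_count minimum summed raw count across chromosomes (default 50).
#' @param min_fold minimum between-member fold change (> 1; default 2).
#' @param min_pairs number of pairs that must individually pass `min_fold`
#'   (default: all pairs).
#' @return a `kmer_matrix` restricted to the differential k-mers, with the
#'   normalized chromosomes-by-kmers matrix attached as `$matrix`.
#' @export
select_differential_kmers <- function(km, map, min_count = 50L, min_fold = 2,
                                      min_pairs = NULL) {
  stopifnot(inherits(km, "kmer_matrix"))
  if (min_fold <= 1) stopf("'min_fold' must be > 1")
  min_pairs <- min_pairs %||% nrow(map)
  tot <- km$counts[, list(total = sum(count)), by = "kmer"]
  keep0 <- tot$kmer[tot$total >= min_count]
  if (length(keep0) == 0L)
    stop(errorCondition("no differential k-mers: no k-mer reaches min_count",
                        class = c("no_differential_kmers", "error")))
  norm <- kmer_norm_matrix(km, keep0)
  a <- norm[map$chrom_a, , drop = FALSE]
  b <- norm[map$chrom_b, , drop = FALSE]
  hi <- pmax(a, b); lo <- pmin(a, b)
  fold <- ifelse(lo == 0, ifelse(hi > 0, Inf, 1), hi / lo)
  npass <- colSums(fold >= min_fold)
  keep <- colnames(norm)[npass >= min_pairs]
  if (length(keep) == 0L)
    stop(errorCondition(
      "no differential k-mers between homoeologs (possible autopolyploid or identical homoeologs)",
      class = c("no_differential_kmers", "error")))
  out <- km
  out$counts <- km$counts[km$counts$kmer %in% keep, ]
  out$matrix <- norm[, keep, drop = FALSE]
  out
}

#' Phase chromosomes into subgenomes from differential k-mers
#'
#' K-means (K = 2, 10 restarts, internally seeded) on log1p-transformed
#' length-normalized differential k-mer counts, followed by a per-pair
#' repair step enforcing the bipartite constraint: each homoeologous pair
#' contributes exactly one chromosome to each cluster, choosing the
#' orientation with the smaller summed distance to the centroids (ties broken
#' lexicographically by chromosome name and flagged low-confidence). PCA
#' coordinates and a silhouette-style confidence accompany each label.
#'
#' Which cluster is the maternal subgenome cannot be decided from k-mers
#' alone (it comes from external evidence such as the mitochondrial genome);
#' `maternal` names one chromosome known to be maternal. By default the
#' cluster containing the alphabetically first chromosome is labelled subM.
#'
#' @param diff a differential `kmer_matrix` from [select_differential_kmers()].
#' @param map a [homoeolog_map()].
#' @param maternal optional chromosome name anchoring the subM label.
#' @return object of class `subgenome_assignment`: data.frame (`chrom`,
#'   `subgenome`, `confidence`, `PC1`, `PC2`, `low_confidence`) with the
#'   per-cluster enriched k-mer lists in `attr(, "enriched_kmers")`.
#' @export
phase_subgenomes <- function(diff, map, maternal = NULL) {
  stopifnot(inherits(diff, "kmer_matrix"))
  m <- diff$matrix %||% kmer_norm_matrix(diff)
  if (ncol(m) < 1L) stopf("need at least one differential k-mer")
  if (nrow(m) < 2L) stopf("need at least two chromosomes")
  m <- m[order(rownames(m)), , drop = FALSE]  # input-order invariance
  x <- log1p(m)
  km <- with_seed(20151L, stats::kmeans(x, centers = 2L, nstart = 10L))
  cent <- km$centers
  d2 <- function(v, c_) sum((v - c_)^2)
  ## per-pair bipartite repair
  cl <- km$cluster
  low <- stats::setNames(rep(FALSE, nrow(x)), rownames(x))
  for (i in seq_len(nrow(map))) {
    ca <- map$chrom_a[i]; cb <- map$chrom_b[i]
    d_a1 <- d2(x[ca, ], cent[1, ]); d_a2 <- d2(x[ca, ], cent[2, ])
    d_b1 <- d2(x[cb, ], cent[1, ]); d_b2 <- d2(x[cb, ], cent[2, ])
    opt1 <- d_a1 + d_b2  # a->1, b->2
    opt2 <- d_a2 + d_b1
    if (isTRUE(all.equal(opt1, opt2))) {
      low[c(ca, cb)] <- TRUE
      first <- sort(c(ca, cb))[1]
      cl[first] <- 1L; cl[setdiff(c(ca, cb), first)] <- 2L
    } else if (opt1 < opt2) {
      cl[ca] <- 1L; cl[cb] <- 2L
    } else {
      cl[ca] <- 2L; cl[cb] <- 1L
    }
  }
  ## silhouette-style confidence from distances to the two centroids
  dmat <- cbind(apply(x, 1, d2, cent[1, ]), apply(x, 1, d2, cent[2, ]))
  own <- sqrt(dmat[cbind(seq_len(nrow(x)), cl)])
  oth <- sqrt(dmat[cbind(seq_len(nrow(x)), 3L - cl)])
  conf <- ifelse(pmax(own, oth) > 0, (oth - own) / pmax(own, oth), 0)
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  pcs <- pca$x[, seq_len(min(2L, ncol(pca$x))), drop = FALSE]
  if (ncol(pcs) < 2L) pcs <- cbind(pcs, PC2 = 0)
  ## external subM anchoring
  anchor <- maternal %||% sort(rownames(x))[1]
  if (!anchor %in% rownames(x)) stopf("'maternal' chromosome '%s' not found", anchor)
  m_cluster <- cl[[anchor]]
  label <- ifelse(cl == m_cluster, "subM", "subP")
  res <- data.frame(chrom = rownames(x), subgenome = unname(label),
                    confidence = unname(conf), PC1 = unname(pcs[, 1]),
                    PC2 = unname(pcs[, 2]), low_confidence = unname(low[rownames(x)]),
                    stringsAsFactors = FALSE)
  ## subgenome-enriched k-mers: higher mean normalized count in that cluster
  mu_M <- colMeans(m[label == "subM", , drop = FALSE])
  mu_P <- colMeans(m[label == "subP", , drop = FALSE])
  attr(res, "enriched_kmers") <- list(subM = colnames(m)[mu_M > mu_P],
                                      subP = colnames(m)[mu_P > mu_M])
  class(res) <- c("subgenome_assignment", "data.frame")
  res
}
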