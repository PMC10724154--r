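# Independent oracles used by the equivalence tests. Each re-derives the
# quantity by a route disjoint from the package implementation.

## Unit-cost Levenshtein DP, column-vectorized (cummin trick); N mismatches
## everything, including N.
lev_oracle <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  if (n == 0L) return(m)
  prev <- 0:n
  idx <- 0:n
  for (j in seq_len(m)) {
    cost <- as.integer(A != B[j] | A == "N" | B[j] == "N")
    t_ <- pmin(prev[2:(n + 1)] + 1L, prev[1:n] + cost)
    u <- c(j, t_)
    prev <- idx + cummin(u - idx)
  }
  prev[n + 1]
}

rc_oracle <- function(s)
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))

ned_oracle <- function(ref, obs)
  min(lev_oracle(ref, obs), lev_oracle(rc_oracle(ref), obs)) /
    max(nchar(ref), nchar(obs))

## Canonical k-mer counting by explicit dictionary scan.
kmer_scan_oracle <- function(s, k) {
  env <- new.env(hash = TRUE)
  for (i in seq_len(nchar(s) - k + 1L)) {
    km <- substr(s, i, i + k - 1L)
    if (grepl("N", km, fixed = TRUE)) next
    rc <- rc_oracle(km)
    can <- if (km <= rc) km else rc
    env[[can]] <- (if (is.null(env[[can]])) 0L else env[[can]]) + 1L
  }
  keys <- ls(env)
  stats::setNames(vapply(keys, function(k2) env[[k2]], integer(1)), keys)
}

## Tandem arrays as connected components of the full pairwise link relation
## (rank gap <= max_gap, same chromosome and family), via union-find.
tandem_oracle <- function(genes, max_gap) {
  g <- genes[!is.na(genes$family), , drop = FALSE]
  n <- nrow(g)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (g$chrom[i] == g$chrom[j] && g$family[i] == g$family[j] &&
        abs(g$rank[i] - g$rank[j]) <= max_gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(g$gene_id, roots)
  comp <- comp[lengths(comp) >= 2L]
  ## canonical form: sorted members of sorted components
  unname(lapply(comp[order(vapply(comp, min, ""))], sort))
}

## Conserved TADs by brute-force all-pairs overlap counting.
conserved_tads_oracle <- function(tads_a, tads_b, genes_a, genes_b, pairs_ab,
                                  min_frac = 0.7, min_genes = 5L) {
  in_tad <- function(g, t)
    g$chrom == t$chrom & g$pos >= t$start & g$pos <= t$end
  partner <- stats::setNames(pairs_ab[[2]], pairs_ab[[1]])
  out <- logical(nrow(tads_a))
  for (i in seq_len(nrow(tads_a))) {
    mem <- genes_a$gene[in_tad(genes_a, tads_a[i, ])]
    coll <- mem[mem %in% names(partner)]
    if (length(coll) < 1) { out[i] <- FALSE; next }
    best <- 0L
    for (j in seq_len(nrow(tads_b))) {
      pmem <- genes_b$gene[in_tad(genes_b, tads_b[j, ])]
      best <- max(best, sum(partner[coll] %in% pmem))
    }
    out[i] <- (best / length(coll)) > min_frac && length(coll) >= min_genes
  }
  out
}

## Expected mean normalized edit distance for sequences mutated by point
## substitution at a per-site rate, estimated by direct simulation through
## the DP oracle (independent of the package's distance code).
expected_ned_oracle <- function(rate, lens, nsim = 400) {
  bases <- c("A", "C", "G", "T")
  mean(vapply(seq_len(nsim), function(i) {
    L <- sample(lens, 1L)
    ref <- sample(bases, L, replace = TRUE)
    obs <- ref
    k <- rbinom(1L, L, rate)
    if (k > 0) {
      posn <- sample.int(L, k)
      shift <- sample.int(3L, k, replace = TRUE)
      idx <- match(obs[posn], bases)
      obs[posn] <- bases[((idx - 1L + shift) %% 4L) + 1L]
    }
    ned_oracle(paste(ref, collapse = ""), paste(obs, collapse = ""))
  }, numeric(1)))
}

## Per-bp occupancy scan for TE density.
te_density_oracle <- function(tes, lo, hi) {
  if (lo > hi) return(NA_real_)
  occ <- logical(hi - lo + 1L)
  for (i in seq_len(nrow(tes))) {
    s <- max(tes$start[i], lo); e <- min(tes$end[i], hi)
    if (s <= e) occ[(s - lo + 1L):(e - lo + 1L)] <- TRUE
  }
  mean(occ)
}
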