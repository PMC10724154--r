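#' Sliding-window gene retention per subgenome
#'
#' For each window of `w` consecutive reference genes (step `step`), the
#' fraction still retained in each subgenome. Terminal windows shorter than
#' `w` are dropped; chromosomes with fewer than `w` genes are skipped with a
#' message.
#'
#' @param syntelogs data.frame with `ref_chrom`, `ref_rank` (strictly
#'   increasing within chromosome) and `gene_P` / `gene_M` columns (NA =
#'   fractionated).
#' @param w window size in genes (default 100, the standard profile width).
#' @param step window step in genes (default 1).
#' @return data.frame of class `retention_profile`: `ref_chrom`,
#'   `start_rank`, `retention_P`, `retention_M`.
#' @export
window_retention <- function(syntelogs, w = 100L, step = 1L) {
  if (w < 1L || step < 1L) stopf("'w' and 'step' must be >= 1")
  out <- list()
  for (ch in unique(syntelogs$ref_chrom)) {
    s <- syntelogs[syntelogs$ref_chrom == ch, , drop = FALSE]
    s <- s[order(s$ref_rank), , drop = FALSE]
    if (any(duplicated(s$ref_rank))) stopf("duplicated ref_rank on %s", ch)
    n <- nrow(s)
    if (n < w) { message(sprintf("window_retention: skipping %s (%d < w)", ch, n)); next }
    hasP <- cumsum(c(0L, !is.na(s$gene_P)))
    hasM <- cumsum(c(0L, !is.na(s$gene_M)))
    starts <- seq(1L, n - w + 1L, by = step)
    out[[ch]] <- data.frame(
      ref_chrom = ch, start_rank = s$ref_rank[starts],
      retention_P = (hasP[starts + w] - hasP[starts]) / w,
      retention_M = (hasM[starts + w] - hasM[starts]) / w,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stopf("no chromosome has >= w genes")
  res <- do.call(rbind, out); rownames(res) <- NULL
  class(res) <- c("retention_profile", "data.frame")
  res
}

#' Chi-square test of departure from a 1:1 count balance
#'
#' Goodness-of-fit of two observed counts against equal expectation, one
#' degree of freedom, no continuity correction:
#' `X2 = (n1 - n2)^2 / (n1 + n2)`.
#'
#' @param n1,n2 non-negative counts.
#' @return list with `chisq`, `df` (1) and `p`.
#' @export
balance_chisq <- function(n1, n2) {
  if (n1 < 0 || n2 < 0) stopf("counts must be non-negative")
  if (n1 + n2 <= 0) stopf("need n1 + n2 > 0")
  x2 <- (n1 - n2)^2 / (n1 + n2)
  list(chisq = x2, df = 1L, p = pchisq(x2, df = 1, lower.tail = FALSE))
}

#' Detect tandem gene arrays
#'
#' Two genes of the same family on the same chromosome are linked when their
#' rank difference is at most `max_gap`; arrays are the connected components
#' of this link relation with at least two members (so chains 1-11-21 at gap
#' 10 form a single array).
#'
#' @param genes data.frame with `gene_id`, `chrom`, `rank` (unique within
#'   chromosome) and `family` (NA = unassigned, ignored with a message).
#' @param max_gap maximum rank gap linking two members (default 10, the
#'   standard tandem-duplication setting).
#' @return object of class `tandem_array_set`: list with `arrays` (data.frame
#'   `array_id`, `chrom`, `family`, `gene_id`, `rank`) and `summary`
#'   (`n_tandem_genes`, `n_arrays`, `n_large_arrays` with large = > 5 genes).
#' @export
detect_tandem_arrays <- function(genes, max_gap = 10L) {
  need <- c("gene_id", "chrom", "rank", "family")
  if (!all(need %in% names(genes))) stopf("'genes' needs columns %s", paste(need, collapse = ", "))
  nofam <- is.na(genes$family)
  if (any(nofam))
    message(sprintf("detect_tandem_arrays: %d genes without family ignored", sum(nofam)))
  g <- genes[!nofam, , drop = FALSE]
  arrays <- list(); aid <- 0L
  for (key in split(seq_len(nrow(g)), paste(g$chrom, g$family, sep = "\r"))) {
    s <- g[key, , drop = FALSE]
    if (anyDuplicated(s$rank)) stopf("ranks not unique on chromosome %s", s$chrom[1])
    s <- s[order(s$rank), , drop = FALSE]
    if (nrow(s) < 2L) next
    brk <- c(0L, cumsum(diff(s$rank) > max_gap))
    for (comp in split(seq_len(nrow(s)), brk)) {
      if (length(comp) < 2L) next
      aid <- aid + 1L
      arrays[[aid]] <- data.frame(array_id = aid, chrom = s$chrom[comp],
                                  family = s$family[comp],
                                  gene_id = s$gene_id[comp], rank = s$rank[comp],
                                  stringsAsFactors = FALSE)
    }
  }
  arr <- if (length(arrays)) do.call(rbind, arrays) else
    data.frame(array_id = integer(), chrom = character(), family = character(),
               gene_id = character(), rank = integer())
  sizes <- if (nrow(arr)) table(arr$array_id) else integer(0)
  res <- list(arrays = arr,
              summary = data.frame(n_tandem_genes = nrow(arr),
                                   n_arrays = length(sizes),
                                   n_large_arrays = sum(sizes > 5)))
  class(res) <- "tandem_array_set"
  res
}

#' @export
print.tandem_array_set <- function(x, ...) {
  cat(sprintf("tandem arrays: %d genes in %d arrays (%d with > 5 genes)\n",
              x$summary$n_tandem_genes, x$summary$n_arrays, x$summary$n_large_arrays))
  invisible(x)
}

#' Per-subgenome tandem summary
#'
#' Runs [detect_tandem_arrays()] separately on each subgenome's genes.
#'
#' @param genes as in [detect_tandem_arrays()] plus a `subgenome` column.
#' @param max_gap see [detect_tandem_arrays()].
#' @return data.frame with one row per subgenome and the three summary counts.
#' @export
tandem_by_subgenome <- function(genes, max_gap = 10L) {
  out <- lapply(split(genes, genes$subgenome), function(s) {
    suppressMessages(detect_tandem_arrays(s, max_gap))$summary
  })
  res <- do.call(rbind, out)
  res$subgenome <- names(out)
  res[, c("subgenome", "n_tandem_genes", "n_arrays", "n_large_arrays")]
}

#' Classify orthogroups into pangenome categories
#'
#' Core = present in all species of the panel, softcore = missing from at
#' most `softcore_miss` species, private = present in exactly one,
#' dispensable = everything in between. For a 36-species panel the default
#' boundaries are 36 / 32-35 / 2-31 / 1. An allopolyploid species counts as
#' carrying an orthogroup if either of its subgenomes does; collapse such
#' columns first with [collapse_polyploid_presence()].
#'
#' @param presence logical matrix, orthogroups x species.
#' @param softcore_miss how many species a softcore orthogroup may lack
#'   (default 4).
#' @return data.frame of class `pangenome_classes`: `orthogroup`,
#'   `n_species`, `class`; summary via [summary()].
#' @export
classify_pangenome <- function(presence, softcore_miss = 4L) {
  if (!is.matrix(presence)) presence <- as.matrix(presence)
  mode(presence) <- "logical"
  n_sp <- ncol(presence)
  cnt <- rowSums(presence)
  if (any(cnt == 0)) stopf("orthogroup present in no species (malformed input)")
  cls <- ifelse(cnt == n_sp, "core",
         ifelse(cnt >= n_sp - softcore_miss, "softcore",
         ifelse(cnt >= 2, "dispensable", "private")))
  res <- data.frame(orthogroup = rownames(presence) %||% seq_len(nrow(presence)),
                    n_species = cnt, class = cls, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("pangenome_classes", "data.frame")
  res
}

#' @export
summary.pangenome_classes <- function(object, ...) {
  lev <- c("core", "softcore", "dispensable", "private")
  n <- table(factor(object$class, levels = lev))
  data.frame(class = lev, n = as.vector(n),
             fraction = as.vector(n) / nrow(object),
             percent = round(100 * as.vector(n) / nrow(object), 1))
}

#' Collapse polyploid subgenome columns of a presence matrix
#'
#' @param presence logical matrix, orthogroups x columns.
#' @param groups named list: each element gives the column names to merge by
#'   logical OR into one species column named after the element.
#' @return presence matrix with merged columns.
#' @export
collapse_polyploid_presence <- function(presence, groups) {
  keep <- setdiff(colnames(presence), unlist(groups))
  merged <- vapply(groups, function(cols)
    rowSums(presence[, cols, drop = FALSE]) > 0, logical(nrow(presence)))
  cbind(presence[, keep, drop = FALSE], merged)
}
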