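## Levenshtein distance with N treated as matching nothing (not even N):
## encode N differently on the two sides before handing off to adist.
edit_distance <- function(a, b) {
  a <- chartr("N", "!", a)
  b <- chartr("N", "?", b)
  drop(adist(a, b))
}

#' Normalized edit distance between a reference CNS and a lifted sequence
#'
#' `d = min(ED(ref, obs), ED(revcomp(ref), obs)) / max(len(ref), len(obs))`
#' where ED is unit-cost Levenshtein distance. Taking the minimum over the
#' reverse complement makes the metric strand-agnostic; dividing by the longer
#' sequence bounds it to [0, 1]. N bases mismatch everything.
#'
#' @param ref,obs non-empty DNA strings over A/C/G/T/N.
#' @return normalized distance in [0, 1].
#' @export
normalized_edit_distance <- function(ref, obs) {
  if (!nzchar(ref) || !nzchar(obs)) stopf("sequences must be non-empty")
  ed <- min(edit_distance(ref, obs), edit_distance(revcomp_str(ref), obs))
  ed / max(nchar(ref), nchar(obs))
}

#' Mean CNS divergence of one subgenome
#'
#' Unweighted mean normalized edit distance over records, after applying the
#' 8-100 nt reference-length filter and dropping records without a lifted
#' copy in the requested subgenome. Per-chromosome means are retained for
#' the departure error estimate.
#'
#' @param records data.frame with `id`, `chrom`, `ref_seq` and the lifted
#'   sequence column `subP_seq` / `subM_seq` (NA or "" = not lifted).
#' @param subgenome "subP" or "subM".
#' @param len_range length filter bounds (default `c(8, 100)`).
#' @return list `mean` (genome-wide mean d), `per_chrom` (data.frame `chrom`,
#'   `mean_d`, `n`), `n_used`, `n_filtered`, `n_unlifted`, `d` (per-record).
#' @export
subgenome_divergence <- function(records, subgenome = c("subP", "subM"),
                                 len_range = c(8L, 100L)) {
  subgenome <- match.arg(subgenome)
  col <- paste0(sub("sub", "sub", subgenome), "_seq")
  lens <- nchar(records$ref_seq)
  pass <- lens >= len_range[1] & lens <= len_range[2]
  lifted <- !is.na(records[[col]]) & nzchar(records[[col]])
  use <- pass & lifted
  if (!any(use)) stopf("no usable records for %s after filtering", subgenome)
  d <- mapply(normalized_edit_distance, records$ref_seq[use], records[[col]][use],
              USE.NAMES = FALSE)
  per <- stats::aggregate(d, by = list(chrom = records$chrom[use]),
                          FUN = function(v) c(mean(v), length(v)))
  per_chrom <- data.frame(chrom = per$chrom, mean_d = per$x[, 1], n = per$x[, 2],
                          stringsAsFactors = FALSE)
  list(mean = mean(d), per_chrom = per_chrom, n_used = sum(use),
       n_filtered = sum(!pass), n_unlifted = sum(pass & !lifted),
       d = data.frame(id = records$id[use], chrom = records$chrom[use], d = d,
                      stringsAsFactors = FALSE))
}

#' Fit the global CNS-vs-neutral divergence model
#'
#' Ordinary least squares of mean CNS divergence on mean neutral divergence
#' across subgenome points; the line models how fast CNSs drift as a function
#' of neutral distance from the reference, so departures from it measure
#' relative constraint.
#'
#' @param points data.frame with columns `x` (mean neutral normalized edit
#'   distance) and `y` (mean CNS normalized edit distance), one row per
#'   subgenome (>= 3).
#' @return object of class `constraint_model`: list `intercept`, `slope`,
#'   `r` (fit correlation), `fit` (the lm object).
#' @export
fit_constraint_model <- function(points) {
  if (nrow(points) < 3L) stopf("need >= 3 subgenome points to fit the model")
  if (sd(points$x) == 0) stopf("degenerate fit: identical x for all points")
  fit <- stats::lm(y ~ x, data = points)
  ## r is undefined (not 0) when y does not vary
  r <- if (sd(points$y) == 0) NA_real_ else cor(points$x, points$y)
  res <- list(intercept = unname(stats::coef(fit)[1]),
              slope = unname(stats::coef(fit)[2]),
              r = r, fit = fit)
  class(res) <- "constraint_model"
  res
}

#' @export
print.constraint_model <- function(x, ...) {
  cat(sprintf("constraint model: y = %.4f + %.4f x (r = %.3f)\n",
              x$intercept, x$slope, x$r))
  invisible(x)
}

#' Constraint departure of a subgenome from the model line
#'
#' Signed perpendicular distance of the subgenome point from the fitted
#' line, `(y - a - b x) / sqrt(1 + b^2)`; negative = below the line = more
#' constrained than the global expectation. The 1-SD error bar is the
#' standard deviation of the per-chromosome points' projections onto the
#' line's unit normal (dispersion of chromosome-level estimates). An
#' alternative error propagating the x and y dispersions through the normal,
#' `sqrt(b^2 sd_x^2 + sd_y^2) / sqrt(1 + b^2)`, is available via
#' `error_method = "propagate"`.
#'
#' @param point list or data.frame row with `x` and `y` for the subgenome.
#' @param model a [fit_constraint_model()] result.
#' @param per_chrom_points optional data.frame of per-chromosome `x`, `y`
#'   points for the same subgenome (>= 2 rows for an error estimate).
#' @param error_method "projection" (default) or "propagate".
#' @return list of class `departure_point`: `x`, `y`, `departure`, `error`
#'   (NA with a warning when < 2 chromosome points).
#' @export
constraint_departure <- function(point, model, per_chrom_points = NULL,
                                 error_method = c("projection", "propagate")) {
  stopifnot(inherits(model, "constraint_model"))
  error_method <- match.arg(error_method)
  a <- model$intercept; b <- model$slope
  dep <- (point$y - a - b * point$x) / sqrt(1 + b^2)
  err <- NA_real_
  if (!is.null(per_chrom_points) && nrow(per_chrom_points) >= 2L) {
    if (error_method == "projection") {
      proj <- (per_chrom_points$y - a - b * per_chrom_points$x) / sqrt(1 + b^2)
      err <- sd(proj)
    } else {
      err <- sqrt(b^2 * stats::var(per_chrom_points$x) +
                    stats::var(per_chrom_points$y)) / sqrt(1 + b^2)
    }
  } else {
    warning("fewer than 2 chromosome points; departure returned without error estimate")
  }
  res <- list(x = point$x, y = point$y, departure = dep, error = err)
  class(res) <- "departure_point"
  res
}

#' @export
print.departure_point <- function(x, ...) {
  cat(sprintf("constraint departure: %+.5f (1 SD %s)\n", x$departure,
              ifelse(is.na(x$error), "n/a", sprintf("%.5f", x$error))))
  invisible(x)
}

#' End-to-end CNS constraint analysis of a simulated (or real) record set
#'
#' Computes per-subgenome CNS and neutral mean divergences, fits the global
#' model over the pooled subgenome points, and returns each subgenome's
#' departure.
#'
#' @param cns,neutral record data.frames as in [subgenome_divergence()].
#' @param extra_points optional additional (x, y) points from other genomes
#'   to stabilize the fit (the model needs >= 3 points).
#' @return list `points`, `model`, `departures` (named by subgenome).
#' @export
cns_constraint_analysis <- function(cns, neutral, extra_points = NULL) {
  sgs <- c("subP", "subM")
  pts <- lapply(sgs, function(sg) {
    dc <- subgenome_divergence(cns, sg)
    dn <- subgenome_divergence(neutral, sg)
    per <- merge(dn$per_chrom[, c("chrom", "mean_d")],
                 dc$per_chrom[, c("chrom", "mean_d")], by = "chrom",
                 suffixes = c("_neut", "_cns"))
    list(x = dn$mean, y = dc$mean,
         per_chrom = data.frame(x = per$mean_d_neut, y = per$mean_d_cns))
  })
  names(pts) <- sgs
  points <- data.frame(x = vapply(pts, `[[`, 0, "x"),
                       y = vapply(pts, `[[`, 0, "y"))
  allp <- rbind(points, extra_points)
  model <- fit_constraint_model(allp)
  deps <- lapply(sgs, function(sg)
    constraint_departure(list(x = pts[[sg]]$x, y = pts[[sg]]$y), model,
                         pts[[sg]]$per_chrom))
  names(deps) <- sgs
  list(points = points, model = model, departures = deps)
}
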