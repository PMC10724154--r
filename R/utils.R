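# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

.datatable.aware <- TRUE

#' @importFrom stats rnorm runif rbinom rpois pchisq sd cor prcomp kmeans
#' @importFrom utils adist head tail
NULL

## Deterministic per-stream seeds: one RNG stream per output type, all derived
## from the master seed so adding an output type never perturbs the others.
## Kept below 2^31 - 1 (R integers are 32-bit).
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream))) %% 100003L
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

## Evaluate expr under a local RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna_vec <- function(n) {
  sample(DNA_BASES, n, replace = TRUE)
}

## Point-mutate a character vector of bases at a given per-site rate.
## Substituted bases are always different from the original.
mutate_bases <- function(x, rate) {
  if (rate <= 0) return(x)
  n <- length(x)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(x)
  pos <- sample.int(n, k)
  shift <- sample.int(3L, k, replace = TRUE)
  idx <- match(x[pos], DNA_BASES)
  x[pos] <- DNA_BASES[((idx - 1L + shift) %% 4L) + 1L]
  x
}

revcomp_str <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1))
    stopf("'%s' must lie in [0, 1]", name)
  invisible(x)
}
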