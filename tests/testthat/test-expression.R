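test_that("TPM aggregation averages replicates per tissue", {
  m <- matrix(c(2, 4, 6, 1, 1, 4), 1,
              dimnames = list("g1", c("brain.1", "brain.2", "brain.3", "liver.1",
                                      "liver.2", "liver.3")))
  agg <- aggregate_tpm(m)
  expect_equal(agg["g1", "brain"], 4)
  expect_equal(agg["g1", "liver"], 2)
  ## single replicate passes through
  m1 <- matrix(5, 1, dimnames = list("g", "eye.1"))
  expect_equal(unname(aggregate_tpm(m1)[1, 1]), 5)
  ## random matrix equals an independent recompute
  set.seed(2)
  mm <- matrix(rexp(1000 * 6), 1000,
               dimnames = list(sprintf("g%04d", 1:1000),
                               paste0(rep(c("a", "b"), each = 3), ".", 1:3)))
  agg2 <- aggregate_tpm(mm)
  expect_equal(unname(agg2[, "a"]), unname(apply(mm[, 1:3], 1, mean)))
  expect_error(aggregate_tpm(mm * -1), ">= 0")
})

test_that("HEB labels follow the fold-change threshold with pseudocount", {
  means <- matrix(c(1, 8, 1, 4,      # t1: p1 = 1 vs 8, p2 = 1 vs 4
                    1, 1, 3, 3), 4, 2,
                  dimnames = list(c("p1_P", "p1_M", "p2_P", "p2_M"),
                                  c("t1", "t2")))
  pairs <- data.frame(gene_P = c("p1_P", "p2_P"), gene_M = c("p1_M", "p2_M"))
  r <- call_heb(pairs, means, eps = 0.5)
  c1 <- r$calls[r$calls$gene_P == "p1_P" & r$calls$tissue == "t1", ]
  expect_equal(c1$log2fc, log2(8.5 / 1.5))   # 2.503 -> M-biased
  expect_equal(c1$label, "M-biased")
  ## 4 vs 1: log2(4.5/1.5) = 1.58 < 2 -> unbiased
  c2 <- r$calls[r$calls$gene_P == "p2_P" & r$calls$tissue == "t1", ]
  expect_equal(c2$label, "unbiased")
  ## equal expression is unbiased; below min_expr is not-expressed
  means2 <- matrix(c(3, 3, 0.4, 0.4), 2, 2,   # t1 expressed, t2 below min_expr
                   dimnames = list(c("q_P", "q_M"), c("t1", "t2")))
  r2 <- call_heb(data.frame(gene_P = "q_P", gene_M = "q_M"), means2)
  expect_equal(r2$calls$label, c("unbiased", "not-expressed"))
  ## label conservation: all evaluated pair-tissues are accounted for
  cnt <- r$counts
  expect_equal(cnt$n_M_biased + cnt$n_P_biased + cnt$n_unbiased +
                 cnt$n_not_expressed, rep(nrow(pairs), 2))
  ## incomplete pairs are excluded, not mislabelled
  r3 <- call_heb(data.frame(gene_P = c("p1_P", NA), gene_M = c("p1_M", "p2_M")),
                 means)
  expect_equal(nrow(r3$calls), 2L)
})

test_that("ancestor correlation matches the textbook formula", {
  x <- c(2, 4, 8, 16, 32, 64)
  expect_equal(correlation_with_ancestor(x, x)$r, 1)
  ## affine-negative profile on the log scale gives r = -1
  y <- 2^(10 - log2(x + 1)) - 1
  expect_equal(correlation_with_ancestor(x, y)$r, -1)
  set.seed(4)
  a <- rexp(6, 0.1); b <- rexp(6, 0.1)
  got <- correlation_with_ancestor(a, b)
  la <- log2(a + 1); lb <- log2(b + 1)
  r_manual <- sum((la - mean(la)) * (lb - mean(lb))) /
    sqrt(sum((la - mean(la))^2) * sum((lb - mean(lb))^2))
  expect_equal(got$r, r_manual)
  expect_equal(got$p, stats::cor.test(la, lb)$p.value)
  ## constant profiles are flagged, not silently correlated
  expect_equal(correlation_with_ancestor(rep(2, 6), a)$flag, "zero-variance")
})

test_that("the fate decision table triggers in its documented order", {
  O <- c(4, 4, 4, 4)
  ## rule 2: one copy silent everywhere
  f <- classify_fate(O, X = c(0.1, 0.2, 0.1, 0.1), Y = O)
  expect_equal(f$category, "nonfunctionalized")
  expect_equal(f$evidence$silenced, "X")
  ## rule 3: reciprocal on/off across tissues with ancestor expressed
  f2 <- classify_fate(O, X = c(8, 8, 0.1, 0.1), Y = c(0.1, 0.1, 8, 8))
  expect_equal(f2$category, "subfunctionalized")
  ## rule 4: expression gained where ancestor and partner are silent
  f3 <- classify_fate(c(0.1, 4, 4, 4), X = c(5, 4, 4, 4), Y = c(0.1, 4, 4, 4))
  expect_equal(f3$category, "neofunctionalized")
  expect_equal(f3$evidence$neo_copy, "X")
  ## rule 5: both copies track the ancestor
  O2 <- c(2, 8, 32, 128)
  f4 <- classify_fate(O2, O2 * 1.1, O2 * 0.9)
  expect_equal(f4$category, "dosage")
  ## rule 1: silence everywhere drops the trio
  f5 <- classify_fate(rep(0.1, 4), rep(0.2, 4), rep(0.1, 4))
  expect_equal(f5$category, "not-expressed")
})

test_that("swapping the two copies permutes but never invents categories", {
  set.seed(9)
  for (i in 1:25) {
    O <- rexp(5, 0.2); X <- rexp(5, 0.2); Y <- rexp(5, 0.2)
    a <- classify_fate(O, X, Y)
    b <- classify_fate(O, Y, X)
    expect_equal(a$category, b$category)
  }
})

test_that("planted fates and bias are recovered exactly without noise", {
  fx <- noiseless_expr()
  means <- aggregate_tpm(fx$expr)
  calls <- classify_fates(fx$expr$trios, means)
  tru <- fx$expr$truth[fx$expr$truth$complete, ]
  m <- merge(calls, tru[, c("ref_gene", "fate")], by = "ref_gene")
  expect_equal(m$category, m$fate)
  ## planted maternal bias excess shows up in the HEB balance test
  heb <- call_heb(fx$expr$trios, means)
  expect_gt(heb$total$n_M_biased, heb$total$n_P_biased)
  expect_lt(heb$total$p, 0.01)
})
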