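mk_calls <- function(pos, mc, tot, context = "CG", chrom = "c", strand = "+") {
  data.frame(chrom = chrom, pos = pos, strand = strand, context = context,
             mc_reads = mc, total_reads = tot, stringsAsFactors = FALSE)
}

test_that("weighted methylation pools reads, not sites", {
  calls <- mk_calls(c(10, 20), c(3, 7), c(10, 10))
  expect_equal(weighted_methylation(calls, "c", 1, 15), 0.3)
  expect_equal(weighted_methylation(calls, "c", 1, 100), 0.5)  # 10/20
  ## empty regions are missing, never zero
  expect_true(is.na(weighted_methylation(calls, "c", 200, 300)))
  ## additivity: splitting a region and pooling reads gives the same level
  set.seed(5)
  big <- mk_calls(sample.int(1000, 50), rbinom(50, 20, 0.6), 20)
  whole <- weighted_methylation(big, "c", 1, 1000)
  halves <- c(sum(big$mc_reads[big$pos <= 500]), sum(big$mc_reads[big$pos > 500])) /
    c(1, 1)
  tot <- c(sum(big$total_reads[big$pos <= 500]), sum(big$total_reads[big$pos > 500]))
  expect_equal(sum(halves) / sum(tot), whole)
  ## matches a brute-force per-site recount
  sel <- big$pos >= 100 & big$pos <= 400
  expect_equal(weighted_methylation(big, "c", 100, 400),
               sum(big$mc_reads[sel]) / sum(big$total_reads[sel]))
})

test_that("metaplots over uniform methylation are flat at the planted level", {
  cfg <- sim_config(seed = 19, n_pairs = 1, chrom_len = 2e5,
                    n_genes_per_chrom = 40, gene_len = 2000,
                    methyl_dip_depth = 0, methyl_baseline = 0.6,
                    diag_copies = 20)
  sim <- simulate_tetraploid(cfg)
  me <- simulate_methylome(sim)
  feats <- data.frame(feature_id = sim$genes$gene_id, chrom = sim$genes$chrom,
                      start = sim$genes$start, end = sim$genes$end,
                      strand = sim$genes$strand)
  mp <- metaplot(feats, me)
  ## every bin within 3 binomial SD of the baseline (reads pooled per bin)
  expect_true(all(abs(mp$track$wml - 0.6) < 3 * sqrt(0.6 * 0.4 / 800)))
})

test_that("strand orientation puts minus-gene upstream on the genomic right", {
  ## methylation high left of the feature, low right of it
  pos <- seq(10, 5000, by = 10)
  p <- ifelse(pos < 2000, 0.9, 0.1)
  set.seed(8)
  calls <- mk_calls(pos, rbinom(length(pos), 50, p), 50)
  f_minus <- data.frame(feature_id = "g", chrom = "c", start = 2000, end = 3000,
                        strand = "-")
  mp <- metaplot(f_minus, calls)
  up <- mp$track$wml[mp$track$region == "upstream"]
  dn <- mp$track$wml[mp$track$region == "downstream"]
  ## upstream of a minus gene = genomic right = low methylation
  expect_lt(mean(up, na.rm = TRUE), 0.3)
  expect_gt(mean(dn, na.rm = TRUE), 0.7)
})

test_that("bias-set comparison recovers a planted upstream-only difference", {
  ## two methylomes over the same gene models: one with the planted upstream
  ## dip, one flat (emulating a biased vs an unbiased gene set)
  mk_cfg <- function(depth) sim_config(seed = 23, n_pairs = 1, chrom_len = 3e5,
                                       n_genes_per_chrom = 60, gene_len = 2000,
                                       methyl_baseline = 0.8,
                                       methyl_dip_depth = depth,
                                       methyl_dip_span = 2000L, diag_copies = 20)
  sim <- simulate_tetraploid(mk_cfg(0.4))
  me_dip <- simulate_methylome(sim)
  me_flat <- simulate_methylome(simulate_tetraploid(mk_cfg(0)))
  feats <- data.frame(feature_id = sim$genes$gene_id, chrom = sim$genes$chrom,
                      start = sim$genes$start, end = sim$genes$end,
                      strand = sim$genes$strand)
  mp_dip <- metaplot(feats, me_dip)
  mp_ref <- metaplot(feats, me_flat)
  cmpd <- compare_bias_sets(mp_dip, mp_ref)
  body <- cmpd$per_bin$region == "body"
  up <- cmpd$per_bin$region == "upstream"
  expect_lt(max(abs(cmpd$per_bin$diff[body])), 0.1)
  expect_lt(cmpd$upstream_mean_diff, -0.3)  # planted depth 0.4 upstream only
  ## identical inputs give a zero difference track; swapping negates it
  self <- compare_bias_sets(mp_dip, mp_dip)
  expect_true(all(self$per_bin$diff == 0, na.rm = TRUE))
  sw <- compare_bias_sets(mp_ref, mp_dip)
  expect_equal(sw$per_bin$diff, -cmpd$per_bin$diff)
  expect_error(compare_bias_sets(mp_dip,
                                 metaplot(feats[1:3, ], me_dip, body_bins = 10)),
               "binning")
})

test_that("TE-proximity gene selection equals an interval-overlap oracle", {
  set.seed(14)
  genes <- data.frame(gene_id = sprintf("g%d", 1:40), chrom = "c",
                      start = sort(sample.int(90000, 40)))
  genes$end <- genes$start + 500
  tes <- data.frame(chrom = "c", start = sort(sample.int(90000, 25)))
  tes$end <- tes$start + sample.int(400, 25)
  got <- genes_near_te(genes, tes, dist = 1000)
  want <- vapply(seq_len(nrow(genes)), function(i)
    any(tes$end >= genes$start[i] - 1000 & tes$start <= genes$end[i] + 1000),
    logical(1))
  expect_equal(got, want)
})
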