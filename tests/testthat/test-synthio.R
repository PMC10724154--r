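test_that("manifest echoes the planted configuration and validates inputs", {
  sim <- small_sim()
  expect_true(all(sim$manifest$diag_families$ratio == 10))
  expect_setequal(unique(sim$manifest$diag_families$enriched), c("subP", "subM"))
  expect_equal(length(sim$sequences), 4L)
  ## invalid configurations are rejected with the constraint named
  expect_error(sim_config(loss_rate_P = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(chrom_len = 1e4, n_genes_per_chrom = 100),
               "chrom_len too small")
  expect_error(sim_config(cns_len_range = c(5, 100)), "8-100")
  expect_error(sim_config(neutral_sub_rate_P = 0.01), "constrained")
})

test_that("the same seed reproduces byte-identical emitted files", {
  cfg <- sim_config(seed = 9, n_pairs = 1, chrom_len = 6e4,
                    n_genes_per_chrom = 20, diag_copies = 30)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(simulate_tetraploid(cfg), d1)
  write_bundle(simulate_tetraploid(cfg), d2)
  for (f in c("genome.fasta", "genes.gff3", "tes.gff3", "syntelogs.tsv")) {
    expect_identical(readBin(file.path(d1, f), raw(), 2e7),
                     readBin(file.path(d2, f), raw(), 2e7), label = f)
  }
  cs1 <- simulate_cns_set(simulate_tetraploid(cfg), 30)
  cs2 <- simulate_cns_set(simulate_tetraploid(cfg), 30)
  expect_identical(cs1$cns, cs2$cns)
})

test_that("genes partition into subgenomes and planted deletions follow the loss rates", {
  cfg <- sim_config(seed = 5, n_pairs = 2, chrom_len = 4e5,
                    n_genes_per_chrom = 1000, gene_len = 150, diag_copies = 20)
  sim <- simulate_tetraploid(cfg)
  ## every annotated gene sits on exactly one subgenome
  lab <- unlist(sim$manifest$subgenome)
  expect_true(all(sim$genes$subgenome == lab[sim$genes$chrom]))
  st <- syntelog_table(sim)
  n <- nrow(st)
  for (side in c("P", "M")) {
    rate <- if (side == "P") cfg$loss_rate_P else cfg$loss_rate_M
    lost <- sum(is.na(st[[paste0("gene_", side)]]))
    expect_lt(abs(lost - n * rate), 3 * sqrt(n * rate * (1 - rate)))
    ## manifest and emitted annotation agree
    expect_setequal(st$ref_gene[is.na(st[[paste0("gene_", side)]])],
                    sim$manifest[[paste0("deleted_", side)]])
  }
})

test_that("planted expression effects are exact in the noiseless limit", {
  fx <- noiseless_expr()
  means <- aggregate_tpm(fx$expr)
  tr <- fx$expr$truth
  ## planted M-bias pairs: log2 ratio equals fc_magnitude exactly
  bm <- tr$ref_gene[tr$bias == "M"]
  expect_gt(length(bm), 10)
  lfc <- log2(means[paste0(bm, "_M"), ] / means[paste0(bm, "_P"), ])
  expect_equal(unname(range(lfc)), c(3, 3))
  ## nonfunctionalized (P off): subP TPM < 1 everywhere
  poff <- tr$ref_gene[!is.na(tr$nonf_off) & tr$nonf_off == "P"]
  if (length(poff))
    expect_true(all(means[paste0(poff, "_P"), ] < 1))
  ## planted bias counts match the configured fractions
  ncmp <- sum(tr$complete)
  expect_equal(sum(tr$bias == "M"), round(0.2 * ncmp))
  expect_equal(sum(tr$bias == "P"), round(0.1 * ncmp))
  expect_error(simulate_expression(fx$sim, replicates = 1), ">= 2")
})

test_that("CNS pools honour the planted substitution rates", {
  cfg0 <- sim_config(seed = 13, n_pairs = 2, chrom_len = 6e4,
                     n_genes_per_chrom = 20, cns_sub_rate_M = 0,
                     cns_sub_rate_P = 0.05, cns_indel_rate = 0,
                     cns_len_range = c(100, 100), diag_copies = 30)
  cs <- simulate_cns_set(simulate_tetraploid(cfg0), 300)
  dM <- subgenome_divergence(cs$cns, "subM")
  expect_equal(dM$mean, 0)
  dP <- subgenome_divergence(cs$cns, "subP")
  ## expected edit distance ~ 5 of 100 sites, binomial SD over 300 records
  se <- sqrt(0.05 * 0.95 / 100) / sqrt(300)
  expect_lt(abs(dP$mean - 0.05), 3 * se + 0.002)
  expect_error(simulate_cns_set(simulate_tetraploid(cfg0), 10,
                                len_range = c(4, 50)), "8-100")
})

test_that("contact matrices are symmetric with planted checkerboard structure", {
  sim <- small_sim()
  h <- simulate_hic(sim, n_bins = 40)
  m <- h$matrices[[1]]
  expect_identical(m, t(m))
  expect_true(all(m >= 0))
  lab <- h$compartments$label[h$compartments$chrom == names(h$matrices)[1]]
  same <- outer(lab, lab, "==")
  off_diag <- row(m) != col(m)
  expect_gt(mean(m[same & off_diag]), mean(m[!same]))
  expect_error(simulate_hic(sim, n_bins = 10), "compartment_block_len")
})

test_that("methylome calls match the planted baseline, dip and CH ceiling", {
  sim <- small_sim()
  me <- simulate_methylome(sim)
  ch <- weighted_methylation(me, names(sim$sequences)[1], 1, 1e5, "CH")
  expect_lt(ch, 0.005)  # CH stays under 0.5%
  ## no planted dip: genome-wide CG level sits at the baseline, and
  ## upstream equals gene-body level
  cfg0 <- sim_config(seed = 8, n_pairs = 1, chrom_len = 1e5,
                     n_genes_per_chrom = 30, methyl_dip_depth = 0,
                     diag_copies = 30)
  sim0 <- simulate_tetraploid(cfg0)
  me0 <- simulate_methylome(sim0)
  cg <- me0$context == "CG"
  cg_all <- sum(me0$mc_reads[cg]) / sum(me0$total_reads[cg])
  n_reads <- sum(me0$total_reads[cg])
  expect_lt(abs(cg_all - 0.8), 3 * sqrt(0.8 * 0.2 / n_reads))
  g1 <- sim0$genes[1, ]
  up <- weighted_methylation(me0, g1$chrom, g1$start - 2000, g1$start - 1, "CG")
  body <- weighted_methylation(me0, g1$chrom, g1$start, g1$end, "CG")
  expect_lt(abs(up - body), 3 * sqrt(0.8 * 0.2 / 500))
})

test_that("the truth manifest round-trips losslessly through JSON", {
  cfg <- sim_config(seed = 4, n_pairs = 2, chrom_len = 6e4,
                    n_genes_per_chrom = 15, diag_copies = 20)
  ds <- simulate_dataset(cfg, n_cns = 30, n_bins = 40)
  p <- withr::local_tempfile(fileext = ".json")
  write_manifest(ds$manifest, p)
  m2 <- read_manifest(p)
  expect_identical(unlist(ds$manifest$subgenome), unlist(m2$subgenome))
  expect_identical(ds$manifest$deleted_P, m2$deleted_P)
  expect_identical(ds$manifest$deleted_M, m2$deleted_M)
  expect_equal(ds$manifest$expression$fates$fate, m2$expression$fates$fate)
  expect_equal(ds$manifest$hic$conserved_tads$tad_P, m2$hic$conserved_tads$tad_P)
  ## every manifest-referenced gene exists in the emitted annotation
  st <- syntelog_table(ds$genome)
  expect_true(all(m2$deleted_P %in% st$ref_gene))
  expect_true(all(unlist(m2$expression$bias_M) %in% st$ref_gene))
})
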