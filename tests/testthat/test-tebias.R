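mk_assignment <- function(chroms, labels)
  data.frame(chrom = chroms, subgenome = labels, stringsAsFactors = FALSE)

test_that("TE counts per homoeologous pair are direct and complete", {
  asg <- mk_assignment(c("c1P", "c1M"), c("subP", "subM"))
  map <- homoeolog_map("c1P", "c1M")
  tes <- data.frame(chrom = rep("c1P", 3), start = c(1, 100, 200),
                    end = c(50, 150, 250), family = "F1")
  tab <- count_te_by_homoeolog(tes, asg, map)
  expect_equal(tab$N_A[tab$family == "F1"], 3L)
  expect_equal(tab$N_B[tab$family == "F1"], 0L)
  ## empty input: empty table, no error
  empty <- count_te_by_homoeolog(tes[0, ], asg, map)
  expect_equal(nrow(empty), 0L)
  expect_error(count_te_by_homoeolog(transform(tes, chrom = "cX"), asg, map),
               "cX")
})

test_that("planted diagnostic families reproduce their copy-rate ratio", {
  sim <- small_sim()
  asg <- mk_assignment(names(unlist(sim$manifest$subgenome)),
                       unname(unlist(sim$manifest$subgenome)))
  map <- homoeolog_map(sim$map$chrom_a, sim$map$chrom_b)
  tab <- count_te_by_homoeolog(sim$tes, asg, map)
  fams <- sim$manifest$diag_families
  agg <- stats::aggregate(cbind(N_A, N_B) ~ family, data = tab, FUN = sum)
  for (i in seq_len(nrow(fams))) {
    r <- agg[agg$family == fams$family[i], ]
    ratio <- if (fams$enriched[i] == "subP") r$N_A / r$N_B else r$N_B / r$N_A
    expect_gt(ratio, 7)  # planted 10:1, minus occasional failed placements
  }
})

test_that("SBI hits its boundary values and scaling/relabel invariances", {
  tab <- data.frame(family = c("a", "a", "b", "c"), pair = c(1, 2, 1, 1),
                    N_A = c(20L, 10L, 5L, 30L), N_B = c(0L, 0L, 5L, 10L))
  class(tab) <- c("te_count_table", "data.frame")
  r <- compute_sbi(tab, min_copies = 5)
  expect_equal(r$sbi[r$family == "a"], 1)      # all copies one side
  expect_equal(r$sbi[r$family == "b"], 0)      # balanced
  expect_equal(r$sbi[r$family == "c"], 0.5)    # |30-10|/40
  expect_equal(r$biased_subgenome, c("subP", "none", "subP"))
  ## uniform scaling leaves SBI unchanged
  tab2 <- transform(tab, N_A = N_A * 7L, N_B = N_B * 7L)
  class(tab2) <- class(tab)
  expect_equal(compute_sbi(tab2, min_copies = 5)$sbi, r$sbi)
  ## swapping subgenomes flips the label, not the value
  tab3 <- tab; tab3$N_A <- tab$N_B; tab3$N_B <- tab$N_A
  class(tab3) <- class(tab)
  r3 <- compute_sbi(tab3, min_copies = 5)
  expect_equal(r3$sbi, r$sbi)
  expect_equal(r3$biased_subgenome[1], "subM")
  ## per-pair variant differs when biases cancel across pairs
  tab4 <- data.frame(family = "d", pair = c(1, 2), N_A = c(10L, 0L),
                     N_B = c(0L, 10L))
  class(tab4) <- class(tab)
  expect_equal(compute_sbi(tab4)$sbi, 0)
  expect_equal(compute_sbi(tab4, per_pair = TRUE)$sbi, 1)
})

test_that("TE density uses union coverage in strand-oriented windows", {
  genes <- data.frame(gene_id = c("g+", "g-"), chrom = "c",
                      start = c(20001, 20001), end = c(21000, 21000),
                      strand = c("+", "-"))
  tes <- data.frame(chrom = "c", start = c(17501, 17501, 21500),
                    end = c(20000, 18500, 21999), family = "F")
  prof <- te_density_windows(genes, tes, window = 10000)
  ## 2500 bp of the upstream window, overlap counted once
  expect_equal(prof$upstream[1], 0.25)
  ## minus strand: upstream lies right of the gene
  expect_equal(prof$upstream[2], 0.05)
  expect_equal(prof$downstream[2], 0.25)
  ## truncation at the chromosome start shortens the denominator
  g2 <- data.frame(gene_id = "g0", chrom = "c", start = 4001, end = 5000,
                   strand = "+")
  p2 <- te_density_windows(g2, data.frame(chrom = "c", start = 1, end = 1000,
                                          family = "F"), window = 10000)
  expect_equal(p2$upstream, 1000 / 4000)
})

test_that("densities equal a per-bp occupancy oracle on random placements", {
  set.seed(3)
  tes <- data.frame(chrom = "c",
                    start = sort(sample.int(49000, 60)))
  tes$end <- tes$start + sample.int(800, 60)
  genes <- data.frame(gene_id = sprintf("g%d", 1:10), chrom = "c",
                      start = seq(12000, 39000, length.out = 10),
                      end = seq(12000, 39000, length.out = 10) + 999,
                      strand = rep(c("+", "-"), 5))
  prof <- te_density_windows(genes, tes, window = 5000)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    up <- if (g$strand == "+") c(g$start - 5000, g$start - 1) else
      c(g$end + 1, g$end + 5000)
    expect_equal(prof$upstream[i], te_density_oracle(tes, up[1], up[2]))
    expect_equal(prof$intragenic[i], te_density_oracle(tes, g$start, g$end))
  }
})

test_that("syntelog density differences are antisymmetric and tested", {
  prof <- data.frame(gene_id = c("a_P", "a_M", "b_P", "b_M"), chrom = "c",
                     upstream = c(0.4, 0.1, 0.3, 0.2),
                     intragenic = 0, downstream = 0)
  st <- data.frame(gene_P = c("a_P", "b_P"), gene_M = c("a_M", "b_M"))
  r <- density_difference_test(prof, st)
  expect_equal(r$differences$diff, c(0.3, 0.1))
  ## swapping subgenome columns negates the differences exactly
  st_sw <- data.frame(gene_P = st$gene_M, gene_M = st$gene_P)
  prof_sw <- prof
  r2 <- density_difference_test(prof_sw, st_sw)
  expect_equal(r2$differences$diff, -r$differences$diff)
  ## identical densities: t = 0, p = 1
  prof_eq <- transform(prof, upstream = 0.2)
  r3 <- density_difference_test(prof_eq, st)
  expect_equal(r3$t, 0)
  expect_equal(r3$p, 1)
  expect_error(density_difference_test(prof, st[0, ]), ">= 2")
})
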