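# subdom — subgenome dominance analysis for allopolyploid genomes

Allopolyploid genomes carry two subgenomes inherited from different diploid
progenitors (paternal **subP**, maternal **subM**). The two subgenomes
typically diverge asymmetrically: one loses more genes, expresses its
homoeologs more weakly, carries more transposable elements near genes, or
lets its regulatory sequences drift faster. `subdom` implements the
statistics used to measure these asymmetries in allotetraploid fish
genomes, for anyone analysing a subgenome-resolved polyploid assembly:

* **Subgenome phasing** from differential canonical 15-mers: K-means with
  the homoeologous-pair constraint (one subP + one subM per pair), PCA
  coordinates and a silhouette-style confidence per chromosome.
* **TE bias** — the subgenome biased index per TE family,
  `SBI = |ΣN_A − ΣN_B| / Σ(N_A + N_B)` ∈ [0, 1], and TE density in
  strand-oriented 10 kb gene-flanking windows with a Welch t-test between
  syntelog sets.
* **Fractionation and gene content** — retention per subgenome in 100-gene
  sliding windows; tandem arrays (rank gap ≤ 10); core / softcore /
  dispensable / private pangenome classes; the 1:1 balance test
  `X² = (n1 − n2)² / (n1 + n2)` used throughout.
* **Expression** — homoeolog expression bias at `|log2FC| > 2` on
  replicate-averaged TPM, and an ordered on/off decision table classifying
  each ancestor–ohnolog trio as dosage-retained, nonfunctionalized,
  subfunctionalized or neofunctionalized.
* **CNS constraint** — normalized edit distance
  `min(ED(ref,obs), ED(revcomp(ref),obs)) / max(len)` for conserved
  noncoding sequences against a neutral 4D-site control, a global
  least-squares line across subgenomes and each subgenome's perpendicular
  departure from it (negative = more constrained).
* **Chromatin** — A/B compartments from PC1 of the Hi-C correlation matrix
  (gene-density–anchored orientation), compartment content summaries, and
  conserved TADs (> 70% of ≥ 5 collinear genes in one partner TAD).
* **Methylome** — weighted methylation level metaplots (20 body bins +
  2 kb flanks) and bias-set comparisons.
* **Synthetic data** — `simulate_tetraploid()` and friends generate a
  complete allotetraploid dataset (FASTA/GFF3/TSV/JSON manifest) with every
  effect planted at a known magnitude, so each stage is testable without
  any external download.

## Worked example

```r
library(subdom)

cfg <- sim_config(seed = 1, n_pairs = 2, chrom_len = 2e5, n_genes_per_chrom = 80)
sim <- simulate_tetraploid(cfg)
map <- homoeolog_map(sim$map$chrom_a, sim$map$chrom_b)

asg <- phase_subgenomes(
  select_differential_kmers(count_kmers(sim$sequences), map, min_count = 30),
  map, maternal = "chr01M")
asg[, c("chrom", "subgenome", "confidence", "PC1")]
#>    chrom subgenome confidence       PC1
#> 1 chr01M      subM  0.8998694 -55.09445
#> 2 chr01P      subP  0.9336644  53.44795
#> 3 chr02M      subM  0.8966094 -51.57070
#> 4 chr02P      subP  0.9335224  53.21720
```

All four chromosomes separate cleanly (confidence ~0.9 on a [−1, 1] scale)
and match the planted labels. Downstream, the planted maternal dominance is
visible in retention and expression:

```r
prof <- window_retention(syntelog_table(sim), w = 50)
c(subP = mean(prof$retention_P), subM = mean(prof$retention_M))
#>  subP  subM
#> 0.868 0.956        # planted loss rates 0.15 vs 0.05

heb <- call_heb(simulate_expression(sim)$trios,
                aggregate_tpm(simulate_expression(sim)))
heb
#> HEB: 170 M-biased vs 100 P-biased pair-tissues (chi-square p = 2.04e-05)
```

The same balance test applied to published count pairs:

```r
balance_chisq(609, 448)     # maternally retained BUSCO singletons
#> X2 = 24.52, p = 7.3e-07   # < 0.001
```

## Command-line use

A thin wrapper over the same functions is installed at
`exec/subdom` for tabular workflows:

```sh
subdom=$(Rscript -e 'cat(system.file("exec", "subdom", package = "subdom"))')
Rscript $subdom phase --fasta genome.fasta --pairs pairs.tsv --out assign.tsv
Rscript $subdom chisq 609 448
```

See `vignettes/subgenome-dominance.Rmd` for the model, every tunable
parameter and the package's numerical choices.
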