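---
title: "Analysing subgenome dominance in allopolyploid genomes with subdom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing subgenome dominance in allopolyploid genomes with subdom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subdom)
```

## The problem

An allopolyploid genome carries two subgenomes inherited from distinct
diploid progenitors — here called subP (paternal donor) and subM (maternal
donor). After whole-genome duplication the two subgenomes rarely evolve
symmetrically: one may retain more genes, express its homoeologs more
strongly, accumulate fewer transposable elements near genes, or keep its
regulatory sequences under tighter constraint. `subdom` packages the
statistics used to quantify these asymmetries in allotetraploid fish
genomes, together with a synthetic-data generator that plants every effect
at a known magnitude so the whole pipeline can be validated end to end.

The pipeline stages and their core quantities are:

* **Phasing** — assign chromosomes to subgenomes from differential 15-mers,
  K-means with the homoeologous-pair constraint, PCA diagnostics.
* **TE bias** — the subgenome biased index
  $\mathrm{SBI}(f) = |\sum_i N_{iA} - \sum_i N_{iB}| \,/\, \sum_i (N_{iA} + N_{iB})$
  per TE family, and TE density in 10 kb gene-flanking windows.
* **Fractionation** — gene retention per subgenome in 100-gene sliding
  windows; tandem arrays (rank gap ≤ 10); pangenome classes;
  the 1:1 balance test $X^2 = (n_1 - n_2)^2/(n_1 + n_2)$, df = 1.
* **Expression** — homoeolog expression bias at $|\log_2 \mathrm{FC}| > 2$
  on replicate-averaged TPM, and an ordered on/off decision table assigning
  each ohnolog pair a fate (dosage-retained, non-, sub-, or
  neofunctionalized).
* **CNS constraint** — a normalized edit distance
  $d = \min(\mathrm{ED}(r,o), \mathrm{ED}(\overline{r},o)) / \max(|r|,|o|)$
  for conserved noncoding sequences versus a neutral 4D-site control, a
  global least-squares line of CNS on neutral divergence across subgenomes,
  and each subgenome's signed perpendicular departure from it.
* **Chromatin** — A/B compartments from the sign of PC1 of the Hi-C
  correlation matrix; conserved TADs when > 70% of a TAD's ≥ 5 collinear
  genes land in a single partner TAD.
* **Methylome** — weighted methylation level
  $\mathrm{wML} = \sum m_c / \sum \mathrm{total}$ in 20-bin metaplots over
  bodies and 2 kb flanks.

## What the generator emulates

`sim_config()` fixes the study conditions. Each homoeologous pair descends
from one ancestral sequence; the copies then diverge by 2% point
substitution, so most 15-mers are shared and phasing must rely on the
planted signal: a handful of diagnostic repeat families inserted at a 10:1
copy-rate ratio between subgenomes, mirroring the repeat-driven divergence
real subgenomes accumulate between hybridization and the present. Defaults
(2 pairs × 1 Mb, 250 genes per chromosome) keep a full run on a laptop
scale while leaving every statistic comfortably powered; all sizes are
arguments.

Maternal dominance is planted throughout, in the direction the fish
genomes show:

* gene loss at 0.15 (subP) versus 0.05 (subM) per gene — biased
  fractionation;
* 20% of complete ohnolog pairs planted M-biased versus 10% P-biased, at a
  log2 fold change of 3 (above the |2| calling threshold), with log-normal
  replicate noise of SD 0.2 — chosen so planted effects are recoverable but
  individual replicates are visibly noisy, as in real TPM data;
* ohnolog fates drawn at 90% dosage-retained / 4% nonfunctionalized /
  2% subfunctionalized / 4% neofunctionalized, in the region of the
  published fate spectrum;
* CNS substitution rates below the neutral rates per subgenome
  (constraint), with indels at 1% of sites;
* a noiseless checkerboard contact structure (within-compartment contacts
  5× between-compartment) and gene densities of 8 versus 2 genes per bin in
  A versus B compartments, which anchors PC1 orientation;
* CG methylation at 0.8 with a 0.4 dip in the 1.5 kb upstream of TSSs and
  CH contexts at 0.2%, below the 0.5% ceiling typical of fish genomes.

What the generator does **not** emulate: read-level noise (no FASTQ, no
mapping ambiguity), segmental rearrangements, TE nesting and decay,
distance-dependent Hi-C contact decay, bisulfite non-conversion error, and
correlated gene loss along chromosomes. Passing the recovery tests
therefore demonstrates the estimators are correct and well-calibrated on
their stated models, not that they are robust to every artefact of real
assemblies.

## Worked example

```{r pipeline, eval = FALSE}
cfg <- sim_config(seed = 1)
sim <- simulate_tetraploid(cfg)
map <- homoeolog_map(sim$map$chrom_a, sim$map$chrom_b)
asg <- phase_subgenomes(
  select_differential_kmers(count_kmers(sim$sequences), map), map,
  maternal = "chr01M")
table(asg$subgenome == unlist(sim$manifest$subgenome)[asg$chrom])
#> TRUE: 4
```

## Numerical and design choices

Choices the underlying methods leave open, and what this package does:

* **SBI formula.** The aggregate signed form
  $|\Sigma N_{iA} - \Sigma N_{iB}| / \Sigma(N_{iA}+N_{iB})$ is the default
  because it attains 1 exactly when all copies lie in one subgenome and 0
  under perfect balance, matching the index's stated range and reading. A
  per-pair-absolute variant ($\Sigma_i |N_{iA}-N_{iB}| / \Sigma(N_{iA}+N_{iB})$),
  which does not cancel opposing biases across chromosome pairs, is
  available via `per_pair = TRUE`.
* **Differential k-mer thresholds.** Fold ≥ 2 between pair members
  (length-normalized to copies/Mb, removing chromosome-length confounding)
  in all pairs, summed count ≥ 50; all exposed as arguments. K-means runs
  on log1p-transformed normalized counts (stabilizes heavy-tailed repeat
  counts) with 10 restarts and an internal fixed seed so phasing is
  deterministic; equidistant pairs are tie-broken lexicographically and
  flagged low-confidence.
* **Maternal identity is external.** k-mers separate the subgenomes but
  cannot say which is maternal (that comes from mitochondrial evidence),
  so `phase_subgenomes(maternal =)` anchors the subM label; the default
  anchor (alphabetically first chromosome) merely makes output
  deterministic.
* **Retention windows** default to step 1; terminal windows shorter than
  100 genes are dropped rather than rescaled, so every reported value is a
  fraction of the same denominator.
* **Balance tests** use no continuity correction and no multiple-testing
  adjustment, matching how the counts are conventionally reported.
* **Fate rule order** is loss > sub > neo > dosage: silencing of a whole
  copy is the strongest signal, reciprocal on/off patterns need the
  ancestor expressed in both tissues, gain requires ancestor and partner
  silent in the gained tissue, and correlation-based dosage retention
  (r > 0.75, test p < 0.1; relaxed tier r > 0.6 behind a flag) is only
  consulted when no on/off asymmetry fired. A t-test between the copies'
  log2(TPM+1) profiles is attached as evidence but deliberately not used as
  a trigger. The pseudocount for log2FC is 0.5, bounding the fold change
  for silent copies without masking true bias.
* **Edit distance** treats N as matching nothing (conservative), and the
  CNS filter keeps reference lengths in [8, 100] nt before any averaging.
  Means are unweighted by length; the departure error bar is the SD of
  per-chromosome projections onto the line's unit normal, with a
  variance-propagation alternative behind `error_method = "propagate"`.
  Note two systematic effects any user of departure estimates should
  expect: multiple hits make observed distances slightly sub-linear in the
  substitution rate, and an ordinary least-squares line partially absorbs
  the departure of any point included in its own fit. The recovery tests
  compute their expected values through an independent dynamic-programming
  oracle so both effects are accounted for rather than ignored.
* **Compartment orientation** is anchored on gene density (A = gene-rich);
  with no gene track the track is returned unoriented with a warning. Bins
  with zero contacts are masked as NA, never labelled. Gene-to-bin and
  gene-to-TAD assignment use the midpoint.
* **Conserved TADs**: the gene-count gate is read as ≥ 5 and the overlap
  gate as strictly > 0.70; both are arguments, and both per-direction and
  reciprocal counts are reported since conservation need not be symmetric.
* **Metaplots** pool reads across features per bin (the weighted level);
  per-feature averaging is available via `per_feature = TRUE`. Flank bins
  are 100 bp (2 kb / 20). CH methylation is reported as a global level
  only.
* **Coordinates** are 1-based closed inside R (the IRanges/GRanges
  convention); writers emit GFF3 1-based closed and BED / methylation
  `pos0` 0-based, converting at the boundary.

## Problem sizes

The bundled tests and the acceptance script run the generator at 2 pairs ×
1 Mb for phasing, 2,000 reference genes for fractionation, ~1,050 complete
pairs for expression bias, 400 CNS records against a 10-point global line,
60-bin contact matrices and 2 × 20 TADs — sizes at which every planted
effect is ≥ 3 SD from its null while a full run stays under a minute per
stage on one core.

## Limitations

Phasing assumes homoeologous pairs are known (from synteny against a
diploid reference); it will not discover them. The fate classifier
inherits the coarseness of on/off rules — with few tissues,
subfunctionalization is systematically under-called, consistent with the
low published rates. Compartment calls on real Hi-C data depend on ICE
correction quality, which is upstream of this package. The CNS model line
needs ≥ 3 subgenome points; with a single allotetraploid, reference points
from related genomes must be supplied.
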