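# sgevo

Dating and molecular evolution of the fire-ant social supergene.

Colony social organization in *Solenopsis* fire ants is controlled by a
supergene on chromosome 16 — a ~13 Mb non-recombining region with an
ancestral, X-like haplotype (*SB*) and a derived, Y-like haplotype (*Sb*).
`sgevo` is an R package for the comparative-genomic questions this system
raises: **how old is the supergene, does its formation pre- or post-date the
speciation of the socially polymorphic species, and how does the loss of
recombination reshape the *Sb* haplotype?** It is aimed at population
geneticists and molecular evolution researchers working with haploid genome
assemblies, RAD-seq panels and SNP catalogues from supergene or sex-chromosome
systems.

## What it computes

Given haplotype alignments of the non-recombining region, an outgroup, and a
sample-to-haplotype-group assignment, the package runs an inference chain of
classical estimators:

- **Homology/uniqueness filters** assign scaffolds or RAD reads to the
  non-recombining region: the top BLAST hit must land in the region with
  E ≤ 10⁻⁴, and the query is rejected if the second-best hit has E ≤ 10⁻⁴,
  at least half the top hit's base matches, or at most half its mismatch
  percentage (RAD mode: top hit ≤ 4 mismatches, second hit must have more
  than double the top hit's mismatches).
- **Alignment QC**: blocks shorter than 60 columns are dropped and columns
  with alignment-confidence scores below 60% are masked to `N`.
- **Jukes–Cantor distances**: substitutions are counted with pairwise
  deletion, pooled across blocks, and corrected for multiple hits,
  *d* = −(3/4)·ln(1 − (4/3)·*p*).
- **Trees**: neighbor-joining on the corrected distances, rooted on the
  outgroup.
- **Rate acceleration**: λ = mean *Sb* path / mean *SB* path from the
  *SB*–*Sb* divergence node, with a two-sided Wilcoxon rank-sum test
  (exact at small n).
- **Ratio-calibrated dating**: R = (mean *SB* depth to the *SB*–*Sb* node) /
  (mean *SB* depth to the ingroup–outgroup node); with the outgroup split
  dated at 25 (18–32) MYA, the supergene age is 25·R MYA, with a CI that
  combines the calibration interval with a tip bootstrap of R. Only *SB*
  paths enter R, so the accelerated *Sb* rate cannot bias it.
- **Event ordering**: the within-species *SB*–*Sb* distance decomposes as
  D_morph = t·r_B(1 + λ), so t·r_B = D_morph/(1 + λ); the between-species
  *SB*–*SB* distance gives s·r_B = D_species/2. Speciation preceded the
  supergene iff s·r_B > t·r_B.
- **Tajima's D** in non-overlapping 100-kb windows from the 1989 formulas,
  after read-depth filters (≥ 6 reads), with significance from the
  beta-distribution approximation on the statistic's theoretical support.

A simulator (`simulate_haplotypes()`, `simulate_rad_dataset()`,
`simulate_genotype_matrix()`, `make_hit_fixture()`) generates every input the
chain consumes — JC69 evolution along a configurable supergene genealogy with
a rate multiplier on the *Sb* clade, RAD read stacks with depths and errors,
and SNP panels with an optional single-founder bottleneck — each with a
ground-truth record, so every estimator is testable against known answers.

## Worked example

Simulate a 200-kb alignment of the default scenario (outgroup split 25 MYA,
speciation 1.2 MYA, supergene 1.05 MYA, 1.4-fold *Sb* acceleration), estimate
distances, build the tree and fit the dating model:

```r
library(sgevo)
cfg  <- sg_sim_config(seq_length = 2e5, n_blocks = 10, seed = 7)
sim  <- simulate_haplotypes(cfg)
dm   <- pairwise_matrix(sim$blocks)
tree <- build_nj_tree(dm)
fit  <- sg_date(tree, sg_groups(cfg), distmat = dm, seed = 7)
fit
#> Supergene dating fit
#>   acceleration factor (Sb/SB): 1.40 +/- 0.10 (Wilcoxon p = 0.00404)
#>   depth ratio R = 0.0477 (1:21.0)
#>   supergene age: 1.2 (0.8-1.6) MYA [calibration 25 (18-32)]
#>   ordering: t*rB = 2.09, s*rB = 2.40 -> speciation_first
```

The fit recovers the simulated truth: the acceleration factor (true λ = 1.4),
a depth ratio near 1:21 (the *SB*–*Sb* coalescence for the full tip set sits
at the 1.2 MYA speciation node, and 25/1.2 ≈ 21), an age estimate of 1.2 MYA
bracketed by the CI, and the correct event order (t·r_B ≈ 2.1 < s·r_B = 2.4
substitutions per 1,000 sites, so speciation came first). Group-level
distance summaries (`group_distance_summary(dm, sg_groups(cfg))`) report
means ± SD per 1,000 sites for each haplotype-group pair, e.g. 3.18 ± 0.06
within *invicta SB* and ~101 against the outgroup in this run.

`run_pipeline(sg_run_config(seed = 1))` executes the whole chain — simulation,
hit filtering, QC, distances, tree, dating, windowed Tajima's D on a neutral
*SB* panel and a bottlenecked *Sb* panel — and writes a report bundle (TSVs,
newick, VCF, log, resolved configuration) to an output directory;
`inst/scripts/run_pipeline.R` is a shell wrapper over it.

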