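---
title: "Methods: dating a social supergene from haplotype divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dating a social supergene from haplotype divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgevo)
```

# The system and the questions

The fire-ant social chromosome carries two haplotypes of a ~13 Mb
non-recombining supergene: the ancestral *SB*, which still recombines in
*SB*/*SB* queens, and the derived *Sb*, which — like a Y chromosome — does
not. `sgevo` implements the estimators needed to (i) test whether *Sb*
accumulates substitutions faster than *SB*, (ii) date the *SB*–*Sb*
divergence against an outgroup calibration, (iii) decide whether the
supergene formed before or after the speciation of the two socially
polymorphic species, and (iv) detect the population-genetic footprint of the
*Sb* bottleneck in the introduced range through Tajima's D.

# Models and assumptions

## Substitution model

All distance estimation assumes the Jukes–Cantor (1969) model: equal base
frequencies, a single substitution rate, site independence. The observed
mismatch proportion $p$ between two haplotypes is corrected for multiple hits
by

$$d = -\tfrac{3}{4}\,\ln\!\left(1 - \tfrac{4}{3}\,p\right),$$

which is strictly increasing and convex on $[0, 0.75)$ and undefined at
saturation ($p \ge 0.75$; `jc69_correct()` raises an error rather than
returning a value). Substitution counts use **pairwise deletion** — a column
is excluded only for pairs in which either member carries a gap or an
ambiguous base — and counts are **pooled across alignment blocks before
correction**. Pooling matters because the correction is nonlinear: averaging
per-block corrected distances is not a consistent estimator of the corrected
pooled proportion, while the pooled count is. The per-pair number of valid
sites is retained, and a pair with zero valid sites gets an `NA` distance,
never 0.

## Rate acceleration

With a rooted tree in substitutions/site, the divergence node of *SB* and
*Sb* is their most recent common ancestor. The acceleration factor is

$$\hat\lambda = \frac{\overline{\ell}_{Sb}}{\overline{\ell}_{SB}},$$

the ratio of mean root-to-tip path lengths from that node. Its SD is
propagated to first order from the two per-group SDs
($\mathrm{SD}(\hat\lambda) = \hat\lambda\sqrt{(s_b/\bar\ell_b)^2 +
(s_B/\bar\ell_B)^2}$); the method behind the published "± 0.2" is not
specified in the source literature, and the delta method is the simplest
defensible choice. The difference between the two path-length sets is tested
with a two-sided Wilcoxon rank-sum test, which `stats::wilcox.test` computes
exactly for tie-free samples of the sizes used here (7 vs 7).

## Ratio-calibrated dating

The depth ratio

$$R = \frac{\text{mean } SB\text{-tip depth to } \mathrm{mrca}(SB, Sb)}
         {\text{mean } SB\text{-tip depth to } \mathrm{mrca}(\text{ingroup},
          \text{outgroup})}$$

uses **only SB paths**, so the accelerated *Sb* rate cancels out of both
numerator and denominator; $R$ is invariant to rescaling all branch lengths.
With a calibration age $T$ for the outgroup split (default 25 MYA, 95% CI
18–32), the supergene age is $T \cdot R$.

**Confidence interval.** The calibration CI alone understates the
uncertainty because $R$ is itself estimated. `sg_date()` bootstraps $R$ by
resampling SB tips with replacement on the fixed rooted tree and multiplies
the 2.5%/97.5% bootstrap quantiles of $R$ by the matching calibration bounds
— a conservative outer product rather than an independence-normality
assumption. This is one reasonable construction; the original analysis does
not state how its wider-than-calibration interval was obtained.

**Root placement.** With a single outgroup, the position of the root along
the outgroup branch is not identifiable from distances, yet the calibration
node depth depends on it. `root_with_outgroup()` therefore places the root at
the **clock midpoint**: the point at which the outgroup tip depth equals the
mean ingroup tip depth. On ultrametric (clock-like) data this recovers the
true age ratio exactly; under rate asymmetry between the ingroup and outgroup
lineages it biases $R$ by the asymmetry, a limitation shared by any
single-outgroup ratio calibration. A numeric `position` argument overrides
the midpoint when an external rooting is preferred.

## Event ordering

The mean *SB*–*Sb* distance within one species decomposes as
$D_\mathrm{morph} = t\,r_B + t\,r_b = t\,r_B(1+\lambda)$, where $t$ is the
time since supergene formation; the mean between-species *SB*–*SB* distance
is $D_\mathrm{species} = 2\,s\,r_B$ with $s$ the time since speciation.
`ordering_test()` compares $t\,r_B = D_\mathrm{morph}/(1+\lambda)$ with
$s\,r_B = D_\mathrm{species}/2$; the verdict is scale-invariant. When the
underlying pairwise-distance sets are supplied, a two-sided Wilcoxon test on
the transformed sets gates the verdict, returning "indistinguishable" when
the sets do not separate at $\alpha = 0.05$. The decomposition assumes both
species share the background rate $r_B$ and that $\lambda$ measured in one
comparison applies to the other.

## Tajima's D

`tajimas_d()` implements the 1989 formulas directly:
$D = (\pi - S/a_1)\big/\sqrt{e_1 S + e_2 S(S-1)}$ with the full constants
table in `tajima_constants()`. $\pi$ is the mean number of pairwise
differences among haploid calls per window (absolute, not per site), matching
the formula's inputs. $D$ is undefined — reported `NA`, never 0 — when
$S = 0$. Significance follows Tajima's beta approximation: $D$ is confined to
a support $[D_{\min}, D_{\max}]$ determined by $n$ (the even/odd-aware
maximum $\pi$ per mutation), and the null is the beta density on that
interval moment-matched to mean 0, variance 1. Flags are two-sided at 0.05;
the source analysis does not state its sidedness or level, so this choice is
documented rather than inherited. For $n < 4$ the approximation is unreliable
and the flag is "undefined".

**Windows.** `windowed_scan()` tiles the chromosome with non-overlapping
100-kb windows (step = width). The literature phrase "sliding window"
notwithstanding, the cited tooling computes non-overlapping bins, and tiling
keeps windows independent; the width is exposed. Sites with any missing call
are dropped listwise within their window.

**Depth filters.** Whole-genome mode keeps a site if at most one individual
has depth < 6; RAD mode (fewer individuals per group) requires depth ≥ 6 in
every individual. Both rules are boundary-exact as quoted in their source.

## Homology filters

Genome mode accepts a scaffold iff its top hit lands on a region subject with
E ≤ 10⁻⁴ and no second hit betrays ambiguity; all three second-hit clauses —
E ≤ 10⁻⁴, base matches ≥ half the top's, mismatch percentage ≤ half the
top's — are **boundary-inclusive**, following the quoted rule text literally
("≤", "or more", "or less"). RAD mode accepts iff the top hit has ≤ 4
mismatches and any second hit has strictly more than double the top's. Two
corners follow from literal arithmetic: a top hit with 0% mismatches rejects
any 0% second hit, and a RAD top hit with 0 mismatches is rejected only by a
0-mismatch second hit. Hit ranking ties break by descending bitscore, then
subject id, for determinism.

# The simulator: what it emulates, and what it does not

`simulate_haplotypes()` evolves sequences under JC69 along a genealogy with
four haplotype groups (*invicta SB*, *richteri SB*, *invicta Sb*,
*richteri Sb*) plus an outgroup, in one of three topologies: the
nested-supergene arrangement (default — the *Sb* clade inside the *richteri*
subtree, speciation older than the supergene), its mirror with the *Sb* split
basal to speciation, and a single-species design (7 *SB* vs 7 *Sb*, the
whole-genome sampling layout). The rate multiplier $\lambda$ applies to every
branch inside the *Sb* clade including its stem, so the *Sb* root-to-tip
expectation is exactly $\lambda$ times the *SB* expectation — the property
the acceleration test estimates.

Default parameters are the study conditions: outgroup age 25 (time units read
as MY), speciation 1.2, supergene 1.05, within-group coalescence 0.75, base
rate 0.002 substitutions/site/MY (so the *SB* depth to the supergene node is
2.1 per 1,000 sites and the between-species *SB* distance 4.8 per 1,000), and
$\lambda = 1.4$. The SNP simulator's bottleneck default of 30 private
mutations per haplotype per 100-kb window reproduces the observed SNP density
of the introduced-range *Sb* panel (~200 segregating sites per window at
$n = 6$–7). One global seed expands into fixed per-stage child seeds, so a
fixed seed makes every output byte-identical while stages stay independently
reproducible.

Deliberate simplifications:

- **No indel process** — gaps and ambiguity enter only via masking; block
  length filtering is therefore exercised on fixtures, not emergent indels.
- **No recombination** within the *SB* pool; none of the estimators requires
  it, but real *SB* haplotypes are mosaics, which narrows their path-length
  variance relative to this simulator.
- **Star coalescence within groups** rather than a sampled coalescent
  genealogy for the haplotype alignments (the SNP simulator, by contrast,
  draws a true neutral coalescent per window via `ape::rcoal()`).
- **Founder bottleneck as clone + private mutations**: all introduced-range
  haplotypes copy one founder and then accumulate independent singleton
  mutations. This reproduces the excess-rare-allele signature (strongly
  negative D) without a demographic trajectory; it cannot produce the
  intermediate-frequency variants a partial bottleneck would leave.
- **RAD reads are error-free by default**; the read error rate is a free
  knob (`rad_error_rate`) because no sequencing-error model is stated for
  the source data.

Passing tests on these simulations therefore demonstrate estimator
correctness under the assumed models — not robustness to alignment error,
indels, recombination, selection or demographic complexity in real data.

# Numerical choices

- **Coordinates** are 1-based closed in every emitted text format (MAF-like
  container, BLAST tabular, VCF, confidence sidecars) and converted at the
  boundary.
- **Neighbor joining** (via `ape::nj()`) can return small negative branch
  lengths on noisy matrices; `build_nj_tree()` clamps them to zero and moves
  the deficit onto the sibling branch (bounded iteration, then a hard clamp),
  preserving total tree length. Additive matrices are reproduced to machine
  tolerance.
- **Degenerate inputs** fail loudly: saturated distances, zero valid sites,
  a supergene node coinciding with the calibration node, non-clade outgroups,
  unsorted hit groups, empty RAD datasets and empty segments all raise errors
  rather than returning silently wrong numbers.
- **Display units** are substitutions per 1,000 sites in summaries and
  reports; storage is always per-site, avoiding unit drift.
- **Confidence scores** are consumed per column (one score per alignment
  column), not per residue; a per-residue dialect would need only a wider
  sidecar table.

# Test problem sizes

The test suite exercises the estimators at sizes chosen to make sampling
noise negligible relative to the tested tolerances while keeping the default
run quick: JC69 recovery uses 100 pairs of 10⁵ sites (mean relative bias
< 2%); λ-recovery uses 50 replicates of 7 + 7 tips at 10⁶ sites (within ±0.1
of the true 1.5 in ≥ 90%); event-order recovery uses 50 replicates of the
12-sample design at 5 × 10⁵ sites per scenario; the neutral Tajima panel uses
500 independent 100-kb window genealogies at n = 7 (|mean D| ≤ 0.2, ≤ 10%
flagged); filter equivalence uses 10⁴ random hit groups against a naive
clause-by-clause oracle.

# Known limitations

- The ratio calibration inherits the single-outgroup rooting ambiguity
  discussed above; a second outgroup would make the calibration depth
  identifiable.
- The acceleration SD is a first-order approximation; for very small path
  sets a bootstrap over tips is preferable (`bootstrap_ratio()` shows the
  pattern).
- The beta significance for Tajima's D is an approximation whose accuracy
  degrades at very small $n$ and very small $S$; per-window flags are not
  corrected for multiple testing (a genome scan at 0.05 expects 5% false
  positives under neutrality).
- The pipeline's external-input mode is limited to the formats the package
  writes (MAF-like blocks, BLAST tabular, SAM subset, VCF subset, newick);
  it does not ingest arbitrary aligner output.
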