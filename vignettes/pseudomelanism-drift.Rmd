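---
title: "Drift, consensus genotyping and individual identification for a pseudomelanism allele"
author: "PseudoDrift authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Drift, consensus genotyping and individual identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PseudoDrift)
```

# Scope and scientific setting

A small, isolated tiger population carries a recessive coat-pattern allele
(pseudomelanism; *Taqpep* p.H454Y, written *m*) at high frequency, while the
allele is absent from every other surveyed population. `PseudoDrift`
implements the quantitative backbone of the neutral explanation for that
pattern and of the field workflow that measures it:

1. a forward Wright–Fisher drift simulator with bottleneck founding,
   logistic recovery and optional genetic rescue, validated against an
   exact absorbing-Markov-chain oracle;
2. consensus genotyping of noninvasive samples from up to three calling
   methods with a multiple-tube replication rule, and aggregation of
   recaptures into individual genotypes;
3. individual identification from pairwise PI-HAT relatedness with a
   locus/sample filter cascade and probability-of-identity statistics;
4. the supporting population-genetic statistics (heterozygosity, two F_ST
   estimators, exact HWE test, inbreeding F, Mantel tests); and
5. synthetic-data generators that provide ground truth for all of the
   above.

# The drift model

Generations are discrete and non-overlapping. The population holds `n`
individuals contributing `copiesPerIndividual` gene copies each to the
gamete pool. Population size follows the logistic map

$$ n' = n + r\,n\,(1 - n/K), $$

with defaults $r = 0.15$ per generation (an annual growth rate of 0.03 at a
5-year generation time) and carrying capacity $K = 104$. Each generation the
new pool of `round(copiesPerIndividual * n')` copies is drawn
$\mathrm{Binomial}(\text{pool}, p)$ from the parental frequency $p$ —
neutral drift, no selection, single locus.

**Bottleneck runs** (`simulateBottleneck`, `probabilityGrid`) start from
$N_0$ founders with a diploid pool ($2N_0$ copies) and, in the default
`forced_het` mode, exactly one heterozygous founder, so $p_0 = 1/2N_0$. The
quantity of interest is $P(p_G \ge 0.5)$ — the probability that after $G$
generations of recovery the allele has drifted to at least the observed
frequency — evaluated on the final generation, mapped over bottleneck sizes
2–20 and drift times 10–50. The alternative `sampled` founding mode draws
the founder pool binomially from a user-supplied source frequency
(`pSource`), which is deliberately a required parameter in that mode.

**Fixation runs** (`simulateToFixation`) start at $p_0$ (default 0.5) and
continue until absorption. Genetic rescue adds `migrantCopies` wild-type
copies (2 = one wild-type homozygous migrant) to the *parental* gamete pool
before offspring sampling, so the effective parental frequency is
$p\,c/(c+m)$ with $c$ the parental pool size; population size itself is not
changed by migration. With $m > 0$ the all-mutant state is no longer
absorbing — migrants keep arriving — so the mutant is eventually lost in
every replicate; a generation cap (default $10^5$) guards non-termination
and capped replicates are reported separately.

## Numerical conventions, and why they matter

*Real-valued population sizes.* The logistic map is iterated on real
numbers and only the sampled gene-copy pool is rounded to an integer. With
integer rounding every generation, $n = 2$ and $n = 3$ are fixed points at
$r = 0.15$ (e.g. $2 + 0.3\,(1 - 2/104) = 2.294$ rounds back to 2), so a
severely bottlenecked population could never recover — precisely the
regime the probability grid is about. Rounding only the pool preserves both
the integer-copy sampling model and the recovery dynamics.

*Gene-pool size.* Bottleneck runs use a diploid pool (`copiesPerIndividual
= 2`), matching the founding model "$N_0$ individuals, pool built $2N_0$
times". For the future-fixation scenarios the pool convention is genuinely
underdetermined: a "population of 10 with no intrinsic growth" may mean a
pool of 10 or of 20 copies. We default to `copiesPerIndividual = 1` there
(a 10-copy pool), the convention closest on diffusion scale to the
published absorption times for this scenario family; both conventions are
plain parameters and nothing is hard-coded. Users should know that the
*exact* expected absorption time from $p_0 = 0.5$ is 12.59 generations for
a 10-copy pool and 26.23 for a 20-copy pool (`markovOracle(10, 0.5)`,
`markovOracle(20, 0.5)`), so reported means in this family are
convention-sensitive at the tens-of-percent level; the package therefore
treats the exact Markov chain, not any particular printed mean, as the
correctness surface for the simulator.

*Migration accounting.* One migrant homozygote per generation contributes
2 wild-type copies additively to the parental pool. The main alternative
(replacing one resident individual) changes the effective frequency by
$p(1 - 2/c)$ versus $p/(1 + 2/c)$ — indistinguishable at these pool sizes;
additive is the default because it does not silently shrink the resident
gene pool.

*Starting size of growth scenarios.* The logistic fixation scenarios start
from the constant-size case (population 10) by default; this too is an
explicit parameter (`n0`).

*Randomness.* Every stochastic function takes a `seed`; a single R RNG
stream is seeded once per call, so fixed seed means bit-identical output.
Replicates are vectorized over one stream rather than given per-replicate
substreams — simpler, serial, and fully reproducible; grids consume one
stream cell by cell in row-major order.

## The exact oracle

`markovOracle(nCopies, p0, migrantCopies)` builds the full binomial
transition matrix over mutant copy counts $0..n$ (with the migration
adjustment) and solves the absorbing-chain systems $(I-Q)t = \mathbf{1}$
and $(I-Q)h = R$ for expected absorption times and fixation probabilities.
Two facts anchor the suite: without migration the fixation probability is
exactly $p_0$ (the neutral martingale), and for a 2-copy pool from
$p_0 = 0.5$ the expected absorption time is exactly 2 generations. The test
suite checks the simulator against the oracle to 3 standard errors for
pools up to 30 copies, with and without migration.

# Consensus genotyping

Calls at the diagnostic site arrive as categorical strings (`+/+`, `+/m`,
`m/m`, `x/x`), case-insensitively parsed, with `m/+` normalized to `+/m`.
Per sample (`sampleConsensus`):

- all non-missing method calls agree → that genotype, support = number of
  agreeing methods;
- methods disagree → the AS-PCR replicates decide (multiple-tube rule):
  accepted, and flagged, only when exactly three replicates exist and are
  unanimous; otherwise the sample is flagged missing.

Majority voting across methods is deliberately not used: the observed
resolution mechanism is replication and recapture, never 2-of-3 voting, so
an unreplicated disagreement stays missing (conservative). Per individual
(`individualGenotype`) the modal non-missing consensus across recaptures
wins; ties yield missing with a conflict flag (no tie occurs in the
packaged table, so the conservative rule costs nothing).

The packaged call table (`similipalCalls()`; 37 samples, 12 individuals)
reproduces the published genotype tally — 2 `+/+`, 6 `+/m`, 4 `m/m`,
allele frequency $14/24 \approx 0.58$ — including the one recapture whose
single-method `m/m` call is outvoted to `+/m` at the individual level. For
the three samples whose methods disagreed, the printed consensus implies a
unanimous AS-PCR triplicate, and the fixture encodes exactly that
(replicate rows 1–3).

# Individual identification

`applyFilters` runs the filter cascade — locus missingness > 10 %,
monomorphic loci, minor allele count < 2, loci out of HWE (exact test, α =
0.05) in ≥ 2 populations, then samples with < 50 called loci — recomputing
locus filters after sample removal until stable, and reports every removal
with its reason.

`estimateRelatedness` implements the method-of-moments IBD estimator:
observed IBS 0/1/2 counts over co-called loci are equated with their
expectations under IBD 0/1/2 computed from reference allele frequencies,
solved sequentially for $P(\text{IBD}=k)$, clamped and renormalized;
PI-HAT $= P(2) + P(1)/2$. The reference frequencies are an explicit input
(in the field they come from an external genome panel); when omitted, the
function warns and falls back to within-sample frequencies, which biases
relatedness downward among relatives. Supplied frequencies are treated as
known — no finite-reference-panel correction — which pedigree validation
shows is adequate: parent–offspring and full-sib pairs recover 0.5 and
unrelated pairs 0 within 0.1 at 400–500 informative loci. Pairs sharing
fewer than 10 co-called loci are flagged unreliable rather than estimated.

`clusterIndividuals` marks pairs with PI-HAT above the recapture threshold
(default 0.78, the minimum observed among technical replicates in the
source workflow — exposed as a parameter, with no auto-calibration) as the
same individual and takes the single-linkage closure; chains whose
intermediate links fall below the threshold still merge, with a warning.
For cross-cluster pairs in the ambiguous zone (0.6, 0.78] one member is
dropped so a recapture is never double-counted; the rule drops the sample
with more missing data (the less informative one), breaking ties toward
the lexicographically later id so the outcome is deterministic and
order-invariant.

`probabilityOfIdentity` gives the standard biallelic PID and PID-sibs per
locus and their products across a panel; PID ≤ PID-sibs locus-wise and the
product is non-increasing in panel size, both asserted as properties.

# Population statistics

- `heterozygosity`: $H_o$ = fraction of called genotypes heterozygous,
  $H_e = 2p(1-p)$.
- `wrightFst`: $(H_T - H_S)/H_T$ with *unweighted* population means —
  the convention that makes a population at $p = 0.5$ against a fixed
  population give exactly $1/3$.
- `weirCockerhamFst`: the 1984 variance-components θ (diploid form),
  per-locus components $a, b, c$ and the ratio-of-sums global estimate;
  single-individual populations are excluded per locus. On island-model
  data generated at $F_{ST} = 0.1$ (Balding–Nichols frequencies, 2 × 100
  individuals, 200 loci) the estimator recovers 0.1 within 0.03; small
  negative per-locus values are expected and kept.
- `hweExactTest`: the plain (not mid-p) exact conditional test; the
  enumeration probabilities sum to 1 to $10^{-12}$ and the suite
  cross-checks an extreme configuration against a random-pairing Monte
  Carlo oracle. No multiple-testing correction is applied in the filter
  cascade — filtering uses raw α = 0.05 in ≥ 2 populations by design.
- `inbreedingF`: $F = (O_{hom} - E_{hom})/(L - E_{hom})$ with the
  $2n/(2n-1)$ small-sample correction to expected homozygosity; negative
  values (heterozygosity excess) are reported, not clamped.
- `mantelTest` / `mantelCorrelogram` wrap `vegan::mantel` and
  `vegan::mantel.correlog` (999 permutations by default, so the smallest
  attainable p is 0.001); p-values can never fall below
  $1/(\text{permutations}+1)$, and the null calibration of the permutation
  p (approximate uniformity) is asserted in the suite.

# The synthetic-data generators

`simulateHWEPopulation` draws genotypes at HWE proportions;
`simulatePedigree` gene-drops haplotypes through an arbitrary acyclic
pedigree and labels every pair's true relationship class;
`simulateNoninvasiveCalls` degrades a single diagnostic locus with
per-method call failure (defaults complement the printed success rates:
0.48/0.40/0.32 for Sanger/NGS/AS-PCR) and symmetric allelic dropout — a
heterozygote becomes either homozygote with equal probability, and a
homozygote is never mis-called heterozygous. The default dropout rate
(0.1) is a placeholder, not an estimate: the source workflow never
measured its dropout rate. `simulateRecaptureSamples` produces noisy
multilocus recaptures with known individual identity;
`simulateIBDLandscape` diverges population frequencies on the logit scale
with spatial correlation $\exp(-d/\text{decay})$ (σ = 0.5 by default,
moderate differentiation), the weakest structure a Mantel analysis
assumes — monotone distance–divergence; `simulateIslandModel` uses
Balding–Nichols frequencies with exact expected $F_{ST}$.

What these generators deliberately do not emulate: sequencing reads,
linkage between loci, microsatellites, genotype-quality-dependent error,
or the demographic history of any real population. Passing tests therefore
demonstrate correctness of the estimators and rules on data satisfying
their own assumptions, not performance on raw field data.

# Problem sizes

The test suite and acceptance script run at the scales the analysis
itself uses where those are cheap (1,000-replicate grid cells,
2,000-replicate fixation runs) and at reduced but statistically justified
scales elsewhere: 30 seeded end-to-end identification runs (12 individuals,
60 loci), 150 Mantel null replicates at 199 permutations, 20
goodness-of-fit replicates at n = 10,000. Tolerances are 3 standard errors
for stochastic comparisons and $10^{-10}$–$10^{-12}$ for algebraic
identities.

# Known limitations

- Single-locus neutral model only: no selection, no linkage, no spatially
  explicit dynamics.
- Published summary statistics that depend on the study's unpublished
  multi-locus genotype matrix (between-population F_ST tables, mean
  heterozygosities and relatedness, the empirical PID, the observed Mantel
  p) are not recomputable from in-package data; the corresponding machinery
  is validated on synthetic ground truth instead.
- The future-fixation absorption times are convention-sensitive (pool
  size, migration accounting, starting size); the package documents its
  defaults and validates against the exact chain rather than any one
  printed value.
- The PI-HAT estimator assumes reference frequencies are known; with small
  reference panels its finite-sample bias is uncorrected.
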