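---
title: "Missing-homozygosity scans for recessive lethal haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missing-homozygosity scans for recessive lethal haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A fully recessive embryonic-lethal variant is invisible to ordinary
phenotyping in a breeding population: carriers are healthy, and homozygous
conceptuses die before any record is made. What the variant does leave
behind is a statistical footprint — haplotypes that are never, or almost
never, observed in homozygous state even though the realized matings should
have produced homozygotes. `hapdeficit` implements this
missing-homozygosity screen for artificial-insemination (AI) dairy
populations: sliding 50-SNP haplotype windows over phased genotypes, an
exact per-window deficit test under two pedigree designs, false-discovery
control, mixed-model association of the implicated haplotypes with
fertility/birth/survival breeding values, and LD-based prioritization of
candidate causal variants inside the implicated regions.

## The deficit model

For a target haplotype allele in one window, each offspring with suitable
genotyped ancestors contributes a per-offspring homozygosity probability
$\pi_i$. Writing $t(c)$ for the probability that an ancestor with $c$
copies transmits the allele, $t(0)=0$, $t(1)=\tfrac12$, $t(2)=1$:

* **trio design** (sire and dam genotyped):
  $\pi_i = t(c_{\mathrm{sire}})\, t(c_{\mathrm{dam}})$ — transmission fully
  determined by the parents.
* **pgp design** (sire and maternal grandsire genotyped): the dam's
  paternal haplotype is tracked through the grandsire with probability
  $\tfrac12$; her untracked (granddam-derived) haplotype is modelled at the
  population allele frequency $q$:
  $\pi_i = t(c_{\mathrm{sire}})\left(\tfrac12 t(c_{\mathrm{mgs}}) +
  \tfrac12 q\right)$.

The expected homozygote count is $\sum_i \pi_i$ and the observed count is
the number of offspring whose two phased window haplotypes both match the
allele string exactly. The number of homozygotes is a sum of independent
Bernoulli($\pi_i$) indicators — a Poisson-binomial variable — so the
one-sided deficit p-value $P(X \le \mathrm{observed})$ is evaluated
*exactly* by dynamic-programming convolution, truncated at the observed
count (cost $O(n \cdot \mathrm{observed})$). This conditions on the
realized matings, reduces to a binomial tail for homogeneous matings, and
needs no asymptotic approximation at the small observed counts that matter
here. The test suite verifies the DP against exhaustive enumeration over
all $2^n$ outcomes for mating sets up to $n = 12$.

The pgp $\tfrac12 q$ term is a deliberate modelling choice: the pgp design
carries real uncertainty about the maternal contribution, and ignoring it
(setting the term to zero, available via `pgp_use_popfreq = FALSE`)
understates the expectation and is offered only for sensitivity analysis.

### Multiplicity, testing floor, and regions

Windows advance by one SNP (`step = 1`), the most sensitive choice and the
common practice in missing-homozygosity work; every allele with frequency
at least `maf_floor` (default 0.01) is examined and every examined allele
with expected count at least `min_expected` (default 10) is tested. The
floor of 10 reflects the reporting convention for this kind of screen: a
"never observed" haplotype is only remarkable when a double-digit number
of homozygotes was expected. Raw p-values are adjusted by
Benjamini–Yekutieli across all tested alleles of a scan — the BY procedure
remains valid under the strong positive dependence created by overlapping
windows. `scan_deficit()` returns *all* tested alleles with a `deficit`
flag rather than only the deficit ones; conditioning the output on
`observed < expected` would make the returned lower-tail p-values
uninterpretable as a group (the type-I suite relies on the unselected
set). Significant deficit windows (BY-adjusted p < 0.05, the conventional
level) that share at least one SNP on a chromosome are merged into a named
region; overlapping step-1 windows of one lethal share the same allele
lineage in practice, so the merge is purely positional. Each region
reports its most significant window, with ties broken by larger expected
count and then leftmost position — a deterministic, testable rule.

## Association with breeding values

Estimated breeding values (EBVs) are shrunken predictors; dividing by the
reliability $r^2$ removes the shrinkage, giving a pseudo-phenotype with
$E[\mathrm{EBV}/r^2 \mid \mathrm{TBV}] = \mathrm{TBV}$, plus the
information weight $r^2/(1-r^2)$ (capped at 20 so near-unit reliabilities
cannot dominate; weights are reported but not applied by default).
The association model is the standard animal model
$y = \mu + \beta x + g + e$, $g \sim N(0, G\sigma^2_g)$,
$e \sim N(0, I\sigma^2_e)$, with $x$ the 0/1/2 risk-allele dosage and $G$
the VanRaden genomic relationship matrix
$G = ZZ^\top / (2\sum_j p_j(1-p_j))$. REML is exact and deterministic: a
single eigendecomposition of $G$ rotates the problem to independent
observations, the variance ratio $\delta = \sigma^2_g/\sigma^2_e$ is
profiled on a 33-point logarithmic grid over $[10^{-4}, 10^4]$ and refined
by 1-D optimization between the flanking grid points, and the boundary
$\delta = 0$ is checked explicitly. With $\delta = 0$ the fit reduces to
ordinary least squares, which the tests verify against `lm()`. The
genome-wide scan (`gwas_scan()`) estimates the variance components once
under the covariate-free null and reuses them for every SNP — the standard
two-stage approximation — so each SNP costs one generalized least-squares
solve; significance uses a Bonferroni threshold $\alpha/m$ over the $m$
polymorphic SNPs, with $\alpha$ fully configurable.

## Variant prioritization

Candidate SNVs and short indels inside a region expanded by ±2 Mb are
filtered by array-design rules: hard-filter pass (taken from the VCF
FILTER column; re-deriving sequencing quality filters is out of scope), at
least one carrier of the target breed, carrier fraction at most 0.75
(inclusive; carrier = at least one alt allele; missing genotypes excluded
from denominators), at most one homozygous-alt animal, and a
protein-changing consequence class when required. Survivors are ranked by
$r^2$ — the squared Pearson correlation between variant dosage and
haplotype diplotype over pairwise-complete animals — with ties broken by
smaller carrier fraction and then position. A one-degree-of-freedom HWE
chi-square against expectations at the sample allele frequency accompanies
each candidate; a truly linked variant shows the same heterozygote
excess / homozygote deficit as the haplotype.

## What the simulator emulates — and what it does not

`simulate_population()` provides the controlled truth the validation
suites need. It emulates the features of an AI breeding population that
give the scan its power and its pitfalls:

* few sires in service per generation with geometrically decaying usage
  weights (`n_sires_per_gen`, `sire_usage_decay`), which concentrates
  carrier matings when a carrier bull is popular;
* all males genotyped, females only at `female_genotyping_rate`, which
  makes the trio dataset smaller than the pgp dataset, as in routine data;
* one risk haplotype — a fixed allele pattern across a contiguous
  `risk_window_size`-SNP stretch — seeded into founder haplotypes at
  `risk_hap_freq`, at most one copy per founder (a lethal does not
  survive in adult homozygotes);
* silent lethality: a conceptus homozygous for the risk pattern is
  removed with probability `penetrance` *before* genotyping, leaving no
  record — downstream code can only infer the loss from the deficit;
* meiosis under Haldane's model (Poisson crossover count, uniform
  placement, no interference), adequate at the ~1 Mb window scale;
* chromosomes are simulated as *segments at array density*: by default
  100 SNPs over 2.5 cM (1 Mb per cM), so a 50-SNP window spans ~1.25 cM —
  the window scale of a ~114k-SNP genome-wide map. Simulating whole
  100 cM chromosomes at 100 SNPs would put ~50 cM inside each window and
  destroy the transmission model that both the scan and real arrays rely
  on;
* polygenic trait values descend the pedigree as an infinitesimal model
  (founders $N(0, h^2)$, Mendelian sampling variance $h^2/2$), EBVs follow
  the classical shrinkage form $\mathrm{EBV} = r^2\,\mathrm{TBV} + e$ with
  $\mathrm{var}(e) = r^2(1-r^2)\mathrm{var}(\mathrm{TBV})$, so declared
  reliabilities are honest and deregression is unbiased.

It deliberately does **not** emulate: linkage-disequilibrium structure
calibrated to real cattle maps, selection on the simulated EBVs across
generations, imputation or phasing error (the simulator is the phaser and
emits phase as known), the X chromosome, or genotyping error. Passing the
validation suites therefore demonstrates that the statistical machinery is
correct under its stated assumptions — not that real imputed array data
are free of the artefacts (imputation bias, allele-frequency
misestimation) that a real screen must also contend with.

## Validation scenarios and problem sizes

The test suite exercises the pipeline at desk scale, with scenarios fixed
by what each property requires:

* **Null (type-I) suite**: 120 founders, 3 generations, 4 offspring per
  dam (~1,700 offspring), `penetrance = 0`, 20 replicates. Every tested
  window allele is a true null; the pooled fraction of raw p < 0.05 must
  stay within binomial noise of 0.05 — in practice the discrete exact test
  is conservative and the fraction is far below the nominal level.
* **Power suite**: 400 founders, 3 generations, 3 offspring per dam,
  founder risk frequency 0.25, a 40-sire panel with mild usage decay,
  90% female genotyping, full lethality, 20 replicates. The scenario is
  sized so that the truth window carries at least ~20 expected homozygotes
  in *every* replicate of *both* designs — the regime in which a lethal is
  considered detectable — despite drift through the sire panel. At the
  field-typical carrier frequencies of a few percent this would require
  tens of thousands of genotyped animals, which is exactly why real
  screens run on national populations; the simulation trades frequency
  for population size while preserving the mating structure.
* **Mixed-model suite**: n = 500 animals, $h^2 = 0.5$, 20 phenotype
  replicates for heritability recovery; effect-sign recovery at
  $\beta = -0.5$ trait SD on ~1,000 animals.
* **Prioritization suite**: 20 replicates of a smaller population with a
  causal variant placed on every risk-haplotype copy among two kinds of
  decoys (common-SNP decoys that the array rules mostly reject, and rare
  haplotype-indicator decoys that survive and compete on LD).

## Numerical and degenerate-input choices

* Window indices are 1-based inclusive throughout (R convention);
  reported coordinates are 1-based bp as in VCF.
* Haplotype identity is exact string match over the window's biallelic
  sites — no mismatch tolerance, matching the haplotype-as-allele
  treatment of array-based screens.
* The DP tail is truncated at the observed count; probabilities of zero
  are dropped first, so offspring with non-carrier sires cost nothing.
* `expected_homozygotes(numeric(0))` returns 0 with a warning; a scan in
  which no allele reaches `min_expected` returns an empty, classed result
  with a warning rather than an error.
* The GRM applies a ridge of $10^{-6}$ (logged) only if the smallest
  eigenvalue is materially negative; tiny negative eigenvalues from
  floating-point are clipped to zero.
* A constant tested covariate, non-finite phenotypes, unknown trait
  codes, fewer than 30 informative animals, unknown breed labels, and
  unphased genotype input are all rejected with specific errors rather
  than propagated.
* Determinism: a configuration plus seed reproduces bit-identical
  pedigrees, haplotypes and output files; the JSON-lines run log carries
  wall-clock times and is the one output excluded from determinism
  comparisons.

## Known limitations

The pgp expectation treats the dam's untracked haplotype as an
independent draw at frequency $q$; in a deep pedigree the granddam is
herself related to the sire panel, so the pgp test is exact only to the
extent that assumption holds (the trio test is exact outright).
Recombination inside a window makes a transmitted haplotype occasionally
non-identical to either parental window haplotype; at ~1 cM per window
this erodes expectations by ~1% and is ignored. The association layer
fits additive dosage only — a purely recessive lethal with no carrier
effect will show no signal, which mirrors how such screens behave on real
data. Deregression uses the reliability-scaled form without
parent-average correction; with simulated EBVs this is exact by
construction, but national-evaluation EBVs would need the full
parent-average machinery before the weights are trustworthy.
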