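---
title: "Methods: exhaustive SNP-combination scanning in case-control cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exhaustive SNP-combination scanning in case-control cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpcombo)
```

## The problem

Genome-wide association studies of urinary bladder cancer have validated a
handful of common risk variants — each with a modest individual odds ratio —
alongside the long-known *GSTM1* deletion. Two questions follow naturally
from such a panel. Do particular *combinations* of risk genotypes confer a
higher risk than any single variant? And are the relevant combinations the
same in smokers, whose urothelium is chronically exposed to tobacco
carcinogens, as in non-smokers? `snpcombo` implements the full analysis
chain for questions of this type on a small panel (here six SNPs plus the
binary *GSTM1* present/null polymorphism) in a smoking-stratified
case-control design, together with a synthetic cohort generator that makes
every stage testable without access to subject-level data.

## Risk indicators and combinations

Each biallelic SNP, coded as a minor-allele count $g \in \{0, 1, 2\}$, is
collapsed to binary *risk indicators*: subsets of genotype codes designated
as "exposed". Only order-respecting (contiguous) proper subsets are
admissible — $\{0\}$, $\{0,1\}$, $\{1,2\}$, $\{2\}$ — which are exactly the
dominant and recessive codings of the two alleles. A binary polymorphism
contributes $\{0\}$ and $\{1\}$ (present / null). A *combination* of order
$k$ is a conjunction of $k$ indicators on distinct polymorphisms; a subject
is exposed if every member indicator is true, and has undefined exposure if
any member genotype is missing (complete-case per combination).

The number of order-$k$ candidates over $n$ SNPs and $b$ binary
polymorphisms is

$$\sum_j \binom{n}{k-j} 4^{\,k-j} \binom{b}{j} 2^{\,j},$$

which for the 6 + 1 panel gives 26 singletons, 288 two-way and 1,760
three-way combinations. The restriction to contiguous subsets is what makes
these counts come out; splits like $\{0,2\}$ vs $\{1\}$ have no
dominant/recessive interpretation and are excluded.

```{r}
count_combinations(6, 1, 2)
count_combinations(6, 1, 3)
```

## Scoring and ranking

Each candidate is scored on its $2\times2$ exposure-by-status table
($a$ exposed cases, $b$ exposed controls, $c$, $d$ unexposed) within the
selected smoking stratum:

* odds ratio $\widehat{OR} = ad/bc$ with the Woolf interval
  $\exp\!\left(\ln \widehat{OR} \pm z_{1-\alpha/2}
  \sqrt{1/a + 1/b + 1/c + 1/d}\right)$;
* Wald statistic $(\ln \widehat{OR}/SE)^2$, referred to $\chi^2_1$;
* Bonferroni-adjusted p-value with the per-order candidate count as the
  denominator (288 for a two-way scan, 1,760 for a three-way scan) — each
  scan is its own testing family.

Numerical choices, all of which matter for an exhaustive scan over sparse
cells:

* **Zero cells.** If any single cell is zero the Haldane–Anscombe
  correction adds 0.5 to all four cells. If an entire margin is empty (no
  exposed subject in either group, or no unexposed one, or a stratum
  without cases) the OR is undefined: the candidate is excluded from the
  ranking and reported in the scan's `excluded` attribute rather than
  scored with an arbitrary value.
* **Ranking and ties.** The default metric is the raw p-value (two-sided,
  so protective combinations with $OR < 1$ compete on equal terms with
  risk combinations); an OR-maximizing metric is available since "optimal"
  profiles can reasonably be read either way. Ties are broken by larger
  $|\ln OR|$ and then lexicographically by the canonical combination
  identifier, making rankings fully deterministic and invariant to subject
  row order and panel column order.
* **Low-count flag.** Results whose exposed-case or exposed-control count
  falls below 100 are flagged; their ORs rest on few subjects and can be
  wildly variable under resampling.

## Permutation calibration

Whether the $\chi^2_1$ reference is trustworthy for high-order conjunctions
is an empirical question: as $k$ grows the exposed cell thins out. The
calibration report permutes case-control labels with the exposure column
fixed, recomputes the Wald statistic each time, and summarizes the permuted
statistics by their mean (should be $\approx 1$), variance
($\approx 2$) and the permutation p-value $(r+1)/(P+1)$, where $r$ counts
permuted statistics at or above the observed one — the add-one convention
avoids impossible zero p-values.

Because all four margins are fixed under label permutation, the permuted
table is determined by its exposed-case cell, which follows a
hypergeometric distribution; the implementation draws that cell directly
with `rhyper`, which is distribution-identical to explicit shuffling and
makes $P = 100{,}000$ routine. Permuted zero-cell tables get the same
Haldane–Anscombe treatment as the scan, so the two routes never diverge on
degenerate tables.

## Bootstrap rank stability

The scan's product is a ranking, so its stability is assessed on the rank
scale: cases and controls are resampled separately with replacement at
their original sizes (stratified bootstrap — the scheme preserves the
case-control balance, which an unstratified bootstrap would jitter), the
scan is repeated with identical settings, and for each original top-10
combination the report counts how often it re-enters the bootstrap top 10,
top 20 and top 50. Counts are monotone across list sizes by construction.
A combination wholly unexposed within a replicate simply cannot enter that
replicate's lists; such replicates are tallied, not fatal, because extreme
replicate tables are an expected feature of sparse high-order conjunctions.

## Adjusted odds ratios and stratum heterogeneity

Covariate-adjusted ORs come from logistic regression
(`status ~ exposure + age + gender + smoking + site`) via `stats::glm`
with a deviance tolerance of $10^{-8}$ and at most 100 IRLS iterations;
with no covariates the exponentiated slope reproduces the crude 2×2 OR
exactly, which the test suite uses as a cross-route identity. Separation
is flagged (boundary fitted probabilities), not repaired — no penalized
fallback is attempted, the fit is simply marked non-converged.

Whether a combination's OR differs between smoking strata is tested with
the three-term interaction model
$\text{logit}\, P(\text{case}) = \beta_0 + \beta_C C + \beta_S S +
\beta_{CS} CS$ on the union of two disjoint strata, using the Wald test of
$\beta_{CS}$. The default comparison is ever smokers versus non-smokers,
and the default model carries no further covariates (an adjusted variant
is available); in the covariate-free model $e^{\beta_{CS}}$ equals the
ratio of the two stratum ORs exactly. Categorical covariates are
reference-coded with the first level as reference; covariates constant on
the analysis subset are dropped rather than left to make the design
singular.

## Population attributable risk

Four calculators cover the attributable-risk algebra:

* Levin: $PAR = f(RR-1)/(1 + f(RR-1))$ with $f$ the exposure prevalence
  among controls — appropriate for crude ORs;
* case-based (Miettinen): $PAR = p_c (RR-1)/RR$ with $p_c$ the prevalence
  among cases — remains valid with confounder-adjusted ORs, and is
  therefore the default wherever adjusted ORs enter;
* multi-level: the case-based form summed over non-reference genotype
  levels;
* combined: $1 - \prod_i (1 - PAR_i)$ for independent factors.

`rr_given_par` inverts Levin's formula,
$RR = 1 + PAR/\!\left(f(1-PAR)\right)$, answering how strong a risk factor
of frequency $f$ must be to sustain a target attributable fraction; the
curve for a 30% PAR runs from $RR = 5.3$ at $f = 0.10$ through 2.1 at
$f = 0.40$ down to its floor $1 + PAR/(1-PAR) = 1.43$ as $f \to 1$:

```{r}
round(rr_given_par(0.30, c(0.10, 0.40, 1.00)), 2)
```

The pairing of formula and OR is deliberate: the crude smoking PARs
(Levin with prevalence among all controls and the crude OR against
non-smokers) reproduce the motivating study's printed 29% / 39% / 51% for
current / former / ever smokers, and only this pairing does.

## The synthetic cohort generator

No subject-level data are distributed with studies of this kind, so the
generator creates cohorts with exactly the structure the analysis assumes,
and nothing more:

* genotypes drawn under Hardy–Weinberg equilibrium at configured control
  frequencies, independent across loci (no linkage disequilibrium, no
  population stratification — both are out of scope and the tests say
  nothing about them);
* disease status from a logistic model in the planted conjunction
  exposures, so each planted (combination, stratum) pair carries its exact
  conditional OR; recovery tests therefore compare against the conditional
  OR, which is the well-defined "truth" of this design;
* case-control ascertainment by oversampling a source population until
  per-stratum quotas fill — odds ratios are invariant under
  outcome-dependent sampling, so planted ORs survive ascertainment;
* an optional confounding switch: a latent stratum (surfaced as the `site`
  column) with elevated genotype frequencies and elevated baseline risk,
  so that crude ORs are biased and site-adjusted ones recover the planted
  effect.

Fixed generator conditions (chosen once, not tuned): stratum quotas
default to the motivating study's smoking-known table — 321/752 (non),
742/656 (former), 431/315 (current) cases/controls, 3,217 subjects in all;
control genotype frequencies for rs1014971, rs9642880 and rs710521 are
back-calculated from that study's printed non-smoking-control genotype
frequencies, the remaining loci sit at literature-typical European values
(`default_panel()$freq`); the baseline disease probability is 0.05,
i.e. the rare-disease regime, which keeps sampled control genotypes within
Hardy–Weinberg sampling noise of their configured frequencies even in the
presence of planted effects. Age is Gaussian given status (66 ± 10 cases,
63 ± 11 controls), gender 80/20 male/female, four study sites — all
configurable, and a YAML scenario file
(`inst/extdata/study_scenario.yaml`) reproduces the default design.

What passing tests on these cohorts do *not* show: robustness to linked
markers, to genotyping error, to misspecified smoking recall, or to
population structure. The generator emulates the sampling design, not the
messiness of real genotype data.

## Problem sizes used by the test suite

The suite exercises the pipeline at the sizes the analyses are designed
for while staying desk-scale: permutation calibration at $P = 10{,}000$
on a balanced 500 + 500 null cohort (the $P = 100{,}000$ of a full
analysis is reachable through the `P` argument); parameter recovery over
100 replicates of a planted two-way OR 2.0 at 2,000 + 2,000 subjects;
familywise-error control over 500 null two-way scans at 500 + 500;
bootstrap stability at $B = 100$ (default `B = 500` for analyses); the
interaction test's type-I error over 1,000 null replicates. Monte-Carlo
acceptance bands are set from binomial/Monte-Carlo standard errors at
those sizes.

## Known limitations

* Exhaustive enumeration is exponential in the panel size; the design
  targets focused panels (here $\le 7$ polymorphisms, $\le 6{,}400$
  four-way candidates), not genome-wide scans.
* Bonferroni within each (order, stratum) family is conservative under the
  strong positive dependence of overlapping conjunctions; no FDR
  alternative is provided.
* PARs are reported as point values; no interval estimates.
* Separation in logistic fits is diagnosed, not repaired (no Firth
  correction).
* Whether a published "optimal" profile maximizes the OR or minimizes the
  p-value is ambiguous in general; both metrics are implemented and the
  choice is explicit in every call.
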