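# snpcombo

Exhaustive SNP-combination risk scanning for case-control studies.

Genetic association panels for urinary bladder cancer — and many other
complex diseases — consist of a handful of validated common variants, each
with a modest individual odds ratio. `snpcombo` answers the next question:
do particular *combinations* of risk genotypes carry a higher risk than any
single variant, and are the relevant combinations the same in smokers and
non-smokers? It is written for genetic epidemiologists analyzing focused
panels (up to seven polymorphisms) in smoking-stratified case-control
designs.

## What it computes

Every biallelic SNP (minor-allele count 0/1/2) is collapsed into its four
dominant/recessive risk indicators {0}, {0,1}, {1,2}, {2}; a binary
polymorphism such as the *GSTM1* deletion contributes {present}, {null}.
A k-way *combination* is the conjunction of k indicators on distinct
polymorphisms, scored on its 2×2 exposure-by-status table:

- OR = ad/bc with the Woolf interval
  exp(ln OR ± z·√(1/a + 1/b + 1/c + 1/d)),
- Wald statistic (ln OR / SE)² against χ²(1),
- Bonferroni correction over the per-order candidate family
  (288 two-way and 1,760 three-way candidates for a 6 SNP + 1 binary
  panel).

Around the scan: permutation calibration of the χ²(1) approximation
(mean ≈ 1, variance ≈ 2 of permuted Wald statistics), stratified bootstrap
rank-stability counts (top-10/20/50 membership across replicates),
logistic-regression adjusted ORs and a stratum-heterogeneity test on the
exposure × smoking interaction coefficient, and population attributable
risk algebra — Levin `f(RR−1)/(1+f(RR−1))`, case-based `p_c(RR−1)/RR`,
multi-level, combined `1 − Π(1 − PAR_i)`, and the inverse
`RR = 1 + PAR/(f(1−PAR))`. A synthetic cohort generator (Hardy–Weinberg
genotypes, configurable smoking strata, planted conjunction effects,
optional confounding) makes the whole chain testable without subject-level
data. See the methods vignette (`vignettes/snp-combination-scanning.Rmd`)
for model details and design decisions.

## Worked example

Simulate a cohort with the default study structure (3,217 subjects across
non/former/current smoking strata) and a two-way conjunction planted in
non-smokers with conditional OR 1.9, then scan all 288 two-way
combinations in that stratum:

```r
library(snpcombo)

cfg <- sim_config(effects = list(
  list(combination = "rs9642880:12,rs1014971:0", stratum = "non", or = 1.9)))
coh <- simulate_cohort(cfg, seed = 42)

combo_scan(coh, k = 2, stratum = "non")
#> <combo_scan> k=2 stratum=non metric=p m=288 (2 excluded)
#>  rank                                      label   a   b    or ci_lo ci_hi
#>     1     rs1014971 [C/C] x rs9642880 [G/T, T/T] 139 223 1.812 1.382 2.375
#>     2     rs1014971 [C/C] x rs8102137 [C/C, C/T] 153 262 1.703 1.306 2.221
#>     3 rs1014971 [C/T, T/T] x rs710521 [A/A, A/G] 139 422 0.597 0.459 0.777
#>    p_adj flagged
#>  0.00483   FALSE
#>  0.02429   FALSE
#>  0.03654   FALSE
```

The planted combination ranks first: 139 of 321 non-smoking cases and 223
of 752 non-smoking controls are exposed, the estimated OR 1.81
(CI 1.38–2.37) covers the planted 1.9, and the Bonferroni-adjusted
p-value 0.0048 already accounts for all 288 candidates. Is its effect
specific to non-smokers?

```r
interaction_test(coh, "rs9642880:12,rs1014971:0", strata = c("ever", "non"))
#> <heterogeneity_test> rs1014971:0,rs9642880:12 : ever vs non
#>   beta_int = -0.6326 (OR ratio 0.531), p = 0.000162
#>  stratum   a   b   c   d    or ci_lo ci_hi
#>     ever 341 290 832 681 0.962 0.799  1.16
#>      non 139 223 182 529 1.812 1.382  2.37
```

The interaction test rejects homogeneity (p = 1.6×10⁻⁴): the combination
raises risk in non-smokers (OR 1.81) but not in ever smokers (OR 0.96),
exactly as planted. Bootstrap stability and permutation calibration
confirm the finding is not a ranking artifact:

```r
bootstrap_stability(coh, k = 2, stratum = "non", B = 100, seed = 7)
#>  rank                                  label    or top10 top20 top50
#>     1 rs1014971 [C/C] x rs9642880 [G/T, T/T] 1.812    87    95    99
#>  ...

permutation_calibration(coh, "rs9642880:12,rs1014971:0", P = 10000,
                        stratum = "non", seed = 1)
#>               combination wald_obs     p_raw    p_perm mean_stat var_stat
#>  rs1014971:0,rs9642880:12    18.53 1.676e-05 9.999e-05     1.008    2.067
```

The permuted Wald statistics have mean 1.008 and variance 2.07 — the
χ²(1) reference is trustworthy for this combination — and the top hit
re-enters the bootstrap top 10 in 87 of 100 replicates.

Attributable-risk algebra works directly from published 2×2 counts; with
the bundled smoking-stratum counts (`ubc_smoking_counts`):

```r
odds_ratio_ci(431, 315, 321, 752)   # current smokers vs non-smokers
#>        or    ci_lo    ci_hi
#>  3.20538  2.636427 3.897115
round(100 * par_levin(315 / 1723, 3.2054))
#> [1] 29
```

i.e. a crude current-smoker OR of 3.21 (CI 2.64–3.90) and a population
attributable risk of 29% of cases.

## Command-line use

A thin CLI over the same functions ships in `inst/cli/snpcombo`:

```sh
Rscript inst/cli/snpcombo simulate --scenario inst/extdata/study_scenario.yaml \
    --seed 1 --out cohort.tsv
Rscript inst/cli/snpcombo scan --input cohort.tsv --order 2 --stratum ever --top 10
Rscript inst/cli/snpcombo par solve --par 0.30 --f 0.10
```
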