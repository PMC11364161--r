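---
title: "Estimating polygenic-index-by-SES interactions with family designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating polygenic-index-by-SES interactions with family designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxefam)
```

## The scientific question

Two competing hypotheses predict opposite signs for the interaction between
a child's genetic propensity for education and the family's socioeconomic
status (SES). Under the Scarr-Rowe view, enriched environments let genetic
potential express itself, so polygenic indices (PGIs) should predict
educational outcomes *more* strongly in high-SES families (a positive
PGI × SES interaction). Under the compensatory-advantage view, advantaged
parents buffer a low genetic endowment — tutoring, track appeals, high
expectations — so the index should predict *less* strongly in high-SES
families (a negative interaction).

Estimating that interaction is confounded by passive gene-environment
correlation (rGE): parents transmit both alleles and environments, so a
child's PGI correlates with the rearing environment even without any causal
gene-environment interplay. `gxefam` implements the three designs used to
triangulate around this confound:

* **between-family** — regression across children, the standard but
  rGE-vulnerable design;
* **within-family** — family fixed effects on sibling/DZ-twin pairs,
  exploiting random segregation at meiosis and absorbing everything
  families share;
* **trio** — child-level regression conditioning on both parents' PGIs,
  which makes the child's index exogenous given the parents'.

Each design is run for two z-scored indices (cognitive and noncognitive
skills) and seven educational outcomes — mother-reported mathematics and
reading grades at ages 7 and 10 (1–5 scale), the standardised end-of-primary
test score (501–550, z-scored for analysis), upper-secondary track
attendance, and adult higher-education attainment — a grid of
2 × 7 × 3 = 42 analyses.

Because the register data such analyses run on cannot be redistributed, the
package pairs the estimation machinery with a synthetic family-cohort
generator under which every stage is testable, and under which the designs'
bias-removal claims can be verified by parameter recovery rather than
asserted.

## The generator

`simulate_cohort()` draws, per family, a father and mother with independent
genotypes at `n_loci` unlinked biallelic loci (allele frequencies uniform on
`[maf_low, maf_high]`), then simulates meiosis: each non-identical child
receives one random allele per locus from each parent; a monozygotic pair is
one meiosis duplicated. This reproduces exactly the covariance structure the
designs rely on: MZ co-twin index correlation 1, DZ/sibling and parent–child
0.5, child vs mid-parent √½. Linkage disequilibrium is deliberately absent —
the designs need the transmission algebra, not realistic haplotypes — which
is the main sense in which passing tests do *not* certify behaviour on real
genotype panels.

Each PGI is a fixed weighted dosage sum (weights drawn once per scenario),
z-standardised against the genotyped children. Parental education follows a
propensity `rge_strength · (PGI_cog + PGI_noncog)/√2 + N(0,1)`, thresholded
so that the family-level *dominance* indicator — SES = 1 if either parent is
highly educated — has the configured base rate (default 0.41, the share of
higher-educated fathers typical of genotyped twin-register samples). With
`rge_strength > 0` this is a pure passive-rGE channel: conditioning on both
parents' indices removes the child-index/SES association entirely, which is
the trio design's identification property and is asserted as a test.

Outcomes follow a latent linear model per outcome,

`Y* = α + β_cog·PGI_cog + β_noncog·PGI_noncog + β_ses·SES +
γ_cog·PGI_cog·SES + γ_noncog·PGI_noncog·SES +
η_cog·midparent_cog + η_noncog·midparent_noncog + u_fam + e`,

with a family-shared deviate `u_fam` and individual noise. The `η`
(genetic-nurture) terms are zero by default; switching them on creates the
bias that distinguishes the designs. Observed scales:

* **grades** — `Y*` rounded to the nearest integer and clipped to 1–5
  (fixed cut-points 1.5/2.5/3.5/4.5); default latent scale gives an
  observed SD ≈ 0.9. The rounding map is nearly linear (slope attenuation
  ≈ 3% at the default noise level), which is why recovery tests use grades.
* **test score** — the standardised latent mapped affinely and censored to
  [501, 550]; the pre-censoring location/scale (539.81, 10.44) are frozen
  constants calibrated once so the censored, rounded score has mean 538.9
  and SD 9. A z-score column is computed empirically, as analysts do.
  Because of the ceiling and the empirical standardisation, coefficients on
  the z-scored test are mildly scale-contaminated relative to the latent
  ones; tests that need an exact estimand avoid this outcome.
* **track / attainment** — probit-style: standardised latent plus
  threshold-specific noise, cut at the configured prevalence (0.5 for the
  upper track, mirroring the ≈ 535 recommendation boundary; 0.35 for
  higher education; both calibration choices, not published register
  values).

Ancestry principal-component stand-ins are standard normal and the
genotyping platform is a family-level two-level factor, both independent of
genotype by default; `structure_strength` optionally tilts the first
component towards mean allele dosage. Genotype missingness is person-wise
(default 0.25) and applies to parents as well as children, since the trio
filter exists precisely because parents are often ungenotyped. SES and
outcomes are generated from the *true* indices — genetics act regardless of
measurement — while observed `pgi_*` columns are missing for masked
persons; `pgi_*_true` columns carry the generator's ground truth.

Default scale is 2,500 families (mix: 30% MZ pairs, 40% DZ pairs, 15%/15%
twin-pair-plus-sibling), which after selection yields roughly 3,700
between-family, 2,250 within-family and 2,050 trio children per outcome —
comparable to the age-7/10 grade rows of large register analyses — and is
rescaled with one multiplier.

## Sample construction

`build_between()` keeps children with complete index, SES and outcome data
and randomly drops one co-twin from each complete MZ pair (an identical
pair adds no genetic variation). `build_within()` keeps a balanced two
children per family, applying in order: a complete DZ pair; one remaining
co-twin plus a (random) complete sibling; a complete MZ pair contributing
one random co-twin plus a sibling. `build_trio()` further requires both
parental indices. Every random draw is seeded per (design, outcome), so
outcome-specific samples differ the way per-outcome register samples do;
whether random exclusions should instead be drawn once per design is
undecidable from published descriptions, and per-(design, outcome) seeding
is this package's documented choice. Zygosity is family-level in the
generator, so the ambiguous "MZ pair and DZ pair in one family" case cannot
arise from simulated data; mixed user data triggers a warning and the MZ
rule. All rules are family-local — a family's selection depends only on its
own rows and its own seeded draw — a property the bootstrap exploits
(below).

## Estimation conventions

Continuous outcomes are fit by least squares, binary ones by linear
probability models (predictions are deliberately not truncated to [0, 1]),
with a logistic variant as robustness. All covariances are family-clustered
sandwiches with the CR1 small-sample factor `G/(G−1) · (N−1)/(N−K)` and t
tests on `G − 1` degrees of freedom — the de-facto convention of the
applied family-regression literature; no publication states its exact
small-sample rule, so this is a documented default rather than a replicated
constant. The within-design estimator demeans within family (numerically
identical to per-family indicators, and tested against that oracle), counts
the absorbed intercepts in `K`, reports family-constant controls as
*inestimable* — SES in a within formula is rejected outright, since a
family-constant regressor cannot be estimated by design — and treats an
index with zero within-family variance (an MZ-pair-only sample) as a
singularity. Collinear columns are dropped and logged, never silently.

The interacted models follow the full Keller-style expansion: the focal
index and SES are each interacted with the other index, every control, and
(trio) every parental index — 39 slopes between-family, 51 in the trio —
so the G×E coefficient cannot absorb confounded covariate interactions.
Covariate × covariate terms are never generated. The platform indicator
is interacted per indicator level, and SES × platform is included under
"all controls". A tercile recoding of the focal index (boundaries computed
on the design sample, bottom tercile as reference, every interaction
inherited indicator-wise) is available as a nonlinearity check.

The within design has no estimable SES main effect or product term, so its
grid cell is the high-minus-low SES *stratified slope difference* with
standard error `sqrt(se_high² + se_low²)` — equivalent, for the point
estimate, to a fully SES-interacted pooled fixed-effects fit because SES
partitions whole families (asserted at 1e-8 in the tests). This makes the
42 cells comparable across designs: every cell is "how much flatter is the
index slope in high-SES families".

## Multiplicity

Each (index, design) pair contributes a family of seven tests, corrected
two ways. Bonferroni: adjusted p `min(1, 7p)`, per-test threshold
0.05/7 ≈ 0.007. Romano–Wolf step-down maxT under a *pairs cluster
bootstrap*: families are resampled with replacement jointly for all seven
outcomes (preserving cross-outcome dependence despite differing
subsamples), each outcome's design sample is rebuilt from the resample,
models are refit, and recentred studentised statistics feed the step-down
max rule with the `(1 + count)/(B + 1)` convention, monotonicity enforced
and adjusted p floored at the raw p. Because sample selection is
family-local, "rebuilding the sample from the resample" is exactly the
concatenation of the drawn families' original selections, which is how the
loop is implemented; singular refits are redrawn up to a cap and counted.
`B` defaults to 1,000 (desk-scale runs in tests use 250, the smallest B at
which the step-down tail is still resolved at α = 0.05).

Familywise error control under the global null is verified by simulation.
One caveat worth stating: with 39 slopes and only one-to-two hundred
clusters, plain CR1 t-based p values are slightly anti-conservative, so
Bonferroni (which inherits them) can occasionally reject where the
bootstrap-calibrated Romano–Wolf does not; "Romano–Wolf is less stringent"
is a property of calibrated raw inference, not a pointwise theorem, and the
test suite asserts it accordingly (exactly, in a strong-signal regime;
in the vast majority of runs, under the null at reduced n).

## Power

`min_detectable_delta_r2()` inverts the noncentral-F power curve of the
one-degree-of-freedom incremental test — the interaction term is one
additional tested covariate — with noncentrality `n · ΔR²/(1 − R²_full)`,
by root-finding to 1e-12 (checked against a grid-scan oracle at 1e-6).
The base explained variance is an explicit argument (default 0) since no
canonical value exists. `monte_carlo_power()` runs the full chain —
generate, select, expand, fit — per replicate and reports the rejection
rate with its binomial Monte-Carlo standard error. It uses the *generating*
effect sizes, not estimated ones; post-hoc power computed from observed
effects is known to be uninformative, and the result object says so.

## Numerical choices and degenerate inputs

Frozen constants: test-score map N(539.81, 10.44) censored to [501, 550];
grade cut-points 1.5/2.5/3.5/4.5; tercile boundaries are type-1 quantiles
(exactly n/3 per group at divisible n, ties raise a degenerate-coding
error). Collinearity is resolved by pivoted QR at tolerance 1e-9.
Zero-weight index vectors, constant reference sets, families without two
parents, empty SES strata, perfect logistic separation and infeasible power
requests all raise typed errors rather than propagating NaNs; an empty
cohort round-trips with its full column schema. All randomness flows from
one master seed through named sub-seeds (`subseed(seed, label, ...)`), so
identical configurations are bit-identical and a single `--seed` argument
to the scripts reaches every stage.

## Test problem sizes

The suite verifies moment-level claims at 10,000 families (kinship
correlations), coverage claims at 200–250 families × 200 replicates
(nominal CI coverage of β₁, β₂, γ in all three designs with rGE off),
interaction recovery of γ = −0.1 at 800 families × 120 replicates,
bias-contrast (nurture + rGE on, trio unbiased, between inflated) at 700
families × 40 replicates, familywise error at 100 families × 200 cohorts ×
B = 250, and the default-scale 42-cell sign tally at 2,500 families. These
sizes were chosen as the smallest at which the binomial/Monte-Carlo error
bars still separate the hypotheses being checked.

## Known limitations

No linkage disequilibrium, no assortative mating, no sibling interaction
effects; outcomes are conditionally independent across the seven measures
given the structural terms and family effect, which understates real
cross-outcome correlation (the joint bootstrap still sees the dependence
induced by shared regressors and families). The test-score ceiling makes
its z-scored coefficients mild underestimates of latent effects — real in
registries too, but worth remembering when reading recovery numbers. The
logistic robustness fit reports coefficients on the log-odds scale and is
not folded into the grid, which uses linear probability models throughout,
as the primary analyses do.
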