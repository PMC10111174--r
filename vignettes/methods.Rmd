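---
title: "Models and methods behind msatcoal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind msatcoal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`msatcoal` re-implements, as one tested pipeline, the computational chain
of a microsatellite survey of a poorly dispersing insect colonizing a
coastal transect: diversity and F-statistics, isolation by distance,
coalescent simulation of allele-length markers under competing
demographic scenarios, ABC scenario choice and parameter estimation, and
joint Bayesian estimation of inbreeding and null alleles. This vignette
explains the models, their assumptions, the tunable parameters, and the
design choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Data model

A `genotype_matrix` holds diploid allele-length calls (integer repeat
codes, stored exactly as read — no binning) for `n` individuals at `L`
loci, with a population label per individual. Missingness is a property
of the whole call: both allele slots are `NA` together, and half-missing
codes are a parse error, mirroring the field practice of discarding a
locus that fails to amplify. GenePop (2- and 3-digit) and a CSV dialect
are supported; 3-digit output is the default because allele sizes exceed
99.

## Diversity and F-statistics

Expected heterozygosity uses Nei's unbiased estimator
$\tilde n/(\tilde n - 1)\,(1 - \sum_a p_a^2)$ with $\tilde n$ the number
of gene copies; the biased version is available by argument. Whether a
published table used the corrected or uncorrected form is usually
unstated, so both are implemented and the unbiased one is the default.

Global F-statistics follow Nei (1987) basic statistics with the
Nei–Chesser correction: per locus, $H_o$, $H_s$ (within-population gene
diversity, harmonic-mean sample size $\bar n$),
$H_t = 1 - \sum \bar p_a^2 + H_s/(\bar n r) - H_o/(2\bar n r)$; overall
values are ratios of locus means, so the decomposition
$(1-F_{IT}) = (1-F_{IS})(1-F_{ST})$ holds to machine precision (tested at
1e-12 against an independent direct-count oracle). A consequence worth
knowing: for two *identical finite samples* the corrected $F_{ST}$ is not
exactly zero but $O(1/n)$ negative; the tests assert $|F_{ST}| < 0.005$
at $n = 200$ rather than exact zero. Weir–Cockerham variance components
are deliberately out of scope.

Per-population $F_{IS}$ in the diversity table is
$1 - \bar H_O/\bar H_E$ over loci (ratio of means) — stable when some
loci are nearly monomorphic, which a mean of per-locus ratios is not.

HWE tests are genotype-class $\chi^2$ with the Yates continuity
correction, $df = k(k+1)/2 - k$ for $k$ alleles, at a Bonferroni level
$\alpha/(\text{populations} \times \text{loci})$ (240 tests at survey
scale). Exact (Guo–Thompson) tests are out of scope. The LD test is a
permutation test on the two-locus genotype contingency $\chi^2$,
permuting one locus within population; the statistic is a design choice
— the cited toolchain specifies contingency tables and permutations but
not the statistic — and p-values are $(\#\{T^* \ge T\}+1)/(B+1)$, hence
always in $(0,1]$.

Null-allele moment estimators: Chakraborty
$(H_E-H_O)/(H_E+H_O)$ and Brookfield-1 $(H_E-H_O)/(1+H_E)$; negative
values are clamped to zero and flagged, since frequencies cannot be
negative.

Individual heterozygosity indices (`PHt`, `Hs_exp`, `IR`, `HL`) follow
their standard definitions; reference allele frequencies default to the
whole dataset (population-scoped by argument). Group comparisons use
Kruskal–Wallis with tie correction (verified against
`stats::kruskal.test`) and Dunn z-tests; the multiplicity adjustment is
Bonferroni by default because the source toolchain does not state one —
it is an argument.

## Distances, trees, and IBD

The chord distance uses the multi-locus normalization
$D_C = \frac{2}{\pi L}\sum_l \sqrt{2(1-\sum_a\sqrt{x_a y_a})}$; several
variants exist, and this bounded form was chosen and recorded. Loci
untyped in either population are skipped with $L$ reduced. $D_{AS}$
averages the per-locus shared-allele proportion (min-count rule) over all
cross-population individual pairs. Neighbor joining and bipartition
counting use `ape`; bootstrap resamples **loci** with replacement —
the natural unit for multilocus distance trees; the source description
("maximum likelihood with 1000 bootstrap replicates" for an NJ tree) is
ambiguous, and this reading is the recorded resolution. Geographic
distances are haversine on a 6371.0 km sphere; ellipsoidal corrections
(<0.5% here) are ignored.

The Mantel test correlates lower triangles, permutes one matrix's labels
jointly over rows and columns, and is one-tailed for positive
association, because isolation by distance is a directional hypothesis.

## The coalescent simulator

Scenarios are declarative: sampled populations plus unsampled ancestors,
and a backward-ordered list of divergence events (child merges into
parent at time `t`) and pulse admixtures (each lineage of the target goes
to source A with probability `ra`, else B). Each founding event can carry
a founder bottleneck: size `N` for `db` generations immediately before
the event (looking backward). No printed prior exists for `db`; it is
fixed at 5 generations and exposed as an argument. Continuous migration
is out of scope — the hypotheses under test are pulse events.

Time is discrete in generations because effective sizes as small as
`Ne = 10` (and founder sizes down to 1) make the continuous-time
approximation poor. Within an interval of constant size, waiting times to
the next pairwise merger are $1+\mathrm{Geom}(p)$ with
$p = \binom{k}{2}/2N_e$. When the density $\binom{k}{2}/2N_e$ exceeds
0.3, serial pairwise merging with a capped rate distorts the marginal
coalescence law of a pair (we measured a −12% bias on the
$E[(\delta\mu)^2] = 2\mu t$ check), so the simulator switches to exact
Wright–Fisher parent-picking generations in that regime. This is the one
deliberate refinement of the stated design; it keeps the model fully
discrete while restoring the pairwise marginals, and the closed-form
checks (equilibrium $H_E = 1 - 1/\sqrt{1+8N_e\mu}$ under strict SMM,
$(\delta\mu)^2 \approx 2\mu t$ after isolation) pass within Monte-Carlo
error.

Mutations are Poisson on branches. The generalized stepwise model draws a
magnitude $k \ge 1$ with $P(k) = (1-P)P^{k-1}$ ($P = 0.22$ default,
$P = 0$ gives strict SMM) and a symmetric sign, confined to 40 contiguous
allelic states. Steps that would exit the range are resampled by default
(preserves stationarity better than clamping); reflection is available.
The root allele is the mid-range state, maximizing head-room. Priors
default to the colonization-study settings: `Ne` uniform 10–1500, founder
`N` 1–100, times t1 10–500, t2 100–500, t3 100–1000, t4/t5 500–3000 under
the full order chain `t5 > t4 > t3 > t2 > t1` (rejection sampling),
`ra` 0.001–0.999, mean mutation rate uniform 1e-4–1e-3 with per-locus
rates Gamma(shape 2) around the mean truncated to 1e-5–1e-2. The Gamma
shape is not printed anywhere; 2 is the recorded choice.

The scenario library spans three hypothesis families over clusters I–V:
a serial south-to-north stepping stone (scenario 1), origin in the most
diverse cluster(s) (scenarios 2–6), and independent introductions with
cluster II created by admixture of I and III (scenarios 7–10; scenario 9
is the structure the source study selected, and scenario 8 is its nearest
neighbor, differing only in cluster V's parent, so the published
8-vs-9 confusability is structurally represented). Only scenarios 1 and 9
are described in the main text of the source; the others are templates
for their families, not claimed identical to the originals.

## ABC

The summary-statistic set is the single most consequential free choice —
the source never lists its selection — and mirrors the standard one- and
two-sample microsatellite statistics of the standard reference-table ABC
toolchain: per cluster,
mean alleles/locus, mean unbiased $H_E$, mean allele-size variance, mean
Garza–Williamson $M = A/(\text{size range}+1)$; per cluster pair, Nei
$F_{ST}$, $(\delta\mu)^2$, and $D_{AS}$ ($4G + 3G(G-1)/2$ numbers for
$G$ clusters). Statistics are normalized by their reference-table MAD
(zero-MAD statistics dropped with a warning), distances are Euclidean,
and the tolerance fraction (default 0.01) of nearest rows is retained.

Model choice fits a weighted multinomial logistic regression of scenario
on $(s - s_{obs})$ with Epanechnikov weights
$w_i = 1-(d_i/d_{max})^2$, evaluated at $s_{obs}$ (where the covariates
vanish, so the posterior is the softmax of the intercepts). A fixed tiny
ridge (1e-6), as first specified, collapses to degenerate 0/1 posteriors
whenever the retained set is small relative to the ~44 statistics
(complete separation); the implementation therefore penalizes **slopes
only** with ridge $0.5\,p/n_{retained}$ and damps Newton steps. In the
shrinkage limit this estimator tends to the weighted class frequencies —
i.e. it degrades gracefully toward the direct rejection estimate instead
of saturating. Parameter posteriors logit-transform each parameter to its
(empirical) prior range, apply the weighted local-linear adjustment
$\theta^* = \hat\theta(s_{obs}) + r_i$, back-transform, and report
weighted 2.5/50/97.5% quantiles — so intervals cannot leave the prior
support. A singular design falls back to unadjusted rejection quantiles,
flagged. Confusion analysis classifies prior-drawn pseudo-observed
datasets by highest logistic posterior; type I is the rejection rate of
the focal scenario on its own pods, type II the acceptance rate on
competitors' pods.

Reference-table rows derive per-row sub-seeds from the master seed, so
tables are bit-identical regardless of worker partitioning; a failed row
is retried with a fresh sub-seed and logged.

## Joint inbreeding / null-allele estimation

Per individual and locus, the observation is blank, an apparent
homozygote, or a heterozygote. The generative model: with probability
$\beta$ the genotyping fails (blank); otherwise with probability $F$ the
genotype is identical by descent (one draw from the allele frequencies,
doubled), else two independent draws; the frequency vector of each locus
**within each population** includes a null allele, a null/visible call
shows as a homozygote, and null/null shows as blank. All latent
indicators are conjugate given the observed class, so the sampler is pure
Gibbs over grouped multinomial counts — cells sharing (population, locus,
observed allele) are updated as one multinomial draw, which is why
survey-scale data (329 × 15) run in seconds per thousand iterations.
Priors: $F \sim U(0,1)$, $\beta \sim U(0, 0.2)$ (truncated Beta
updates), and an empirical-Bayes Dirichlet on each population's allele
frequencies: total mass `freq_mass = 2` spread in proportion to the
dataset-wide allele profile, plus `null_alpha = 0.5` on the null
category. The frequency prior matters more than is obvious: a flat
Dirichlet(1) over the full allele support flattens the frequency
estimates of very small populations (samples of 4 individuals against a
dozen allele categories), which inflates expected heterozygosity under
the model and pushes the homozygote excess into $F$ (measured ≈ +0.06
at survey scale); starving the null category instead attributes
null-driven homozygote excess to $F$ when the true $F$ is zero. The
defaults were chosen on exactly those two opposing checks — F = 0 with
nulls must stay below 0.1, and F = 0.45 must be recovered — both of
which are asserted in the test suite. Reported:
posterior mean of $F$ with a 95% shortest (HPD) interval, per-locus null
frequencies (sample-size-weighted over populations), DIC
($2\bar D - D(\bar\theta)$) for the full model versus a nulls-only model
with $F \equiv 0$, and a split-chain $\hat R$ warning above 1.1.
Population-specific frequencies matter: with a single pooled frequency
vector the Wahlund effect would be absorbed into $F$, and the estimator
could not recover a genotype-level $F = 0.45$ in structured data.
Exact numerical agreement with any particular published whole-dataset
estimate is a soft target — chain settings and priors of the original
software are not printed.

## The synthetic world

`generate_study_like()` emulates the survey the pipeline was built
around: 16 populations with the published sample sizes (329 individuals),
15 loci with 8–18 alleles on 40 contiguous states, genotype-level
inbreeding $F = 0.45$ (with probability $F$ both alleles copy one draw —
imposed at genotype formation because that directly controls the
quantity the estimators target), per-locus null rates drawn
uniform(0, 0.10) acting independently per allele copy, and missingness
topped up to exactly `round(0.032 · n · L)` cells. Sites sit on a
straight 800 km transect — only distance ranks matter for the IBD tests.

Allele frequencies follow a Dirichlet chain along the transect: deme
$i+1$ is drawn with concentration $c = 4\,\text{deme\_size}\cdot m$
around a blend $(1-\lambda)f_i + \lambda f_{anc}$, where
$\lambda = $ `lr_mix` is a long-range migration component that saturates
differentiation over a horizon of $\sim 1/\lambda$ demes. A first
island-model derivation of the default $m$ ignored the shared drift that
a serial chain induces (all demes inherit deme 1's drift, deflating
global $F_{ST}$ well below the mean pairwise value); a one-off
calibration scan of the chain model then fixed the defaults
($m = 0.01$, deme size 100, `lr_mix` 0.1, ancestral Dirichlet α = 1),
giving a default dataset with global $F_{ST} \approx 0.30$, mean
within-population $H_E \approx 0.41$ and a strong 1-D Mantel signal —
the regime the emulated survey reports. These defaults were frozen
before being asserted on and are not revisited per test.

What the generator does **not** emulate: the island-specific excess of
private alleles that the real survey's most diverse population shows
(the chain is spatially homogeneous, so no synthetic population
accumulates ~14 private alleles), cluster-specific admixture geometry,
temporal sampling, or allele-size homoplasy structure. Consequently a
green test on synthetic data establishes estimator correctness under the
stated generative model — not agreement with any particular field
dataset.

## Numerical and degenerate-input choices

Permutation p-values use the add-one rule and are one-tailed where the
hypothesis is directional. Monomorphic loci yield `NA` statistics rather
than zeros. Populations with a locus entirely missing have that locus
skipped from their means rather than imputed. `inject_missing` warns
instead of deleting data when the dataset already exceeds the target.
The logit transform pads its range by 1e-6 of the span to keep boundary
draws finite. HPD intervals use the shortest-window rule on sorted
draws. All stochastic entry points take explicit integer seeds; the
pipeline derives per-stage sub-seeds from one master seed so stage
results do not depend on which other stages run.

## Known limitations

Scenario templates 2–8 and 10 approximate unpublished topologies. The
desk-scale reference tables (10³–10⁴ rows) cannot reproduce posterior
probabilities obtained from 10⁷-row tables; the acceptance report's ABC
numbers are stochastic, order-of-magnitude reproductions, and the
divergence-time posterior median in particular remains close to its
ordering-conditioned prior at this scale. The LD permutation statistic is
not the exact statistic of the cited software. The Gibbs sampler
estimates one dataset-level $F$, not individual inbreeding coefficients.
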