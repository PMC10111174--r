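# msatcoal

Microsatellite population genetics and coalescent ABC for reconstructing
colonization history.

`msatcoal` implements the full computational chain of a
microsatellite-based study of post-glacial colonization along a coastal
transect: descriptive population genetics, isolation-by-distance testing,
a coalescent simulator for microsatellites under declarative demographic
scenarios, approximate Bayesian computation (ABC) for scenario choice and
parameter estimation, joint Bayesian estimation of inbreeding and null
alleles, and a synthetic-data generator that emulates such a survey
(16 populations, 329 diploid individuals, 15 loci) so that every stage is
testable without external downloads.

It is aimed at population geneticists working with diploid
allele-length (SSR) genotypes who want a scripted, reproducible pipeline
from a GenePop file to scenario posteriors.

## What it computes

**Diversity and structure.** Per population: sample size `n`, allele
counts `N_A`, private alleles `P_A`, observed/expected heterozygosity
(`H_O`, unbiased `H_E`) and `F_IS = 1 − H̄_O/H̄_E`. Globally, Nei (1987)
basic statistics with the Nei–Chesser small-sample correction:

    F_IS = 1 − Ho/Hs,   F_ST = (Ht − Hs)/Ht,   F_IT = 1 − Ho/Ht

averaged over loci as ratios of means, so `(1−F_IT) = (1−F_IS)(1−F_ST)`
holds exactly. Hardy–Weinberg χ² tests with Yates correction and
Bonferroni adjustment, linkage-disequilibrium permutation tests,
Chakraborty `(H_E−H_O)/(H_E+H_O)` and Brookfield `(H_E−H_O)/(1+H_E)`
null-allele estimators, the individual heterozygosity indices `PHt`,
`Hs_exp`, `IR`, `HL`, Kruskal–Wallis/Dunn group comparisons, and the
Evanno ΔK statistic from clustering run log-likelihoods.

**Distances and IBD.** Cavalli-Sforza & Edwards chord distance
`D_C = (2/πL) Σ_l sqrt(2(1 − Σ_a sqrt(x_a y_a)))`, shared-allele distance
`D_AS`, haversine great-circle distances, neighbor-joining trees with
locus-bootstrap support (via `ape`), and a one-tailed Mantel permutation
test.

**Coalescent simulator.** Backward-in-time, discrete generations, with
divergence, pulse admixture (rate `ra`), founder bottlenecks (`N` founders
for `db` generations) and piecewise-constant sizes. Mutations follow a
generalized stepwise model: step size `k ≥ 1` with
`P(k) = (1−P)P^(k−1)` (`P = 0.22` by default), symmetric sign, confined
to 40 contiguous allelic states. The compiled core simulates ~150
datasets/second at study scale.

**ABC.** Summary statistics per cluster (mean alleles/locus, `H_E`,
allele-size variance, Garza–Williamson `M`) and per cluster pair
(`F_ST`, `(δμ)²`, `D_AS`); MAD-normalized rejection; scenario posteriors
by local multinomial logistic regression with Epanechnikov weights;
parameter posteriors by logit-transformed weighted local-linear
adjustment; type I/II confusion from pseudo-observed datasets.

**Inbreeding.** A Gibbs sampler jointly estimating a dataset-level
inbreeding coefficient `F`, per-locus null-allele frequencies and a
genotyping-failure rate, with 95% HPD intervals and DIC model comparison
(full model vs nulls-only).

## Worked example

```r
library(msatcoal)

## a survey-like synthetic dataset: 16 populations, 329 individuals,
## 15 loci, inbreeding F = 0.45, nulls <= 10%, 3.2% missing
syn <- generate_study_like(synth_config(seed = 100))
validate_gm(syn$gm)
#> genotype validation: 329 individuals x 15 loci
#> overall missing fraction: 0.0320

population_diversity(syn$gm)[c(1, 2, 17), ]
#>     pop  n N_A P_A       H_O       H_E      F_IS
#> 1   Vuo  4  27   2 0.1722222 0.2865079 0.3988920
#> 2   Nad 22  42   0 0.1903053 0.4268236 0.5541359
#> 17 Mean NA  44   2 0.2238705 0.4272326 0.4762211

global_fstats(syn$gm)
#> F_IS = 0.4873  F_ST = 0.3148  F_IT = 0.6487

## isolation by distance along the coastal transect
mantel_test(chord_distance_matrix(syn$gm),
            great_circle_matrix(syn$sites), n_perm = 999, seed = 1)
#> Mantel r = 0.8340, p = 0.001 (999 permutations, one-tailed)

## scenario choice: serial stepping stone vs admixture origin
lib <- scenario_library()[c("scenario1", "scenario9")]
ss  <- c(I = 10L, II = 10L, III = 10L, IV = 10L, V = 10L)
tab <- build_reference_table(lib, 2000L, ss, n_loci = 15L, seed = 7L)
draw <- sample_priors(lib$scenario9, n_loci = 15L, seed = 42L)
pod  <- simulate_dataset(lib$scenario9, draw, ss)
model_choice(tab, summary_stats(pod), tolerance = 0.01)
#> ABC model choice (40 retained rows):
#>          scenario1 scenario9
#> direct      0.3250    0.6750
#> logistic    0.0357    0.9643

## joint inbreeding / null-allele estimation
gibbs_inbreeding_null(syn$gm, n_iter = 4000, burnin = 1000, thin = 3,
                      seed = 1)
#> inbreeding F = 0.398 (95% HPD 0.364-0.431), model nfb_full
#> failure rate = 0.0025, DIC = 13400.3
```

The pod was simulated under the admixture scenario and the logistic
posterior attributes it there with probability 0.96; the inbreeding
posterior sits a little below the generating F = 0.45 on this seed and
short chain — longer default chains tighten it.

(The numbers above are the output of this exact code; the model-choice
call warns that 40 retained rows is below the recommended 50 — use a
larger table in real analyses.)

The same stages are scriptable:

```sh
Rscript -e 'msatcoal::msat_cli(commandArgs(TRUE))' synth --out work --seed 1
Rscript -e 'msatcoal::msat_cli(commandArgs(TRUE))' stats \
    --input work/synthetic.genepop --out work
Rscript -e 'msatcoal::msat_cli(commandArgs(TRUE))' mantel \
    --input work/synthetic.genepop --sites work/synthetic_sites.csv \
    --out work --n-perm 999
```

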