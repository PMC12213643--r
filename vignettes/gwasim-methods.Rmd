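---
title: "Simulating and benchmarking GWAS in diverse populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and benchmarking GWAS in diverse populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasim)
```

`gwasim` is a self-contained laboratory for case-control GWAS methodology in
structured and admixed populations: it simulates cohorts whose causal
architecture and local-ancestry mosaic are known exactly, scores them with a
battery of in-package association statistics, and evaluates power, false
positive rates and cross-population replication against the designed truth.
This vignette is the package's own account of the models it implements, the
parameters that matter, and the choices made where the design was genuinely
open.

## 1. Synthetic reference panels

Real benchmark studies start from merged reference haplotypes (for example
several European and West African populations from a public panel). The
stand-in here is generated, in two layers.

**Allele frequencies: Balding–Nichols.** Each site draws an ancestral
frequency `p ~ Uniform(0.05, 0.95)`; population `k`'s frequency is
`f_k ~ Beta(p (1-F_k)/F_k, (1-p)(1-F_k)/F_k)`, so `F_k` is that population's
divergence (FST) from the shared ancestral pool. `hudson_fst()` (the
ratio-of-averages Hudson estimator) recovers the generating `F` to within
±0.02 at 2,000 sites and 200 haplotypes; this recovery is a tested
invariant.

**Haplotypes: a founder-copying walk.** Each population carries a pool of
`n_founders = 20` founder haplotypes; every emitted haplotype copies along
each chromosome from one founder at a time, switching to a uniformly drawn
founder between adjacent sites with probability `1 - exp(-d_cM /
ld_block_len)`. This produces r² that decays with genetic distance at scale
`ld_block_len` (default 0.1 cM) on top of a long-range floor from the finite
pool — both local and long-range LD, without a coalescent.

One numerical subtlety: founder alleles are not drawn site-wise Bernoulli
from `f_k`. Independent draws would add `f(1-f)/20` of spurious drift per
population and visibly inflate realised FST. Instead the founder pool
quantises `20 f_k` to an allele count with a stochastic remainder, which
keeps the realised frequencies pinned to the Balding–Nichols draws while
retaining the 20-founder LD structure. A minor-allele-frequency floor
(`maf_min = 0.01`, a common-SNP panel) is enforced on the emitted
haplotypes; violating sites get fresh frequency and founder draws re-read
through the stored copying paths, so their LD context survives.

**Default scale.** Five mock chromosomes ("2", "6", "11", "15", "20" — the
chromosomes the scenario presets place risk on), 4,000 SNPs each, evenly
spaced over 100 Mb under a uniform 1 cM/Mb map (the standard convention;
spacing is forced even so tract midpoints are integers). Scaled-down maps
keep the 100 cM genetic length per chromosome, so recombination behaviour is
preserved when tests use fewer SNPs. Panels default to 200 haplotypes per
population; substantially smaller panels make resampled cohorts measurably
inbred (cryptic relatedness inflates cross-chromosome correlations), which
is worth knowing before shrinking them for speed.

## 2. Forward simulation with exact ancestry

`meiosis()` draws a Poisson crossover count per chromosome with mean
`total cM / 100`, places breakpoints uniformly on the cM scale (no
interference), copies alternating parental segments starting from a fair
coin, and flips each emitted allele independently with probability
`mutation_rate` (default 1e-8 per site per meiosis, a human-scale rate;
setting it to 0 makes several exactness invariants hold verbatim).
Local-ancestry labels travel with the segments at site resolution —
exactness over memory — and are compressed to half-open `[start_bp, end_bp)`
tracts whose boundaries are midpoints between flanking SNPs, with a
symmetric extension at chromosome ends so tracts tile each chromosome
exactly. With a uniform map this makes the cM-weighted global ancestry of
`global_ancestry_from_tracts()` agree with per-site label counting to
numerical precision, which is tested.

Homogeneous cohorts resample offspring of panel individuals
(`grow_homogeneous()`): two distinct parents drawn uniformly with
replacement, one gamete each. Admixture is single-point
(`admixture_scenario()`): a founding pool of `n_out` diploids sampled from
the parental populations with the scenario proportions, then `G` (default
10) rounds of random mating at constant size, selfing excluded. Expected
global ancestry equals the proportions; the realised cohort mean drifts with
the founding multinomial plus mating noise (about ±1.5 percentage points
around a 70% contribution at `n_out = 1000`), which the tests treat as
sampling error, not bias.

## 3. Disease models

Penetrance is multi-locus logistic with genotype-class coding:
`logit P(case) = b0 + sum_l [log(rr_het_l) 1(g_l = 1) + log(rr_hom_l)
1(g_l = 2)]`. "Relative risks" are therefore genotype odds ratios inside the
logistic model — an exact risk-ratio interpretation is not
logistic-compatible, and at the default prevalence of 0.10 the two nearly
coincide. The baseline `b0` is calibrated by a monotone root-find so the
mean penetrance over a source-population sample equals the target prevalence
(to 1e-6). Cases and controls are rejection-sampled: candidates are
generated from the haplotype source, assigned case status by a Bernoulli
draw on their penetrance, and accumulated until both quotas are met exactly
(attempt cap 1000 × total n). Case-control sampling preserves the
genotype-class odds ratios; their recovery within 15% at n = 5,000 is a
tested invariant.

**Signal classes** (configurable defaults): strong = odds ratios 1.8 / 3.24
(het / hom), weak = 1.15 / 1.32, null = 1 / 1; ancestry deviations strong =
0.15, very strong = 0.25, weak = 0.05. The published design this emulates
left its relative-risk table in supplementary material, so these values are
the package's own calibration: strong loci are detectable at a total n of
about 1,000, weak loci are marginal even at 5,000 — reproducing the
qualitative pattern the presets need.

**Tag pairs.** Cross-population replication designs need SNP pairs in
complete LD (`r² = 1`) in a design population. Natural pairs are not
guaranteed in a small synthetic panel, so `manufacture_tag_pair()` copies
the anchor column into its neighbour in the complete-LD populations and
copies-with-flips (default flip probability 0.1) elsewhere, giving high but
imperfect LD there. Only the anchor carries a penetrance term: because the
partner's genotype column is identical in the complete-LD population, it
shows exactly the anchor's association — giving the partner its own term as
well would square the effective odds ratio (an early implementation did,
and the weak chromosome-11 signal stopped being weak).

**Ancestry risk.** `ancestry_risk_spec()` requests a case-minus-control
local-ancestry difference in a region. During case formation each case
haplotype's regional segment is re-drawn from the parental panels: target
ancestry with probability `pi_a + deviation`, else one of the others with
renormalised probability. `pi_a` is the realised regional ancestry fraction
of the untouched controls, so the achieved difference equals the requested
deviation regardless of founding drift (recovery within ±0.02 at
2,500+2,500 is a tested invariant). The price of this construction is that
case regional segments are single-ancestry panel copies rather than
post-admixture mosaics; ancestry outside the region is untouched.

**Presets.** `build_scenario()` wires the full designs: homogeneous
European-like / African-like cohorts with the chromosome 2/20
misreplication pairs (complete LD in the European-like population only,
anchor causal there, partner causal in the African-like cohort), the
chromosome 11 pair in complete LD in both (strong in one cohort, weak in
the other), shared strong SNPs on 6 and 15; and three-way (70/15/15) and
five-way (30/25/20/15/10) admixed cohorts with the regional ancestry risks
described above (ancestry-risk regions are ±2 Mb around the risk SNP,
targeting the majority ancestry). `force_null = TRUE` turns every class off
for calibration studies. Sizes: small = 500 cases + 500 controls, large =
2,500 + 2,500, both exact.

## 4. Association statistics

All tests fill one fixed result schema (`id, chrom, pos, a1, maf, beta, se,
stat, p, log_bf, ppa, n, qc_flag`; p-values floored at 1e-300, never 0) and
serialise to a stable TSV.

* **Trend**: Cochran–Armitage with additive scores; the statistic equals
  `N r²(g, y)` and matches the textbook 2×3 formula exactly.
* **Logistic**: per-SNP ML fit (additive coding) with optional covariates;
  Wald test; separation and non-convergence are flagged, never imputed.
* **Mixed model (EMMAX-style)**: the 0/1 phenotype is modelled on the
  observed scale (as the tools being mimicked do; no liability
  transformation). Step 1 estimates `delta = se2/sg2` by REML on the null
  model via one eigendecomposition of the GRM (`Z Z'/M` over standardised
  genotypes) and Brent optimisation of the restricted likelihood over
  `log delta` in [-10, 10] (tolerance 1e-8). Step 2 runs per-SNP GLS Wald
  tests with the correlation structure fixed at the null `delta`; the
  residual *scale* is re-estimated per SNP and the reference distribution is
  t with the OLS degrees of freedom, so an identity GRM reduces *exactly* to
  ordinary least squares (a tested oracle). LOCO mode rebuilds GRM, REML and
  rotation per excluded chromosome.
* **Bayes factors**: Laplace / asymptotic-normal approximation around the
  logistic MLE, `log BF = 0.5 log(se²/(se²+s²)) + 0.5 z² s²/(se²+s²)` with
  prior SD `s = 0.2` on the additive log-odds effect (configurable). On a
  Gaussian conjugate toy this approximation is within 0.05 of the exact
  marginal-likelihood ratio (tested). The decisive threshold is 4.61, the
  conventional rounding of `log(100)` on Jeffreys' scale, compared with a
  strict `>=`.
* **Local-ancestry-aware joint test**: the phased genotype decomposes into
  ancestry-specific dosages `X_a` and haplotype counts `L_a`
  (`sum X_a = g`, `sum L_a = 2`, exact by construction); the model adds
  `L_a` terms (reference ancestry `K-1` dropped against the intercept,
  recorded in the output metadata) and tests all `beta_a` jointly. The
  joint test is a likelihood ratio for `K >= 2` — a Wald block on the same
  fit proved conservative (inflation factor ~0.85) in sparse
  minority-ancestry strata — and is exactly the logistic Wald statistic in
  the degenerate `K = 1` case. Strata with fewer than `min_stratum = 10`
  haplotypes or without dosage variation are flagged
  `untestable_in_stratum`, not silently dropped.
* **Admixture mapping**: logistic regression of the phenotype on the local
  ancestry dosage of a target ancestry with the individual's global
  proportion of that ancestry as covariate; Wald p plus a Laplace log BF.
* **Joint PPA**: `posterior odds = pi/(1-pi) × exp(log BF_geno + log
  BF_anc)`, `PPA = odds/(1+odds)`, default per-SNP prior `pi = 1e-4`. This
  independence combination is an explicit *analog* of joint SNP/ancestry
  posterior scoring, not a re-derivation of any published tool's exact
  model; it is monotone in both inputs and equals 0.5 at posterior odds 1.
* **Supervised global ancestry**: per-individual EM maximisation of the
  binomial likelihood `sum_m [g log(q'f_m) + (2-g) log(1-q'f_m)]` on the
  simplex with panel frequencies fixed (clipped to [1e-4, 1-1e-4]);
  convergence when the mean per-individual log-likelihood gain falls below
  1e-6. Numerically identical parental frequency vectors make the
  likelihood flat, and the result is flagged `unidentifiable` rather than
  returned with false confidence.
* **QC**: MAF, exact Hardy–Weinberg (in controls; full conditional
  enumeration) and missingness filters, with a removal log naming each SNP
  and rule; designed risk SNPs that QC removes are flagged loudly, since a
  quality filter silently deleting a true signal is exactly the failure
  mode worth reproducing.

True simulated tracts serve as the local-ancestry input by default (no
ancestry-inference step); `noisy_local_ancestry()` corrupts labels with a
per-site error rate for sensitivity studies.

## 5. Meta-analysis and replication

`fixed_effects()` is inverse-variance pooling; `random_effects()` reports
the DerSimonian–Laird `tau²`, Cochran's Q and I², the DL normal test
(`re_p`), and additionally a random-effects likelihood-ratio test (`re2_p`)
of the joint null `beta = 0, tau² = 0` against the Self–Liang 50:50
chi-square(1)/chi-square(2) mixture. The second statistic exists because the
DL z-test can never be more liberal than fixed effects under equal weights,
whereas the documented behaviour of random-effects models that *gain* power
under heterogeneity — and therefore replicate falsely across heterogeneous
populations — is a likelihood-ratio phenomenon. Both are reported; the
false-replication comparisons use `re2_p`.

`m_values()` computes per-study posterior probabilities of effect by exact
Bayesian model averaging over all `2^k` effect configurations (k ≤ 20);
active studies share a common effect with a Normal(0, 0.2²) prior integrated
analytically; the priors default to `prior_effect_prob = 0.5` and are
configurable since the emulated tool's priors are not printed.
`binary_effects()` is an m-value-weighted Stouffer combination with
sample-size weights — labelled an analog, the exact published
binary-effects likelihood ratio not being reproduced here.
`replication_report()` classifies designed loci between two studies as
replicated-same-SNP (significant, direction-concordant in both),
replicated-via-LD-partner (the population-specific causal partner fires in
the second study — the misreplication pattern the chromosome 2/20 design
exists for), population-specific, or non-replicated. Allele harmonisation
is by id plus allele pair; strand flips are out of scope for synthetic,
strand-consistent data.

## 6. What the simulator does and does not emulate

It emulates: divergent allele-frequency spectra with a controllable FST;
local and long-range LD; recombination on a genetic map and realistic
mutation rates; exact multi-way admixture tracts; genotype and ancestry
risk of controllable strength; exact case-control quotas; population-
specific LD around tag pairs.

It does not emulate: coalescent genealogies (the founder-copying walk is
first-order Markov, so fine-scale haplotype block structure is stylised);
continuous or multi-wave gene flow (admixture is single-point by design);
selection, imputation error or genotyping missingness (cohorts are complete
by construction — QC's missingness filter exists for imported data);
local-ancestry inference error, unless injected via
`noisy_local_ancestry()`; and sequence-level realism (sites are abstract
biallelic SNPs). Passing tests therefore demonstrate correctness of the
machinery and reproduction of the designed qualitative patterns, not that
any statistic will behave identically on real cohorts.

## 7. Numerical choices and degenerate inputs

Seeding: every stochastic operation derives a child stream from
`(master seed, operation label, replicate index)` (`derive_seed()`, a
multiplicative hash modulo 2^31-1), so modules are independently
reproducible and repeated runs are byte-identical. Monomorphic sites:
r² is an explicit error (undefined, not 0); monomorphic SNPs in tests are
flagged and excluded from statistics; a monomorphic designed risk locus
warns and proceeds with the effect recorded as unobservable. GRMs are
checked symmetric to 1e-10 and positive semi-definite to an eigenvalue
tolerance of -1e-6 relative. Separation in logistic fits flags the SNP
`non_converged` with no fabricated p-value. File formats: 1-based
coordinates, half-open tracts, `.` for missing, explicit C-locale number
formatting; VCF GT uses `|` only when true haplotypes are retained.

## 8. Problem sizes used by the shipped tests

The unit and acceptance suites run at scaled-down map sizes chosen so the
whole suite completes in minutes: 40–2,000 SNPs per chromosome depending on
the check, with each chromosome keeping its 100 cM length, and reference
panels at the default 200 haplotypes per population. Cohort sizes follow the
study design wherever the check concerns it: null-calibration runs use the
small preset (500+500 homogeneous, 250+250 admixed), power comparisons use
500+500 versus 2,500+2,500, the three-way large preset is exercised at its
full 2,500+2,500, and the replication ladder uses 250/750/1,250 cases per
study. `scripts/acceptance.R` regenerates its three quantities at 100–200
SNPs per chromosome with full-size cohorts in about two minutes.

## 9. Known limitations

The mixed model treats the binary phenotype as quantitative (as the emulated
tools do); its p-values are slightly deflated in admixed cohorts when the
tested chromosome is inside the GRM, which is the documented proximal-
contamination behaviour rather than a defect, and the LOCO variant shows the
opposite trade-off. The joint-PPA combination assumes independence of
genotype and ancestry evidence, which is optimistic inside ancestry-risk
regions where the two are correlated. Exact m-value enumeration is capped at
20 studies. The rejection sampler's cost scales with 1/prevalence; rare
diseases (prevalence well below a few percent) make candidate generation the
dominant cost.
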