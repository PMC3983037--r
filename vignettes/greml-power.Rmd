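---
title: "Sampling variance and power for SNP-based (co)heritability estimates"
author: "gremlpower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling variance and power for SNP-based (co)heritability estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gremlpower)
```

## The model and why a closed form exists

GREML models a phenotype vector as $y = g + e$, where the covariance of
the genetic values among $N$ conventionally unrelated individuals is
$\sigma^2_g A$ with $A$ the SNP-derived genetic relationship matrix
(GRM).  The parameter of interest is the SNP heritability
$h^2_{SNP} = \sigma^2_g / (\sigma^2_g + \sigma^2_e)$, or, in a bivariate
analysis, the genetic correlation
$r_G = \sigma_{g12}/\sqrt{\sigma^2_{g1}\sigma^2_{g2}}$.  The REML
standard error comes from the inverse information matrix, which has no
closed form in an arbitrary sample.  In unrelated samples, however, the
off-diagonal relatedness values are tiny and REML is asymptotically
equivalent to an ordinary regression of pairwise phenotype products
$Z_{jk} = y_j y_k$ on pairwise relatedness $A_{jk}$ over the $N(N-1)/2$
contrasts (Haseman–Elston regression).  For standardized phenotypes the
residual variance of that regression is essentially
$\mathrm{var}(Z) \approx 1$, because the relatedness explains almost
none of it, so the slope's sampling variance collapses to

$$\mathrm{var}(\hat h^2) \approx \frac{2}{N^2\,\mathrm{var}(\pi)},$$

where $\mathrm{var}(\pi)$ is the variance of the off-diagonal GRM
entries.  Two properties follow and are tested as invariants: the SE
depends on the sample size but *not* on the heritability, and it scales
as $1/\sqrt{\mathrm{var}(\pi)}$.

**Assumptions.** Unrelated individuals (pairwise relatedness small and
centred on zero), standardized phenotypes, and a relatedness variance
that is a property of the population and SNP set rather than of the
sample.  Cryptic relatedness violates the first assumption and inflates
$\mathrm{var}(\pi)$; `empirical_var_pi()` therefore excludes pairs above
a relatedness cutoff of 0.025 by default, the conventional pruning
threshold for nominally unrelated samples.

## Parameters that matter

* `var_pi` — variance of off-diagonal SNP-derived relatedness.  Default
  `2e-5`, the theoretical value for genome-wide common SNPs in human
  populations (effective population size $\approx 10^4$).  It is an
  explicit argument of every formula because it genuinely varies: it is
  about $1/m$ for $m$ independent loci, smaller when rare SNPs are
  added, larger with cryptic relatedness or haplotype-based matrices.
  Measure it from data with `empirical_var_pi()` when a GRM is
  available.
* `K` (prevalence) and `v` (sample case proportion) — both must be
  supplied for case-control designs; they are independent design knobs
  (ascertainment fixes `v` regardless of `K`) and no default links
  them.
* `rp` — the phenotypic correlation, required in same-sample bivariate
  designs.  It has no defensible default: a common modelling choice is
  $r_P = r_G\sqrt{h^2_1 h^2_2}$ (no residual correlation), but because
  the result is sensitive to this choice the package refuses to guess
  and fails loudly when `rp` is missing.
* `alpha` (0.05), `target_power` (0.80) — the usual reporting
  conventions.

## The liability-scale transformation

Disease status is analysed on the observed 0/1 scale, where the
univariate variance formula applies unchanged with $N$ the total of
cases and controls.  Converting to the population-level liability scale
multiplies both the heritability and its SE by

$$c(K, v) = \frac{K^2(1-K)^2}{z^2\,v(1-v)} = \frac{(1-K)^2}{i^2\,v(1-v)},$$

with $z$ the standard-normal density at the threshold
$t = \Phi^{-1}(1-K)$ and $i = z/K$ the selection intensity.  At
$K = v = 0.5$, $c = \pi/2$.  The direction of the effect is worth
stating because it is easy to get backwards: at $v = 0.5$, $c$
*decreases* as the disease gets rarer and drops below 1 near
$K \approx 0.07$.  Oversampling cases of a rare disease concentrates
liability-scale information, so the liability SE shrinks and power
rises — e.g. the conversion factor for a 1%-prevalence disease in a
balanced study is $c \approx 0.552$, which is also the published ratio
between observed- and liability-scale heritability estimates for
schizophrenia.  Because the transformation is linear, the Wald
non-centrality parameter is identical on the two scales; power is
scale-invariant, which is asserted in the tests.

## Bivariate designs

For traits on *different* samples there is no residual covariance
between disjoint unrelated sets, so the genetic covariance
$\hat c$ (slope of the cross-set HE regression over all $N_1 N_2$
ordered pairs) has $\mathrm{var}(\hat c) = 1/(N_1 N_2 \mathrm{var}(\pi))$,
and a second-order Taylor expansion of
$\hat r_G = \hat c/\sqrt{\hat h^2_1 \hat h^2_2}$ gives

$$\mathrm{var}(\hat r_G) \approx \frac{1}{\mathrm{var}(\pi)}\Big[
  \tfrac{1}{h^2_1 h^2_2 N_1 N_2} + \tfrac{r_G^2}{2h^4_1 N_1^2}
  + \tfrac{r_G^2}{2h^4_2 N_2^2}\Big].$$

For traits on the *same* sample the package uses

$$\mathrm{var}(\hat r_G) \approx
  \frac{(1-r_G r_P)^2 + (r_G-r_P)^2}{N^2\,\mathrm{var}(\pi)\,h^2_1 h^2_2}.$$

This form has the two limits that older pedigree approximations
(Reeve–Robertson, Koots–Gibson) fail to respect simultaneously: it
reduces to $1/(N^2\mathrm{var}(\pi) h^2_1 h^2_2)$ for independent
traits, and it vanishes continuously (rather than spuriously collapsing)
as $r_G, r_P \to 1$.  It was validated three ways before adoption: a
$10^6$-draw Monte-Carlo delta-method oracle (run in the test suite at
$r_P = 0$ and equal heritabilities, where the component estimates are
uncorrelated and the independent-normal oracle is exact), full
simulation-plus-estimation replicates, and agreement with reported
standard errors from published analyses.  For independent traits the
same-vs-different efficiency ratio is simply $N_1 N_2/N^2$ — the ratio
of informative contrasts.

Case-control traits enter these formulas through their observed-scale
heritability; $\hat r_G$ itself is invariant to the linear liability
transformation, so no output conversion is applied.

## Power and minimum sample size

The Wald statistic $(\hat\theta/\mathrm{SE})^2$ is treated as
non-central $\chi^2_1$ with $\lambda = \theta^2/\mathrm{var}(\hat\theta)$;
power is $P[\chi^2_1(\lambda) > \chi^2_{1,1-\alpha}]$.  The plain
two-sided $\chi^2_1$ threshold is used (no one-sided boundary
correction for variance components): $\lambda \approx 7.85$ for 80%
power at $\alpha = 0.05$.  Because $\lambda \propto N^2$ univariately,
power grows quadratically in sample size.  `min_n_for_power()` solves
the monotone problem by bisection; the reported minimum is rounded up
to the next multiple of 100 by default (`ceil_100`), the convention
under which the canonical minimum sample sizes 8900/4500/3000/2300 for
$h^2 = 0.1\ldots0.4$ arise, and the unrounded integer solution is always
reported alongside (e.g. 2215 behind the rounded 2300).  For two-sample
bivariate designs the $N_2/N_1$ ratio must be fixed by the user — the
problem is otherwise underdetermined — and both samples are scaled
together.

## What the synthetic-data generator emulates

`simulate_genotypes()` draws allele frequencies uniformly (default MAF
0.05–0.5) and genotypes Binomial(2, p): Hardy–Weinberg and linkage
equilibrium, unrelated individuals.  Independent loci make
$\mathrm{var}(\pi) = 1/m$, so $m$ SNPs play the role that genome-wide
common SNPs play in real data and the whole verification loop is
self-contained at desk scale.  `simulate_trait()` draws causal effects
normal on the standardized genotype scale, rescales genetic values to a
*realized* variance of exactly $h^2$, and adds normal residuals with
variance $1-h^2$.  Genetic correlation is induced either by sharing a
fraction $r_G$ of causal variants with identical effects
(`shared_fraction`, the classical shared-architecture reading; the
fraction shared *is* the correlation) or by drawing effect pairs from a
bivariate normal (`correlated_effects`, which also covers negative
$r_G$).  Case-control data are produced by simulating a population pool
(`pool_mult` times the target sample, default `max(5, 2v/K)`),
thresholding liability at $\Phi^{-1}(1-K)$ and sampling cases and
controls without replacement — exact ascertainment by oversampling.

`run_replicates()` simulates the genotype panel (and hence the GRM)
once per run and redraws causal effects and residuals each replicate,
the same conditioning used in simulation studies on a fixed real
genotype panel; `new_genotypes = TRUE` regenerates genotypes per
replicate.  Per-replicate sub-seeds are drawn up front so any replicate
is reproducible in isolation.

**What it does not emulate:** linkage disequilibrium, rare-variant
architectures, cryptic relatedness, population stratification, or
non-normal residuals.  Passing verification therefore shows that the
closed forms are correct *under the model's own assumptions* — it says
nothing about, for example, LD-weighted GRMs, where
$\mathrm{var}(\pi)$ itself changes.

## Verification scale and results

The default harness runs $n = 2000$ individuals per sample,
$m = 10{,}000$ SNPs, 1000 causal variants and 100 replicates — a few
minutes end to end on one CPU — for univariate
$h^2 \in \{0.2, 0.5, 0.8\}$, same-sample $r_G \in \{0, 0.4, 0.8\}$ and
different-samples $r_G \in \{0, 0.4\}$.  The acceptance tests assert
unbiasedness (mean estimate within 3 SEM of the truth) and that the SD
of estimates across replicates is within 20–25% of the theory SE
evaluated at the *empirical* relatedness variance of the simulated GRM
(using $1/m$ blindly would conflate two sources of error; the package
reports both).  With 100 replicates the sampling error of the SD itself
is about 7%, so these bands are comfortably wider than chance while
still able to catch a mis-scaled formula.

## Numerical choices and edge cases

* Normal quantile/density and (non-)central $\chi^2$ probabilities come
  from R's standard double-precision implementations; no bespoke
  approximations.  Prevalences within $10^{-6}$ of 0 or 1 are rejected:
  $z/K$ is numerically fragile there and outside the regime the
  transformation is meant for.
* Heritabilities of exactly 0 are rejected wherever a formula divides by
  $h^2$; values below $10^{-3}$ warn, since the delta-method expansion
  degrades as the denominator estimate becomes noisy relative to its
  mean.
* HE fits are computed from closed-form moment sums ($O(N^2)$ memory-free
  passes over the GRM rather than materializing $N(N-1)/2$ contrast
  rows); the tests verify exact agreement (to $10^{-10}$) with a naive
  pair-expansion OLS.  The empirical slope SE uses the population
  ($1/n$) residual-variance convention consistent with the asymptotic
  formula.
* Negative heritability estimates propagate as an explicit
  `rg_defined = FALSE` flag; the correlation is never silently clipped.
* Monomorphic SNPs are dropped with a message; missing genotypes are
  handled per-pair complete-case with per-pair SNP counts, mirroring
  GCTA, so `n_snps` stays interpretable.
* Reported tables round to 3 decimals, matching the precision at which
  reference values are published; full-precision values are always
  available in the returned objects.

## Known limitations

The approximations are asymptotic in the number of contrasts and assume
the GRM's off-diagonal variance summarizes all the information; they are
not exact for small $N$, strong relatedness structure, or heritabilities
near the boundary.  The same-sample $r_G$ variance treats $r_P$ as
known.  Minimum-sample-size results for bivariate designs depend on the
assumed $r_P$ convention; published bivariate minimum-N figures are not
reproducible without knowing that convention, so the package reports
whatever follows from the user's explicit `rp` and makes no attempt to
match any particular published bivariate minimum.  Binary GCTA GRM files
and PLINK genotype formats are out of scope; the text GRM dialect is
supported because it is sufficient and auditable.
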