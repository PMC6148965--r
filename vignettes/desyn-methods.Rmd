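---
title: "DESyn: testing mean and dispersion jointly for syndrome RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DESyn: testing mean and dispersion jointly for syndrome RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DESyn)
```

## The problem

In a syndrome, different afflicted individuals express different
combinations of aberrant genes. For a gene involved in the syndrome, perhaps
one of four disease replicates is strongly shifted while the others look
normal: the group mean barely moves, but the disease-group variance — and
under a negative-binomial (NB) model, the dispersion — inflates. Methods
that test only the group-mean difference under an equal-dispersion
assumption are nearly blind to this pattern. DESyn instead tests the mean
and the dispersion simultaneously, then asks, gene by gene, *which* disease
replicates deviate.

## Model

Normalized counts are modelled as $Y_{gij} \sim \mathrm{NB}(\mu_{gi},
\phi_{gi})$ with $\mathrm{Var}(Y) = \mu + \phi\mu^2$, so $\phi = 0$ is the
Poisson limit. For each gene the screening statistic is the likelihood ratio

$$LR_g = 2\left\{\ell(\hat\mu_{g1}, \hat\phi_{g1}) +
\ell(\hat\mu_{g2}, \hat\phi_{g2}) - \ell(\hat\mu_{g}, \hat\phi_{g})\right\},$$

comparing group-specific fits against a single pooled fit, referred to
$\chi^2_2$. With 50 replicates per group this reference distribution is
accurate (the test suite checks a rejection rate of 3.5–6.5% at nominal 5%
on 2000 null genes); with 4 replicates it is only a screen, used to select
"null-like" genes, never to declare significance.

### Dispersion shrinkage

At $n = 4$ per group the dispersion MLE is very noisy. Each fitting context
(pooled, group 1, group 2) receives a genome-wide two-level normal working
model, $\hat\phi_g \mid \phi_g \sim \mathrm N(\phi_g, \tau^2_g)$ and
$\phi_g \sim \mathrm N(\phi_0, \tau^2_0)$, giving the posterior mean

$$\hat\phi^B_g = \frac{\hat\phi_g/\tau^2_g + \phi_0/\tau^2_0}
{1/\tau^2_g + 1/\tau^2_0},$$

floored at 0 because the normal prior admits negative values while the NB
model does not. $\tau^2_g$ is the inverse observed Fisher information of the
profile log-likelihood at the MLE. The hyperprior is estimated from all
genes by moments: $\phi_0$ is the mean of the per-gene estimates, and
$\tau^2_0 = \max\{0, \mathrm{var}(\hat\phi_g) - \mathrm{median}(\tau^2_g)\}$.

The **median**, not the mean, of the per-gene sampling variances is a
deliberate robustness choice. With few replicates the Fisher-information
variances are extremely heavy-tailed — genes with nearly flat profile
likelihoods contribute enormous (occasionally infinite) values — and a
mean-based noise correction is then dominated by that tail: it pushes
$\tau^2_0$ onto the zero boundary for some group labelings and not others.
Because the permutation null (below) re-estimates the hyperprior within
every relabeling, that on/off boundary behaviour shifts *every* gene's
statistic coherently within a relabeling and destroys the calibration of the
pooled null. The median-based correction keeps $\tau^2_0$ stably positive
across relabelings; with homogeneous sampling variances the two versions
coincide. Genes whose profile carries no curvature information at all
(infinite $\tau^2_g$) still contribute their point estimate to $\phi_0$ but
are shrunk fully to the prior mean.

### Pooled permutation test

Plugging the shrunken dispersions into the likelihood ratio (re-maximizing
only the means, which at fixed dispersion are the sample means) gives
$LR^B_g$. The plug-in breaks the nesting of the two models, so $LR^B_g$ can
be negative and is deliberately **not clipped**; its null distribution is
estimated empirically:

1. screen with the $\chi^2_2$ p-values; genes with $p \ge 0.1$ are
   *null-like* (the 0.1 default is exposed as `null_cutoff`);
2. enumerate the distinct unordered sample partitions of sizes
   $(n_1, n_2)$, excluding the observed labeling; when $n_1 = n_2$ a
   partition and its label swap are counted once, since the statistic is
   label-symmetric (34 partitions for 4 vs 4). Above `max_perms` (default
   200) a seeded uniform subsample is used;
3. for every permutation, refit all genes under the relabeled groups,
   re-estimate the group-context hyperpriors from all genes, and pool the
   null-like genes' $LR^{B(m)}_g$ values into one null distribution (the
   pooled context does not depend on the labeling and is computed once);
4. each gene's p-value is $p^B_g = (1 + \#\{v \ge LR^B_g\})/(L + 1)$, the
   add-one convention guaranteeing a valid, strictly positive permutation
   p-value.

Pooling across genes assumes the null-like $LR^B$ values are exchangeable
across genes — a modelling assumption, not a theorem; the global-null
calibration checks in the test suite measure how well it holds. Storey's
q-values (single $\lambda = 0.5$) convert $p^B$ to FDR-adjusted
significance; genes whose fit fails (an all-zero pseudo-group) are reported
`NA` and excluded from the multiple-testing denominator.

### Replicate classification

For each declared DE gene an equal-tailed NB interval is built from the
normal group's $(\hat\mu_{g1}, \hat\phi^B_{g1})$ by pmf summation. It is a
**prediction interval for a single new observation**, not a confidence
interval for the mean: individual disease counts are compared against it,
which a mean-CI could not support. The per-comparison level is Bonferroni
`fwer`$/n_2$ within each gene — the family is the gene's $n_2$ disease
replicates, since classification happens after the gene has already been
declared DE; `global_bonferroni = TRUE` switches to a genes × replicates
family for users who prefer the stricter reading. A DE gene may end up with
zero aberrant replicates; it is reported as such, not suppressed.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `filter_threshold` | 10 | discard genes with total raw count ≤ 10 across all samples, before normalization |
| `null_cutoff` | 0.1 | screening p-value bound defining null-like genes |
| `max_perms` | 200 | cap on label permutations; exhaustive for 4–6 per group |
| `fdr` | 0.05 | Storey q-value threshold for the DE list |
| `fwer` | 0.05 | family-wise level of the per-gene replicate classification |
| `phi_max` | 50 | upper bound of the dispersion search (dimensionless) |

TMM normalization follows the published defaults: the reference sample is
the one whose upper-quartile count (scaled by library size) is closest to
the mean upper quartile; genes zero in either compared column are excluded;
M-values are trimmed 30% and A-values 5% per tail; surviving M-values are
averaged with inverse delta-method variances; factors are centered to
geometric mean 1. Normalized counts are rescaled to the mean library size so
they stay count-like. Filtering is applied **before** TMM (the factors are
computed on the filtered genes); computing factors on unfiltered genes is a
defensible alternative that typically changes factors by well under 1%.

## Numerical choices

* **Optimization.** For fixed $\phi$ the NB score in $\mu$ vanishes at the
  sample mean, so every fit is a 1-D profile maximization over $\phi$ on
  $[0, 50]$ by deterministic golden-section search (tolerance $10^{-8}$),
  with the $\phi = 0$ (Poisson) endpoint checked explicitly. No random
  starts; identical inputs give identical fits.
* **$\tau^2_g$.** Central finite differences of the profile log-likelihood
  (step $10^{-4}$), one-sided at the $\phi = 0$ boundary, floored at
  $10^{-6}$; non-positive curvature yields $\tau^2_g = \infty$.
* **Counts.** Normalized counts are rounded to the nearest integer before
  likelihood evaluation, keeping the NB pmf exact; the gamma-function
  continuous extension was rejected as it changes the likelihood's meaning
  for no practical gain at count scales.
* **Degenerate inputs.** All-zero genes in a context are untestable (`NA`
  with a reason flag); a dataset where more than half the genes fail to fit
  under some relabeling aborts with a data-pathology error; an all-constant
  dataset yields an all-zero permutation null and p-values of 1.
* **Ties.** Empirical p-values count ties as exceedances; ROC curves group
  tied scores and integrate trapezoidally.

## The simulation framework

The generator emulates the study design used to characterize the method:
normal-group parameters $(\mu_{g1}, \phi_{g1})$ drawn from a pool, disease
group either identical in law (EE) or modified by scenario —

* **Scenario 1**: $\phi_{g2} = \phi_{g1} + X_\phi\delta_\phi$ in every
  disease replicate, $\delta_\phi \sim \mathrm{Beta}(2, 2)$, $X_\phi = 0.4$;
* **Scenario 2**: the same shift in only the last $k_g$ replicates,
  $k_g \sim U\{1, 2, 3, 4\}$;
* **Scenario 3**: $X_\phi = 0.3$ plus a mean shift
  $\mu_{g2} = \mu_{g1} + 2\,\delta_\mu\,\sigma_{g1}$ with
  $\delta_\mu \sim \mathrm{Beta}(2, 4)$ and $\sigma_{g1}$ the NB standard
  deviation of the normal group, computed from the pool parameters.

Studies 1–3 use an 80/20 EE/DE split; study 4 mixes 79% EE with the three
scenarios in equal 7% shares. Library sizes are equal by construction, so
simulated counts are treated as already normalized and TMM is skipped inside
simulation studies (a flag exposes the alternative).

The default **synthetic pool** draws $\log_{10}\mu \sim \mathrm N(2, 0.5^2)$
truncated to $\mu \ge 1$ and $\phi \sim \mathrm{Gamma}(2)$ with mean 0.15 —
chosen once as a plausible bulk RNA-seq profile spanning low-count to
highly-expressed genes. It is a documented stand-in: real data additionally
contain many highly expressed genes with very small dispersion, for which an
additive dispersion shift of 0.2 is a many-fold relative change and hence
far easier to detect. Power measured on the synthetic pool is therefore
conservative relative to an empirical pool of per-gene fits from real
normal-group counts (`build_parameter_pool` accepts such a table), and
passing tests on synthetic data demonstrate calibration, ordering and
machinery — not the absolute power attainable on real data. The generator
also does not emulate library-size variation, batch effects, gene-gene
correlation, or outlier contamination.

## Problem sizes used in the checks

The packaged checks run the study-1 design at 1000 genes (800 EE / 200 DE)
with 10 repetitions for each of 4, 5 and 6 replicates per group, a
1000-gene global-null calibration over 10 seeds, and the 2000-gene
$\chi^2_2$ calibration at 50 replicates per group — sizes chosen so the
whole battery runs on a laptop in a few minutes while leaving Monte-Carlo
standard errors well below the margins being asserted. Per-repetition seeds
are derived as `base_seed + repetition`, so every run is reproducible and
permutation subsampling, when triggered, is part of the seeded stream.

## Known limitations

* The pooled permutation null trades gene-wise exactness for feasibility at
  tiny $n$; heterogeneity across genes leaves mild miscalibration that the
  global-null KS checks quantify.
* With 4 vs 4 replicates only 34 distinct relabelings exist, so the null
  resolution per gene comes from pooling; a single gene's p-value can never
  be smaller than $1/(L+1)$.
* One grossly outlying disease replicate is indistinguishable from a
  genuine single-replicate aberration — under this model it *is* a
  dispersion signal; orthogonal evidence is needed to tell them apart.
* Two-group designs only: no covariates, no multi-group GLMs, no
  quasi-likelihood variance inflation.
* The normal prior on dispersions is a working model; its posterior mean is
  used as a point estimate and no posterior uncertainty is propagated.
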