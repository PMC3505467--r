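---
title: "A global hierarchical Bayesian model for differential protein expression in 2D PAGE"
author: "BayesPAGE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A global hierarchical Bayesian model for differential protein expression in 2D PAGE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BayesPAGE)
```

## The problem

Two-dimensional polyacrylamide gel electrophoresis (2D PAGE) separates
proteins by isoelectric point and molecular weight; after spot detection and
matching, a case–control experiment yields a spots × gels table of
intensities. Analysed on the log2 relative percent-volume scale, a value can
never exceed $\nu = \log_2(100) \approx 6.64$ (a spot cannot carry more than
100% of its gel), and a large fraction of cells are missing. Missingness has
two distinct causes that ordinary two-sample tests cannot separate: the
protein was not expressed in that individual, or it was expressed but below
the limit of detection $d$ (default $-8.67$ on the log2 percent-volume
scale). BayesPAGE models both causes explicitly and classifies spots as
differentially expressed (DE) either in mean intensity, in probability of
expression, or both.

## The two-layer model

**Local layer.** Each spot $s$ has four parameters: the control-group mean
intensity $\mu_s$; the case-minus-control difference $\delta_s$ (case mean
$\mu_s + \delta_s$); a logit-scale expression propensity $\kappa_s$ with
control expression probability $p_0 = \mathrm{logit}^{-1}(\kappa_s)$; and a
logit-scale difference $\tau_s$ with case probability
$p_1 = \mathrm{logit}^{-1}(\kappa_s + \tau_s)$. Both groups share one spot
standard deviation $\sigma_s$. An observed intensity
$c \in [d, \nu]$ contributes
$\rho_x \, \phi((c-\mu_x)/\sigma_s) / (\sigma_s \lambda)$, where
$\lambda = \Phi((\nu-\mu_x)/\sigma_s) - \Phi((d-\mu_x)/\sigma_s)$
renormalizes the truncated normal over the detection window; a missing cell
contributes the mixture $(1-\rho_x) + \rho_x \Phi((d-\mu_x)/\sigma_s)$ of
non-expression and censoring. The censored branch deliberately uses the
*untruncated* lower tail: as a consequence the two branches together carry
mass $1 + \rho_x\Phi((d-\mu_x)/\sigma_s)$ rather than exactly 1 — the
below-detection expressed mass is counted in both branches. We keep this
form because it is how the model is defined; the discrepancy vanishes as
$\mu_x$ moves above $d$ and the unit tests pin down the exact identity.

**Global layer.** Information is pooled across spots:
$\mu_s \sim N(\mu_g, \sigma_g)$, with the common spot standard deviation
tied to the global scale by $\sigma_s = \psi\,\sigma_g$;
$\delta_s$ follows an asymmetric Laplace law with rate $\lambda_\delta$ and
up-regulated weight $\phi_\delta$ (two exponential tails glued at zero, the
positive side carrying weight $\phi_\delta$); and
$\kappa_s \sim N(\mu_\kappa, \sigma_\kappa)$,
$\tau_s \sim N(\mu_\tau, \sigma_\tau)$. The priors are weakly informative:
$N(-3, 5)$ on $\mu_g$ (one of ~1000 equal spots is 0.1% of a gel,
$\log_2 0.1 \approx -3.3$), inverse-gamma(0.001, 0.001) on the variances
$\sigma_g^2, \sigma_\kappa^2, \sigma_\tau^2$, Uniform(0.001, 2) on $\psi$,
Exponential(1) on $\lambda_\delta$, Beta(2, 2) on $\phi_\delta$, and
$N(0, 3)$ on $\mu_\kappa, \mu_\tau$. The tight $N(0,3)$ reflects that
expression probabilities beyond $\approx 0.95$ ($\kappa \approx 2.94$) are
biologically indistinguishable from 1. Because the sampler walks on the
standard deviations, the variance-scale priors are evaluated as densities in
$\sigma$ (the $2\sigma$ change-of-variables factor is included); this is
what makes `jointLogPosterior()` an actual unnormalized density in the
reported coordinates.

## Posterior computation

All parameters are recovered by random-walk Metropolis–Hastings with three
mixing aids.

**Block updating.** Parameters are proposed jointly with one accept/reject
decision per block: per spot $(\mu_s, \delta_s)$ and $(\kappa_s, \tau_s)$;
globally $(\mu_g, \sigma_g)$, $(\lambda_\delta, \phi_\delta)$, $\psi$,
$(\mu_\kappa, \sigma_\kappa)$, $(\mu_\tau, \sigma_\tau)$, plus the three
expansion blocks below — eight global blocks in all.

**Parameter expansion.** Each mean/variance pair is linked by a redundant
multiplier: $\mu_g = \alpha_\mu \mu_g'$, $\sigma_g^2 = \alpha_\mu^2
\sigma_g'^2$ (likewise $\alpha_\kappa$, $\alpha_\tau$), each $\alpha$
carrying a Uniform(0.01, 10) prior and its own update block. The multiplier
lets the chain escape the sticky region near zero variance. Because the
natural-to-primed Jacobian depends only on $\alpha$, the pushforward of the
sampled posterior onto the natural scale is unchanged — the package's
`expand = FALSE` sampler targets the same posterior, and the test suite
verifies the two agree.

**Adaptive proposal scales.** Every 500 iterations during burn-in, each
block's proposal sd is rescaled by
$\Phi^{-1}(\rho_{opt}/2)/\Phi^{-1}(\rho_{cur}/2)$, with $\rho_{cur}$
averaged over a 3000-iteration window and clamped away from 0 and 1 by one
window count. Targets are $\rho_{opt} = 0.44$ for single-parameter blocks
and $0.234$ for multi-parameter blocks (both configurable). Adaptation is
frozen at the end of burn-in, so the retained chain is a fixed-kernel,
detailed-balance-respecting sampler; the trace records both the windowed
acceptance at the freeze point (what tuning controls) and the post-burn-in
rates.

**Proposal kernels.** $\lambda_\delta$ uses a lower-truncated normal and
$\phi_\delta$ a logit-scale normal walk, exactly with their Hastings
corrections (kernel-mass ratio and Jacobian respectively);
$\mu_s, \delta_s$ use symmetric normals scaled by the current $\sigma_s$;
$\kappa_s, \tau_s$ use symmetric normals scaled by a shrinkage-aware width
(prior precision $1/\sigma_\kappa^2$ or $1/\sigma_\tau^2$ plus a Bernoulli
information floor per informative gel). For the three mean/sd global blocks
we use a log-normal walk on the primed sd and a mean step proportional to
it, with the exact state-dependent Hastings correction, and for the $\alpha$
and $\psi$ blocks the truncated-normal step is normalized by the block's
natural-scale sensitivity. These scale-aware kernels replace fixed
absolute-scale steps because the posterior scale of the hierarchical
variance parameters moves over burn-in; with fixed scales, block acceptance
drifted far from target after tuning froze, while with them every
multi-parameter block settles near 0.234 and stays there. All state
quantities used for scaling are held fixed within their block, so each
kernel remains a valid MH proposal; supports ($\sigma \ge 0.01$,
$\psi \in [0.001, 2]$, $\alpha \in [0.01, 10]$) are enforced by rejection.

Initialization is moment-based: $\mu_s$ from the spot's observed mean
(fallback $-3$), $\delta_s = \tau_s = 0$, $\kappa_s$ from the logit of the
observed expression fraction clamped to $\pm 2.94$, globals by moments over
the locals, $\alpha = 1$, all proposal sds 0.5. A non-finite initial
posterior triggers one fallback to a generic in-support state. Local blocks
are swept in a fixed spot order, and the whole run is bit-reproducible given
`seed`. Cached likelihood terms are recomputed from scratch every 10,000
iterations and at every recorded state, so floating-point drift cannot
accumulate; the stored log posterior therefore always matches an independent
evaluation of `jointLogPosterior()`.

## Classification and diagnostics

After discarding the burn-in fraction (default 10%) of a thinned trace, a
spot is DE when the 95% highest posterior density interval of $\delta_s$
excludes zero (direction up/down by sign), when the 95% HPD of $\tau_s$
excludes zero, or both. HPDs are computed as the shortest window of
$\lceil 0.95 n \rceil$ consecutive order statistics — exact for unimodal
marginals, which is how these posteriors behave; ties take the lowest lower
bound. Effective sample sizes use initial-positive-sequence truncation of
the empirical autocorrelations, matching standard trace-analysis tools;
constant chains are flagged rather than given an infinite ESS. ESS above
~1000 per parameter is a useful quality bar, reported but not enforced.

## The univariate LRT baseline

The comparison method fits the same censored mixture to each spot in
isolation, with a free per-spot $\sigma_s$ — precisely the contrast with the
global model's pooled $\psi\sigma_g$ — and tests
$\delta_s = \tau_s = 0$ against a $\chi^2_2$ reference (two constrained
parameters; $\alpha = 0.05$). The likelihood surface of a censored mixture
is multimodal: a degenerate "everything expressed but censored" mode
($\mu \ll d$, large $\sigma$, $p \to 1$) can dominate the honest mode.
Optimization is therefore multi-start (a moment start, jittered copies, and
censoring-heavy starts), $\kappa, \tau$ are box-constrained to $|\cdot| \le
10$, and the full and null fits cross-seed each other's optima so that the
test statistic never reflects one model finding a mode the other missed.
Spots with no observed value at all sit on the $p \to 0$ boundary with log
likelihood 0 and are flagged, not tested. At 12 gels per group the
$\chi^2_2$ reference is still mildly anticonservative (empirically ~6–7%
at nominal 5% on null data) — a property of the asymptotics, not of the
implementation.

## The synthetic-data generators

`simPreset()` reproduces four validation designs: **sim1** — spot means
$N(-5, 1)$, spot sd 0.7, $\delta_s$ asymmetric-Laplace with
$\lambda_\delta = 0.5$, $\phi_\delta = 0.5$, $\kappa_s \sim N(1,1)$,
$\tau_s \sim N(0,2)$, limit of detection $-8.67$; **sim2** — uniform
propensity laws $\kappa_s \sim U(-1,3)$, $\tau_s \sim U(-2,2)$; **sim3** — a
smaller intensity gap (rate 0.7 by default; 0.66 is the equivalent
"1.5 × spot sd" reading and is settable) with $\tau_s$ split half/half
between $N(-3, 0.25)$ and $N(2, 0.25)$; **sim4** — the null,
$\delta_s = \tau_s = 0$ everywhere, for false-positive-rate studies at 12,
18 or 24 gels per group. Group sizes for sims 1–3 default to 12 + 12,
matching the 24-individual, one-gel-per-individual experiment the designs
emulate, and are configurable. Expressed
intensities are drawn conditional on not exceeding $\nu$ via the inverse
CDF — identical in law to redrawing impossible values, but guaranteed to
terminate even when a heavy-tailed $\delta_s$ pushes a case mean above
$\nu$ (such spots peg at 100% of the gel). Draws below $d$ are recorded
missing with a censoring indicator, so every missing cell is attributable
to exactly one cause and generator-level truth (including per-cell
expression and censoring) is available to score any classifier.

What the generators do *not* emulate: gel-to-gel normalization artefacts,
spot-matching errors, spatial warping, or spot-specific variances. Passing
tests on these data demonstrate correctness of the inference machinery
under the model's own assumptions, not robustness to violations of them —
in particular the equal-variance assumption, whose violation is the known
failure mode where the per-spot LRT can find spots the global model misses.

## Problem sizes and numerical choices

At full scale (100 spots and up), chains of tens of millions of iterations
are needed for comfortable mixing — around a day of compute per run. The
package's test suite and acceptance script therefore use reduced but
faithful problem sizes, chosen once from mixing diagnostics: recovery of
the five shared global parameters ($\mu_g, \sigma_g, \psi, \lambda_\delta,
\phi_\delta$) on sim1 with 60 spots and 600k iterations across five
seeds (minimum ESS ≈ 900); null behaviour on sim4 with 40 spots; and the
method comparison on 30 spots, where the global model flags at least as
many spots as the LRT and ≥90% of LRT calls are also global calls — the
full-scale printed counts are single-realization quantities and are not
re-run at desk scale. Other constants: log-space computation throughout
with a $10^{-300}$ floor on probability masses (never a division by zero);
$-\infty$ posteriors only ever compared at the MH accept step; HPDs require
≥20 samples; ESS requires ≥10.

## Using the package

```{r example, eval = FALSE}
sim <- simulateGels(simPreset("sim1", S = 20L), seed = 1)
gm  <- simGelMatrix(sim)                     # a GelMatrix
tr  <- runChain(gm, iterations = 2e5, thin = 200, seed = 1)
summarizeGlobals(tr)                         # means, 95% HPDs, ESS
cl  <- classifySpots(tr)                     # per-spot DE flags + direction
countClassifications(cl,
  otherSpots = with(lrtClassify(gm), spot_id[significant]))
```

Real data enter through `readIntensityTable()` (spots × gels TSV/CSV with
`NA` missing markers plus a gel→group design) or, from raw volumes,
`toRelativeLog2()`. `writeTrace()` emits a tab-delimited trace log readable
by standard MCMC trace viewers, and `densityExport()` produces the
plot-ready prior/posterior curves for the global parameters.

## Known limitations

Equal case/control variance and a single shared spot sd are model
assumptions, not options; unequal variances are known to impair convergence
of this sampler family. The asymmetric Laplace is a unimodal effect-size
law; strongly multimodal effect distributions are absorbed by inflating
$\sigma_\tau$ (as the two-component sim3 design shows) rather than resolved.
Chains for hundreds of spots need tens of millions of iterations to mix;
parallel or coupled chains are out of scope here beyond independent seeds.
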