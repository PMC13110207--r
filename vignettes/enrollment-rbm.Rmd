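---
title: "Enrollment-centric site risk scoring: models and methods"
author: "rbmscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enrollment-centric site risk scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbmscore)
```

## The problem

Centralized risk-based monitoring (RBM) of multicenter clinical trials
tracks operational key risk indicators per site, but the enrollment
process itself — who gets screened, who gets enrolled, and how
eligibility thresholds are applied — is rarely audited quantitatively.
Sites under recruitment pressure may admit participants whose
eligibility values sit just inside the protocol threshold; sites with
inconsistent assays or practices show shifted eligibility-value
distributions or drifting screen-failure reasons. These are
*distributional* phenomena: they are visible in the shape of per-site
data long before they appear in conventional deviation counts.

`rbmscore` scores each site on six enrollment-integrity indicators and
fuses them into a single posterior risk score with full uncertainty,
so that escalation decisions can be proportionate to both the size and
the certainty of a signal.

## The indicators

For site $s$, with the protocol threshold $\tau_{lab}$ (e.g. creatinine
clearance 60 mL/min):

| indicator | definition | likelihood | transform |
|---|---|---|---|
| `bii` | enrolled values in the closed band $[\tau_{lab}-\delta,\ \tau_{lab}+\delta]$, out of enrolled assessed | Binomial | logit |
| `fail_rate` | screen failures / screened | Binomial | logit |
| `window` | window-period violations / enrolled | Binomial | logit |
| `duration` | median of log screening times (days) | Normal | identity |
| `edd` | two-sample distance between the site's eligibility values and the pooled values of *other* sites | log-Normal | log |
| `sfps` | binary flag: has the composition of screen-failure reasons shifted between the earlier and later half of the periods? | Bernoulli | logit |

All indicators point in the higher-is-risk direction by construction
(violations are counted rather than adherence). The borderline
half-width $\delta$ is a protocol-level choice in the units of the lab
value; it defaults to 5% of $\tau_{lab}$ because the band is meant to
be "narrow and clinically meaningful" relative to the threshold. The
distance defaults to the exact two-sample Kolmogorov–Smirnov statistic
(the distance itself, not a test); the energy distance
$2\,E|X-Y| - E|X-X'| - E|Y-Y'|$ is available where sensitivity to
variance and shape differences matters. The drift detector is a
deliberately simple two-window Pearson chi-square on the pooled
earlier/later reason table at level $\alpha = 0.05$; richer sequential
detectors (CUSUM, multiple break-point models) are out of scope.

The optional `cmg` indicator (exclusions attributable to criteria that
modern guidance considers unnecessarily restrictive) is
benchmark-referenced: Stage 1 centers its logit posterior at
$\mathrm{logit}(\rho_0)$, so sites excluding more than the expected
proportion $\rho_0$ carry positive risk.

## The three-stage composite

**Stage 1 — posteriors per indicator.** Proportions get conjugate Beta
updates, $\pi \mid y, n \sim \mathrm{Beta}(1+y,\ 1+n-y)$, drawn and
mapped to $\mathrm{logit}(\pi)$; the flat prior's two pseudo-counts
keep logits finite at $y \in \{0, n\}$ and shrink small sites toward
one half. The binary drift flag gets the same update with $n = 1$. The
duration and distance statistics have no convenient conjugate form, so
they are bootstrapped (resample with replacement, same size, both
samples independently for the distance), with the distance clamped at
$10^{-6}$ before the log. Each (site, indicator) pair draws from its
own RNG substream derived from the master seed, so adding or removing
a site never perturbs the other sites' draws.

**Stage 2 — robust standardization.** Site-level posterior means act
as anchors per indicator; across sites the center is their median and
the scale is $1.4826 \times \mathrm{MAD}$ (consistent with the SD
under normality), falling back to the SD when the MAD is zero and to 1
(with a warning) when both are. Every draw is standardized with the
same affine map, yielding unitless risk z-scores.

Anchors are computed *analytically* where a closed form exists
($E[\mathrm{logit}\,\pi] = \psi(a) - \psi(b)$ for Beta posteriors,
with $\psi$ the digamma function) and as empirical draw means for the
bootstrap indicators. This is not cosmetic: all non-drifted sites share
literally the same Beta posterior for the drift indicator, so their
anchors tie exactly and the MAD is exactly zero, which correctly
triggers the SD fallback. Empirical draw-mean anchors would differ by
Monte-Carlo jitter of order $M^{-1/2}$, the MAD would be that jitter,
and the drift indicator would dominate the composite by two orders of
magnitude — an artifact, not a signal.

**Stage 3 — composite.** Per draw $m$,
$$S_s^{(m)} = \sum_k w_k\, z_{ks,\mathrm{std}}^{(m)},\qquad w_k \ge 0,\ \sum_k w_k = 1,$$
with two alternatives: the softmax
$S^{(\lambda)} = \lambda^{-1}\log \sum_k \exp(\lambda w_k z_k)$
("OR-leaning", emphasizing any single extreme indicator) and the
geometric mean $\prod_k (c + z_k)^{w_k} - c$ ("AND-leaning",
rewarding consistency; it errors loudly when $c + z \le 0$ rather than
silently clamping). Two analytic facts are worth recording because
they are easy to get wrong: $S^{(\lambda)}$ is *nonincreasing* in
$\lambda$ and converges to $\max_k w_k z_k$ from above; it is **not**
in general bounded below by the linear composite (take all $z_k$ equal
and positive and $\lambda$ large). The property tests assert the
correct bounds.

Weights can be fixed (auto-normalized), sampled from a
$\mathrm{Dirichlet}(\alpha)$ prior encoding critical-to-quality
priorities (weight draw $m$ multiplies score draw $m$), or derived
from the data as dispersion-rewarding weights proportional to the MAD
of each indicator's anchors — the package's concrete rendering of
"reward indicators with higher cross-site dispersion"; a formula had
to be fixed and MAD-proportionality is the robust choice consistent
with Stage 2.

Summaries per site: posterior mean, equal-tailed 95% credible interval
(the interval type is a package choice; nothing downstream depends on
it), $\Pr(S > \tau)$, and $\Pr(\text{Top-}K)$ from per-draw descending
ranks. Rank ties within a draw are broken by site order so that runs
are bit-reproducible.

## Flagging

The dual-key rule flags site $s$ only when
$\Pr(S_s > \tau \mid \text{data}) > p^\*$ *and* the posterior-mean
standardized score of an operational corroborator (default
`fail_rate`) strictly exceeds a cut $c$ (default 0.5). Both keys are
reported for every site as an audit trail. The Bayesian FDR of a flag
set $\mathcal F$ is $|\mathcal F|^{-1}\sum_{s \in \mathcal F}
\Pr(S_s \le \tau \mid \text{data})$ — the posterior expected
false-discovery proportion — and `calibrate_policy()` picks, among
grid points whose flag set satisfies $\widehat{\mathrm{FDR}} \le q$,
the one flagging the most sites (ties toward larger $p^\*$). Because
every flagged site satisfies key 1, the estimated FDR of a dual-key
set can never exceed $1 - p^\*$; this algebraic bound is asserted in
the test suite. The corroborator cut is applied to the posterior-mean
standardized score rather than to a posterior probability; both
quantities are exported, so users preferring a probability-form second
key can apply it directly.

## The latent-factor model

The two-stage composite treats indicators independently. The
one-factor hierarchical model instead links them through a latent site
risk $R_s \sim N(0,1)$:

- binomial layers: $y_{ks} \sim \mathrm{Binom}(n_{ks},
  \mathrm{logit}^{-1}(\eta_{ks}))$, $\eta_{ks} \sim N(\beta_{k0} +
  \beta_k R_s,\ \sigma_{k\pi}^2)$;
- normal layers (median log duration, log distance): $x_{ks} \sim
  N(\mu_{ks}, \sigma_{k,\mathrm{obs}}^2)$, $\mu_{ks} \sim
  N(\gamma_{k0} + \gamma_k R_s,\ \sigma_{k\mu}^2)$;
- drift layer: $m_s \sim \mathrm{Bern}(\mathrm{logit}^{-1}(\delta_0 +
  \delta R_s))$, with no residual term — the drift layer is kept
  exactly as stated, linking the flag to $R_s$ deterministically on
  the logit scale.

Priors: intercepts $N(0, 5^2)$, loadings half-normal $N^+(0,1)$
(nonnegative, so higher $R_s$ always means higher risk and no sign
flip exists; location and scale of $R_s$ are fixed by its standard
normal prior), scales Half-Cauchy(0, 1).

**Sampler.** Metropolis-within-Gibbs with conjugate draws wherever the
conditional is exact: latent $\mu_{ks}$, intercepts, and the
nonnegative Gaussian-layer loadings (truncated normals); random-walk
Metropolis for $\eta_{ks}$ (three cheap vectorized sweeps per
iteration to loosen the $\eta$–$R$ coupling), log-scale proposals for
all scale parameters, and Bernoulli-layer parameters by scalar
Metropolis. The full conditional of $R_s$ is Gaussian except for the
drift layer, so $R_s$ is proposed from that exact Gaussian and
Metropolis-corrected only for the Bernoulli factor — exact Gibbs when
the drift layer is absent. Proposal scales adapt toward 44% acceptance
during warmup only. Split-$\widehat R$ and a crude
initial-positive-sequence effective sample size are reported for every
parameter; any $\widehat R > 1.1$ raises a prominent warning and marks
the fit non-converged, never silently.

Two caveats, verified rather than assumed. First, with one observation
per site the two scales of a normal layer
($\sigma_{k,\mathrm{obs}}, \sigma_{k\mu}$) are only jointly
identified; their individual chains mix slowly along the ridge and may
show elevated $\widehat R$ even when $R_s$ and the loadings are well
behaved. Second, "prior recovery" is subtler than it sounds: when data
are generated with zero loadings, the *estimated* nonnegative loadings
still absorb spurious cross-layer correlation at small $S$, so the
posterior SD of $R_s$ sits visibly below 1 (about 0.7–0.9 at five
sites). The test suite pins the sampler against an independent JAGS
fit of the identical model, which reproduces the same spread, and
checks calibration globally by simulation-based calibration (rank
statistics of prior-drawn parameters uniform across 60 prior-predictive
replicates of a 2-indicator, 10-site model).

The model-based composite standardizes the risk-aligned latent
contributions ($\eta_{ks}$ for proportions, $\mu_{ks}$ for log-times
and log-distances, $\delta_0 + \delta R_s$ for drift) by robust
trial-level centers and scales — the median and $1.4826 \times
\mathrm{MAD}$ of the site posterior-mean contributions, mirroring
Stage 2, since no closed form is prescribed — and sums them with
simplex weights, yielding a per-site posterior distribution summarized
exactly like the two-stage composite.

## The simulator

`simulate_trial()` generates a multicenter trial with known atypical
sites: per site, screened count $\sim$ DiscreteUniform(20, 100);
eligibility values $N(80, 15)$ against threshold 60 mL/min, with 10%
of sites atypical and their site mean shifted by $-12$ (toward the
threshold, inflating borderline inclusions and distributional
divergence); screening durations log-normal with median 7 days and
log-SD 0.4 (read as the log-scale location $\log 7$, so the documented
"30% higher median durations" of atypical sites is the clean
log-location shift $\log 1.3$); window violations
$\mathrm{Binom}(n_{\mathrm{enr}}, 1 - \theta_s)$ with $\theta_s \sim
U(0.80, 0.95)$.

Where the reference conditions leave parameters open, the package
fixes them once: screen failures combine the eligibility channel (lab
$\le 60$) with an independent non-lab channel whose site-level
probability is Beta with mean $\sim U(0.10, 0.40)$ and concentration
20; drift-flag probabilities are 0.05 for typical and 0.50 for
atypical sites; the borderline half-width is $\delta = 5$ (band
[55, 65]); and `n_bii` equals the enrolled count. All of these are
config knobs.

What the simulator does *not* emulate matters for interpreting green
tests: real trials have persistent site-level heterogeneity in
duration medians, lab means and drift behavior even among unremarkable
sites, plus calendar-time accrual dynamics, regional structure and
informative missingness. In this generator, typical sites carry a
persistent identity only through their screen-failure and
window-adherence parameters; BII, EDD, duration and the drift flag are
exchangeable noise for them. Consequently, cross-replicate rank
stability of the full composite is structurally moderate here, and a
passing simulation suite says nothing about, for example, robustness
to assay batch effects.

## Evaluation harness

`run_replicates()` repeats simulate → score → classify against the
known labels and aggregates sensitivity, specificity and FDR
($FP/\max(TP{+}FP, 1)$; an empty flag set counts as FDR 0, and
sensitivity is reported as undefined under a null generator) with
Monte-Carlo standard errors. A site is classified atypical when its
posterior mean composite exceeds $\tau = 1.5$; thresholding the
exceedance probability instead is a config option. "Ranking accuracy"
is reported two ways: mean pairwise Spearman correlation of
posterior-mean rankings across replicates of a *fixed* site
configuration (participant data redrawn each replicate), and the
probability that all truly atypical sites rank within the top
$2\times$ their count.

Problem sizes used by the shipped checks: the test suite runs the
operating characteristics at 100 replicates of the 50-site
configuration with 1000 posterior draws, rank stability at 50
replicates, latent-factor recovery at 50 sites with 200 observations
per site, and simulation-based calibration at 60 replicates of a
10-site model; the acceptance script rewinds the operating
characteristics at 500 replicates. These sizes give Monte-Carlo
standard errors well under the decision tolerances while keeping a
full run on one core in the minutes range.

## Numerical choices and degenerate inputs

- Distance floor $10^{-6}$ before the log; bootstrap draws of a zero
  distance all land exactly at $\log 10^{-6}$.
- Even-length medians are the midpoint of the central pair, on the log
  scale for durations.
- Sites whose denominators make an indicator undefined are dropped
  from scoring with a logged warning, never imputed.
- Single-site standardization and empty EDD pools are errors with
  instructive messages, not silent NAs.
- The bootstrap inner loops (KS/energy distance, median-of-log) are
  compiled; resamples are represented as multiset counts over the
  pre-sorted support, so one KS bootstrap draw costs $O(n + m)$ with
  no per-draw sorting, and the generator is a deterministic splitmix64
  stream seeded from R's RNG so `set.seed()` fully reproduces runs.
- Chi-square drift statistic is the closed-form Pearson statistic
  (no continuity correction), cross-checked against
  `chisq.test(correct = FALSE)` in the tests.

## Known limitations

Indicator posteriors in the two-stage pipeline are independent across
indicators (the latent-factor model is the remedy when dependence
matters). The EDD accepts one laboratory variable at a time. The drift
detector is binary and two-window. Weights are user governance
choices; nothing in the package learns them from audit outcomes. The
normal-layer variance split in the latent model is weakly identified
at one observation per site. Operating characteristics quoted anywhere
are properties of the simulator's study conditions, not of any real
trial.
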