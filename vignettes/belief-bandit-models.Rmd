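---
title: "Cognitive models of two-armed bandit reversal learning and their dopamine signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cognitive models of two-armed bandit reversal learning and their dopamine signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beliefbandit)
```

## The task and the scientific question

In the probabilistic reversal task implemented here (a two-armed bandit,
2ABT), a mouse pokes a center port to initiate a trial and then chooses a
left or right reward port. One side is "correct" at any moment: a correct
choice pays out with probability $\rho_1 = 0.75$, the other side pays
nothing. After the animal has earned a block's worth of rewards — a
target drawn uniformly from 7 to 23 — the rewarded side reverses without
any cue. Because rewards are probabilistic, a single omission is
ambiguous: it may be bad luck within the block, or the first sign of a
reversal. The scientific question the package addresses is *which
trial-by-trial learning computation best explains choices in this regime,
and whether the same computation is reflected in outcome-locked dopamine
release* (dLight photometry in the nucleus accumbens core).

The package provides: the generative task and agent simulators
(`task_config()`, `simulate_agent()`), ten cognitive agents under one
choice policy (`bb_models()`), maximum-likelihood fitting and AIC
comparison (`fit_agent()`, `aic_compare()`), a
simulate/cross-fit/confusion protocol (`identification_study()`,
`parameter_recovery()`), trial-history behavioural statistics
(`stay_probability_by_2history()`, `switch_probability_by_history()`, and
friends), photometry preprocessing (`preprocess_photometry()`), and the
RPE-to-dopamine regressions with cross-validated arbitration
(`cv_llk_compare()`, `build_lagged_design()`).

## Models

Every agent maps a value difference $D_t$ between the right and left
port into a choice probability through the same policy,

$$P(c_t = 1) = \sigma(\beta D_t + \phi\, c_{t-1}),$$

with inverse temperature $\beta$ and stickiness $\phi$ (the perseveration
bias toward repeating the previous choice; the term is dropped on the
first trial of a session). What differs is how $D_t$ is maintained.

**Q-learning family.** `RL4p` updates the chosen value by
$\Delta Q(c) = \alpha_t \delta_t$ with $\delta_t = r_t - Q_t(c_t)$ and an
asymmetric rate ($\alpha_+$ for $\delta \ge 0$, $\alpha_-$ otherwise).
`RLCF` additionally pushes the unchosen value toward the counterfactual
outcome via $\tilde\delta_t = 1 - r_t - Q_t(-c_t)$, using the same trial
rate. `RLFQ3p` instead *forgets* the unchosen value,
$Q_{t+1}(-c_t) = \zeta\, Q_t(-c_t)$, with $\zeta$ tied to the learning
rates as $\zeta = 1 - (\alpha_+ + \alpha_-)/2$ and no stickiness term —
forgetting itself produces perseveration. With symmetric rates this model
is *exactly* the `RFLR` recursion
$D_{t+1} = e^{-1/\tau} D_t + \alpha\, r_t c_t$ under
$e^{-1/\tau} = 1 - \alpha$, an identity the test suite checks to 1e-10.
(The $\zeta$ convention is genuinely ambiguous in the source material;
the package adopts the reading that preserves this equivalence and
exposes the alternative through `zeta_convention = "mean"`.)

**Dynamic learning rates.** `RL_meta` adapts its negative learning rate
to *unexpected uncertainty* $\nu_t = |\delta_t| - \omega_{t-1}$, where
$\omega$ is a running (rate $\alpha_\nu$) estimate of $|\delta|$:
when $\delta_t < 0$,
$\alpha^-_t = \psi(\nu_t + \alpha^-_0) + (1-\psi)\alpha^-_{t-1}$. The
update order is $\delta \to \nu \to \alpha^- \to \omega \to Q$, which
resolves the circular reference in the source description
($\nu$ is used before it is defined there). The adapted rate is clamped
to $[0, 1]$: non-negativity is stated by the source; the upper cap is
this package's choice so that values remain inside the reward range and
prediction errors inside $[-1, 1]$. `PearceHall` instead scales both
rates by an associability $\alpha_\nu \leftarrow \alpha_\nu +
\psi(|\delta_t| - \alpha_\nu)$ (the refreshed value is used in the same
trial's Q step, following the source's equation order), and decays the
unchosen value toward the initial value $Q_0 = 0.5$. Its parameter table
in the source omits $\beta$ and $\psi$; because the common policy
requires a $\beta$ and the associability update requires a $\psi$, both
are treated as free parameters here.

**Belief-state family.** The Bayesian agents track the posterior
probability $b_t$ that the right side is currently correct, via the
two-state HMM forward recursion: multiply the prior by the reward
likelihood (with assumed probabilities $\rho_1 = 0.75$ and
$\rho_2 = 10^{-4}$; the latter is kept slightly positive so the filter
never collapses under model misspecification), normalize, then apply the
symmetric transition with switch rate $q$. `BIfp` uses $D_t = 2b_t - 1$
directly. The hybrid `BRLfwr` computes
$Q(c) = w_1 b(c) + w_2 b(-c)$ and learns $w_1$ by the
confidence-weighted gradient step $\Delta w_1 = \alpha \delta_t b(c_t)$
($w_2$ stays pinned at $\rho_2$; `BRLfw` and `BRLwrp` relax this).
With $\alpha = 0$ the hybrid collapses onto `BIfp` exactly, up to the
reparameterization $\beta_{\mathrm{BI}} = \beta_{\mathrm{BRL}}
(\rho_1 - \rho_2)$, because the two value differences differ by that
constant factor; the equivalence test applies this exact mapping.

All agents initialize Q-values at 0.5 (the midpoint of the reward range;
the source is silent), beliefs at 0.5, and reset latent state at session
boundaries, since sessions are separate behavioural days. Agents without
an explicit prediction error (`RFLR`) refuse to emit one; `BIfp` emits a
*pseudo-RPE*, observed minus belief-weighted expected reward.

## Fitting and model comparison

`negative_log_likelihood()` runs an agent across all sessions of a
subject (state resets per session; missed trials are skipped without a
state update; choice probabilities floored at $10^{-12}$).
`fit_agent()` performs multi-start bounded L-BFGS-B over the natural
parameter scale; starts are drawn from the initialization distributions
used in the original analysis (uniform for rates, $\Gamma(2, 0.2)$ for
stickiness, $\mathrm{Exp}(1)$ for $\beta$ and the RFLR scales,
$\mathcal N(0,1)$ for the RFLR stickiness, $\mathrm{Unif}(0, 0.05)$ for
$q$) and nested in the seed so that adding starts can only improve the
optimum. Bounds: rates in $[0,1]$, $\beta \in [0, 50]$,
$\phi \in [0, 10]$ ($[-10, 10]$ for RFLR, where $\beta \equiv 1$),
$q \in (0, 0.5]$, $\tau \in [0.05, 100]$. Model comparison uses
$\mathrm{AIC} = 2k - 2\log L$ reported relative to `RL4p`
(`aic_compare()`); `around_switch_loglik()` restricts the summed
likelihood to the first five trials after each reversal while letting
latents evolve everywhere, reusing the globally fitted parameters (the
source does not say whether it refit on the subset; reusing global fits
is the conservative reading and is documented here).

## Identification protocol and its study conditions

`identification_study()` draws generating parameters uniformly from
per-model ranges, simulates sessions, fits every candidate, and
tabulates the AIC winner (ties broken by parsimony, then name). The
original analysis drew from the empirical range of its mouse fits, which
are not deposited; `default_param_ranges()` therefore ships plausible
ranges chosen once around the values the study reports — standard-RL
learning rates 0.5–0.95 (the reported subject means are $\alpha_+
\approx 0.85$, $\alpha_- \approx 0.73$), $\beta$ 1–4 for value scales
near 1 and 2–8 for the belief models (whose $D \in [-1,1]$), stickiness
0.1–1.5, and belief switch rates 0.01–0.08 bracketing the task's
effective reversal rate of roughly one block per 25 trials. These are
free settings of the study, not fitted quantities.

Desk-scale defaults are deliberately smaller than the original
1000-iteration protocol: 100 iterations, 5 × 500 trials for parameter
recovery, and 2 × 500 trials with two optimizer starts for the 8 × 8
confusion study. At these sizes the qualitative structure is stable: the
Bayesian pair (`BIfp`, `BRLfwr`) is mutually confusable but cleanly
separated from `RL4p`, and the complex RL models form their own
confusable cluster — the task discriminates *between* families, not
within them. Recovery correlations for the 3–4-parameter models are high at these
sizes (typically 0.85–0.98; the positive learning rate of `RL4p` is the
weakest, near 0.7, since with frequent rewards the chosen value saturates
and large $\alpha_+$ values become interchangeable). The
7-parameter dynamic-learning
models (`RL_meta`, `PearceHall`) recover $\beta$ and $\phi$ well but
their learning-rate parameters are structurally confounded (the
associability multiplies the rates; only products are well constrained),
so their truth-estimate correlations sit well below the 0.7 bar that the
simpler models clear — consistent with the poor identifiability the
original study itself reports for its most complex model.

## Behavioural statistics

Trial-history encodings follow the field's conventions: the two-outcome
stay analysis (`RR`/`RU`/`UR`/`UU`) conditions on the same port having
been chosen at $t-2$ and $t-1$ (the qualifying rule applied here; the
port of those trials is the reference), and the three-trial code over
`{A, a, B, b}` takes the port at $t-3$ as reference, uppercase for
rewarded. Block-switch alignment defines offset 0 as the first trial
under the new contingency. History windows never cross session
boundaries. The history logistic designs provide both the decaying
choice-reward-interaction form and the reward-blocking variant that
splits lag-$i \ge 2$ interactions by whether trial $t-1$ was rewarded;
the lag-1 reward and choice main effects are retained in the blocking
variant (the source formula is ambiguous on this point; including them
nests the simpler model).

## Photometry and the RPE-dopamine link

Preprocessing mirrors standard dLight practice: per-channel baselining
by adaptive iteratively reweighted penalized least squares (Whittaker
smoothing with a second-difference penalty and weights that ignore
points above the running baseline), robust Huber regression of the
isosbestic 415 nm channel onto the 470 nm channel with subtraction of
the fit, and per-session z-scoring. The default penalty
$\lambda = 10^8$ at 20 Hz (smoothing length about 5 s) suits
bleaching trends of real recordings; the synthetic-recovery tests use
$\lambda = 10^{10}$ (about 16 s), matched to the minutes-scale
exponential bleach the generator injects — with fast negative
transients in the signal, too flexible a baseline chases the lower
envelope and erodes reward-omission dips. Trial filters are inclusive
thresholds (`center_dur` ≤ 0.8 s, `port_dur` ≤ 6 s, `MVMT` ≤ 3 s,
`SO_lat` ≤ 1 s); the side-out-latency threshold follows the source's
formula rather than its prose (which contradicts itself), and both are
configurable.

The synthetic dopamine generator writes the per-trial summary
`da_pt` as a sign-split linear function of the generating model's RPE
plus port-duration terms and Gaussian noise — exactly the structure of
the arbitration regression — and the continuous-trace generator
(`simulate_photometry()`) embeds RPE-scaled transients, a shared motion
artifact and channel-specific bleach at 20 Hz. What these synthetic data
do *not* emulate: hemodynamic-like slow drifts correlated with
behaviour, sensor nonlinearity and saturation, movement artifacts that
differ between channels, or session-to-session expression changes.
Passing the recovery tests therefore shows the pipeline is correct and
well-conditioned in its assumed regime, not that real recordings meet
those assumptions.

Arbitration (`cv_llk_compare()`) fits the Gaussian regression
`da_pt ~ rpe:sign + port_dur:sign + ego_action + session_num +
log(MVMT) + log(center_dur)` per candidate RPE set on a shared random
70–30 split and compares held-out summed log-likelihood against the
`RL4p` baseline; the split is per-subject with a recorded seed, and log
covariates are floored at 1 ms. The lagged design counts rewards at the
currently chosen (`R_chosen`) and opposite (`R_unchosen`) port over the
past 4 trials, interacted with switch/stay; the fixed-effects path is
plain OLS (appropriate for single-subject synthetic data) and the
hierarchical path delegates per-subject random slopes to `lme4`.

## Worked example

```{r, eval = FALSE}
theta <- c(beta = 5, phi = 0.8, q = 0.045)
sim <- simulate_agent("BIfp", theta, task_config(n_trials = 1000),
                      sessions = 5, seed = 1)
fits <- lapply(c("RL4p", "RLCF", "BIfp", "BRLfwr"), function(m) {
  fit_agent(sim, m, n_starts = 5, seed = 1)
})
aic_compare(fits, baseline = "RL4p")
```

On belief-generated sessions the Bayesian models win the AIC comparison
by a wide margin and the fitted `q` lands near its generating value; the
README shows actual printed output of this analysis.

## Numerical choices and limitations

Beliefs are propagated in linear space (two states; $\rho_2 > 0$
guarantees a positive normalizer). Likelihood floors, optimizer bounds
and tie-breaks are described above; all state is double precision.
Deterministic reproducibility is guaranteed by deriving one RNG
substream per session from `(seed, session)` and one per optimizer
start from `(seed, start)`.

Known limitations: no hierarchical (across-subject) fitting — each
subject is fit independently; no Bayesian posterior inference over
parameters; the environment offers no missed-trial generation by
default (missed trials are supported by the data model and skipped by
the likelihood); and the dynamic-learning models' rate parameters are
weakly identified at realistic data sizes, so conclusions about those
specific parameters should rest on the confusion study rather than
point estimates.
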