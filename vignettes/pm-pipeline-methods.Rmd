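---
title: "Models and methods behind the pmkinetics pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the pmkinetics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmkinetics)
```

## The data and the problem

Phenotype MicroArrays (PMs) measure cellular respiration on 96 distinct
substrates at once: each well of a microplate couples a substrate to a
tetrazolium dye whose reduction, driven by respiration, produces a colour
signal read at regular intervals (typically every 15 minutes for about
48 hours). The time series of one well is a *metabolic profile*. Three
questions recur in every PM study:

1. **Grouping** — on which substrates is the organism metabolically
   *active* (a positive, saturating signal) and on which is it
   *non-active* (no signal beyond a drifting baseline)?
2. **Normalization** — replicate plates of the same condition often show
   systematic, plate-wide signal shifts (array effects, from plate or
   inoculum quality); these must be removed before conditions can be
   compared.
3. **Effect identification** — when conditions are a two-factor design
   (say, strain x temperature), which substrates respond to each factor,
   and is there an interaction?

`pmkinetics` answers these with a model-based pipeline built around two
kinetic models per well.

## Kinetic models

An active profile is described by a three-parameter logistic curve

$$F(t) = \frac{Asym}{1 + \exp\!\big((xmid - t)/scale\big)},$$

where $Asym$ is the asymptotic signal, $xmid$ the time at which the
signal reaches $Asym/2$, and $scale$ the inverse of the maximum growth
rate. A non-active profile is a line $F(t) = b_0 + b_1 t$. Both are
fitted by least squares (Levenberg–Marquardt damped least squares via
`minpack.lm`); fitted values below zero are truncated to zero, since a
negative metabolic signal is not biologically meaningful.

Numerical choices, all of which the original description leaves open:

* **Starting values** for the logistic fit use a self-starting
  heuristic: $Asym_0 = \max(signal)$, $xmid_0$ = the first
  half-maximum crossing, $scale_0$ = half the 25%–75% rise time,
  floored at one grid step. When several profiles are pooled the
  heuristic works on per-time-point means.
* **Failure** of the logistic fit is defined as optimizer
  non-convergence (200 iterations, parameter tolerance 1e-8),
  non-finite estimates, or $\widehat{Asym} \le 0$. On failure the
  linear model is fitted instead (the *linear fallback*), so every
  profile always has a fitted curve. $scale$ is not sign-constrained,
  so decreasing profiles remain representable.

## Grouping by hard-assignment EM

Each plate is grouped separately. The mixture of the logistic and
linear model over wells is optimized by a *classification* (hard
assignment) EM:

* **M-step**: fit one logistic base curve to the pooled points of all
  currently-active wells (with the linear fallback) and one line to the
  pooled points of all non-active wells; truncate both at zero.
* **E-step**: assign each well to the base curve with the smaller
  residual sum of squares. Ties go to non-active (a conservative
  activity call).

Iteration stops when the label vector stops changing, or after
`max_iter` (default 50) iterations. An optional **threshold** (signal
units) short-circuits and stabilizes the procedure: a well strictly
below the threshold at *every* time point is always non-active — before,
during and after EM — and if every well on a plate is below the
threshold the EM is skipped entirely. This is how a plate with no
metabolic activity at all is handled correctly; without a threshold a
two-group method will invent a split. There is deliberately no default
threshold: its meaning depends on the reader's signal units, and values
near 100–150 OmniLog units are typical in practice.

Without a threshold, initial labels are a fair coin flip per well
(seeded). Two pathologies of random starts are handled explicitly:

* **Label swap.** The logistic model can imitate a flat line, so the
  two mixture components are only weakly identified by model class
  alone; a random start can converge with the groups interchanged.
  Since *active* means the stronger signal by definition, the groups
  are re-oriented after each M-step: if the active base curve has the
  smaller time-summed signal, the labels are swapped and the bases
  refitted.
* **Group death.** If the E-step empties the non-active group, the
  group is re-seeded once with the weakest well; if it empties again
  the all-active solution is accepted. An emptied *active* group is
  accepted immediately as the all-non-active solution, mirroring the
  all-below-threshold shortcut.

With these rules, random restarts on separable data reach the same
partition, and the assigned residual sum of squares is non-increasing
across iterations of a thresholded run.

## Normalization over replicates

Array effects are modeled as multiplicative, and active and non-active
wells are normalized *separately*: an artefact can scale the strong
saturating signals differently from the near-flat baseline wells, and a
plate with few active wells would otherwise have its factor dominated
by the uninformative majority.

For each condition (a "setup" = one factor-level combination with its
replicates):

1. Optionally **stabilize** the labels: a well is called active in all
   replicates if at least a proportion $p$ (default 0.5, i.e. an exact
   half counts) of replicates call it active, else non-active in all.
   This removes false signals seen in a minority of replicates, and
   makes active counts identical across replicates. Stabilization is on
   by default; base curves are re-fitted under the stabilized labels.
2. Fit per-plate **base curves** for each group (logistic / line to the
   pooled group wells, truncated at zero).
3. Choose the **reference array** per group: the replicate minimizing
   the sum of Euclidean distances between base-curve vectors (over the
   full time grid), ties to the smallest array id.
4. Scale every other array's group wells by the **normalization
   factor**

   $$NF_{j,k} = \frac{\sum_{\tau} Base_{\tau, R(k), k}}
                     {\sum_{\tau} Base_{\tau, j, k}},$$

   the ratio of time-summed base curves of the reference $R(k)$ and
   array $j$ for group $k$; negative results are truncated to zero (and
   the reference is left untouched, $NF_{R(k),k} = 1$ exactly).

A condition with a single replicate cannot be normalized and passes
through with factor 1 and a warning.

## Bayesian two-factor effect identification

The third stage works substrate by substrate on *denoised* data: each
array's profile for the well is replaced by its own fitted curve
(logistic if active on that array, else linear), evaluated at a thinned
set of time points $T^* \subset T$ (default: every 16th point, i.e.
one point per 4 h on a 0.25 h grid, always keeping the first and last
point) and truncated at zero. For arrays $i$ with factor levels
$(a_i, b_i)$, control at $(1, 1)$:

$$y_{i,t} \sim N(\mu_{i,t},\ \sigma^2), \qquad
\mu_{i,t} = \zeta_t + \alpha_{a_i,t}\,[a_i \ne 1]
          + \beta_{b_i,t}\,[b_i \ne 1]
          + \gamma_{a_i,b_i,t}\,[a_i, b_i \ne 1],$$

with $\zeta_t \sim U(0, 400)$ for the control level and independent
zero-centred normal priors on the effects. Every time point is modeled
independently (no temporal smoothing term).

**The effect priors.** The priors are intended to be uninformative. A
zero-centred normal with variance as small as 1000 (sd $\approx 32$)
is *not* uninformative at metabolic-signal scales: it visibly shrinks
effects of the size this analysis exists to detect (tens to hundreds
of signal units), and drags frequentist coverage of the 95% credible
intervals well below nominal for effects of magnitude ~100. The
package therefore defaults the effect-prior variance to $10^6$
(effectively flat for this data scale) and exposes it as
`effect_prior_var` for users who want genuine shrinkage.

**The model error $\sigma^2$** is the sensitivity knob of the analysis
and is fixed by the user (default 100 signal units²): a small value
makes small condition differences significant, a large one makes the
analysis liberal. Because $y$ is denoised fitted values, $\sigma^2$
does not estimate measurement noise; it encodes how large a difference
should count. An optional `sigma2 = "estimate"` mode places an
Inverse-Gamma(0.001, 0.001) prior on $\sigma^2$; it is estimated per
substrate (a joint sampler across all 96 substrates would couple
otherwise independent analyses for little gain).

**Sampling.** All full conditionals are normal (truncated normal for
$\zeta_t$), so a single-site Gibbs sampler is exact; updates across
time points are independent and vectorized. Defaults: 5000 iterations,
1000 burn-in, 2 chains, all seeded. If the data pull the control level
outside $[0, 400]$ the conditional concentrates at the bound and a
warning is emitted. Posterior summaries are means with equal-tailed
95% credible intervals; an effect is *significant* when its interval
excludes zero. No multiplicity correction is applied by default (an
optional Benjamini–Hochberg helper, `adjust_significance()`, converts
the normal summaries to pseudo p-values across substrates).

**Averaged versus time-point-wise estimates.** The per-draw mean of an
effect across $T^*$ gives a single averaged estimate per effect. It is
convenient but cancels effects that change sign over time, and it
*attenuates* effects that act on the asymptote: all curves coincide
near $t = 0$, so an asymptote shift of $-50$ produces an averaged
effect nearer $-35$ to $-40$ depending on how much of $T^*$ lies in
the saturated phase. The time-point-wise estimates recover the full
late-time magnitude; the two views complement each other.

## What the synthetic generator emulates — and what it does not

`simulate_experiment()` produces the shape of a small PM study: a
2 x 2 factorial (e.g. temperature x strain) with 3 replicate plates per
condition, 96 wells read every 0.25 h for 48 h; per-condition active
fractions default to (0.44, 0.44, 0.33, 0.22), echoing activity rates
where temperature stress suppresses one strain more than the other.
Active wells follow logistic curves with per-well parameters
($Asym \in [150, 300]$, $xmid \in [8, 16]$ h, $scale \in [1.5, 3]$ h);
non-active wells are near-flat lines (level 10–50, slope 0–0.3 per h);
each array is scaled by a multiplicative factor (default
$U(0.85, 1.15)$, matching the size of factors seen in real studies);
i.i.d. Gaussian noise (sd 5) is added and signals truncated at zero.
Activity labels and curve parameters are shared across replicates of a
condition — exactly the situation normalization assumes — and each
plate draws noise from its own seeded stream, so adding plates does not
perturb existing ones. Injected condition effects shift the logistic
asymptote of chosen wells in off-control conditions.

The generator does **not** emulate plate-reader optics or dye
chemistry, temporally autocorrelated noise, non-sigmoid active shapes
(Michaelis–Menten-like dynamics, lag phases, biphasic curves), edge
effects, or wells whose activity status itself differs between
replicates of one condition. Tests passing on this generator therefore
demonstrate correctness of the algorithms under the stated model, not
robustness to every artefact of real PM data; the two-model assumption
itself is the method's declared scope.

## Verification strategy and problem sizes

The test suite checks each stage against an independent oracle:
grid-search-refined least squares for the logistic fit, closed-form
normal equations for the line, brute-force distance sums for reference
selection, generative constructions for grouping and normalization
factors, and the closed-form conjugate Gaussian posterior for the Gibbs
sampler. Simulation studies use sizes chosen to make their statistical
statements sharp while keeping the suite quick to run routinely:
interval coverage is measured over 200 simulated effect datasets
(2 x 2 x 3 design, effects drawn uniformly in ±100, matched
$\sigma^2 = 100$, chains of 2000); end-to-end sign recovery uses 20
seeds of a 12-plate experiment with 24 wells on a 0.5 h grid, all wells
active (so that activity status carries no condition effect and
unmanipulated wells are genuinely null), with asymptote shifts
$\alpha = -50$, $\beta = -150$, $\gamma = -120$ on four wells.

## Known limitations

* Only two profile shapes; outlying active shapes are absorbed by the
  linear fallback rather than modeled.
* Effects are modeled independently per time point; there is no
  temporal random-walk or smoothing prior, so time-point-wise intervals
  are wider than a smoothing model could achieve.
* The control-level prior support $[0, 400]$ caps the modelable signal
  level; data above it pin the control estimate at the bound (a
  warning is emitted). Rescale signals or widen `zeta_support` if your
  reader produces larger values.
* Normalization assumes a purely multiplicative array effect; additive
  drifts are not corrected.
* Missing time points are a hard error by design; the kinetic fits and
  the EM assume a complete grid.
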