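---
title: "Estimating fluorosequencing error rates with fluorfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fluorosequencing error rates with fluorfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorfit)
```

## The problem

Single-molecule protein fluorosequencing reads out peptides by labeling
specific residues with fluorescent dyes, attaching the peptides to a flow
cell, and alternating fluorescence imaging with Edman degradation, which
removes one N-terminal residue per cycle. Each read is a short time series
of fluorescence intensities — one value per color channel per imaging
timepoint — for one peptide molecule. The chemistry is imperfect, and the
usefulness of the technology hinges on knowing how imperfect: what fraction
of Edman cycles fail, how quickly dyes are destroyed, how often whole
peptides detach, how many dyes were dark from the start, and how often the
N-terminus is chemically blocked so that sequencing halts.

`fluorfit` estimates these rates from reads of a known peptide. The
parameter set (`seq_params()`) is:

* `edman_failure` — per-cycle probability the Edman removal fails;
* `detach` — per-cycle probability the whole peptide is lost;
* `initial_block` / `cyclic_block` — probability the N-terminus is blocked
  before sequencing / acquires a block per cycle;
* `dye_loss` (per channel) — per-cycle probability each fluorophore is
  destroyed (chemical destruction and photobleaching folded together);
* `dud` (per channel) — probability a fluorophore is dark from the start;
* an intensity model per channel (`mu`, `sigma`, plus `bg_mu`, `bg_sigma`),
  held fixed while the rates are fitted.

All rates live in `[0, 1)`; intensities are in arbitrary camera units
(defaults emulate a one-dye peak at 6000 a.u. over a background of width
350 a.u., the scale typical of TIRF fluorosequencing data).

## The hidden Markov model

A peptide's latent state during sequencing is summarized by the merged
tuple (successful Edman cycles `n`, fluorophore counts `k` per channel,
blocked flag), plus one absorbing detached state. Merging microstates with
the same observable signature keeps the state count polynomial in the
number of labels; a blocked twin of every state is needed because blocking
halts Edman chemistry but not fluorescence (`build_state_space()`).

The one-cycle transition matrix is factored into one sparse row-stochastic
factor per error mechanism (`transition_factors()`), applied in the order

1. cyclic blocking (a block acquired this cycle already gates this cycle's
   Edman step),
2. detachment,
3. dye loss per channel (destruction happens during the chemistry
   incubations, before the next image),
4. Edman degradation.

The order is an argument rather than a constant so alternates can be
tested; the factored product is verified against a brute-force enumeration
of joint outcomes in the test suite, so the factorization loses no
accuracy. Before cycle 1, duds are realized in the initial distribution and
an initial-block factor is applied.

Two modeling choices deserve a note:

* **Edman removal of a labeled residue.** When the residue at position
  `n + 1` carries a label, the merged state does not know whether that
  specific fluorophore is still alive. Because dud realization and dye loss
  act exchangeably across a channel's labels, the removed label is alive
  with probability `k / R`, where `R` is the number of that channel's
  labels still attached — so the count decrements by one with exactly that
  probability. This is exact for the merged chain, not an approximation.
* **Emissions.** A state with `k` fluorophores in a channel emits a normal
  intensity with mean `bg_mu + k (mu - bg_mu)` and variance
  `bg_sigma^2 + k sigma^2` — the sum of `k` independent one-dye signals on
  top of background. The detached state emits pure background: a detached
  spot looks like empty glass, and reads keep their fixed length.

Likelihoods come from a scaled forward/backward pass applied
factor-by-factor (`forward_backward()`), which exposes state posteriors at
every sub-step boundary. Scaling at each emission keeps the recursion
finite for any finite read; emission densities are floored at `1e-300` so a
grossly contaminated intensity degrades the likelihood without producing
`-Inf`. Rates exactly 0 or 1 are clamped to `[1e-9, 1 - 1e-9]` inside
likelihood evaluation only; reported estimates are never clamped.

## Baum-Welch with tied parameters

Classical Baum-Welch re-estimates every transition probability
independently. Here the transition matrix is a deterministic function of
six physical rates, so the M-step instead computes a weighted maximum
likelihood estimate of each rate directly. For every factor the E-step
accumulates the expected number of Bernoulli trials `n` and events `x`;
the M-step sets the rate to `x / n`:

* dye loss: trials are posterior-weighted fluorophore counts entering the
  dye-loss sub-step; events are the expected count drop across it;
* detachment: trials are the attached mass entering the detach sub-step;
  events the mass flowing into the detached state;
* Edman failure: trials are the unblocked attached mass entering the Edman
  sub-step; events are trials minus the expected advance in `n`;
* cyclic blocking: trials are unblocked mass entering the block sub-step;
  events the flow into blocked states;
* initial block and duds: read off the timepoint-0 posterior through the
  initial-distribution factorization.

Because each factor changes exactly one state coordinate monotonically,
these expectations are functions of the state marginals at adjacent
sub-step boundaries; pairwise sub-transition posteriors are never needed in
the E-step (though `forward_backward(want_xi = TRUE)` exposes them). Each
tied rate maximizes an expected binomial log-likelihood, so the EM ascent
property holds; the suite asserts a non-decreasing log-likelihood trace to
`1e-8` relative slack.

### Censoring correction for dud rates

A peptide whose fluorophores are all dud never appears as a read, so the
naive dud MLE from visible reads is biased low. Following the iterative
scheme for the truncated binomial: at each EM iteration, the current dud
estimates give the probability `x` that a peptide is invisible; the
expected number of censored reads is `N x / (1 - x)`, and that weight is
added to each channel's dud statistics as all-dud pseudo-peptides. The HMM
is simultaneously conditioned on visibility (`condition_on_visible`), so
the observed-data likelihood is the correct truncated-sampling likelihood
and the pseudo-reads restore the uncensored M-step. Channels are treated
independently when distributing the pseudo-read weight.

### Identifiability

With a single fluorophore several parameters are not identifiable
(`identifiability_constraints()`): dye loss and detachment are visibly
equivalent; no all-dud peptide is ever seen; and the observable
removal-cycle distribution depends on the Edman failure and cyclic block
rates only through the product `e(1 - c)` (see `kappa_distribution()`, a
closed form the simulator is tested against). Such designs pin `detach`,
`dud`, and `cyclic_block` to zero; two or more labels leave all six rates
free.

### Initialization and convergence

EM starts from all rates at 0.05 (`n_starts = 3` by default: the base start
plus jittered variants each run 8 burn-in iterations, and the best
log-likelihood continues). Convergence fires on a maximum relative
parameter change below `tol = 1e-6`, a relative log-likelihood gain below
`1e-9`, or `max_iter = 1000`, whichever is first. On 50,000 two-label
reads the fit typically converges in 40–60 iterations.

## The dye-track RMSE fitter

The second, independent estimator reduces each read to a *dye track* — the
per-timepoint fluorophore count with the highest emission density, ties
broken toward the smaller count (`reduce_to_dyetrack()`) — and matches the
histogram of observed tracks against simulated ones. The objective
(`rmse_objective()`) simulates `n_sim` reads at the candidate rates,
reduces and histograms them the same way, rescales counts by
`n_data / n_sim`, and returns the root mean squared count difference over
the union of track keys.

Two design choices matter:

* **Common random numbers.** Every evaluation re-seeds the simulator
  identically, so the objective is a deterministic function of the
  parameters. Determinism alone is not enough for line searches: the
  simulator draws a *fixed number* of uniforms and normals per read,
  independent of the parameter values, and converts them by inverse-CDF
  sampling, so the same seed yields simulations that vary smoothly with the
  rates instead of decorrelating at every parameter change (ordinary
  `rbinom`-style streams consume a parameter-dependent amount of
  randomness, which makes a common-seed objective jagged at exactly the
  scale the optimizer needs). The frozen noise still displaces the optimum
  by an amount that shrinks as `n_sim` grows, which is why the final
  refinement minimizes the mean RMSE over three independent noise banks of
  `4 * n_sim` reads each — averaging independent common-seed surfaces
  shrinks the displacement of the minimum by a further `sqrt(3)` (the
  global stage runs at 10,000, since it only needs the right basin). Because the random stream is
  parameter-independent, the fitter pre-draws it once per resolution and
  caches the reduction of every possible emission draw, making repeated
  evaluations RNG-free and numerically identical to `rmse_objective()`.
* **Optimization.** Powell-style line minimization alone halts in local
  minima and zigzags across the shallow coupled valley linking the Edman,
  blocking, and detachment rates. A coordinate-trisection global search
  (`direct_search()`: test two points above and below the current point
  along one dimension, keep the best of three, cycle dimensions, shrink the
  step threefold per cycle) finds the basin; `powell_minimize()` then
  refines with bounded Brent line searches over a direction set that starts
  as the coordinate axes and is updated with Powell's conjugate-direction
  replacement rule, followed by a narrow second pass (`refine_bracket =
  0.05`, `refine_line_tol = 2e-4`) that sets the final parameter
  resolution. Default box bounds are `[0, 0.5]` per rate and 500 global
  evaluations.

## Bootstrap uncertainty

`bootstrap_fit()` resamples reads with replacement (same size), refits, and
reports percentile confidence intervals (`percentile_ci()`, linear
interpolation). Replicate `i` draws its indices from a stream seeded at
`seed + i`, so replicates are reproducible individually and independent of
read order conventions. Replicate fits warm-start from the original-data
estimate with a looser tolerance (EM: `tol = 1e-4`, single start; RMSE:
no global phase, two Powell sweeps within a `0.05` bracket at
`n_sim = 10000`): a replicate's optimum lies within a few tenths of a
percentage point of the original, so the warm restart re-optimizes fully
at a fraction of the cost. Bootstrap interquartile ranges scale like
`1/sqrt(N)` in the read count, which the suite checks across
N = 1,000–100,000.

## What the simulator emulates — and what it does not

`simulate_reads()` draws the merged-state chain exactly as the HMM defines
it (dud realization, initial block, then the per-cycle factor order) and
adds normal intensity noise; invisible all-dud peptides are redrawn unless
`keep_invisible = TRUE`, and the invisible fraction is reported. Truth
tracks record the pre-noise counts for oracle tests. Because generator and
model agree by construction, passing recovery tests demonstrates the
estimators, not the realism of the model. Real data add effects the model
does not describe: contaminant fluorophores, non-normal intensity tails,
per-cycle brightness drift, and spatial artifacts. The package's answer to
the first two is pre-processing — `fit_channel_distribution()` fits `mu`
and `sigma` from the smoothed mode and half-width at half-maximum of an
intensity histogram (robust to shoulders, and scale-equivariant), and
`filter_reads()` drops any read containing an intensity outside the
allowed per-channel ranges (closed intervals; one bad value removes the
whole read). Background `sigma` is an input, normally computed upstream by
the imaging pipeline from local background pixels.

## Numerical and testing choices

* Sub-step marginals are accumulated in a compiled chunked pass (1024 reads
  per chunk keeps the working set cache-resident); memory is flat in the
  read count.
* Emission densities are precomputed once per fit: intensity parameters are
  held fixed, so EM iterations only rebuild the sparse factors.
* Test and validation problem sizes were chosen to make Monte-Carlo noise
  small relative to the tolerances being asserted while keeping the default
  suite comfortably runnable on a laptop: 50,000 reads and 50 bootstrap
  replicates for the two-label recovery experiment (estimator standard
  errors ≈ 0.002); 60 replicates per size for the dispersion-scaling check;
  100,000 draws for distribution-matching checks at three standard errors.
* The recovery experiment's generating rates (0.06, 0.05, 0.05, 0.02, 0.04,
  0.07) sit in the ranges reported for current real experiments, with the
  two-label one-channel design (positions 2 and 4, 10 cycles) that makes
  all six rates identifiable.

## Known limitations

* Designs with many labels per channel grow the state space as the product
  of per-channel counts; the implementation is tuned for the ≤3-channel,
  few-label designs used in practice.
* The RMSE fitter's accuracy is limited by the frozen simulation noise in
  its objective; with `n_sim` equal to the data size its estimates are
  roughly 2–5× more dispersed than the EM fitter's, consistent with its
  role as an independent cross-check rather than the primary estimator.
* Intensity parameters are not re-estimated inside EM by design; a grossly
  wrong intensity model biases all rate estimates. Fit them first
  (`fit_channel_distribution()`), or supply values from expert judgment.
* The dud correction assumes dud states are independent across channels
  and labels.
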