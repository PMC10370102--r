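# fluorfit

Parameter estimation for single-molecule protein fluorosequencing
experiments.

Fluorosequencing reads out individual peptides by labeling specific
residues with fluorescent dyes and alternating fluorescence imaging with
Edman degradation, which removes one N-terminal residue per cycle. Each
read is a short time series of per-channel fluorescence intensities for a
single molecule. Interpreting these experiments — and classifying reads
against a peptide database — requires knowing the error rates of the
chemistry. `fluorfit` estimates them from reads of a known peptide:

| parameter | meaning |
|---|---|
| `edman_failure` | per-cycle probability an Edman removal fails |
| `detach` | per-cycle probability the whole peptide is lost |
| `initial_block` | probability the N-terminus is blocked before sequencing |
| `cyclic_block` | per-cycle probability of acquiring an N-terminal block |
| `dye_loss` (per channel) | per-cycle probability a fluorophore is destroyed |
| `dud` (per channel) | probability a fluorophore is dark from the start |

Two independent estimators are provided:

* **Modified Baum-Welch** (`fit_baum_welch()`): expectation-maximization on
  a hidden Markov model whose states merge peptides by Edman count,
  per-channel fluorophore counts, and N-terminal blocking, with the
  one-cycle transition matrix factored into one sparse factor per error
  mechanism. Instead of re-estimating every transition probability, the
  M-step computes a weighted maximum-likelihood estimate of each tied
  physical rate directly (for rate θ with expected event count x over
  expected trials n, θ̂ = x/n), which ties the fit to the generative model
  and resists overfitting. An iterative censoring correction adds
  N·x/(1−x) all-dud pseudo-peptides per iteration to undo the bias from
  invisible (all-dark) peptides never appearing as reads.
* **Dye-track RMSE matching** (`fit_dyetrack()`): reduces reads to integer
  fluorophore-count tracks, then minimizes the RMSE between observed and
  simulated dye-track count histograms with a coordinate-trisection global
  search followed by Powell's method (bounded line searches over an updated
  conjugate direction set), using common random numbers so the objective is
  deterministic.

Both share a Monte Carlo read simulator (`simulate_reads()`), percentile
bootstrap confidence intervals (`bootstrap_fit()`), intensity-model fitting
(`fit_channel_distribution()`), and contaminant read filtering
(`filter_reads()`). Results are tibbles throughout; fits have `tidy()` /
`glance()` methods and bootstrap summaries have an `autoplot()`.

## Worked example

Simulate a two-fluorophore peptide (one dye color, labels at residue
positions 2 and 4, ten Edman cycles) at known rates, then recover them:

```r
library(fluorfit)

design <- peptide_design(c(2, 4), n_cycles = 10)
truth <- seq_params(
  edman_failure = 0.06, detach = 0.05, initial_block = 0.05,
  cyclic_block = 0.02, dye_loss = 0.04, dud = 0.07,
  mu = 6000, sigma = 900, bg_mu = 0, bg_sigma = 350
)
sim <- simulate_reads(design, truth, n_reads = 50000, seed = 7)

fit <- fit_baum_welch(sim$reads, design, init = seq_params(), seed = 11)
fit
#> <fluorfit_fit> method: baum_welch, 50000 reads
#>   log-likelihood -4367356.1012 after 51 iterations (converged: TRUE)
#>   edman_failure   0.06143
#>   detach          0.04952
#>   initial_block   0.04493
#>   cyclic_block    0.02173
#>   dye_loss_ch0    0.03942
#>   dud_ch0         0.07064
```

Every estimate lands within half a percentage point of its generating value
(compare the printed rates with `truth`); `tidy(fit)` returns the same
numbers as a tibble. Uncertainty comes from the bootstrap, warm-started at the fit:

```r
bs <- bootstrap_fit(
  sim$reads,
  function(r, s = 1) fit_baum_welch(r, design, init = fit$params,
                                    n_starts = 1, tol = 1e-4, seed = s),
  n_boot = 50, seed = 99, point = fit
)
tidy(bs)        # term, estimate, conf.low, conf.high, median
autoplot(bs, truth = c(
  edman_failure = 0.06, detach = 0.05, initial_block = 0.05,
  cyclic_block = 0.02, dye_loss_ch0 = 0.04, dud_ch0 = 0.07
))
```

A command-line surface wrapping the same functions (verbs `simulate`,
`filter`, `fit`, `bootstrap`, `kappa`) ships in
`inst/scripts/fluorfit`; designs, intensity models, and filters are read
from a YAML/JSON config (`read_run_config()`).

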