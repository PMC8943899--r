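---
title: "How the DP5 probability is computed: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How the DP5 probability is computed: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dp5)
```

## The question the package answers

A chemist proposes one structure for one compound and has a 1-D ^13^C NMR
spectrum plus calculated (typically DFT) shifts for the proposal. Comparative
metrics (MAE, DP4-style ranking) need a list of alternatives; the DP5
probability instead answers the standalone question *"how likely is it that
this structure is correct, given these prediction errors?"* It does so by
scoring each carbon's prediction error against an error distribution
*conditioned on that carbon's local environment*, because DFT shift errors
vary strongly and non-linearly with atomic environment: a 3 ppm error is
routine for some carbons and alarming for others.

## Pipeline

For a molecule with conformers $c$ and carbons $i$:

1. **Assignment.** The conformer's calculated shifts are matched to the
   experimental peaks by minimum-total-$|\Delta\delta|$ linear assignment
   (Jonker–Volgenant, exact). Peaks with multiplicity $m$ are expanded into
   $m$ slots. With more carbons than peak slots the optimal subset is
   matched and the rest flagged unassigned.
2. **Internal scaling.** A per-conformer least-squares fit
   $\delta_{exp} \approx a\,\delta_{calc} + b$ removes systematic
   slope/offset error; the scaled error is
   $\Delta_i = (a\,\delta_{calc,i} + b) - \delta_{exp,i}$. With fewer than
   three assigned carbons (or a degenerate fit) the unscaled errors are used
   and a warning raised. Scaling is per conformer, keeping the per-conformer
   probability pipeline intact.
3. **Environment descriptor.** Each carbon gets a rotation- and
   translation-invariant vector: per-element-channel (C, H, O, N) radial
   histograms of its neighbours within 5&nbsp;Å, Gaussian-smeared
   (width 0.5&nbsp;Å, 24 bins), each neighbour damped by $r^{-4}$.
4. **Similarity weighting.** The test descriptor is compared with every
   record of a reference error database through a Gaussian kernel
   $k(d) = \exp(-d^2 / 2\sigma^2)$ with unit prefactor, so $k \in (0, 1]$
   reads as a similarity; records from the test molecule itself can be
   excluded exactly (leave-one-out).
5. **Bespoke error density.** A weighted kernel density estimate over the
   database errors, $f_i(x) = \sum_j \tilde w_j\, N(x;\, e_j, h^2)$, with
   $\tilde w$ the normalised similarity weights.
6. **Atomic probability.** $p_i = \int_{\Delta_i - \varepsilon^*}^{\Delta_i
   + \varepsilon^*} f_i(x)\,dx$ where $\varepsilon^*$ is the database-wide
   mean absolute error (the `window` scheme; closed-form Gaussian-mixture
   CDF). A `two_tail` alternative $P(|X| \ge |\Delta_i|)$ is available.
7. **Conformer averaging.** Per-conformer atomic probabilities are
   Boltzmann-averaged with $w_c \propto \exp(-E_c / RT)$,
   $R = 8.31446\times10^{-3}$ kJ mol$^{-1}$ K$^{-1}$, $T = 298.15$ K.
8. **Molecular probability.** With $g(p)$ the geometric mean,
   $P_n = g(p) / (g(p) + g(1 - p))$.
9. **Bayes correction.** $\mathrm{DP5} = P(\text{correct} \mid P_n) =
   \pi f_c(P_n) / (\pi f_c(P_n) + (1 - \pi) f_i(P_n))$ using empirical
   densities of $P_n$ for known-correct and known-incorrect pairs and a
   prior $\pi$ (default 0.5).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `descriptor.cutoff` | 5 | Å | covers roughly three bonded shells |
| `descriptor.n_radial_bins` | 24 | – | ~0.2 Å resolution before smearing |
| `descriptor.width` | 0.5 | Å | tolerates vibrational-scale geometry noise |
| `descriptor.decay_power` | 4 | – | see below |
| `kernel.sigma` | `"auto"` | descriptor units | quantile heuristic, see below |
| `kernel.sigma_quantile` | 0.1 | – | see below |
| `error_model.scheme` | `window` | – | see below |
| `error_model.bandwidth` | `"auto"` | ppm | weighted Silverman, floored at 0.1 ppm |
| `calibration.prior_correct` | 0.5 | – | proposal a priori as likely right as wrong |
| `temperature_K` | 298.15 | K | ambient NMR acquisition |

**Radial damping ($r^{-4}$).** Without damping, a 5 Å neighbourhood in a
medium-sized molecule contains many more distant atoms than bonded ones, and
Euclidean distances between descriptors are dominated by the outer shell;
environments with different bonding patterns then look nearly equidistant
and the similarity weighting cannot condition on what matters. The $r^{-4}$
damping (the two-body decay used by physics-inspired representations)
makes the bonded first shell dominate. The damping distance is floored at
0.9 Å so a pathological close contact in a user-supplied geometry cannot
blow up the vector.

**Kernel length scale.** `kernel.sigma = "auto"` uses a low quantile (0.1)
of the pairwise descriptor distances rather than the median. Environment
descriptors form groups of comparable environments, so the pairwise-distance
distribution is multimodal; the median sits between groups and yields
near-uniform weights — every environment looks similar to every other,
which silently reduces the bespoke density to the marginal error
distribution. The 0.1 quantile tracks the within-group distance mode: on
the reference synthetic corpus it places ~87% of the kernel mass on
records from the test atom's own environment class while keeping the
weighted KDE's effective sample size in the hundreds. `quantile = 0.5`
restores the plain median heuristic.

**Integration scheme.** The `window` scheme asks "how much of this
environment's error mass lies within one typical error
($\varepsilon^*$) of the observed error?" It is large for errors typical
of the environment — including environments with a systematic bias, where
a biased error is *expected* and an unbiased one is suspicious — and small
for outliers. This reproduces the qualitative behaviour that atoms with
larger errors can receive higher probabilities than atoms with smaller
errors, and vice versa. `two_tail` is the conventional two-sided tail
probability; it cannot reward bias-consistent errors and is provided for
comparison.

**Molecular probability.** The contract is: symmetric in the $p_i$,
equal to $c$ when all $p_i = c$, monotone non-decreasing in each $p_i$, and
built on the geometric mean (which prevents one extreme atom from
dominating, unlike a plain product). The odds form
$g(p)/(g(p)+g(1-p))$ satisfies all four and is the natural two-hypothesis
combination of per-atom evidence. Atomic probabilities are clipped to
$[10^{-12}, 1-10^{-12}]$ before logarithms.

**Calibration.** Class densities of $P_n$ are estimated on the logit scale
(weighted Gaussian KDE, back-transformed with the Jacobian and renormalised)
so they are proper on $[0,1]$ without boundary artefacts. Two stabilisers
are applied, both motivated by the fact that a *ratio* of densities is far
more sensitive to estimation noise than either density: the reference
bandwidth is doubled, and each density is mixed with a 10% uniform
component. The uniform floor encodes that no $P_n$ value is impossible for
either class; it pulls the posterior toward the prior where data are
sparse and means the calibrated probability can approach but never reach 0
or 1 — the "never fully certain" ceiling that an honest single-structure
verifier must have, since an incorrect structure can always produce an
equally convincing error set. The maximum attainable DP5 therefore depends
on the database, the descriptor and the intrinsic prediction error level,
and is reported by the benchmark rather than asserted.

**Calibration refits in the benchmark.** Exact per-pair leave-one-out
calibration is quadratic in the corpus; the benchmark refits the
calibration k-fold over structures (default 10), so every pair is scored
by a calibration fitted without any pair of its own structure. The error
database exclusion, by contrast, is exact per molecule.

## The synthetic corpus: what it emulates, what it does not

`generate_corpus()` builds randomly grown acyclic C/H/O/N molecules
(5–9 carbons, 0–2 heteroatoms, clash-avoiding 3-D geometry, explicit
hydrogens). Every carbon belongs to one of three latent environment
clusters determined by its bonding pattern (heavy-atom degree and
heteroatom neighbours), so the geometric descriptor genuinely carries the
cluster signal. Cluster $k$ contributes:

* a baseline calculated shift (25, 75, 135 ppm) plus N(0, 6 ppm) spread —
  plausible aliphatic / mid-range / unsaturated ^13^C regions;
* an error law $\mathrm{loc}_k + \mathrm{scale}_k\, t_5$ with locations
  (+1.5, −1.5, 0) ppm and scales (0.8, 1.5, 3.0) ppm.

Student-t tails (df 5) reflect that wide-tailed laws are required to
describe DFT prediction errors. The locations emulate systematic
environment-specific biases; they are deliberately *non-monotone* in the
baseline shifts so the per-molecule linear scaling cannot absorb them —
with monotone biases a slope adjustment would remove exactly the signal
the environment conditioning exists to detect. The resulting corpus MAE is
≈1.9 ppm, in the 1.5–2 ppm regime of well-optimised DFT protocols.

Incorrect pairs are made by redrawing each carbon's error from a randomly
resampled cluster (environment mismatch), scaled by an inflation factor:
3.0 for the "case 1" regime (grossly wrong spectra, then filtered at
max error < 10 ppm as a chemist would discard absurd pairings) and 1.0 for
the "case 2" regime, where the incorrect pairs are indistinguishable from
correct ones by their MAE distribution and only the environment-error
mismatch remains. Case-2 incorrect pairs additionally receive
MAE-matching importance weights (KDE density ratio, clipped at the 99.5th
percentile, normalised to mean 1).

The generator does **not** emulate: rings and stereochemistry,
conformational flexibility (single conformer per molecule), correlated
errors between neighbouring atoms, solvent/referencing effects, peak
overlap or missing peaks. Passing benchmarks therefore demonstrate that
the statistical machinery extracts environment-conditioned error
information when it exists; they do not certify performance on real
DFT/NMR data, which requires a user-supplied error database.

## Reference study sizes

The shipped evaluation uses 500 molecules (~3,500 error records),
500 correct + 500 incorrect pairs per regime, leave-one-out database
exclusion, 10-fold calibration refits, and 200 bootstrap resamples for the
hard-regime AUROC confidence bound. These sizes give stable estimates
(AUROC standard error ≈ 0.015) while keeping a full run in tens of
seconds on one CPU.

## Numerical choices and degenerate inputs

* Squared descriptor distances from the inner-product expansion are
  clamped at 0 and snapped to 0 below a relative threshold of $10^{-12}$,
  so identical environments have self-similarity exactly 1.
* Mixture components with normalised weight below $10^{-12}$ are pruned
  from atomic densities (then renormalised).
* If every kernel weight underflows to zero the run stops with advice to
  increase `kernel.sigma` — silently falling back to uniform weights would
  change the science.
* Conformer energies are shifted so the minimum is 0 before Boltzmann
  weighting; a single conformer gets weight exactly 1.
* `fit_calibration` refuses classes with fewer than 30 samples.
* Ties in candidate ranking resolve to the earliest input, and the
  assignment algorithm is deterministic, so repeated runs are
  byte-identical given identical inputs and seeds.

## Known limitations

^13^C only; no ^1^H or multi-spectrum fusion. The descriptor is a
documented FCHL-like radial representation, not published FCHL; externally
computed representations can be supplied via `error_database()`. No DFT is
run: calculated shifts and conformer energies are inputs. The calibration
ceiling depends on the regularisation weight as well as the data, so
absolute DP5 values should be compared only within one database and
configuration.
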