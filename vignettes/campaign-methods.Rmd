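---
title: "Methods: ML-guided variant campaigns with FRET-based fitness scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ML-guided variant campaigns with FRET-based fitness scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

aldesim implements a create–test–learn loop for engineering a protease by
mutating a handful of residues simultaneously. This vignette is the
package's own account of the underlying models and of the design decisions
taken where the procedure admitted more than one reasonable reading. The
worked example in the README shows the code in action; here we explain what
the code assumes and why.

## The campaign model

A *region* is a small ordered set of mutable residue positions — in the
built-in presets, positions 167/169/172 (wild type `HLF`, region A) and
217/218/219 (wild type `LQE`, region B) of a Con1-family protease. A
variant is described only by its letters at those positions, so the design
space of a three-position region is $20^3 = 8000$ sequences.

A campaign alternates:

1. **Create.** Round 1 draws a random library: each position sampled
   uniformly from the 20 canonical amino acids, duplicates rejected and
   redrawn. We exclude the wild type from the random draw (it is measured
   on every plate anyway as the normalization reference); `random_library()`
   flags this and takes `exclude_wt = FALSE` where the full space is wanted.
2. **Test.** Each variant's catalytic activity is measured by a FRET
   cleavage assay and converted to a fitness score (below).
3. **Learn.** An ensemble surrogate is fitted to all accumulated
   (sequence, fitness) pairs and the next batch is proposed by Thompson
   sampling over the full enumerated space, excluding everything already
   measured.

Fitness here means the initial rate of substrate cleavage at fixed
substrate concentration, normalized so the wild-type protease scores 1.

## FRET scoring

The assay substrate carries a CFP donor and YFP acceptor joined by the
protease's cut site; cleavage separates the pair, so donor emission
(480 nm) grows at the expense of acceptor emission (520 nm) under 430 nm
excitation. The reported quantity is the blank-subtracted channel ratio

$$ r(t) = \frac{F_{480}(t) - B_{480}(t)}{F_{520}(t) - B_{520}(t)}, $$

with $B$ the per-timepoint mean over the plate's water-blank wells. The
scoring chain is: ratio → truncation → slope → normalization.

**Truncation.** Initial-rate fitting requires the early, approximately
linear part of the trace. `truncate_series()` keeps the prefix strictly
before the *first* timepoint at which the ratio reaches the threshold
(default 0.55). We deliberately use a first-crossing rule rather than
keeping all sub-threshold points: with noise, a trace can dip back under
the threshold after crossing, and re-admitting such late points would leak
plateau curvature into an initial-rate estimate. A trace left with fewer
than two points is flagged unscorable rather than guessed at.

**Slope.** Ordinary least squares of ratio against time with a free
intercept. Forcing the fit through the first observed point was the main
alternative; the free intercept is more robust to a noisy first read and is
the default behaviour of common curve-fitting software, so we adopt it (the
threshold and the fitting window are the config surface that matters).

**Normalization and clipping.** Every replicate slope is divided by the
mean slope of the wild-type replicates on the same plate; a variant's
fitness is the mean of its normalized replicates and its error bar is their
SD. The wild type therefore scores exactly 1 by construction — an identity
the test suite asserts literally. Since negative catalytic activity is not
physical, the aggregated fitness is clipped at zero. We clip the aggregate
rather than each replicate: per-replicate clipping would give noise-only
wells a systematic positive bias (half-normal mean), whereas the clipped
mean of noise-only replicates stays near zero. Raw per-replicate slopes,
including negative ones, are retained in the well-level table attached to
every score table.

## The surrogate ensemble

Sequences are one-hot encoded (20 bits per position, position-major,
alphabetical letter order, no physicochemical information). The surrogate
is an ensemble of $k = 5$ feed-forward neural-network regressors, each
trained on its own random 90 % subsample of the data, drawn without
replacement; the subsample size is $\lfloor 0.9 n \rfloor$ (so 44 of the
49 round-1 records). The spread of member predictions is treated as an
approximate Bayesian posterior: the member mean is the exploitation signal,
their disagreement the exploration signal.

Design choices worth stating explicitly:

* **Architecture.** Members are single-hidden-layer networks
  (`nnet::nnet`, 8 logistic units, linear output, squared-error loss,
  BFGS, 300 iterations). With 60 binary inputs and ~50–200 training
  records this capacity is ample — wider or deeper members did not change
  ranking quality on our synthetic landscapes, only cost time. The
  ensemble contract is architecture-agnostic: any fit/predict regressor
  can stand behind it, and `hidden`, `decay` and `maxit` are config.
* **No weight decay by default.** This is deliberate and a little subtle.
  A one-hot bit that never occurs in a member's subsample contributes no
  data gradient, so with any positive L2 penalty the optimizer drives its
  input weights to zero at convergence — every member then agrees on a
  bland baseline exactly in the unexplored corners of sequence space, and
  the posterior spread collapses where exploration is needed most. With
  `decay = 0` those weights retain each member's random initialization,
  which is precisely the bootstrap ensemble's uncertainty signal far from
  data. The test suite checks this localization property directly.
* **Targets unscaled, inputs unscaled.** Inputs are binary; fitness is
  already on the interpretable WT-normalized scale.
* **Dead variants stay in.** Zero-fitness records are informative about
  which residues are intolerant, and a mutation-intolerant region produces
  many of them; they are never filtered from training.

## Thompson-sampling acquisition

Each batch slot draws one member uniformly at random and proposes the
argmax of that member's prediction over candidates not yet measured and
not already in the batch; ties break to the lowest enumeration index so
the procedure is deterministic given the member draws. The member index
used for every slot is logged in the proposal table, which makes an
acquisition run auditable after the fact.

We do not refit or condition on hallucinated observations between slots
("Kriging-believer"-style batch construction): no interim fitness data
exists mid-batch, and pure batched Thompson sampling with exclusion keeps
the procedure simple and honest about what it knows. The measured-variant
exclusion set always includes the wild type.

A uniform `random_batch()` with the same interface is provided purely as
the control arm for quantifying the value of model-guided acquisition.

## The synthetic data generator

The simulator exists so every stage of the pipeline — scoring, surrogate,
acquisition, campaign bookkeeping — can be exercised end-to-end without
instrument data. It has two layers.

**Landscapes.** Ground truth is a Potts-like function: per-position field
terms $h_i(a)$ plus pairwise couplings $J_{ij}(a,b)$, all measured relative
to the wild-type letters ($h_i(\mathrm{wt}_i) = 0$,
$J_{ij}(\mathrm{wt}_i,\mathrm{wt}_j) = 0$) so the wild type scores exactly
1 without any post-hoc rescaling. Fields-plus-couplings is the minimal
family that can express the epistasis that simultaneous mutagenesis is
designed to navigate. Three kinds emulate the qualitative contrast seen
between mutation-intolerant and mutation-tolerant sites:

* `dense` (tolerant): $f = e^{\text{score}}$ with field SD 0.3 and
  coupling SD 0.1 — every variant retains some activity, a substantial
  minority beats the wild type, and the best variants run several-fold
  above it, matching the dynamic range a tolerant surface loop shows.
* `sparse` (intolerant): every substitution carries a strictly negative
  penalty ($-0.15 - |N(0, 0.8)|$), $f = \max(0, 1 + \text{score})$, and at
  least 80 % of the space is gated to zero (lowest-scoring variants first,
  never the wild type). The wild type is near-optimal, as expected of a
  catalytically essential site.
* `additive`: couplings off — a no-epistasis control on which the
  surrogate's ranking should (and in tests does) recover the true optimum.

**Plates.** A variant of true fitness $f$ follows the single-exponential
trajectory $r(t) = r_0 + (r_\mathrm{max} - r_0)(1 - e^{-\kappa f t})$
(first-order cleavage at fixed substrate), realized as two channels
$F_{520} = b + S/(1+r) + \varepsilon$ and
$F_{480} = b + S\,r/(1+r) + \varepsilon$ with i.i.d. Gaussian channel
noise, so the blank-subtracted ratio recovers $r(t)$ exactly in
expectation. The initial slope of the noiseless ratio is
$(r_\mathrm{max}-r_0)\,\kappa f$ — proportional to fitness, which is the
property the scorer is built to recover.

Defaults, with reasoning:

| parameter | default | why |
|---|---|---|
| $r_0$, $r_\mathrm{max}$ | 0.40, 0.90 | uncut vs fully cleaved ratio; brackets the 0.55 truncation threshold |
| $\kappa$ | $-\ln(0.7)/30 \approx 0.0119\ \mathrm{min}^{-1}$ | WT crosses 0.55 at 30 min — mid-assay, leaving headroom both ways |
| duration, interval | 90 min, 1 min | reads every minute; long enough that variants ~2× slower than WT still cross the threshold |
| replicates | 3 | triplicate wells per variant |
| signal, blank | 10 000, 500 AU | arbitrary-unit scale; scoring is provably invariant to it |
| noise SD | 150 AU | sized so WT replicate fitness scatters with SD ≈ 0.1, a realistic plate-reader error bar |

The noise calibration is a judgment call (instrument noise depends on gain
and optics), so it is config, not a claim. The simulator deliberately omits
gain drift, edge effects, evaporation, photobleaching and expression-level
variability between wells; passing tests therefore demonstrate the
*pipeline's* correctness and the *policy's* value under a clean noise
model, not robustness to every artifact real plates show.

Truncating at a fixed ratio has a useful side effect worth knowing: every
active variant is fitted over the same ratio range ($r_0$ to 0.55), so the
curvature bias of fitting a line to an exponential largely cancels in the
WT-normalized score. Noiseless end-to-end recovery is accurate to a few
percent across a 16-fold fitness range (the residual comes from the
1-minute sampling grid), which is why the test suite can assert a 5 %
relative tolerance without any fudge.

## Numerical and procedural conventions

* Alphabet order is fixed alphabetical one-letter (`A, C, D, …, Y`);
  enumeration is lexicographic, position-major. Any fixed order works —
  fixing one makes enumeration indices, tie-breaks and one-hot layouts
  reproducible across sessions.
* All randomness flows from user-supplied integer seeds; campaign rounds
  derive per-round streams from the master seed, and every with-seed
  operation restores the caller's RNG state.
* Variant identifiers are `<region>_<letters>` (e.g. `B_LQE`), so tables
  are self-describing and joins cannot silently cross regions.
* A rejection-sampled library falls back to uniform sampling of the
  remaining enumeration when the request approaches the space size; the
  resulting distribution over distinct sets is identical and termination
  is guaranteed.
* Blank subtraction uses the per-timepoint mean over all blank wells.
  Non-positive denominators mask individual timepoints with a warning;
  wholly masked traces are errors, not zeros.

## Problem sizes in the test suite

The suite exercises the reference round structure (48 random + 10 proposed
on an intolerant landscape; 48 random + 32 proposed on a tolerant one —
138 measured variants in total) and checks the policy-level claims as
paired-seed comparisons: over 20 seeded replicate campaigns, Thompson
sampling must beat an equal-budget random screen on best-found true
fitness in at least 15, with round-2 mean and maximum fitness improving on
round 1 at the same rate, and the intolerant landscape must show a lower
round-1 active fraction than the tolerant one in at least 19. Twenty
paired replicates keep the whole suite comfortably inside a coffee break
on one core while leaving the comparisons statistically meaningful; a
complete simulated two-round campaign runs in a few seconds.

## Known limitations

* The surrogate's uncertainty is a bootstrap heuristic, not a calibrated
  posterior; we test its *localization* (higher spread far from data),
  not its coverage.
* Landscapes are Potts-like by construction; real epistasis can be
  higher-order. The campaign machinery does not care, but simulated
  performance guarantees do not transfer automatically.
* The scorer assumes the ratio rises on cleavage and starts below the
  truncation threshold; assays with inverted orientation need their
  channels swapped at ingestion.
* Regions are optimized independently; joint multi-region design is out
  of scope.
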