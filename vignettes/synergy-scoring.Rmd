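---
title: "Scoring drug-combination screens with synscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drug-combination screens with synscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synscreen)
```

## The problem

A combination screen measures a readout — here percent inhibition, with 0 =
untreated control and 100 = complete inhibition — over a grid of dose
combinations of two or more drugs, often across many biological samples.
"Synergy" is not an absolute quantity: it is the excess of the observed
combination response over what a *no-interaction reference model* predicts
from the monotherapies. Different reference models encode different
assumptions, and a favourable choice of model can manufacture synergy where
none exists. `synscreen` computes all the standard references, a
conservative consensus of them, and quality-control and post-analysis
layers that make the resulting calls more reproducible.

Responses outside [0, 100] are deliberately preserved end to end:
stimulation (< 0) and super-inhibition (> 100) are genuine signals.
Clamping happens only where a formula requires it, and each such place is
documented below.

## Data model

A `combination_block` is one experiment: `n >= 2` drugs, a per-drug dose
grid that starts at 0, and an n-dimensional response tensor. Single-agent
responses live on the tensor axes; the all-zero-dose cell is the control,
defined as 0. Replicate wells are averaged into the working tensor (the
replicate stack is retained; replicate-level significance testing is out of
scope). Missing values are tolerated only on single-agent axes and only
while at least two finite non-zero-dose points per drug remain for curve
fitting; a missing combination cell is an error, because every downstream
surface is defined cellwise. Dose units are carried as labels only — the
concentration-weighting scheme (below) makes the scoring insensitive to
heterogeneous dose ranges, so no unit conversion is ever attempted.

## Monotherapy curves

Single agents are fitted with the field's standard four-parameter
log-logistic model

$$y(d) = l + \frac{u - l}{1 + (\mathrm{EC}_{50}/d)^h},$$

with $y(0) = l$ taken as the closed-form limit (never `log(0)`). Parameters
are bounded ($l \in [-50, 150]$, $u \in [l, 200]$, $h \in (0.05, 20]$) and
fitted by L-BFGS-B least squares from a fixed 3×3 multi-start grid
(EC50 starts at the smallest positive dose, the geometric mid-range and the
largest dose; slope starts at 0.5, 1, 3). Best residual sum of squares
wins; ties break to smaller $h$, then smaller EC50 — fits are fully
deterministic. Non-monotone data are still fitted monotone (the bounds
enforce $l \le u$) with a poor-fit warning when RSS/df exceeds 100 %inh².
Curve inversion returns 0 below the lower asymptote and `Inf` at or above
the upper asymptote, so the Loewe solver can recognize saturation instead
of erroring.

## Reference models and the consensus

For each all-positive-dose cell with single-agent responses $y_i$:

- **Bliss**: $100(1 - \prod_i (1 - y_i/100))$. The $y_i$ are clamped to
  [0, 100] *inside the product only* — survival fractions outside [0, 1]
  are unphysical and destabilize higher-order products.
- **HSA**: $\max_i y_i$, with negative responses allowed.
- **Loewe**: the effect $y^*$ solving $\sum_i d_i / D_i(y^*) = 1$, found by
  bisection over the overlap of the curves' response ranges to a tolerance
  of $10^{-6}$ on the dose-fraction sum; if the sum exceeds 1 even at the
  smallest upper asymptote the combination is saturated and that asymptote
  is returned. Non-overlapping response ranges are a degenerate-curves
  error.
- **ZIP** (two-drug only; the delta construction is directional-pairwise):
  conditional curves are refitted along each row and column with the
  zero-dose anchor pinned to the partner's fitted response, and the delta
  is the mean directional difference from the Bliss combination of the two
  fitted monotherapy values.

Bliss and HSA use the *measured* single-agent axis responses (after
optional outlier correction), matching the observed-minus-expected
convention; Loewe and ZIP necessarily use the fitted curves. Where an axis
measurement is missing, the fitted value substitutes.

The **consensus** expected effect is the pointwise maximum of the Bliss,
Loewe and HSA expectations; its delta is therefore the pointwise minimum of
the three model deltas — the most conservative call. ZIP is excluded by
design because it shares Bliss's multiplicative-survival principle and
would double-weight that assumption. Since the HSA expectation never
exceeds Bliss for responses in [0, 100], the consensus is effectively a
Bliss/Loewe consensus. It is defined for any number of drugs. When Loewe is
undefined (degenerate curves) the consensus is reported as missing with a
warning rather than silently falling back to a Bliss/HSA maximum: the score
is defined as a three-model consensus and a two-model stand-in would be a
different (less conservative) quantity.

Summary scores are the plain mean of the delta over all-positive-dose cells
(zero-dose rows/columns are excluded — their delta is 0 by construction and
would dilute the score) and the most-synergistic-area (MSA) score: the
maximal windowed mean, default window edge 3 per axis, user-adjustable and
clipped to the grid with a warning. Blocks whose consensus mean score falls
strictly below −5 are flagged `low_confidence` — a candidate false-positive
synergy that deserves de-prioritization or closer post-analysis.

## Outlier detection and replacement

Isolated measurement errors are a dominant source of false synergy calls.
Dose-response surfaces are smooth and approximately low-rank, so each
combination cell is predicted from the rest of the matrix: the response
matrix is shifted to be non-negative (subtracting its minimum — this makes
the whole procedure shift-equivariant), and the cell's prediction is the
average over 5 fixed-seed refits of a rank-2 non-negative matrix
factorization fitted with that cell masked. Cells deviating from their
prediction by strictly more than 20 %inhibition (in either direction —
both are experimental errors) are flagged; a deviation of exactly 20 is
not. Replacement by the prediction is opt-in, and corrections are applied
before all downstream scoring so that corrected single-agent values also
feed the Bliss/HSA expectations.

Three numerical hardenings matter in practice and are part of the method:

1. *Ridge-regularized updates.* The masked entry is unconstrained by the
   fitting objective, and masked NMF has a degeneracy in which a factor
   component grows in a direction that only changes masked cells. A small
   ridge penalty (10⁻² of the data maximum) on both factors removes the
   drift; convergence is judged on the reconstruction itself rather than
   the visible-cell objective, which plateaus first.
2. *Range clamping.* Each refit's prediction is clamped to the observed
   data range before averaging — an extrapolated prediction outside the
   observed range carries no evidence about an outlier.
3. *Candidate refinement.* An outlier left in the matrix contaminates the
   reconstruction of its own row and column: its clean neighbours acquire
   spurious deviations, and those neighbours in turn can shield the
   outlier. Candidates (cells over the cutoff) are therefore re-predicted
   with the *other* candidates masked; the strongest surviving candidate is
   flagged, provisionally replaced by its prediction, and the cells sharing
   its row or column are re-evaluated, iterating until the flag set is
   stable. On simulated null blocks with plate noise (sd 3 %inh) and a
   single ±30 %inh spike, this takes recall from ~0.95 with ~1.3 false
   flags per block (single pass) to ~1.0 recall with ~0.02 false flags per
   block.

Single-agent axes get the analogous treatment with leave-one-out curve
refits and the same 20 %inhibition cutoff; axes with fewer than 4 points
are skipped with a warning. For blocks of more than two drugs,
reconstruction operates on every two-drug slice with the other doses fixed
(single pass), and a cell flagged in any slice is flagged.

## Concentration-weighted synergy

Synergy observed at low doses is clinically more valuable than synergy at
near-saturating doses. Rather than using raw concentrations (whose ranges
and units differ across drugs), each cell's delta is weighted by

$$w = \sqrt{\prod_n \frac{100 - y_n}{100 - l_n}},$$

with $y_n$ the measured single-agent response of drug $n$ at its dose in
the cell and $l_n$ its fitted lower asymptote. Each factor is clamped to
[0, 1] before the product: the printed form is over-unity or undefined for
$y < l$ or $y > 100$, and the weight's role is purely to down-weight
high-effect cells. The weight is 1 at baseline and 0 once any single agent
saturates. The weighted summary is the mean of weight × delta over
all-positive cells and is deliberately *not* renormalized by the mean
weight — a block whose synergy sits entirely at saturating doses is meant
to score near zero, not to keep its unweighted score. A fitted $l_n \ge
100$ makes the weight undefined and raises a degenerate-curve error.

## MuSyC potency/efficacy decomposition

MuSyC models the two-drug surface as the steady state of a four-state
mass-action scheme (cells unaffected, affected by drug 1, by drug 2, by
both). With cooperativity interactions fixed at 1 (out of scope here), the
steady state of the four-state cycle has a closed form via the
Markov-chain tree theorem, which makes surface evaluation exact and fast.
Effects are modeled on the inhibition scale normalized to [0, 1] with
baseline $E_0 = 0$. The interaction parameters are:

- $\alpha_{12}, \alpha_{21}$ — one drug's multiplicative shift of the
  other's effective potency (potency synergy when their geometric mean
  exceeds 1);
- $\beta = E_3 - \max(E_1, E_2)$ — the gain of the combination's maximal
  effect over the stronger single agent on the normalized scale (efficacy
  synergy when positive).

Fitting is bounded least squares over the whole grid, seeded by the
single-agent curve fits, with a fixed multi-start over
$\alpha \in \{0.1, 1, 10\}$ (both alphas started equal) — deterministic by
construction. Requires at least 4 doses per drug including 0. Non-sigmoidal
monotherapies trigger a quality warning (the model assumes monotone
sigmoidal monotherapies) but the fit proceeds. Mode classification uses
dead zones of 0.1 log₁₀ units on the geometric-mean alpha and 0.05 on beta;
these are configurable defaults, not literature constants.

A caveat established while validating the fitter: on a 6×6 grid with noise
of 2 %inh, $\alpha$ is only weakly identified — a fit with
$\alpha \approx 2.6$ can have lower residual error than the generating
$\alpha = 1$ because small effect/potency shifts compensate. Parameter
*recovery* under synergy ($\alpha = 5$, $\beta = 0.2$) is accurate at that
noise level, but the null-consistency check ($\alpha \to 1$,
$\beta \to 0$) is meaningful only on noiseless surfaces, and the test suite
treats it as such. Interpret single-block alphas near 1 with caution;
larger grids or replicates sharpen them.

## Multi-sample analytics

Batches are scored block-by-block (curve fits, optional QC, surface,
summary); a failure in one block becomes a missing cell with a diagnostic,
never a batch abort. Combination identity is the sorted drug-name set, so
(A, B) and (B, A) blocks are the same combination (duplicates in a sample
are averaged with a warning). Exports: a wide combination × sample score
matrix (rows sorted by cross-sample mean, ties by name; missing cells stay
missing, never 0), the long form, per-sample waterfalls (descending score,
name tie-break) and a per-combination consistency table (n, mean, sd —
missing for a single sample — min, max, fraction of samples with positive
score). The consistency statistics are pragmatic defaults for separating
recurrent from context-specific synergies, not literature-prescribed
quantities.

## The synthetic-data generator

Every layer above is validated against `simulate_block()`, which generates
blocks with known ground truth: Hill-curve single agents, combination cells
from a chosen null model (Bliss, Loewe, HSA, or a MuSyC surface with given
$\alpha$, $\beta$), an injected synergy delta, Gaussian noise on the
percent-inhibition scale (the simple, standard model for plate-reader
error), and optional injected outlier shifts. The defaults emulate a
typical cell-viability checkerboard: one fully efficacious drug (u = 95)
and one partial agonist (u = 80), five non-zero doses per drug log-spaced
over EC50/10…EC50·10, and noise sd 3 %inh. Seeds determine everything;
ground truth retains every noiseless intermediate.

What the generator does *not* emulate — and hence what passing tests do not
establish about real screens — includes spatial plate effects (edge
evaporation, gradients), correlated or heteroscedastic noise, biphasic or
bell-shaped dose-responses, and batch effects between samples. The
between-sample jitter model (log-normal on EC50 and slope, Gaussian on the
upper asymptote) is a convenience for testing multi-sample plumbing, not a
biological model.

## Problem sizes and numerical choices

The validation suite uses 6×6 two-drug grids (plus 4³–5³ three-drug
blocks), 50-block outlier-recovery sweeps, 100-curve fit-recovery sweeps
and a 10⁴-point dominance scan — sizes at which every property is exercised
in a few minutes on one core. Key tolerances: Loewe bisection 10⁻⁶ on the
dose-fraction sum; masked-NMF convergence 10⁻⁵ of the data maximum on the
reconstruction; outlier and de-prioritization cutoffs are strict
inequalities at exactly 20 and −5 as defined above; Bliss/HSA closed forms
are exact. All multi-starts and seeds are fixed, so every pipeline output
is reproducible bit-for-bit given the same configuration and seed.

## Known limitations

- ZIP and MuSyC are two-drug only (consensus and the other references
  handle any order).
- The outlier reconstruction assumes an approximately low-rank response
  surface; strongly non-monotone surfaces reduce its accuracy, and the
  n-drug slice-wise path is single-pass (no candidate refinement).
- No replicate-level inference or confidence intervals on synergy scores.
- The count-to-inhibition normalization supports a single positive-control
  level per run, not per-plate positive controls.
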