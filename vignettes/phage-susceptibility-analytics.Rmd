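---
title: "Phage susceptibility analytics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phage susceptibility analytics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagekit)
library(dplyr)
```

phagekit quantifies how well candidate bacteriophages kill clinical
bacterial isolates, starting from the two standard laboratory read-outs:
the double agar overlay plaque assay (DPA, solid phase, three-level
calls) and the planktonic killing assay (PKA, liquid phase, OD600 growth
curves). Everything downstream — virulence indices, method concordance,
resistance classes, therapeutic scores, cocktail design — is arithmetic
on those calls and curves. This vignette explains the models and the
choices behind them.

## The PKA model

A PKA compares an infected culture's growth curve against the
uninfected control of the same strain over 24 h (OD600 every 15 min).
The statistic is the normalized area under the curve

$$\mathrm{AUC_{norm}} = \frac{\int_0^{24}\mathrm{OD_{infected}}(t)\,dt}
                             {\int_0^{24}\mathrm{OD_{control}}(t)\,dt},$$

with lysis called **strictly** below 0.8: `classify_pka(0.79)` is lysis,
`classify_pka(0.80)` is not. Integrals are trapezoidal on the raw OD
series — no blank or pathlength correction is applied, deliberately:
the statistic is a ratio of raw integrals, and subtracting a baseline
would change it. This matters when comparing numbers across
laboratories; `trapezoid_auc()` documents it prominently.

The *time of lysis* is the first sampled time $t$ at which the
expanding-window ratio $\mathrm{AUC_{norm}}[0,t]$ drops below the
cutoff. Because both numerator and denominator grow with $t$, the ratio
is smooth and the first crossing is well defined; it is reported only
for pairs whose full-window call is lysis, so the two outputs can never
disagree. At the first sample the ratio is a single trapezoid — a
control with zero area there (an empty well) raises a
degenerate-control error rather than returning 0/0.

Replicates are pooled as curves (pointwise mean OD) before integration,
matching how triplicate MOI assays are usually handled; per-replicate
ratios remain available via `pka_replicate_stats()` for dispersion
checks. The replicate count for host-range PKAs is rarely reported in
protocols, so pooling is an assumption, not a protocol fact. Curves
shorter than 24 h are integrated to the common final time with a
warning; the call is then over the available window.

## Virulence indices

For the MOI-dependent assay (MOI ladder 1, 0.1, …, 1e-4), the local
virulence index at one MOI is

$$v_i = 1 - \frac{\int_0^{T_s}\mathrm{OD_{infected}}}
                 {\int_0^{T_s}\mathrm{OD_{control}}},$$

integrated to the control's stationary-phase onset $T_s$, and the
global index is $v_p = A_p / A_{max}$, where $A_p$ is the trapezoidal
area under the $v_i$-versus-$\log_{10}(\mathrm{MOI})$ curve and
$A_{max}$ the width of the log-MOI range (4 for the default ladder).

Three genuinely open points were resolved as follows:

* **Stationary-phase onset.** The onset rule in the source protocols
  ("first local maximum with a threshold value of 5") is ambiguous
  about the unit of 5. We read it as a 5-**sample** forward-looking
  window (75 min at 15-min cadence): the onset is the first sample
  whose OD no later sample in the window exceeds by more than `tol`
  (default 0 OD). This is the simplest rule consistent with "first
  local maximum"; it lives in one function
  (`detect_stationary_onset()`) with `window` and `tol` exposed, so
  alternative readings are pluggable. For noisy plateaus a small `tol`
  (≈ the noise sd) avoids onset jitter. A strictly rising control falls
  back to the final time point.
* **Onset is detected on the control only**, and the infected curve is
  integrated to the same bound — both integrals in $v_i$ must share the
  upper limit for the ratio to be meaningful.
* **Clamping.** $v_i$ is clamped to $[0, 1]$. Regrowth above the
  control (raw $v_i < 0$) carries no extra information about killing
  and would corrupt $A_p$; this is a deviation from a literal reading
  of the index definition and is flagged here so users comparing
  against unclamped implementations know why low-MOI values differ.

`vp` is order-invariant in the MOI entries, monotone under pointwise
lowering of any infected curve, and always in $[0, 1]$ — these are
tested properties, not aspirations.

## Host-range matrices and concordance

DPA calls are three-level (`no_lysis`, `reduced_growth`, `lysis`), PKA
calls two-level. Comparing the methods pair-by-pair yields six groups
(1: both negative; 2: reduced/negative; 3: DPA lysis only; 4: PKA lysis
only; 5: reduced/PKA-lysis; 6: both lysis). **Concordance counts only
groups 1 and 6.** Group 2 — reduced growth on the plate, no killing in
liquid — is ambiguous, not agreement: reduced growth is a weak,
non-plaque signal, and treating it as concordant-negative would inflate
agreement with the weakest calls. Per-genus breakdowns recompose the
global fractions exactly when weighted by pair counts (a tested
invariant).

Missing cells (`NA`, untested pairs) are excluded from every count and
denominator, with the exclusion count messaged. Percentages shown as
integers are rounded half-up (`round_half_up()`, 44.5 → 45) because
that is how laboratory reports round; machine output always retains
full precision, and intermediates are never rounded — independently
rounded group percentages may therefore not sum to the rounded total,
which is expected behavior.

## MRGN classification

Zone diameters are interpreted against a breakpoint table
(S if diameter ≥ `s_min_mm`, R if < `r_max_mm`, I between). Breakpoints
are **data, never constants**: EUCAST revises them annually, so every
analysis must state its vintage; the bundled
`synthetic_breakpoints()` table is an illustration fixture, labelled
synthetic, not an official release. The German 3MRGN/4MRGN scheme then
counts resistant *lead* substances of the four antibiotic classes
(default leads: piperacillin, ceftazidime, meropenem, ciprofloxacin);
exactly three resistant leads give 3MRGN, four give 4MRGN. "I" counts
as non-resistant, matching RKI practice, with `i_as_resistant = TRUE`
as a sensitivity switch. Combination agents are carried through
`sir_calls()` but never decide the class.

## Ranking rubric

`score_phages()` awards 1–3 points each for DPA coverage, PKA coverage
and $v_p$, plus 0/1 for genomic safety (strictly lytic, no virulence or
resistance genes — supplied as a boolean, since genome screening is
upstream of this package). The published bin edges overlap ("≥ 42" vs
"21–42"); we resolve them as half-open intervals with inclusive lower
bounds — $[42, \infty)$, $[21, 42)$, $[0, 21)$ — because the "≥"
clauses are explicit, so the middle bin's upper edge must be exclusive.
The default edges (42/21 DPA, 63/31 PKA, 0.6/0.3 vp) are fractions of a
141-strain panel and scale to other panels via the `*_bins` arguments.
Ties in the total are broken by (PKA points, DPA points, vp points,
name) for a fully deterministic order.

## Cocktail optimization

Cocktail design is maximum coverage: choose $k$ phages maximizing the
number of strains lysed by at least one member. Only `lysis` counts —
reduced growth is not a therapeutic hit (an `include_reduced` flag
exists for sensitivity analysis). At panel scale ($n = 18$ safe phages,
$k = 6$, $\binom{18}{6} = 18{,}564$ subsets) exhaustive enumeration is
cheap, so it is the default whenever $\binom{n}{k} \le 10^6$; it
enumerates *all* co-optimal sets (capped at 10,000 with an overflow
flag) because knowing a combination is one of several equally good
options matters clinically. The greedy alternative (best marginal gain,
lexicographic tie-break) is deterministic and carries the classical
$1 - 1/e$ guarantee, asserted empirically against the exhaustive
optimum in the test suite. There is no randomness anywhere in the
solver; all ties resolve lexicographically on phage names.

## The synthetic-data generator

The generator exists so that every pipeline stage is testable with
known ground truth. It is phenomenological by design: the pipeline only
ever consumes OD curves, so a piecewise logistic/exponential model —
logistic growth $OD(t) = K\,od_0 / (od_0 + (K - od_0)e^{-rt})$ until
the MOI-dependent lysis onset $t_L = \max(0,\; t_0 - \tau
\log_{10}\mathrm{MOI})$, then exponential decay toward a debris floor,
with optional seeded regrowth — gives closed-form noise-free curves
that serve as analytic oracles, which a mechanistic phage–bacteria ODE
would not. Defaults: $od_0 = 0.1$ (the inoculation OD), $r = 0.6\,
h^{-1}$, $K = 1.2$ (plateau by ~10 h, as typical for *P. aeruginosa*
in rich medium), noise sd 0.01 OD, $t_0 = 2$ h, $\tau = 0.75$ h per
decade, $\lambda = 1.5\,h^{-1}$, floor 0.05 OD. `lam = 0` disables
lysis entirely and reproduces the control exactly (the null phage — the
natural zero of the model). Noise is additive truncated-Gaussian on OD;
multiplicative noise was rejected because it would make the AUC oracles
nonlinear in the noise.

Determinism is structural: every generator is a pure function of
(params, seed), and a plate's global seed fans out to per-well
substreams by stable string hashing of (strain, phage, MOI, replicate),
so adding wells never perturbs existing ones.

Host-range matrices are generated with genus-block structure
(within-block lysis probability 0.7, between 0.1 by default). A
`planted_set` is post-edited to be the *unique* maximum-coverage set of
its size: each planted phage gets a private signature strain, and every
strain covered only by outsiders is also handed to a planted phage —
any other set of that size then misses at least one signature strain.
The default antibiogram resistance probabilities (penicillin,
cephalosporin and fluoroquinolone leads always resistant; carbapenem
lead resistant with probability 0.61) emulate a heavily resistant
clinical panel in which every strain is at least 3MRGN and the
3MRGN/4MRGN split is about 39/61.

What the generator does **not** emulate: condensation artifacts and
plate-edge effects, diauxic or biphasic growth, partial lysis
plateaus, phage–phage interference within wells, and correlated noise
across neighboring wells. Passing tests therefore demonstrate that the
arithmetic and the decision rules are right, not that the pipeline is
robust to every failure mode of real plate data.

## Numerical choices

* Trapezoid integration with linear interpolation at window endpoints:
  exact for piecewise-linear curves and invariant under grid
  refinement (tested). Irregular grids are accepted.
* Expanding-window ratios reuse the same control truncated to $[0, t]$;
  zero-area control prefixes raise errors rather than NaN.
* Degenerate inputs fail loudly with classed conditions
  (`phagekit_validation_error`, `phagekit_degenerate_control_error`,
  ...), never with silent NA propagation.
* Percent display rounding is half-up; machine columns keep full
  precision.

## Problem sizes used in the checks

The test suite verifies the optimizer against a brute-force oracle on
200 random instances with up to 12 phages at every $k$, recovers
planted 3-phage optima end-to-end from simulated plates (6 phages × 15
strains, duplicate wells, OD noise 0.02), and checks virulence recovery
over 20 seeds of triplicate MOI ladders. The acceptance script runs the
same workflow at panel scale (141 strains, 18 phages). These sizes were
chosen as representative of real susceptibility panels while keeping a
full run comfortably fast on a laptop.

## Known limitations

* The PKA lysis cutoff (0.8) and the rubric bins are conventions
  adopted from clinical phage-typing practice, not fitted quantities;
  both are parameters.
* $v_p$ depends on the stationary-onset rule; alternative readings of
  the onset threshold change $T_s$ and hence the absolute $v_i$ values
  (the ranking is usually stable, the absolute numbers are not).
* The cocktail model treats coverage as a pure set union — no synergy,
  antagonism, receptor competition or resistance evolution.
* MIC-based interpretation and ECOFFs are out of scope; only
  disc-diffusion zones are supported.
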