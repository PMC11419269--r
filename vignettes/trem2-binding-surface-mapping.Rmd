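---
title: "Mapping TREM2 ligand-binding surfaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping TREM2 ligand-binding surfaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trem2map)
```

TREM2 is a single-pass immunoreceptor on microglia whose V-type Ig
ectodomain engages a promiscuous set of disease-associated ligands --
apolipoprotein E, oligomeric amyloid-beta, TDP-43 oligomers, complement C1q
and the cytokine IL-34 -- through a small number of surfaces: a hydrophobic
patch formed by the CDR-like loops, an electropositive "basic site" around
the midsection of the domain, and a third surface called site 2. `trem2map`
implements the computational side of mapping which ligand uses which
surface: a sequence-based hydropathy-complementarity screen that proposes
binding regions, a 1:1 Langmuir model for biolayer interferometry (BLI)
sensorgrams with steady-state and kinetic dissociation-constant fitting
across a structured point-variant panel, and quantification of sequential
competition-binding experiments. Because raw instrument data for such
experiments are rarely deposited, the package also ships seeded generators
that produce every input the pipeline consumes.

## The hydropathy-complementarity screen

The screen rests on the observation that interacting protein segments tend
to pair hydrophobic against hydrophilic stretches in register. Sequences
are first converted to binary hydrophobicity maps: residue $i$ receives the
sign of its Kyte-Doolittle index $H(i)$ (`kd_hydropathy()`; the scale spans
$-4.5$ for Arg to $+4.5$ for Ile, and no residue sits at zero, so the sign
is always defined). A candidate motif of length $L$ is slid along the
target in single-residue steps, in forward and in reverse residue order --
the reverse pass models antiparallel backbone pairing. Each alignment is
scored twice:

* **percent match** -- the percentage of aligned positions whose signs are
  complementary (one $+$, one $-$);
* **degree of complementary hydropathy**
  $$C = \frac{\sum_{i=1}^{L} \lvert H(i) - H'(i) \rvert}{9\,L},$$
  the mean absolute index difference normalized by the scale span, so that
  $C \in [0, 1]$ with $C = 1$ exactly when every pair is Ile-against-Arg.
  The absolute value is required for the stated range: a signed sum could
  be negative.

An alignment is a *good hit* when percent match exceeds 75 **and** $C$
exceeds 0.5, both strictly; values landing exactly on a threshold are
rejected, and no rounding is applied before the comparison.

### Clustering hits into regions

Good hits are merged into candidate binding regions by interval union:
spans separated by at most `gap_tolerance` unhit residues (default 3) are
bridged. `cluster_hits()` implements the pure union (`min_hits = 1`), is
idempotent, and reports per-residue hit counts so regions can be shaded by
support depth. The full bidirectional screen additionally requires a
region to be supported by at least two good hits (`min_hits = 2`): a
single isolated alignment at these thresholds is indistinguishable from
background and does not constitute a cluster. Both knobs are exposed
because the clustering rule is genuinely a design choice -- region
*boundaries* move by a few residues as `gap_tolerance` varies, which is
why `run_binding_site_screen()` treats the region count, not exact
boundaries, as the robust output, and the acceptance suite reports counts
across gap tolerances 1-6.

### Screening configuration

`run_binding_site_screen()` runs both directions of the TREM2/IL-34
screen: the six IL-34 helices against the TREM2 Ig domain (precursor
residues 18-130), and the three TREM2 CDR loops (CDR1 39-46, CDR2 69-75,
CDR3 88-91) plus the four basic-site strands (47-50, 62-68, 76-78,
112-114) against the mature IL-34 sequence (residue 21 onward; residues
1-20 are the signal peptide). All coordinates are 1-based inclusive on the
full precursor, so residue labels like R47 and R76 mean what they do in
the variant panel; a 0-based half-open BED export is available but opt-in
(`write_regions_bed()`), to avoid silent convention mixing.

The bundled precursor sequences (`trem2map_extdata()`) were validated
against the residue identities the variant panel assumes -- every mutated
position (M41 through K123) carries the expected wild-type residue, which
`apply_mutations()` re-checks on every call. The IL-34 helix *spans* are
configuration, not data: helices 2-6 use the annotated helical regions of
the mature cytokine (71-85, 90-100, 119-129, 142-151, 156-179) and helix 1
is assigned to the N-terminal helix (35-53). Users with a
secondary-structure assignment from an actual structure should pass their
own table via `il34_motifs=`; region counts are stable under small span
shifts but individual helix hit counts are not.

### What the screen does and does not claim

On the bundled sequences at default settings the screen proposes two TREM2
regions -- one covering the central basic strands plus the entirety of
CDR2, one covering the strand that carries site 2 -- and five IL-34
regions. This is a hypothesis generator: it knows nothing about fold,
burial or glycosylation, and a good hit is a statement about sequence
hydropathy only. The companion BLI modules exist precisely to test such
hypotheses against binding data.

## The 1:1 Langmuir sensorgram model

For analyte concentration $c$ over a surface with capacity $R_{max}$,
association follows
$$R(t) = R_{eq}\left(1 - e^{-k_{obs} t}\right),\qquad
k_{obs} = k_{on} c + k_{off},\qquad
R_{eq} = \frac{R_{max}\, c}{c + K_D},$$
and dissociation decays as $R(t) = R_0 e^{-k_{off} (t - t_0)}$ with
$K_D = k_{off}/k_{on}$. `simulate_binding()` evaluates these closed forms
over a baseline/association/dissociation schedule (defaults 60/600/600 s
at 1 Hz -- long enough that the slowest default trace reaches >99% of its
plateau) plus optional additive Gaussian noise and linear drift.
`double_reference()` applies the standard correction: sample minus
loaded-sensor-in-buffer minus unloaded-sensor-in-analyte, after per-trace
baseline alignment.

Affinity tables print only $K_D$, so the generators accept any
$(k_{on}, k_{off})$ factorization at fixed $K_D$; the default pins
$k_{off} = 0.01\,\mathrm{s}^{-1}$, a mid-range off-rate for these ligands,
and derives $k_{on}$. Fitted $k_{on}$/$k_{off}$ from synthetic data are
therefore only meaningful relative to that convention; $K_D$ is the
portable quantity.

### Two fitting paths

* **Steady state** (`extract_req()` + `fit_steady_state()`): equilibrium
  responses -- the mean of the final 10% of the association phase, flagged
  if the signal is still rising by more than 2% projected over the phase --
  are fitted to the one-site isotherm $R_{eq}(c) = R_{max} c / (c + K_D)$.
  Used for the low-affinity, fast-exchanging ligand measured over a wide
  series (0.012-50 uM).
* **Kinetic** (`fit_kinetics()`): global Levenberg-Marquardt least squares
  of shared $k_{on}$, $k_{off}$, $R_{max}$ over the association and
  dissociation phases of the whole concentration series, on log-parameters
  to enforce positivity. Starts: $R_{max}$ from the top response times
  1.2, $k_{off}$ from a log-linear fit of the top trace's dissociation
  tail, $K_D$ from the concentration nearest half-maximal response.

Both paths recover generating values to well under 1% on noiseless traces,
and agree with each other to under 2% on equilibrated data; the test suite
asserts both, plus the linearity of fitted single-exponential rates in
concentration (slope $k_{on}$, intercept $k_{off}$).

### Biphasic traces

Oligomeric analytes produce sensorgrams that are sums of kinetic classes,
for which a 1:1 fit is not appropriate. `fit_kinetics()` therefore also
fits a two-component model (sum of two 1:1 terms) and raises
`biphasic_flag` when that model improves the residual RMS by more than a
factor of 2 -- a deliberately blunt criterion: it asks "is 1:1 clearly
wrong?", not "what is the true number of classes?". Numerically perfect
1:1 fits (residual RMS below $10^{-6}$ of the signal) skip the comparison,
since ratios of floating-point noise are meaningless. An equal-parameter
"two-component" mixture is correctly not flagged (it *is* 1:1).

### Fold changes and sentinels

`fold_change()` reports the $K_D$ ratio as a factor $\ge 1$ with an
explicit direction: `affinity-increase` when the variant binds tighter
than wild type. Published tables sometimes annotate direction
inconsistently; the package always derives it from the ratio. Variant
entries that are qualitative ("No Binding", "N.B.D.", "Binding (not
fit)", "Decreased binding") are typed sentinels in
`trem2_variant_table()` -- `NA` in the numeric columns with the verbatim
text in `*_note` columns -- and `fold_change()` returns a typed
not-computable result for them rather than NaN.

## Sequential competition binding

A competition experiment loads the receptor on the sensor, associates a
first ligand (or buffer, the control arm), dissociates in buffer, then
associates a second ligand. The readout
(`extract_assoc2_magnitude()`) is the *step height* of the second
association -- end minus start -- which insulates the metric against
incomplete dissociation of the first ligand;
`percent_decrease()` is $100\,(1 - m_{with}/m_{without})$, clipped at 100
when the competitor arm's step goes negative.

`simulate_competition()` integrates the two-species kinetics
(`deSolve::ode`, rtol $10^{-8}$/atol $10^{-10}$, phase-chained so each
boundary sample opens its phase with the continuous state):
$$\frac{dR_A}{dt} = k_{on,A} c_A (R_{max} - R_A - R_B) - k_{off,A} R_A$$
under the shared-site model (symmetrically for B), or independent
capacities when sites do not overlap. The second-association well contains
no first ligand, so bound competitor can only dissociate -- this single
protocol fact generates the order-of-addition asymmetry seen in real data:
a slow-off ligand pre-bound blocks a fast-off ligand far more than the
reverse, with no thermodynamic asymmetry required. The titration curve
(`titration_block_curve()`) is monotone in competitor concentration for
the shared-site model, and flat (up to competitor dissociation bleeding
into the total signal) for independent sites. Classification cutoffs --
full block at $\ge 90\%$, none below $10\%$, complete-block titration
level 95% -- are conventions, exposed as arguments.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their parameters and an explicit
integer seed; re-running with the same arguments is bit-identical, and
every trace embeds its generator parameters in metadata (and in the CSV
header comments written by `write_sensorgram_csv()`). Defaults mirror the
study conditions of the motivating experiments: concentration series
0.012-50 uM (13-point two-fold, steady-state ligand) and 62.5-1000 nM
(5-point two-fold, high-affinity ligands); Gaussian noise in the
0.005-0.02 RU range and linear drift around $10^{-5}$ RU/s when noise is
requested.

`make_complementary_pair()` plants a labelled benchmark for the screen: a
random motif plus a target whose planted window opposes each motif residue
with an index difference of at least `min_gap` (default 5, guaranteeing
100% match and $C \ge 5/9 > 0.5$ by construction). Residues that admit no
such partner at the requested gap (glycine at the default) are excluded
from generated motifs; impossible constraints are rejected rather than
silently relaxed. Background composition is uniform over the 20 residues.

What the generators deliberately do not emulate: spike/step artifacts,
mass-transport limitation, bivalent or avidity effects, analyte depletion,
and instrument-specific drift shapes. Passing tests therefore demonstrate
the *estimators'* correctness on data that satisfy the model assumptions --
they do not certify performance on real sensorgrams, where model
misspecification, not noise, is the dominant error source.

## Problem sizes and numerical choices

The test suite works at sizes chosen to exercise every code path while
staying interactive: 50-case property sweeps for the screen statistics, 30
random span sets against the brute-force clustering oracle, a 3x2
$(K_D, k_{on})$ recovery grid, 60-seed noise studies for the steady-state
fitter, 20 noisy-family kinetic refits, and 20-seed planted-window
recovery. Tie-break and degeneracy handling worth knowing: clustering on
an empty hit set returns an empty table (not an error); a steady-state
series with no curvature is reported as non-convergent rather than
returning an arbitrary extrapolation; `percent_decrease()` refuses a
non-positive control magnitude; and the ODE integrator reports failures
instead of returning partial traces.

## Known limitations

* The screen's IL-34 helix spans are annotation-derived configuration;
  a structure-based assignment may shift individual helix hit counts.
* Region boundaries from clustering are sensitive at the +/- few residue
  level to `gap_tolerance`; counts are the robust statistic.
* Kinetic fits assume the 1:1 model family; the biphasic flag detects
  gross violations but the package intentionally offers no
  mass-transport or bivalent models.
* Competitive $K_i$ estimation from competition traces is out of scope;
  the competition module quantifies block, it does not fit affinities.
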