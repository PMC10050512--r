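---
title: "A theta-gamma neural-mass model of working memory: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A theta-gamma neural-mass model of working memory: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`thetagamma` simulates a four-layer network of *neural masses*: each unit
("cortical column") is not a neuron but the mean-field description of four
interacting neural populations — pyramidal cells, excitatory interneurons,
and two classes of GABAergic interneurons with slow and fast synaptic
kinetics.  Each population transforms its average membrane potential into an
average spike density through a sigmoid,

$$z(v) \;=\; \frac{2e_0}{1+e^{-r\,(v-v_0)}},$$

with $e_0 = 2.5$, $r = 0.56\ \mathrm{mV^{-1}}$, $v_0 = 6\ \mathrm{mV}$, so
spike densities live on a 0–5 scale (an object trace of 5 means all of its
features are fully active; 4 means roughly 80% are; a 70% cue produces 3.5).
Synapses are second-order linear kernels with alpha-function impulse
response $h(t) = G\,\omega\,t\,e^{-\omega t}$; each population owns one
kernel per input class.  Every column is identical; one column codes one
binary feature, and an "object" (an item held in memory) is a set of
features on a 20 × 20 lattice (400 features by default).

The four layers divide the labor:

* **WM** maintains items: its pyramidal populations carry an auto-excitatory
  loop $C_{pp}$ that latches a cued item at saturation.  Presenting a new
  cue suspends $C_{pp}$ for the duration of the cue, which resets the old
  content — the reset is what lets the store be refreshed.
* **L1** is an auto-associative layer: Hebbian excitatory synapses $W$
  between the features of an object let a 70% cue recover the missing 30%.
  With moderate input from WM, the interplay of this recurrent excitation
  with the slow GABAergic population makes the layer relax-oscillate at
  theta (~5 cycles/s): each ON phase reconstructs the whole object, each
  OFF phase silences it.
* **L2** generates gamma.  Hebbian synapses $K$ run from pyramidal cells to
  the *fast* interneurons of other columns **within** an object (net effect:
  reciprocal inhibition, which synchronizes), and anti-Hebbian ultrafast
  synapses $A$ run to the fast interneurons of **other** objects (net
  effect: near-instantaneous cross-object suppression, which segments).  A
  disinhibition gate normally clamps all L2 fast interneurons; it opens when
  the summed L1 activity crosses a threshold, so L2 is only active during
  theta ON phases.
* **L3** repeats the K/A arrangement, which sharpens the segmentation, and —
  in the sequence modality — sends trained hetero-associative excitatory
  synapses $W^{L_2L_3}$ back to L2, from each list item to its successor.
  An item bursting in L3 thereby ignites the next item in L2, and the chain
  replays the stored list inside each theta ON phase: a gamma sequence
  nested in theta.

Two modalities share the same trained network and differ in two couplings
only: the **semantic** configuration triples the WM→L1 gain (L1 saturates
tonically, no theta; several items are held at once and segmented purely in
gamma) and keeps $W^{L_2L_3} = 0$; the **sequence-ordering** configuration
uses the weaker WM→L1 gain (theta present) and trains $W^{L_2L_3}$.

## Training

Objects are presented one at a time with drives strong enough to clamp the
stimulated populations at saturation, so no oscillation occurs during
training and the learning rules see essentially binary activities.  Step i
(2000 epochs) forms $W$ in L1 (Hebbian, pyramidal–pyramidal), $K$ in L2/L3
(Hebbian, pyramidal → fast interneuron; both populations are driven), and
$A$ in L2/L3 (anti-Hebbian: potentiated when the presynaptic pyramidal
population is active while the postsynaptic fast interneuron is silent;
depressed to zero when both are active, so features shared by two
overlapping objects build no fast inhibition onto either of them).  Step ii
(1000 epochs, sequence modality only) presents consecutive list items to
L3/L2 simultaneously and forms $W^{L_2L_3}$.

Because the clamped activities are constant across epochs, the saturating
per-epoch recurrence $w \leftarrow w + \lambda\,\mathrm{pre}\,\mathrm{post}\,
(w_\mathrm{cap}-w)$ has a closed form, which the implementation uses; a test
verifies it equals iterating the single-epoch rules.  After the epochs the
synapses entering each column are normalized: $W$ rows to `W_sum` = 90, $K$
rows to `K_sum` = 200, $A$ rows so the mean nonzero incoming synapse equals
`A_max`, and $W^{L_2L_3}$ rows to `W23_sum` = 700.  The normalization is the
reason objects of different sizes receive the same total drive and
oscillate at the same frequencies, and it makes the trained network
independent of the epoch count once the rules have saturated.

## Parameters

The column constants follow the classical alpha-rhythm mass-model family:
excitatory kernel $G_e = 3.25$ mV, $\omega_e = 100\,\mathrm{s^{-1}}$; slow
GABA $G_s = 22$ mV, $\omega_s = 40\,\mathrm{s^{-1}}$; fast GABA $G_f = 40$
mV, $\omega_f = 250\,\mathrm{s^{-1}}$; internal couplings $C_{ep} = 135$,
$C_{pe} = 108$, $C_{sp} = C_{ps} = 33.75$, $C_{fp} = 40.5$, $C_{pf} = 108$,
$C_{fs} = 13.5$, $C_{ff} = 18$ (fast-interneuron auto-inhibition), and
$C_{pp} = 250$ in WM only.  The long-range classes have time constants of
about 7.7 ms ($W$, excitatory), 6.8 ms ($K$, onto fast interneurons) and
0.8 ms ($A$, first-order ultrafast).  The gains that are genuinely free in
this architecture — the four inter-layer couplings, the four normalization
targets and the ultrafast gain `G_A` — were calibrated once, jointly,
so that the emergent rhythms sit where the model family places them: an
isolated noise-driven column peaks near 10 Hz (alpha), the trained L1
oscillates near 5 cycles/s (theta), a single object in L2 near 30–35 Hz
(gamma), four simultaneously cued objects segment at a ~55–70 Hz summed
burst rhythm, and the cued list replays completely within each theta ON
phase.  They were frozen before the statistical batteries were run and are
exposed in `tg_params()`.

Noise is uniform per column, redrawn every `noise_dt` = 1 ms and held in
between.  Holding the samples makes the noise *band-limited*: its effective
strength is independent of the integration step (independent draws per
0.1 ms step would be filtered to physical irrelevance by the synaptic
kernels).  Ranges: WM background U(0, 40), other layers U(0, 150), the
isolated-column experiment U(200, 400), and the dreaming drive U(80, 160)
applied to every L1 pyramidal population while both WM↔L1 couplings are cut.

## Numerical choices

Integration is fixed-step explicit Euler at `dt` = 0.1 ms, small against
the fastest kernel (0.8 ms); halving `dt` changes a 1 s column trajectory by
less than 1% relative L2 norm (tested).  Recordings are stored at 1 kHz.
All kernel states start at zero and the first 50 ms are excluded from all
metrics.  The theta gate opens when the summed L1 pyramidal activity
exceeds half the saturated activity of an average-sized object and closes
below 90% of that threshold (the hysteresis prevents chatter); the clamp on
L2 fast interneurons is routed through the ultrafast kernel so the gate
switches within a millisecond.  Clamped training states are computed
algebraically (damped fixed-point iteration on the DC equations) rather
than by integrating to steady state; a test confirms both routes agree.

Spectral peaks are estimated from a smoothed periodogram (about 1 Hz
smoothing bandwidth, 10% taper); a trace whose band maximum does not exceed
three times the band's spectral median is reported as arrhythmic (`NA`).
Recognition events use the activity scale directly: an object is recognized
when its mean trace crosses 4 (≥ ~80% of features) while every other
object is below 1; the classification is insensitive to the exact
thresholds on clean runs (tested for high ∈ [3.5, 4.5], low ∈ [0.5, 1.5]).
Theta cycles for sequence decoding are taken from the gate state recorded
during the simulation, not re-estimated from the traces, which avoids
estimator circularity.

## What the pattern generator does and does not emulate

`generate_collection()` builds the study conditions: nine orthogonal
objects with equal (16) or spread (8–24) sizes, or ten equal-sized objects
with 20% feature overlap on the pairs (2, 10) and (4, 6).  Feature
positions are uniform on the lattice — position carries no information, and
a connected-blob mode exists only for visualization.  These are abstract
binary feature sets; passing the package's tests shows that the *dynamical
machinery* (maintenance, completion, binding, segmentation, ordered replay,
spontaneous recombination) works on such idealized items.  It does not show
anything about graded features, correlated real-world feature statistics,
or items sharing more than a small fraction of features — the replay
mechanism cannot disambiguate an item that appears in two lists, so stored
lists must overlap only partially.

## Design decisions taken where the design was open

* **Epoch semantics.** One epoch = one pass over all objects (step i) or
  all consecutive pairs (step ii), in listed order.  Clamped-steady-state
  learning plus normalization makes the result order-insensitive (tested).
* **Active/silent threshold** for the learning rules: 2.5, the midpoint of
  the 0–5 scale; clamped activities are bimodal, so any mid threshold is
  equivalent.
* **Ultrafast synapses** are a first-order kernel with τ = 0.8 ms rather
  than algebraic coupling; at `dt` = 0.1 ms this is well resolved and keeps
  the stepping uniform.
* **C_pp reset** lasts exactly the cue duration and restores instantly at
  cue offset.
* **Gate in the semantic modality**: the same mechanism is used; because L1
  is tonically saturated there, the gate simply stays open, which
  reproduces the absence of theta without a separate code path.
* **Anti-Hebbian reset**: one co-active presentation resets the synapse to
  zero.  This is what leaves shared features of overlapping objects free of
  mutual fast inhibition, the ingredient that lets the dreaming mode link
  one list's end to the other list through the shared features.
* **Cue feature subsets** (which 70% of an object is stimulated) are drawn
  at run time from the trial seed and stored in the recording.

## Problem sizes

The full network is 4 × 400 columns; training is algebraic and takes well
under a second; one second of simulated time takes a few seconds of compute.
The statistical battery (`table2_battery()`) runs 20 independent trials of
1.5 s by default, each with a freshly drawn collection and noise stream; the
test suite scales it to 10 trials with correspondingly widened binomial
bands.  Unit tests run on a miniature 8 × 8 lattice with four 6-feature
objects, which preserves all structural behaviors.

## Known limitations

* The number of items that segment cleanly in the semantic configuration is
  4–6.  With stronger ultrafast inhibition (`A_max` 0.15 → 0.20) the
  collective rhythm slows from ~60–70 Hz toward ~17–20 Hz as competition
  deepens, but with 7–9 simultaneous items the network tends toward a
  symmetric mutually-suppressed state in which not every item reaches an
  exclusive recognition, rather than the slow serialized popping that would
  recognize all nine.  The summed-activity rhythm and its slowing with load
  are reproduced; the 9-item success statistics are not.
* The replayed list length is bounded by the theta ON phase: about six
  items per cycle with the default kinetics.
* Lowering the fast-interneuron auto-inhibition $C_{ff}$ — a perturbation
  of interest because it weakens the machinery that paces gamma — leaves
  the replay intact in this parameterization, while *raising* it four-fold
  truncates the replay to two or three repeating items.  The qualitative
  failure mode exists but its sensitivity direction is inverted relative to
  what one might expect from the disinhibition argument; the packaged
  perturbation `apply_pathology(net, "cff_quarter")` keeps the faithful
  direction (reduction).
* Weakening the ultrafast synapses (`a_quarter`) reliably produces the
  expected breakdown: items superimpose within the theta cycle and
  segmentation fails.
* Spontaneous (dreaming) replay is majority-structured: most transitions
  between successive bursts follow a stored list or jump between lists via
  the shared features, but isolated irregular transitions (reversals,
  skips) occur, so not every decoded episode is a perfect sublist or
  suffix-plus-sublist concatenation.

## Reproducing the numbers

`scripts/acceptance.R` (repository root) re-runs the isolated-column,
theta, gamma, nine-object, battery and dreaming experiments from scratch
with a single seed and writes the measured quantities as JSON; see the
README for the command.
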