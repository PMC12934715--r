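---
title: "Modelling whole-brain default-mode dynamics with AdEx mean fields"
author: "mfbrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling whole-brain default-mode dynamics with AdEx mean fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`mfbrain` simulates large-scale brain dynamics as a network of coupled
excitatory/inhibitory (E/I) mean-field nodes. Each brain region contains
one excitatory and one inhibitory population of adaptive exponential
(AdEx) integrate-and-fire neurons; the population rates $r_E$, $r_I$ obey
relaxation dynamics towards a fitted transfer function $F_\mu$,

$$T\,\frac{dr_\mu^i}{dt} = F_\mu\!\big(r_{E}^i + r^{i}_{\mathrm{ext},\mu},\,
r_I^i,\, w^i\big) - r_\mu^i ,$$

with $T$ the relaxation time (default 5 ms) and $w$ the mean
spike-frequency adaptation current of the excitatory population,

$$\frac{dw^i}{dt} = -\frac{w^i}{\tau_w} + b\, r_E^i .$$

Regions are coupled through a directed, weighted connectome: only
excitatory rates propagate, with transmission delays $D_{ij}/v_{ax}$
derived from tract lengths ($v_{ax} = 3$ m/s by default). The afferent
drive of region $i$,

$$a_i(t) = g \sum_{j \ne i} C_{j \to i}\, r_E^j\!\left(t -
\tfrac{D_{ij}}{v_{ax}}\right) + \nu_{\mathrm{bg}} + \xi_i(t),$$

reaches the E population with weight $R_E = 1$ and the I population with
weight $R_I = R$. The ratio $R$ — how strongly long-range excitation
targets inhibitory versus excitatory neurons in destination regions — is
the central circuit-level parameter: the stimulation analyses default to
$R = 1.4$.

### The transfer function

$F_\mu$ uses the semi-analytic conductance-based formulation. From the
presynaptic rates, the synaptic quanta ($Q_e$, $Q_i$), synapse counts
($K_e$, $K_i$) and decay time (5 ms), the mean, standard deviation and
autocorrelation time of the membrane potential are computed; the
effective spike threshold is a second-order polynomial in the normalised
statistics; and the output rate is

$$F = \frac{1}{2\tau_V}\,\mathrm{erfc}\!\left(\frac{V^{\mathrm{eff}}_{\mathrm{thr}}
- \mu_V}{\sqrt{2}\,\sigma_V}\right).$$

The ten polynomial coefficients are not taken from the literature: they
are fitted with `fit_transfer()` against the package's own AdEx spiking
oracle (`measure_transfer_grid()` runs unconnected AdEx populations under
Poisson drive and records stationary rates; the fit inverts the erfc
relation at every positive-rate sample and solves a linear least-squares
problem). The shipped default coefficients
(`default_transfer_functions()`) were produced by
`tools/fit_default_transfer.R` over a $8 \times 8 \times 2$ drive grid
(0–30 Hz excitatory, 0–60 Hz inhibitory per-synapse rates, adaptation 0
and 100 pA). Because the quanta enter the membrane statistics
analytically, regional $Q_E$/$Q_I$ perturbations require no refitting.

This form is accurate in the fluctuation-driven regime (output rates
roughly below $1/(2\tau_V) \approx 100$ Hz). Inputs outside the fitted
domain are clamped to its boundary, so extreme drives saturate rather
than extrapolate; a network pushed into that ceiling freezes, which is
how the high-$Q_E$ loss-of-responsiveness regime manifests here.

A saturating-sigmoid fallback (`sigmoid_transfer()`) exists for fast
tests; it is not fitted to spiking data and is not used in the
scientific analyses.

### Biophysical constants

Membrane capacitance 200 pF, leak conductance 10 nS, leak reversals
−63 mV (E) / −65 mV (I), spike sharpness 2 mV (E) / 0.5 mV (I),
threshold −50 mV, membrane noise 0.0315 pA, quanta $Q_e = 1.5$ nS,
$Q_i = 5$ nS with 5 ms decay, adaptation off ($b = 0$) unless an
experiment varies it. Synaptic reversal potentials are not part of that
set and default to the standard conductance-based values 0 mV and
−80 mV. The adaptation decay time defaults to 500 ms — the conventional
AdEx timescale — and is config-exposed, as are $T$ and the reversal
potentials. The adaptation increment `b` is applied to the adaptation
*current* once per spike; we quote its magnitudes (0–100) without
attaching a conductance unit.

## The spiking oracle

`simulate_spiking()` integrates the full AdEx equations
(Euler–Maruyama; conductance-based synapses with exponential decay;
spike at $V_{thr} + 5\Delta$, reset to $E_L$, no refractory period) for
a small network — by default 80 E and 20 I neurons at 5% random directed
connectivity. It serves two roles: the sampling engine behind
`fit_transfer()`, and an independent check that the mean-field fixed
points track a genuinely spiking network (the acceptance suite compares
stationary excitatory rates on a 3×3 grid of external drives and
requires mean agreement within 20%, a tolerance that acknowledges both
finite-size sampling error and the mean-field approximation itself).
In the sharp-threshold, noise-free limit the simulator reproduces the
closed-form leaky integrate-and-fire interspike interval to better than
2%, which pins down the membrane integration independently of any rate
model.

## The synthetic brain

Real tracer connectomes are not redistributable here, so every analysis
runs on a generated 24-region bilateral connectome
(`synthetic_connectome()`) that reproduces the structural features the
scientific claims rest on:

* a DMN-like core (`RSCv`, `Cgv`, `PrL`) with strong within-module
  coupling, plus a posterior extension (`RSCd`, `PTLp`);
* an insula-like hub (`AI`) with **no direct projection to the core**
  but an indirect pathway `AI → Rel1 → Rel2 → core`;
* a frontal pair reciprocally connected with the hub, background
  regions, and callosal edges between homotopic partners;
* mirrored weights and tract lengths (lognormal, median 3 mm within
  hemisphere and 6 mm across, so delays are of order 1–2 ms).

The relay pathway deliberately has **odd length (three hops)**. At the
default operating point with $R > 1$ the network is
inhibition-dominated: a sustained increase in the afferent drive of any
region *lowers* its stationary excitatory rate, so each hop inverts the
sign of a propagating perturbation. Hub stimulation (delivered to the
hub's E population) excites the hub, suppresses the first relay,
disinhibits the second, and suppresses the core — net suppression after
three hops, with the defining feature that the hub has no monosynaptic
route to the core. With $R = 1$ the operating point shifts and the
suppression weakens below detectability; raising the core's $Q_E$ to
2.5 nS drives it into the saturated unresponsive regime and the evoked
delta vanishes entirely. These two contrasts — suppression under
E-to-I-biased routing, loss of suppression under balanced routing with
excess local excitation — are the mechanism the acceptance suite checks.

What the generator does *not* emulate: the heavy-tailed weight
distribution, in-strength heterogeneity and hundreds of regions of a
tracer connectome, laminar structure, or multiple interneuron classes.
Passing tests therefore demonstrate the mechanism on the motif, not
quantitative reproduction of any atlas-scale result.

### Frozen default conditions

The operating point was calibrated once, before the acceptance suite was
finalised, and is not adjusted per analysis: background drive
$\nu_{\mathrm{bg}} = 0.6$ Hz, Ornstein–Uhlenbeck afferent noise with
stationary sd 0.1 Hz and 5 ms correlation time, global coupling scale
$g = 0.5$, hub-entry weight 1, relay-chain weight 2, within-module
weight 1, between-module weight 0.3. At these values the spontaneous
excitatory rates sit at 0.3–1 Hz on the steep flank of the transfer
function (the fluctuation-driven regime of this model family), spontaneous
functional connectivity shows a DMN cluster segregated from an
insular–frontal cluster, and the 0.1 Hz stimulus produces core deltas of
order $3 \times 10^{-3}$ Hz — small against the baseline but
sign-consistent across every realization.

An alternative normalisation for raw tracer weights (divide by the
maximum in-strength, `coupling_scale()`) is provided for imported
connectomes; with the synthetic brain's fitted operating point it leaves
afferents too weak to propagate perturbations, hence the constant
default.

## Stimulation, perturbation and sweep experiments

The stimulation protocol follows the optogenetic paradigm: square
pulses of firing rate, amplitude 0.1 Hz, 0.5 s on every 2 s, beginning
after a 5 s transient; the full protocol runs 150 s (72 complete
epochs), while parameter sweeps use the reduced 35 s / 20 realization
design. Stimulation is added to the afferent drive of the target
regions' E populations; a config flag (`stim_to_I`) routes it to both
populations scaled by $R_\mu$, but with $R > 1$ that makes the
stimulated region suppress itself, which contradicts the excitatory
intent of the paradigm, so E-only is the default. Multi-subdivision
targets are stimulated simultaneously at equal amplitude.

`apply_ei_perturbation()` implements regional E/I imbalance by replacing
$Q_I$ (or $Q_E$, or $b$) in the target regions bilaterally, leaving the
rest of the network untouched. `parameter_sweep()` crosses regional
$Q_E$ (0.1–4.1 nS, step 0.2) and $Q_I$ (4–6 nS, step 0.1) — 441 cells
per plane — with $R \in \{1, 1.2, 1.4, 1.6\}$ and
$b \in \{0, 25, 50, 100\}$ (7,056 cells in total), persisting each cell
to CSV so interrupted sweeps resume and re-runs are idempotent.

Each sweep cell is labelled with a regime: `robust_suppression`,
`unresponsive`, `local_reversal`, `distributed_reversal` or
`fragmentation`, by `classify_failure_mode()`. The rules need explicit
thresholds that heatmap descriptions leave open; we use: significance
from the within-cell Wilcoxon tests at FDR 0.05; unresponsiveness when
the retrosplenial delta is non-significant and smaller in magnitude than
5% of the across-grid interquartile range of that delta; fragmentation
when the DMN group occupies two or more clusters when the
complete-linkage tree of spontaneous FC is cut at height 0.95 on the
$1 - r$ scale (between the height at which the intact DMN completes,
about 0.89, and the height at which it would join the insular–frontal
branch). Precedence on conflict: fragmentation, then distributed
reversal, then local reversal, then unresponsive; cells matching no rule
are conservatively labelled unresponsive. Frozen (zero-variance) cells
have undefined FC and are never labelled fragmented.

## Statistics

The suppression statistic is the pre/post delta: trials are 2 s windows
starting 1 s before each pulse onset; the delta is the mean of the
trial-averaged trace over the post-onset second minus the pre-onset
second. An epoch counts only when the full stimulation period containing
it fits inside the run, so a 150 s run yields
$\lfloor (150 - 5)/2 \rfloor = 72$ trials.

Per-seed deltas are tested against zero with a two-tailed one-sample
Wilcoxon signed-rank test, and paired designs (same seeds, two
conditions) with the paired test on per-seed differences. The
implementation computes the exact tie-aware null distribution (zeros
dropped, midranks for ties, dynamic programming over doubled ranks) for
$n \le 25$ and a tie-corrected normal approximation above; a full
sign-assignment enumeration oracle verifies it for all $n \le 10$ in the
test suite, and `stats::wilcox.test` cross-checks the tie-free cases.
All-zero difference vectors are flagged as untestable and treated as
non-significant. FDR correction (Benjamini–Hochberg via
`stats::p.adjust`) is applied over the readout regions of one
experiment, never across experiments.

Functional connectivity is the Pearson correlation of excitatory rate
series after transient removal, averaged elementwise over realizations
with the diagonal forced to 1 (which population's rate enters FC is a
free choice; E rates are the modelled output of interest). Clustering
is complete linkage on $1 - r$ via `stats::hclust`; merge tables and a
nested-list text serialization are exported.

## Numerical choices

* Integration: stochastic Heun by default (Euler selectable), fixed
  step 0.1 ms; rates clamped at 0 Hz after each step; no upper clamp
  (the transfer-function domain box provides saturation).
* Delays are rounded to integer multiples of the step; connected pairs
  whose delay rounds to zero are propagated with a one-step delay, since
  the explicit scheme reads the rate history before the current step is
  written.
* The afferent noise is an exactly-discretised Ornstein–Uhlenbeck
  process sharing the R RNG stream, so a single integer seed fixes
  initial conditions and the noise realization bit-for-bit; homotopic
  pairs can share one realization (`mirror_noise`) for symmetry tests.
* Each realization starts from the uncoupled stationary state of its
  region (damped fixed-point iteration, residual below $10^{-8}$ Hz),
  jittered by a uniform 0.5–1.5 factor so different seeds explore
  different basins.
* Fitting excludes zero-rate samples (they carry no threshold
  information) and samples at the rate ceiling ($2 r \tau_V \ge 2$,
  where the erfc inversion is undefined); a rank check rejects
  degenerate designs.
* Trial windows are aligned by nearest recorded sample; the default
  recording interval of 1 ms is far below the 1 s analysis windows.

## Problem sizes

The test and acceptance runs use desk-scale versions of each analysis:
transfer-function fits on a $5 \times 5 \times 2$ grid with 60 neurons
per population and 5 s per point; oracle comparisons on a $3 \times 3$
grid with 100-neuron networks and 10 s runs; stimulation campaigns of
20 realizations at 35 s (the sweep design); surrogate calibrations with
200 null campaigns of 20 realizations each. These sizes were chosen so
that every claim is recomputed from scratch in minutes while keeping
the statistics meaningful (20 sign-consistent realizations already
saturate the exact Wilcoxon at $p \approx 2 \times 10^{-6}$).

## Known limitations

* The mean-field treats all excitatory and all inhibitory neurons within
  a region as identical; no laminar structure, no interneuron subtypes,
  and the same E/I template for all regions.
* Only one neuromodulatory axis (spike-frequency adaptation) is
  represented.
* The erfc transfer form degrades in the mean-driven regime; analyses
  keep the network in the fluctuation-driven range, and excursions
  beyond it saturate by construction.
* The inhibition-dominated sign-inversion mechanism means conclusions
  about multi-hop pathways depend on path parity and on each relay's
  operating point; on heterogeneous real connectomes both enhanced and
  suppressed intermediates will coexist, which the homogeneous synthetic
  motif only caricatures.
* Evoked effect sizes at the default stimulus amplitude are three orders
  of magnitude smaller than baseline rates; they are detectable because
  they are locked to the protocol and consistent across realizations,
  not because they are large.
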