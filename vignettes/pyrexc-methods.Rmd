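---
title: "Models and methods behind pyrexc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pyrexc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pyrexc)
```

`pyrexc` simulates how small parameter variants of voltage-gated ion
channels and Ca²⁺ transporters alter the excitability and input/output
repertoire of layer V pyramidal cells (L5PCs). This vignette documents the
model, the numerical choices, the protocol parameters and their defaults,
and what the reduced, desk-scale setting can and cannot show.

## The reduced cell and its currents

The default morphology is a deliberate reduction: a cylindrical soma
(25 × 25 µm), twelve apical segments of 100 µm spanning path distances
0–1200 µm — so every protocol site (200, 600, 685–885, 700, 850, > 1000 µm)
falls on a distinct compartment — and one lumped basal cylinder. Full SWC
morphologies are accepted through `read_swc()`, but all packaged results
use the reduced cell. Membrane capacitance is 1 µF/cm², axial resistivity
150 Ω·cm.

Thirteen currents are available: fast and persistent Na⁺ (`Nat`, `Nap`),
h-current (`Ih`), muscarinic, persistent, transient and Kv3.1-type K⁺
(`Im`, `Kp`, `Kt`, `Kv31`), high-, low- and medium-voltage-activated Ca²⁺
(`CaHVA`, `CaLVA`, `CaMVA`), the Ca²⁺-activated SK and BK K⁺ currents, and
leak. Every voltage-dependent gate is a Boltzmann steady state
`1/(1 + exp(-(v - v_half)/slope))` raised to a small integer power, with a
constant, Gaussian-bell or sigmoid voltage-dependent time constant; SK and
BK carry Hill-type Ca²⁺ gates. These parameterizations are
package-authored: they were tuned only to reproduce the qualitative
regimes described below, and no attempt is made to replicate any published
kinetic parameter set or trace. `CaMVA` is treated as a kinetic alias of
the low-voltage-activated current with a modestly depolarized activation
range rather than given invented distinct kinetics.

Channel densities follow per-region distribution rules: constant,
exponential, linear-then-constant, sigmoid, and the hot-zone profile that
multiplies the apical HVA/LVA Ca²⁺ densities by 10× / 100× inside
685–885 µm. Intracellular Ca²⁺ follows a single-pool model per
compartment: a fraction γ of the inward Ca²⁺ current charges the pool
(shell depth 0.1 µm) and the pool relaxes exponentially to the 10⁻⁴ mM
resting level; outward pumping beyond the resting level is folded into the
decay term, so the pool never undershoots rest.

### The two reference profiles

* **tonic** — regular single-spike firing across its 0.3–1.4 nA analysis
  range (≈3.5–9 Hz), somatic SK as the dominant rate control
  (γ = 0.02, decay 120 ms, somatic CaHVA 10⁻³ S/cm²). The apical Ca²⁺
  densities are small outside the hot zone so that synaptically evoked
  dendritic Ca²⁺ transients straddle the 1.1–1.2 × 10⁻⁴ mM discretization
  thresholds of the coding analysis instead of saturating them.
* **bursting** — rhythmic bursts of 3–5 spikes at the 0.75 nA reference
  current. The mechanism is a two-region relaxation oscillation: a dense
  apical CaHVA conductance (3 × 10⁻³ S/cm², thicker 4-µm trunk) supports a
  collective dendritic plateau ignited by back-propagating spikes; the
  slow apical SK gate (τ = 30 ms) terminates the plateau after a few
  somatic spikes; and the dendritic Ca²⁺ pool (γ = 1.6 × 10⁻³, decay
  150 ms — scaled so plateau transients peak a few-fold above the SK
  half-activation of 4.3 × 10⁻⁴ mM) sets the interburst interval. A single
  100-µm segment cannot hold a plateau against its axial load; the plateau
  is collective, which is why the density and trunk diameter matter.

Raising SK density in the bursting profile shrinks the modal burst
monotonically (4 → 3 → 2 → 1 across a 1–4× scan). In the tonic profile,
raising apical fast-Na⁺ density by up to +120% strengthens backpropagation
and hot-zone Ca²⁺ entry but does **not** convert the reduced cell to
bursting: the modal spikes-per-burst scan is constant at 1. The
non-decrease property therefore holds, but without the burst conversion
seen in full-morphology models; this is a known limitation of the
14-compartment reduction (somatic afterhyperpolarization and dendritic
load are lumped too coarsely for the conversion boundary to be crossed).

## Numerics

The cable equation is advanced by a θ-scheme (θ = 0.5, Crank–Nicolson
style) with a Hines-ordered tree solve; gates use staggered Rush–Larsen
exponential updates from lookup tables (0.025 mV resolution); the Ca²⁺
pool relaxes exponentially within each step. The default step is
dt = 0.025 ms. Correctness is enforced by tests, not scheme identity: a
one-compartment configuration tracks an independent stiff ODE solve
(`deSolve::lsoda`) to < 0.2 mV over 500 ms, and halving dt moves spike
times by < 1 ms over ≈1-s windows on both profiles. Spike-time
discrepancies accumulate as phase drift in long tonic trains (each
interspike interval ends in a slow threshold approach), so convergence is
stated over protocol-length windows, not arbitrary horizons. Simulations
are bit-deterministic given model, stimuli, events and dt; divergence
(non-finite state) raises an error naming the first offending time. Every
protocol discards a 500-ms equilibration. Spikes are upward 0-mV crossings
at the soma with a 2-ms lockout; bursts are separated by interspike gaps
above 50 ms and the first two bursts of each train are discarded.

## Synapses and stimulation

Dual-exponential conductances are peak-normalized so one event's maximum
equals `g_max`; the alpha probe peaks one time constant after its event.
NMDA is filtered by the Jahr–Stevens Mg²⁺ sigmoid
`1/(1 + exp(-0.062 V) [Mg]/3.57)` at 1 mM, evaluated at the compartment's
instantaneous potential. Short-term depression is the depression-only
resource recursion with recovery D = 800 ms and release fraction
U_se = 0.6 (glutamatergic) or 0.25 (GABAergic). The in-vivo-like
background places 10,000 glutamatergic synapses (co-located AMPA + NMDA
pairs sharing Poisson event trains at 0.72 Hz, 0.4 nS per receptor — the
AMPA:NMDA peak ratio is 1:1 by default and configurable) and 2,500
GABAergic synapses (7.0 Hz, 1.0 nS, reversal −80 mV) uniformly over the
apical and basal trees by path length (not per compartment); the soma
receives none. On the reduced cell this background acts primarily as a
~0.35 µS shunt: the membrane sits near −75 mV and spontaneous rates stay
far below the single-hertz rates such a background produces on a
full-size cell, because the reduced membrane area makes the fixed synapse
count overwhelmingly dominate the leak. The up/down-state protocols
remain well defined — they probe stimulus-evoked responses on top of the
shunt — but absolute spontaneous rates should not be read off this model.

## Variant representation and downscaling

A variant is a set of parameter deltas: additive mV shifts on
half-activation voltages; multiplicative factors on slopes, time
constants, conductances and the Ca²⁺ decay constant. Deltas address
parameters by dotted paths (`CaHVA.act.v_half`, `SK.gbar`,
`calcium.decay_tau`); applying them never mutates the input model, and a
delta naming a channel absent from the model is an explicit error.

The downscaling conditions are: (I) the threshold amplitude of a 5-ms
somatic square pulse, (II) the threshold peak conductance of a distal
apical alpha conductance (τ = 5 ms; the probe sits at 850 µm, the same
distal site the coincidence protocol uses for its far EPSP), and (III) the
joint threshold of the combined stimulus (alpha conductance 2.5 ms after
the somatic pulse) may each change by at most 15%; (IV) the integrated
absolute f-I difference may be at most 10% of the control f-I integral.
Because condition III names one bound but two amplitudes, the combined
stimulus is parameterized by a single scale applied to the fixed control
pair (A1, A2); the 15% bound applies to that scale. This is a design
choice, not an assertion about the original protocol's intent. All
thresholds are bisected to 0.5% relative tolerance; the scale *c* is the
smallest point of an ascending 0.05-resolution scan of (0, 2] at which any
condition fails (checked cheapest-first), with *c* = 2 when none fails —
the original variant then serves as its own ε = 1/2 scaling. Multiplicative
deltas scale linearly in the effect, `f → 1 + cε(f − 1)`, so ε-mirrored
variants are exact opposites; geometric scaling (`f^{cε}`) was rejected
because it breaks that antisymmetry. Strongly nonlinear variants (e.g.
large Na⁺-conductance factors) can violate a condition in the mirrored
direction even at |cε| < c; the ε-consistency property is therefore
checked on variants in the near-linear regime, and the per-variant
asymmetry ratio |(P₊−P₀)+(P₋−P₀)|/|P₊−P₋| is reported by the analysis
scripts rather than asserted.

## Phenotype protocols

**f-I curves.** Somatic DC for 3.5 s, rate from the final 3 s; analysis
ranges 0.3–1.4 nA (tonic) and 0.65–0.9 nA (bursting); the integral average
is the trapezoid integral divided by the range width.

**Coincidence windows.** Up state: a 600-ms holding pulse at 200 µm at 85%
of its own spike threshold, a 5-ms somatic pulse in its middle at 40% of
the somatic threshold *resolved under the holding depolarization* (at the
resting threshold the pulse is suprathreshold in the up state and the
window degenerates to the flat back-propagating-spike response — the
state-conditioned threshold keeps the probe genuinely subthreshold), and
an EPSP-like current (rise 0.5 ms, decay 5 ms) at 600 µm at 50% of its own
threshold (an 850 µm / 15% preset is also provided). Down state: no
holding pulse and a 135% somatic pulse resolved at rest. The response per
inter-stimulus interval (positive ISI = apical after somatic) is the
maximum potential at 700 µm over the window from the earlier stimulus
onset to 300 ms after the somatic pulse; window integrals subtract a
baseline (−50 mV default) and integrate over ISI ∈ [−30, 70] ms. The
noisy variant replaces the holding pulse by background-rate modulation
(0.504 / 0.792 Hz excitatory drive, i.e. 0.72 Hz × 0.7 or × 1.1), uses a
25% EPSP amplitude in the up state, and averages the mean 700-µm
potential over the 20 ms after the somatic pulse across 125 repetitions
(fewer in the scaled-down test runs) differing only in background seed.

**Prepulse adaptation.** 3,000 alpha synapses (τ = 5 ms, E_rev = 0)
uniformly over the apical tree beyond 300 µm; the threshold per-synapse
conductance g_th for one somatic spike is bisected, the probe is fired at
1.1 g_th at t = 0 and again after each ISI at `factor × g_th`; the
threshold factor for any additional spike after the second volley is
bisected per ISI. The factor returns to 1 at ISI = 2 s (within 0.02). In
the reduced tonic cell the SK/Ca²⁺ after-effect of the first volley is
absolute for ISIs below ≈150 ms — no factor up to the bracket cap of 4
elicits an additional spike — so the default grid starts at 200 ms and
shorter censored ISIs record the cap value; the summary statistic is the
maximal factor over ISIs above 40 ms. Censoring at the cap keeps
strongly-adapting variants ordered correctly instead of dropping them.

**Coding capacity.** The apical tree is partitioned into six 200-µm bands
(the last unbounded) plus the basal tree; 1,000 alpha synapses per region;
per-region threshold conductances are bisected with only that region
active. All 128 binary input patterns are evaluated with active-region
synapses firing simultaneously, either at half the region's threshold
("relative") or at one absolute per-synapse conductance. The output is the
spike count capped at 3 plus the maximal Ca²⁺ level at each apical region
midpoint (the unbounded region reads out halfway between 1000 µm and the
apical tip) over a 300-ms window, discretized at 1.1 × 10⁻⁴ and
1.2 × 10⁻⁴ mM; the basal level is included only when the model carries
basal Ca²⁺ dynamics (the bursting profile). Output diversity is the
number of distinct output rows, averaged over eleven somatic bias
amplitudes (−0.1…0.1 nA, step 0.02); the absolute-conductance sweep
defaults to the 2.5–50 pS range with the small/large split at 35 pS —
the per-synapse thresholds of the reduced cell (≈3–8 pS) fall inside that
range, so the sweep spans silent to saturated tables. Patterns whose
realized stimulus is identical (e.g. all conductances zero) share one
simulation; this is an exact reduction, not an approximation.

## The synthetic variant generator

Real effect tables assign each gene a handful of measured deltas. The
generator emulates that structure: each variant draws 1–4 deltas from its
gene class's admissible channels only (Ca-channel → CaHVA/CaLVA gates and
conductances; Ca-transporter → the Ca²⁺ decay constant only; Na-channel →
Nat/Nap; K-channel → Kv3.1/Kt/Kp/Im/SK/BK; HCN → Ih), with
half-activation shifts uniform on ±10 mV, slope factors log-uniform on
[0.8, 1.25], and time-constant/conductance/decay factors log-uniform on
[0.5, 2]. The ranges are wide enough that the downscaling search exercises
both its branches (c < 2 and c = 2). The focused
`generate_ca_gate_variants()` ensemble draws only CaHVA/CaLVA
half-activation shifts and conductance factors and is the basis of the
direction-replication analysis. What passing that analysis shows is that
the *sign structure* — steady-state firing anticorrelated with both
prepulse adaptation and up-state coincidence sensitivity across Ca²⁺-gene
variants, via the shared SK pathway — survives the reduction to a
desk-scale cell; the coefficient magnitudes are model-dependent and only
reported, never asserted.

## Problem sizes

The packaged analyses and tests run at deliberately reduced sizes, chosen
as the package's own desk-scale defaults: condition-IV f-I grids of 6
amplitudes × 2 s (12 × 3.5 s for the reference curves), coincidence grids
of 6–11 ISIs, prepulse grids of 3–6 ISIs with a 1,500-synapse probe,
noisy-state repetitions in the single digits, 400–1,000 synapses per
coding region, and 20-variant ensembles. The full published-scale settings
(125 repetitions, 21-point conductance sweeps, 0.05 c-scan resolution)
are plain function arguments.

## Known limitations

* The reduced tonic profile does not convert to bursting under apical
  fast-Na⁺ elevation (see above), and its coincidence windows have low
  contrast (~1 mV modulation) because the reduced hot zone cannot ignite
  a regenerative Ca²⁺ spike from a back-propagating spike plus EPSP alone.
* The fixed-size in-vivo background over-shunts the reduced membrane;
  spontaneous-rate phenomena are out of scope.
* Ca²⁺ handling is a single pool per compartment with no buffering,
  diffusion, or store exchange; the discretization thresholds read out
  peak concentration only.
* Published per-region threshold values and Hamming distances from
  full-morphology models are not comparable to the reduced cell and are
  not asserted anywhere in the package.
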