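---
title: "Personalizing ventricular action-potential models with a modified genetic algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalizing ventricular action-potential models with a modified genetic algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cardiofit)
```

## The problem

Optical mapping of human ventricular tissue yields steady-state action
potential (AP) waveforms at several pacing cycle lengths (PCLs), in
arbitrary fluorescence units. `cardiofit` estimates, from such recordings,
the maximal conductances and fluxes of the O'Hara–Rudy (2011) endocardial
ventricular myocyte model that reproduce them: fast/late sodium (gNa),
rapid/inward-rectifier/slow potassium (gKr, gK1, gKs), L-type calcium
permeability (PCaL), transient outward current (gto), the Na/K pump (gNaK),
the Na/Ca exchanger (gNCX), the sarcolemmal calcium pump (gpCa), SR release
and uptake (Jrel, Jup), calmodulin buffering (CMDN) and the CaMKII pool.
All are expressed as dimensionless multipliers of the published model
values, searched in [0.01, 4].

Two properties make this inverse problem unusual and drive the design:

1. **The paced steady state is not unique.** The slow state variables —
   intracellular sodium and network-SR calcium — equilibrate over hundreds
   of seconds, and different initial concentrations end in different limit
   cycles. Pacing the baseline model at 1 Hz for 1000 s from
   ([K⁺]ᵢ = 145, [Na⁺]ᵢ = 5, [Ca²⁺]NSR = 0.5 mM) versus
   (120, 8, 4 mM) leaves a resting-potential difference of several mV and
   an APD difference of over ten ms (`scripts/acceptance.R` recomputes
   both). A fit that ignores this reproduces the data with concentrations
   the real cell never visits.
2. **Optical APs have no absolute scale.** Fluorescence is an affine
   transform of membrane potential with unknown gain and offset, and the
   optical upstroke is distorted by photon scattering.

## The optimizer

The search is a real-coded genetic algorithm over the 13 multipliers
*plus*, for every PCL in the data, the initial `[Na⁺]ᵢ` and `[Ca²⁺]NSR` of
that PCL's simulation (bounds 1–20 mM and 0.3–6 mM). Potassium is excluded
from the genome: a 10 mM change of `[K⁺]ᵢ` moves the Nernst potential by
only about 2%, so its slow drift has little immediate effect on the
waveform. With 4 PCLs the genome has 13 + 8 = 21 genes.

One generation (`run_ga()`):

* **Evaluation** (`evaluate_organism()`): per PCL, the organism's persisted
  state vector is restored, the slow-variable genes overwrite `[Na⁺]ᵢ`
  (and the subspace sodium) and `[Ca²⁺]NSR` (junctional SR calcium is
  rescaled proportionally to avoid an unphysical inter-compartment jump),
  the model is paced for 9 beats, and the 9th beat is scored. The final
  state is persisted for the next generation and the reached slow
  concentrations are written back into the genome. The odd beat count makes
  1:1 alternans visible: an alternating organism scores its two alternate
  beats on alternate generations and cannot keep a spuriously low RMSE.
  Because states persist, each organism drifts toward its own steady state
  as generations pass; a genome that only fits transiently is punished one
  generation later. This gene/state handshake — genes overwrite the state
  at evaluation start, reached values are written back — is an
  interpretation: it keeps mutation exploring around the trajectory while
  selection discards non-steady solutions.
* **Selection**: size-2 tournaments over two shuffled copies of the
  population; lower total RMSE wins.
* **SBX crossover** (probability 0.9 per pair): per-gene spread factors
  from the order-10 polynomial distribution, then a 0.5 genewise swap;
  children inherit the persisted states of their respective parents.
* **Cauchy vector mutation** (probability 0.9 per organism): a direction
  drawn uniformly on the unit sphere in baseline-normalized gene space and
  a signed step length from a Cauchy distribution with half-width at half
  maximum γ = 0.18, truncated to the admissible range along that direction
  (the truncation is the normalization of the heavy-tailed density to the
  bounded search box). Moving all genes at once matters: per-gene "point"
  mutation almost never moves diagonally, which stalls descent along the
  correlated valleys of the ionic model (`mutation_op = "point"` is kept
  for exactly this comparison).
* **Elitism**: the best 6.6% of the generation are copied unmodified into
  the next one, replacing the worst offspring. Elite copies keep their
  genomes but carry their newest persisted states, so even elite fitness
  values keep moving while concentrations settle — an asserted behaviour,
  not a bug.

The initial population draws multipliers log-uniformly (fold changes above
and below baseline treated symmetrically; the spanned range is two orders
of magnitude) and slow genes uniformly in bounds.

## The fitness function

`ap_fitness()` computes a weighted (unnormalized, equal-weight by default)
sum of per-PCL RMSEs. In optical mode each comparison first superimposes
the half-maximum depolarization points, then rescales the *input* trace by
the closed-form least-squares affine map onto the model AP, and excludes
the model's depolarization prefix below −20 mV (the optical upstroke is
scattering-distorted, so those samples carry no usable information; the
mask is defined on the model trace, which knows true mV, and always removes
a single contiguous prefix). Candidates with an AP amplitude under 30 mV at
any PCL — sub-threshold responses — receive a large penalty (10³ mV)
instead of an RMSE, as do failed integrations.

Two degenerate corners deserve note, because the optimizer reliably finds
both if they are left open. First, a candidate that depolarizes but never
repolarizes (a flat plateau filling the window) can be "matched" by the
affine map collapsing the input's dynamic range onto the plateau, yielding
a small residual in model-mV units; we therefore also discard candidates
for which the *rescaled input* has an amplitude under 30 mV — the
sub-threshold rule applied on the other side of the comparison. Second,
the stimulus itself deflects the membrane by tens of mV (−80 A/F for
0.5 ms is a ≈40 mV kick), so a passive, non-firing cell still clears a
naive 30 mV amplitude check; in optical mode a candidate that never
reaches −20 mV — the mask level, i.e. one with no AP on the compared
support — is discarded as sub-threshold. Both guards only complete the
stated intent of the amplitude rule (eliminate sub-threshold
depolarizations); neither touches genuinely propagating fits.

## Forward models

* **Single cell** (`integrate_cell()`, `pace_to_steady_state()`): the
  O'Hara–Rudy 2011 endocardial cell (41 state variables), written from the
  published equations with the 13 multipliers applied multiplicatively.
  The gNa multiplier scales both the fast and the late sodium conductance
  (both Nav1.5 products); the Jup multiplier scales the SERCA pump term
  but not the leak; CaMKII scales the total CaMK pool.
* **Integrator**: Rush–Larsen exponential updates for the 31 gating-type
  variables (including the relaxation forms of the release fluxes and the
  `nca` mode variable), explicit updates for voltage and concentrations.
  The step adapts to at most 0.2 mV of voltage change and at most 3%
  relative change of any calcium pool per step, floored at 5·10⁻³ ms and
  capped at 1 ms (the floor is a stated protocol constant; the cap and the
  ΔV target are our choices, justified by the self-convergence test:
  halving the cap changes steady-paced APD90 by well under 1 ms).
  Concentration updates fall back to a positivity-preserving multiplicative
  form when an explicit step would cross zero — relevant only in
  calcium-overloaded transients, where SR release can transiently empty
  the junctional SR. Integration failures (non-finite state or |V| >
  200 mV) return a flagged result so a GA run assigns the penalty instead
  of aborting.
* **1D cable** (`simulate_cable()`): 30 cells, one node per cell, coupled
  at 5 mS/μF with no-flux ends, diffusion taken explicitly inside the same
  adaptive step (cap reduced to keep the explicit scheme stable). The end
  three cells are paced with a 2 ms, −80 A/F pulse — tissue loading raises
  the end-stimulation threshold, so the single-cell 0.5 ms pulse does not
  capture. Conduction velocity is the least-squares slope of distance
  versus −20 mV-crossing time over the interior cells (5 excluded per
  boundary). The 0.01 cm cell length used to convert delays to cm/s is the
  published cell length of the ionic model; with it, 5 mS/μF propagates at
  ≈ 26 cm/s. Within the physiological CV range the central-cell APD is
  insensitive to the exact coupling (asserted in the tests), which is what
  justifies fitting tissue recordings with a fixed conductivity.
* **Toy model** (`toy_ap()`): a closed-form AP — resting level, amplitude,
  duration, and a rate-dependent shortening exponent
  (`APD(PCL) = apd·exp(−rst·exp(−(PCL−300)/250))`), each controlled by
  exactly one positive factor — used to exercise selection, crossover,
  mutation, elitism and the fitness end-to-end in seconds. The four
  controls act on nearly disjoint features of the waveform by design: the
  toy exists to test the machinery, and a deliberately well-conditioned
  problem separates optimizer defects from identifiability limits. Its
  restitution is monotone in PCL like the real model's.

## Synthetic data and what passing tests mean

`make_baselines()` paces the model with a hidden truth scaling to steady
state (1000 s unless stated), optionally adds white Gaussian noise at a
stated SNR, and in optical mode min-max normalizes the traces so that the
renormalizing fitness is actually exercised. The generator reproduces the
features the method relies on — steady-state restitution, affine scale
loss, Gaussian noise — and none it does not: no photon-scattering kernel,
no motion artifacts, no pixel heterogeneity, no drift. Passing recovery
tests therefore demonstrate the optimizer and fitness work as specified,
not that real optical recordings are free of systematic distortions.

Experiment sizes used in the tests are desk-scale by design: toy recovery
uses population 50 for 100 generations (three seeded replicates, scoring
the lowest-RMSE fit — the selection a practitioner would make, made
without reference to the truth); the reduced ionic-model run uses
population 40 for 150 generations at 4 PCLs in single-cell mode, on
absolute-scale (mV) baselines. The mode matters: the optical
renormalization deliberately discards the resting level, the amplitude
and the masked upstroke, and recovering conductances through what remains
requires the full published budget — at 6,000 evaluations an optical-mode
run is still on the sloppy plateau (~10 mV) where compensated solutions
(e.g. IKr traded against IKs) are indistinguishable. Absolute-mode
baselines keep that information, and the same machinery then pins the
best-identified conductances within ~10%. All reduced experiments are
scaled-down versions of the published cluster-scale ones
(population ≳ 100, 700 generations, 7 PCLs, 30-cell cable, 9 replicates,
optical mode), and their tolerances are correspondingly looser.

At this reduced scale the toy's recovery error is optimizer-limited, not
noise-limited: with ~1300 compared samples per PCL, 20 dB of frozen
Gaussian noise shifts the toy's fitness optimum by well under 0.1% in any
parameter, so a 28 dB vs 20 dB comparison on the toy measures seed luck.
The noise-sensitivity comparison is therefore run on the reduced
ionic-model problem, whose sloppy parameter directions are what amplify
noise into parameter error in the first place.

## Expression-based rescaling

`rescale_by_expression()` maps a fitted genome to a second subject by
multiplying each conductance by the target/reference expression ratio of
the gene encoding its pore-forming subunit (SCN5A→gNa, KCNH2→gKr,
KCNJ2→gK1, KCNQ1→gKs, CACNA1C→PCaL, KCNA4→gto, ATP1A1→gNaK, SLC8A1→gNCX,
ATP2B4→gpCa, RYR2→Jrel, ATP2A2→Jup, CALM1→CMDN, CAMK2D→CaMKII). The
operation is multiplicative, local and exactly invertible. Rescaled
multipliers may leave the GA's search range — the search bounds constrain
the *optimizer*, not the biology — so clipping applies only to optional,
user-supplied validity limits. Slow-variable genes are dropped: the new
subject's concentrations must re-equilibrate by pacing, which is how
restitution predictions (`restitution_curve()`) are generated. Tables with
multiple promoters or transcripts per gene must be aggregated to one row
per gene by the caller.

## Numerical and design choices, collected

* Stimulus: −80 A/F for 0.5 ms (single cell) / 2 ms into cells 1–3
  (cable); declared defaults, configurable — no protocol values are
  printed for them in the source experiments.
* Output sampling: 1 ms grid (1 kHz optical cameras), linear interpolation
  from the adaptive grid.
* Penalty constant 10³ mV: any value far above physiological RMSE works;
  only fitness ranks matter to tournament selection.
* Half-max alignment uses the first upstroke crossing; multi-hump traces
  (alternans-like) therefore align on the first beat.
* 60 Hz removal: order-2 Butterworth band-stop (58–62 Hz), applied
  forward-backward; zero-phase filtering avoids group delay biasing APD.
* PCA diagnostics (`pca_project()`): snapshots of the 13 multipliers only
  (slow genes excluded), pooled across the generations being compared,
  mean-centered, no unit-variance scaling — multipliers are already
  dimensionless and commensurate. `mce()` is the centroid-to-truth
  distance, `sdist()` the cluster spread, both in the 2-component plane.
* Tournament ties (equal RMSE) go to the first-drawn organism; with
  continuous fitness this is measure-zero.
* Checkpoint and exchange formats are delimited text, JSON and YAML
  throughout, chosen for text-only portability.

## Known limitations

* Endocardial variant only; epi/M-cell scalings are not exposed.
* The cable is one-dimensional with one node per cell; no bidomain, no
  fiber structure, no 2D/3D geometry, no curvature.
* Single-gene expression proxies ignore auxiliary subunits, trafficking
  and post-translational regulation; the rescaling inherits every
  identifiability error of the fit it rescales.
* Pixel selection, motion correction and scattering deconvolution of real
  optical data are out of scope; inputs are assumed to be single-pixel,
  ensemble-averaged, notch-filtered traces.
* Desk-scale GA runs bound what can be asserted: the reduced ionic-model
  experiment checks that the best-identified conductance (gKr) lands
  within 15%, not the full cluster-scale error table.
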