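---
title: "A coupled place-cell / grid-cell attractor network: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled place-cell / grid-cell attractor network: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gridplace)
```

## The model

`gridplace` simulates a standard rate model of the rodent
hippocampal–entorhinal circuit in a one-dimensional periodic environment of
length $D = 192$ cm. Two coupled sub-systems represent the animal's
position:

* a **place-cell network** of $N = 4800$ neurons whose recurrent
  connectivity embeds $L$ spatial maps. In each map $l$ a random
  permutation $\pi_l$ assigns every cell a preferred location on the
  uniform $N$-point lattice, and the synaptic weight between two cells is a
  Gaussian of the periodic distance between their preferred locations,
  $A\,e^{-d^2/2\sigma^2} + h$, summed over maps (a multi-chart,
  Hopfield-like embedding). Each map contributes a continuous attractor
  whose states are localized activity bumps; the other maps act on it as
  *quenched noise*.
* three **grid-cell modules**, each a double-ring attractor of $n = 960$
  neurons with shared weights. Cells sit at angles $\theta_i$ on a ring;
  even-indexed (0-based) presynaptic cells project a Gaussian excitation
  profile displaced $+\Delta\theta$ ahead of their own angle and receive
  $+\varepsilon_\mu v$ velocity current, odd cells mirror both signs. A
  velocity input therefore shifts the balance between the two
  sub-populations and moves the bump — the standard ring-attractor
  implementation of path integration. Ring phases tile each environment
  with periods $\lambda = 64, 48, 38.4$ cm (exactly 3, 4 and 5 cycles of
  $D$), with an independent random phase offset $\Delta_{l,\mu}$ per map
  and module (grid realignment under global remapping).

The two sub-systems are joined by bidirectional synapses whose strength is
linear in the overlap of the cells' idealized tuning curves, summed over
maps: $M^{\mu} = \sum_l (\alpha\, m^{l,\mu} + \beta)$, where
$m^{l,\mu}_{ij} \in [0,1]$ is the normalized periodic integral of the
product of place template $i$ and grid template $j$ in map $l$.

Activity evolves by Euler integration of

$$\tau \dot S_i = -S_i + \phi\Big[\textstyle\sum_j J_{ij} S_j +
\gamma_g \sum_\mu \sum_k M^\mu_{ik} s^\mu_k + I_{pc}\Big] + \eta_i,$$

and correspondingly for each ring with gain $\gamma_p$, per-module currents
$I^\mu_{gc} \pm \varepsilon_\mu v + I_{per}$, and transfer function
$\phi(x) = \sqrt{x}$ for $x > 0$, else $0$. The square-root form follows
from the sub-linear F–I requirement together with the Hz² units of the
printed currents; a rectified-linear variant is available via
`phi_form = "linear"` for sensitivity checks. Optional Poisson-like noise
adds Gaussian increments of standard deviation $\sqrt{R_i\,\mathrm{d}t}$ to
the activations after each deterministic update (Euler–Maruyama); it is off
everywhere except the drift-coordination experiment, where it is the object
of study.

All state-to-position readout is template matching: the bump score of map
$l$ is $Q_l = \max_x \sum_i P_i^l(x) R_i$ over the $N$-point position
lattice, the winning map is the arg-max (ties to the lowest map index, then
the smallest position), and each module's position is the
$\lambda_\mu$-periodic template match nearest the place bump. On small
instances the decoder is verified against brute-force maximization over
every (map, position) pair.

## Implementation: everything is a circulant

Every linear operator in the model is a circulant matrix up to relabeling:
the place recurrent matrix is $\sum_l P_l C P_l^{\mathsf T}$ with $C$
circulant, the ring kernels are circulant in the angle, and the coupling
blocks are a single length-$N$ *overlap generator* $H_\mu$ evaluated at
lattice lags $qj - c_\mu p_i - \Delta_{l,\mu}$ (with $q = N/n$ and
$c_\mu = D/\lambda_\mu$ both integers; the random phases are quantized to
the $2\pi/N$ lattice, an error below $10^{-3}$ rad). Each Euler step
therefore costs a handful of length-$N$ FFTs instead of dense
matrix–vector products — about three orders of magnitude faster at the
reference size, and exact: the test suite checks the FFT path against
dense matrix products to $10^{-10}$.

## Parameter choices that the printed table leaves open

Several constants are exposed in `model_params()` with defaults fixed by
the following calibrations, chosen once against the model's qualitative
operating regime and not revisited:

* **Ring kernel width $\rho$ and offset $\Delta\theta$.** With the printed
  $B = 0.75$, $k = -0.693$, $I_{gc} = -5$, the isolated ring holds a bump
  only for $\rho = 2\pi/3$; narrower candidate readings collapse to
  silence because the uniform inhibition outweighs the local excitation
  integrated over the bump. $\Delta\theta = 2\pi/16$ accompanies it. The
  resulting grid fields are $\approx \lambda/6$ wide, and the place fields
  $\approx 13$ cm FWHM with $\approx 10$ Hz peaks — consistent with the
  2.5 Hz / 12 cm classification thresholds the analysis uses.
* **Coupling normalization.** The normalization $z_\mu$ of the overlap
  matrices only constrains $m \in [0,1]$; the package chooses $z_\mu$ so
  that the *mean* overlap equals $|\beta|/\alpha$ in every module. The
  uniform offset $\beta < 0$ then cancels the mean coupling drive exactly
  (a zero-mean embedding of every map), which removes a module-imbalanced
  DC component that otherwise destabilizes the joint network, and makes
  the grid-side compensation current exactly zero.
* **Coupling strengths.** The two directions of the coupling play
  different roles and are calibrated separately, with
  `beta/alpha = -0.197` held fixed throughout:
  the grid-to-place gain (`gamma_g * alpha`) sets both how strongly the
  moving grid representation drags the place bump and how much
  grid-borne quenched noise reaches the place network — it is set to the
  largest value at which the baseline $L = 6$ network persists in its
  initialized map and traverses the environment coherently, which puts
  the depolarized state just inside the mixed-state regime;
  the place-to-grid gain (`gamma_p * alpha`) must correct slow
  incompatible module drifts but must stay well below the ring's own
  stiffness, because a place bump that can capture the rings stalls path
  integration the moment the place network transiently remaps under
  depolarization. The defaults are `alpha = 2.06e-3`,
  `beta = -4.06e-4`, `gamma_g = 4`, `gamma_p = 5`.
* **Velocity gains $\varepsilon_\mu$.** Chosen, as the model prescribes,
  so that path integration reproduces the grid spacings: the isolated-ring
  bump speed is measured as a function of drive and inverted at
  $2\pi v/\lambda_\mu$ ($v = 10$ cm/s), then a single common factor is
  refined in the coupled network, where pinning by the place attractor and
  its quenched landscape adds a large drag (the refinement measures the
  decoded speed over a stretch covering a full coarse grid period, since
  the drag varies along the environment). `build_model()` performs both
  stages; the result is deterministic given the parameters and map seed.
* **Compensation currents.** The constant external currents contain a term
  proportional to $L - 1$ that cancels the spatial mean of the input
  contributed by each additional embedded map, computed from the mean
  connectivity times the idealized bump's total activity. With the
  zero-mean coupling normalization only the place-recurrent term is
  nonzero.

## Experiment protocols

The package reproduces the full experiment suite: persistence mapping from
consistent / inconsistent / random initial conditions
(`persistence_experiment`), path integration under a synthetic foraging
velocity model and the place-behind-grid lag (`path_integration_experiment`,
`lag_mse`), noise- and incompatible-velocity-driven drift with and without
coupling (`drift_experiment`, `module_msd`), across-field rate variability
versus map count (`cv_experiment`, `field_cv`), perturbation of grid-cell
excitability with ranked bump scores against unembedded control maps
(`perturbation_experiment`), and traversal rate maps with the seven-way
place-cell response classification (`traversal_rate_maps`,
`classify_response`).

Protocol details the source experiments leave open were fixed as follows:

* **Traversal scan coordinate.** Rate maps are binned by the position
  *represented* by the grid modules (their consensus, decoded in the
  baseline map), not by the integral of the velocity drive, and the
  traversal runs until the decoded position completes a full lap. Both
  perturbation polarities change the effective path-integration speed, so
  integrated-position binning would smear every cell; the grid modules
  keep their firing phases under perturbation, which is what makes them a
  valid condition-independent position signal. An `bin_by = "integrated"`
  mode is kept for the deterministic grid-spacing measurements, where the
  traversal is unperturbed.
* **Traversal speed** is 10 cm/s (one lap ≈ 19 s), keeping the per-bin
  dwell (≈ 150 ms) an order of magnitude above $\tau = 15$ ms so binned
  rates are quasi-stationary.
* **Synthetic velocity model.** Speeds are gamma-distributed (shape 3,
  mean 12 cm/s — a right-skewed, unimodal stand-in for rodent foraging
  speeds), resampled every 0.5 s with a fair direction flip. Only the
  unimodal shape and scale matter for the lag and tracking results; no
  claim is made that it matches any measured trajectory.
* **Field detection** uses local maxima of the binned map above the 2.5 Hz
  classification floor, with minimum separation 12 cm for place cells and
  half the grid spacing for grid cells. The classification precedence is:
  turned-off, minor-field, then additional-field (maintained near-peak
  plus a far field), multiple-fields (several far fields, no near field),
  shifted (a far field otherwise), rate-remapped / unaffected (near field
  only, split at a 33% rate change). These seven categories partition
  every admissible input (property-tested on randomized rate-map pairs).
* **Unembedded controls** are freshly drawn random maps *without* the
  identity reference map, scored by the same decoder.

## Numerical choices

* Euler step $\mathrm{d}t$: the published 0.2 ms is the `"full"` preset.
  The `"desk"` preset keeps the full network but uses 1 ms
  ($\tau/15$); halving $\mathrm{d}t$ moves decoded positions by less than
  one lattice spacing (tested), and all headline analyses use `"desk"`.
  The `"small"` / `"tiny"` presets shrink the network 4× / 8× for tests,
  rescaling the synaptic amplitudes by $4800/N$ so the summed input per
  neuron — and hence the operating point — is preserved. Reduced networks
  have proportionally stronger quenched noise (interference scales like
  $\sqrt{L/N}$), so tests that need multiple maps use $L = 2$ at reduced
  size; the headline experiments use the full $N$ with $L = 6$.
* Stationarity of the idealized tuning profiles is enforced (construction
  errors if the uncoupled settling run keeps moving); profiles are
  recentered by circular center of mass, and the ring profile is
  interpolated to the fine lattice band-limitedly.
* Bump nucleation from random initial rates passes through a stiff global
  transient (the whole population swings between silence and uniform
  activity before a bump separates); the coarse 1 ms step turns that
  transient into a spurious see-saw, so protocols that start from random
  states integrate with the published 0.2 ms step
  (`simulate_net(..., dt = 2e-4)`); all bump-state protocols are
  insensitive to the step (tested).
* Tie-breaks everywhere are deterministic: lowest map index, then smallest
  position.
* Problem sizes of the headline analyses: classification and grid-spacing
  measurements run the full N = 4800, L = 6 network at the 1 ms step; the
  lag analysis runs 20 sampled-velocity trajectories of 10 s on the same
  network at a 1.25 ms step (the lag estimate is step-insensitive between
  1 and 1.25 ms; both are well below τ/10); reduced-size property tests
  use the small/tiny presets with L = 2.

## What the synthetic setting does and does not show

All inputs are generated: random map permutations, random grid phases, and
the synthetic velocity model. The simulations therefore probe the internal
consistency of the circuit model — persistence, coordination,
error-correction, and perturbation phenomenology — under exactly the
stated assumptions (idealized tuning, identical cells, no sensory input,
no plasticity, one spatial dimension). Passing tests say nothing about
real neural data beyond what the model architecture encodes; in
particular, the absolute classification percentages depend on the exact
parameter point and the classification thresholds, and the velocity
distribution is a stand-in, not a measurement.

## Known limitations

* Two-dimensional environments, border/sensory inputs, plasticity, and
  spiking dynamics are out of scope.
* At the calibrated operating point the grid rings run at low rates
  (a few Hz), so the hyperpolarizing current silences them rather than
  merely reducing their rates. The hyperpolarization phenomenology at the
  place-cell level — the winning map and place fields are unaffected — is
  reproduced, because the place network sustains its own attractor
  without entorhinal input; a hyperpolarized *traversal*, however, has no
  path-integration signal to scan with.
* Under depolarization the represented position advances much more slowly
  than the commanded velocity (the pedestal of recruited grid cells
  shrinks the ring bump's effective velocity asymmetry); traversals
  therefore run with a generous time budget and bin by the represented
  position.
* The place representation lags the grid representation during path
  integration, as it must given that velocity enters only the grid
  equations, but the magnitude of the lag at this operating point is
  about half again as large as 100 ms; it is set by the ratio of the
  place bump's pinning to the grid-to-place drag, not by an independent
  dial.
* The classification percentages are single-realization statistics of one
  seeded map set; different seeds move the tallies by several percentage
  points.
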