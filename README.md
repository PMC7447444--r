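# gridplace

Simulation of a coupled hippocampal place-cell / entorhinal grid-cell
attractor network in a one-dimensional periodic environment, with the full
experiment and analysis suite for studying multi-map embedding, joint
persistent states, path integration, grid-module coordination under noise,
across-field rate variability, and artificial remapping of place fields
under grid-cell depolarization.

## Who this is for

Computational neuroscientists studying continuous attractor models of the
hippocampal–entorhinal circuit: how several spatial maps can be embedded in
one recurrent network (multi-chart, Hopfield-style), how bidirectional
synapses keep place cells and grid-cell modules representing the same
position, and what happens when grid-cell excitability is perturbed.

## The model

* **Place network**: $N = 4800$ rate neurons on a 192 cm periodic track.
  For each of $L$ maps, a random permutation assigns preferred locations;
  recurrent weights sum over maps $J = \sum_l J^l$ with
  $J^l_{ij} = A e^{-(d^l_{ij})^2/2\sigma^2} + h$ (Gaussian excitation plus
  uniform inhibition, zero diagonal). Each map is a continuous attractor of
  localized bumps; the other maps contribute quenched noise.
* **Grid modules**: three double-ring attractors of $n = 960$ cells with
  spacings $\lambda = 64, 48, 38.4$ cm (3, 4, 5 cycles per environment) and
  map-specific random phase shifts. Even/odd sub-populations project with
  $\pm\Delta\theta$ offsets and receive $\pm\varepsilon_\mu v$ velocity
  current — the ring-attractor implementation of path integration.
* **Coupling**: synapse between place cell $i$ and grid cell $j$ is linear
  in the overlap of their idealized tuning curves summed over maps,
  $M^\mu = \sum_l (\alpha\, m^{l,\mu} + \beta)$, $m \in [0,1]$.
* **Dynamics**: $\tau \dot S = -S + \phi[\,J S + \gamma_g \sum_\mu M^\mu
  s^\mu + I_{pc}\,] + \eta$ (and symmetrically for the rings, with
  $\gamma_p$, velocity and perturbation currents), $\phi(x) = \sqrt{x_+}$,
  Euler integration, optional Poisson-like noise.
* **Decoding**: template matching — per-map bump scores
  $Q_l = \max_x \sum_i P^l_i(x) R_i$, winning map, place position, and
  spacing-periodic grid positions disambiguated toward the place bump.

Every linear operator is circulant up to relabeling, so the integrator
runs on FFTs instead of dense matrix products (exact; verified against
dense references in the tests). See the methods vignette
(`vignettes/gridplace-methods.Rmd`) for the model account, parameter
calibrations, and protocol choices.

## Worked example

```r
library(gridplace)

params <- preset_params("small", L = 2)   # reduced size for a quick demo
model  <- build_model(params, seed = 1)

# persistence of a joint bump state over 1 s
st  <- initial_state(model, "consistent", map = 1, x = 50)
tr  <- simulate_net(model, st, duration = 1)
dec <- decode_state(model, tr$rates$place, matrix(tr$rates$grid, ncol = 1))
dec$winning_map        # 1         — the initialized map wins
dec$x_place            # 46.08     — near the initialized position (cm)
round(dec$Q[, 1])      # 6493 1069 — winning vs losing bump score

# path integration: drive the grid modules at 10 cm/s for 2 s
tr2  <- simulate_net(model, tr$final, 2, v = 10, record_every = 0.05)
dec2 <- decode_trajectory(model, tr2)
tail(dec2$x_place, 3)  # 60.16 60.32 60.48 — moved ~14 cm toward the
                       # commanded 20 cm
```

The first block shows that a state initialized as consistent bumps in
map 1 persists for a second with a clear winning-map margin, drifting a
few centimetres in the quenched multi-map landscape; the second shows
the place representation following the velocity drive. At this
8×-reduced demo size the quenched pinning is strong relative to the
velocity drive, so the bump under-integrates the command; the full-size
network tracks the velocity integral to within a couple of centimetres
(the acceptance script measures this). Experiment-level drivers
(`persistence_experiment`,
`path_integration_experiment`, `drift_experiment`, `cv_experiment`,
`perturbation_experiment`, `traversal_rate_maps`, `classify_all`)
reproduce the full protocol suite; a thin command-line driver is in
`inst/cli/gridplace.R`.

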