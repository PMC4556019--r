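# hubsync

Kuramoto-model simulation of hub-mediated synchronization on structural
brain networks.

High-degree hub regions of the cortex and their dense mutual wiring (the
"rich club") are hypothesized to integrate otherwise segregated functional
modules by leading and gating neural synchronization. `hubsync` is an R
package for testing that hypothesis in silico. It is aimed at researchers
in network neuroscience and computational systems biology who want a
reproducible pipeline from a binary structural connectome to
synchronization phenotypes, and at methodologists who need the individual
pieces (order parameters, mean-field influence decomposition, rich-club
statistics, permutation machinery) as well-tested functions.

## The model

Each of *N* brain regions carries a phase oscillator

    dθ_i/dt = ω_i + λ Σ_j W_ij sin(θ_j − θ_i)

on a binary symmetric adjacency matrix *W*, with uniform random internal
frequencies ω ∈ [0, 1), uniform random initial phases, and a global
cortical coupling strength λ swept from incoherence to whole-brain
synchrony. Observables per coupling value (trial-averaged over seeded
independent runs):

* global phase coherence *r* (time-averaged modulus of the mean phasor)
  and synchronized-pair fraction *r*_link (mean edgewise synchrony C_ij);
* the binary synchrony matrix *F* (top `round(r_link · N(N−1)/2)` pairs)
  and its trial average *r_ij*, the pairwise synchronization probability;
* intramodular, intermodular, intra-hub and hub–module synchrony
  r_αβ = mean of r_ij over group pairs (self-pairs excluded);
* mean-field influences R_{β,α}: how coherently module α (or the hub set)
  drives the nodes of module β, from the group-wise decomposition of the
  neighbour-phasor centroid R_k e^{iφ_k} = (1/D_k) Σ_j W_kj e^{iθ_j}.

Experiments: group-consensus thresholding of subject stacks, degree-based
hub selection, normalized rich-club coefficients against degree-preserving
nulls, modularity-based module detection, hub-edge suppression versus
matched random suppression, and nodal frequency perturbation with modular
frequency tracking. Synthetic generators provide 219-node rich-club and
78-node macaque-style connectomes with planted modules and hubs, so the
whole pipeline is testable without any data download.

## Worked example

```r
library(hubsync)

net  <- generate_connectome(synth_spec(seed = 1))
conn <- net$connectome   # <connectome> 219 nodes, 2936 edges (density 0.123)
part <- net$partition    # 11 modules (sizes 14/16/11/12/21/20/27/28/11/31/28), 39 hubs

rec <- run_sweep(conn, part, lambda_grid = c(0.012, 0.020, 0.028),
                 n_trials = 20, base_seed = 1000)
rec$summary
#>  lambda         r     r_link global_sync
#>   0.012 0.1145418 0.08532981  0.08533367
#>   0.020 0.3307009 0.37120030  0.37120146
#>   0.028 0.7905051 0.94482395  0.94482217

intra <- subset(rec$modular, group_a == group_b & lambda == 0.020)
head(intra[order(-intra$sync), c("group_a", "sync")])
#>  group_a      sync
#>     hubs 0.8286100
#>        6 0.4500000
#>       11 0.4318783
#>        8 0.4214286
#>        5 0.4169048
#>       10 0.4153763
```

The sweep shows the critical regime: between λ = 0.012 and λ = 0.028 the
network jumps from incoherence (r_link ≈ 0.09) to near-global synchrony
(r_link ≈ 0.94). In the middle of the transition (λ = 0.02) the hub set is
far ahead of every functional module in internal synchrony (0.83 vs at
most 0.45) even though its wiring density is on par with module density —
the rich club leads the modules into synchronization. Suppressing
hub-to-hub edges (vs an equal number of random edges) raises the
intramodular-to-global synchrony ratio (1.151 vs 1.099 at λ = 0.02, 20
trials), and perturbing hub frequencies (+1) delays the whole-brain
synchronization point beyond that of matched random-set or single-module
perturbations — the three headline hub phenomena, asserted with
permutation tests in `tests/testthat/test-acceptance.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the core analysis from scratch against the installed package:
it generates the default synthetic rich-club connectome, verifies hub
selection, runs a coupling sweep across the critical regime with
trial-averaged synchronization metrics, runs the paired hub/random
suppression contrast, logs all results, and writes the JSON result file.

## Layout

* `R/` — connectome construction and I/O, partitions and module
  detection, the Kuramoto integrator (`src/` Rcpp core), synchronization
  metrics, experiments, synthetic generators, pipeline orchestration.
* `vignettes/hub-synchrony.Rmd` — methods vignette: model, estimators,
  numerical choices, the synthetic world and its rationale, limitations.
* `tests/testthat/` — unit, property and acceptance suites.
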