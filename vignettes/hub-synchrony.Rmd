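---
title: "Hub-mediated synchronization on structural brain networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hub-mediated synchronization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

High-degree hub regions of the mammalian cortex, and the dense "rich club"
of connections among them, are hypothesized to act as the backbone of
intermodular neural communication: spatially distributed across functional
modules, they may lead and gate the transition from locally synchronized
modules to whole-brain synchrony. `hubsync` implements the full simulation
workflow for testing that hypothesis in silico: coupled phase oscillators
on a binary structural connectome, synchronization observables at global,
modular and hub level, a mean-field decomposition of who drives whom, and
the two causal manipulations — removing hub-to-hub edges, and detuning hub
frequencies — that probe the hubs' role directly.

## The model

Each brain region $i$ carries a phase oscillator
$$\dot\theta_i \;=\; \omega_i + \lambda \sum_{j=1}^{N} W_{ij}
  \sin(\theta_j - \theta_i),$$
with $W$ a binary, symmetric, zero-diagonal adjacency matrix, $\omega_i$
a fixed internal angular frequency and $\lambda$ the single global
*cortical coupling strength* swept in all experiments. Initial phases are
uniform on $[-\pi, \pi)$ and frequencies uniform on $[0, 1)$ — the
half-open upper bound differs from the closed interval only on a set of
measure zero. Because $W$ is symmetric the coupling terms cancel pairwise,
so the population-mean phase velocity equals $\bar\omega$ at all times and
the fully synchronized attractor rotates at the mean internal frequency;
both facts are asserted as tests.

### Integration protocol

A fixed-step classical Runge–Kutta (RK4) scheme with `dt = 0.05`
integrates from $t = 0$ to `t_total = 700`; the first `t_transient = 300`
time units are discarded and the remainder sampled at unit intervals,
yielding exactly 400 post-transient samples per trial. Phases are stored
unwrapped (needed by the Fourier frequency analysis); phasor-based metrics
wrap them implicitly. Numerical convergence: away from the critical
coupling, halving `dt` moves sampled phases by $<10^{-6}$ over the full
protocol, and the step-halving error ratio is 16, the clean fourth-order
signature. *Inside* the critical regime the microscopic trajectories are
chaotic, so step-halving differences grow to $O(1)$ there — that is
sensitivity to initial conditions, not integrator failure, and it is why
all critical-regime claims in this package are made about trial-averaged
observables rather than single trajectories.

### Mean-field form

Each node's input can be summarized by the centroid of its neighbours'
unit phasors,
$$R_k e^{i\phi_k} = \frac{1}{D_k}\sum_j W_{kj}\, e^{i\theta_j},$$
with $D_k$ the node degree. Substituting into the model gives
$\dot\theta_k = \omega_k + \lambda D_k R_k \sin(\phi_k - \theta_k)$: the
centroid radius $R_k$ (local coherence among the nodes $k$ listens to)
scales the pull toward the local mean phase. The package treats the
original pairwise equation as ground truth and verifies this substituted
form as an identity to $10^{-10}$; a reduced form without the
$\lambda D_k$ factor circulates in the literature but is dimensionally
inconsistent with the pairwise equation and is not used.

Splitting the neighbour sum by node group gives the influence
decomposition
$$\frac{1}{D_k}\Big[ D_{k,\alpha} R_{k,\alpha} e^{i\phi_{k,\alpha}} +
  D_{k,\beta} R_{k,\beta} e^{i\phi_{k,\beta}} + \dots \Big],$$
where group $\alpha$ runs over the functional modules and, separately, the
hub set. A group connected to $k$ by a single edge has $R = 1$
identically, which carries no coherence information, so only instances
with $D_{k,\alpha} > 1$ enter any average (`evaluable` flag). Group-level
influences $R_{\beta,\alpha}$ average the per-node radii over the
evaluable nodes of the target module and over the sampled window; the
exact evaluation times are not prescribed anywhere, so the package
averages over the post-transient samples (optionally strided, default
every 8th sample inside sweeps) — an instantaneous variant is obtained by
passing a single-column trajectory.

## Synchronization observables

* **$r$** — time-averaged modulus of the population-mean phasor; global
  phase coherence.
* **$C_{ij}$** — modulus of the time-averaged phasor of the pairwise phase
  difference; 1 for phase-locked pairs (including constant lags), near 0
  for drifting pairs. This matrix is the simulated functional
  connectivity.
* **$r_\mathrm{link}$** — mean off-diagonal $C_{ij}$, read as the fraction
  of synchronized pairs.
* **$F_{ij}$** — binary synchrony: the $\mathrm{round}(r_\mathrm{link}
  \cdot N(N-1)/2)$ unordered pairs with the largest $C$ are marked 1,
  mirrored symmetrically. The textbook statement of this construction
  counts $N(N-1)$ *ordered* pairs, which double-counts a symmetric matrix;
  operating on unordered pairs preserves the stated property that the
  edge count of $F$ matches the count predicted by $r_\mathrm{link}$.
  Rounding (rather than floor/ceiling) of the threshold count and a
  deterministic tie-break — $C$ descending, then row, then column — are
  package choices where the construction is otherwise silent.
* **$r_{ij}$** — mean of $F_{ij}$ over trials: the probability that a pair
  is synchronized, the unit of all modular statistics.
* **Modular synchrony $r_{\alpha\beta}$** — mean $r_{ij}$ over pairs with
  $i \in \alpha$, $j \in \beta$, $i \neq j$, denominator
  $N_\alpha N_\beta - |\alpha \cap \beta|$. For disjoint modules this is
  the plain cross-pair mean; for $\alpha = \beta$ it excludes self-pairs
  (denominator $N_\alpha(N_\alpha - 1)$) so module size does not bias
  intramodular synchrony. The generalization to arbitrary overlapping node
  sets is what lets the hub set act as a pseudo-module (intra-hub and
  hub–module synchrony) even though hubs belong to modules.

A sweep (`run_sweep`) runs `n_trials` independent trials per coupling
value — trial $l$ at the $i$-th coupling uses seed
`base_seed + (i-1)*n_trials + (l-1)`, so records are bit-reproducible and
trials independent — and aggregates all of the above.

## Network construction

* **Group consensus** (`consensus_matrix`): an edge enters the group
  matrix when present in at least 40% of subjects; the threshold is
  inclusive, following the usual "at least" phrasing.
* **Hub selection** (`select_hubs`): the $n$ highest-degree nodes, ties at
  the cutoff broken by node index so the selection is deterministic and
  nested in $n$.
* **Rich club** (`rich_club_coefficient`): density among nodes of degree
  $> k$, normalized by the mean over degree-preserving rewired nulls
  (double-edge swaps, $10E$ attempts per null). The null ensemble is a
  package choice — publications often omit theirs — and the normalization
  is validated by checking that a member of the null ensemble scores
  $\approx 1$.
* **Module detection** (`detect_modules`): Newman-modularity maximization
  by best-of-10-restart Louvain, followed by merging any module below
  `min_size` into its most strongly connected neighbour. Greedy
  agglomeration (fast-greedy) was evaluated first and systematically
  under-resolved planted 13-node blocks in dense 78-node networks, so the
  stronger optimizer is the default; any maximizer of within-group edges
  satisfies the same contract, and the tests assert recovery of planted
  partitions rather than one algorithm's output.
* **Majority vote** (`majority_vote_modules`): nodes take the module with
  the largest voxel count; ties go to the lowest module id.

## Experiments

* **Connectivity suppression** (`suppress_edges`): all edges with *both*
  endpoints in the chosen set are zeroed — hubs stay connected to the rest
  of the network — and a matched number of uniformly random edges is
  removed in the reference condition (`suppress_random_edges`). The
  contrast statistic is the ratio of mean intramodular synchrony to
  whole-brain synchrony (`modularity_ratio`); paired conditions share the
  per-trial random draws through a common `base_seed`.
* **Frequency perturbation** (`perturb_frequencies`,
  `run_frequency_track`): the chosen set's internal frequencies are
  offset by $+1$ *after* the random initial conditions are drawn, so
  perturbed and unperturbed conditions are paired draw-for-draw. Each
  module's dominant frequency is the angular frequency of the
  maximal-power DFT bin (DC excluded, resolution $2\pi/400$) of the
  group-mean phasor signal $\frac{1}{N_g}\sum_{j \in g} e^{i\theta_j(t)}$
  — chosen over mean unwrapped phase velocity because it is robust to
  wrapping and to a minority of stragglers inside a group. Whole-brain
  synchronization is declared at the smallest coupling where the lowest
  group frequency is within 5% of the highest. Variance heterogeneity of
  modular frequencies is tested with Bartlett's test (wrapping the
  standard chi-square implementation, cross-checked against the textbook
  formula); the sampling unit entering the test is the per-trial dominant
  frequency of each unperturbed module at the coupling immediately prior
  to synchronization — the published description is ambiguous between
  this and per-module point estimates, and per-trial samples are the
  choice that gives the test its nominal distribution.
* **Permutation tests** (`permutation_test`): two-sided label-shuffle
  tests on a mean difference with add-one smoothing
  ($p \geq 1/(n_\mathrm{perm}+1)$); statistic and sidedness are package
  choices where only the permutation count is conventionally reported.

## The synthetic world

No empirical connectome ships with the package; generators provide inputs
with the statistical structure the analysis assumes.

`synth_spec()` describes a 219-node planted-partition network: 11 modules
with sizes drawn uniformly in 11–31 (adjusted within that range to sum to
219), within-module edge probability 0.30 against an intermodular
background of 0.06, and 18% of nodes (39) promoted to hubs — at least one
per module, allocated proportionally to module size. Hub pairs gain edges
with probability 0.35 and hub–non-hub pairs with 0.10, combined with the
base probabilities as unions. The reasoning behind the numbers:

* module-internal density far above the global density (~0.12), because
  functional modules in real consensus networks are the densest
  structures;
* hub–hub density *on par with* module-internal density, not far above
  it — in the empirical networks the rich club's mutual density is
  comparable to module density, and the hubs' special role arises from
  their degree and their spread across modules, not from an implausibly
  dense clique;
* the extra hub wiring lifts planted hub degrees (~48) well clear of the
  non-hub distribution (~22), so the realized top-degree set coincides
  with the planted hubs and the normalized rich-club coefficient exceeds
  1 over interior degrees.

With these choices the network's critical regime sits at
$\lambda \approx 0.012$–$0.03$, closely matching the 0.02–0.04 regime
reported for the 219-node human consensus network, and all three headline
hub phenomena emerge without further adjustment. A reported average module
size of $17.9 \pm 5.1$ is only loosely consistent with 11 modules covering
219 nodes (mean 19.9); the generator follows the explicit 11–31 size
range.

`generate_macaque_like()` emulates the 78-node, 27.6%-dense,
6-module case. The density budget is tight: 27.6% density forces a mean
degree of ~21 while a ~13-node module can supply at most 12 within-module
neighbours, so most edges are intermodular no matter what. The generator
therefore wires modules at 0.9 internal density, draws module sizes in a
narrow 10–16 band (so degree reflects hub status rather than module
size), and then adds/removes randomly chosen intermodular non-hub edges
until the exact target edge count is met. With the first, laxer
parameterization the merged 5-module partition had *higher* modularity
than the planted 6-block one — i.e. the planted structure was not the
optimum any correct detector should return — which is why the block
contrast is as strong as it is; the calibration was fixed from that
modularity analysis, not from test outcomes.

`generate_subject_stack()` degrades a template connectome per subject
(edge kept with probability 0.9, spurious edge with probability 0.005),
the regime in which 40%-consensus thresholding provably recovers the
template (binomial tails of order $10^{-15}$).

All generators are seeded and bit-reproducible; disconnected realizations
are repaired with minimal random bridging edges rather than rejected.

### What the synthetic world does and does not establish

The generators reproduce the *topological* premises — modular blocks, a
spread-out high-degree rich club, realistic densities — but not spatial
embedding, streamline-length biases, hemispheric symmetry, or weighted
connections. A green contrast test therefore establishes that the
analysis pipeline detects hub-mediated synchronization phenomena *when
the assumed topology is present*; it does not re-establish the empirical
claims about the human or macaque cortex, whose connectomes are not
distributed with the package. Publication-scale $p$-values (e.g. $<10^{-4}$ at
$10^3$ trials) are likewise scaled down: acceptance tests use $10^2$
trials and assert directions at $p < 0.05$.

## Degenerate inputs and sentinels

Isolated nodes have undefined mean fields ($R_k = \mathrm{NA}$); influence
groups with $\leq 1$ connection are flagged not evaluable; a rich-club
threshold leaving fewer than two survivors returns NA; intra-group
synchrony of a singleton set, Bartlett with a zero-variance group, and
empty trial lists raise errors rather than returning numbers.

## Worked example

```{r example}
library(hubsync)

net <- generate_connectome(synth_spec(seed = 1))
conn <- net$connectome
part <- net$partition

rec <- run_sweep(conn, part, lambda_grid = c(0.012, 0.020, 0.028),
                 n_trials = 20, base_seed = 1000)
rec$summary

intra <- subset(rec$modular, group_a == group_b & lambda == 0.020)
intra[order(-intra$sync), ]

hub_sup <- suppress_edges(conn, part$hubs)
rnd_sup <- suppress_random_edges(conn, attr(hub_sup, "n_removed"), seed = 2)
modularity_ratio(run_sweep(hub_sup, part, 0.02, 20, base_seed = 1500))
modularity_ratio(run_sweep(rnd_sup, part, 0.02, 20, base_seed = 1500))
```

## Known limitations

Binary undirected coupling only (no weights, delays, noise or inertia);
influence averaging assumes the sampled window is representative; the
binarization threshold interpretation of $r_\mathrm{link}$ is crisp only
when synchronized and unsynchronized pairs separate clearly; Louvain
restarts make module detection stochastic across seeds (controlled by the
`seed` argument); and the macaque-style generator trades wiring realism
for identifiability under its severe density constraint.
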