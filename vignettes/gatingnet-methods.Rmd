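---
title: "Residue communication networks and gating energetics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue communication networks and gating energetics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gatingnet implements a two-armed analysis for voltage-gated ion channels:
a **network arm** that infers residue-to-residue communication pathways
from molecular dynamics (MD) trajectories, and an **energetics arm** that
quantifies how mutations perturb gating from voltage-clamp measurements.
The two meet in a correlation analysis: residues predicted to carry the
electromechanical signal should, when mutated, shift the gating free
energy.

This vignette documents the models, the tunable parameters, the synthetic
data used for validation, and the numerical and design choices made where
the methodology leaves latitude.

## The network arm

### Edge weights

The protein is a weighted undirected graph: nodes are residues, and an
edge between residues $i$ and $j$ carries

$$w_{ij} = -\log\!\left(C_{ij}\, M'_{ij}\right),$$

where $C_{ij}$ is a time-averaged semi-binary contact map and $M'_{ij}$
the normalized mutual information of the two residues' side-chain
displacements. The product lies in $[0, 1]$, so all weights are
non-negative — the precondition for Dijkstra's algorithm. A small weight
means the pair is both in contact and moving in a correlated way:
communication is cheap along such edges.

**Contact map.** Each frame contributes a truncated Gaussian kernel of
the C$\alpha$–C$\alpha$ distance $d_{ij}$:

$$K(d) = \begin{cases} 1 & d \le c \\ e^{-(d^2 - c^2)/2\sigma^2} & d > c,\end{cases}$$

averaged over frames (`compute_contact_map()`). The cut-off is
$c = 7\,\mathrm{\AA}$; the width $\sigma$ is not set directly but
calibrated by imposing a negligible kernel value at a second distance:
`solve_kernel_width(7, 10, 1e-5)` solves $K(10\,\mathrm{\AA}) = 10^{-5}$
in closed form, giving $\sigma = 1.488\,\mathrm{\AA}$. The kernel is
continuous at $d = c$ and monotone, so the contact map is a smooth,
bounded relaxation of a binary contact count.

**Motion correlation.** For each residue, the displacement series is the
Euclidean norm of the deviation of its side-chain heavy-atom center of
mass from its time-average position (`compute_displacements()`). Pairs of
series are discretized on equal-width bins (each residue spanning its own
observed range) and the plug-in mutual information is computed from the
joint histogram, normalized by the joint Shannon entropy:
$M'_{ij} = M_{ij} / H_{ij} \in [0, 1]$. The scalar-magnitude reading of
the displacement is the default; a `mode = "components"` flag preserves
the 3D deviation vectors for sensitivity checks.

**Paths and centrality.** Minimal paths between user-defined regions
(e.g. the S4 voltage-sensor helix, the S6 gate, the selectivity filter)
use Dijkstra's algorithm; per-residue betweenness centrality uses
Brandes' algorithm, both through igraph. $d_{\min}$ is the summed weight
of the best region-to-region path; $\Delta d_{\min} = d_{\min}^{MUT} -
d_{\min}^{WT}$ summarizes a mutation's effect on communication (positive
= impaired). Betweenness is reported raw and normalized by
$(n-1)(n-2)/2$, endpoints excluded.

**Uncertainty.** The trajectory is split into $N_B$ consecutive blocks
(`block_weight_std()`), the full weight pipeline is recomputed per block,
and each edge gets

$$\sigma(w_{ij}) = \sqrt{\tfrac{1}{N_B (N_B - 1)} \sum_B \left(w^B_{ij} - \bar w_{ij}\right)^2},$$

the standard error of the block mean under the assumption of uncorrelated
blocks. The formula is implemented exactly in this form (`block_sd()`);
whether its prefactor is read as an SD of blocks or an SE of the mean is
a known ambiguity of block analyses, and the printed SE-of-mean form is
used. Block length is expressed in frames, with a nanosecond convenience
conversion via `frame_time_ns`; 25 ns is a typical choice for
several-hundred-nanosecond production runs.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `c` | 7.0 | Å | contact cut-off (kernel = 1 below) |
| `d_cut`, `kernel_target` | 10, 1e-5 | Å, – | kernel-width calibration |
| `n_bins` | 20 | – | displacement discretization per residue |
| `log_base` | e | – | MI and weight scale; path *identity* is base-invariant |
| `floor_eps` | 1e-12 | – | smallest `C*M'` that still defines an edge |
| `block_length` | user | frames | block analysis resolution |
| `stride`, `first_frame`, `last_frame` | 1, all | frames | analysis window |

Choices worth explaining:

* **Natural log by default.** The weight definition leaves the base
  open; changing base rescales every weight by the same factor, so which
  residues form the minimal path and the betweenness ranking are
  unchanged — only $d_{\min}$ magnitudes move. Both `"e"` and `"2"` are
  supported.
* **20 equal-width bins, no bias correction.** The plug-in estimator is
  the simplest faithful reading of the double-sum MI definition. It is
  positively biased at finite sampling — on independent series the bias
  scales like (bins²)/(2·frames) — which inflates all `M'` entries by a
  similar floor rather than reordering them; the test suite quantifies
  the decay of this floor from 500 to 5000 frames so users can trade
  bins against frames deliberately.
* **Edge floor instead of huge weights.** Products below `floor_eps`
  would give $-\log$ weights above ~28 nats; numerically zero products
  are undefined. Such pairs are dropped from the edge set entirely,
  matching the physical meaning (no communication channel), rather than
  carried as arbitrarily large but finite weights.
* **Superposition.** Displacements are meaningless while rigid-body
  drift dominates, and the alignment protocol is rarely stated in
  published network analyses. The default superposes every frame onto
  the time-average structure over all analyzed C$\alpha$s (Kabsch,
  iterated twice so the average is self-consistent); a fixed reference
  frame is available. Internal distances are invariant to this step, so
  the contact map does not depend on it.
* **Glycine.** Residues without side-chain heavy atoms fall back to the
  C$\alpha$ position as their center of mass; such residues carry only
  backbone motion and users may prefer to exclude them from regions of
  interest.
* **Ties.** Among equal-weight paths the package prefers fewer hops,
  then the lexicographically smallest node sequence — determinism that
  matters for regression tests, not for science.
* **Degenerate inputs.** Constant displacement series (zero entropy) get
  `M' = 0` with a warning; unreachable region pairs produce a typed
  unreachable record and are excluded from subunit averages with a
  warning, never silently turned into infinities.
* **Region aggregation.** The region-to-region distance is the minimum
  over member pairs (a "best path between key regions" reading); a
  mean-over-pairs mode exists for sensitivity. $d_{\min}$ is reported
  per subunit (chain) by default, with a tetramer-global mode, since
  published analyses do not always say which convention they use.

## The energetics arm

### Boltzmann fits

Conductance–voltage curves from tail currents follow a two-state model,
increasing with voltage:

$$G(V) = \frac{1}{1 + \exp\!\left(\frac{z_G F}{RT}(V_{1/2} - V)\right)},$$

and steady-state inactivation (availability) the mirrored, decreasing
form. `fit_gv()` / `fit_inactivation()` estimate $(z, V_{1/2})$ by
Levenberg–Marquardt least squares with logit-regression starting values;
standard errors are asymptotic. Fits are unweighted, and per-experiment
normalization precedes cross-experiment averaging
(`extract_gv_points()`). The default temperature is 290.65 K (~17.5 °C,
a typical cut-open oocyte recording temperature); it affects only the
fitted steepness, never the energies below.

**Tail currents.** The per-sweep conductance point is the sign-aware
extremum of the tail segment, searched after a guard interval (default
2 ms) that excludes capacitive transients; the synthetic generator
plants a deliberate capacitive spike to keep this guard honest.

**Triple-pulse correction.** In the classical three-pulse inactivation
protocol the brief hyperpolarizing P2 lets channels recover from
inactivation, and the P3 peak indexes availability. Below a threshold
voltage (default −120 mV) channels also begin to deactivate during P2,
so the raw P3 peak underestimates availability.
`correct_inactivation_peaks()` fits a mono-exponential to the P2 falling
phase and extrapolates it back to the start of P2; the extrapolated
amplitude replaces the raw peak for those sweeps only. Sweeps whose P2
does not actually decay keep the raw peak, with a warning.

A method-inherent systematic worth knowing: availability is normalized
by the in-protocol maximum, and at −180 mV the true availability is
~0.986 for typical WT parameters, so the normalized curve is ~1.4% above
the model; this biases the fitted midpoint by roughly +4 mV. The
recovery tests budget for this; protocols reaching deeper hyperpolarized
plateaus reduce it.

### Free energies

The gating free energy of either process is $\Delta G = z F V_{1/2}$
with $F = 23.061\ \mathrm{kcal\,mol^{-1}\,V^{-1}}$ and $V_{1/2}$ in
volts; perturbations are $\Delta\Delta G = \Delta G_{MUT} - \Delta
G_{WT}$ (`gating_energy_table()`). Errors propagate per channel as

$$\delta = F\sqrt{(\delta z\, V_{1/2})^2 + (\delta V_{1/2}\, z)^2}.$$

This per-channel expression is ambiguous about the wild type's
contribution to $\delta\Delta\Delta G$; the table therefore reports both
the mutant-only value (`ddg_se_channel`) and the mutant⊕WT quadrature
combination (`ddg_se`), avoiding a silent reinterpretation.
`herg_fit_table()` ships published $(z, V_{1/2})$ fits for WT hERG and
ten mutants; running the energy table on it reproduces the published
energy and perturbation tables to one unit in the last printed digit
(the residual discrepancies are exactly the rounding of the printed
inputs, which the tests bound by explicit error propagation).

Finally, `correlate_metric_vs_energy()` relates any per-construct
network metric (betweenness of the mutated residue, $\Delta d_{\min}$)
to $\Delta\Delta G$ with a Pearson correlation and an OLS line — the
package's analogue of the mechanics-vs-energetics comparison.

## Synthetic data: what it emulates, and what it does not

Both arms are validated against generators with known ground truth, so
the full pipeline runs without any external download.

**Planted-chain trajectories** (`generate_chain_trajectory()`): residues
sit on a jittered cubic lattice (spacing 6 Å, inside the 7 Å cut-off)
so that a rich off-chain contact network exists; a chosen chain of
residues occupies one lattice row and shares a latent 3D AR(1) signal
(lag-1 correlation 0.9, stationary SD 1 Å) mixed at `coupling_strength`
into their side-chain displacements, on top of independent Gaussian
noise (default 0.3 Å) that every residue receives. C$\alpha$s carry
0.15 Å of jitter around fixed sites, making the contact map essentially
static. The AR(1) choice gives the block analysis realistic
autocorrelation to work against, rather than trivially white noise.
Fixtures are written as PDB + DCD (the DCD writer is a minimal CHARMM
format implementation) so the real readers are exercised end to end.

Under the default study conditions (30 residues, chain of 6, coupling
0.8, noise 0.3 Å, 2000 frames) the minimal path between the chain
endpoints recovers the planted chain and its interior residues rank
above the 90th percentile of off-chain betweenness in ≥95% of seeds.
What this does *not* show: real channels have flexible backbones, a
contact map that breathes on the same timescale as the side chains,
solvent- and lipid-mediated couplings, and four-fold symmetry with
inter-subunit paths. Passing the synthetic suite demonstrates the
estimator and graph machinery are correct, not that a 500 ns trajectory
of a real channel is converged.

**Synthetic clamp data** (`generate_boltzmann_currents()`,
`generate_tail_current_traces()`, `generate_triple_pulse_traces()`):
two-state Boltzmann ground truth with additive, unclipped Gaussian noise
(so sample means are unbiased for the curve); tail sweeps with
activation-dependent inward tails and a capacitive spike; triple-pulse
sweeps whose P2 decays mono-exponentially (`tau_decay`, default 10 ms)
below the deactivation threshold, attenuating the raw P3 peak so the
extrapolation correction has real work to do. Not emulated: leak and
series-resistance artifacts, rundown, kinetic (multi-state) gating.

## Problem sizes and reproducibility

The test suite's simulation studies use: 40 seeds × 2000 frames × 30
residues for path recovery; 100 seeds for Boltzmann parameter-recovery
bias; 200 random graphs (≤8 nodes) checked against exhaustive
simple-path enumeration for both Dijkstra and Brandes results; 50 seeds
for the planted-MI ordering; 20 seeds × (500, 1500, 5000) frames for MI
convergence. These sizes give stable pass/fail behaviour at the stated
thresholds while keeping a full run to a couple of minutes. All
generators are seeded; the same seed reproduces outputs bit-for-bit, and
pipeline runs record their configuration, input checksums and timings in
a JSON manifest.

## Known limitations

* The MI estimator is the uncorrected plug-in; its positive bias cancels
  in rankings but inflates absolute `M'` values at few frames.
* Trajectories are assumed whole (no periodic-boundary unwrapping) and
  are read from DCD or multi-model PDB; XTC is not supported.
* Region membership (which residues constitute S4, S6, SF) is user
  configuration, not something the package infers from structure.
* The energetics arm covers two-state fits only: no gating-current Q–V
  analysis, no kinetic modelling, no leak subtraction.
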