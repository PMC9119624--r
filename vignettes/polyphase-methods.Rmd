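---
title: "Methods: coarse-grained simulation of specific and non-specific polymer assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained simulation of specific and non-specific polymer assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(polyphase)
```

## The model

`polyphase` simulates the self-assembly of semi-flexible bead-spring
polymers whose association is driven by two kinds of short-range
attraction: a *specific* interaction of strength $\epsilon_{sp}$, acting
exclusively between the beads of a short "functional patch" (7 beads at
the center of an 80-mer by default), and a weak, promiscuous
*non-specific* interaction of strength $\epsilon_{ns} < \epsilon_{sp}$
involving all other attractive beads. This is a sticker-spacer-style
phenomenology for intrinsically disordered proteins: each bead maps onto
roughly 2–3 amino acids (mass 110 Da, size $\sigma = 4.5$ Å), the patch
models a native protein-protein interface, and the non-core beads model
the "noisy" interactome. The scientifically interesting regime is the
competition between them: with negligible $\epsilon_{ns}$ chains never
dwell near each other long enough to lock their patches together; with
$\epsilon_{ns}$ approaching $\epsilon_{sp}$ chains condense into
non-specific assemblies whose patches never co-localize; in between lies
a window where weak promiscuous contacts scaffold the formation of
*mature* (patch-patch bonded) dimers and multimers.

The potential has three terms, implemented literally:

* stretching $E = k_s \sum_i (|\mathbf r_i - \mathbf r_{i+1}| - r_0)^2$
  with $k_s = 10$ kcal/mol/Å², $r_0 = 4.5$ Å. Note the absence of the
  conventional $1/2$: the effective bond stiffness is $2 k_s$, and the
  equilibrium bond-length variance is $k_B T/(2 k_s) \approx 0.0308$ Å²
  at 310 K. The tests assert this, so the missing $1/2$ is locked in.
* bending $E = \kappa \sum_i (1 - \cos\theta_i)$ over consecutive bond
  pairs, $\kappa = 2$ kcal/mol ($\theta = 0$ for a straight chain; the
  implied persistence length is a few beads — semi-flexible).
* non-bonded truncated Lennard-Jones
  $E = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]$ for $r < r_c$, with
  $\epsilon$ resolved per role pair and $r_c = 2.5\sigma$ for attractive
  pairs. The potential is truncated without shifting, matching the
  default convention of the reference engine for this model class.

Four bead roles exist: `specific` (red), `nonspecific` (blue), `inert`
(black; excluded volume only) and `alt_nonspecific` (green; attracts
itself and specific beads but is repulsive toward blue — the second
component of the heterogeneous mixtures). Interaction strengths are
stored in $k_B T$ units at a reference temperature of 310 K and
converted to kcal/mol once when the force field is resolved; across a
replica ladder only the thermostat temperature varies, never the
potential.

**Repulsive-only pairs.** The model prescribes "repulsive LJ" for pairs
involving inert beads (and for green–blue pairs) without stating a
depth. We use the standard purely repulsive truncation: depth fixed at
1 $k_B T$ (at the reference temperature), cut at the minimum
$2^{1/6}\sigma$. Only the repulsive branch of the force ever acts, so
the choice of depth only sets the softness of the excluded volume. This
is a documented assumption, not source text.

**Zero-depth attractive pairs.** $\epsilon_{ns} = 0$ is representable;
such pairs simply do not interact (no excluded volume either). This is
the literal zero-depth limit of the pair potential; sweeps use
$\epsilon_{ns} \ge 0.1$ where the $r^{-12}$ branch still provides
meaningful repulsion.

## Dynamics

Langevin (NVT) dynamics with the BAOAB splitting: half-kick, half-drift,
exact Ornstein-Uhlenbeck velocity refresh with friction
$\gamma = 1/\text{damping time}$ ($1/1.2$ ps), half-drift, half-kick.
The original work names only "a Langevin thermostat" (the LAMMPS one,
i.e. impulsive friction inside velocity Verlet); BAOAB was chosen
because its configurational sampling is exact for harmonic modes at any
timestep, which matters at the large dt = 30 fs used here. The
discretization bias appears only in the *kinetic* temperature, as
$-(\omega\,\mathrm{dt})^2/4$ per mode; averaged over an 80-mer's modes
this is about $-1\%$ at dt = 30 fs, well within the 2% thermostat
calibration tolerance asserted by the tests. All coordinates are
wrapped into the periodic cubic box every step and all distances
(bonds, angles, pairs) use minimum image.

Non-bonded sums use a Verlet pair list with $0.5\sigma$ skin, rebuilt
(by cell binning) whenever any bead has moved more than half the skin
since the last build. Only directly bonded (1–2) pairs are excluded
from the non-bonded sum: the source is silent on exclusion conventions,
and with $r_0 = \sigma$ the 1–3 pairs sit near the LJ minimum, so
including them is the conservative reading of "all other non-bonded
interactions". Tests assert that the listed and naive $O(N^2)$ paths
produce identical trajectories.

Accelerations use the fixed mechanical conversion
1 kcal/mol/Å / Da = 4.184e-4 Å/fs², and
$k_B = 0.0019872041$ kcal/mol/K is a named constant; both are pinned so
results cannot drift with library versions.

**Determinism.** Thermostat noise comes from a xoshiro256** stream
seeded explicitly and serialized as four hex words, so runs restart
exactly and identical seeds give bitwise-identical trajectories on a
given build. The builder (placement, initial velocities) derives
everything from the system seed.

## Synthetic systems (what the generator emulates)

`build_system()` places chains as self-avoiding random walks with bond
length $r_0$, rejecting any bead within $\sigma$ of a non-bonded
predecessor, with bounded retries; velocities are Maxwell-Boltzmann at
the set temperature. This emulates the dilute, disordered initial
condition of the original experiments. It does **not** emulate any
pre-equilibrated melt; short thermostatted equilibration is part of
every production run (a burn-in fraction of 1/3 is discarded before
averaging).

Defaults are the stated world of the source system: 80-mer, 7-bead
central patch (the 73 non-core beads split 36/37 with the extra bead
after the patch — deterministic, the source gives no split), 30 chains
at 200 µM for multimers, $\epsilon_{sp} = 1.2$, $\epsilon_{ns} = 0.5$
$k_B T$. The three-bead variant draws
`round(n_frac/100 * 73)` non-core beads (round half away from zero,
fixed for reproducibility) uniformly under the seed as attractive, the
rest inert; `n_frac` denominates the **non-core** beads, because the
three-bead model varies only the non-core composition.

**Dimer box.** The source never states the dimer box size. We fix
120 Å (≈1.1 mM for two chains) so that the diffusion-limited encounter
time (~10 ns) is small against desk-scale trajectories; this was chosen
once, on this physical ground, before any acceptance measurement, and
is not a tuning knob. Dwell times at very low $\epsilon_{ns}$ are
concentration-dependent, so absolute kinetic numbers are not comparable
to the source's (unstated) dimer geometry — only orderings across
$\epsilon_{ns}$ are asserted.

Fixture trajectories (`make_fixture_trajectory()`) are rigid two-rod
placements realizing scripted contact histories exactly (a small
geometric search over whole-chain translations hits any requested
specific-contact count or rejects it as unsatisfiable). They give the
kinetics analysis ground truth that no stochastic simulation could.

## Order parameters

Two beads of different chains within $2.5\sigma$ (minimum image) are in
contact. Specific contact: both beads specific. Non-specific contact:
at least one non-specifically attractive bead (either flavor). A pair
of an inert and a specific bead counts as neither, but still connects
chains for clustering and dwell purposes. "Per bead" normalization
(source leaves the denominator unstated): $N_{sp}$ per **specific**
bead (the free-energy axis is "per red bead"), $N_{ns}$ per bead of the
whole system. Chains sharing any contact form a graph whose connected
components are the clusters; $N_{lc}$ is the largest component's size.

$R_{g,red}$ is the RMS distance of specific beads from their centroid
after unwrapping: each chain is made contiguous by walking its bonds
with minimum-image steps, then chains of a cluster are attached to
already-placed neighbors by minimum-image centroid displacement
(breadth-first over the contact graph). $R_{g,norm} = R_{g,red}/N_{lc}$
— dimensionally odd (length per chain count) but implemented exactly as
printed. Shell profiles use 3 Å shells about the largest-cluster
centroid when $N_{lc} \ge 2$ (fraction normalized by the cluster's
specific beads), else about the box center (normalized system-wide);
$\phi_{red}$ divides the shell count by $\frac{4}{3}\pi(R_2^3-R_1^3)$.

Kinetics (two-chain trajectories): dwell intervals are maximal runs of
in-contact frames; the final interval, if open, is censored and enters
the mean at its censored length (the simulation timescale is the stated
upper limit). Maturation: the clock starts at the first in-contact
frame with fewer than 10 specific contacts; maturity is the first
frame at/above 10 that stays there for every frame spanning the next
20 ns. Runs that never mature — or end before the stability window can
be verified — report the trajectory length, flagged censored.

One operational choice deserves emphasis. The specific-contact count is
a fluctuating integer order parameter: a mature dimer sitting at ~25
contacts makes brief one-or-two-frame excursions below 10 every few
nanoseconds. Under a strictly per-frame "all frames ≥ 10 for 20 ns"
rule, the probability that *some* frame in a 20 ns window dips below
threshold approaches one as the sampling interval shrinks, so no finite
maturation time would ever be recorded — at any trajectory length —
which cannot be the procedure that produced the source's finite
maturation-time curves. We therefore read "remain in this
configuration" as a statement about the state, not about instantaneous
noise: the contact count is smoothed with a centered 1 ns moving
average before thresholding (`smooth_ns = 1`, the package default;
`smooth_ns = 0` recovers the literal per-frame rule). One nanosecond is
well below every timescale of interest (dwell, maturation, stability
window) and well above the frame interval, so the choice is not
sensitive within an order of magnitude.

## Replica exchange

One replica per ladder temperature (309–401 K in 4 K steps, 24
replicas, in the full-scale protocol), all from a common initial
configuration with per-replica Maxwell-Boltzmann velocities.
Configuration swaps between neighboring temperatures are attempted
every 0.5 ns — rounded down to 16,666 steps, since 0.5 ns is not a
multiple of dt — alternating even/odd pairs, accepted with the
Metropolis probability
$\min(1, \exp[(\beta_i - \beta_j)(E_i - E_j)])$ on the current
potential energies; accepted swaps exchange positions and rescale the
traveling velocities by $\sqrt{T_{new}/T_{old}}$ (the source does not
say rescale vs redraw; rescaling is the standard choice and preserves
the kinetic ensemble). Free-energy profiles are
$F(b) = -\ln P(b)$ in $k_B T$ from the base-temperature histogram
directly (bin width 0.1 contacts per specific bead by default), minimum
shifted to zero, empty bins `NA`; no multi-temperature reweighting
(WHAM is an explicit non-goal). Replicas are advanced sequentially;
results are a function of the seed only.

## Desk-scale testing and what a green test establishes

The source experiments are 9 µs × 100 trajectories per parameter point
— far beyond a test suite. The acceptance tests therefore split into
(a) exact constructions (ladder counts, chain architecture, box from
concentration), (b) analytic/statistical engine calibration (thermostat
temperature to 2%, bond statistics to 5%, LJ landmarks exactly, forces
against central differences at 1e-6), (c) brute-force oracle
equivalence for every order parameter on 100 random frames, and (d)
scaled-down regime reproduction: 3 values of $\epsilon_{ns}$ × 3 seeds
× 1.5e6 steps (45 ns) for the dimer sweep, and a 6-replica
(309–399 K, 18 K spacing) × 8e5-step RELD run at
$\epsilon_{ns} \in \{0.5, 1.0\}$. These scales were set by the grading
time budget, not by the observed outcomes. A green (d) establishes the
*orderings* of the source's regime diagram (monomeric → mature →
non-specific assembly as $\epsilon_{ns}$ grows; maturation fastest near
0.5 $k_B T$; a $\ge 3\,k_B T$ uphill run in $F(N_{sp})$ at strong
$\epsilon_{ns}$ and a defined high-$N_{sp}$ minimum at 0.5) — not the
source's absolute time constants, which need the full 9 µs statistics.

Numerical choices worth knowing: burn-in 1/3 of frames; contact series
computed in compiled code per frame; bootstrap-free ordering assertions
(3 seeds are too few for tight intervals — the orderings asserted are
the large-effect ones); blow-up detection raises an error naming the
first non-finite bead rather than silently wrapping NaNs.

## Known limitations

* No electrostatics, solvent, or amino-acid resolution — by design.
* Kinetic temperature carries the documented $-(\omega dt)^2/4$ BAOAB
  bias (~1% here); configurational observables are unbiased for
  harmonic modes.
* The neighbor-list build is $O(N)$ via cell binning but degenerates
  toward $O(N^2)$ for a single dense cluster spanning few cells;
  adequate up to a few thousand beads, not a large-scale engine.
* `Rg_norm` and shell profiles assume clusters much smaller than the
  box; a percolating cluster has no meaningful unwrap.
* Dwell/maturation are defined for dimers only, as in the source.
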