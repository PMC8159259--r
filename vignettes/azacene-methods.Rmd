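---
title: "Evolutionary aza-acene design and charge-transport evaluation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary aza-acene design and charge-transport evaluation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azacene)
```

## The problem

Finding a good n-type organic semiconductor means finding a molecule that
simultaneously (i) reorganises little when it accepts an electron, so that
hopping between molecules in the crystal is fast; (ii) has a high enough
solid-state electron affinity that electrons can be injected from a common
metal electrode without a large Schottky barrier; and (iii) crystallises in
a packing with strong intermolecular electronic coupling.  The first two
are single-molecule properties and can be optimised directly; the third
depends on the crystal structure and is assessed afterwards over each
candidate's landscape of predicted crystal structures.

`azacene` implements this workflow for the chemical space of aza-substituted
acenes: molecules made of fused six-membered aromatic rings whose CH units
may be replaced by pyridine-type nitrogen.  The expensive physics — quantum
chemical energies and electronic couplings, and crystal structure
prediction — enters only through pluggable inputs: a lookup table of real
results, a deterministic surrogate, coupling files, or toy crystal
generators.

## Exact molecular representation

Every molecule in this space is a fused polycyclic of six-membered aromatic
rings, which embeds exactly on a hexagonal lattice: rings are lattice cells
and atoms are cell vertices.  The package stores a molecule as its set of
cell centres plus the set of nitrogen-bearing vertices, using an integer
coordinate frame in which all twelve lattice point-group operations (six
rotations, with and without reflection) are exact integer maps.

This turns three otherwise delicate tasks into finite, exact computations:

* **Canonical identity.**  The canonical form minimises the serialised cell
  set over the twelve operations plus translation, breaking remaining ties
  by the nitrogen-position bitmask.  Two molecules have equal canonical
  keys exactly when they are the same compound (verified in the test suite
  against colored-graph isomorphism via igraph's canonical labelling, and
  against OpenBabel canonical SMILES).  The user-visible key is an aromatic
  SMILES written deterministically from the canonical form.
* **Valence rules.**  A vertex shared by one cell is a CH position (and may
  carry N); a vertex shared by two cells is a ring-fusion carbon and can
  never be nitrogen (a bridgehead aza nitrogen would be charged); three
  shared cells mark peri-fusion.
* **Region analysis.**  Concave perimeter regions are found as empty cells
  whose occupied neighbours form a contiguous arc of $k \ge 2$ cells,
  exposing $k+1$ perimeter atoms: 3 a fissure, 4 a bay, 5 a cove
  (benzo[c]phenanthrene), 6 a fjord (pentahelicene).  Placing a ring on
  such a cell is precisely the "filling" move that creates pyrene-like
  peri-fused arrangements.

One representational limit is documented rather than hidden: helicenes with
six or more rings cannot be drawn on the plane without overlap, so the
parser rejects them.  Within the five-ring space used throughout, the
lattice embedding of every molecule is exact.

### Fissures and the bay rule

The space definition forbids additions into bay, cove and fjord regions so
that every molecule stays cata-fused.  Three-atom fissures (the shallow
notch of any linear acene) are not bays by the naming convention, but
filling a fissure produces exactly the same pyrene-type peri-fusion as
filling a bay; the package therefore groups fissure fills under the `"bay"`
exclusion class.  With all three regions forbidden, the operators provably
preserve cata-fusion.

## The transformation operators

* **Addition** ortho-fuses a fragment across a perimeter bond: a random
  bonding position is drawn first, then a random orientation, and invalid
  draws are rejected.  Both bond atoms (on molecule and fragment) must be
  carbon, since they become ring-fusion positions.
* **Crossover** cuts each parent at a random ring-fusion bond of its
  dualist tree, then fuses one fragment from each parent at a random
  position and orientation; both fragment pairings are possible.  The
  heavy-atom multiset of the two children equals that of the parents.
* **Recombination** is self-crossover: cut once, re-fuse somewhere else,
  producing an isomer with identical formula and ring count.
* **Mutation** replaces one matched position with a different fragment from
  the SMARTS list.  The package implements a restricted single-atom
  aromatic SMARTS dialect (`c`, `n`, `[cH]`, `[nH0]`), which is the whole
  vocabulary this chemistry needs; the default list `[cH]`, `n` makes
  mutation a single-site CH↔N flip.

Operators that run out of legal moves return `NULL` (addition, crossover)
or the unchanged input (recombination, mutation), and the search layer
decides the fallback — for crossover, copying the parents.

## The size of the space

Exhaustive enumeration grows all allowed skeletons by region-respecting
addition from benzene (twelve cata-fused pentacyclics, from pentacene to
pentahelicene plus two branched forms), then counts CH→N substitution
patterns per skeleton deduplicated under the skeleton's symmetry group.
Each orbit count is cross-checked internally against the Burnside formula,
and the pentacene skeleton alone carries 4,224 distinct patterns.

Summed over the twelve skeletons there are **135,744** distinct molecular
graphs.  The package also exposes a second, *complement-paired* counting
convention in which every substitution pattern is identified with its full
CH↔N complement; there are 384 self-complementary classes, so this
convention counts $(135{,}744 + 384)/2 = \mathbf{68{,}064}$ entries.
Equivalently: all molecules with at most six nitrogens plus one
representative of each complementary pair at exactly seven.
`enumerate_space()` defaults to the paired convention, which is the space
size quoted for this search problem in the organic-semiconductor
literature; membership checks in the operator-closure tests use the plain
molecular-graph convention, because a molecule and its complement are of
course different compounds.  Both conventions are first-class and
documented so users can choose deliberately.

## The evolutionary engine

The defaults are the study conditions used in all packaged experiments:
populations of 100, 30 generations, 10% elitism, 2-way tournament
selection, crossover for every non-elite child, then mutation and
recombination each with probability 5%; initial molecules are built from a
random base fragment by random additions to five rings and scrambled by 500
mutation steps.  Determinism choices the literature leaves open are fixed
as: elite count `round(rate × size)` with fitness ties broken by canonical
key; tournaments sample distinct individuals and the fitter always wins
(ties again by key); children receive mutation before recombination,
matching the order the operations are described in; termination is a fixed
generation count, with an optional mean-fitness stall criterion off by
default.  A canonical-key cache guarantees each unique molecule is
evaluated once per run; oracle failures are recorded as `+Inf` fitness so
the molecule can never become an elite.  All randomness flows through R's
global RNG, seeded from `ea_config(seed = )`, so a run is exactly
reproducible from (seed, space, config, oracle).

With the packaged surrogate oracle, ten seeded default runs all locate the
known global minimum (pentacene) in 8–16 generations while evaluating
roughly 1.8–2.2% of the 68,064-entry space — the behaviour the acceptance
suite asserts as "at least 9 of 10 runs, under 5% of the space".

## Fitness functions and the surrogate

$F_A = \lambda_-$ is the four-point electron reorganisation energy,
$\lambda_- = [E_-(R_0) - E_0(R_0)] + [E_0(R_-) - E_-(R_-)]$ (eV).
$F_B = \lambda_- + \max(W - A_s, 0)$ adds the Schottky–Mott injection
barrier from an electrode of work function $W = 4.1$ eV (matching Ag, Cu,
Au) whenever the solid-state electron affinity $A_s$ falls below $W$; the
penalty is continuous at $A_s = W$.  $A_s$ comes from the gas-phase
adiabatic electron affinity through a linear calibration whose default
slope 1.0 and intercept 1.4 eV are an explicitly flagged placeholder of the
right physical magnitude (thin-film polarisation stabilises the anion by
roughly 1–2 eV); users with inverse-photoemission calibration data should
supply their own `ea_calibration()`.

The surrogate oracle stands in for quantum chemistry with a documented
deterministic form (eV):
$\lambda_- = 0.10 + 0.03\,d + 0.005\,n_N + 0.002\,h$ and
$A_{gas} = 1.30 + 0.12\,n_N - 0.02\,d + 0.002\,h$, where $d$ is the
non-linearity degree, $n_N$ the nitrogen count and $h \in [0,1)$ a
deterministic hash of the canonical key.  The constants are arbitrary by
design; tests assert only the structure: the strict global $\lambda_-$
minimum at pentacene, monotone increase of $\lambda_-$ with bending and
substitution, strict increase of $A_{gas}$ under any single CH→N
substitution (0.12 dominates the 0.002 jitter), and the resulting
λ–EA trade-off front.  Passing tests under the surrogate demonstrates the
search machinery, not chemistry: real reorganisation energies are not a
smooth function of two descriptors, and real searches will be noisier.

The **non-linearity degree** counts, over all rings with two or more fused
neighbours, the pairs of fusion bonds not in the para (linear)
arrangement: 0 for linear acenes, 1 per angular kink, 3 for a trigonal
branch ring — giving degrees 0–4 across the pentacyclic skeletons.

## Charge transport

Hopping rates use the standard non-adiabatic Marcus expression
$k = \frac{2\pi}{\hbar}|V_{ab}|^2(4\pi\lambda k_BT)^{-1/2}
\exp[-(\Delta G+\lambda)^2/4\lambda k_BT]$ with $\hbar$ in eV·s and $k_B$
in eV/K, $\Delta G = 0$ for hops between identical molecules (a per-edge
$\Delta G$ remains available), and all couplings scaled by 1.325 before
entering the rate — the accepted alignment of fragment-orbital DFT
couplings with high-level references.  The hopping network includes every
dimer with an atom–atom contact inside the Bondi van der Waals radii sum
plus 1.5 Å, over all periodic images that can reach; geometrically
identical dimers (Kabsch RMSD < 0.001 Å, proper rotations only, both
molecule orderings tried) share a single coupling evaluation.  Every edge
stores its image shift and centroid displacement, and its reverse.

The kinetic Monte Carlo is the rejection-free n-fold way: each step picks a
hop with probability $k_j/\Sigma k$ and advances the clock by an
exponential waiting time of mean $1/\Sigma k$ — exponential rather than
deterministic, so the time statistics are unbiased.  Trajectories
(default 100,000 of 1,000 hops, at 300 K) start uniformly cycled over the
sites.  The diffusion tensor is the pooled ratio
$D = \sum_i \Delta r_i \Delta r_i^{\mathsf T} / (2\sum_i t_i)$; the
per-trajectory ratio average was rejected because its $1/n_{\text{steps}}$
bias is comparable to three standard errors at $10^4$ trajectories, while
the pooled estimator's bias is smaller by a further factor of
$n_{\text{traj}}$.  Mobilities follow from the Einstein relation
$\mu = qD/k_BT$ (displacements are accumulated in Å², converted by
$10^{-16}$ to cm²/s), and the scalar figure of merit is
$\bar\mu = \operatorname{tr}(\mu)/3$.  For single-site networks the walk
has independent increments and
$D = \tfrac12\sum_e k_e d_e d_e^{\mathsf T}$ exactly
(`analytic_transport()`), which anchors the estimator tests: on a 1-D
stack the kMC mean mobility must sit within three standard errors of
$k a^2$-based closed form, and on a cubic equal-rate network the tensor
must be isotropic to sampling error.  The C++ walker uses R's RNG, so
`set.seed()` governs trajectories too.

## Landscape statistics

A molecule's predicted crystal structures within 7 kJ/mol (inclusive) of
its global lattice-energy minimum — the window that covers most
experimentally observable polymorphs — receive Boltzmann-like observation
probabilities $P_i \propto \exp(-\Delta E_i/\tau)$ with
$\tau = 2.70$ kJ/mol, an empirical polymorph energy-difference scale.
Normalisation happens after windowing: structures outside the window are
treated as unobservable and their mobilities are never computed, which is
also why the summary refuses windowed entries with missing mobilities.
The summary reports $\bar\mu_{GM}$ (the $\Delta E = 0$ structure, first by
stable order if degenerate), the landscape average
$\langle\bar\mu\rangle = \sum_i P_i\bar\mu_i$ and the spread
$\langle\Delta\bar\mu^2\rangle^{1/2}$, a risk measure that vanishes for a
uniform landscape and recovers $\bar\mu_{GM}$ as $\tau \to 0$ and the
plain mean as $\tau \to \infty$ — all asserted against a naive two-pass
oracle in the tests.

## Synthetic fixtures and what they do not show

`make_toy_crystal()` builds three motifs around a four-atom rigid plate:
a pure 1-D stack (optionally with order-of-magnitude-weaker transverse
pathways, emulating predominantly one-dimensional conductors), an isotropic
cubic reference, and a two-molecule herringbone cell with a
distance-decaying coupling generator that exercises the dimer
deduplication.  `make_reference_landscape()` draws relative energies from
an exponential of mean 3 kJ/mol above a global minimum at zero and
mobilities from a log-normal (meanlog 0.5, sdlog 0.8) — the dense-low-energy
shape of predicted landscapes.  None of these fixtures have the energetics
of real force fields or the coupling anisotropy of real π-stacks; they
validate estimators and bookkeeping, not materials predictions.

## Numerical and interface choices

* Coordinates are exact integers (lattice) or Cartesian Å (crystals);
  fractional coordinates appear only at the CIF boundary.  The CIF reader
  covers cell parameters, the atom_site loop and an optional symmetry-ops
  loop expanded to P1, grouping atoms into molecules by the label prefix
  before the first underscore.
* Problem sizes in the default test run: full-space enumeration (seconds),
  twenty 100-molecule initial populations, ten 30-generation searches,
  $10^4$-trajectory kMC on reference networks, and $10^4$ operator-closure
  checks.
* Known limitations: no five- or seven-membered rings or substituents
  beyond aza-substitution; helicenes beyond five rings are not
  representable; crossover and recombination require cata-fused inputs;
  SMARTS support is the single-atom dialect above; crystal-structure
  prediction and electronic-structure computation are out of scope by
  design and enter as data.
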