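# azacene

Evolutionary design of aza-substituted acene semiconductors, with
charge-transport evaluation of their crystal structures.

## What it does, and for whom

Discovering an n-type organic semiconductor means searching an enormous
space of candidate molecules for ones that combine a small electron
reorganisation energy λ₋ (fast hopping), a high solid-state electron
affinity *A*ₛ (easy electron injection from a metal electrode), and crystal
packing with strong intermolecular coupling.  `azacene` is for
computational chemists who want to run that search over fused six-membered
aromatic C/N ring systems — the aza-acenes — without exhaustively computing
every molecule.

The package provides:

* an **exact molecular representation** of fused aromatic C/N ring systems
  on a hexagonal lattice, with canonical SMILES identity, bay/cove/fjord
  region analysis and exhaustive space enumeration
  (the five-ring aza-acene space: 68,064 entries under the complement-paired
  counting convention; 135,744 distinct molecular graphs);
* the four **transformation operators** — addition, crossover,
  recombination, SMARTS mutation — and a **generational evolutionary
  engine** (elitism, tournament selection, fitness caching);
* two **fitness functions**: *F*<sub>A</sub> = λ₋ and the
  Schottky-penalised *F*<sub>B</sub> = λ₋ + max(*W* − *A*ₛ, 0) with
  *W* = 4.1 eV, behind pluggable property oracles (lookup tables of real
  quantum chemistry results, or a documented deterministic surrogate);
* **Marcus-theory hopping networks** from crystal structures (van der
  Waals + 1.5 Å contact cutoff, Kabsch dimer deduplication at 0.001 Å,
  couplings scaled by 1.325), **rejection-free kinetic Monte Carlo**
  mobility tensors via the Einstein relation μ = qD/k_BT at 300 K, and
* **energy–structure–function landscape statistics**: Boltzmann-like
  structure probabilities (τ = 2.70 kJ/mol) inside a 7 kJ/mol window, the
  landscape-averaged mobility ⟨μ̄⟩ and its spread ⟨Δμ̄²⟩¹ᐟ².

Everything is data-frame first: populations, run logs, enumerations and
landscapes are tibbles; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods.

## A worked search

```r
library(azacene)

space <- space_definition()       # five fused rings, aza substitutions,
                                  # no bay/cove/fjord additions
enumerate_space(space) |> nrow()
#> [1] 68064

run <- run_evolution(space, ea_config(seed = 11), surrogate_oracle())
run
#> <azc_evo_run> 30 generations, 1003 unique molecules sampled
#>   best: c1cccc2c1cc3cc4cc5ccccc5cc4cc3c2 (fitness 0.1018 eV, first seen generation 3)
glance(run)
#> # A tibble: 1 × 6
#>   n_generations best_key          best_fitness best_first_generation n_unique_sampled n_failed
#>           <int> <chr>                    <dbl>                 <int>            <int>    <int>
#> 1            30 c1cccc2c1cc3cc4c…        0.102                     3             1003        0
```

The run located the surrogate's known global minimum — pentacene, the
unsubstituted linear pentacyclic — in generation 3 after evaluating 1,003
unique molecules, about 1.5% of the space.  `autoplot(run)` draws the
mean/min fitness trajectory; `tidy(run)` returns the per-generation log.

Transport on a toy 1-D π-stack, against the exact closed form:

```r
toy <- make_toy_crystal("stack_1d", spacing = 3.8, coupling = 0.010)
net <- build_network(toy$crystal, toy$couplings, lambda = toy$lambda)
kmc_mobility(net, n_traj = 1e4, n_steps = 1000, seed = 5)
#> <azc_transport> mean mobility 0.03871 cm^2/(V s) (se 0.00055), eigenvalues 0.1161, 0, 0
analytic_transport(net)$mu_mean
#> [1] 0.03778396
```

The mobility is carried entirely by one eigenvalue (the stack axis), and
the kinetic Monte Carlo estimate agrees with the exact single-site result
*D* = *k a*² within two standard errors.  Landscape statistics summarise a
molecule's predicted crystal structures:

```r
l <- landscape(data.frame(structure_id = c("gm", "p2"),
                          relative_energy = c(0, 2.70),
                          mean_mobility = c(10, 2)))
summarise_landscape(l)
#> # A tibble: 1 × 4
#>   n_structures_in_window mu_gm mu_avg mu_spread
#>                    <int> <dbl>  <dbl>     <dbl>
#> 1                      2    10   7.85      3.55
```

Command-line wrappers for both workflows live in `inst/scripts/`
(`evolve.R`, `mobility.R`).

## Scope

Quantum chemistry (reorganisation energies, electron affinities, electronic
couplings) and crystal structure prediction are deliberately out of scope:
they enter as pluggable tables, files and toy generators.  See the methods
vignette (`vignettes/azacene-methods.Rmd`) for the models, conventions and
numerical choices.
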