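# acetylwall

Structure and transport analysis of acetylated plant secondary cell wall
models.

## The problem this package addresses

Acetylation — replacing exposed hydroxyl groups on hemicellulose and lignin
with acetyl groups (–C(=O)CH₃) — makes wood resistant to fungal decay, and
the open mechanistic question is *why*: do acetyl groups bind diffusing
ions directly, or does acetylation displace cell-wall water so that
transport slows by dehydration? Molecular-dynamics models of the secondary
cell wall can separate the two effects, but doing so takes a substantial
analysis pipeline. `acetylwall` implements that pipeline for R users
working with such models:

* **Acetylation bookkeeping** — exposure-based hydroxyl selection,
  weight-percent gain WPG = 100·(m_post − m_pre)/m_pre, constant-volume
  water removal N = round(ρ·N_A·ΔV/MW), and inverse atom-count arithmetic.
* **Diffusion** — displacement-based unwrapping, translation-only drift
  removal, mean-squared displacement, and two Einstein-relation estimators
  (D = MSD/6t): a linear MSD fit and a sliding-window variant, both with
  block-averaged standard errors.
* **Interactions** — switching-function contacts
  C = Σ [1 + e^{5(d−5 Å)}]⁻¹ over heavy-atom pairs, radial distribution
  functions, relative ion-binding free energies
  ΔG = −RT ln(P_s/P_c) with propagated 20-block errors, and ion dwell-time
  distributions with censoring flags and time-weighted CDFs.
* **Solvent structure** — the percentage of water molecules at least 5 Å
  from every biopolymer atom ("bulk water pockets"), per frame.
* **Synthetic generators** — seeded Brownian, two-state binding,
  Boltzmann-occupancy, and toy cell-wall fixtures with exact ground truth,
  so every estimator is validated without microsecond trajectories.

All periodic geometry is exact minimum-image on orthorhombic boxes;
topologies are read from PDB (via bio3d), trajectories from DCD or a
plain-text CSV fixture format.

## Worked example

Acetylate a toy cell wall at the 3 Å exposure cutoff in constant-volume
mode, then recover a planted diffusion coefficient and planted binding
free energies from synthetic trajectories:

```r
library(acetylwall)

toy <- gen_toy_cellwall(toy_cellwall_spec(n_bound_water = 10,
                                          n_bulk_water = 10, seed = 1))
plan <- acetylation_plan(toy$trajectory, cutoff = 3, mode = "constant",
                         n_water_removed = 4)
plan
#> acetylation_plan: 12 sites (cutoff 3 A ), mode constant
#>   dry mass 1817.2 -> 2321.6 g/mol, WPG 27.76%
#>   waters removed: 4 (policy displace )
res <- apply_plan(toy$trajectory, plan)
```

Twelve hydroxyls sit within 3 Å of water; acetylating them adds
12 × 42.037 g/mol of dry mass (a 27.8% weight gain on this tiny fixture)
and removing 4 waters drops the moisture content from 16.5% to 11.0%.
The inverse bookkeeping recovers the site count exactly:
`sites_from_atom_counts(res$report$pre_atoms, res$report$post_atoms, 4)`
returns `12`.

```r
g <- gen_brownian(brownian_spec(d_true = 6.1, n_particles = 500,
                                n_frames = 1000, dt = 0.1, seed = 1))
un <- unwrap_trajectory(g$trajectory)
diffusion_linear(msd_time_averaged(un, seq_len(500)))
#> D = 6.116e-07 cm^2/s (6.116 A^2/ns) +/- 1.1e-10, estimator: linear_fit
```

The planted 6.1 Å²/ns (the diffusion scale of monovalent ions in a
water-saturated cell wall) is recovered within 0.3%.

```r
st <- data.frame(group = c("carboxyl", "acetyl", "hydroxyl"),
                 count = c(60, 240, 120), energy = c(0, 1.18, 2.26))
bz <- gen_boltzmann_sites(boltzmann_site_spec(st, n_ions = 120,
                                              n_frames = 400, seed = 1))
binding_free_energy_table(bz$trajectory,
                          atom_select(bz$trajectory, component = "ion"))
#>     group    method delta_g   sigma
#>  carboxyl atom_pair    0.00 0.00000
#>  carboxyl       rdf    0.00 0.00000
#>    acetyl atom_pair    1.18 0.00267
#>    acetyl       rdf    1.18 0.00267
#>  hydroxyl atom_pair    2.26 0.01801
#>  hydroxyl       rdf    2.26 0.01801
```

Both free-energy routes — direct contact counting and RDF integration to
the first minimum — recover the planted offsets (1.18 and 2.26 kcal/mol
relative to the carboxyl reference) within their reported uncertainties.
The carboxyl row is exactly 0 ± 0 by construction.

The full staged pipeline (generate/load → unwrap/align → analyses → CSV
reports plus a JSON manifest) is driven by `run_config()` and
`run_pipeline()`.

## Package layout

```
R/                  implementation (core model, generators, acetylation,
                    dynamics, interactions, solvent, pipeline)
tests/testthat/     unit, property, and acceptance tests with brute-force
                    oracles built in code
vignettes/          methods vignette: models, assumptions, parameters,
                    design decisions, limitations
scripts/            acceptance script (see above)
```
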