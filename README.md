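# bmchex

Geometry, classification and energetics of bacterial microcompartment (BMC)
shell hexamer assemblies, with fully synthetic ground-truth generators.

BMC shells tile from cyclic hexamers (BMC-H) whose lateral interfaces adopt a
small set of recurring arrangements. `bmchex` provides a tidyverse-native
toolkit for the quantities that characterize those interfaces:

- **Structures** — PDB/mmCIF reading (cell and symmetry included), PDB
  writing, atom tables as tibbles, residue landmark maps
  (`read_structure()`, `write_model()`, `landmark_map()`).
- **Lattice** — crystal-symmetry expansion to a 2D layer, hexamer detection,
  tri-hexamer assembly (`expand_layer()`, `detect_hexamers()`,
  `build_trihexamer()`).
- **Arrangement** — inter-hexamer metrics (lysine edge distance `d_lys`,
  spacing, lateral offset, contact flags) and Arr-A/B/C/D classification
  (`interface_metrics()`, `classify()`, `survey()`).
- **Trajectory geometry** — signed bending/tilting dihedrals per interface
  (negative bending = toward the convex face), average structures, RMSD
  series, center-of-mass deviations, plane representations
  (`angle_series()`, `com_deviation()`, `plane_representation()`).
- **Interface analytics** — per-residue side-chain RMSD profiles, energy
  intervals and interface enrichment, key-residue ranking, a naive
  Coulomb/Lennard-Jones screen (`sidechain_rmsd_profile()`,
  `energy_interval()`, `rank_key_residues()`, `naive_residue_score()`).
- **Regrafting** — Kabsch superposition, regrafting a donor hexamer onto an
  Arr-A template lattice, steric clash reports, alanine mutations
  (`superpose()`, `regraft_arrA()`, `mutate_alanine()`, `clash_report()`).
- **PMF** — WHAM reconstruction from umbrella windows, block-bootstrap
  errors, binding-energy readout, laterally-restrained profiles
  (`wham()`, `bootstrap_error()`, `binding_energy()`,
  `restrained_profile()`).
- **Synthetic ground truth** — toy hexamers with exact C6 symmetry and
  designed landmarks, lattices per arrangement class, trajectories with
  imposed hinge angles, umbrella samples from known potentials, a
  planted-clamp fixture (`make_toy_hexamer()`, `make_lattice()`,
  `make_trajectory()`, `make_umbrella_samples()`, `make_clamp_fixture()`).

Result objects ship `tidy()`, `glance()` and `autoplot()` methods.

## Example

```r
library(bmchex)

# a synthetic tri-hexamer trajectory bending -25 deg toward the convex face
tr <- make_trajectory(toy_lattice_spec(bend = -25, noise = 0.3,
                                       n_snapshots = 100))
as <- angle_series(tr)
glance(as)
autoplot(as)

# classify the canonical lattices
lats <- lapply(canonical_specs(), make_lattice, n_hex = 3)
survey(lats)

# reconstruct a PMF from umbrella samples of a known double well
u <- model_potential("double_well", centre = 7, half_sep = 4, barrier = 6)
s <- make_umbrella_samples(u, centers = 0:14, k = 1000)
pm <- wham(s)
autoplot(pm, se = bootstrap_error(s, B = 30))
```

## Installation and checks

```sh
R CMD INSTALL .
Rscript -e 'testthat::test_dir("tests/testthat", package = "bmchex")'
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

`scripts/acceptance.R` recomputes the headline quantities (angle recovery,
classification accuracy, WHAM errors vs bootstrap SE, regraft exactness,
planted-clamp recovery) and writes them as JSON.

See the methods vignette (`vignettes/bmchex-methods.Rmd`) for conventions,
the decision rule, and the validation design.

## License

MIT
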