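# memtun

Geometric and statistical analysis of membrane-anchored cytochrome P450
models: how the enzyme sits in a lipid bilayer, which residues touch the
lipids, how flexible it is, when the tunnels between its buried active
site and the surface are open, and how the internal aromatic gate behind
those tunnels behaves.

Microsomal P450s are anchored in the endoplasmic-reticulum membrane by a
single N-terminal transmembrane helix, with the catalytic domain facing
the cytosol and the heme-containing active site buried inside it.
Substrates and products must travel through discrete tunnels, and the
membrane itself influences which tunnels open. memtun implements the
quantitative machinery for characterizing such systems:

* **Orientation** — with the bilayer in the xy plane: the signed
  z-projection *d* of the protein–membrane center-of-mass separation, and
  the angles *α* and *β* between the z axis and two vectors defined by
  Cα-window midpoints (**v1** along helix I, residues 285–289 → 312–316;
  **v2** from helix C to helix F, 127–131 → 197–201). Predominant
  orientations are the peaks of the (d, α, β) histograms; representative
  snapshots are frames within 1 % of all three peaks. Helix tilt, heme
  tilt and height above the membrane complete the descriptor set.
* **Protein–lipid contacts** — residues classified into membrane /
  head-group / cytosol z-slabs ("M-HG-C" location strings), and contact
  tables (heavy-atom distance < 4 Å) by residue category (hydrophobic,
  aromatic, hydrophilic, charged, Gly, Pro) × lipid part (head, middle,
  tail); percent of the domain in contact; area per lipid.
* **Flexibility** — Kabsch superposition, residue-range RMSD series in
  the frame of the fitted domain, and B-factors
  B = (8π²/3)⟨|r − ⟨r⟩|²⟩.
* **Tunnels** — clearance grids (distance to the nearest atom surface)
  and widest-path (maximin bottleneck) search from a buried start point
  to the surface; tunnels assigned to named entrances (2a, 2b, 2c, 2ac,
  2e, 2f, S) by an exclusive 5 Å rule; a tunnel is *open* when its
  minimum radius exceeds 1.2 Å; open fractions and opening/closing
  co-occurrence (phi coefficient).
* **Aromatic gate** — phenyl-ring-center distances d1 (F100–F114) and d2
  (F100–F476); the gate is open when d2 > 7 Å; ring mobility as the area
  covered by ring centers projected onto the heme plane (binned min/max
  estimator with outlier trimming).
* **Coarse-grain tools** — heavy-atom-centroid bead mapping, elastic
  networks (springs between backbone beads closer than 7 Å,
  k = 10.75 kcal mol⁻¹ Å⁻², linker 23–37 decoupled), randomized linker
  dihedrals for unbiased starting orientations, and template-library
  lipid backmapping with a < 1.5 Å conversion-RMSD bound.
* **Synthetic systems** — toy bilayers, an annotated anchored protein,
  rigid-body trajectories whose orientation parameters equal prescribed
  targets *exactly*, Gaussian-fluctuation trajectories, tilted-helix pose
  sets and cavity fixtures with channels of known bottleneck radius.
  These replace MD trajectories and give every estimator a ground truth.

Structures are read from PDB (via bio3d, including multi-model
trajectories) and GRO files; the grid search runs in compiled code
(Rcpp).

## Worked example

```r
library(memtun)

# build a synthetic membrane-anchored system
protein <- build_toy_anchored_protein()
bilayer <- build_toy_bilayer(8, 8, 8, seed = 1)
system  <- combine_systems(protein, bilayer)
system
#> structure_model: 1363 atoms, 628 residues
#>   roles: heme=4, lipid=768, protein=591
#>   box: 64.00 x 64.00 x 102.00 A

# rigid-body trajectory posed at the first predominant orientation
rb <- generate_rigid_body_trajectory(
  system,
  schedule = list(d = 39.5, alpha = 100, beta = 123,
                  sigma_d = 2.5, sigma_alpha = 9, sigma_beta = 8),
  nframes = 2000, seed = 1)
records <- orient_trajectory(rb$trajectory)
peaks <- histogram_peak_select(records)
round(peaks$peaks, 2)
#>      d  alpha   beta
#>  39.44  99.78 122.80
peaks$frame
#> [1] 1329

gate_state(frame_model(rb$trajectory, peaks$frame))
#> gate_state: d1 = 5.00 A, d2 = 6.50 A, closed
area_per_lipid(system)
#> [1] 64

# tunnels through a cavity fixture with a known 2.0 A channel
fx <- build_cavity_fixture(bottleneck_radius = 2.0)
grid <- clearance_grid(fx$model, spacing = 0.5)
tun <- find_tunnels(grid, fx$start_point)
sprintf("tunnels: %d, bottleneck %.2f A, open: %s",
        length(tun), tun[[1]]$min_radius, classify_open(tun[[1]]))
#> [1] "tunnels: 1, bottleneck 1.96 A, open: TRUE"
```

The histogram peaks recover the generating orientation (d = 39.5 Å,
α = 100°, β = 123°) to within a fraction of a bin; frame 1329 is the
earliest frame within 1 % of all three peaks. The fixture's 2.0 Å channel
is found with its bottleneck accurate to one 0.5 Å grid spacing and
correctly classified open (> 1.2 Å).

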