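# pocketgrid

Grid-based prediction and evaluation of protein–ligand binding sites in R.

Most of what a protein does, it does by binding small molecules, and it
binds them at specific pockets on its surface. `pocketgrid` implements the
full computational machinery of a voxel-based deep-learning approach to
finding those pockets, for structural bioinformaticians who want every step
— data curation, featurization, model, and metrics — as testable library
code rather than a frozen pipeline:

- **Structure I/O** — TRIPOS mol2 and PDB reading (via bio3d) into tidy
  atom tables; mol2 export of structures and predicted pocket point clouds.
- **Featurization** — an 18-channel per-atom descriptor: a 9-class element
  one-hot (B, C, N, O, P, S, Se, halogen, metal), hybridization,
  heavy-neighbor and heteroatom-neighbor counts, Gasteiger partial charge,
  and five pharmacophore flags (hydrophobic, aromatic, acceptor, donor,
  ring), computed on the perceived molecular graph with Open Babel as the
  chemistry backend.
- **Voxelization** — a 36×36×36 cube (2 Å voxels, 70 Å total extent)
  placed at the protein center; atoms accumulate their feature vectors
  channel-wise, binding sites become binary occupancy masks.
- **Data cleaning** — the structural-similarity deduplication pipeline:
  protein sequences are cut into 3-mers, each 3-mer is fingerprinted as a
  tripeptide molecule with 167-bit MACCS keys, whole-protein fingerprints
  are compared by a sliding-window maximum Tanimoto index, structures are
  clustered by UniProt accession, the longest-sequence representative is
  kept per cluster, chains not in contact with the site are removed, and
  structures whose site lies more than 70 Å from the protein center are
  dropped.
- **Model** — a 3D residual U-Net built from three block types
  (convolution / identity / up-sampling blocks of 12 / 10 / 14 layers),
  5 + 13 + 4 blocks in total, 252 layers, with exact layer and parameter
  accounting, dice loss, a deterministic scaled-down training loop, and a
  skip-connection ablation switch. The deep-learning engine (3D
  convolutions, batch normalization, Adam) is implemented in the package
  with RcppArmadillo.
- **Evaluation** — DCC (center–center distance, hits at ≤ 4 Å), success
  rate, DVO (Jaccard overlap of voxelized site volumes), PLI (proportion
  of the ligand inside the predicted site), and the TP/FP/FN → F1
  protocol, where a structure with no predicted pocket counts as a false
  negative:

  F1 = 2·TP / (2·TP + FP + FN),  DVO = |V_pred ∩ V_site| / |V_pred ∪ V_site|,
  PLI = |V_lig ∩ V_pred| / |V_lig|.

A deterministic fixture generator (`make_toy_protein()`,
`make_cleaning_batch()`, `make_probability_grid()`) produces chemically
sane toy proteins, sites, ligands, and probability grids, so the entire
pipeline runs and is tested without downloading any external dataset.

## Worked example

```r
library(pocketgrid)

# a deterministic toy protein with a binding site on chain A
tp   <- make_toy_protein(fixture_config(n_residues = 15, seed = 1))
spec <- grid_spec(center = structure_center(tp$structure))

# featurize and voxelize
grid <- voxelize_atoms(featurize_structure(tp$structure), spec)
mask <- voxelize_site(tp$site, spec, dilate = 1)

# overfit a reduced-width build on this single example
fit <- train_scaled(
  build_puresnet(reduced_schedule()),
  list(list(grid = grid, mask = mask)),
  train_config(learning_rate = 0.01, steps = 200, batch_size = 1, seed = 1)
)
tail(tidy(fit), 1)
#> # A tibble: 1 × 2
#>    step    loss
#>   <int>   <dbl>
#> 1   200 0.00101

# extract the predicted pocket and score it
prob    <- predict(fit, grid)
pockets <- extract_pockets(prob, spec)
dvo(pockets[[1]], mask)
#> [1] 1
```

The final dice loss near zero says the network can represent and fit the
site mask; the DVO of 1 says the pocket recovered from its probability
grid exactly reproduces the training mask voxel set.

The production-scale build reports its full accounting:

```r
glance(build_puresnet())
#> # A tibble: 1 × 6
#>   layers trainable non_trainable conv_blocks identity_blocks upsampling_blocks
#>    <int>     <dbl>         <dbl>       <int>           <int>             <int>
#> 1    252  13840903         16992           5              13                 4
```

A command-line interface covering the whole pipeline (`fixtures`, `clean`,
`voxelize`, `build`, `train`, `predict`, `pockets`, `eval`, `convert`)
ships under `inst/cli/pocketgrid`.

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "pocketgrid",
                               load_package = "installed")'
```

## Scope

The package implements the computational method at fixture scale. Training
on the full curated structure database and reproducing published
success-rate/DVO/PLI numbers on external benchmark sets requires the
original data and trained weights and is out of scope; the methods
vignette (`vignettes/pocketgrid-methods.Rmd`) spells out what the fixture
experiments do and do not demonstrate.
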