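---
title: "pocketgrid: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pocketgrid: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and procedures, the tunable parameters and why their defaults
are what they are, what the synthetic fixtures do and do not emulate, and
the design choices made where the method left room.

## The problem

Ligands bind proteins at geometrically and chemically distinctive pockets.
The approach implemented here treats pocket detection as 3D image
segmentation: the protein is rendered into a fixed-size voxel grid of
atomic features, a volumetric residual U-Net maps that grid to a per-voxel
pocket probability, and discrete pockets are read off the probability map
by thresholding and connected-component labeling. Around that core sit two
supporting pieces that matter as much as the network: a
structural-similarity cleaning pipeline that deduplicates the training
corpus, and an evaluation suite (DCC/DVO/PLI/F1) that scores predictions
against known sites.

## Voxel representation

A cube of side `2 * max_dist` is placed at the protein's geometric center
(the unweighted mean of heavy-atom coordinates — the method never defines
"center" more precisely, and mass-weighting would complicate the
translation-equivariance contract for no measurable benefit on this task).
Defaults are `max_dist = 35` Å and `resolution = 2` Å per voxel, giving a
36-voxel side and a ~70 Å total extent. A finer 1 Å voxel size is
geometrically incompatible with a 36-voxel side spanning 70 Å, so the
2 Å/35 Å pair is the default and both knobs stay configurable. The 70 Å
extent also motivates the cleaning filter that drops structures whose site
lies more than 70 Å from the center: such a site cannot be represented
inside the box at all.

Atoms inside the box add their 18-channel feature vector to the voxel
containing them (channel-wise sum). Summation, not max, is deliberate: it
makes voxelization additive over atom sets, which is a linearity property
the tests exercise directly. The voxel index along each axis is
`floor((x - center + max_dist) / resolution)`, so an atom exactly at the
center of the default grid lands at 0-based index (17, 17, 17); the tests
pin this against a brute-force nearest-voxel-center assignment, which is
the same map expressed differently.

Site masks are raw occupancy (a voxel is 1 iff a site point falls in it).
Whether the original labels were dilated is not stated anywhere we could
pin down, so raw occupancy is the default and `voxelize_site(dilate = r)`
exposes a Chebyshev dilation radius for users who want padded labels; the
training fixtures use `dilate = 1` to give the network a target thicker
than a single voxel shell.

## The 18 channels

The feature set names nine atomic properties but occupies 18 channels; the
only layout consistent with both facts is the one used by the established
grid featurizers this package follows: a 9-class element one-hot
(B, C, N, O, P, S, Se, halogen = {F, Cl, Br, I}, metal = fixed lookup
table), hybridization (1/2/3), heavy-neighbor count, heteroatom-neighbor
count, Gasteiger partial charge, and five binary pharmacophore flags
(hydrophobic, aromatic, acceptor, donor, ring). The channel order is
frozen and documented in `featurize_structure()`; saved tensors depend on
it.

Chemical perception is delegated to Open Babel: the structure is written
out, `obabel` adds explicit hydrogens, assigns TRIPOS atom types (which
carry hybridization and aromaticity) and Gasteiger charges, and perceives
bonds for PDB input. The five flags are then evaluated in R on the
perceived molecular graph: hydrophobic = carbon whose neighbors are all
carbon or hydrogen; aromatic = perceived aromatic atom type; acceptor =
oxygen, or nitrogen with no attached hydrogen that is neither an amide
nitrogen nor bonded to more than two heavy atoms; donor = N/O/S with at
least one attached hydrogen; ring = atom on any cycle of the bond graph
(an atom is on a cycle iff it is an endpoint of a non-bridge edge, which
`igraph::bridges()` gives directly). No R package exposes per-atom SMARTS
matching, so the flags are implemented as these graph rules; they were
frozen after cross-checking representative cases (amide N and O,
carboxylates, aromatic rings, aliphatic side chains) against an
independent SMARTS evaluation with a second toolkit, and the unit tests
keep those cases pinned. Hydrogens are never featurized — the
representation is heavy-atom only — but they count toward their heavy
neighbor's donor flag and the charge model. Non-finite charges (which
Gasteiger can produce on exotic inputs) are clamped to zero with a
warning.

## k-mer MACCS fingerprints and the sliding Tanimoto

The cleaning pipeline needs a structure-similarity measure that works on
sequences of very different lengths without alignment. A protein of N
residues yields N−2 overlapping 3-mers (frame 3, stride 1); each 3-mer is
embodied as a tripeptide molecule — neutral free termini, no
stereochemistry, since MACCS substructure keys are blind to chirality —
and fingerprinted with 167-bit MACCS keys (ChemmineOB / Open Babel; key k
lives at column k+1 of the matrix, column 1 being the conventionally
unused key 0). The fingerprint of the whole protein is the (N−2) × 167
bit matrix of its 3-mer keys.

Comparing two equal-length matrices pools each into one long row-aligned
bit vector and takes the Tanimoto (Jaccard) index of the on-bit sets. The
pooled reading is the simplest interpretation of "the Tanimoto index
between A1 and A2"; two all-zero vectors are identical objects and score
1 by convention. For unequal lengths, a window the length of the shorter
matrix slides along the longer at stride 1 and the maximum windowed index
is returned. The implementation is checked against an exhaustive
brute-force window enumeration on hundreds of random instances.

With ~8000 possible 3-mers, fingerprints are cached per 3-mer in a
package-level environment, so fingerprinting a 500-residue sequence costs
one batched backend call, not 498.

## Cleaning pipeline

`run_cleaning()` applies, in order: parse-failure removal (structures the
reader cannot load are recorded as `dropped_parse`, mirroring the upstream
exclusion of unloadable files), UniProt clustering (the accession mapping
is a required input — no live web queries), representative selection,
site-chain retention, and the 70 Å distance filter. Dispositions always
partition the input; per-structure failures never abort the batch.

Representative selection keeps the longest sequence per cluster — always
exactly one, with ties broken to the lexicographically smallest id for
determinism — and reports the cluster's mean pairwise sliding Tanimoto,
flagging clusters whose mean falls below the 0.8 similarity threshold
rather than keeping extra members. The original procedure resolved
ambiguous cases by manual visual inspection; the package automates that
step as `retain_site_chains()`: a chain survives iff it has a heavy atom
within 4 Å (a standard contact cutoff) of any site point, and a structure
with no contacting chain is flagged for review instead of silently
dropped. The distance filter is strict (`> 70` Å drops, exactly 70 keeps).

## The network

The architecture is a residual U-Net over the 36³ × 18 grid producing a
36³ × 1 sigmoid probability map, built from three block types whose layer
counts are fixed regardless of widths (every graph node — convolution,
normalization, activation, add, up-sampling, input — counts as one
layer):

- **convolution block**, 12 layers: a bottleneck main path
  (1³ conv → BN → ReLU → 3³ conv → BN → ReLU → 1³ conv → BN) plus a
  projection shortcut (1³ conv → BN), add, ReLU;
- **identity block**, 10 layers: the same main path with the unmodified
  input as shortcut;
- **up-sampling block**, 14 layers: the convolution block with
  nearest-neighbor upsampling on both paths; its shortcut input is the
  identity-processed skip from the encoder, so the skip merge is the
  block's own additive junction rather than an extra layer.

The assembled network has 5 convolution blocks, 13 identity blocks
(5 encoder, 4 skip-path, 4 decoder), 4 up-sampling blocks, a
conv–BN–ReLU stem and a 1³ sigmoid head — 252 layers in total. Encoder
resolutions run 36 → 18 → 9 → 5 → 3 via stride-2 convolutions (ceiling
division with 'same' padding); the decoder upsamples to the exact
matching encoder resolution by index mapping, which handles the odd sizes
(3 → 5 → 9) without cropping layers.

### The filter schedule

The published accounting for this architecture is 252 layers with
13,840,903 trainable and 16,992 non-trainable parameters; the per-block
filter widths themselves live in supplementary material that is not
redistributable here. The package therefore fixes its default schedule by
constrained integer search: within the block structure above, stage
widths, stem width and head kernel were solved so that the default build
reproduces the published totals exactly. The solution shipped as
`default_schedule()` is stem 56 and stage widths (38, 76, 92, 96, 342)
with unit bottleneck ratio and a 1³ head. The search found multiple
schedules consistent with the printed totals; this one was chosen for
monotone widths and a small stem. The block census, per-block layer
counts and the 252-layer total are structural and hold for *any*
schedule, which the tests assert separately from the parameter totals.
Non-trainable parameters are exactly the batch-norm running moments
(2 per channel), trainable parameters are convolution kernels + biases
and batch-norm scale/shift.

### Training

`train_scaled()` is a deterministic scaled-down training loop: Adam with
L2 kernel regularization applied as weight decay on convolution kernels,
dice loss by default (`1 − (2Σpm + 1)/(Σp + Σm + 1)`), binary
cross-entropy behind a flag. Dice is the right default here because
occupied site voxels are ~0.1% of the grid; BCE's per-voxel averaging is
dominated by the empty class. Defaults in `train_config()` mirror the
production optimization settings (learning rate 1e-4, L2 1e-4, batch
size 5, 4 folds); the fixture-scale smoke tests pass learning rate 0.01
and 200 steps, a configuration chosen by pilot run as the smallest budget
that reliably overfits one example. Batch normalization uses batch
statistics during training and running moments (momentum 0.9) at
inference; because an exponential average never catches up with the
weights over a short run, `train_scaled()` finishes by re-estimating the
batch-norm statistics with one training-mode pass over its training
inputs (the standard recalibration), so `predict()` agrees with the
network that was actually fitted. Weight initialization
is Glorot-uniform from the seeded R RNG; two runs with the same seed
produce bit-identical traces. Divergence (non-finite loss) raises a
structured error carrying the partial trace.

`grouped_kfold()` implements the leakage-aware split: all structures of
one protein family land in the same fold (greedy balancing, largest
groups first).

The engine itself — im2col 3D convolution with BLAS matrix products,
pointwise convolutions as plain GEMMs, C++ batch-norm, autograd over the
layer DAG — lives in the package because no deep-learning framework is
part of its dependency footprint. Gradients are verified against central
finite differences in the test suite.

### The ablation switch

`build_puresnet(skip_connections = FALSE)` removes every additive
shortcut (residual and skip-path alike; the add nodes become single-input
pass-throughs so the layer accounting stays aligned), leaving a plain
deep network. The package asserts only the qualitative claim the original
observation supports at this scale: on the same fixture and seed, the
default build reaches a strictly lower dice loss at step 200 than the
ablated build.

## Evaluation

Each structure contributes exactly one record. With no extracted pocket
the record is a false negative; otherwise the actual site is paired with
the pocket minimizing DCC (`policy = "min_dcc"`), and the pair is a true
positive iff DCC ≤ 4 Å, else a false positive. DVO (Jaccard overlap of
voxel sets on the common 36³ grid — never continuous volumes) and PLI
(fraction of ligand voxels inside the pocket) are computed for true
positives only. F1 = 2TP/(2TP+FP+FN); there are no true negatives since
every structure has a site. A `policy = "top_ranked"` flag scores only
the highest-confidence pocket instead; published per-fold success rates
are lower than their TP counts alone would imply, suggesting a stricter
per-site protocol, so both policies are exposed and neither is asserted
as canonical. Printed F1 values are compared at half-up rounding to two
decimals.

## Fixtures: what they show and what they cannot

The generators are pure functions of their seed. `make_toy_protein()`
builds helix-like chains from residue templates with real amino-acid
topology (correct elements, bond orders, aromatic rings), which is what
lets the Open Babel perception pipeline operate on sane chemistry; side
chains are geometrically idealized, not rotamer-sampled. The binding site
is a point cloud hugging a chosen residue of chain A, with a smaller
ligand cloud inside it; additional chains are placed far away so
chain-retention has an unambiguous ground truth. `make_cleaning_batch()`
constructs one case per disposition branch (a truncated file, a
same-accession near-duplicate pair differing by one terminal residue, a
site planted 80 Å out). `make_probability_grid()` lays Gaussian blobs
over sub-threshold uniform noise and records expected component
memberships from the construction.

Passing tests on these fixtures demonstrates that the machinery is
correct: featurization matches the documented chemistry, voxelization
matches brute-force assignment, cleaning reproduces constructed
dispositions, the network can represent and fit a site mask, and the
metrics match set arithmetic. They do not demonstrate predictive accuracy
on real proteins: toy helices lack real pocket geometry, the class
imbalance (~0.1% positive voxels) is milder here, and no claim about
success rates, DVO or PLI on benchmark datasets is made or testable
without the original training corpus and weights.

## Numerical choices and degenerate inputs

- Batch-norm epsilon 1e-3 (inside the square root), matching the common
  convention of the frameworks this engine mirrors.
- Dice smoothing constant 1; the loss of a perfect binary prediction is
  therefore not 0 but ≤ smooth/(2·|mask|), which the tests account for.
- Pocket extraction uses 26-connectivity and threshold 0.5 by default;
  both are configurable since neither is fixed by the method. Components
  are returned sorted by decreasing mean probability; `min_voxels` (default
  1) drops speckle components if asked.
- Two all-zero fingerprint vectors score Tanimoto 1 (identical objects).
- An empty pocket list is a legal result (the FN case); an all-zero grid
  is a legal voxelization result (empty box).
- Mol2 coordinates print at 4 decimals; round trips are exact to 3.
- Sequence extraction maps nonstandard residues to "X"; fingerprinting a
  sequence containing "X" raises an error naming the offending 3-mer, so
  unknown chemistry is never silently fingerprinted.

## Problem sizes used by the shipped experiments

Tests and the acceptance script run at fixture scale, chosen so the whole
suite exercises every code path on one CPU: toy proteins of 8–20
residues, the production 36³ grid, fingerprint property checks up to
N = 500, 200 random matrix pairs for the similarity oracle, 50 random
blob grids for component labeling, and two 200-step training runs
(overfit and ablation) on a reduced-width schedule (stem 4, stages
4-8-8-16-16). These sizes are the package's own reproducibility
choices; scaling the training loop up is a matter of budget, not code.

## Known limitations

- The chemistry backend is Open Babel; RDKit-grade aromaticity/charge
  models may differ in corner cases. The flag rules are deliberately
  protein-oriented; exotic hetero-chemistry may be misflagged.
- The default filter schedule is a reconstruction constrained by the
  published totals, not the original supplementary table; any schedule
  with the same totals is observationally equivalent at the accounting
  level, and per-layer width differences would only matter for weight
  transplantation, which the package does not support.
- `mol2` chain assignment relies on the SUBSTRUCTURE section; files
  without it are treated as single-chain.
- The training loop holds activations for one example at a time
  (batching is sequential accumulation), trading throughput for memory
  predictability on small machines.
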