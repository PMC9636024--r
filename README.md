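# vemtools

Desk-scale analysis tools for whole-brain volume electron microscopy
(vEM) connectomics, for researchers who run or evaluate dense neurite
reconstruction pipelines. The package implements the computational
stages that sit around the (out-of-scope) deep-learning models:

- **Acquisition planning** — the X-ray-mask-targeted tile mosaic:
  elongated tiles of fixed width *w* and length in `[y_min, y_max]`
  stacked across the brain mask, with one field-of-view positioning move
  per tile and coverage fraction against the mask's bounding box
  (`plan_tiles`, `plan_summary`).
- **Tissue-map post-processing** — the defocus detector (Gaussian σ = 1 →
  discrete Laplacian → 21×21 windowed s.d. → 128× area-averaged
  downsampling → threshold < 57 on 8-bit) and soma candidates (exclusion
  masking → 3D components → ball erosion r = 5 → components → volume
  > 1,000 voxels) (`defocus_mask`, `soma_candidates`).
- **Segmentation evaluation** — skeleton edge accuracy with the
  correct/split/merged/omitted taxonomy, adjacent-neurite point-pair
  merge screening, forward/reverse oversegmentation consensus
  (components of constant label pairs), segment post-processing, and
  top-k checkpoint-pair selection (`edge_accuracy`,
  `pair_separation_count`, `oversegmentation_consensus`,
  `select_checkpoint_pair`).
- **Proofreading backend** — an in-memory supervoxel agglomeration graph
  with an append-only JSONL edit log written before acknowledgement,
  strict deterministic replay, connected-component queries,
  nucleus-separation-constrained agglomeration, per-cell effort
  accounting and a stress-replay harness (`agglo_graph`, `replay`,
  `constrained_agglomerate`, `effort_report`, `replay_load_test`).
- **Synapse geometry and validation** — contact areas from smoothed
  iso-surface meshes (half-surface convention for thin contacts),
  per-section Feret profile lengths, sampled medians per region,
  vesicle-cloud volume fractions, and object-wise precision/recall
  (`contact_area`, `profile_lengths`, `objectwise_pr`).
- **Connectome assembly** — cleft → partner assignment by contact ranking
  with vesicle-based direction, directed edge lists with synapse counts,
  recurrency (cycle) checks and shared-partner fractions
  (`assign_partners`, `build_edges`, `recurrency_check`).
- **Skeleton morphometrics** — SWC I/O, path length, branch-point and
  synapse densities, region-wise branch-point profiles, consensus
  skeletons from redundant tracings, and fragment sampling at 750 nm
  (`path_length`, `densities`, `consensus_skeleton`,
  `sample_fragments`).
- **Registration** — block-wise least-squares affine transforms from
  landmark correspondences (default 42 × 28 × 2-unit blocks with a
  one-block surround and global-affine fallback) (`fit_blockwise_affine`,
  `apply_blockwise`).
- **Synthetic phantoms** — tubes, somata with nuclei, cleft slabs,
  vesicle clouds, planted split/merge errors and sharp/defocused texture
  stacks, all seeded and bit-reproducible, so the entire pipeline is
  testable with no acquisition data (`make_phantom`,
  `make_oversegmentation`, `make_focus_stack`).

## Worked example

Generate a phantom, plant one merger and random splits, evaluate the
candidate segmentation, and assemble the connectome:

```r
library(vemtools)

spec <- phantom_spec(shape = c(256, 96, 48), n_neurites = 6,
                     n_synapses = 5, seed = 11)
ph <- make_phantom(spec)

ov <- make_oversegmentation(ph$truth, error_spec(split_rate = 0.5, seed = 2),
                            ph$adjacent_pairs, merge_pairs = 1L)
acc <- edge_accuracy(ph$skeletons, ov$supervoxels)
acc$accuracy
#> [1] 0.9852744
acc$counts
#> correct   split  merged omitted
#>    1472       6      16       0

pp <- phantom_point_pairs(ph)
pair_separation_count(ov$supervoxels, pp)[c("n_separated", "n_merged")]
#> $n_separated
#> [1] 4
#> $n_merged
#> [1] 1

asg <- assign_partners(ph$cleft_labels, ph$vesicle_labels, ph$truth,
                       dilation_nm = 60)
build_edges(asg)$edges
#>   pre post count clefts
#> 1   1    2     1      1
#> 2   3    2     1      2
#> 3   3    4     1      3
#> 4   4    5     1      4
#> 5   6    5     1      5
```

Of the 1,494 ground-truth skeleton edges, the 6 split edges are the ones
crossing the planted cut planes and the 16 merged edges are the ones
whose segment absorbed the planted merger; the one merged point pair is
exactly the pair whose tubes share a supervoxel. The recovered edge list
equals the generator's cleft-to-partner map, direction included, because
each cleft's presynaptic tube carries the vesicle cloud.

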