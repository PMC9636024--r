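---
title: "Methods: desk-scale volume-EM connectomics with vemtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale volume-EM connectomics with vemtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vemtools)
```

vemtools implements the desk-scale computational stages of a whole-brain
volume electron microscopy (vEM) connectomics workflow: planning an
X-ray-targeted tile mosaic, post-processing tissue-classifier maps,
evaluating and combining candidate neurite segmentations against skeleton
ground truth, proofreading an agglomeration graph through an append-only
edit log, measuring synaptic contact geometry, validating a synapse
detector, assembling a connectome, computing skeleton morphometrics, and
registering image stacks block-wise from landmarks. Every stage is
exercised on synthetic phantom volumes generated in code, so the package
is fully testable without any acquisition data.

This vignette explains the models and conventions behind each module, the
parameters that matter, and what the phantom does and does not emulate.

## Conventions

All raster data travel as a `vem_volume`: a 3D array with a physical
voxel size in nm and a voxel offset in a global frame. Coordinates are
0-based voxel indices in axis order (x, y, z) with half-open extents; the
physical position of a voxel is `(offset + index) * voxel_size` nm. The
reference grid is anisotropic, 14 x 14 x 25 nm, with coarser 56 x 56 x
100 nm grids for classifier outputs. Label volumes reserve 0 for
background. Connected components default to 26-connectivity in 3D and
8-connectivity in 2D; because the choice is a genuine degree of freedom,
every public operation takes it explicitly. Component labels are assigned
in raster-scan order of each component's first voxel, which makes every
labeling operation deterministic.

Volumes are stored in a minimal zarr-style directory container (a JSON
metadata file plus raw little-endian binary), with bit-exact round trips
for data, voxel size and offset.

## The phantom generator

`make_phantom()` builds the structures the pipeline assumes: neurite
tubes (radius range defaulting to 50–150 nm, covering the thinnest
neurites the imaging resolves), somata each containing exactly one
nucleus strictly inside, synaptic cleft slabs 1–2 voxels thick (25–50 nm,
the scale of a postsynaptic density) planted in the gap between adjacent
tubes, and a vesicle cloud inside the designated presynaptic tube next to
each cleft. Tubes run along x in rows; tubes within a row share one
smooth random jitter path, which keeps the inter-tube surface gap exactly
equal to the cleft thickness everywhere — that constancy is what
guarantees, by construction, that every cleft touches exactly its two
partner cells. Synapse sites within a row are separated along x by more
than a vesicle-cloud diameter, so one synapse's vesicles can never fall
into a neighboring cleft's partner-assignment neighborhood. Identical
seeds give bit-identical phantoms.

`make_oversegmentation()` plants controlled errors into the truth
labeling: a *split* cuts an object at a random plane; a *merger* creates
a supervoxel spanning two adjacent objects around their contact position.
Both can be driven by rates or planted deterministically, and every
planted error is returned for bookkeeping, which is what makes exact
expectations ("50 pairs minus m mergers") possible downstream.

`make_focus_stack()` emulates contrast-normalized EM planes as binary
band-pass granular noise (full 0/255 range, granule spectrum at membrane
scale, obtained by thresholding the difference of two Gaussian-smoothed
noise fields with sigmas of 1 and 2 px). The defocus detector's published
threshold presumes high-contrast texture of roughly this scale; on this
texture the sharp and defocused classes sit at local-contrast values of
about 62 and 0.1 against the threshold of 57, so classification is
stable. What the phantom does **not** emulate: real membrane topology,
staining gradients, section artifacts, or realistic EM noise spectra —
tests passing on phantoms demonstrate the correctness of the
*computations*, not detector performance on real tissue.

## Tile planning

`plan_tiles()` reproduces the arithmetic of mask-targeted acquisition:
per section, columns of the fixed scan width step across the mask's x
extent (anchored at the whole-stack mask bounding box left edge — the
anchoring is unstated in the underlying workflow, so it is fixed here for
determinism); within a column, each disjoint y-interval of mask occupancy
gets its own run of tiles with lengths in `[y_min, y_max]` and a
configured overlap — covering each interval separately rather than
spanning gaps minimizes scanned area, which is the stated point of
targeted tiling. One positioning move is counted per tile, and moves
between sections are not counted separately. For a full-rectangle mask
the tile count reduces to the closed form
`ceil(W/w) * ceil((H - overlap)/(y_max - overlap))`.

Because the published coverage figure ("58% of the cuboid bounding box")
can be read against either the whole-stack cuboid or per-section bounding
boxes, `plan_summary()` reports both variants, counting only scanned
pixels inside the respective box so the fraction is bounded by 1 even
when tiles overhang the mask.

## Tissue-map post-processing

The defocus detector is the literal filter chain: Gaussian (sigma 1),
discrete 5-point Laplacian, per-pixel population standard deviation over
a centered 21 x 21 window (edge-truncated), 128x in-plane area-averaged
downsampling, and a strict `< 57` threshold on the 8-bit scale. Border
handling uses replicated edges for the convolutions and shrinking windows
for the standard deviation; the Laplacian makes the statistic invariant
to intensity offsets. CLAHE parameters are not part of the published
chain, so the operation accepts pre-normalized input; an optional
built-in CLAHE (8-bit, 64 x 64 tiles, clip limit 2.0, via EBImage) is
recorded in configuration when used.

Soma candidates follow the published recipe exactly: binarize the nucleus
prediction, zero any voxel predicted as an excluded class, 3D connected
components, morphological erosion with a digitized ball of radius 5
(radius in voxels, isotropic in index space, since the recipe states no
units; an nm-metric ball is available), recompute components, and retain
objects with **strictly more than** 1,000 voxels at the prediction grid.
The published exclusion list includes the class "soma", which taken
literally would erase nuclei inside somata; the list is therefore
configuration, defaulting to the literal text.

## Segmentation evaluation and consensus

`edge_accuracy()` classifies each ground-truth skeleton edge as omitted
(an endpoint on background), split (endpoints in different segments),
merged (the shared segment also holds nodes of another skeleton), or
correct. The merged definition uses a node-level witness by default; a
stricter variant requiring the witness in the same spatial connected
component is available. Accuracy pools edges; per-skeleton means are also
reported because the weighting is a genuine open choice.

`oversegmentation_consensus()` marks a voxel foreground iff both inputs
do, and its segments are connected components of constant label pairs —
a refinement of both inputs, verified against an independent graph-based
oracle in the tests. `pair_separation_count()` is the merge-screening
statistic: the number of annotated adjacent-neurite point pairs carrying
two distinct nonzero ids; pairs touching background are reported
separately as uninformative rather than counted as merged.
`select_checkpoint_pair()` screens the top-k candidates by edge accuracy
(k defaults to 7) and returns the pair whose consensus separates the most
point pairs, ties broken lexicographically.

`postprocess_segments()` applies two cleanups to a fixpoint: interior
background (not 6-connected to the volume border) surrounded by a single
label is filled, and a segment whose entire outside neighborhood is one
other segment — with no background path to the border — is absorbed. Both
operations are defined here explicitly because the underlying workflow
names them without definitions; the operation is idempotent.

## The proofreading backend

The agglomeration graph lives in memory; every edit (edge addition or
removal) is appended to an on-disk JSONL log with a strictly increasing
sequence number *before* it is acknowledged, and `replay()` rebuilds the
live state from the base proposal agglomeration plus the log. Replay is
strict: an out-of-order or inapplicable record halts replay loudly with
the offending sequence number, so divergence cannot pass silently.
Removing a base edge and removing a user-added edge are logged
identically. Crash consistency follows from the write-ahead ordering:
truncating the log after any prefix reproduces exactly the state after
that many edits (the test suite verifies all 1,000 prefixes of each
random session). `replay_load_test()` replays a log through the
serialized single-writer path with emulated parallel submitters and
reports 1st/50th/99th percentile latencies per operation; it is
reporting-only, since absolute times are hardware-bound.

`constrained_agglomerate()` accepts scored candidate edges in descending
score order (ties by id pair) unless acceptance would put two distinct
detected nuclei into one component — the mechanism that keeps somata
separate during automatic agglomeration. `effort_report()` counts, per
final cell, removals (merge fixes) and additions (split fixes) touching
it, the proofreading effort bookkeeping.

## Synaptic contact geometry

Contact surfaces are meshed by marching tetrahedra on the binary mask
(iso 0.5, padded so surfaces close), vertices welded, then smoothed with
20 iterations of Taubin's lambda/mu filter (0.5 / -0.53), which removes
the voxel staircase without the shrinkage of plain Laplacian smoothing.
The iteration count was fixed by validating against analytic areas: a
digitized sphere of radius 10 voxels lands within ~5% of its true
surface, and thin slabs retain their face area. The reported contact
area is **half** the closed-mesh area, because a synaptic contact
annotation is a thin slab whose mesh has two faces; the convention's
accuracy degrades for compact objects where side walls contribute
(for a 10 x 10 x 1-voxel slab at 14 x 14 x 25 nm the side walls add
roughly a sixth), so the full mesh area is always reported alongside.

Per-section profile lengths slice the object along a cardinal axis and
measure the Feret (maximum caliper) diameter of the largest in-plane
component, end-capped by the pixel footprint along the maximizing
direction so that axis-aligned runs measure `count * pitch` exactly; a
single-voxel slice reports the larger in-plane pitch. Because the
published contact lengths could pool sections over any slicing axis, the
function takes the axis explicitly and reports make the pooling choice
visible. `contact_sample_report()` reproduces the sampled-median
protocol (100 objects per region by default) with seeded sampling.

Object-wise precision/recall uses greedy one-to-one matching by
descending overlap voxel count, any overlap counting, ties by smaller id
pair — the criterion itself is unstated in the source workflow, so the
simplest deterministic rule is used and cross-checked against exhaustive
optimal matching on small detector-like instances.

## Connectome assembly

`assign_partners()` ranks the cells within a physical dilation radius of
each cleft (default 100 nm, about cleft plus membrane thickness) by
contact voxel count; the top two are the partners, and the presynaptic
side is the partner with more vesicle-cloud overlap in the same
neighborhood — the automatic counterpart of the manual "vesicle cloud in
the axon" criterion. Ambiguity is surfaced, never resolved silently: no
or tied vesicle evidence leaves the direction null and flagged, and
clefts touching fewer than two cells are flagged unpaired, so synapse
counts are conserved across edges, undirected and unpaired lists.
`recurrency_check()` enumerates elementary cycles canonically
(smallest-cell-first DFS) and reports bidirectional pairs;
`shared_partner_fraction()` is plain set arithmetic with a Jaccard
variant alongside.

## Skeletons and morphometrics

Skeletons are node/edge forests with nm positions, SWC files as the
interchange format (compartment via the SWC structure type). Path length
is the Euclidean edge-length sum restricted to a compartment; branch
points are nodes of degree >= 3 unless explicit annotations exist, which
win. Densities are counts per micrometer of the relevant compartment
length, flagged undefined when that length is zero. Region-wise
branch-point profiles count only branch points (not all nodes, to avoid
counting mere pass-throughs) and normalize per cell.

`consensus_skeleton()` retains a node when at least `quorum - 1` other
tracings place a node within the tolerance, merges retained nodes by
single-linkage clustering at that tolerance (cluster mean as position),
and induces edges from the supporting tracings. The reference procedure's
exact parameters are not restated in the source workflow, so tolerance
defaults to 1 um and quorum to a majority, both configurable; tolerance 0
on jittered tracings legitimately yields an empty consensus and is
documented as the degenerate case. `sample_fragments()` draws locations
uniformly along a compartment's path length (200 per compartment, 750 nm
radius by default, seeded); diameter measurement itself was a manual step
in the source workflow, so fragments are extracted for external
measurement rather than measured here.

## Registration

`fit_blockwise_affine()` fits, per block of a configurable grid (42 x
28 x 2 units by default, in the working resolution of the landmarks),
the least-squares affine to all landmark pairs whose source lies in the
block's surround (the block dilated by one block size per axis, the
"surround" being otherwise unspecified). Blocks with fewer than four
usable, non-degenerate points fall back to the global affine and are
flagged — the field stays defined everywhere. Application is
piecewise-constant per block with no blending, matching per-block
calculation and application; points outside the grid use the nearest
block and are flagged. Any single global affine is recovered exactly
regardless of the partition, which is the invariant the tests pin down.

## Numerical choices and problem sizes

Degeneracy of point configurations is detected by the smallest singular
value of the centered source matrix (relative tolerance 1e-9). Window
statistics use the population variance formula. Erosion treats voxels
outside the array as background. Tie-breaks are always by smallest id or
lexicographic order, never arbitrary. The test suite runs the
proofreading service at 10,000 supervoxels with 1,000-edit sessions (20
sessions), segmentation evaluation phantoms near 100 x 200 x 100 voxels
with ~50 neurites, and consensus oracles at 32^3 — sizes chosen so the
full suite completes in a few minutes on one core while still exercising
non-trivial component structure.

## Known limitations

The package deliberately excludes everything upstream of its inputs:
CNN/FFN training and inference, tile stitching, diffeomorphic atlas
registration, and microscope control. Phantom tubes are geometrically
simple (no branching within a tube, no realistic tortuosity), so
morphometric tests on phantoms validate bookkeeping rather than biology.
The half-surface contact-area convention is exact only in the thin-slab
limit. Latency percentiles from the stress harness characterize this
R implementation, not the original backend's C++-scale performance.
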