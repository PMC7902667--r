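---
title: "slidekit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{slidekit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slidekit)
```

slidekit is a headless toolkit for the bookkeeping side of expert image
annotation on large microscopy images: who drew which geometry where, under
which label schema, seen and verified by whom, frozen in which version.
Everything a collaborative annotation server would track is available here
as scriptable R functions over tibbles, so annotation campaigns can be
simulated, audited and exported without any service running. This vignette
explains the models and conventions behind each component, the parameters
that matter, and where we made design calls that the problem itself left
open.

## The data model

A project (`slide_project()`) holds tibble registries of images, image
sets, annotation templates, products, users, annotations and verification
records. An annotation is one labelled geometry on one image: a template
reference, an ordered coordinate vector, creator and last editor with
timestamps, a free-form metadata list, and a soft-delete flag. Five
geometry kinds are supported — box, polygon, line, circle and *global*
(a whole-image classification with no geometry) — with per-kind arity
rules: boxes are exactly two corners, polygons at least three vertices,
lines at least two, circles a centre plus a point on the rim.

Conventions worth stating because nothing downstream works without them:

* **Coordinates** are 0-based pixels, origin at the top-left; boxes are
  half-open, `[x1, x2) x [y1, y2)`. Half-open boxes make tiling arithmetic
  exact: a box may end at `x2 == width` and adjacent tiles share no pixel.
* **Out-of-bounds coordinates are an error**, never silently clamped.
  Silent clamping would hide upstream bugs in click handling or imports.
  The one deliberate exception is `single_click_annotation()`, whose
  *documented job* includes clipping the default-size box at image borders.
* **Inverted box corners are normalised** (elementwise min/max) rather than
  rejected, matching how interactive drawing produces them.
* **Circles are stored as centre + rim point**, not as a bounding box. This
  is a dialect decision — either encoding carries the same information —
  chosen so that the vector is a plain point list like every other kind.
* **Timestamps are ISO-8601 UTC strings with millisecond precision.**
  Strings, not date-time objects, so exports are byte-stable and ordering
  is lexicographic. An edit always advances `edited_at`, even when the
  clock reports the creation instant (the bump is +1 ms).
* **Deletion is a flag.** Physical removal would orphan verification
  records and silently rewrite history under version snapshots.

The coordinate vector serialises to a flat JSON mapping
`{"x1":…, "y1":…, "x2":…}` with 1-based point indices (list-of-pairs input
is also accepted). The flat form keeps individual coordinates addressable
by key in stores that can index into JSON documents.

Templates carry a default size, which is what makes single-click
annotation possible: a click places a centred box (or circle) of the
structure's typical extent, encoding the annotator's prior knowledge. In
the cytology use case that motivates the synthetic generator, cell classes
differ in size by a factor of two or more, so per-class defaults genuinely
save a drawn rectangle per cell.

## Pseudonymised image names

Filenames of clinical material leak information (patient names, case
numbers, dates). At registration every image therefore gets a public name
`yymmdd-hhmm-####`: the registration date-time plus a four-digit decimal
hash of the original name. The digest is FNV-1a (32-bit) over the UTF-8
bytes, reduced mod 10000 — any stable digest would satisfy the contract;
FNV-1a is trivial to implement exactly and has no process-randomised
variant to guard against. Four digits cannot be injective, so collisions
across different names are tolerated; *within* one image set, uniqueness is
restored by appending a counter (`-2`, `-3`, …) and flagging the collision
in the image's metadata. Exports emit only public names; the private name
never leaves the project store except through `save_project()`, which is
the project's own persistence, not an exchange format.

Implementation note: R has no unsigned 32-bit integers, and
`hash * 16777619` overflows the 53-bit double mantissa, so the multiply is
split at 16 bits and reduced mod 2^32 — exact integer arithmetic in
doubles.

## Guided screening grids

A screening map divides an image into patches of exactly
`patch_width x patch_height` pixels with a relative overlap (default 15%,
exposed as a parameter since nothing forces a fixed value). Per axis the
stride is `patch - round(overlap * patch)`; start offsets run
`0, stride, 2*stride, …`, and the final start is replaced by
`image_dim - patch`. This is the only scheme that satisfies both
requirements at once — every patch the same size, every pixel covered —
at the cost of a larger overlap for the last pair of rows/columns. For a
1000 px axis with 300 px patches at 15%, the starts are
`0, 255, 510, 700`: interior neighbours overlap by exactly 45 px, the edge
pair by 110 px. With zero overlap and an image that is an exact multiple of
the patch size, the grid degenerates to a perfect non-overlapping tiling.

The map stores a visited flag per patch and the current position; both
survive JSON serialisation, which is what makes screening resumable across
sessions. `next_unvisited()` walks the grid in serpentine order (odd rows
left-to-right, even rows right-to-left) so consecutive patches stay
adjacent on the slide — the traversal order is a convenience choice, not a
contract. The "zoom level" a viewer would offer maps to the patch size in
pixels here; converting viewer zoom to pixels is a presentation concern and
is out of scope.

## Version snapshots

A snapshot freezes an image set's state under a tag: the image list, full
copies of all non-deleted annotations, and their verification records
(included so that a frozen data set carries its quality evidence; the
alternative — verification history living outside versions — would make a
"verified data set" unreproducible). Snapshots store copies, not deltas:
the semantics wanted is state capture for reproducible training sets, and
at the scale of annotation records copies are cheap.

A snapshot is immutable with exactly two qualifications:

1. **Artifact attachment.** Training outputs (metrics, exported files,
   model identifiers) append to the version without touching frozen state.
2. **Image deletion.** Slides of many gigabytes are not versioned, so an
   image's removal necessarily removes its annotations from every
   version's output. We implement this as *filtering by surviving image
   ids* at read time rather than destructively editing snapshots — the
   frozen rows still exist, so restoring the image restores the history.

User removal deliberately does *not* touch annotations: a departing user
is deactivated and their display name replaced by an opaque token, while
creator/editor identifiers on annotations stay intact. Versioned
annotations are therefore never affected by personnel changes.

`virtual_split()` partitions a version's image list into train/val/test.
Sizes follow largest-remainder (Hamilton) apportionment of the requested
fractions — deterministic, fraction-faithful, no stochastic rounding — and
membership is a seeded permutation. Exports (`export_version()`) sort by
image id then annotation id and use the fixed timestamp format, so a given
snapshot always exports identical bytes.

## Validation maps

Validation maps are generated images that pack annotation crops for rapid
visual review, each with a tile index mapping canvas coordinates back to
source annotations.

**The crop.** The problem statement never defines what "the annotation's
image" is, so we fixed it: the annotation's bounding box, expanded to a
square about its centre, padded by 10% per side, clamped to the image, and
resampled to the tile size with bilinear interpolation (via EBImage).
Square-plus-pad keeps cells visually comparable regardless of their
aspect ratio; clamping can make edge crops non-square, which the resize
absorbs.

**Annotation maps** pack all crops of one label row-major,
`tiles_per_row` per row, in a stable order (source image id, then
annotation id). Zero gutters between tiles — a gutter would only spend
canvas on nothing; `map_to_source()` already distinguishes "between tiles"
from "on a tile" in the partial last row.

**Cluster maps** place crops near their two-dimensional feature embedding
without overlaps. The contract is: scale the embedding affinely onto the
grid of `floor(W/tile) x floor(H/tile)` cells, then assign each patch, in
insertion order, to the nearest free cell (Euclidean distance between cell
centres, ties broken by row-major cell index). Greedy nearest-free-cell is
the simplest fully deterministic rule that satisfies both "nearest" and
"does not overlay"; it is not globally optimal, but the tests verify it
dominates random assignment by a wide margin, and determinism is worth
more here than optimality.

**Density maps** visualise a continuous grade in `[0, 4]` — the
hemosiderin content of alveolar macrophages in lung cytology, where each
cell receives a score between 0 (no iron) and 4 (saturated). Cells are
binned along the x-axis into `n_bins` equal intervals (default 41, a 0.1
grade step; the last bin is right-closed so a score of exactly 4.0 lands
in it) and stacked bottom-up in score order along the y-axis. Column
heights are then a histogram of the score distribution, and a reviewer can
concentrate on the cells sitting at grade borders. Tile size is fixed
rather than scaled with count — column height already encodes quantity,
and mixed tile sizes would break the back-mapping's uniformity.

**Corrections.** Edits made on a validation map are restricted to
relabel / delete / confirm; geometry editing belongs on the source image,
where the full context is visible. `apply_map_correction()` routes the
change to the *source* annotation (template swap, soft delete, or a
confirmed verification record) and marks the tile stale so callers know
the rendered canvas is out of date. The back-mapping itself is the exact
affine inverse of the crop-and-resize, so a point on tile pixels maps to
source-image pixels with no accumulated error.

## Feature embeddings

`reduce_features()` turns per-annotation feature vectors into 2-D
coordinates. Three methods, chosen by how much machinery they need:

* `pca` — closed-form projection onto the first two principal components
  (`stats::prcomp`); deterministic, parameter-free, the default for tests.
* `tsne` — an exact, non-approximated t-SNE implemented in the package
  (per-point precisions tuned by bisection to the target perplexity,
  default `min(30, (n-1)/3)`; 500 gradient-descent iterations with
  momentum 0.5→0.8 and 12x early exaggeration for the first 100). The
  quadratic cost is fine at validation-map scale (hundreds to a few
  thousand patches). The only randomness is the seeded initialisation, so
  a fixed seed reproduces coordinates bit-for-bit.
* `umap` — delegated to the Python `umap-learn` library through an
  on-disk bridge (`system2("python")`, `random_state = seed`); available
  when such a Python is on the PATH and absent otherwise with a clear
  error. Nothing else in the package depends on it.

Degenerate input (all feature vectors identical) returns all-zero
coordinates for every method rather than failing: a cluster map of
identical patches is still a valid, reviewable object.

The bundled extractor (`generate_feature_table()`) is deliberately simple
— mean RGB, 4-bin per-channel intensity histograms, log box area; 16
numbers — because feature extraction is an input to this package, not its
subject. Real pipelines substitute learned features behind the same
interface.

## Crowd-annotation policies

Three modes govern visibility and completion, configured per image set:

| mode | sees | image complete when |
|---|---|---|
| cooperative | everything | any one user has verified the image |
| competitive (blind) | own annotations only | every enrolled user has verified the image |
| second opinion | everything | every annotation has ≥ k confirmed verdicts from distinct users |

Completion is tracked at the level each mode's definition names: image
level for cooperative/competitive, annotation level for second opinion.
Rejected verdicts never count toward the k confirmations, and a later
verdict by the same user replaces the earlier one, so a single user can
never satisfy a two-user requirement by repetition. Whether second-opinion
mode should *also* hide other users' annotations is genuinely open; we
default to visible (hiding is what defines competitive mode) and the
policy functions take the mode explicitly, so a caller wanting blind
second opinions composes `visible_annotations(..., competitive)` with
`image_complete(..., second_opinion)`. Completion is monotone by
construction: verifications only accumulate evidence.

## The synthetic slide generator

`generate_slide()` produces the study conditions every test runs under:
cytology-like images with known ground truth. Cells are filled ellipses
with Gaussian-perturbed radii (15% coefficient of variation), placed by
rejection sampling with pairwise separation so blobs never merge; each
carries a class, a class-coloured fill with slight per-cell jitter, and a
continuous grade drawn from `4 * Beta(2, 2)` — a symmetric, mid-heavy
score distribution over `[0, 4]`. The five default classes mirror the
differential-count setting (eosinophils, mast cells, neutrophils,
macrophages, lymphocytes) with distinct colours and mean radii from 8 to
18 px, so class is recoverable from colour features alone — which is
exactly what the cluster-map tests assert. One seed fixes every draw, and
pixel values are quantised to the 8-bit grid so a PNG round trip is
lossless and "identical bytes for a fixed seed" is a meaningful contract.

What the generator does *not* emulate: staining variability, focus and
illumination gradients, overlapping or clumped cells, tissue background,
and scanner formats. Passing tests therefore demonstrate the correctness
of the *bookkeeping and geometry* — grids, crops, back-mappings, versions,
policies — not robustness of any image analysis on real slides.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in well under a minute of compute per component:
synthetic slides of 640–1024 px with 25–200 cells, 1,000-cell score sets
for density maps, 10,000-name fuzz corpora for pseudonyms, 100-edit
random sequences against snapshots, and exhaustive 4,096-subset
enumeration for the crowd-mode truth tables. Multi-gigapixel inputs would
exercise the same code paths through the region-reader contract
(`read_region(x, y, w, h)`), which is how a pyramidal backend would plug
in; only plain PNG/TIFF readers ship here.

Small decisions that would otherwise be invisible: overlap pixels are
`round(overlap * patch)`; cluster-map ties break by row-major cell index;
density bins are left-closed except the last; box normalisation happens at
creation, not at export; id counters advance past imported ids so imports
and new records cannot collide; `resume()` returns exactly the stored
index with no recomputation.

## Limitations

* No concurrency: the project store is a single in-memory environment;
  multi-user write coordination is a server concern, out of scope.
* No proprietary scanner formats (.svs, .ndpi, …) — the region-reader
  contract is where such a backend would attach.
* Cluster-map placement is greedy, not an optimal assignment; with nearly
  full canvases late patches can land far from their embedding position.
* The UMAP path requires an external Python with `umap-learn`; pca and
  tsne are native and always available.
* Version storage is full-copy per snapshot; projects with very many
  large snapshots would want delta storage, which we deliberately did not
  build.
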