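# slidekit

Headless annotation management for whole-slide and large microscopy
images: the full bookkeeping layer of a collaborative annotation
platform — data model, privacy, screening, version control, validation
imagery, crowd policies — as plain R functions over tibbles, with no
server, database or browser anywhere.

It is written for two audiences. Annotation-study organisers (pathology,
cytology, and any field that labels large images) get reproducible
campaign mechanics: standardised label schemas, pseudonymised image names,
resumable guided screening, and versioned exports. Machine-learning
practitioners get the other half: version-pinned training data,
train/val/test splits frozen to a snapshot, artifact tracking per version,
and generated validation images to audit label quality at a glance.

## What it implements

* **Annotation data model** — templates (label, geometry kind, colour,
  default size, shortcut) grouped into products; annotations as ordered
  coordinate vectors in 0-based pixel coordinates with half-open boxes
  `[x1, x2) × [y1, y2)`; creator/editor audit fields; soft deletion;
  single-click annotation from template default sizes; JSON import/export.
* **Privacy** — public image names `yymmdd-hhmm-####` (registration
  date-time + 4-digit FNV-1a hash of the filename, mod 10⁴); private
  filenames never appear in any export.
* **Guided screening** — a persistent grid of equal-sized patches with
  relative overlap ω (default 0.15): per-axis stride
  `s = p − round(ω·p)`, last patch shifted inward to `D − p`, so every
  patch is exactly `p` pixels and every pixel is covered. Visited flags,
  progress, and a resumable position that survives serialisation.
* **Version control** — snapshots freeze an image set's image list,
  annotations and verifications under a tag; exports are byte-stable;
  training artifacts attach to versions; virtual train/val/test splits
  use largest-remainder apportionment with a seeded shuffle. Deleting an
  image removes its annotations from every version; nothing else can.
* **Validation maps** — per-label *annotation maps* (row-major crop
  matrices), *cluster maps* (crops placed greedily on the nearest free
  grid cell to their scaled 2-D embedding; PCA / exact t-SNE / optional
  UMAP via Python), and *density maps* (cells binned by a continuous
  grade over [0, 4] on the x-axis, default 41 bins, stacked in score
  order on the y-axis). Every tile carries an exact affine back-mapping;
  relabel/delete/confirm corrections land on the source annotations.
* **Crowd modes** — cooperative, competitive (blind) and second-opinion
  visibility and completion policies.
* **Synthetic fixtures** — a deterministic generator of cytology-like
  slides (five cell classes with distinct sizes and colours, continuous
  grades from `4·Beta(2,2)`) with ground truth, so the entire pipeline is
  testable offline.

## Worked example

```r
library(slidekit)

# A synthetic slide with 80 cells of 5 classes, as a ready-made project
prj <- synthetic_project(synthetic_slide_spec(width = 768, height = 768,
                                              n_cells = 80, seed = 42))
prj
#> <slide_project 'synthetic'>
#>   images: 1 in 1 set(s); templates: 5 in 1 product(s)
#>   annotations: 80 live, 0 deleted; verifications: 0; versions: 0

# Guided screening at 300 px patches, 15% overlap
create_screening_map(prj, images(prj)$image_id[1], 300, 300, user = "reviewer")
#> <screening_map img_0001 by reviewer: 3x3 patches of 300x300 px, overlap 15%, progress 0.0%>

# Features -> 2-D embedding -> cluster map (similar cells end up adjacent)
emb <- reduce_features(generate_feature_table(prj), method = "pca")
cm  <- build_cluster_map(prj, emb, tile_size = 48,
                         canvas_width = 768, canvas_height = 768)
cm
#> <validation_map kind=cluster: 80 tiles of 48x48 px on 768x768 canvas>

# Any point on the generated image maps back to its source annotation
map_to_source(cm, tidy(cm)$px[1] + 24, tidy(cm)$py[1] + 24)
#> $annotation_id      [1] "ann_0001"
#> $source_image_id    [1] "img_0001"
#> $x                  [1] 74.5
#> $y                  [1] 704

# Density map of the hemosiderin-style grades: column heights = histogram
dm <- build_density_map(prj, tile_size = 24, n_bins = 41, render = FALSE)
head(density_columns(dm)[density_columns(dm)$count > 0, ], 4)
#> # A tibble: 4 × 4
#>     bin score_lo score_hi count
#>   <int>    <dbl>    <dbl> <int>
#> 1     3    0.195    0.293     1
#> 2     6    0.488    0.585     2
#> 3     7    0.585    0.683     1
#> 4     8    0.683    0.780     3

# Freeze the state; splits and exports are pinned to the snapshot
snapshot(prj, image_sets(prj)$set_id[1], "v1", "ground truth as generated")
virtual_split(prj, "v1", c(0.6, 0.2, 0.2), seed = 1)
export_version(prj, "v1", format = "json", path = "v1.json")
```

The three map kinds read naturally: an annotation map of one label should
look homogeneous (outliers are labelling errors), a cluster map groups
look-alike cells spatially, and a density map's silhouette is the score
histogram with each column stacked in score order. `write_validation_map()`
writes the canvas as PNG/TIFF plus a sidecar JSON tile index;
`autoplot()` methods show layouts, embeddings and screening progress as
ggplots; `tidy()`/`glance()` return the underlying tables.

A thin command-line wrapper ships at `inst/cli/slidekit`
(`fixture`, `screen`, `snapshot`, `export`, `split`, `map`, `pseudonym`).

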