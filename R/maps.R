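# Validation maps: generated images that pack annotation crops for rapid
# visual review — per-label matrices (annotation maps), embedding-driven
# layouts (cluster maps), and score-ordered stacks (density maps). Every
# placed tile keeps the back-mapping to its source annotation, so a
# correction made on the generated image lands on the original data.

# Crop rectangle for one annotation: bounding box, expanded to a square
# about its centre, padded 10% per side, clamped to the image. Square + pad
# keeps cells visually comparable across sizes; clamping can trim edge cells.
annotation_crop_rect <- function(m, kind, width, height, pad = 0.1) {
  if (nrow(m) == 0L) abort("annotation has no geometry to crop (global label)")
  bb <- bbox_of(m, kind)
  cx <- (bb[["x1"]] + bb[["x2"]]) / 2
  cy <- (bb[["y1"]] + bb[["y2"]]) / 2
  side <- max(bb[["x2"]] - bb[["x1"]], bb[["y2"]] - bb[["y1"]], 2) * (1 + 2 * pad)
  x1 <- max(0, floor(cx - side / 2)); y1 <- max(0, floor(cy - side / 2))
  x2 <- min(width, ceiling(cx + side / 2)); y2 <- min(height, ceiling(cy + side / 2))
  c(x = x1, y = y1, w = x2 - x1, h = y2 - y1)
}

# Bilinear resample of a crop to the tile size.
resize_bilinear <- function(pix, w, h) {
  img <- EBImage::Image(aperm(pix, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(img, w = w, h = h, filter = "bilinear")
  pmin(pmax(aperm(EBImage::imageData(out), c(2, 1, 3)), 0), 1)
}

new_validation_map <- function(kind, label, canvas_w, canvas_h, tw, th, tiles, image) {
  structure(list(map_kind = kind, label = label,
                 canvas_width = canvas_w, canvas_height = canvas_h,
                 tile_width = tw, tile_height = th,
                 tiles = tiles, image = image),
            class = "validation_map")
}

empty_tiles <- function() {
  tibble(annotation_id = character(), source_image_id = character(),
         sx = double(), sy = double(), sw = double(), sh = double(),
         px = double(), py = double(), pw = double(), ph = double(),
         score = double(), stale = logical())
}

#' @export
print.validation_map <- function(x, ...) {
  cat(sprintf("<validation_map kind=%s%s: %d tiles of %dx%d px on %dx%d canvas>\n",
              x$map_kind, if (is.na(x$label)) "" else paste0(" label=", x$label),
              nrow(x$tiles), x$tile_width, x$tile_height,
              x$canvas_width, x$canvas_height))
  invisible(x)
}

#' Tile index of a validation map
#'
#' @param x A `validation_map`.
#' @param ... Unused.
#' @return A tibble, one row per placed tile: source rectangle
#'   (`sx, sy, sw, sh`), placed rectangle (`px, py, pw, ph`), optional
#'   `score`, and the `stale` flag set by corrections.
#' @method tidy validation_map
#' @export
tidy.validation_map <- function(x, ...) x$tiles

#' @rdname tidy.validation_map
#' @method glance validation_map
#' @export
glance.validation_map <- function(x, ...) {
  tibble(map_kind = x$map_kind, label = x$label, n_tiles = nrow(x$tiles),
         canvas_width = x$canvas_width, canvas_height = x$canvas_height,
         tile_width = x$tile_width, tile_height = x$tile_height)
}

render_tiles <- function(canvas_w, canvas_h, tiles, prj_anns, readers, tw, th) {
  canvas <- array(1, c(canvas_h, canvas_w, 3))
  for (i in seq_len(nrow(tiles))) {
    t <- tiles[i, ]
    rd <- resolve_reader(readers, t$source_image_id)
    pix <- read_region(rd, t$sx, t$sy, t$sw, t$sh)
    canvas[(t$py + 1):(t$py + th), (t$px + 1):(t$px + tw), ] <- resize_bilinear(pix, tw, th)
  }
  canvas
}

tiles_for <- function(prj, anns) {
  if (!nrow(anns)) return(empty_tiles())
  kinds <- prj$templates$kind[match(anns$template_id, prj$templates$template_id)]
  if (any(kinds == "global")) abort("global annotations have no geometry to crop")
  rects <- purrr::map2(anns$vector, seq_len(nrow(anns)), function(m, i) {
    img <- get_image(prj, anns$image_id[i])
    annotation_crop_rect(m, kinds[i], img$width, img$height)
  })
  scores <- purrr::map_dbl(anns$meta, ~ as.double(.x$score %||% NA_real_))
  tibble(annotation_id = anns$annotation_id, source_image_id = anns$image_id,
         sx = purrr::map_dbl(rects, "x"), sy = purrr::map_dbl(rects, "y"),
         sw = purrr::map_dbl(rects, "w"), sh = purrr::map_dbl(rects, "h"),
         px = NA_real_, py = NA_real_, pw = NA_real_, ph = NA_real_,
         score = scores, stale = FALSE)
}

#' Build a per-label annotation map
#'
#' Packs square crops of every annotation carrying one label into a
#' matrix-like image, row-major in a stable order (source image id, then
#' annotation id), `tiles_per_row` per row. Outliers — mislabelled cells —
#' stand out immediately when all tiles should show the same class, and
#' corrections flow back through [apply_map_correction()].
#'
#' @param prj A [slide_project()].
#' @param label Template name or id; all packed annotations carry it.
#' @param annotations Optional pre-filtered annotation tibble (must share one
#'   template); default: all live annotations with `label`.
#' @param readers Pixel source: the project itself (stored rasters), a named
#'   list of [region_reader()]s by image id, or a single reader.
#' @param tile_size Tile edge in pixels.
#' @param tiles_per_row How many annotations to show per row.
#' @param render Draw the canvas (`FALSE` = layout and index only).
#' @return A `validation_map` (kind `"annotation"`).
#' @export
build_annotation_map <- function(prj, label = NULL, annotations = NULL, readers = prj,
                                 tile_size = 64, tiles_per_row = 10, render = TRUE) {
  check_project(prj)
  if (tiles_per_row < 1L) abort("`tiles_per_row` must be >= 1")
  anns <- annotations %||% slidekit::annotations(prj, label = label)
  if (nrow(anns) && length(unique(anns$template_id)) != 1L) {
    abort("an annotation map holds exactly one label")
  }
  label_id <- if (nrow(anns)) anns$template_id[[1L]] else
    if (!is.null(label)) label_to_template_ids(prj, label)[[1L]] else NA_character_
  anns <- arrange(anns, .data$image_id, .data$annotation_id)
  tiles <- tiles_for(prj, anns)
  n <- nrow(tiles)
  tw <- th <- as.integer(tile_size)
  n_rows <- ceiling(n / tiles_per_row)
  canvas_w <- as.integer(tiles_per_row * tw)
  canvas_h <- as.integer(max(n_rows, 1L) * th)
  if (n > 0L) {
    idx <- seq_len(n) - 1L
    tiles$px <- (idx %% tiles_per_row) * tw
    tiles$py <- (idx %/% tiles_per_row) * th
    tiles$pw <- tw; tiles$ph <- th
  }
  image <- if (render && n > 0L) render_tiles(canvas_w, canvas_h, tiles, prj, readers, tw, th)
           else array(1, c(canvas_h, canvas_w, 3))
  new_validation_map("annotation", label_id, canvas_w, canvas_h, tw, th, tiles, image)
}

#' Map a point on a validation image back to its source annotation
#'
#' Inverts the crop-and-resize transform: if the point falls inside a placed
#' tile, returns that tile's annotation id and the corresponding pixel in
#' the source image; a gutter point returns `NULL`. A point outside the
#' canvas is an error.
#'
#' @param map A `validation_map`.
#' @param x,y Point on the map canvas (0-based pixels).
#' @return `list(annotation_id, source_image_id, x, y)` or `NULL`.
#' @export
map_to_source <- function(map, x, y) {
  if (!inherits(map, "validation_map")) abort("`map` must be a validation_map")
  if (x < 0 || y < 0 || x > map$canvas_width || y > map$canvas_height) {
    abort("point outside the map canvas")
  }
  t <- filter(map$tiles, .data$px <= .env$x, .env$x < .data$px + .data$pw,
              .data$py <= .env$y, .env$y < .data$py + .data$ph)
  if (!nrow(t)) return(NULL)
  t <- t[1L, ]
  list(annotation_id = t$annotation_id, source_image_id = t$source_image_id,
       x = t$sx + (x - t$px) / t$pw * t$sw,
       y = t$sy + (y - t$py) / t$ph * t$sh)
}

#' Apply a correction made on a validation map to the source annotation
#'
#' The map is only a view: a relabel changes the source annotation's
#' template (geometry untouched), a delete soft-deletes it, and a confirm
#' records a confirmed verification by `user`. The affected tile is marked
#' stale so the caller knows the rendered canvas no longer reflects the
#' store.
#'
#' @param prj A [slide_project()].
#' @param map A `validation_map`.
#' @param annotation_id Tile to correct, identified by its annotation.
#' @param correction `"relabel"`, `"delete"` or `"confirm"`.
#' @param template_id Target label for a relabel.
#' @param user Correcting user id.
#' @param time Correction time (`NULL` = now).
#' @return The map with the tile marked stale.
#' @export
apply_map_correction <- function(prj, map, annotation_id,
                                 correction = c("relabel", "delete", "confirm"),
                                 template_id = NULL, user = "default", time = NULL) {
  check_project(prj)
  if (!inherits(map, "validation_map")) abort("`map` must be a validation_map")
  correction <- match.arg(correction)
  i <- match(annotation_id, map$tiles$annotation_id)
  if (is.na(i)) abort(sprintf("annotation '%s' has no tile on this map", annotation_id))
  switch(correction,
    relabel = {
      if (is.null(template_id)) abort("relabel needs a `template_id`")
      edit_annotation(prj, annotation_id, template_id = template_id, user = user, time = time)
    },
    delete = delete_annotation(prj, annotation_id, user = user, time = time),
    confirm = verify_annotation(prj, annotation_id, user = user, verdict = "confirmed", time = time)
  )
  map$tiles$stale[i] <- TRUE
  map
}

#' Build a cluster map from 2-D embedded annotations
#'
#' Lays annotation crops out on a regular grid so that each lands as close
#' as possible to its (scaled) two-dimensional embedding position without
#' overlapping any other: similar patches end up adjacent, making initial
#' labelling and validation fast. Placement is greedy in insertion order —
#' each patch takes the nearest free cell (Euclidean distance between cell
#' centres, ties broken by row-major cell index) — hence fully
#' deterministic and overlap-free.
#'
#' @inheritParams build_annotation_map
#' @param embedding A tibble from [reduce_features()] (`annotation_id`, `u`,
#'   `v`).
#' @param canvas_width,canvas_height Canvas size in pixels; must hold at
#'   least `nrow(embedding)` grid cells.
#' @return A `validation_map` (kind `"cluster"`).
#' @export
build_cluster_map <- function(prj, embedding, readers = prj, tile_size = 64,
                              canvas_width = 1024, canvas_height = 1024,
                              render = TRUE) {
  check_project(prj)
  tw <- th <- as.integer(tile_size)
  ncx <- canvas_width %/% tw; ncy <- canvas_height %/% th
  n <- nrow(embedding)
  if (ncx * ncy < n) {
    abort(sprintf("canvas holds %d cells but %d tiles are needed", ncx * ncy, n))
  }
  anns <- filter(prj$annotations, .data$annotation_id %in% embedding$annotation_id)
  anns <- anns[match(embedding$annotation_id, anns$annotation_id), ]
  if (anyNA(anns$annotation_id)) abort("embedding refers to unknown annotations")
  tiles <- tiles_for(prj, anns)
  if (n > 0L) {
    scale01 <- function(z) if (max(z) > min(z)) (z - min(z)) / (max(z) - min(z)) else rep(0, length(z))
    ideal_col <- scale01(embedding$u) * (ncx - 1L)
    ideal_row <- scale01(embedding$v) * (ncy - 1L)
    cells <- expand.grid(col = seq_len(ncx) - 1L, row = seq_len(ncy) - 1L)  # row-major order
    cells <- cells[order(cells$row, cells$col), ]
    free <- rep(TRUE, nrow(cells))
    cx <- (cells$col + 0.5) * tw; cy <- (cells$row + 0.5) * th
    for (i in seq_len(n)) {
      want_x <- (ideal_col[i] + 0.5) * tw; want_y <- (ideal_row[i] + 0.5) * th
      d <- (cx - want_x)^2 + (cy - want_y)^2
      d[!free] <- Inf
      j <- which.min(d)  # ties: earliest (row-major) index wins
      free[j] <- FALSE
      tiles$px[i] <- cells$col[j] * tw; tiles$py[i] <- cells$row[j] * th
      tiles$pw[i] <- tw; tiles$ph[i] <- th
    }
  }
  image <- if (render && n > 0L) render_tiles(canvas_width, canvas_height, tiles, prj, readers, tw, th)
           else array(1, c(canvas_height, canvas_width, 3))
  new_validation_map("cluster", NA_character_, as.integer(canvas_width),
                     as.integer(canvas_height), tw, th, tiles, image)
}

#' Build a density map of scored annotations
#'
#' Orders cells by a continuous score in `[0, 4]` along the x-axis —
#' `n_bins` equal intervals, last bin right-closed — and stacks the cell
#' crops of each bin bottom-up in score order along the y-axis. Column
#' height equals the bin count, so the silhouette is a histogram of the
#' score distribution and a reviewer can focus on cells sitting on grade
#' borders.
#'
#' @inheritParams build_annotation_map
#' @param annotations Annotation tibble; scores default to each annotation's
#'   `meta$score`.
#' @param scores Optional numeric vector overriding the per-annotation
#'   scores (same length/order as `annotations`).
#' @param n_bins Number of score bins over `[0, 4]`; the default 41 gives a
#'   0.1 grade step.
#' @return A `validation_map` (kind `"density"`) whose tiles carry `score`.
#' @export
build_density_map <- function(prj, annotations = NULL, scores = NULL, readers = prj,
                              tile_size = 64, n_bins = 41, render = TRUE) {
  check_project(prj)
  if (n_bins < 1L) abort("`n_bins` must be >= 1")
  anns <- annotations %||% slidekit::annotations(prj)
  tiles <- tiles_for(prj, anns)
  if (!is.null(scores)) {
    if (length(scores) != nrow(tiles)) abort("`scores` must match the annotations")
    tiles$score <- as.double(scores)
  }
  if (anyNA(tiles$score)) abort("every annotation needs a score in [0, 4]")
  if (any(tiles$score < 0 | tiles$score > 4)) abort("scores must lie in [0, 4]")
  tw <- th <- as.integer(tile_size)
  # bin of a score over [0,4]: equal intervals, final bin right-closed
  bin <- pmin(floor(tiles$score / 4 * n_bins), n_bins - 1L) + 1L
  counts <- tabulate(bin, nbins = n_bins)
  canvas_w <- as.integer(n_bins * tw)
  canvas_h <- as.integer(max(counts, 1L) * th)
  if (nrow(tiles)) {
    ord <- order(bin, tiles$score, tiles$annotation_id)
    tiles <- tiles[ord, ]; bin <- bin[ord]
    pos_in_bin <- stats::ave(seq_along(bin), bin, FUN = seq_along)
    tiles$px <- (bin - 1L) * tw
    tiles$py <- canvas_h - pos_in_bin * th   # stacked bottom-up in score order
    tiles$pw <- tw; tiles$ph <- th
  }
  image <- if (render && nrow(tiles)) render_tiles(canvas_w, canvas_h, tiles, prj, readers, tw, th)
           else array(1, c(canvas_h, canvas_w, 3))
  map <- new_validation_map("density", NA_character_, canvas_w, canvas_h, tw, th, tiles, image)
  map$n_bins <- as.integer(n_bins)
  map
}

#' Column heights of a density map
#'
#' @param map A density `validation_map`.
#' @return A tibble with one row per score bin: interval bounds and tile
#'   count.
#' @export
density_columns <- function(map) {
  if (!inherits(map, "validation_map") || map$map_kind != "density") {
    abort("`map` must be a density validation_map")
  }
  nb <- map$n_bins
  counts <- tabulate(map$tiles$px / map$tile_width + 1L, nbins = nb)
  tibble(bin = seq_len(nb), score_lo = (seq_len(nb) - 1L) * 4 / nb,
         score_hi = seq_len(nb) * 4 / nb, count = counts)
}

#' Write a validation map image and its tile index
#'
#' The canvas goes to PNG (or TIFF) and the tile index to a sidecar JSON
#' (`<stem>.json`) holding the source/placed rectangles and scores — enough
#' to re-associate any edit made on the image with its source annotation.
#'
#' @param map A `validation_map`.
#' @param path Output image path (`.png`, `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_validation_map <- function(map, path) {
  if (!inherits(map, "validation_map")) abort("`map` must be a validation_map")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(map$image, path),
    tif = ,
    tiff = tiff::writeTIFF(map$image, path),
    abort(sprintf("unsupported output format '.%s'", ext))
  )
  idx <- list(map_kind = map$map_kind,
              label = if (is.na(map$label)) NULL else map$label,
              canvas = list(width = map$canvas_width, height = map$canvas_height),
              tile = list(width = map$tile_width, height = map$tile_height),
              tiles = lapply(seq_len(nrow(map$tiles)), function(i) {
                t <- map$tiles[i, ]
                list(annotation_id = t$annotation_id, source_image_id = t$source_image_id,
                     source_rect = list(x = t$sx, y = t$sy, w = t$sw, h = t$sh),
                     placed_rect = list(x = t$px, y = t$py, w = t$pw, h = t$ph),
                     score = if (is.na(t$score)) NULL else t$score)
              }))
  writeLines(to_json_text(idx), paste0(tools::file_path_sans_ext(path), ".json"), sep = "")
  invisible(path)
}
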