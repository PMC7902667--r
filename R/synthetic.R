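# Synthetic slide fixtures: deterministic cytology-like images with known
# ground truth, so grids, maps, embeddings and crowd policies are all
# testable without any external image. Cells are filled ellipses with
# Gaussian-perturbed radii and class-specific colour; each carries a
# continuous grade in [0, 4] drawn from a scaled Beta distribution.

default_cell_classes <- function() {
  tibble(
    name = c("eosinophil", "mast_cell", "neutrophil", "macrophage", "lymphocyte"),
    size_mean = c(12, 14, 10, 18, 8),
    colour_r = c(0.85, 0.60, 0.30, 0.55, 0.20),
    colour_g = c(0.30, 0.30, 0.45, 0.40, 0.25),
    colour_b = c(0.30, 0.70, 0.80, 0.25, 0.55)
  )
}

#' Specify a synthetic slide
#'
#' Defines the study conditions for one generated image: canvas size, how
#' many cells, the cell classes (default: the five visually distinguishable
#' cytology classes — eosinophils, mast cells, neutrophils, macrophages,
#' lymphocytes — each with its own typical size and stain colour), the
#' grade distribution (`4 * Beta(shape1, shape2)`, default `Beta(2, 2)`),
#' and the background. One seed fixes every random draw.
#'
#' @param width,height Canvas size in pixels.
#' @param n_cells Number of cells to place.
#' @param class_names Cell class names.
#' @param class_size_means Mean radius in pixels per class (same length as
#'   `class_names`).
#' @param score_shape1,score_shape2 Beta shape parameters of the grade
#'   distribution over `[0, 4]`.
#' @param background `"flat"` or `"noise"`.
#' @param seed Integer seed.
#' @return A `synthetic_slide_spec` object.
#' @export
synthetic_slide_spec <- function(width = 1024, height = 1024, n_cells = 200,
                                 class_names = default_cell_classes()$name,
                                 class_size_means = default_cell_classes()$size_mean,
                                 score_shape1 = 2, score_shape2 = 2,
                                 background = c("flat", "noise"), seed = 1L) {
  background <- match.arg(background)
  if (length(class_names) != length(class_size_means)) {
    abort("`class_names` and `class_size_means` must have the same length")
  }
  if (any(class_size_means <= 0)) abort("class sizes must be positive")
  if (n_cells < 0) abort("`n_cells` must be >= 0")
  classes <- default_cell_classes()[rep_len(seq_len(nrow(default_cell_classes())),
                                            length(class_names)), ]
  classes$name <- class_names
  classes$size_mean <- class_size_means
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_cells = as.integer(n_cells), classes = classes,
                 score_shape1 = score_shape1, score_shape2 = score_shape2,
                 background = background, seed = as.integer(seed)),
            class = "synthetic_slide_spec")
}

#' Generate a synthetic slide with ground truth
#'
#' Renders the specified cells as ellipses on the background and returns
#' both the raster and a ground-truth table (class, grade, bounding box).
#' Cell centres are sampled with pairwise separation so ellipses do not
#' collide; when `n_cells` exceeds what the canvas can hold at the given
#' sizes, generation fails rather than overlapping cells. Output is
#' byte-identical for a fixed seed (pixel values are quantised to the 8-bit
#' grid, so a PNG round trip is lossless).
#'
#' @param spec A [synthetic_slide_spec()].
#' @return A list with `image` (`height x width x 3` array) and `cells`, a
#'   tibble: `cell`, `class`, `score`, centre, radii and box corners.
#' @export
generate_slide <- function(spec) {
  if (!inherits(spec, "synthetic_slide_spec")) abort("`spec` must come from synthetic_slide_spec()")
  withr::with_seed(spec$seed, generate_slide_impl(spec))
}

generate_slide_impl <- function(spec) {
  w <- spec$width; h <- spec$height
  img <- array(0, c(h, w, 3))
  base <- c(0.93, 0.90, 0.95)
  for (k in 1:3) img[, , k] <- base[k]
  if (spec$background == "noise") {
    for (k in 1:3) img[, , k] <- pmin(pmax(img[, , k] + rnorm(h * w, sd = 0.015), 0), 1)
  }
  n <- spec$n_cells
  cls <- spec$classes
  cells <- tibble(cell = integer(), class = character(), score = double(),
                  cx = double(), cy = double(), rx = double(), ry = double(),
                  x1 = double(), y1 = double(), x2 = double(), y2 = double())
  if (n > 0L) {
    ki <- sample.int(nrow(cls), n, replace = TRUE)
    rx <- pmax(3, cls$size_mean[ki] * (1 + rnorm(n, sd = 0.15)))
    ry <- pmax(3, cls$size_mean[ki] * (1 + rnorm(n, sd = 0.15)))
    rmax <- pmax(rx, ry)
    cx <- numeric(n); cy <- numeric(n)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 200L * n
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort(sprintf("cannot place %d cells of these sizes on a %dx%d canvas", n, w, h))
      }
      x <- runif(1, rmax[placed + 1L], w - rmax[placed + 1L])
      y <- runif(1, rmax[placed + 1L], h - rmax[placed + 1L])
      if (placed == 0L ||
          all((cx[seq_len(placed)] - x)^2 + (cy[seq_len(placed)] - y)^2 >
              (rmax[seq_len(placed)] + rmax[placed + 1L] + 2)^2)) {
        placed <- placed + 1L
        cx[placed] <- x; cy[placed] <- y
      }
    }
    scores <- 4 * rbeta(n, spec$score_shape1, spec$score_shape2)
    jitter <- matrix(rnorm(3 * n, sd = 0.02), n, 3)
    xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
    ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
    for (i in seq_len(n)) {
      x_lo <- max(1L, floor(cx[i] - rx[i])); x_hi <- min(w, ceiling(cx[i] + rx[i]))
      y_lo <- max(1L, floor(cy[i] - ry[i])); y_hi <- min(h, ceiling(cy[i] + ry[i]))
      sub_x <- xs[y_lo:y_hi, x_lo:x_hi]; sub_y <- ys[y_lo:y_hi, x_lo:x_hi]
      inside <- ((sub_x - cx[i]) / rx[i])^2 + ((sub_y - cy[i]) / ry[i])^2 <= 1
      col <- pmin(pmax(c(cls$colour_r[ki[i]], cls$colour_g[ki[i]], cls$colour_b[ki[i]]) +
                       jitter[i, ], 0), 1)
      for (k in 1:3) {
        plane <- img[y_lo:y_hi, x_lo:x_hi, k]
        plane[inside] <- col[k]
        img[y_lo:y_hi, x_lo:x_hi, k] <- plane
      }
    }
    cells <- tibble(cell = seq_len(n), class = cls$name[ki], score = scores,
                    cx = cx, cy = cy, rx = rx, ry = ry,
                    x1 = pmax(0, cx - rx), y1 = pmax(0, cy - ry),
                    x2 = pmin(w, cx + rx), y2 = pmin(h, cy + ry))
  }
  img <- round(img * 255) / 255
  list(image = img, cells = cells, spec = spec)
}

#' Build a ready-to-use project from a synthetic slide
#'
#' Registers the generated image (with its raster), one box template per
#' cell class grouped into a product, and one ground-truth box annotation
#' per cell with the grade stored as `meta$score`.
#'
#' @param slide Output of [generate_slide()] (or a
#'   [synthetic_slide_spec()], which is generated first).
#' @param user Creator recorded on the ground-truth annotations.
#' @param time Registration/creation time (`NULL` = a fixed reference time,
#'   keeping the project fully deterministic).
#' @return A [slide_project()] with `$slide` attached.
#' @export
synthetic_project <- function(slide, user = "synth", time = "2021-02-23 14:05:00") {
  if (inherits(slide, "synthetic_slide_spec")) slide <- generate_slide(slide)
  spec <- slide$spec
  prj <- slide_project("synthetic")
  add_user(prj, user)
  set <- add_image_set(prj, "synthetic-slides")
  img <- register_image(prj, set$set_id, sprintf("synthetic_slide_seed%d.png", spec$seed),
                        spec$width, spec$height, raster = slide$image, time = time)
  tpl_ids <- character(nrow(spec$classes))
  for (i in seq_len(nrow(spec$classes))) {
    col <- grDevices::rgb(spec$classes$colour_r[i], spec$classes$colour_g[i],
                          spec$classes$colour_b[i])
    tpl_ids[i] <- add_template(prj, spec$classes$name[i], kind = "box", colour = col,
                               default_width = 2 * spec$classes$size_mean[i],
                               default_height = 2 * spec$classes$size_mean[i],
                               sort_index = i)$template_id
  }
  add_product(prj, "cytology", tpl_ids, description = "synthetic cell classes")
  attach_product(prj, set$set_id, products(prj)$product_id[[1L]])
  names(tpl_ids) <- spec$classes$name
  for (i in seq_len(nrow(slide$cells))) {
    c_ <- slide$cells[i, ]
    create_annotation(prj, img$image_id, tpl_ids[[c_$class]],
                      rbind(c(c_$x1, c_$y1), c(c_$x2, c_$y2)), user = user,
                      meta = list(score = c_$score, cell = c_$cell), time = time)
  }
  prj$slide <- slide
  prj
}

#' Per-annotation feature vectors from image content
#'
#' A deliberately simple feature extractor for validation-map pipelines:
#' mean RGB, a 4-bin intensity histogram per channel, and the log box area
#' — 16 numbers per annotation. Identical crops give identical vectors.
#' Real deployments would substitute learned features; the downstream
#' contract ([reduce_features()], [build_cluster_map()]) is the same.
#'
#' @param prj A [slide_project()].
#' @param annotations Annotation tibble (default: all live annotations).
#' @param readers Pixel source, as in [build_annotation_map()].
#' @return A tibble: `annotation_id` plus numeric feature columns `f01`...
#' @export
generate_feature_table <- function(prj, annotations = NULL, readers = prj) {
  check_project(prj)
  anns <- annotations %||% slidekit::annotations(prj)
  feats <- lapply(seq_len(nrow(anns)), function(i) {
    img <- get_image(prj, anns$image_id[i])
    kind <- get_template(prj, anns$template_id[i])$kind
    bb <- bbox_of(anns$vector[[i]], kind)
    x1 <- max(0, floor(bb[["x1"]])); y1 <- max(0, floor(bb[["y1"]]))
    x2 <- min(img$width, ceiling(bb[["x2"]])); y2 <- min(img$height, ceiling(bb[["y2"]]))
    rd <- resolve_reader(readers, anns$image_id[i])
    pix <- read_region(rd, x1, y1, max(1, x2 - x1), max(1, y2 - y1))
    means <- apply(pix, 3, mean)
    hists <- unlist(lapply(1:3, function(k) {
      tabulate(pmin(floor(pix[, , k] * 4) + 1L, 4L), nbins = 4L) / length(pix[, , k])
    }))
    c(means, hists, log1p((x2 - x1) * (y2 - y1)))
  })
  X <- do.call(rbind, feats)
  colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
  out <- tibble(annotation_id = anns$annotation_id)
  bind_cols_safe(out, X)
}

bind_cols_safe <- function(df, X) {
  for (j in seq_len(ncol(X))) df[[colnames(X)[j]]] <- X[, j]
  df
}
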