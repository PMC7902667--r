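# Guided screening: a persistent grid of equal-sized, overlapping patches
# over one image, with visited flags and a resumable position, so a slide
# can be screened systematically across sessions.

# Patch start offsets along one axis. Stride = patch - round(overlap * patch);
# the final start is shifted inward to image_dim - patch so every patch keeps
# the exact requested size while the grid still reaches the image edge (the
# far edge pair simply overlaps more).
grid_starts <- function(image_dim, patch, overlap_fraction) {
  if (patch > image_dim) abort("patch dimension exceeds image dimension")
  if (overlap_fraction < 0 || overlap_fraction >= 1) abort("overlap fraction must be in [0, 1)")
  if (patch == image_dim) return(0)
  stride <- patch - round(overlap_fraction * patch)
  if (stride <= 0) abort("overlap too large: stride is not positive")
  starts <- seq(0, image_dim - patch, by = stride)
  if (tail(starts, 1) != image_dim - patch) starts <- c(starts, image_dim - patch)
  starts
}

#' Create a guided-screening map
#'
#' Divides the image into equal-sized patches with a fixed relative overlap
#' (default 15%) and stores the resulting map on the project, keyed by image
#' and user. All patches have exactly `patch_width x patch_height` pixels —
#' the last row/column is shifted inward rather than shrunk — and their
#' union covers every pixel of the image.
#'
#' @param prj A [slide_project()].
#' @param image_id Image to screen.
#' @param patch_width,patch_height Patch size in pixels (the "zoom level":
#'   how much of the slide is on screen at once).
#' @param overlap_fraction Relative overlap between neighbouring patches in
#'   `[0, 1)`; the pixel overlap is `round(overlap_fraction * patch)` per
#'   axis.
#' @param user Screening user id.
#' @return A `screening_map` object (also stored in the project).
#' @export
create_screening_map <- function(prj, image_id, patch_width, patch_height,
                                 overlap_fraction = 0.15, user = "default") {
  check_project(prj)
  img <- get_image(prj, image_id)
  map <- new_screening_map(image_id, img$width, img$height, patch_width,
                           patch_height, overlap_fraction, user)
  prj$screening_maps[[screening_key(map)]] <- map
  map
}

#' @rdname create_screening_map
#' @param width,height Image dimensions, for a map built without a project.
#' @export
new_screening_map <- function(image_id, width, height, patch_width, patch_height,
                              overlap_fraction = 0.15, user = "default") {
  x_starts <- grid_starts(width, patch_width, overlap_fraction)
  y_starts <- grid_starts(height, patch_height, overlap_fraction)
  structure(list(
    image_id = image_id, user = user, width = width, height = height,
    patch_width = patch_width, patch_height = patch_height,
    overlap_fraction = overlap_fraction, x_starts = x_starts, y_starts = y_starts,
    visited = matrix(FALSE, nrow = length(y_starts), ncol = length(x_starts)),
    current_index = c(1L, 1L)
  ), class = "screening_map")
}

screening_key <- function(map) paste(map$image_id, map$user, sep = "/")

#' @export
print.screening_map <- function(x, ...) {
  cat(sprintf("<screening_map %s by %s: %dx%d patches of %dx%d px, overlap %.0f%%, progress %.1f%%>\n",
              x$image_id, x$user, nrow(x$visited), ncol(x$visited),
              x$patch_width, x$patch_height, 100 * x$overlap_fraction,
              100 * progress(x)))
  invisible(x)
}

#' Patch grid of a screening map as a tibble
#'
#' @param x A `screening_map`.
#' @param ... Unused.
#' @return A tibble with one row per patch: `row`, `col`, rectangle
#'   `x1, y1, x2, y2` (half-open) and `visited`.
#' @method tidy screening_map
#' @export
tidy.screening_map <- function(x, ...) {
  g <- expand.grid(row = seq_along(x$y_starts), col = seq_along(x$x_starts))
  tibble(row = g$row, col = g$col,
         x1 = x$x_starts[g$col], y1 = x$y_starts[g$row],
         x2 = x$x_starts[g$col] + x$patch_width,
         y2 = x$y_starts[g$row] + x$patch_height,
         visited = x$visited[cbind(g$row, g$col)])
}

#' Mark a patch as screened
#'
#' Sets the visited flag and moves the stored current position there. If the
#' map came from [create_screening_map()], pass `prj` to persist the change
#' on the project.
#'
#' @inheritParams tidy.screening_map
#' @param map A `screening_map`.
#' @param row,col 1-based patch indices.
#' @param prj Project to persist into (`NULL` = value-only update).
#' @return The updated map.
#' @export
mark_visited <- function(map, row, col, prj = NULL) {
  check_screening_index(map, row, col)
  map$visited[row, col] <- TRUE
  map$current_index <- c(as.integer(row), as.integer(col))
  if (!is.null(prj)) { check_project(prj); prj$screening_maps[[screening_key(map)]] <- map }
  map
}

check_screening_index <- function(map, row, col) {
  if (!inherits(map, "screening_map")) abort("`map` must be a screening_map")
  if (row < 1L || row > nrow(map$visited) || col < 1L || col > ncol(map$visited)) {
    abort(sprintf("patch index (%d, %d) out of range for a %dx%d grid",
                  row, col, nrow(map$visited), ncol(map$visited)))
  }
}

#' Resume position and progress of a screening map
#'
#' `resume()` returns the stored `(row, col)` position, which survives
#' serialisation round trips; `progress()` is the fraction of patches
#' visited.
#'
#' @inheritParams mark_visited
#' @return `resume()`: integer `(row, col)`; `progress()`: a number in
#'   `[0, 1]`.
#' @export
resume <- function(map) {
  if (!inherits(map, "screening_map")) abort("`map` must be a screening_map")
  map$current_index
}

#' @rdname resume
#' @export
progress <- function(map) {
  if (!inherits(map, "screening_map")) abort("`map` must be a screening_map")
  mean(map$visited)
}

#' Next unvisited patch in serpentine order
#'
#' Traverses rows top to bottom, alternating direction within rows (odd rows
#' left to right, even rows right to left) so consecutive patches stay
#' adjacent on the slide, starting after the current position and wrapping
#' around once.
#'
#' @inheritParams mark_visited
#' @return Integer `(row, col)` of the next unvisited patch, or `NULL` when
#'   all patches are visited.
#' @export
next_unvisited <- function(map) {
  if (!inherits(map, "screening_map")) abort("`map` must be a screening_map")
  nr <- nrow(map$visited); nc <- ncol(map$visited)
  order_idx <- do.call(rbind, lapply(seq_len(nr), function(r) {
    cols <- if (r %% 2L == 1L) seq_len(nc) else rev(seq_len(nc))
    cbind(r, cols)
  }))
  pos <- which(order_idx[, 1] == map$current_index[1] & order_idx[, 2] == map$current_index[2])
  rot <- if (pos < nrow(order_idx)) rbind(order_idx[(pos + 1):nrow(order_idx), , drop = FALSE],
                                          order_idx[seq_len(pos), , drop = FALSE]) else order_idx
  for (i in seq_len(nrow(rot))) {
    if (!map$visited[rot[i, 1], rot[i, 2]]) return(as.integer(rot[i, ]))
  }
  NULL
}

# --- serialisation ---------------------------------------------------------
# Only parameters, the visited bitmap and the position are stored; the grid
# is re-derived on load.

screening_to_list <- function(map) {
  list(image_id = map$image_id, user = map$user, width = map$width, height = map$height,
       patch_width = map$patch_width, patch_height = map$patch_height,
       overlap_fraction = map$overlap_fraction,
       visited = as.integer(t(map$visited)),
       current_index = as.list(map$current_index))
}

screening_from_list <- function(lst) {
  map <- new_screening_map(lst$image_id, as.integer(lst$width), as.integer(lst$height),
                           as.integer(lst$patch_width), as.integer(lst$patch_height),
                           lst$overlap_fraction, lst$user)
  v <- as.integer(unlist(lst$visited))
  map$visited <- matrix(as.logical(v), nrow = nrow(map$visited), byrow = TRUE)
  map$current_index <- as.integer(unlist(lst$current_index))
  map
}

#' Serialise a screening map to JSON text
#'
#' @inheritParams mark_visited
#' @return JSON text; parse back with [screening_map_from_json()].
#' @export
screening_map_to_json <- function(map) {
  if (!inherits(map, "screening_map")) abort("`map` must be a screening_map")
  to_json_text(screening_to_list(map))
}

#' @rdname screening_map_to_json
#' @param text JSON produced by [screening_map_to_json()].
#' @export
screening_map_from_json <- function(text) {
  screening_from_list(jsonlite::fromJSON(text, simplifyVector = FALSE))
}

#' List screening maps stored on a project
#'
#' @inheritParams create_screening_map
#' @return A tibble with one row per stored map.
#' @export
screening_maps <- function(prj) {
  check_project(prj)
  if (!length(prj$screening_maps)) {
    return(tibble(image_id = character(), user = character(), n_rows = integer(),
                  n_cols = integer(), progress = double()))
  }
  bind_rows(lapply(unname(prj$screening_maps), function(m) {
    tibble(image_id = m$image_id, user = m$user, n_rows = nrow(m$visited),
           n_cols = ncol(m$visited), progress = progress(m))
  }))
}
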