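# Annotation CRUD. Coordinates are 0-based pixels, origin top-left; boxes are
# half-open [x1, x2) x [y1, y2), so a box's far edge may equal the image
# dimension and tiling arithmetic stays exact.

validate_vector <- function(m, kind, width, height) {
  n <- nrow(m)
  switch(kind,
    box = if (n != 2L) abort("box requires exactly 2 points (top-left, bottom-right)"),
    polygon = if (n < 3L) abort("polygon requires ≥ 3 points"),
    line = if (n < 2L) abort("line requires ≥ 2 points"),
    circle = if (n != 2L) abort("circle requires exactly 2 points (centre, radius point)"),
    global = if (n != 0L) abort("global annotations carry no geometry")
  )
  if (n > 0L && (any(m[, 1] < 0) || any(m[, 2] < 0) ||
                 any(m[, 1] > width) || any(m[, 2] > height))) {
    abort(sprintf("coordinates outside image bounds [0, %d] x [0, %d]", width, height))
  }
  if (kind == "box") {
    # inverted corners from interactive drawing are normalised, not rejected
    m <- cbind(x = c(min(m[, 1]), max(m[, 1])), y = c(min(m[, 2]), max(m[, 2])))
  }
  m
}

#' Create an annotation
#'
#' Validates the coordinate vector against the template's geometry kind
#' (box: 2 points, polygon: \eqn{\ge 3}, line: \eqn{\ge 2}, circle: centre +
#' radius point, global: none) and against the image bounds — out-of-bounds
#' coordinates are an error, never silently clamped. Inverted box corners are
#' normalised to (top-left, bottom-right).
#'
#' @param prj A [slide_project()].
#' @param image_id,template_id Owning image and label template.
#' @param vector Point coordinates: an `n x 2` matrix, a data frame with
#'   `x`/`y`, a list of `(x, y)` pairs, or the flat mapping
#'   `list(x1 = , y1 = , x2 = , ...)`.
#' @param user Creating user id.
#' @param meta Optional JSON-serialisable metadata list.
#' @param time Creation time (`NULL` = now).
#' @return The stored annotation as a one-row tibble with
#'   `creator == last_editor` and `created_at == edited_at`.
#' @export
create_annotation <- function(prj, image_id, template_id, vector = NULL,
                              user, meta = list(), time = NULL) {
  check_project(prj)
  img <- get_image(prj, image_id)
  tpl <- get_template(prj, template_id)
  m <- validate_vector(as_coord_matrix(vector), tpl$kind, img$width, img$height)
  now <- iso_now(time)
  row <- tibble(annotation_id = new_id(prj, "ann"), image_id = image_id,
                template_id = template_id, vector = list(m), creator = user,
                last_editor = user, created_at = now, edited_at = now,
                meta = list(meta), deleted = FALSE)
  prj$annotations <- bind_rows(prj$annotations, row)
  row
}

#' Single-click annotation from a template's default size
#'
#' Places a box (or circle) of the template's default size centred on the
#' clicked point, encoding the annotator's prior knowledge of the structure's
#' typical extent — one click instead of a drawn rectangle. Near the image
#' border the box is clipped to the image; a click whose clipped box would be
#' empty is an error.
#'
#' @inheritParams create_annotation
#' @param x,y Click position in image pixels.
#' @return The stored annotation as a one-row tibble.
#' @export
single_click_annotation <- function(prj, image_id, template_id, x, y, user,
                                    meta = list(), time = NULL) {
  check_project(prj)
  img <- get_image(prj, image_id)
  tpl <- get_template(prj, template_id)
  if (!tpl$kind %in% c("box", "circle")) {
    abort(sprintf("single-click requires a box or circle template, not '%s'", tpl$kind))
  }
  if (is.na(tpl$default_width) || is.na(tpl$default_height)) {
    abort(sprintf("template '%s' has no default size", tpl$name))
  }
  if (x < 0 || y < 0 || x > img$width || y > img$height) abort("click outside image")
  if (tpl$kind == "circle") {
    r <- tpl$default_width / 2
    r <- min(r, x, y, img$width - x, img$height - y)
    if (r <= 0) abort("clipped circle has zero area")
    vec <- rbind(c(x, y), c(x + r, y))
  } else {
    box <- rect_intersect(
      c(x1 = x - tpl$default_width / 2, y1 = y - tpl$default_height / 2,
        x2 = x + tpl$default_width / 2, y2 = y + tpl$default_height / 2),
      c(x1 = 0, y1 = 0, x2 = as.double(img$width), y2 = as.double(img$height))
    )
    if (is.null(box)) abort("clipped box has zero area")
    vec <- rbind(c(box[["x1"]], box[["y1"]]), c(box[["x2"]], box[["y2"]]))
  }
  create_annotation(prj, image_id, template_id, vec, user, meta = meta, time = time)
}

#' Edit an annotation
#'
#' Updates geometry and/or label; `creator` and `created_at` are immutable,
#' `last_editor` and `edited_at` record the change (`edited_at` always
#' advances, even for a no-op edit). Deleted annotations cannot be edited.
#'
#' @inheritParams create_annotation
#' @param annotation_id Annotation to edit.
#' @param vector New coordinates (`NULL` = keep).
#' @param template_id New template (`NULL` = keep).
#' @return The updated annotation as a one-row tibble.
#' @export
edit_annotation <- function(prj, annotation_id, vector = NULL, template_id = NULL,
                            user, time = NULL) {
  check_project(prj)
  i <- match(annotation_id, prj$annotations$annotation_id)
  if (is.na(i)) abort(sprintf("unknown annotation '%s'", annotation_id))
  if (prj$annotations$deleted[i]) abort("cannot edit a deleted annotation")
  img <- get_image(prj, prj$annotations$image_id[i])
  tpl_id <- template_id %||% prj$annotations$template_id[i]
  tpl <- get_template(prj, tpl_id)
  m <- if (is.null(vector)) prj$annotations$vector[[i]] else as_coord_matrix(vector)
  m <- validate_vector(m, tpl$kind, img$width, img$height)
  prj$annotations$vector[[i]] <- m
  prj$annotations$template_id[i] <- tpl_id
  prj$annotations$last_editor[i] <- user
  prj$annotations$edited_at[i] <- iso_after(time, prj$annotations$edited_at[i])
  prj$annotations[i, ]
}

#' Soft-delete an annotation
#'
#' Sets the `deleted` flag instead of removing the row, so version snapshots
#' and verification history stay consistent.
#'
#' @inheritParams edit_annotation
#' @return The updated annotation row, invisibly.
#' @export
delete_annotation <- function(prj, annotation_id, user, time = NULL) {
  check_project(prj)
  i <- match(annotation_id, prj$annotations$annotation_id)
  if (is.na(i)) abort(sprintf("unknown annotation '%s'", annotation_id))
  if (prj$annotations$deleted[i]) return(invisible(prj$annotations[i, ]))
  prj$annotations$deleted[i] <- TRUE
  prj$annotations$last_editor[i] <- user
  prj$annotations$edited_at[i] <- iso_after(time, prj$annotations$edited_at[i])
  invisible(prj$annotations[i, ])
}

#' Live annotations as a tibble
#'
#' @inheritParams create_annotation
#' @param image_id Restrict to one image (`NULL` = all).
#' @param label Restrict to one template by name or id (`NULL` = all).
#' @param include_deleted Include soft-deleted annotations.
#' @return A tibble, one row per annotation, stably ordered by image then
#'   annotation id.
#' @export
annotations <- function(prj, image_id = NULL, label = NULL, include_deleted = FALSE) {
  check_project(prj)
  out <- prj$annotations
  if (!include_deleted) out <- filter(out, !.data$deleted)
  if (!is.null(image_id)) out <- filter(out, .data$image_id %in% .env$image_id)
  if (!is.null(label)) {
    ids <- label_to_template_ids(prj, label)
    out <- filter(out, .data$template_id %in% ids)
  }
  arrange(out, .data$image_id, .data$annotation_id)
}

label_to_template_ids <- function(prj, label) {
  ids <- prj$templates$template_id[prj$templates$template_id %in% label |
                                   prj$templates$name %in% label]
  if (!length(ids)) abort(sprintf("unknown label '%s'", paste(label, collapse = ", ")))
  ids
}

#' Record a verification verdict on an annotation
#'
#' At most one record is kept per (annotation, user); a later verdict
#' replaces the earlier one. Used by the second-opinion crowd mode, where a
#' configured number of distinct users must confirm each annotation.
#'
#' @inheritParams edit_annotation
#' @param verdict `"confirmed"` or `"rejected"`.
#' @return The verification record as a one-row tibble.
#' @export
verify_annotation <- function(prj, annotation_id, user, verdict = c("confirmed", "rejected"),
                              time = NULL) {
  check_project(prj)
  verdict <- match.arg(verdict)
  if (!annotation_id %in% prj$annotations$annotation_id) {
    abort(sprintf("unknown annotation '%s'", annotation_id))
  }
  row <- tibble(annotation_id = annotation_id, user = user, verdict = verdict,
                timestamp = iso_now(time))
  prj$verifications <- bind_rows(
    filter(prj$verifications, !(.data$annotation_id == .env$annotation_id & .data$user == .env$user)),
    row
  )
  row
}

#' Record that a user has screened a whole image
#'
#' Image-level verification drives completion in the cooperative and
#' competitive crowd modes ([image_complete()]).
#'
#' @inheritParams create_annotation
#' @return The record as a one-row tibble.
#' @export
verify_image <- function(prj, image_id, user, time = NULL) {
  check_project(prj)
  get_image(prj, image_id)
  row <- tibble(image_id = image_id, user = user, timestamp = iso_now(time))
  prj$image_verifications <- bind_rows(
    filter(prj$image_verifications, !(.data$image_id == .env$image_id & .data$user == .env$user)),
    row
  )
  row
}
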