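# Git-like snapshots of an image set's annotation state.
#
# Snapshots store full copies of the non-deleted annotation state, not
# deltas: state capture is the semantics wanted for reproducible training
# sets, and at desk scale copies are cheap. A snapshot is immutable except
# for artifact attachment; the single outside influence on its output is
# image deletion, which removes that image's annotations from every version
# (full-size slides are not versioned, so their annotations cannot outlive
# them).

#' Snapshot an image set's annotation state
#'
#' Freezes the set's current image list and all non-deleted annotations (and
#' their verification records) under a tag unique within the set. Later
#' edits never alter the snapshot.
#'
#' @param prj A [slide_project()].
#' @param set_id Image set to version.
#' @param tag Version tag, unique within the set.
#' @param description Optional free-text description.
#' @param time Snapshot time (`NULL` = now).
#' @return A one-row tibble describing the new version.
#' @export
snapshot <- function(prj, set_id, tag, description = NULL, time = NULL) {
  check_project(prj)
  s <- match(set_id, prj$image_sets$set_id)
  if (is.na(s)) abort(sprintf("unknown image set '%s'", set_id))
  stopifnot_scalar_chr(tag, "tag")
  same_set <- purrr::keep(prj$versions, ~ .x$set_id == set_id)
  if (tag %in% purrr::map_chr(same_set, "tag")) {
    abort(sprintf("version tag '%s' already exists in set '%s'", tag, set_id))
  }
  frozen_ids <- prj$image_sets$image_ids[[s]]
  frozen <- filter(prj$annotations, !.data$deleted, .data$image_id %in% frozen_ids)
  frozen_ver <- filter(prj$verifications, .data$annotation_id %in% frozen$annotation_id)
  version_id <- new_id(prj, "ver")
  prj$versions[[version_id]] <- list(
    version_id = version_id, set_id = set_id, tag = tag,
    description = description, created_at = iso_now(time),
    frozen_image_ids = frozen_ids, frozen_annotations = frozen,
    frozen_verifications = frozen_ver, artifacts = list()
  )
  version_row(prj$versions[[version_id]])
}

version_row <- function(v) {
  tibble(version_id = v$version_id, set_id = v$set_id, tag = v$tag,
         description = v$description %||% NA_character_, created_at = v$created_at,
         n_images = length(v$frozen_image_ids), n_annotations = nrow(v$frozen_annotations),
         n_artifacts = length(v$artifacts))
}

#' List a project's versions
#'
#' @inheritParams snapshot
#' @return A tibble, one row per version.
#' @export
versions <- function(prj) {
  check_project(prj)
  if (!length(prj$versions)) return(version_row(list(version_id = character(0)))[0, ])
  bind_rows(lapply(prj$versions, version_row))
}

resolve_version <- function(prj, version) {
  if (version %in% names(prj$versions)) return(prj$versions[[version]])
  hit <- purrr::keep(prj$versions, ~ .x$tag == version)
  if (length(hit) == 1L) return(hit[[1L]])
  abort(sprintf("unknown version '%s'", version))
}

#' Annotations frozen at a version
#'
#' Returns the snapshot's annotation state, optionally restricted to one
#' label. Annotations of images deleted from the project after the snapshot
#' are excluded — image deletion is the only mutation that reaches into
#' versions.
#'
#' @inheritParams snapshot
#' @param version Version id or tag.
#' @param label Template name or id to filter on (`NULL` = all labels).
#' @return A tibble of frozen annotations, ordered by image then annotation
#'   id.
#' @export
annotations_at_version <- function(prj, version, label = NULL) {
  check_project(prj)
  v <- resolve_version(prj, version)
  out <- filter(v$frozen_annotations, .data$image_id %in% prj$images$image_id)
  if (!is.null(label)) {
    ids <- label_to_template_ids(prj, label)
    out <- filter(out, .data$template_id %in% ids)
  }
  arrange(out, .data$image_id, .data$annotation_id)
}

#' Export a version to JSON or CSV
#'
#' Output is deterministic — annotations are sorted by image id then
#' annotation id and timestamps are fixed-format ISO-8601 — so exporting the
#' same snapshot twice yields identical bytes. Only public image names are
#' emitted. The JSON form round-trips through [import_set_json()].
#'
#' @inheritParams annotations_at_version
#' @param format `"json"` or `"csv"`.
#' @param path Output file (`NULL` = return the text invisibly without
#'   writing).
#' @return The exported text, invisibly.
#' @export
export_version <- function(prj, version, format = c("json", "csv"), path = NULL) {
  check_project(prj)
  format <- match.arg(format)
  v <- resolve_version(prj, version)
  anns <- annotations_at_version(prj, version)
  imgs <- filter(prj$images, .data$image_id %in% v$frozen_image_ids) |>
    arrange(.data$image_id)
  txt <- if (format == "json") {
    set_json_text(prj, imgs, anns, version = list(
      version_id = v$version_id, tag = v$tag,
      description = v$description %||% NA, created_at = v$created_at))
  } else {
    annotations_csv_text(prj, imgs, anns)
  }
  if (!is.null(path)) writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Attach a training artifact to a version
#'
#' Versions accumulate experiment outputs — performance metrics, exported
#' annotation files, model identifiers — without ever touching the frozen
#' annotation state.
#'
#' @inheritParams annotations_at_version
#' @param name Artifact name (unique per version; re-attaching replaces).
#' @param payload Any JSON-serialisable value (metrics list, file path, ...).
#' @param metadata Optional metadata list.
#' @return The updated version as a one-row tibble.
#' @export
attach_artifact <- function(prj, version, name, payload, metadata = list()) {
  check_project(prj)
  v <- resolve_version(prj, version)
  stopifnot_scalar_chr(name, "name")
  prj$versions[[v$version_id]]$artifacts[[name]] <-
    list(name = name, payload = payload, metadata = metadata)
  version_row(prj$versions[[v$version_id]])
}

#' Retrieve a version's artifacts
#'
#' @inheritParams attach_artifact
#' @param name One artifact by name, or `NULL` for the full named list.
#' @return The artifact (or list of artifacts).
#' @export
artifacts <- function(prj, version, name = NULL) {
  check_project(prj)
  v <- resolve_version(prj, version)
  if (is.null(name)) return(v$artifacts)
  if (!name %in% names(v$artifacts)) abort(sprintf("no artifact '%s'", name))
  v$artifacts[[name]]
}

#' Anonymise and deactivate a user
#'
#' Replaces the display name with an opaque token and marks the user
#' inactive; annotations keep their creator/last-editor identifiers
#' untouched, so versioned annotation content is unaffected. Idempotent.
#'
#' @inheritParams snapshot
#' @param user_id User to anonymise.
#' @return The updated user row, invisibly.
#' @export
anonymise_user <- function(prj, user_id) {
  check_project(prj)
  i <- match(user_id, prj$users$user_id)
  if (is.na(i)) abort(sprintf("unknown user '%s'", user_id))
  prj$users$display_name[i] <- sprintf("anonymous-%04d", fnv1a32(user_id) %% 10000)
  prj$users$active[i] <- FALSE
  invisible(prj$users[i, ])
}

#' Virtual train/validation/test split of a version's images
#'
#' Partitions the frozen image list into three disjoint subsets. Subset
#' sizes follow largest-remainder apportionment of the requested fractions
#' (deterministic and fraction-faithful); membership is a seeded permutation,
#' so a fixed seed reproduces the split exactly.
#'
#' @inheritParams annotations_at_version
#' @param fractions Numeric length-3 `(train, val, test)`, summing to 1.
#' @param seed Integer seed for the shuffle.
#' @return Named list of character vectors `train`, `val`, `test` whose
#'   union is the version's image list.
#' @export
virtual_split <- function(prj, version, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  check_project(prj)
  v <- resolve_version(prj, version)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    abort("`fractions` must be three non-negative numbers summing to 1")
  }
  ids <- v$frozen_image_ids
  n <- length(ids)
  sizes <- largest_remainder(n, fractions)
  shuffled <- withr::with_seed(seed, sample(ids, n))
  list(train = shuffled[seq_len(sizes[1])],
       val = shuffled[seq_len(sizes[2]) + sizes[1]],
       test = shuffled[seq_len(sizes[3]) + sizes[1] + sizes[2]])
}

# Largest-remainder (Hamilton) apportionment; ties go to the earlier part.
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  sizes <- floor(exact)
  left <- n - sum(sizes)
  if (left > 0) {
    ord <- order(exact - sizes, decreasing = TRUE)
    sizes[ord[seq_len(left)]] <- sizes[ord[seq_len(left)]] + 1
  }
  as.integer(sizes)
}
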