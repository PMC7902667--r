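# Serialisation: per-set annotation JSON (the exchange format), CSV export,
# and whole-project persistence as a directory of JSON documents + PNGs.
# Exports carry public image names only; the private (original) filename
# never leaves the project store through any export path.

to_json_text <- function(x) {
  paste0(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                          pretty = TRUE), "\n")
}

ann_to_list <- function(row) {
  list(
    annotation_id = row$annotation_id, image_id = row$image_id,
    template_id = row$template_id, vector = coords_to_flat(row$vector[[1L]]),
    creator = row$creator, last_editor = row$last_editor,
    created_at = row$created_at, edited_at = row$edited_at,
    meta = row$meta[[1L]], deleted = row$deleted
  )
}

anns_from_list <- function(lst) {
  if (!length(lst)) return(empty_annotations())
  bind_rows(lapply(lst, function(a) {
    tibble(annotation_id = a$annotation_id, image_id = a$image_id,
           template_id = a$template_id, vector = list(as_coord_matrix(a$vector)),
           creator = a$creator, last_editor = a$last_editor,
           created_at = a$created_at, edited_at = a$edited_at,
           meta = list(if (length(a$meta)) a$meta else list()),
           deleted = isTRUE(a$deleted))
  }))
}

set_json_text <- function(prj, imgs, anns, version = NULL) {
  tpl_list <- function(tid) {
    t <- get_template(prj, tid)
    list(template_id = t$template_id, name = t$name, kind = t$kind, colour = t$colour,
         default_width = if (is.na(t$default_width)) NULL else t$default_width,
         default_height = if (is.na(t$default_height)) NULL else t$default_height,
         sort_index = t$sort_index,
         shortcut = if (is.na(t$shortcut)) NULL else t$shortcut)
  }
  prods <- lapply(seq_len(nrow(prj$products)), function(i) {
    p <- prj$products[i, ]
    list(product_id = p$product_id, name = p$name, description = p$description,
         templates = lapply(p$template_ids[[1L]], tpl_list))
  })
  doc <- list(
    schema_version = 1L,
    images = lapply(seq_len(nrow(imgs)), function(i) {
      list(image_id = imgs$image_id[i], public_name = imgs$public_name[i],
           width = imgs$width[i], height = imgs$height[i], set_id = imgs$set_id[i])
    }),
    products = prods,
    annotations = lapply(seq_len(nrow(anns)), function(i) ann_to_list(anns[i, ]))
  )
  if (!is.null(version)) doc$version <- version
  to_json_text(doc)
}

csv_quote <- function(x) paste0('"', gsub('"', '""', x), '"')

annotations_csv_text <- function(prj, imgs, anns) {
  header <- "annotation_id,image_id,public_name,label,template_id,vector,creator,last_editor,created_at,edited_at"
  if (!nrow(anns)) return(paste0(header, "\n"))
  pub <- imgs$public_name[match(anns$image_id, imgs$image_id)]
  lab <- prj$templates$name[match(anns$template_id, prj$templates$template_id)]
  vec <- vapply(anns$vector, function(m) {
    as.character(jsonlite::toJSON(coords_to_flat(m), auto_unbox = TRUE, digits = NA))
  }, character(1))
  rows <- paste(anns$annotation_id, anns$image_id, csv_quote(pub), csv_quote(lab),
                anns$template_id, csv_quote(vec), csv_quote(anns$creator),
                csv_quote(anns$last_editor), anns$created_at, anns$edited_at, sep = ",")
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}

#' Export an image set's live annotation state as JSON
#'
#' One JSON document per set — `{images, products, annotations}` — with
#' ISO-8601 timestamps, stable field order and a stable sort (image id, then
#' annotation id), so identical states export to identical bytes.
#'
#' @param prj A [slide_project()].
#' @param set_id Image set to export.
#' @param path Output file (`NULL` = return text only).
#' @param include_deleted Include soft-deleted annotations.
#' @return The JSON text, invisibly.
#' @export
export_set_json <- function(prj, set_id, path = NULL, include_deleted = FALSE) {
  check_project(prj)
  s <- match(set_id, prj$image_sets$set_id)
  if (is.na(s)) abort(sprintf("unknown image set '%s'", set_id))
  imgs <- filter(prj$images, .data$set_id == .env$set_id) |> arrange(.data$image_id)
  anns <- annotations(prj, image_id = imgs$image_id, include_deleted = include_deleted)
  txt <- set_json_text(prj, imgs, anns)
  if (!is.null(path)) writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Import an image-set JSON document into a fresh project
#'
#' Inverse of [export_set_json()] / the JSON form of [export_version()]:
#' rebuilds images, products/templates and annotations under their original
#' identifiers. Because exports carry only public names, imported images use
#' the public name as their private name too.
#'
#' @param text JSON text, or `path` to read from.
#' @param path File to read when `text` is `NULL`.
#' @return A new [slide_project()] containing the imported set.
#' @export
import_set_json <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (!identical(as.integer(doc$schema_version), 1L)) {
    abort(sprintf("unsupported schema version '%s'", doc$schema_version))
  }
  prj <- slide_project("imported")
  set_ids <- unique(purrr::map_chr(doc$images, "set_id"))
  for (sid in set_ids) {
    prj$image_sets <- bind_rows(prj$image_sets,
      tibble(set_id = sid, name = sid, team = "default",
             image_ids = list(character()), product_ids = list(character())))
  }
  for (im in doc$images) {
    prj$images <- bind_rows(prj$images,
      tibble(image_id = im$image_id, private_name = im$public_name,
             public_name = im$public_name, width = as.integer(im$width),
             height = as.integer(im$height), set_id = im$set_id, meta = list(list())))
    s <- match(im$set_id, prj$image_sets$set_id)
    prj$image_sets$image_ids[[s]] <- c(prj$image_sets$image_ids[[s]], im$image_id)
  }
  for (p in doc$products) {
    tids <- character()
    for (t in p$templates) {
      if (!t$template_id %in% prj$templates$template_id) {
        prj$templates <- bind_rows(prj$templates,
          tibble(template_id = t$template_id, name = t$name, kind = t$kind,
                 colour = t$colour,
                 default_width = as.double(t$default_width %||% NA_real_),
                 default_height = as.double(t$default_height %||% NA_real_),
                 sort_index = as.integer(t$sort_index),
                 shortcut = t$shortcut %||% NA_character_))
      }
      tids <- c(tids, t$template_id)
    }
    prj$products <- bind_rows(prj$products,
      tibble(product_id = p$product_id, name = p$name,
             description = p$description %||% "", template_ids = list(tids)))
    for (sid in set_ids) attach_product(prj, sid, p$product_id)
  }
  prj$annotations <- anns_from_list(doc$annotations)
  advance_counters(prj)
  prj
}

# After an import, push id counters past every stored id so new entities
# cannot collide with imported ones.
advance_counters <- function(prj) {
  bump <- function(kind, ids) {
    num <- suppressWarnings(as.integer(sub(paste0("^", kind, "_"), "", ids)))
    num <- num[!is.na(num)]
    if (length(num)) prj$counters[[kind]] <- max(prj$counters[[kind]] %||% 0L, max(num))
  }
  bump("set", prj$image_sets$set_id); bump("img", prj$images$image_id)
  bump("tpl", prj$templates$template_id); bump("prod", prj$products$product_id)
  bump("ann", prj$annotations$annotation_id); bump("ver", names(prj$versions))
}

# --- whole-project persistence ---------------------------------------------

#' Save / load a whole project directory
#'
#' A project on disk is one directory of diffable JSON documents (registries,
#' annotations, verifications, versions, screening maps) plus `images/` with
#' one PNG per stored raster. `save_project()` is deterministic for a fixed
#' state; `load_project()` refuses a schema-version mismatch. Unlike the
#' export paths, persistence keeps private image names — it is the project's
#' own store, not an exchange format.
#'
#' @param prj A [slide_project()].
#' @param dir Project directory.
#' @return `save_project()`: `dir`, invisibly. `load_project()`: the restored
#'   project.
#' @export
save_project <- function(prj, dir) {
  check_project(prj)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  w <- function(x, f) writeLines(to_json_text(x), file.path(dir, f), sep = "")
  w(list(schema_version = prj$schema_version, name = prj$name, counters = prj$counters,
         users = df_to_list(prj$users),
         image_sets = df_to_list(prj$image_sets),
         templates = df_to_list(prj$templates),
         products = df_to_list(prj$products)), "project.json")
  w(df_to_list(prj$images), "images.json")
  w(lapply(seq_len(nrow(prj$annotations)), function(i) ann_to_list(prj$annotations[i, ])),
    "annotations.json")
  w(df_to_list(prj$verifications), "verifications.json")
  w(df_to_list(prj$image_verifications), "image_verifications.json")
  w(lapply(unname(prj$versions), function(v) {
    list(version_id = v$version_id, set_id = v$set_id, tag = v$tag,
         description = v$description, created_at = v$created_at,
         frozen_image_ids = as.list(v$frozen_image_ids),
         frozen_annotations = lapply(seq_len(nrow(v$frozen_annotations)),
                                     function(i) ann_to_list(v$frozen_annotations[i, ])),
         frozen_verifications = df_to_list(v$frozen_verifications),
         artifacts = v$artifacts)
  }), "versions.json")
  w(lapply(unname(prj$screening_maps), screening_to_list), "screening.json")
  for (id in sort(names(prj$rasters))) {
    png::writePNG(prj$rasters[[id]], file.path(dir, "images", paste0(id, ".png")))
  }
  invisible(dir)
}

df_to_list <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- lapply(df[i, ], function(col) {
      v <- if (is.list(col)) col[[1L]] else col
      if (length(v) == 1L && is.na(v) && !is.list(v)) NULL else v
    })
    row[!vapply(row, is.null, logical(1))]
  })
}

list_to_df <- function(lst, proto) {
  if (!length(lst)) return(proto)
  bind_rows(lapply(lst, function(row) {
    out <- proto[0, ]
    vals <- lapply(names(proto), function(nm) {
      v <- row[[nm]]
      if (is.list(proto[[nm]])) return(list(v %||% list()))
      if (is.null(v)) return(proto[[nm]][1L])  # typed NA from the empty prototype column
      v
    })
    names(vals) <- names(proto)
    tibble::as_tibble(vals)
  }))
}

#' @rdname save_project
#' @export
load_project <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("no project directory at '%s'", dir))
  rd <- function(f) jsonlite::fromJSON(file.path(dir, f), simplifyVector = FALSE)
  head_doc <- rd("project.json")
  if (!identical(as.integer(head_doc$schema_version), 1L)) {
    abort(sprintf("unsupported schema version '%s'", head_doc$schema_version))
  }
  prj <- slide_project(head_doc$name)
  prj$counters <- lapply(head_doc$counters, as.integer)
  prj$users <- list_to_df(head_doc$users, prj$users)
  sets <- list_to_df(head_doc$image_sets, prj$image_sets)
  if (nrow(sets)) {
    sets$image_ids <- lapply(sets$image_ids, function(x) as.character(unlist(x)))
    sets$product_ids <- lapply(sets$product_ids, function(x) as.character(unlist(x)))
  }
  prj$image_sets <- sets
  imgs <- list_to_df(rd("images.json"), prj$images)
  if (nrow(imgs)) { imgs$width <- as.integer(imgs$width); imgs$height <- as.integer(imgs$height) }
  prj$images <- imgs
  tpls <- list_to_df(head_doc$templates, prj$templates)
  if (nrow(tpls)) {
    tpls$default_width <- as.double(tpls$default_width)
    tpls$default_height <- as.double(tpls$default_height)
    tpls$sort_index <- as.integer(tpls$sort_index)
  }
  prj$templates <- tpls
  prods <- list_to_df(head_doc$products, prj$products)
  if (nrow(prods)) {
    prods$template_ids <- lapply(prods$template_ids, function(x) as.character(unlist(x)))
  }
  prj$products <- prods
  prj$annotations <- anns_from_list(rd("annotations.json"))
  prj$verifications <- list_to_df(rd("verifications.json"), prj$verifications)
  prj$image_verifications <- list_to_df(rd("image_verifications.json"), prj$image_verifications)
  for (v in rd("versions.json")) {
    prj$versions[[v$version_id]] <- list(
      version_id = v$version_id, set_id = v$set_id, tag = v$tag,
      description = v$description, created_at = v$created_at,
      frozen_image_ids = as.character(unlist(v$frozen_image_ids)),
      frozen_annotations = anns_from_list(v$frozen_annotations),
      frozen_verifications = list_to_df(v$frozen_verifications,
                                        tibble(annotation_id = character(), user = character(),
                                               verdict = character(), timestamp = character())),
      artifacts = v$artifacts
    )
  }
  for (sm in rd("screening.json")) {
    m <- screening_from_list(sm)
    prj$screening_maps[[screening_key(m)]] <- m
  }
  for (f in list.files(file.path(dir, "images"), pattern = "\\.png$", full.names = TRUE)) {
    id <- sub("\\.png$", "", basename(f))
    r <- png::readPNG(f)
    if (length(dim(r)) == 2L) r <- array(rep(r, 3L), c(dim(r), 3L))
    prj$rasters[[id]] <- r[, , 1:3, drop = FALSE]
  }
  prj
}
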