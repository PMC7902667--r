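#' Create an empty annotation project
#'
#' A `slide_project` is the in-memory store every other function operates on:
#' registries of images, image sets, annotation templates, products, users,
#' annotations, verification records and version snapshots, all held as
#' tibbles. It is environment-backed, so operations such as
#' [create_annotation()] update the store in place and return the affected
#' records as tibbles.
#'
#' @param name Project name.
#' @return A `slide_project` object.
#' @examples
#' prj <- slide_project("demo")
#' prj <- add_user(prj, "alice")
#' @export
slide_project <- function(name = "project") {
  stopifnot_scalar_chr(name, "name")
  prj <- new.env(parent = emptyenv())
  prj$name <- name
  prj$schema_version <- 1L
  prj$counters <- list()
  prj$users <- tibble(user_id = character(), display_name = character(), active = logical())
  prj$image_sets <- tibble(set_id = character(), name = character(), team = character(),
                           image_ids = list(), product_ids = list())
  prj$images <- tibble(image_id = character(), private_name = character(),
                       public_name = character(), width = integer(), height = integer(),
                       set_id = character(), meta = list())
  prj$templates <- tibble(template_id = character(), name = character(), kind = character(),
                          colour = character(), default_width = double(), default_height = double(),
                          sort_index = integer(), shortcut = character())
  prj$products <- tibble(product_id = character(), name = character(),
                         description = character(), template_ids = list())
  prj$annotations <- empty_annotations()
  prj$verifications <- tibble(annotation_id = character(), user = character(),
                              verdict = character(), timestamp = character())
  prj$image_verifications <- tibble(image_id = character(), user = character(),
                                    timestamp = character())
  prj$versions <- list()
  prj$screening_maps <- list()
  prj$rasters <- list()
  class(prj) <- "slide_project"
  prj
}

empty_annotations <- function() {
  tibble(annotation_id = character(), image_id = character(), template_id = character(),
         vector = list(), creator = character(), last_editor = character(),
         created_at = character(), edited_at = character(), meta = list(),
         deleted = logical())
}

#' @export
print.slide_project <- function(x, ...) {
  cat(sprintf("<slide_project '%s'>\n", x$name))
  cat(sprintf("  images: %d in %d set(s); templates: %d in %d product(s)\n",
              nrow(x$images), nrow(x$image_sets), nrow(x$templates), nrow(x$products)))
  cat(sprintf("  annotations: %d live, %d deleted; verifications: %d; versions: %d\n",
              sum(!x$annotations$deleted), sum(x$annotations$deleted),
              nrow(x$verifications), length(x$versions)))
  invisible(x)
}

#' One-row summary of a project
#'
#' @param x A `slide_project`.
#' @param ... Unused.
#' @return A one-row tibble of entity counts.
#' @method glance slide_project
#' @export
glance.slide_project <- function(x, ...) {
  tibble(name = x$name, n_images = nrow(x$images), n_sets = nrow(x$image_sets),
         n_templates = nrow(x$templates), n_annotations = sum(!x$annotations$deleted),
         n_deleted = sum(x$annotations$deleted), n_verifications = nrow(x$verifications),
         n_versions = length(x$versions))
}

#' Register a user
#'
#' @param prj A [slide_project()].
#' @param user_id Stable user identifier (never rewritten, even on
#'   anonymisation).
#' @param display_name Human-readable name; replaced by an opaque token when
#'   the user is anonymised.
#' @return The new user as a one-row tibble.
#' @export
add_user <- function(prj, user_id, display_name = user_id) {
  check_project(prj)
  stopifnot_scalar_chr(user_id, "user_id")
  if (user_id %in% prj$users$user_id) abort(sprintf("user '%s' already exists", user_id))
  row <- tibble(user_id = user_id, display_name = display_name, active = TRUE)
  prj$users <- bind_rows(prj$users, row)
  row
}

#' Create an image set
#'
#' Image sets act as folders for images; products attach to sets to fix the
#' annotation schema used on them.
#'
#' @inheritParams add_user
#' @param name,team Set name and owning team.
#' @return The new set as a one-row tibble.
#' @export
add_image_set <- function(prj, name, team = "default") {
  check_project(prj)
  stopifnot_scalar_chr(name, "name")
  set_id <- new_id(prj, "set")
  row <- tibble(set_id = set_id, name = name, team = team,
                image_ids = list(character()), product_ids = list(character()))
  prj$image_sets <- bind_rows(prj$image_sets, row)
  row
}

#' Define an annotation template
#'
#' A template is a label definition: geometry kind, display colour, sort
#' order, keyboard shortcut and a default size that enables single-click
#' annotation. Kind `global` is a whole-image classification and carries no
#' geometry.
#'
#' @inheritParams add_user
#' @param name Label name.
#' @param kind One of `"box"`, `"polygon"`, `"line"`, `"circle"`, `"global"`.
#' @param colour Display colour (any R colour string).
#' @param default_width,default_height Default size in pixels; required
#'   (positive) for box and circle templates before single-click use.
#' @param sort_index Display order.
#' @param shortcut Optional single-character keyboard shortcut.
#' @return The new template as a one-row tibble.
#' @export
add_template <- function(prj, name, kind = "box", colour = "#FF0000",
                         default_width = NA_real_, default_height = NA_real_,
                         sort_index = NA_integer_, shortcut = NA_character_) {
  check_project(prj)
  stopifnot_scalar_chr(name, "name")
  kind <- match.arg(kind, c("box", "polygon", "line", "circle", "global"))
  if (kind %in% c("box", "circle") && (!is.na(default_width) && default_width <= 0 ||
                                       !is.na(default_height) && default_height <= 0)) {
    abort("default sizes must be positive")
  }
  if (!is.na(shortcut) && nchar(shortcut) != 1L) abort("shortcut must be a single character")
  if (is.na(sort_index)) sort_index <- nrow(prj$templates) + 1L
  template_id <- new_id(prj, "tpl")
  row <- tibble(template_id = template_id, name = name, kind = kind, colour = colour,
                default_width = as.double(default_width), default_height = as.double(default_height),
                sort_index = as.integer(sort_index), shortcut = shortcut)
  prj$templates <- bind_rows(prj$templates, row)
  row
}

#' Group templates into a product
#'
#' Products bundle templates into a named annotation schema that can be
#' attached to image sets, enforcing one naming scheme across a study.
#' Template names within one product must be unique.
#'
#' @inheritParams add_user
#' @param name,description Product name and free-text description.
#' @param template_ids Templates in display order.
#' @return The new product as a one-row tibble.
#' @export
add_product <- function(prj, name, template_ids, description = "") {
  check_project(prj)
  stopifnot_scalar_chr(name, "name")
  missing <- setdiff(template_ids, prj$templates$template_id)
  if (length(missing)) abort(sprintf("unknown template(s): %s", paste(missing, collapse = ", ")))
  tnames <- prj$templates$name[match(template_ids, prj$templates$template_id)]
  if (anyDuplicated(tnames)) abort("template names within a product must be unique")
  product_id <- new_id(prj, "prod")
  row <- tibble(product_id = product_id, name = name, description = description,
                template_ids = list(as.character(template_ids)))
  prj$products <- bind_rows(prj$products, row)
  row
}

#' Add a template to an existing product
#'
#' Re-checks name uniqueness on every mutation.
#'
#' @inheritParams add_user
#' @param product_id,template_id Identifiers.
#' @return The updated product row, invisibly.
#' @export
product_add_template <- function(prj, product_id, template_id) {
  check_project(prj)
  i <- match(product_id, prj$products$product_id)
  if (is.na(i)) abort(sprintf("unknown product '%s'", product_id))
  if (!template_id %in% prj$templates$template_id) abort(sprintf("unknown template '%s'", template_id))
  ids <- unique(c(prj$products$template_ids[[i]], template_id))
  tnames <- prj$templates$name[match(ids, prj$templates$template_id)]
  if (anyDuplicated(tnames)) abort("template names within a product must be unique")
  prj$products$template_ids[[i]] <- ids
  invisible(prj$products[i, ])
}

#' Attach a product to an image set
#'
#' @inheritParams add_user
#' @param set_id,product_id Identifiers.
#' @return The updated set row, invisibly.
#' @export
attach_product <- function(prj, set_id, product_id) {
  check_project(prj)
  i <- match(set_id, prj$image_sets$set_id)
  if (is.na(i)) abort(sprintf("unknown image set '%s'", set_id))
  if (!product_id %in% prj$products$product_id) abort(sprintf("unknown product '%s'", product_id))
  prj$image_sets$product_ids[[i]] <- unique(c(prj$image_sets$product_ids[[i]], product_id))
  invisible(prj$image_sets[i, ])
}

#' Register an image in a set
#'
#' The original filename is kept as the image's private name and never leaves
#' the store through any export; a pseudonymised public name
#' (`yymmdd-hhmm-####`, see [pseudonymize()]) is generated at registration.
#' Should two registrations in one set collide on the public name, a
#' disambiguating counter is appended and flagged in the image's metadata.
#'
#' @inheritParams add_user
#' @param set_id Owning image set.
#' @param private_name Original filename (stays private).
#' @param width,height Image dimensions in pixels (strictly positive).
#' @param raster Optional in-memory pixel array (`height x width x 3`, values
#'   in `[0, 1]`) used by map builders and [region_reader()].
#' @param time Registration time (`NULL` = now); fixes the pseudonym prefix.
#' @return The new image as a one-row tibble (public name only is exported
#'   downstream).
#' @export
register_image <- function(prj, set_id, private_name, width, height,
                           raster = NULL, time = NULL) {
  check_project(prj)
  i <- match(set_id, prj$image_sets$set_id)
  if (is.na(i)) abort(sprintf("unknown image set '%s'", set_id))
  stopifnot_scalar_chr(private_name, "private_name")
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || is.na(height) || width <= 0L || height <= 0L) {
    abort("width and height must be strictly positive integers")
  }
  public <- pseudonymize(private_name, time)
  meta <- list()
  existing <- prj$images$public_name[prj$images$set_id == set_id]
  if (public %in% existing) {
    k <- 2L
    while (paste0(public, "-", k) %in% existing) k <- k + 1L
    public <- paste0(public, "-", k)
    meta$pseudonym_collision <- TRUE
  }
  image_id <- new_id(prj, "img")
  row <- tibble(image_id = image_id, private_name = private_name, public_name = public,
                width = width, height = height, set_id = set_id, meta = list(meta))
  prj$images <- bind_rows(prj$images, row)
  prj$image_sets$image_ids[[i]] <- c(prj$image_sets$image_ids[[i]], image_id)
  if (!is.null(raster)) prj$rasters[[image_id]] <- check_raster(raster, width, height)
  row
}

check_raster <- function(raster, width, height) {
  if (!is.array(raster) || length(dim(raster)) != 3L || dim(raster)[3] != 3L) {
    abort("raster must be a height x width x 3 array")
  }
  if (dim(raster)[1] != height || dim(raster)[2] != width) {
    abort("raster dimensions do not match the declared width/height")
  }
  raster
}

#' Delete an image from its set
#'
#' Removing an image discards its annotations everywhere: live state and
#' every version snapshot stop reporting them (full-resolution slides are too
#' large to version, so an image's removal cannot leave versioned annotations
#' behind). Implemented as filtering by surviving image ids, so re-registering
#' is possible without corrupting snapshots.
#'
#' @inheritParams add_user
#' @param image_id Image to remove.
#' @return The removed image row, invisibly.
#' @export
delete_image <- function(prj, image_id) {
  check_project(prj)
  i <- match(image_id, prj$images$image_id)
  if (is.na(i)) abort(sprintf("unknown image '%s'", image_id))
  row <- prj$images[i, ]
  prj$images <- prj$images[-i, ]
  s <- match(row$set_id, prj$image_sets$set_id)
  if (!is.na(s)) {
    prj$image_sets$image_ids[[s]] <- setdiff(prj$image_sets$image_ids[[s]], image_id)
  }
  prj$annotations <- filter(prj$annotations, .data$image_id != .env$image_id)
  prj$rasters[[image_id]] <- NULL
  invisible(row)
}

#' Accessors for project registries
#'
#' `images()`, `templates()`, `products()`, `image_sets()` and `users()`
#' return the corresponding registry as a tibble.
#'
#' @inheritParams add_user
#' @return A tibble.
#' @export
images <- function(prj) { check_project(prj); prj$images }

#' @rdname images
#' @export
templates <- function(prj) { check_project(prj); prj$templates }

#' @rdname images
#' @export
products <- function(prj) { check_project(prj); prj$products }

#' @rdname images
#' @export
image_sets <- function(prj) { check_project(prj); prj$image_sets }

#' @rdname images
#' @export
users <- function(prj) { check_project(prj); prj$users }

check_project <- function(prj) {
  if (!inherits(prj, "slide_project")) abort("`prj` must be a slide_project")
  invisible(prj)
}

get_image <- function(prj, image_id) {
  i <- match(image_id, prj$images$image_id)
  if (is.na(i)) abort(sprintf("unknown image '%s'", image_id))
  prj$images[i, ]
}

get_template <- function(prj, template_id) {
  i <- match(template_id, prj$templates$template_id)
  if (is.na(i)) abort(sprintf("unknown template '%s'", template_id))
  prj$templates[i, ]
}
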