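# Region readers: one contract for "give me pixels (x, y, w, h)" whether the
# source is an in-memory array, a PNG/TIFF file, or a project raster. Large
# pyramidal slides would plug in behind the same contract; desk-scale
# fixtures load fully and slice.

#' Open a raster source as a region reader
#'
#' A region reader answers [read_region()] requests for rectangular pixel
#' blocks. `region_reader()` wraps an in-memory `height x width x 3` array
#' (or a project image id); `open_image()` decodes a PNG or TIFF file.
#' Out-of-bounds requests are an error, never padded.
#'
#' @param x A numeric array `height x width x 3` with values in `[0, 1]`.
#' @param image_id Optional source image id carried along for tile indexes.
#' @return A `region_reader` object with `$width`, `$height`.
#' @export
region_reader <- function(x, image_id = NA_character_) {
  if (is.character(x) && length(x) == 1L) return(open_image(x, image_id = image_id))
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (!is.array(x) || length(dim(x)) != 3L) abort("expected a height x width x channels array")
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]   # drop alpha
  if (dim(x)[3] == 1L) x <- array(rep(x, 3L), c(dim(x)[1:2], 3L))
  structure(list(pixels = x, width = dim(x)[2], height = dim(x)[1],
                 image_id = image_id, source = "array"),
            class = "region_reader")
}

#' @rdname region_reader
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @export
open_image <- function(path, image_id = NA_character_) {
  if (!file.exists(path)) abort(sprintf("no such file: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  pix <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("unsupported raster format '.%s' (png/tif/tiff)", ext))
  )
  r <- region_reader(pix, image_id = image_id)
  r$source <- path
  r
}

#' @export
print.region_reader <- function(x, ...) {
  cat(sprintf("<region_reader %dx%d px (%s)>\n", x$width, x$height, x$source))
  invisible(x)
}

#' Read a rectangular pixel region
#'
#' @param reader A [region_reader()].
#' @param x,y Top-left corner (0-based pixels).
#' @param w,h Region size in pixels.
#' @return A `h x w x 3` array; exactly the requested size.
#' @export
read_region <- function(reader, x, y, w, h) {
  if (!inherits(reader, "region_reader")) abort("`reader` must be a region_reader")
  if (w <= 0 || h <= 0) abort("region size must be positive")
  if (x < 0 || y < 0 || x + w > reader$width || y + h > reader$height) {
    abort(sprintf("region (%s,%s,%s,%s) outside image %dx%d",
                  x, y, w, h, reader$width, reader$height))
  }
  reader$pixels[(y + 1):(y + h), (x + 1):(x + w), , drop = FALSE]
}

# Readers for a project's stored rasters, keyed by image id.
project_readers <- function(prj) {
  check_project(prj)
  lapply(stats::setNames(names(prj$rasters), names(prj$rasters)),
         function(id) region_reader(prj$rasters[[id]], image_id = id))
}

resolve_reader <- function(readers, image_id) {
  if (inherits(readers, "slide_project")) {
    r <- readers$rasters[[image_id]]
    if (is.null(r)) abort(sprintf("project stores no raster for image '%s'", image_id))
    return(region_reader(r, image_id = image_id))
  }
  if (inherits(readers, "region_reader")) return(readers)
  r <- readers[[image_id]]
  if (is.null(r)) abort(sprintf("no reader for image '%s'", image_id))
  if (!inherits(r, "region_reader")) r <- region_reader(r, image_id = image_id)
  r
}
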