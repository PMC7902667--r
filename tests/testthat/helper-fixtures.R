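# Shared fixtures, all generated in code at test time.

# Minimal project: one 100x100 image with a flat grey raster, box/polygon/
# circle/global templates, two users.
tiny_project <- function(width = 100L, height = 100L) {
  prj <- slide_project("tiny")
  add_user(prj, "alice")
  add_user(prj, "bob")
  set <- add_image_set(prj, "set-a")
  register_image(prj, set$set_id, "case_001.png", width, height,
                 raster = array(0.5, c(height, width, 3)),
                 time = "2021-02-23 14:05:00")
  add_template(prj, "tumour", kind = "box", default_width = 20, default_height = 10)
  add_template(prj, "vessel", kind = "polygon")
  add_template(prj, "nucleus", kind = "circle", default_width = 12, default_height = 12)
  add_template(prj, "slide_ok", kind = "global")
  add_template(prj, "trace", kind = "line")
  prj
}

tiny_ids <- function(prj) {
  list(img = images(prj)$image_id[[1L]], set = image_sets(prj)$set_id[[1L]],
       box = templates(prj)$template_id[[1L]], poly = templates(prj)$template_id[[2L]],
       circ = templates(prj)$template_id[[3L]], global = templates(prj)$template_id[[4L]],
       line = templates(prj)$template_id[[5L]])
}

# Synthetic cytology project shared by the map tests. Slide rendering
# dominates the cost, so the generated slide is cached (it is immutable
# data); the project is rebuilt per call because tests mutate it.
cyto_project <- local({
  cache <- NULL
  function(n_cells = 60, seed = 11, width = 640, height = 640) {
    key <- paste(n_cells, seed, width, height)
    if (is.null(cache) || cache$key != key) {
      slide <- generate_slide(synthetic_slide_spec(
        width = width, height = height, n_cells = n_cells, seed = seed))
      cache <<- list(key = key, slide = slide)
    }
    synthetic_project(cache$slide)
  }
})

# A box annotation at a given centre, for corpus-building loops.
add_box <- function(prj, img, tpl, cx, cy, w = 10, h = 10, user = "alice", time = NULL) {
  create_annotation(prj, img, tpl,
                    rbind(c(cx - w / 2, cy - h / 2), c(cx + w / 2, cy + h / 2)),
                    user = user, time = time)
}

# Lexicographic ISO-8601 comparison: +1 / 0 / -1.
iso_cmp <- function(a, b) (a > b) - (a < b)

export_version_text_for <- function(prj, set_id) {
  snapshot(prj, set_id, paste0("tmp", length(prj$versions)))
  paste(export_version(prj, utils::tail(names(prj$versions), 1), "csv"), collapse = "\n")
}

default_cell_classes_names <- function() {
  c("eosinophil", "mast_cell", "neutrophil", "macrophage", "lymphocyte")
}
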