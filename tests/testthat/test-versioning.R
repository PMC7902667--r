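ann_state_text <- function(anns) {
  paste(vapply(seq_len(nrow(anns)), function(i) {
    paste(jsonlite::toJSON(slidekit:::ann_to_list(anns[i, ]), auto_unbox = TRUE, digits = NA),
          collapse = "")
  }, character(1)), collapse = "\n")
}

seeded_corpus <- function(n = 12) {
  prj <- tiny_project(400L, 400L)
  id <- tiny_ids(prj)
  register_image(prj, id$set, "case_002.png", 400L, 400L,
                 raster = array(0.4, c(400, 400, 3)), time = "2021-02-23 14:06:00")
  imgs <- images(prj)$image_id
  withr::with_seed(7, {
    for (i in seq_len(n)) {
      add_box(prj, sample(imgs, 1), sample(c(id$box, id$circ), 1),
              runif(1, 20, 380), runif(1, 20, 380),
              time = sprintf("2021-03-01 10:%02d:00", i))
    }
  })
  prj
}

test_that("a snapshot is a deep copy: later edits never reach it", {
  prj <- seeded_corpus()
  id <- tiny_ids(prj)
  before <- annotations(prj)          # manual deep copy taken before the edits
  snapshot(prj, id$set, "v1", "baseline")
  target <- before$annotation_id[[1]]
  edit_annotation(prj, target, vector = rbind(c(0, 0), c(9, 9)), user = "bob")
  delete_annotation(prj, before$annotation_id[[2]], user = "bob")
  frozen <- annotations_at_version(prj, "v1")
  expect_equal(nrow(frozen), nrow(before))
  expect_equal(frozen$vector[[match(target, frozen$annotation_id)]],
               before$vector[[1]])
  expect_identical(ann_state_text(frozen), ann_state_text(before))
  # live state did change
  expect_equal(nrow(annotations(prj)), nrow(before) - 1L)
})

test_that("snapshots of empty sets work and duplicate tags are rejected", {
  prj <- tiny_project()
  id <- tiny_ids(prj)
  prj2 <- slide_project("empty")
  s <- add_image_set(prj2, "none")
  v <- snapshot(prj2, s$set_id, "v0")
  expect_equal(v$n_images, 0L)
  expect_equal(nrow(annotations_at_version(prj2, "v0")), 0L)
  snapshot(prj, id$set, "v1")
  expect_error(snapshot(prj, id$set, "v1"), "already exists")
  expect_error(annotations_at_version(prj, "nope"), "unknown version")
})

test_that("version output filters by label and follows image deletion", {
  prj <- tiny_project(300L, 300L)
  id <- tiny_ids(prj)
  img2 <- register_image(prj, id$set, "case_002.png", 300L, 300L,
                         time = "2021-02-23 14:06:00")
  for (i in 1:10) add_box(prj, id$img, id$box, 20 + i * 10, 50)
  for (i in 1:5) add_box(prj, img2$image_id, id$circ, 20 + i * 10, 50, w = 0, h = 0)
  # circles need centre+radius-point vectors, so build them directly
  snapshot(prj, id$set, "v1")
  expect_equal(nrow(annotations_at_version(prj, "v1", label = "tumour")), 10L)
  expect_equal(nrow(annotations_at_version(prj, "v1", label = "nucleus")), 5L)
  expect_equal(nrow(annotations_at_version(prj, "v1")), 15L)
  delete_image(prj, img2$image_id)
  expect_equal(nrow(annotations_at_version(prj, "v1")), 10L)
  expect_true(all(annotations_at_version(prj, "v1")$image_id == id$img))
})

test_that("exports are byte-stable, CSV-countable, and JSON round-trips", {
  prj <- seeded_corpus()
  id <- tiny_ids(prj)
  snapshot(prj, id$set, "v1")
  j1 <- export_version(prj, "v1", "json")
  j2 <- export_version(prj, "v1", "json")
  expect_identical(j1, j2)
  csv <- export_version(prj, "v1", "csv")
  lines <- strsplit(csv, "\n")[[1]]
  expect_equal(length(lines), nrow(annotations_at_version(prj, "v1")) + 1L)
  back <- import_set_json(j1)
  expect_identical(ann_state_text(annotations(back)),
                   ann_state_text(annotations_at_version(prj, "v1")))
  f <- withr::local_tempfile(fileext = ".json")
  export_version(prj, "v1", "json", path = f)
  expect_identical(paste(readLines(f), collapse = "\n"), sub("\n$", "", j1))
})

test_that("artifacts attach without touching frozen annotations", {
  prj <- seeded_corpus()
  id <- tiny_ids(prj)
  snapshot(prj, id$set, "v1")
  before <- ann_state_text(annotations_at_version(prj, "v1"))
  attach_artifact(prj, "v1", "metrics", list(f1 = 0.9, map50 = 0.74),
                  metadata = list(model = "detector-3"))
  expect_equal(artifacts(prj, "v1", "metrics")$payload$f1, 0.9)
  expect_identical(ann_state_text(annotations_at_version(prj, "v1")), before)
  expect_error(attach_artifact(prj, "v9", "x", 1), "unknown version")
  expect_error(artifacts(prj, "v1", "missing"), "no artifact")
  attach_artifact(prj, "v1", "metrics", list(f1 = 0.95))
  expect_equal(artifacts(prj, "v1", "metrics")$payload$f1, 0.95)
})

test_that("anonymising a user leaves annotation content byte-identical", {
  prj <- seeded_corpus(8)
  before <- ann_state_text(annotations(prj))
  anonymise_user(prj, "alice")
  expect_identical(ann_state_text(annotations(prj)), before)
  u <- users(prj)
  expect_false(u$active[u$user_id == "alice"])
  expect_match(u$display_name[u$user_id == "alice"], "^anonymous-\\d{4}$")
  tok <- u$display_name[u$user_id == "alice"]
  anonymise_user(prj, "alice")  # idempotent
  expect_identical(users(prj)$display_name[users(prj)$user_id == "alice"], tok)
  expect_error(anonymise_user(prj, "nobody"), "unknown user")
})

test_that("virtual splits follow largest-remainder sizes and are reproducible", {
  prj <- slide_project("p")
  s <- add_image_set(prj, "s")
  for (i in 1:10) register_image(prj, s$set_id, sprintf("im%02d.png", i), 10, 10,
                                 time = sprintf("2021-02-23 14:%02d:00", i))
  snapshot(prj, s$set_id, "v1")
  sp <- virtual_split(prj, "v1", c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(lengths(sp), c(train = 6L, val = 2L, test = 2L))
  expect_identical(sp, virtual_split(prj, "v1", c(0.6, 0.2, 0.2), seed = 1))
  expect_false(identical(sp, virtual_split(prj, "v1", c(0.6, 0.2, 0.2), seed = 2)))
  all10 <- virtual_split(prj, "v1", c(1, 0, 0), seed = 3)
  expect_equal(sort(all10$train), sort(images(prj)$image_id))
  expect_error(virtual_split(prj, "v1", c(0.5, 0.2, 0.2)), "summing to 1")

  # largest-remainder oracle over random fraction triples and sizes
  withr::with_seed(5, {
    for (k in 1:25) {
      n <- sample(1:40, 1)
      f <- runif(3); f <- f / sum(f)
      sizes <- slidekit:::largest_remainder(n, f)
      expect_equal(sum(sizes), n)
      # oracle: every floor is respected and remainders are served in order
      expect_true(all(sizes >= floor(n * f)))
      expect_true(all(sizes <= floor(n * f) + 1))
      extra <- which(sizes == floor(n * f) + 1)
      rem <- n * f - floor(n * f)
      if (length(extra) && length(setdiff(1:3, extra))) {
        expect_gte(min(rem[extra]) + 1e-9, max(rem[setdiff(1:3, extra)]) - 1e-9)
      }
    }
  })
})

test_that("split partitions are disjoint and cover the frozen image list", {
  prj <- slide_project("p")
  s <- add_image_set(prj, "s")
  for (i in 1:17) register_image(prj, s$set_id, sprintf("im%02d.png", i), 10, 10,
                                 time = sprintf("2021-02-23 14:%02d:00", i))
  snapshot(prj, s$set_id, "v1")
  withr::with_seed(8, {
    for (k in 1:10) {
      f <- runif(3); f <- f / sum(f)
      sp <- virtual_split(prj, "v1", f, seed = sample.int(1000, 1))
      ids <- unname(unlist(sp))
      expect_equal(sort(ids), sort(images(prj)$image_id))
      expect_false(anyDuplicated(ids) > 0)
    }
  })
})
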