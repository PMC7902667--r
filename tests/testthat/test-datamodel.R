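test_that("create_annotation enforces per-kind vector arity and bounds", {
  prj <- tiny_project()
  id <- tiny_ids(prj)
  a <- create_annotation(prj, id$img, id$box, rbind(c(10, 10), c(50, 40)), user = "alice")
  m <- a$vector[[1]]
  expect_equal(nrow(m), 2L)
  expect_lt(m[1, "x"], m[2, "x"])
  expect_lt(m[1, "y"], m[2, "y"])

  expect_error(create_annotation(prj, id$img, id$poly, rbind(c(1, 1), c(2, 2)), user = "alice"),
               "polygon requires")
  expect_error(create_annotation(prj, id$box, id$box, list(), user = "alice"), "unknown")
  expect_error(create_annotation(prj, id$img, id$box, rbind(c(-1, 0), c(5, 5)), user = "alice"),
               "outside image bounds")
  expect_error(create_annotation(prj, id$img, id$box, rbind(c(0, 0), c(101, 5)), user = "alice"),
               "outside image bounds")
  expect_error(create_annotation(prj, id$img, id$line, rbind(c(0, 0)), user = "alice"), "line")
  expect_error(create_annotation(prj, id$img, id$global, rbind(c(0, 0)), user = "alice"),
               "no geometry")
  g <- create_annotation(prj, id$img, id$global, NULL, user = "alice")
  expect_equal(nrow(g$vector[[1]]), 0L)
})

test_that("inverted box corners are normalised to the brute-force min/max corners", {
  prj <- tiny_project()
  id <- tiny_ids(prj)
  pts <- list(rbind(c(50, 40), c(10, 10)), rbind(c(10, 40), c(50, 10)),
              rbind(c(99, 1), c(1, 99)))
  for (p in pts) {
    got <- create_annotation(prj, id$img, id$box, p, user = "alice")$vector[[1]]
    # independent oracle: elementwise min/max over the raw points
    expect_equal(unname(got),
                 unname(rbind(c(min(p[, 1]), min(p[, 2])), c(max(p[, 1]), max(p[, 2])))))
  }
})

test_that("single-click places the template's default box centred on the click", {
  prj <- tiny_project()
  id <- tiny_ids(prj)
  a <- single_click_annotation(prj, id$img, id$box, 50, 50, user = "alice")
  expect_equal(unname(a$vector[[1]]), rbind(c(40, 45), c(60, 55)))
  c1 <- single_click_annotation(prj, id$img, id$circ, 50, 50, user = "alice")
  expect_equal(unname(c1$vector[[1]]), rbind(c(50, 50), c(56, 50)))
  expect_error(single_click_annotation(prj, id$img, id$poly, 50, 50, user = "alice"),
               "box or circle")
  expect_error(single_click_annotation(prj, id$img, id$box, 120, 50, user = "alice"),
               "outside image")
  prj2 <- tiny_project()
  id2 <- tiny_ids(prj2)
  nodefault <- add_template(prj2, "plain", kind = "box")
  expect_error(single_click_annotation(prj2, id2$img, nodefault$template_id, 5, 5, user = "a"),
               "default size")
})

test_that("border clicks clip to the image, matching rectangle intersection", {
  prj <- tiny_project()
  id <- tiny_ids(prj)
  big <- add_template(prj, "big", kind = "box", default_width = 20, default_height = 20)
  cases <- list(c(5, 5), c(95, 5), c(5, 95), c(99, 99), c(0, 50))
  for (cl in cases) {
    a <- single_click_annotation(prj, id$img, big$template_id, cl[1], cl[2], user = "alice")
    got <- a$vector[[1]]
    # independent oracle: intersect the centred rectangle with the image
    lo <- pmax(cl - 10, c(0, 0)); hi <- pmin(cl + 10, c(100, 100))
    expect_equal(unname(got), rbind(lo, hi), ignore_attr = TRUE)
    expect_gt((got[2, 1] - got[1, 1]) * (got[2, 2] - got[1, 2]), 0)
  }
})

test_that("edits track last_editor and advance edited_at; creator is immutable", {
  prj <- tiny_project()
  id <- tiny_ids(prj)
  a <- create_annotation(prj, id$img, id$box, rbind(c(10, 10), c(20, 20)),
                         user = "alice", time = "2021-01-01 10:00:00")
  expect_identical(a$creator, a$last_editor)
  expect_identical(a$created_at, a$edited_at)
  b <- edit_annotation(prj, a$annotation_id, template_id = id$box, user = "bob",
                       time = "2021-01-01 10:00:00")  # same instant: still advances
  expect_identical(b$creator, "alice")
  expect_identical(b$last_editor, "bob")
  expect_gt(iso_cmp(b$edited_at, b$created_at), 0)
  d <- edit_annotation(prj, a$annotation_id, vector = rbind(c(10, 10), c(20, 20)), user = "bob")
  expect_gt(iso_cmp(d$edited_at, b$edited_at), 0)
  delete_annotation(prj, a$annotation_id, user = "bob")
  expect_error(edit_annotation(prj, a$annotation_id, user = "bob"), "deleted")
  expect_equal(nrow(annotations(prj)), 0L)
  expect_equal(nrow(annotations(prj, include_deleted = TRUE)), 1L)
})

test_that("annotation JSON export round-trips every field", {
  prj <- tiny_project()
  id <- tiny_ids(prj)
  add_product(prj, "schema", c(id$box, id$poly, id$circ))
  attach_product(prj, id$set, products(prj)$product_id[[1]])
  create_annotation(prj, id$img, id$box, rbind(c(1, 2), c(30, 40)), user = "alice",
                    meta = list(note = "edge case", grade = 2.5), time = "2021-03-01 09:00:00")
  create_annotation(prj, id$img, id$poly, rbind(c(0, 0), c(10, 0), c(5, 8.5)),
                    user = "bob", time = "2021-03-01 09:01:00")
  create_annotation(prj, id$img, id$global, NULL, user = "bob", time = "2021-03-01 09:02:00")
  txt <- export_set_json(prj, id$set)
  back <- import_set_json(txt)
  orig <- annotations(prj)
  got <- annotations(back)
  expect_equal(nrow(got), nrow(orig))
  for (col in c("annotation_id", "image_id", "template_id", "creator", "last_editor",
                "created_at", "edited_at", "deleted")) {
    expect_identical(got[[col]], orig[[col]], label = col)
  }
  for (i in seq_len(nrow(orig))) {
    expect_equal(got$vector[[i]], orig$vector[[i]])
  }
  expect_equal(got$meta[[1]]$note, "edge case")
  expect_equal(got$meta[[1]]$grade, 2.5)
  # private filenames never appear in any export
  expect_false(grepl("case_001", txt, fixed = TRUE))
  expect_false(grepl("case_001", export_version_text_for(prj, id$set), fixed = TRUE))
})

test_that("random annotation corpora keep arity matched to kind (round-trip property)", {
  prj <- tiny_project()
  id <- tiny_ids(prj)
  withr::with_seed(42, {
    for (i in 1:40) {
      kind <- sample(c("box", "poly", "circ", "line"), 1)
      tpl <- id[[kind]]
      n <- switch(kind, box = 2L, circ = 2L, poly = sample(3:8, 1), line = sample(2:5, 1))
      m <- cbind(runif(n, 0, 100), runif(n, 0, 100))
      create_annotation(prj, id$img, tpl, m, user = "alice")
    }
  })
  back <- import_set_json(export_set_json(prj, id$set))
  anns <- annotations(back)
  kinds <- templates(prj)$kind[match(anns$template_id, templates(prj)$template_id)]
  ok <- vapply(seq_len(nrow(anns)), function(i) {
    n <- nrow(anns$vector[[i]])
    switch(kinds[i], box = n == 2L, circle = n == 2L, polygon = n >= 3L,
           line = n >= 2L, global = n == 0L)
  }, logical(1))
  expect_true(all(ok))
  for (i in seq_len(nrow(anns))) expect_equal(back$annotations$vector[[i]],
                                              prj$annotations$vector[[i]])
})

test_that("template names must stay unique within a product", {
  prj <- tiny_project()
  t1 <- templates(prj)$template_id[[1]]
  dup <- add_template(prj, "tumour", kind = "polygon")  # same name, other kind
  expect_error(add_product(prj, "p", c(t1, dup$template_id)), "unique")
  p <- add_product(prj, "p", t1)
  expect_error(product_add_template(prj, p$product_id, dup$template_id), "unique")
  ok <- add_template(prj, "stroma", kind = "polygon")
  product_add_template(prj, p$product_id, ok$template_id)
  expect_length(products(prj)$template_ids[[1]], 2L)
})

test_that("image registration validates dimensions and pseudonymises names", {
  prj <- slide_project("p")
  set <- add_image_set(prj, "s")
  expect_error(register_image(prj, set$set_id, "a.png", 0, 10), "strictly positive")
  expect_error(register_image(prj, set$set_id, "a.png", 10, -1), "strictly positive")
  img <- register_image(prj, set$set_id, "patient_mueller_2020.png", 10, 10,
                        time = "2021-02-23 14:05:00")
  expect_match(img$public_name, "^\\d{6}-\\d{4}-\\d{4}$")
  expect_false(grepl("mueller", img$public_name))
  # same name, same minute: collision resolved with a counter + meta flag
  img2 <- register_image(prj, set$set_id, "patient_mueller_2020.png", 10, 10,
                         time = "2021-02-23 14:05:30")
  expect_match(img2$public_name, "^\\d{6}-\\d{4}-\\d{4}-2$")
  expect_true(img2$meta[[1]]$pseudonym_collision)
  expect_false(anyDuplicated(images(prj)$public_name) > 0)
})
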