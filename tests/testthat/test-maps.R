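rects_disjoint <- function(tiles) {
  n <- nrow(tiles)
  if (n < 2) return(TRUE)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (tiles$px[i] < tiles$px[j] + tiles$pw[j] && tiles$px[j] < tiles$px[i] + tiles$pw[i] &&
        tiles$py[i] < tiles$py[j] + tiles$ph[j] && tiles$py[j] < tiles$py[i] + tiles$ph[i]) {
      return(FALSE)
    }
  }
  TRUE
}

test_that("annotation maps lay tiles out row-major with exact geometry", {
  prj <- cyto_project()
  lab <- templates(prj)$template_id[[1]]
  n <- nrow(annotations(prj, label = lab))
  expect_gte(n, 2)
  am <- build_annotation_map(prj, label = lab, tile_size = 32, tiles_per_row = 4,
                             render = FALSE)
  t <- tidy(am)
  expect_equal(nrow(t), n)
  # brute-force layout oracle: tile k sits at (k %% 4, k %/% 4) cells
  for (k in seq_len(n)) {
    expect_equal(t$px[k], ((k - 1) %% 4) * 32)
    expect_equal(t$py[k], ((k - 1) %/% 4) * 32)
  }
  expect_equal(am$canvas_width, 4 * 32)
  expect_equal(am$canvas_height, ceiling(n / 4) * 32)
  expect_true(rects_disjoint(t))
  expect_false(anyDuplicated(t$annotation_id) > 0)
  # stable order: by source image id then annotation id
  expect_equal(t$annotation_id, sort(t$annotation_id))
})

test_that("empty label and global labels behave at the edges", {
  prj <- tiny_project()
  id <- tiny_ids(prj)
  am <- build_annotation_map(prj, label = "tumour", tiles_per_row = 4)
  expect_equal(nrow(am$tiles), 0L)
  create_annotation(prj, id$img, id$global, NULL, user = "alice")
  expect_error(build_annotation_map(prj, label = "slide_ok"), "no geometry")
  expect_error(build_annotation_map(prj, label = "tumour", tiles_per_row = 0), ">= 1")
})

test_that("map_to_source inverts the crop-resize transform exactly", {
  prj <- cyto_project()
  lab <- templates(prj)$template_id[[1]]
  am <- build_annotation_map(prj, label = lab, tile_size = 32, tiles_per_row = 4,
                             render = FALSE)
  t <- tidy(am)
  for (k in seq_len(min(5, nrow(t)))) {
    hit <- map_to_source(am, t$px[k] + 16, t$py[k] + 16)   # tile centre
    expect_identical(hit$annotation_id, t$annotation_id[k])
    expect_equal(hit$x, t$sx[k] + t$sw[k] / 2)
    expect_equal(hit$y, t$sy[k] + t$sh[k] / 2)
    corner <- map_to_source(am, t$px[k], t$py[k])          # tile origin
    expect_equal(c(corner$x, corner$y), c(t$sx[k], t$sy[k]))
    # analytic inverse at an arbitrary interior point
    q <- map_to_source(am, t$px[k] + 7, t$py[k] + 21)
    expect_equal(q$x, t$sx[k] + 7 / 32 * t$sw[k])
    expect_equal(q$y, t$sy[k] + 21 / 32 * t$sh[k])
  }
  # below the last partial row there is empty canvas: no tile hit
  if (nrow(t) %% 4 != 0) {
    expect_null(map_to_source(am, am$canvas_width - 1, am$canvas_height - 1))
  }
  expect_error(map_to_source(am, am$canvas_width + 5, 0), "outside the map canvas")
})

test_that("tile-centre enumeration is a bijection onto the annotations", {
  prj <- cyto_project()
  lab <- templates(prj)$template_id[[1]]
  am <- build_annotation_map(prj, label = lab, tile_size = 32, tiles_per_row = 5,
                             render = FALSE)
  t <- tidy(am)
  hits <- vapply(seq_len(nrow(t)),
                 function(k) map_to_source(am, t$px[k] + t$pw[k] / 2,
                                           t$py[k] + t$ph[k] / 2)$annotation_id,
                 character(1))
  expect_setequal(hits, annotations(prj, label = lab)$annotation_id)
  expect_false(anyDuplicated(hits) > 0)
})

test_that("corrections on a map land on the source annotation only", {
  prj <- cyto_project()
  tpls <- templates(prj)$template_id
  lab <- tpls[[1]]; other <- tpls[[2]]
  am <- build_annotation_map(prj, label = lab, tile_size = 32, render = FALSE)
  target <- am$tiles$annotation_id[[1]]
  before <- annotations(prj)
  am2 <- apply_map_correction(prj, am, target, "relabel", template_id = other, user = "bob")
  expect_true(am2$tiles$stale[[1]])
  after <- annotations(prj)
  # field-level diff: exactly one row changed, and only its template/editor/time
  changed <- which(vapply(seq_len(nrow(before)), function(i) {
    !identical(slidekit:::ann_to_list(before[i, ]), slidekit:::ann_to_list(after[i, ]))
  }, logical(1)))
  expect_equal(before$annotation_id[changed], target)
  i <- changed[[1]]
  expect_identical(after$template_id[i], other)
  expect_identical(after$vector[[i]], before$vector[[i]])
  expect_identical(after$creator[i], before$creator[i])
  # rebuilding per-label maps moves the tile between labels
  expect_false(target %in% build_annotation_map(prj, label = lab, render = FALSE)$tiles$annotation_id)
  expect_true(target %in% build_annotation_map(prj, label = other, render = FALSE)$tiles$annotation_id)

  # delete + confirm corrections
  dm <- apply_map_correction(prj, am2, am2$tiles$annotation_id[[2]], "delete", user = "bob")
  expect_true(annotations(prj, include_deleted = TRUE)$deleted[
    annotations(prj, include_deleted = TRUE)$annotation_id == dm$tiles$annotation_id[[2]]])
  apply_map_correction(prj, am2, am2$tiles$annotation_id[[3]], "confirm", user = "carol")
  v <- prj$verifications
  expect_true(any(v$annotation_id == am2$tiles$annotation_id[[3]] &
                  v$user == "carol" & v$verdict == "confirmed"))
  expect_error(apply_map_correction(prj, am2, "ann_9999", "delete"), "no tile")
  expect_error(apply_map_correction(prj, am2, target, "relabel", template_id = "tpl_9999"),
               "unknown template")
})

test_that("cluster maps place every tile on a free cell near its embedding", {
  prj <- cyto_project()
  ft <- generate_feature_table(prj)
  emb <- reduce_features(ft, "pca")
  cm <- build_cluster_map(prj, emb, tile_size = 32, canvas_width = 640,
                          canvas_height = 640, render = FALSE)
  t <- tidy(cm)
  expect_equal(nrow(t), nrow(emb))
  expect_true(rects_disjoint(t))
  expect_true(all(t$px >= 0 & t$py >= 0 &
                  t$px + t$pw <= 640 & t$py + t$ph <= 640))
  expect_true(all(t$px %% 32 == 0 & t$py %% 32 == 0))

  # n = 1: lands exactly on its scaled cell (the origin cell by convention)
  one <- build_cluster_map(prj, emb[1, ], tile_size = 32, canvas_width = 128,
                           canvas_height = 128, render = FALSE)
  expect_equal(c(one$tiles$px, one$tiles$py), c(0, 0))

  # identical coordinates: second point takes an adjacent free cell
  two <- emb[1:2, ]; two$u <- c(0, 0); two$v <- c(0, 0)
  cm2 <- build_cluster_map(prj, two, tile_size = 32, canvas_width = 128,
                           canvas_height = 128, render = FALSE)
  expect_true(rects_disjoint(cm2$tiles))
  d <- abs(cm2$tiles$px[1] - cm2$tiles$px[2]) + abs(cm2$tiles$py[1] - cm2$tiles$py[2])
  expect_equal(d, 32)

  expect_error(build_cluster_map(prj, emb, tile_size = 320, canvas_width = 320,
                                 canvas_height = 320), "canvas holds")
})

test_that("greedy placement displaces less than random assignment (Monte Carlo)", {
  prj <- cyto_project()
  emb <- reduce_features(generate_feature_table(prj), "pca")
  tw <- 32; W <- 640
  cm <- build_cluster_map(prj, emb, tile_size = tw, canvas_width = W,
                          canvas_height = W, render = FALSE)
  ncx <- W %/% tw
  scale01 <- function(z) if (max(z) > min(z)) (z - min(z)) / (max(z) - min(z)) else rep(0, length(z))
  ideal <- cbind((scale01(emb$u) * (ncx - 1) + 0.5) * tw,
                 (scale01(emb$v) * (ncx - 1) + 0.5) * tw)
  placed <- cbind(cm$tiles$px + tw / 2, cm$tiles$py + tw / 2)
  disp_greedy <- sum(sqrt(rowSums((ideal - placed)^2)))
  cells <- expand.grid(x = (seq_len(ncx) - 0.5) * tw, y = (seq_len(ncx) - 0.5) * tw)
  disp_random <- withr::with_seed(13, vapply(1:100, function(k) {
    pick <- cells[sample(nrow(cells), nrow(emb)), ]
    sum(sqrt(rowSums((ideal - as.matrix(pick))^2)))
  }, numeric(1)))
  expect_lte(disp_greedy, min(disp_random))
})

test_that("density maps bin scores over [0,4] and stack columns bottom-up", {
  prj <- tiny_project(500L, 500L)
  id <- tiny_ids(prj)
  scores <- c(0, 0, 4, 2.05, 2.04, 3.99)
  for (i in seq_along(scores)) {
    create_annotation(prj, id$img, id$box, rbind(c(10 * i, 10), c(10 * i + 8, 18)),
                      user = "alice", meta = list(score = scores[i]))
  }
  dm <- build_density_map(prj, tile_size = 16, n_bins = 5, render = FALSE)
  cols <- density_columns(dm)
  expect_equal(nrow(cols), 5L)
  expect_equal(sum(cols$count), length(scores))
  expect_equal(cols$count[1], 2L)          # the two zeros
  expect_equal(cols$count[5], 2L)          # 3.99 and exactly 4.0: last bin is right-closed
  expect_equal(cols$score_lo[1], 0)
  expect_equal(cols$score_hi[5], 4)
  t <- tidy(dm)
  expect_true(rects_disjoint(t))
  # within a column, lower score sits lower (greater y) in the stack
  col5 <- t[t$px == 4 * 16, ]
  expect_equal(col5$score[order(-col5$py)], sort(col5$score))
  # bottom tile of each column touches the canvas bottom
  for (px in unique(t$px)) {
    expect_equal(max(t$py[t$px == px]) + 16, dm$canvas_height)
  }
  expect_error(build_density_map(prj, scores = rep(5, nrow(annotations(prj))),
                                 render = FALSE), "\\[0, 4\\]")
})

test_that("density column conservation holds for random score sets", {
  prj <- tiny_project(2000L, 50L)
  id <- tiny_ids(prj)
  withr::with_seed(21, {
    n <- 80
    for (i in seq_len(n)) {
      create_annotation(prj, id$img, id$box, rbind(c(20 * i, 10), c(20 * i + 9, 19)),
                        user = "alice", meta = list(score = runif(1, 0, 4)))
    }
  })
  for (nb in c(1, 5, 41)) {
    dm <- build_density_map(prj, tile_size = 8, n_bins = nb, render = FALSE)
    expect_equal(sum(density_columns(dm)$count), 80L)
    expect_equal(dm$canvas_width, nb * 8L)
  }
})

test_that("rendered maps write a PNG plus a faithful sidecar tile index", {
  prj <- cyto_project()
  lab <- templates(prj)$template_id[[1]]
  am <- build_annotation_map(prj, label = lab, tile_size = 24, tiles_per_row = 6)
  f <- file.path(withr::local_tempdir(), "map.png")
  write_validation_map(am, f)
  expect_true(file.exists(f))
  png_back <- png::readPNG(f)
  expect_equal(dim(png_back)[1:2], c(am$canvas_height, am$canvas_width))
  idx <- jsonlite::fromJSON(sub("png$", "json", f), simplifyVector = FALSE)
  expect_equal(length(idx$tiles), nrow(am$tiles))
  expect_identical(idx$tiles[[1]]$annotation_id, am$tiles$annotation_id[[1]])
  expect_equal(idx$tiles[[1]]$placed_rect$w, 24)
})
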