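test_that("IoT limit values: containment gives exactly 1, disjoint or outside-touch exactly 0", {
  u <- make_union(rect_ring(0, 0, 1024, 1024))
  expect_identical(compute_iot(u, tile_footprint(0, 0, 512, 512)), 1)
  # touching the region boundary from inside still scores 1
  expect_identical(compute_iot(u, tile_footprint(512, 512, 512, 512)), 1)
  # sharing only one edge from outside scores 0
  expect_identical(compute_iot(u, tile_footprint(1024, 0, 512, 512)), 0)
  # fully disjoint scores 0
  expect_identical(compute_iot(u, tile_footprint(1124, 0, 512, 512)), 0)
  # empty union is legal and scores 0
  empty <- region_union(annotation_set("s", list()), "tumor")
  expect_identical(compute_iot(empty, tile_footprint(0, 0, 512, 512)), 0)
})

test_that("partial overlap gives the exact covered fraction", {
  u <- make_union(rect_ring(256, 0, 1024, 1024))
  expect_equal(compute_iot(u, tile_footprint(0, 0, 512, 512)), 0.5)
  # axis-aligned overlap fractions multiply
  u2 <- make_union(rect_ring(256, 256, 1280, 1280))
  expect_equal(compute_iot(u2, tile_footprint(0, 0, 512, 512)), 0.25)
})

test_that("region_union has set-union semantics", {
  a <- annotated_region("tumor", rect_ring(0, 0, 100, 100))
  b <- annotated_region("tumor", rect_ring(300, 0, 400, 100))
  u <- region_union(annotation_set("s", list(a, b)), "tumor")
  expect_equal(u$area, 20000)

  # idempotence: identical overlapping squares union to one square
  u2 <- region_union(annotation_set("s", list(a, a)), "tumor")
  expect_equal(u2$area, 10000, tolerance = 1e-9)

  # overlapping annotations never push IoT above 1
  tile <- tile_footprint(0, 0, 100, 100)
  expect_equal(compute_iot(u2, tile), 1)

  # holes subtract: square minus centered quarter-side hole, against the
  # shoelace-with-hole expectation
  s <- 200
  hole <- rect_ring(75, 75, 75 + s / 4, 75 + s / 4)
  r <- annotated_region("tumor", rect_ring(0, 0, s, s), holes = list(hole))
  u3 <- region_union(annotation_set("s", list(r)), "tumor")
  expect_equal(u3$area, shoelace(rect_ring(0, 0, s, s)) - shoelace(hole),
               tolerance = 1e-9)

  # label filter: empty selection yields a legal empty union
  expect_equal(region_union(annotation_set("s", list(a)), "nonexistent")$area, 0)
})

test_that("IoT is invariant under joint scaling and translation to 1e-9", {
  set.seed(7)
  for (rep in 1:20) {
    poly <- random_star_poly(600, 600, 150, 450, n = 10)
    tile0 <- c(runif(1, 200, 700), runif(1, 200, 700), 512, 512)
    base <- compute_iot(make_union(poly), do.call(tile_footprint, as.list(tile0)))
    for (k in c(0.5, 3, 17.2)) {
      scaled <- compute_iot(make_union(poly * k),
                            tile_footprint(tile0[1] * k, tile0[2] * k,
                                           tile0[3] * k, tile0[4] * k))
      expect_lt(abs(scaled - base), 1e-9)
    }
    for (shift in list(c(13, 0), c(0, 1317.25), c(211.5, 97))) {
      moved <- compute_iot(make_union(sweep(poly, 2, shift, "+")),
                           tile_footprint(tile0[1] + shift[1], tile0[2] + shift[2],
                                          tile0[3], tile0[4]))
      expect_lt(abs(moved - base), 1e-9)
    }
  }
})

test_that("IoT stays in [0,1] and matches containment/disjointness exactly", {
  set.seed(11)
  for (rep in 1:50) {
    poly <- random_star_poly(500, 500, 100, 400, n = 8)
    tf <- tile_footprint(runif(1, 0, 900), runif(1, 0, 900),
                         runif(1, 50, 400), runif(1, 50, 400))
    u <- make_union(poly)
    v <- compute_iot(u, tf)
    expect_gte(v, 0)
    expect_lte(v, 1)
    corners <- rbind(c(tf$x, tf$y), c(tf$x + tf$w, tf$y),
                     c(tf$x, tf$y + tf$h), c(tf$x + tf$w, tf$y + tf$h))
    mids <- rbind(c(tf$x + tf$w / 2, tf$y), c(tf$x + tf$w / 2, tf$y + tf$h),
                  c(tf$x, tf$y + tf$h / 2), c(tf$x + tf$w, tf$y + tf$h / 2))
    pts <- rbind(corners, mids)
    # if the tile box is disjoint from the region bbox, IoT must be exactly 0
    bb <- u$bbox
    if (tf$x >= bb[3] || tf$x + tf$w <= bb[1] || tf$y >= bb[4] || tf$y + tf$h <= bb[2]) {
      expect_identical(v, 0)
    }
    # star polygons are star-shaped around the center: a tile whose corners
    # and midpoints are all outside the circumscribed radius is disjoint
    rmax <- max(sqrt((poly[, 1] - 500)^2 + (poly[, 2] - 500)^2))
    if (all(sqrt((pts[, 1] - 500)^2 + (pts[, 2] - 500)^2) > rmax * 1.5)) {
      expect_identical(v, 0)
    }
  }
  # containment iff 1: a tile inside the inscribed box of a disc
  disc <- make_union(cbind(500 + 300 * cos(2 * pi * (0:63) / 64),
                           500 + 300 * sin(2 * pi * (0:63) / 64)))
  expect_identical(compute_iot(disc, tile_footprint(400, 400, 200, 200)), 1)
  expect_lt(compute_iot(disc, tile_footprint(250, 250, 500, 500)), 1)
})

test_that("exact IoT agrees with the rasterized oracle on random polygons and crescents", {
  set.seed(123)
  g <- 512
  tol <- 2 / g + 1e-6
  for (rep in 1:40) {
    shape <- rep %% 2 == 0
    poly <- if (shape) {
      crescent_ring(500, 500, runif(1, 250, 400), runif(1, 100, 300), runif(1, 120, 260))
    } else {
      random_star_poly(500, 500, 100, 450, n = sample(6:20, 1))
    }
    u <- make_union(poly)
    tf <- tile_footprint(runif(1, 100, 600), runif(1, 100, 600),
                         runif(1, 100, 500), runif(1, 100, 500))
    expect_lt(abs(compute_iot(u, tf) - rasterized_iot_oracle(u, tf, g)), tol)
  }
})

test_that("the rasterized oracle is exact on aligned half-splits and limit cases", {
  u <- make_union(rect_ring(0, 0, 1024, 1024))
  expect_equal(rasterized_iot_oracle(u, tile_footprint(0, 0, 512, 512), 64), 1)
  expect_equal(rasterized_iot_oracle(u, tile_footprint(2000, 0, 512, 512), 64), 0)
  # boundary falls between sample columns: exactly 0.5
  uh <- make_union(rect_ring(256, 0, 1024, 1024))
  expect_identical(rasterized_iot_oracle(uh, tile_footprint(0, 0, 512, 512), 512), 0.5)
  expect_error(rasterized_iot_oracle(u, tile_footprint(0, 0, 512, 512), 8), "g >= 16")
})

test_that("tile footprints validate their invariants", {
  expect_error(tile_footprint(-1, 0, 512, 512), "x >= 0")
  expect_error(tile_footprint(0, 0, 0, 512), "w > 0")
  tf <- tile_footprint(512, 1024, 512, 512, level = 1)
  expect_equal(tf$w * tf$h, 512^2)
})
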