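test_that("grid partition drops partial edge tiles and is deterministic row-major", {
  g <- partition_grid(2048, 1536, 512)
  expect_equal(nrow(g), 12)
  expect_equal(g$x[1:4], c(0, 512, 1024, 1536))  # x inner
  expect_equal(g$y[1:4], rep(0, 4))              # y outer
  expect_equal(nrow(partition_grid(700, 700, 512)), 1)
  expect_equal(nrow(partition_grid(511, 511, 512)), 0)
  # completeness: total area and no overlaps
  expect_equal(sum(g$w * g$h), floor(2048 / 512) * floor(1536 / 512) * 512^2)
  expect_equal(anyDuplicated(g[, c("x", "y")]), 0)
})

test_that("annotated extraction gates on IoT then BoT with inclusive thresholds", {
  fx <- get_fixture("basic")
  h <- open_slide(fx$slide_path)
  ann <- parse_annotations(fx$annotation_path)
  m <- extract_annotated(h, ann, extraction_config(iot_thresh = 1, tot_thresh = 0,
                                                   labels = "tumor"))
  expect_equal(m$counts$extracted, 4)
  expect_equal(nrow(m$records), 16)  # every grid location exactly once
  expect_true(all(m$records$decision[m$records$iot < 1] == "rejected_iot"))
  # short-circuit: BoT never computed for IoT-rejected tiles
  expect_true(all(is.na(m$records$bot[m$records$decision == "rejected_iot"])))
  expect_true(all(!is.na(m$records$bot[m$records$decision == "extracted"])))
  # iot_thresh = 0 admits every tile to the background stage
  m0 <- extract_annotated(h, ann, extraction_config(iot_thresh = 0, tot_thresh = 0.2,
                                                    labels = "tumor"))
  expect_true(all(!is.na(m0$records$bot)))
  expect_equal(m0$counts$extracted, 4)  # only the solid-tissue tiles have tissue
})

test_that("no tile raster is read for tiles failing the IoT gate", {
  fx <- get_fixture("basic")
  h <- open_slide(fx$slide_path)
  ann <- parse_annotations(fx$annotation_path)
  before <- slide_read_count(h)
  m <- extract_annotated(h, ann, extraction_config(iot_thresh = 1, tot_thresh = 0,
                                                   labels = "tumor"))
  n_pass <- sum(m$records$iot >= 1)
  expect_equal(slide_read_count(h) - before, n_pass)
})

test_that("an annotation drawn over pure background yields only rejected_bot", {
  spec <- fixture_spec(canvas = c(1024, 1024), blobs = list(),
                       annotations = list(list(label = "tumor",
                                               exterior = rect_ring(0, 0, 1024, 1024))),
                       levels = 1, tile_size = 512)
  fx <- generate_fixture(spec, withr::local_tempdir(), "whiteslide")
  h <- open_slide(fx$slide_path)
  m <- extract_annotated(h, fx$annotations,
                         extraction_config(iot_thresh = 0.1, tot_thresh = 0.2,
                                           labels = "tumor"))
  expect_equal(m$counts$extracted, 0)
  expect_true(all(m$records$decision == "rejected_bot"))
})

test_that("holistic extraction uses the background gate only", {
  h <- open_slide(get_fixture("checkerboard")$slide_path)
  m <- extract_holistic(h, extraction_config(tot_thresh = 0.5))
  expect_true(all(is.na(m$records$iot)))  # not computed, not zero
  # exactly the tissue cells of the checkerboard pass
  gt <- get_fixture("checkerboard")$ground_truth
  expect_equal(m$records$decision == "extracted", gt$tissue_frac == 1)
  # an all-background slide extracts nothing at tot_thresh > 0, everything at 0
  spec <- fixture_spec(canvas = c(1024, 1024), levels = 1, tile_size = 512)
  fx <- generate_fixture(spec, withr::local_tempdir(), "blank")
  hb <- open_slide(fx$slide_path)
  expect_equal(extract_holistic(hb, extraction_config(tot_thresh = 0.2))$counts$extracted, 0)
  expect_equal(extract_holistic(hb, extraction_config(tot_thresh = 0))$counts$extracted, 4)
})

test_that("random subsampling is reproducible, bounded below by one, and relabels", {
  rec <- data.frame(decision = rep("extracted", 100),
                    out_path = rep("x.png", 100), stringsAsFactors = FALSE)
  s1 <- sample_records(rec, 0.1, seed = 17)
  s2 <- sample_records(rec, 0.1, seed = 17)
  expect_equal(sum(s1$decision == "extracted"), 10)
  expect_identical(s1, s2)
  expect_true(all(is.na(s1$out_path[s1$decision == "rejected_sampling"])))
  # at least one survives tiny fractions
  rec5 <- rec[1:5, ]
  expect_equal(sum(sample_records(rec5, 0.1, 1)$decision == "extracted"), 1)
  # identity at fraction 1
  expect_identical(sample_records(rec, 1, 1), rec)
  expect_error(sample_records(rec, 0, 1), "\\(0, 1\\]")
  expect_error(sample_records(rec, 1.5, 1), "\\(0, 1\\]")
})

test_that("sampling inside extraction keeps only non-blank tiles by default", {
  h <- open_slide(get_fixture("checkerboard")$slide_path)
  m <- extract_holistic(h, extraction_config(tot_thresh = 0.5, sample_fraction = 0.5,
                                             seed = 3))
  expect_equal(m$counts$extracted, 4)  # half of the 8 tissue tiles
  expect_equal(m$counts$rejected_sampling, 4)
  # sampled-out tiles still carry their computed BoT
  expect_true(all(!is.na(m$records$bot[m$records$decision == "rejected_sampling"])))
  m2 <- extract_holistic(h, extraction_config(tot_thresh = 0.5, sample_fraction = 0.5,
                                              seed = 3))
  expect_identical(m$records, m2$records)
})

test_that("the preset ladder carries the eight training pairs plus the testing pair", {
  ps <- extraction_presets("cam")
  expect_equal(names(ps), c(LETTERS[1:8], "testing"))
  got <- t(vapply(ps, function(p) c(p$iot_thresh, p$tot_thresh), numeric(2)))
  expected <- rbind(A = c(0.1, 0.0), B = c(0.2, 0.0), C = c(0.2, 0.2),
                    D = c(0.2, 0.5), E = c(0.5, 0.2), F = c(0.5, 0.5),
                    G = c(1.0, 0.2), H = c(1.0, 0.5), testing = c(0.3, 0.3))
  expect_equal(unname(got), unname(expected))
  expect_identical(extraction_presets("paip")$C$iot_thresh, 0.2)
  expect_error(extraction_presets("tcga"), "arg")
})

test_that("manifests round-trip through CSV with counts preserved", {
  fx <- get_fixture("offset_grid")
  h <- open_slide(fx$slide_path)
  ann <- parse_annotations(fx$annotation_path)
  out <- withr::local_tempdir()
  cfg <- extraction_config(iot_thresh = 0.5, tot_thresh = 0, labels = "tumor",
                           out_dir = file.path(out, "tiles"))
  m <- extract_annotated(h, ann, cfg)
  csv <- file.path(out, "manifest.csv")
  write_manifest(m, csv)
  expect_true(file.exists(paste0(csv, ".config.json")))
  back <- read_manifest(csv)
  expect_equal(nrow(back), nrow(m$records))
  expect_equal(as.list(table(back$decision))$extracted, m$counts$extracted)
  # extracted <=> out_path present, and footprint is recoverable from the name
  expect_equal(!is.na(back$out_path), back$decision == "extracted")
  nm <- back$out_path[which(back$decision == "extracted")[1]]
  expect_match(nm, "^offset_grid__x\\d+_y\\d+_l0_ts512\\.png$")
  # written tiles decode byte-identically (lossless PNG)
  ft <- subset(back, decision == "extracted")[1, ]
  raster <- read_region(h, tile_footprint(ft$x, ft$y, ft$w, ft$h, ft$level))
  expect_identical(read_tile(file.path(out, "tiles", ft$out_path)), raster)
})

test_that("threshold monotonicity: stricter configs extract subsets", {
  fx <- get_fixture("offset_grid")
  h <- open_slide(fx$slide_path)
  ann <- parse_annotations(fx$annotation_path)
  key <- function(m) {
    r <- m$records[m$records$decision == "extracted", ]
    paste(r$x, r$y)
  }
  ps <- extraction_presets("cam", labels = "tumor")[LETTERS[1:8]]
  keys <- lapply(ps, function(p) key(extract_annotated(h, ann, p)))
  for (i in seq_along(ps)) {
    for (j in seq_along(ps)) {
      pi <- ps[[i]]; pj <- ps[[j]]
      if (pj$iot_thresh >= pi$iot_thresh && pj$tot_thresh >= pi$tot_thresh) {
        expect_true(all(keys[[j]] %in% keys[[i]]))
      }
    }
  }
})
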