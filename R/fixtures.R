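# Synthetic pyramidal slides with analytic ground truth.
#
# The generator emulates the geometry of an H&E slide — saturated "tissue"
# blobs on a bright near-white "background" canvas — without any texture.
# Colors are constrained to sit firmly on one side of the default HSV
# background predicate so that per-tile decisions are analytic, and the
# ground-truth table marks any tile whose ideal tissue fraction falls within
# 0.03 of a gate threshold as unsafe (NA) rather than guessing how the
# blur/dilation boundary band will tip it.

#' Specification of a synthetic slide fixture
#'
#' @param canvas `c(W, H)` level-0 canvas size in px; both divisible by
#'   `2^(levels - 1)`.
#' @param background_rgb Background color (default near-white 245,245,245).
#' @param blobs List of blobs, each
#'   `list(shape = "rectangle"|"ellipse"|"crescent", bbox = c(x0, y0, x1, y1),
#'   rgb = c(r, g, b), inner_bbox = ...)`; `inner_bbox` (crescent only) is the
#'   bounding box of the subtracted inner ellipse.
#' @param annotations List of `list(label =, exterior =, holes =)` polygon
#'   specs (matrices of level-0 vertices), or `annotated_region` objects.
#' @param levels Pyramid depth (default 3; levels are 2x mean-pooled).
#' @param tile_size Tile size at which ground truth is tabulated (default 512).
#' @param positive_label Label whose IoT drives ground-truth decisions.
#' @param seed Reserved for randomized specs; the builtin cases are
#'   deterministic.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(canvas = c(2048L, 2048L),
                         background_rgb = c(245L, 245L, 245L),
                         blobs = list(), annotations = list(),
                         levels = 3L, tile_size = 512L,
                         positive_label = "tumor", seed = 1L) {
  canvas <- as.integer(canvas)
  levels <- as.integer(levels)
  if (any(canvas %% (2L^(levels - 1L)) != 0L)) {
    stop("canvas dimensions must be divisible by 2^(levels-1)")
  }
  bp <- background_params()
  cls_bg <- color_class(background_rgb, bp)
  if (cls_bg != "background") stop("background_rgb must satisfy the background predicate")
  for (b in blobs) {
    if (!b$shape %in% c("rectangle", "ellipse", "crescent")) {
      stop(sprintf("unknown blob shape '%s'", b$shape))
    }
    if (b$bbox[1] < 0 || b$bbox[2] < 0 || b$bbox[3] > canvas[1] || b$bbox[4] > canvas[2]) {
      stop("blob outside canvas")
    }
    if (color_class(b$rgb, bp) == "ambiguous") {
      stop("blob color is not firmly tissue- or background-class under default HSV thresholds")
    }
  }
  structure(
    list(canvas = canvas, background_rgb = as.integer(background_rgb),
         blobs = blobs, annotations = annotations, levels = levels,
         tile_size = as.integer(tile_size), positive_label = positive_label,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# Classify a color against the background predicate with a safety margin on
# the governing channel (>= 30 units for tissue; the background side must
# satisfy the predicate outright).
#' @keywords internal
#' @noRd
color_class <- function(rgb, params = background_params()) {
  hsv <- grDevices::rgb2hsv(rgb[1], rgb[2], rgb[3], maxColorValue = 255)
  s <- hsv[2L] * 255
  v <- hsv[3L] * 255
  if (s <= params$sat_max && v >= params$val_min) return("background")
  if (s >= params$sat_max + 30 || v <= params$val_min - 30) return("tissue")
  "ambiguous"
}

#' @keywords internal
#' @noRd
blob_mask <- function(blob, W, H) {
  # pixel (col j, row i), 0-based, has center (j + 0.5, i + 0.5)
  xc <- (seq_len(W) - 0.5)
  yc <- (seq_len(H) - 0.5)
  in_bbox_ellipse <- function(bbox) {
    cx <- (bbox[1] + bbox[3]) / 2; cy <- (bbox[2] + bbox[4]) / 2
    a <- (bbox[3] - bbox[1]) / 2;  b <- (bbox[4] - bbox[2]) / 2
    outer(((yc - cy) / b)^2, ((xc - cx) / a)^2, "+") <= 1
  }
  switch(blob$shape,
    rectangle = outer(yc >= blob$bbox[2] & yc < blob$bbox[4],
                      xc >= blob$bbox[1] & xc < blob$bbox[3], "&"),
    ellipse   = in_bbox_ellipse(blob$bbox),
    crescent  = in_bbox_ellipse(blob$bbox) & !in_bbox_ellipse(blob$inner_bbox)
  )
}

#' @keywords internal
#' @noRd
ellipse_ring <- function(bbox, n = 180L) {
  cx <- (bbox[1] + bbox[3]) / 2; cy <- (bbox[2] + bbox[4]) / 2
  a <- (bbox[3] - bbox[1]) / 2;  b <- (bbox[4] - bbox[2]) / 2
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(cx + a * cos(th), cy + b * sin(th))
}

#' @keywords internal
#' @noRd
spec_annotation_set <- function(spec, slide_id) {
  regions <- lapply(seq_along(spec$annotations), function(i) {
    a <- spec$annotations[[i]]
    if (inherits(a, "annotated_region")) return(a)
    annotated_region(a$label, a$exterior,
                     holes = if (is.null(a$holes)) list() else a$holes,
                     region_id = sprintf("fixture_%d", i))
  })
  annotation_set(slide_id, regions)
}

# Exact IoT of a tile against one annotation region: closed form for
# axis-aligned rectangles, rasterized (g = 4096) otherwise.
#' @keywords internal
#' @noRd
gt_tile_iot <- function(union, is_rect, rect_bbox, ft, g = 4096L) {
  if (is_rect) {
    ox <- max(0, min(rect_bbox[3], ft$x + ft$w) - max(rect_bbox[1], ft$x))
    oy <- max(0, min(rect_bbox[4], ft$y + ft$h) - max(rect_bbox[2], ft$y))
    return(ox * oy / (ft$w * ft$h))
  }
  rasterized_iot_oracle(union, ft, g = g)
}

#' @keywords internal
#' @noRd
is_axis_rect_region <- function(region) {
  if (length(region$holes) > 0L) return(NULL)
  m <- unique(region$exterior)
  if (nrow(m) != 4L) return(NULL)
  xs <- sort(unique(m[, 1L])); ys <- sort(unique(m[, 2L]))
  if (length(xs) != 2L || length(ys) != 2L) return(NULL)
  c(xs[1L], ys[1L], xs[2L], ys[2L])
}

#' Generate a synthetic pyramidal slide fixture
#'
#' Writes a multi-page pyramidal TIFF (8-bit RGB, uncompressed, levels
#' 2x mean-pooled), a plain-JSON annotation file, and a per-tile ground-truth
#' table: IoT against the positive label (closed form for axis-aligned
#' rectangle annotations, rasterized at g = 4096 otherwise), the ideal
#' tissue fraction (exact pixel count of painted blobs), and the expected
#' extraction decision under each preset of [extraction_presets()]
#' (`NA` where the tissue fraction sits within 0.03 of that preset's
#' threshold and the decision would hinge on the blur boundary band).
#' Output is deterministic: identical specs yield byte-identical files.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @param slide_id Basename for the emitted files.
#' @return List with `slide_path`, `annotation_path`, `ground_truth_path`,
#'   `ground_truth` (data frame), `annotations` (the [annotation_set()]),
#'   and `spec`.
#' @export
generate_fixture <- function(spec, out_dir, slide_id = "fixture") {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  W <- spec$canvas[1L]; H <- spec$canvas[2L]
  canvas <- array(rep(as.numeric(spec$background_rgb), each = H * W), dim = c(H, W, 3L))
  tissue <- matrix(FALSE, H, W)
  for (b in spec$blobs) {
    m <- blob_mask(b, W, H)
    for (c in 1:3) {
      ch <- canvas[, , c]
      ch[m] <- b$rgb[c]
      canvas[, , c] <- ch
    }
    if (color_class(b$rgb) == "tissue") tissue <- tissue | m
  }
  # pyramid by 2x mean pooling
  pool2 <- function(a) {
    h2 <- dim(a)[1L] / 2L; w2 <- dim(a)[2L] / 2L
    out <- array(0, dim = c(h2, w2, 3L))
    for (c in 1:3) {
      ch <- a[, , c]
      out[, , c] <- (ch[seq(1, 2 * h2, 2), seq(1, 2 * w2, 2)] +
                     ch[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2)] +
                     ch[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2)] +
                     ch[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2)]) / 4
    }
    out
  }
  pyramid <- vector("list", spec$levels)
  pyramid[[1L]] <- canvas
  for (k in seq_len(spec$levels - 1L)) pyramid[[k + 1L]] <- pool2(pyramid[[k]])
  slide_path <- file.path(out_dir, paste0(slide_id, ".tif"))
  tiff::writeTIFF(lapply(pyramid, function(a) round(a) / 255), slide_path,
                  bits.per.sample = 8L, compression = "none")
  annots <- spec_annotation_set(spec, slide_id)
  annotation_path <- file.path(out_dir, paste0(slide_id, ".json"))
  write_annotations_json(annots, annotation_path)
  gt <- fixture_ground_truth(spec, annots, tissue)
  gt_path <- file.path(out_dir, paste0(slide_id, "_ground_truth.csv"))
  utils::write.csv(gt, gt_path, row.names = FALSE)
  list(slide_path = slide_path, annotation_path = annotation_path,
       ground_truth_path = gt_path, ground_truth = gt,
       annotations = annots, spec = spec)
}

#' @keywords internal
#' @noRd
fixture_ground_truth <- function(spec, annots, tissue) {
  ts <- spec$tile_size
  grid <- partition_grid(spec$canvas[1L], spec$canvas[2L], ts)
  pos <- filter_regions(annots, spec$positive_label)
  union <- region_union(pos, spec$positive_label)
  rect <- if (length(pos$regions) == 1L) is_axis_rect_region(pos$regions[[1L]]) else NULL
  presets <- extraction_presets("cam")
  iot <- numeric(nrow(grid))
  tissue_frac <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ft <- tile_footprint(grid$x[i], grid$y[i], grid$w[i], grid$h[i])
    iot[i] <- gt_tile_iot(union, !is.null(rect), rect, ft)
    rows <- (grid$y[i] + 1L):(grid$y[i] + ts)
    cols <- (grid$x[i] + 1L):(grid$x[i] + ts)
    tissue_frac[i] <- mean(tissue[rows, cols])
  }
  gt <- data.frame(x = grid$x, y = grid$y, w = grid$w, h = grid$h,
                   iot = iot, tissue_frac = tissue_frac,
                   stringsAsFactors = FALSE)
  for (nm in names(presets)) {
    cfg <- presets[[nm]]
    dec <- character(nrow(gt))
    for (i in seq_len(nrow(gt))) {
      if (iot[i] < cfg$iot_thresh) {
        dec[i] <- "rejected_iot"
      } else if (tissue_frac[i] %in% c(0, 1) ||
                 abs(tissue_frac[i] - cfg$tot_thresh) >= 0.03) {
        dec[i] <- if (tissue_frac[i] >= cfg$tot_thresh) "extracted" else "rejected_bot"
      } else {
        dec[i] <- NA_character_  # within the blur boundary band of the gate
      }
    }
    gt[[paste0("decision_", nm)]] <- dec
  }
  gt
}

#' Builtin fixture cases
#'
#' \describe{
#'   \item{`basic`}{2048^2 canvas; a 1024^2 tissue square annotated as
#'     "tumor", aligned to the 512 px grid at (512, 512): 4 tiles have
#'     IoT = 1, all others 0.}
#'   \item{`offset_grid`}{The same square shifted to (256, 256), straddling
#'     the grid: per-tile IoT takes values 0.25 / 0.5 / 1 over a 3 x 3 block.}
#'   \item{`checkerboard`}{Alternate 512 px grid cells tissue / background
#'     with the whole canvas annotated: IoT = 1 everywhere, decisions driven
#'     purely by the background gate.}
#'   \item{`concave`}{A disc with an off-center notch (see
#'     [make_concave_case()]): the tile whose eight probe points all lie
#'     inside the region while its IoT is strictly below 1.}
#' }
#'
#' @param case Case name.
#' @return A [fixture_spec()].
#' @export
fixture_case <- function(case = c("basic", "offset_grid", "concave", "checkerboard")) {
  case <- match.arg(case)
  pink <- c(200L, 100L, 150L)
  rect_ann <- function(bbox) {
    list(label = "tumor",
         exterior = cbind(c(bbox[1], bbox[3], bbox[3], bbox[1]),
                          c(bbox[2], bbox[2], bbox[4], bbox[4])))
  }
  switch(case,
    basic = fixture_spec(
      blobs = list(list(shape = "rectangle", bbox = c(512, 512, 1536, 1536), rgb = pink)),
      annotations = list(rect_ann(c(512, 512, 1536, 1536)))
    ),
    offset_grid = fixture_spec(
      blobs = list(list(shape = "rectangle", bbox = c(256, 256, 1280, 1280), rgb = pink)),
      annotations = list(rect_ann(c(256, 256, 1280, 1280)))
    ),
    checkerboard = {
      cells <- expand.grid(i = 0:3, j = 0:3)
      cells <- cells[(cells$i + cells$j) %% 2 == 0, ]
      blobs <- lapply(seq_len(nrow(cells)), function(k) {
        x0 <- cells$i[k] * 512; y0 <- cells$j[k] * 512
        list(shape = "rectangle", bbox = c(x0, y0, x0 + 512, y0 + 512), rgb = pink)
      })
      fixture_spec(blobs = blobs, annotations = list(rect_ann(c(0, 0, 2048, 2048))))
    },
    concave = make_concave_case()$spec
  )
}

#' The concave-region failure case for corner-probing heuristics
#'
#' Constructs an annotated region (a disc with an off-center circular notch)
#' and a tile placement whose four corners and four edge midpoints all lie
#' inside the region while the tile is NOT fully contained: a containment
#' heuristic probing those eight points would extract the tile as "fully
#' inside", whereas its true IoT is strictly below 1 (though well above 0.5 —
#' the notch is a small minority of the tile's area).
#'
#' @return List with `spec` (a [fixture_spec()]), `tile` (the
#'   [tile_footprint()] of the probed tile), and `probe_points`
#'   (an 8 x 2 matrix of the corner and edge-midpoint coordinates).
#' @export
make_concave_case <- function() {
  pink <- c(200L, 100L, 150L)
  outer_bbox <- c(768 - 600, 768 - 600, 768 + 600, 768 + 600)
  notch_bbox <- c(640 - 80, 640 - 80, 640 + 80, 640 + 80)
  ext <- ellipse_ring(outer_bbox, n = 180L)
  hole <- ellipse_ring(notch_bbox, n = 90L)
  spec <- fixture_spec(
    blobs = list(list(shape = "crescent", bbox = outer_bbox,
                      inner_bbox = notch_bbox, rgb = pink)),
    annotations = list(list(label = "tumor", exterior = ext, holes = list(hole)))
  )
  tile <- tile_footprint(512, 512, 512, 512)
  px <- c(512, 1024, 512, 1024, 768, 1024, 768, 512)
  py <- c(512, 512, 1024, 1024, 512, 768, 1024, 768)
  list(spec = spec, tile = tile, probe_points = cbind(x = px, y = py))
}

#' Even-odd point-in-region test
#'
#' Tests points against a [region_union()]'s rings by the even-odd crossing
#' rule; used for probing fixture geometry (e.g. the eight-point heuristic).
#'
#' @param union A [region_union()].
#' @param x,y Point coordinates (vectors).
#' @return Logical vector.
#' @export
points_in_union <- function(union, x, y) {
  stopifnot(inherits(union, "region_union"))
  inside <- rep(FALSE, length(x))
  for (ring in union$rings) {
    rx <- ring$x; ry <- ring$y
    n <- length(rx)
    rx2 <- c(rx[-1L], rx[1L]); ry2 <- c(ry[-1L], ry[1L])
    for (e in seq_len(n)) {
      if (ry[e] == ry2[e]) next
      lo <- pmin(ry[e], ry2[e]); hi <- pmax(ry[e], ry2[e])
      hit <- y >= lo & y < hi
      if (!any(hit)) next
      xh <- rx[e] + (y[hit] - ry[e]) * (rx2[e] - rx[e]) / (ry2[e] - ry[e])
      flip <- xh > x[hit]
      inside[hit][flip] <- !inside[hit][flip]
    }
  }
  inside
}
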