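#' Extraction configuration
#'
#' Houses the thresholds of the gated extraction loop.  `iot_thresh` is the
#' minimum intersection-over-tile against the annotation union; `tot_thresh`
#' is the minimum tissue fraction `1 - BoT`.  Both gates are inclusive
#' (`>=`), so a threshold of 0 admits everything to the next stage.
#'
#' @param tile_size Tile edge in pixels at the extraction level (default 512).
#' @param level Pyramid level to read pixels from (default 0, full resolution).
#' @param iot_thresh IoT threshold in \eqn{[0, 1]}.
#' @param tot_thresh Tissue (`1 - BoT`) threshold in \eqn{[0, 1]}.
#' @param labels Labels forming the positive annotation union (`NULL` = all).
#' @param bg_params A [background_params()].
#' @param sample_fraction Random tile subsample kept, in (0, 1] (default 1).
#' @param seed RNG seed for subsampling.
#' @param out_format `"png"` (lossless, default) or `"jpeg"` (quality 90).
#' @param out_dir Directory for extracted tiles; `NULL` = score only, write
#'   nothing.
#' @param sample_stage When subsampling, whether it is applied `"after_bot"`
#'   (default: only non-blank tiles are sampled) or `"before_bot"` (sampling
#'   among the geometry-passing tiles before any pixels are read).
#' @return Object of class `extraction_config`.
#' @export
extraction_config <- function(tile_size = 512L, level = 0L,
                              iot_thresh = 0, tot_thresh = 0,
                              labels = NULL, bg_params = background_params(),
                              sample_fraction = 1, seed = 1L,
                              out_format = c("png", "jpeg"), out_dir = NULL,
                              sample_stage = c("after_bot", "before_bot")) {
  out_format <- match.arg(out_format)
  sample_stage <- match.arg(sample_stage)
  if (tile_size <= 0) stop("tile_size must be positive")
  if (iot_thresh < 0 || iot_thresh > 1) stop("iot_thresh must be in [0, 1]")
  if (tot_thresh < 0 || tot_thresh > 1) stop("tot_thresh must be in [0, 1]")
  if (sample_fraction <= 0 || sample_fraction > 1) stop("sample_fraction must be in (0, 1]")
  stopifnot(inherits(bg_params, "background_params"))
  structure(
    list(tile_size = as.integer(tile_size), level = as.integer(level),
         iot_thresh = iot_thresh, tot_thresh = tot_thresh, labels = labels,
         bg_params = bg_params, sample_fraction = sample_fraction,
         seed = as.integer(seed), out_format = out_format, out_dir = out_dir,
         sample_stage = sample_stage),
    class = "extraction_config"
  )
}

#' Non-overlapping tile grid over a slide
#'
#' Grid tiling from the top-left corner: footprints at
#' `x = i * ts, y = j * ts` for `i < floor(W/ts)`, `j < floor(H/ts)`.
#' Partial tiles at the right/bottom edge are dropped so every tile has the
#' full fixed dimensions.  Order is row-major (y outer, x inner) and
#' deterministic.  A tile larger than the slide yields an empty grid.
#'
#' @param slide_w,slide_h Slide dimensions, level-0 px.
#' @param tile_size_l0 Tile edge, level-0 px.
#' @return Data frame with columns `x`, `y`, `w`, `h` (one row per tile).
#' @examples
#' nrow(partition_grid(2048, 1536, 512))  # 12
#' @export
partition_grid <- function(slide_w, slide_h, tile_size_l0) {
  if (tile_size_l0 <= 0) stop("tile size must be positive")
  nx <- floor(slide_w / tile_size_l0)
  ny <- floor(slide_h / tile_size_l0)
  if (nx < 1 || ny < 1) {
    return(data.frame(x = numeric(0), y = numeric(0), w = numeric(0), h = numeric(0)))
  }
  g <- expand.grid(x = (seq_len(nx) - 1) * tile_size_l0,
                   y = (seq_len(ny) - 1) * tile_size_l0)
  g <- g[order(g$y, g$x), , drop = FALSE]
  rownames(g) <- NULL
  g$w <- tile_size_l0
  g$h <- tile_size_l0
  g
}

#' @keywords internal
#' @noRd
tile_filename <- function(slide_id, x, y, level, tile_size, ext) {
  sprintf("%s__x%d_y%d_l%d_ts%d.%s", slide_id, as.integer(x), as.integer(y),
          as.integer(level), as.integer(tile_size), ext)
}

#' Write one tile raster to disk
#' @param raster A [tile_raster()].
#' @param path Output file.
#' @param format `"png"` (lossless) or `"jpeg"` (quality 90).
#' @return `path`, invisibly.
#' @export
write_tile <- function(raster, path, format = c("png", "jpeg")) {
  format <- match.arg(format)
  if (!inherits(raster, "tile_raster")) raster <- tile_raster(raster)
  arr <- array(as.numeric(raster) / 255, dim = dim(raster))
  if (format == "png") {
    png::writePNG(arr, path)
  } else {
    jpeg::writeJPEG(arr, path, quality = 0.9)
  }
  invisible(path)
}

#' Read a tile written by [write_tile()]
#' @param path Tile image file (.png or .jpg/.jpeg).
#' @return A [tile_raster()].
#' @export
read_tile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") png::readPNG(path) else jpeg::readJPEG(path)
  tile_raster(array(as.integer(round(arr * 255)), dim = dim(arr)))
}

# Run RNG code under a fixed seed without disturbing the global stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Random subsample of extracted tile records
#'
#' Keeps a uniform without-replacement sample of `round(n * fraction)` of the
#' records currently marked `extracted` (at least 1 when any exist and
#' `fraction > 0`); the rest become `rejected_sampling`.  Reproducible for a
#' fixed seed.  This implements the practice of keeping e.g. a random 10% of
#' the tiles of each negative slide.
#'
#' @param records Manifest records data frame (see [extract_annotated()]).
#' @param fraction Sampling fraction in (0, 1].
#' @param seed RNG seed.
#' @return The records with unsampled `extracted` rows relabeled.
#' @export
sample_records <- function(records, fraction, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  idx <- which(records$decision == "extracted")
  n <- length(idx)
  if (fraction == 1 || n == 0L) return(records)
  k <- max(1L, round(n * fraction))
  keep <- with_seed(seed, sort(sample(idx, k)))
  drop <- setdiff(idx, keep)
  records$decision[drop] <- "rejected_sampling"
  records$out_path[drop] <- NA_character_
  records
}

#' @keywords internal
#' @noRd
new_manifest <- function(config, records, timing_s) {
  counts <- table(factor(records$decision,
                         levels = c("extracted", "rejected_iot",
                                    "rejected_bot", "rejected_sampling")))
  structure(
    list(config = config, records = records, timing_s = timing_s,
         counts = as.list(as.integer(counts)) |>
           stats::setNames(names(counts))),
    class = "extraction_manifest"
  )
}

#' @export
print.extraction_manifest <- function(x, ...) {
  cat(sprintf("<extraction manifest: %d tile(s); %s; %.2f s>\n",
              nrow(x$records),
              paste(sprintf("%s=%d", names(x$counts), unlist(x$counts)),
                    collapse = " "),
              x$timing_s))
  invisible(x)
}

#' @keywords internal
#' @noRd
run_extraction <- function(handle, cfg, union = NULL) {
  t0 <- proc.time()[["elapsed"]]
  lvl <- cfg$level + 1L
  if (lvl > length(handle$downsamples)) stop(sprintf("invalid pyramid level %d", cfg$level))
  ds <- handle$downsamples[lvl]
  ts0 <- cfg$tile_size * ds
  d0 <- handle$level_dims[[1L]]
  grid <- partition_grid(d0[["w"]], d0[["h"]], ts0)
  n <- nrow(grid)
  iot <- rep(NA_real_, n)
  bot <- rep(NA_real_, n)
  decision <- character(n)
  annotated <- !is.null(union)
  # geometry gate first: never read pixels for a tile failing on IoT
  pass <- rep(TRUE, n)
  for (i in seq_len(n)) {
    ft <- tile_footprint(grid$x[i], grid$y[i], grid$w[i], grid$h[i], cfg$level)
    if (annotated) {
      iot[i] <- compute_iot(union, ft)
      pass[i] <- iot[i] >= cfg$iot_thresh
      if (!pass[i]) decision[i] <- "rejected_iot"
    }
  }
  if (cfg$sample_stage == "before_bot" && cfg$sample_fraction < 1) {
    idx <- which(pass)
    if (length(idx) > 0L) {
      k <- max(1L, round(length(idx) * cfg$sample_fraction))
      keep <- with_seed(cfg$seed, sort(sample(idx, k)))
      dropped <- setdiff(idx, keep)
      pass[dropped] <- FALSE
      decision[dropped] <- "rejected_sampling"
    }
  }
  for (i in which(pass)) {
    ft <- tile_footprint(grid$x[i], grid$y[i], grid$w[i], grid$h[i], cfg$level)
    raster <- read_region(handle, ft)
    bot[i] <- compute_bot(raster, cfg$bg_params)
    decision[i] <- if (1 - bot[i] >= cfg$tot_thresh) "extracted" else "rejected_bot"
  }
  records <- data.frame(
    slide_id = rep(handle$slide_id, n),
    x = grid$x, y = grid$y, w = grid$w, h = grid$h,
    level = rep(cfg$level, n),
    iot = iot, bot = bot, decision = decision,
    out_path = NA_character_,
    stringsAsFactors = FALSE
  )
  if (cfg$sample_stage == "after_bot" && cfg$sample_fraction < 1) {
    records <- sample_records(records, cfg$sample_fraction, cfg$seed)
  }
  ext <- if (cfg$out_format == "png") "png" else "jpg"
  sel <- which(records$decision == "extracted")
  records$out_path[sel] <- vapply(sel, function(i) {
    tile_filename(handle$slide_id, records$x[i], records$y[i],
                  cfg$level, cfg$tile_size, ext)
  }, character(1))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in sel) {
      ft <- tile_footprint(records$x[i], records$y[i], records$w[i],
                           records$h[i], cfg$level)
      write_tile(read_region(handle, ft),
                 file.path(cfg$out_dir, records$out_path[i]),
                 cfg$out_format)
    }
  }
  new_manifest(cfg, records, proc.time()[["elapsed"]] - t0)
}

#' Annotation-guided tile extraction
#'
#' The gated extraction loop: the slide grid is scored tile by tile; a tile's
#' IoT against the union of `cfg$labels` regions must reach `iot_thresh`
#' before its pixels are even read, and its tissue fraction `1 - BoT` must
#' then reach `tot_thresh` for the tile to be extracted.  Both comparisons
#' are inclusive.  Every grid location gets exactly one manifest record, with
#' the scores that were actually computed (`bot` stays `NA` for tiles
#' rejected on geometry — the loop short-circuits after the IoT gate).
#'
#' @param handle A [open_slide()] handle.
#' @param annots An [annotation_set()] in level-0 pixels.
#' @param cfg An [extraction_config()].
#' @return An `extraction_manifest`: `config`, `records` (data frame with
#'   columns slide_id, x, y, w, h, level, iot, bot, decision, out_path),
#'   `timing_s`, and `counts` by decision.
#' @export
extract_annotated <- function(handle, annots, cfg) {
  stopifnot(inherits(handle, "slide_handle"), inherits(cfg, "extraction_config"))
  if (!inherits(annots, "annotation_set")) {
    stop("extract_annotated needs an annotation_set; use extract_holistic for unannotated slides")
  }
  if (!identical(annots$space, "level0_pixels")) {
    stop("annotation coordinate space must be level0_pixels")
  }
  union <- region_union(annots, cfg$labels)
  run_extraction(handle, cfg, union = union)
}

#' Holistic (annotation-free) tile extraction
#'
#' Tiles the whole slide with the background gate only: every grid tile is
#' read and extracted iff its tissue fraction `1 - BoT` reaches `tot_thresh`.
#' IoT is recorded as `NA` (not computed), never 0.
#'
#' @inheritParams extract_annotated
#' @return An `extraction_manifest` (see [extract_annotated()]).
#' @export
extract_holistic <- function(handle, cfg) {
  stopifnot(inherits(handle, "slide_handle"), inherits(cfg, "extraction_config"))
  run_extraction(handle, cfg, union = NULL)
}

#' Named threshold presets
#'
#' The ladder of eight training configurations A-H spanning IoT thresholds
#' 0.1/0.2/0.5/1.0 and tissue (`1 - BoT`) thresholds 0.0/0.2/0.5, plus the
#' `testing` preset (0.3, 0.3) used for hold-out extraction.  The same grid
#' applies to both supported dataset tags.
#'
#' @param dataset_tag `"cam"` or `"paip"`.
#' @param ... Passed to [extraction_config()] (e.g. `labels`, `out_dir`).
#' @return Named list of [extraction_config()] objects
#'   (`A` ... `H`, `testing`).
#' @examples
#' names(extraction_presets("cam"))
#' extraction_presets("cam")$C[c("iot_thresh", "tot_thresh")]
#' @export
extraction_presets <- function(dataset_tag = c("cam", "paip"), ...) {
  dataset_tag <- match.arg(dataset_tag)
  grid <- list(
    A = c(0.1, 0.0), B = c(0.2, 0.0), C = c(0.2, 0.2), D = c(0.2, 0.5),
    E = c(0.5, 0.2), F = c(0.5, 0.5), G = c(1.0, 0.2), H = c(1.0, 0.5),
    testing = c(0.3, 0.3)
  )
  lapply(grid, function(p) {
    extraction_config(iot_thresh = p[1], tot_thresh = p[2], ...)
  })
}

#' @keywords internal
#' @noRd
config_as_list <- function(cfg) {
  list(tile_size = cfg$tile_size, level = cfg$level,
       iot_thresh = cfg$iot_thresh, tot_thresh = cfg$tot_thresh,
       labels = cfg$labels,
       bg_params = unclass(cfg$bg_params),
       sample_fraction = cfg$sample_fraction, seed = cfg$seed,
       out_format = cfg$out_format, sample_stage = cfg$sample_stage)
}

#' Write an extraction manifest
#'
#' Writes the per-tile records as CSV (columns slide_id, x, y, w, h, level,
#' iot, bot, decision, out_path) plus a JSON sidecar `<path>.config.json`
#' holding the configuration snapshot and timing.
#'
#' @param manifest An `extraction_manifest`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "extraction_manifest"))
  utils::write.csv(manifest$records, path, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(config = config_as_list(manifest$config),
         timing_s = manifest$timing_s, counts = manifest$counts),
    paste0(path, ".config.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read back a manifest CSV written by [write_manifest()]
#' @param path Manifest CSV path.
#' @return Data frame of tile records.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(slide_id = "character",
                                       out_path = "character"))
  df$out_path[!nzchar(df$out_path) | is.na(df$out_path)] <- NA_character_
  df
}
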