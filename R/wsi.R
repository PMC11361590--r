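#' Open a pyramidal slide
#'
#' Reads a multi-page pyramidal TIFF (each page one resolution level, level 0
#' largest) or a flat PNG/TIFF treated as a 1-level pyramid.  Levels are held
#' in memory as 8-bit RGB arrays; any alpha channel is flattened against
#' white.  The handle also carries a read counter used to audit that gated
#' extraction never decodes pixels for tiles rejected on geometry alone.
#'
#' @param path Slide file (.tif/.tiff multi-page pyramid, or .png).
#' @return Object of class `slide_handle` with fields `slide_id`,
#'   `level_dims` (list of `c(w, h)` per level), `downsamples` (factor per
#'   level relative to level 0), `path`, and `mpp` (microns per pixel,
#'   `NA` when the source carries none).
#' @export
open_slide <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot open slide: file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  pages <- if (ext %in% c("tif", "tiff")) {
    p <- tryCatch(tiff::readTIFF(path, all = TRUE),
                  error = function(e) stop(sprintf("cannot read TIFF %s: %s",
                                                   path, conditionMessage(e))))
    if (!is.list(p)) p <- list(p)
    lapply(p, function(a) round(a * 255))
  } else if (ext == "png") {
    p <- png::readPNG(path)
    list(round(p * 255))
  } else {
    stop(sprintf("unsupported slide format '%s' (expect tif/tiff/png)", ext))
  }
  if (!is.list(pages)) pages <- list(pages)
  levels <- lapply(pages, normalize_level_array)
  # order levels largest first and derive downsample factors
  widths <- vapply(levels, function(a) dim(a)[2L], integer(1))
  ord <- order(widths, decreasing = TRUE)
  levels <- levels[ord]
  dims <- lapply(levels, function(a) c(w = dim(a)[2L], h = dim(a)[1L]))
  ds <- vapply(dims, function(d) dims[[1L]][["w"]] / d[["w"]], numeric(1))
  for (k in seq_along(dims)) {
    if (abs(dims[[1L]][["h"]] / ds[k] - dims[[k]][["h"]]) > 1) {
      stop(sprintf("inconsistent pyramid: level %d dims %dx%d vs downsample %.3g",
                   k - 1L, dims[[k]][["w"]], dims[[k]][["h"]], ds[k]))
    }
  }
  counters <- new.env(parent = emptyenv())
  counters$reads <- 0L
  structure(
    list(slide_id = tools::file_path_sans_ext(basename(path)),
         level_dims = dims, downsamples = ds, path = path,
         mpp = NA_real_, .levels = levels, .counters = counters),
    class = "slide_handle"
  )
}

#' @keywords internal
#' @noRd
normalize_level_array <- function(a) {
  if (is.matrix(a)) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (length(dim(a)) != 3L) stop("slide level must be an RGB(A) raster")
  if (dim(a)[3L] == 4L) {
    alpha <- a[, , 4L] / 255
    out <- array(0, dim = c(dim(a)[1:2], 3L))
    for (c in 1:3) out[, , c] <- round(a[, , c] * alpha + 255 * (1 - alpha))
    a <- out
  } else if (dim(a)[3L] != 3L) {
    stop("slide level must have 3 or 4 channels")
  }
  storage.mode(a) <- "integer"
  a
}

#' @export
print.slide_handle <- function(x, ...) {
  cat(sprintf("<slide '%s': %d level(s)>\n", x$slide_id, length(x$level_dims)))
  for (k in seq_along(x$level_dims)) {
    d <- x$level_dims[[k]]
    cat(sprintf("  level %d: %d x %d (downsample %g)\n",
                k - 1L, d[["w"]], d[["h"]], x$downsamples[k]))
  }
  invisible(x)
}

#' Number of tile reads performed on a handle
#' @param handle A [open_slide()] handle.
#' @return Integer count of [read_region()] calls.
#' @export
slide_read_count <- function(handle) {
  handle$.counters$reads
}

#' Read one tile raster from a slide
#'
#' The footprint addresses level-0 coordinates; pixels are returned at
#' `tile$level`, so a 512 px level-0 footprint read at level 1 (downsample 2)
#' yields a 256 x 256 raster.  Footprints outside the level-0 bounds are an
#' error — no silent padding.
#'
#' @param handle A [open_slide()] handle.
#' @param tile A [tile_footprint()].
#' @return A [tile_raster()].
#' @export
read_region <- function(handle, tile) {
  stopifnot(inherits(handle, "slide_handle"), inherits(tile, "tile_footprint"))
  lvl <- tile$level + 1L
  if (lvl < 1L || lvl > length(handle$.levels)) {
    stop(sprintf("invalid pyramid level %d", tile$level))
  }
  d0 <- handle$level_dims[[1L]]
  if (tile$x + tile$w > d0[["w"]] || tile$y + tile$h > d0[["h"]]) {
    stop(sprintf("tile footprint (%g,%g,%gx%g) exceeds level-0 bounds %dx%d",
                 tile$x, tile$y, tile$w, tile$h, d0[["w"]], d0[["h"]]))
  }
  ds <- handle$downsamples[lvl]
  rows <- (floor(tile$y / ds) + 1L):(floor((tile$y + tile$h) / ds))
  cols <- (floor(tile$x / ds) + 1L):(floor((tile$x + tile$w) / ds))
  handle$.counters$reads <- handle$.counters$reads + 1L
  tile_raster(handle$.levels[[lvl]][rows, cols, , drop = FALSE])
}
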