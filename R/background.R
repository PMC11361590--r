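#' Tile raster (8-bit RGB)
#'
#' Wraps an `h x w x 3` integer array of 8-bit RGB values.  Tiles decoded
#' from PNG/JPEG/TIFF and regions read from a slide handle all take this form.
#'
#' @param pixels Numeric/integer array, dimensions `c(h, w, 3)`, values 0-255.
#' @return Object of class `tile_raster` (the array with attributes).
#' @export
tile_raster <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L) {
    stop("tile raster must be an h x w x 3 RGB array")
  }
  if (min(pixels) < 0 || max(pixels) > 255) stop("tile raster values must be in [0, 255]")
  storage.mode(pixels) <- "integer"
  structure(pixels, class = c("tile_raster", "array"))
}

#' Uniform-color tile raster
#' @param h,w Dimensions in pixels.
#' @param rgb Length-3 vector of 8-bit channel values.
#' @return A [tile_raster()].
#' @export
solid_tile <- function(h, w, rgb) {
  stopifnot(length(rgb) == 3L)
  arr <- array(rep(as.integer(rgb), each = h * w), dim = c(h, w, 3L))
  tile_raster(arr)
}

#' @export
print.tile_raster <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<tile raster %d x %d RGB>\n", d[1L], d[2L]))
  invisible(x)
}

#' Background-segmentation parameters
#'
#' Houses the fixed operators of the background pipeline: Gaussian blur,
#' the HSV background predicate, and the mask-cleanup dilation.  A pixel is a
#' background candidate when its saturation is at most `sat_max` AND its
#' value (brightness) is at least `val_min` — i.e. nearly-grey and bright,
#' which targets the blank glass of an H&E slide while stained tissue (pink
#' or purple, strongly saturated) fails the predicate.  Both thresholds are
#' on the 8-bit 0-255 scale.
#'
#' @param blur_kernel Odd Gaussian kernel size in px (default 5); sigma is
#'   derived from the kernel as `0.3 * ((k - 1)/2 - 1) + 0.8`.
#' @param sat_max Saturation ceiling for background candidates (default 20).
#' @param val_min Value floor for background candidates (default 235).
#' @param dilate_kernel Odd box structuring-element size (default 3).
#' @param dilate_iters Dilation iterations (default 1).
#' @param area_mode How background area is measured: `"contour_fill"`
#'   (default; external contours of background blobs are filled, so holes
#'   inside a background blob count as background) or `"pixel_count"`
#'   (plain nonzero-pixel count).
#' @return Object of class `background_params`.
#' @export
background_params <- function(blur_kernel = 5L, sat_max = 20, val_min = 235,
                              dilate_kernel = 3L, dilate_iters = 1L,
                              area_mode = c("contour_fill", "pixel_count")) {
  area_mode <- match.arg(area_mode)
  blur_kernel <- as.integer(blur_kernel)
  dilate_kernel <- as.integer(dilate_kernel)
  if (blur_kernel < 1L || blur_kernel %% 2L == 0L) stop("blur_kernel must be odd and >= 1")
  if (dilate_kernel < 1L || dilate_kernel %% 2L == 0L) stop("dilate_kernel must be odd and >= 1")
  if (sat_max < 0 || sat_max > 255 || val_min < 0 || val_min > 255) {
    stop("HSV thresholds must be in [0, 255]")
  }
  structure(
    list(blur_kernel = blur_kernel, sat_max = sat_max, val_min = val_min,
         combine = "and", dilate_kernel = dilate_kernel,
         dilate_iters = as.integer(dilate_iters), area_mode = area_mode),
    class = "background_params"
  )
}

# OpenCV-convention Gaussian kernel for a given odd size.
#' @keywords internal
#' @noRd
gaussian_kernel <- function(k) {
  sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  r <- (k - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g <- g / sum(g)
  outer(g, g)
}

#' Segment the background of one tile
#'
#' Fixed pipeline: Gaussian blur (`blur_kernel`, sigma derived from the
#' kernel) on each RGB channel, RGB-to-HSV conversion, the background
#' predicate `saturation <= sat_max AND value >= val_min`, binarisation, then
#' `dilate_iters` box dilations of `dilate_kernel` px to patch minor defects.
#' The background area `s_bg` is then measured per `area_mode`.
#'
#' @param tile A [tile_raster()] (or bare `h x w x 3` array).
#' @param params A [background_params()].
#' @return A list of class `background_mask` with `mask` (0/1 matrix `h x w`)
#'   and `s_bg` (background area, px^2).
#' @export
make_background_mask <- function(tile, params = background_params()) {
  if (!inherits(tile, "tile_raster")) tile <- tile_raster(tile)
  stopifnot(inherits(params, "background_params"))
  d <- dim(tile)
  h <- d[1L]; w <- d[2L]
  arr <- array(as.numeric(tile), dim = d)
  if (params$blur_kernel > 1L) {
    kern <- gaussian_kernel(params$blur_kernel)
    for (c in 1:3) {
      arr[, , c] <- EBImage::filter2(arr[, , c], kern, boundary = "replicate")
    }
  }
  hsv <- grDevices::rgb2hsv(as.vector(arr[, , 1L]), as.vector(arr[, , 2L]),
                            as.vector(arr[, , 3L]), maxColorValue = 255)
  sat <- hsv[2L, ] * 255
  val <- hsv[3L, ] * 255
  mask <- matrix(as.numeric(sat <= params$sat_max & val >= params$val_min),
                 nrow = h, ncol = w)
  if (params$dilate_iters > 0L && params$dilate_kernel > 1L && any(mask > 0)) {
    brush <- EBImage::makeBrush(params$dilate_kernel, shape = "box")
    for (i in seq_len(params$dilate_iters)) {
      mask <- EBImage::dilate(mask, brush)
    }
  }
  s_bg <- if (params$area_mode == "contour_fill" && any(mask > 0)) {
    sum(EBImage::fillHull(mask) > 0)
  } else {
    sum(mask > 0)
  }
  structure(list(mask = mask, s_bg = s_bg, h = h, w = w),
            class = "background_mask")
}

#' Background over tile (BoT)
#'
#' The fraction of a tile classified as blank background:
#' \deqn{BoT = S_{bg} / (h \cdot w)}
#' computed from the mask of [make_background_mask()].  1 means the tile is
#' entirely background (no tissue at all); 0 means it is entirely covered by
#' tissue.  The extraction gate compares the complement `1 - BoT` (tissue
#' over tile, see [tot()]) against a threshold.
#'
#' @inheritParams make_background_mask
#' @return A single number in \eqn{[0, 1]}.
#' @examples
#' compute_bot(solid_tile(64, 64, c(245, 245, 245)))  # 1: all background
#' compute_bot(solid_tile(64, 64, c(200, 100, 150)))  # 0: all tissue
#' @export
compute_bot <- function(tile, params = background_params()) {
  m <- make_background_mask(tile, params)
  min(max(m$s_bg / (m$h * m$w), 0), 1)
}

#' Tissue over tile (ToT)
#'
#' The complement `1 - BoT`: the fraction of a tile covered by tissue.  This
#' is the quantity the extraction gate thresholds.
#'
#' @param bot A BoT fraction in \eqn{[0, 1]}.
#' @return `1 - bot`.
#' @export
tot <- function(bot) {
  if (!is.numeric(bot) || any(is.na(bot)) || any(bot < 0) || any(bot > 1)) {
    stop("bot must be in [0, 1]")
  }
  1 - bot
}
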