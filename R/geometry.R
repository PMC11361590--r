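#' Tile footprint on the level-0 slide grid
#'
#' A tile footprint is the half-open axis-aligned box
#' \eqn{[x, x+w) \times [y, y+h)} in level-0 pixel coordinates, together with
#' the pyramid level at which its pixels are read.  Geometry (IoT) is always
#' a level-0 quantity, so the footprint is independent of the reading level.
#'
#' @param x,y Top-left corner, level-0 pixels (non-negative; fractional allowed).
#' @param w,h Extent in level-0 pixels (strictly positive).
#' @param level Pyramid level index used when reading pixels (0 = full resolution).
#' @return An object of class `tile_footprint`.
#' @examples
#' tile_footprint(0, 0, 512, 512)
#' @export
tile_footprint <- function(x, y, w, h, level = 0L) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(w), is.numeric(h))
  if (x < 0 || y < 0) stop("tile footprint must have x >= 0 and y >= 0")
  if (w <= 0 || h <= 0) stop("tile footprint must have w > 0 and h > 0")
  structure(
    list(x = as.numeric(x), y = as.numeric(y),
         w = as.numeric(w), h = as.numeric(h),
         level = as.integer(level)),
    class = "tile_footprint"
  )
}

#' @export
format.tile_footprint <- function(x, ...) {
  sprintf("<tile %gx%g at (%g,%g) level %d>", x$w, x$h, x$x, x$y, x$level)
}

#' @export
print.tile_footprint <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Union of annotated regions for a set of labels
#'
#' Builds the polygonal set-union of all validated regions whose label is in
#' `labels`.  IoT is always computed against this union, so overlapping
#' annotations of the same class can never push a tile's score above 1.
#' Holes are subtracted.  When the selected regions' bounding boxes are
#' pairwise disjoint the rings are concatenated verbatim (no clipping-library
#' round-trip, keeping coordinates bit-exact); otherwise the union is
#' computed with the Clipper polygon engine.
#'
#' @param annots An [annotation_set()].
#' @param labels Character vector of labels to include; `NULL` selects all.
#' @return An object of class `region_union` with fields `labels`, `rings`
#'   (signed rings: positive exteriors, negative holes), `bbox`
#'   (`c(xmin, ymin, xmax, ymax)`) and `area` (px^2).  An empty selection
#'   yields an empty (zero-area) union, which is legal.
#' @examples
#' sq <- annotated_region("tumor", cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
#' u <- region_union(annotation_set("s", list(sq)), "tumor")
#' u$area
#' @export
region_union <- function(annots, labels = NULL) {
  stopifnot(inherits(annots, "annotation_set"))
  regs <- annots$regions
  if (!is.null(labels)) {
    regs <- regs[vapply(regs, function(r) r$label %in% labels, logical(1))]
  }
  regs <- lapply(regs, validate_region)
  sets <- lapply(regs, region_rings)
  rings <- list()
  if (length(sets) == 1L) {
    rings <- sets[[1L]]
  } else if (length(sets) > 1L) {
    boxes <- lapply(sets, ringset_bbox)
    overlap <- FALSE
    for (i in seq_along(boxes)[-1L]) {
      for (j in seq_len(i - 1L)) {
        a <- boxes[[i]]; b <- boxes[[j]]
        if (a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]) {
          overlap <- TRUE
          break
        }
      }
      if (overlap) break
    }
    if (overlap) {
      rings <- Reduce(ringset_union, sets)
    } else {
      rings <- do.call(c, sets)
    }
  }
  structure(
    list(labels = labels, rings = rings,
         bbox = ringset_bbox(rings), area = ringset_area(rings)),
    class = "region_union"
  )
}

#' @export
print.region_union <- function(x, ...) {
  cat(sprintf("<region union: %d ring(s), area %.6g px^2>\n",
              length(x$rings), x$area))
  invisible(x)
}

#' Intersection over tile (IoT)
#'
#' The fraction of a tile's area covered by the annotated-region union:
#' \deqn{IoT = area(A \cap T) / area(T)}
#' where \eqn{A} is the region union and \eqn{T} the tile box.  The score is
#' 1 exactly when the tile lies inside the region (touching the boundary from
#' inside included), 0 exactly when tile and region are disjoint or touch
#' only along an edge from outside, and strictly between 0 and 1 otherwise.
#'
#' Each region ring is clipped against the tile box by Sutherland-Hodgman
#' half-plane clipping in double precision and the signed clipped areas are
#' summed, so hole rings subtract automatically.  Round-off within 1e-9 of
#' the limit values 0 and 1 is snapped to the limit, then the result is
#' clamped to \eqn{[0, 1]}.
#'
#' @param union A [region_union()].
#' @param tile A [tile_footprint()].
#' @return A single number in \eqn{[0, 1]}.
#' @examples
#' sq <- annotated_region("tumor", cbind(c(0, 1024, 1024, 0), c(0, 0, 1024, 1024)))
#' u <- region_union(annotation_set("s", list(sq)), "tumor")
#' compute_iot(u, tile_footprint(0, 0, 512, 512))    # 1
#' compute_iot(u, tile_footprint(1024, 0, 512, 512)) # 0 (touches from outside)
#' @export
compute_iot <- function(union, tile) {
  stopifnot(inherits(union, "region_union"), inherits(tile, "tile_footprint"))
  s_t <- tile$w * tile$h
  if (s_t <= 0) stop("tile area must be positive")
  if (length(union$rings) == 0L) return(0)
  x0 <- tile$x; y0 <- tile$y
  x1 <- tile$x + tile$w; y1 <- tile$y + tile$h
  bb <- union$bbox
  if (bb[1] >= x1 || bb[3] <= x0 || bb[2] >= y1 || bb[4] <= y0) return(0)
  s_int <- 0
  for (ring in union$rings) {
    rb <- ringset_bbox(list(ring))
    if (rb[1] >= x1 || rb[3] <= x0 || rb[2] >= y1 || rb[4] <= y0) next
    clipped <- ring_clip_box(ring, x0, y0, x1, y1)
    if (length(clipped$x) >= 3L) s_int <- s_int + ring_signed_area(clipped)
  }
  iot <- s_int / s_t
  if (abs(iot) <= 1e-9) iot <- 0
  if (abs(1 - iot) <= 1e-9) iot <- 1
  min(max(iot, 0), 1)
}

#' Brute-force rasterized IoT oracle
#'
#' Estimates IoT by testing a `g` x `g` grid of pixel-center sample points in
#' the tile for containment in the region union (even-odd rule, evaluated by
#' scanline edge crossings).  This path shares no code with [compute_iot()]'s
#' exact polygon clipping and serves as its independent cross-check; its
#' discretization error is bounded by the boundary length, roughly 2/`g` for
#' tile-scale regions.
#'
#' @param union A [region_union()].
#' @param tile A [tile_footprint()].
#' @param g Samples per tile edge (>= 16).
#' @return Fraction of sample points inside the union, in \eqn{[0, 1]}.
#' @export
rasterized_iot_oracle <- function(union, tile, g = 2048L) {
  stopifnot(inherits(union, "region_union"), inherits(tile, "tile_footprint"))
  g <- as.integer(g)
  if (g < 16L) stop("oracle grid must have g >= 16")
  if (length(union$rings) == 0L) return(0)
  x0 <- tile$x; y0 <- tile$y
  dx <- tile$w / g; dy <- tile$h / g
  yc <- y0 + (seq_len(g) - 0.5) * dy
  # collect edge crossings per scanline (half-open rule at vertices)
  row_idx <- integer(0)
  cross_x <- numeric(0)
  for (ring in union$rings) {
    xs <- ring$x; ys <- ring$y
    n <- length(xs)
    xs2 <- c(xs[-1L], xs[1L]); ys2 <- c(ys[-1L], ys[1L])
    for (e in seq_len(n)) {
      ya <- ys[e]; yb <- ys2[e]
      if (ya == yb) next
      lo <- min(ya, yb); hi <- max(ya, yb)
      hit <- which(yc >= lo & yc < hi)
      if (length(hit) == 0L) next
      xh <- xs[e] + (yc[hit] - ya) * (xs2[e] - xs[e]) / (yb - ya)
      row_idx <- c(row_idx, hit)
      cross_x <- c(cross_x, xh)
    }
  }
  if (length(row_idx) == 0L) return(0)
  ord <- order(row_idx, cross_x)
  row_idx <- row_idx[ord]
  cross_x <- cross_x[ord]
  # number of sample centers with x-center < t, clamped to [0, g]
  ncenters <- pmin(pmax(floor((cross_x - x0) / dx + 0.5), 0), g)
  # within-row alternation: odd crossing opens an inside interval, even closes
  k <- stats::ave(rep(1, length(row_idx)), row_idx, FUN = cumsum)
  inside <- sum(ncenters[k %% 2 == 0]) - sum(ncenters[k %% 2 == 1])
  min(max(inside / (g * g), 0), 1)
}
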