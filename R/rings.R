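# Internal polygon-ring primitives.
#
# A "ring" is a list(x, y) of vertex coordinates (closure implicit: the last
# vertex connects back to the first).  A "ringset" is a list of rings where
# filled rings carry positive signed (shoelace) area and holes carry negative
# signed area; the covered region is the even-odd / signed sum of its rings.
# Coordinates are level-0 slide pixels, x rightward, y downward, 0-based.

#' @keywords internal
#' @noRd
ring_signed_area <- function(ring) {
  x <- ring$x
  y <- ring$y
  xn <- c(x[-1L], x[1L])
  yn <- c(y[-1L], y[1L])
  0.5 * sum(x * yn - xn * y)
}

#' @keywords internal
#' @noRd
ringset_area <- function(rings) {
  if (length(rings) == 0L) return(0)
  sum(vapply(rings, ring_signed_area, numeric(1)))
}

#' @keywords internal
#' @noRd
ring_reverse <- function(ring) list(x = rev(ring$x), y = rev(ring$y))

# Orient a ring so its signed area has the requested sign.
#' @keywords internal
#' @noRd
ring_orient <- function(ring, positive = TRUE) {
  a <- ring_signed_area(ring)
  if ((a < 0) == positive) ring_reverse(ring) else ring
}

#' @keywords internal
#' @noRd
ringset_bbox <- function(rings) {
  if (length(rings) == 0L) return(c(Inf, Inf, -Inf, -Inf))
  xs <- unlist(lapply(rings, `[[`, "x"))
  ys <- unlist(lapply(rings, `[[`, "y"))
  c(min(xs), min(ys), max(xs), max(ys))
}

# Drop consecutive duplicate vertices (incl. wrap-around duplicate).
#' @keywords internal
#' @noRd
ring_dedup <- function(ring) {
  x <- ring$x
  y <- ring$y
  n <- length(x)
  if (n == 0L) return(ring)
  keep <- c(TRUE, x[-1L] != x[-n] | y[-1L] != y[-n])
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n > 1L && x[1L] == x[n] && y[1L] == y[n]) {
    x <- x[-n]
    y <- y[-n]
  }
  list(x = x, y = y)
}

# Test whether a closed ring is simple (no two non-adjacent edges intersect).
# O(n^2) segment test; annotation rings are small enough for this.
#' @keywords internal
#' @noRd
ring_is_simple <- function(ring) {
  x <- ring$x
  y <- ring$y
  n <- length(x)
  if (n < 3L) return(FALSE)
  x2 <- c(x[-1L], x[1L])
  y2 <- c(y[-1L], y[1L])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (share an endpoint), incl. the wrap pair (1, n)
      if (j == i + 1L || (i == 1L && j == n)) next
      d1 <- cross(x[i], y[i], x2[i], y2[i], x[j], y[j])
      d2 <- cross(x[i], y[i], x2[i], y2[i], x2[j], y2[j])
      d3 <- cross(x[j], y[j], x2[j], y2[j], x[i], y[i])
      d4 <- cross(x[j], y[j], x2[j], y2[j], x2[i], y2[i])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(FALSE)
      }
      # collinear overlap / touching counts as non-simple only when a vertex
      # of one edge lies strictly inside the other edge
      on_seg <- function(px, py, ax, ay, bx, by) {
        px > min(ax, bx) && px < max(ax, bx) || py > min(ay, by) && py < max(ay, by)
      }
      if (d1 == 0 && on_seg(x[j], y[j], x[i], y[i], x2[i], y2[i])) return(FALSE)
      if (d2 == 0 && on_seg(x2[j], y2[j], x[i], y[i], x2[i], y2[i])) return(FALSE)
    }
  }
  TRUE
}

# Clip one ring against the axis-aligned half-open box [x0,x1) x [y0,y1)
# (Sutherland-Hodgman against the four half-planes).  Returns a ring (possibly
# degenerate) whose signed area is the signed area of ring INTERSECT box.
# Pure double arithmetic: no coordinate quantisation, so results are invariant
# under joint scaling/translation of ring and box to machine precision.
#' @keywords internal
#' @noRd
ring_clip_box <- function(ring, x0, y0, x1, y1) {
  x <- ring$x
  y <- ring$y
  clip_lo <- function(x, y, v, lo, is_x) {
    n <- length(x)
    if (n == 0L) return(list(x = x, y = y))
    inside <- v >= lo
    ox <- numeric(0)
    oy <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if (inside[i]) {
        ox <- c(ox, x[i]); oy <- c(oy, y[i])
      }
      if (inside[i] != inside[j]) {
        t <- (lo - v[i]) / (v[j] - v[i])
        ox <- c(ox, x[i] + t * (x[j] - x[i]))
        oy <- c(oy, y[i] + t * (y[j] - y[i]))
        # snap the clipped coordinate exactly onto the boundary
        if (is_x) ox[length(ox)] <- lo else oy[length(oy)] <- lo
      }
    }
    list(x = ox, y = oy)
  }
  clip_hi <- function(x, y, v, hi, is_x) {
    n <- length(x)
    if (n == 0L) return(list(x = x, y = y))
    inside <- v <= hi
    ox <- numeric(0)
    oy <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if (inside[i]) {
        ox <- c(ox, x[i]); oy <- c(oy, y[i])
      }
      if (inside[i] != inside[j]) {
        t <- (hi - v[i]) / (v[j] - v[i])
        ox <- c(ox, x[i] + t * (x[j] - x[i]))
        oy <- c(oy, y[i] + t * (y[j] - y[i]))
        if (is_x) ox[length(ox)] <- hi else oy[length(oy)] <- hi
      }
    }
    list(x = ox, y = oy)
  }
  p <- clip_lo(x, y, x, x0, TRUE)
  p <- clip_hi(p$x, p$y, p$x, x1, TRUE)
  p <- clip_lo(p$x, p$y, p$y, y0, FALSE)
  p <- clip_hi(p$x, p$y, p$y, y1, FALSE)
  p
}

# Union two ringsets with polyclip (nonzero fill on both sides, matching the
# positive-exterior / negative-hole orientation convention).
#' @keywords internal
#' @noRd
ringset_union <- function(a, b) {
  if (length(a) == 0L) return(b)
  if (length(b) == 0L) return(a)
  polyclip::polyclip(a, b, op = "union", fillA = "nonzero", fillB = "nonzero")
}
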