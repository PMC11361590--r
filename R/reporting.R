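#' Extraction-map preview
#'
#' Renders a slide thumbnail with every grid tile outlined, color-coded by
#' the decision recorded in the manifest (decisions are read from the
#' manifest, never recomputed, so the preview can never disagree with the
#' extraction), and annotation contours drawn on top.
#'
#' @param handle A [open_slide()] handle.
#' @param manifest An `extraction_manifest` from [extract_annotated()] /
#'   [extract_holistic()].
#' @param annots Optional [annotation_set()] whose contours to draw.
#' @param thumb_long_side Long side of the thumbnail in px (>= 64).
#' @param colors Named list of RGB triplets per decision plus `annotation`.
#' @return An RGB array (`h x w x 3`, 0-255) of class `tile_raster`.
#' @export
preview_overlay <- function(handle, manifest, annots = NULL,
                            thumb_long_side = 1024L,
                            colors = list(extracted = c(40, 80, 220),
                                          rejected_iot = c(220, 40, 40),
                                          rejected_bot = c(240, 150, 30),
                                          rejected_sampling = c(150, 150, 150),
                                          annotation = c(30, 160, 60))) {
  stopifnot(inherits(handle, "slide_handle"), inherits(manifest, "extraction_manifest"))
  if (thumb_long_side < 64L) stop("thumbnail long side must be >= 64 px")
  d0 <- handle$level_dims[[1L]]
  f <- thumb_long_side / max(d0[["w"]], d0[["h"]])
  tw <- max(1L, round(d0[["w"]] * f))
  th <- max(1L, round(d0[["h"]] * f))
  # subsample the smallest level at least as large as the thumbnail
  src_lvl <- length(handle$.levels)
  while (src_lvl > 1L && handle$level_dims[[src_lvl]][["w"]] < tw) src_lvl <- src_lvl - 1L
  src <- handle$.levels[[src_lvl]]
  rows <- pmin(dim(src)[1L], pmax(1L, round((seq_len(th) - 0.5) / th * dim(src)[1L])))
  cols <- pmin(dim(src)[2L], pmax(1L, round((seq_len(tw) - 0.5) / tw * dim(src)[2L])))
  img <- src[rows, cols, , drop = FALSE]
  storage.mode(img) <- "integer"
  rec <- manifest$records
  for (i in seq_len(nrow(rec))) {
    col <- colors[[rec$decision[i]]]
    if (is.null(col)) next
    img <- draw_rect(img, rec$x[i] * f, rec$y[i] * f,
                     (rec$x[i] + rec$w[i]) * f, (rec$y[i] + rec$h[i]) * f, col)
  }
  if (!is.null(annots)) {
    for (r in annots$regions) {
      img <- draw_ring(img, r$exterior * f, colors$annotation)
      for (hole in r$holes) img <- draw_ring(img, hole * f, colors$annotation)
    }
  }
  tile_raster(img)
}

#' @keywords internal
#' @noRd
draw_rect <- function(img, x0, y0, x1, y1, rgb) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  r0 <- max(1L, round(y0) + 1L); r1 <- min(h, round(y1))
  c0 <- max(1L, round(x0) + 1L); c1 <- min(w, round(x1))
  if (r0 > r1 || c0 > c1) return(img)
  for (c in 1:3) {
    img[r0, c0:c1, c] <- rgb[c]
    img[r1, c0:c1, c] <- rgb[c]
    img[r0:r1, c0, c] <- rgb[c]
    img[r0:r1, c1, c] <- rgb[c]
  }
  img
}

#' @keywords internal
#' @noRd
draw_ring <- function(img, verts, rgb) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  v2 <- rbind(verts[-1L, , drop = FALSE], verts[1L, , drop = FALSE])
  for (e in seq_len(nrow(verts))) {
    len <- max(abs(v2[e, 1L] - verts[e, 1L]), abs(v2[e, 2L] - verts[e, 2L]), 1)
    t <- seq(0, 1, length.out = ceiling(len) + 1L)
    px <- pmin(w, pmax(1L, round(verts[e, 1L] + t * (v2[e, 1L] - verts[e, 1L])) + 1L))
    py <- pmin(h, pmax(1L, round(verts[e, 2L] + t * (v2[e, 2L] - verts[e, 2L])) + 1L))
    for (c in 1:3) img[cbind(py, px, c)] <- rgb[c]
  }
  img
}

#' Per-slide processing-time summary
#'
#' Location and spread statistics of per-slide wall-clock extraction times:
#' min, max, mean, sd, variance, quartiles (linear interpolation) and total.
#'
#' @param per_slide_seconds Nonempty numeric vector of per-slide seconds.
#' @return A one-row data frame with columns `min`, `max`, `mean`, `sd`,
#'   `variance`, `q1`, `median`, `q3`, `total`.
#' @examples
#' timing_summary(c(2, 4, 6, 8))
#' @export
timing_summary <- function(per_slide_seconds) {
  x <- per_slide_seconds
  if (!is.numeric(x) || length(x) == 0L || any(is.na(x))) {
    stop("need a nonempty numeric vector of per-slide seconds")
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(
    min = min(x), max = max(x), mean = mean(x),
    sd = if (length(x) > 1L) stats::sd(x) else 0,
    variance = if (length(x) > 1L) stats::var(x) else 0,
    q1 = q[1L], median = q[2L], q3 = q[3L], total = sum(x)
  )
}
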