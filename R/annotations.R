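#' One labeled annotation polygon
#'
#' Represents a single hand-drawn region (e.g. a tumor outline) as an exterior
#' vertex ring plus optional hole rings, in level-0 pixel coordinates
#' (0-based, x rightward, y downward — the ASAP / CAMELYON16 convention).
#' Ring closure is implicit: the last vertex need not repeat the first.
#'
#' @param label Class label string, e.g. `"tumor"`.
#' @param exterior Two-column matrix (or coercible) of (x, y) vertices,
#'   at least 3 distinct points; fractional coordinates allowed.
#' @param holes List of two-column vertex matrices, each a hole ring.
#' @param region_id Source identifier string.
#' @return An object of class `annotated_region`.
#' @examples
#' annotated_region("tumor", cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
#' @export
annotated_region <- function(label, exterior, holes = list(), region_id = NA_character_) {
  exterior <- as_vertex_matrix(exterior)
  if (nrow(unique(exterior)) < 3L) {
    stop("annotated region needs >= 3 distinct vertices")
  }
  holes <- lapply(holes, as_vertex_matrix)
  structure(
    list(label = as.character(label), exterior = exterior, holes = holes,
         region_id = as.character(region_id)),
    class = "annotated_region"
  )
}

#' @keywords internal
#' @noRd
as_vertex_matrix <- function(v) {
  m <- as.matrix(v)
  if (!is.numeric(m) || ncol(m) != 2L) stop("vertices must be an n x 2 numeric matrix")
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' @export
print.annotated_region <- function(x, ...) {
  cat(sprintf("<region '%s' (%s): %d vertices, %d hole(s)>\n",
              x$label, x$region_id, nrow(x$exterior), length(x$holes)))
  invisible(x)
}

#' A slide's annotations
#'
#' @param slide_id Slide identifier string.
#' @param regions List of [annotated_region()] objects.
#' @param space Coordinate-space tag; only `"level0_pixels"` is supported.
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(slide_id, regions, space = "level0_pixels") {
  if (!identical(space, "level0_pixels")) {
    stop("annotation space must be 'level0_pixels'")
  }
  stopifnot(all(vapply(regions, inherits, logical(1), "annotated_region")))
  structure(
    list(slide_id = as.character(slide_id), regions = regions, space = space),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotations for '%s': %d region(s); labels: %s>\n",
              x$slide_id, length(x$regions),
              paste(unique(annotation_labels(x)), collapse = ", ")))
  invisible(x)
}

#' Labels present in an annotation set
#' @param annots An [annotation_set()].
#' @return Character vector, one element per region.
#' @export
annotation_labels <- function(annots) {
  vapply(annots$regions, `[[`, character(1), "label")
}

#' Filter an annotation set by label
#' @param annots An [annotation_set()].
#' @param labels Labels to keep; a possibly empty subset is returned.
#' @return A new [annotation_set()].
#' @export
filter_regions <- function(annots, labels) {
  annotation_set(annots$slide_id,
                 annots$regions[annotation_labels(annots) %in% labels],
                 annots$space)
}

#' Validate and repair an annotation region
#'
#' Hand-drawn clinical outlines are frequently self-touching or
#' self-intersecting.  A simple (non-self-intersecting) exterior with valid
#' holes is returned unchanged; otherwise the rings are decomposed by the
#' polygon engine into a valid (multi)polygon under the nonzero fill rule,
#' which preserves the total covered area (a bowtie ring becomes its two
#' triangular lobes).  A repair that yields empty geometry — e.g. a hole
#' swallowing the whole exterior — is an error.
#'
#' @param region An [annotated_region()].
#' @return The region, with a `rings` attribute carrying the validated signed
#'   rings (positive exteriors, negative holes) used by downstream geometry.
#' @export
validate_region <- function(region) {
  stopifnot(inherits(region, "annotated_region"))
  if (!is.null(attr(region, "rings"))) return(region)
  ext <- ring_dedup(list(x = region$exterior[, 1L], y = region$exterior[, 2L]))
  if (length(ext$x) < 3L) {
    stop(sprintf("degenerate region '%s': fewer than 3 distinct vertices", region$region_id))
  }
  hole_rings <- lapply(region$holes, function(h) ring_dedup(list(x = h[, 1L], y = h[, 2L])))
  hole_rings <- hole_rings[vapply(hole_rings, function(r) length(r$x) >= 3L, logical(1))]
  simple <- ring_is_simple(ext) && all(vapply(hole_rings, ring_is_simple, logical(1)))
  if (simple && length(hole_rings) == 0L) {
    rings <- list(ring_orient(ext, positive = TRUE))
  } else {
    # orient exterior positive / holes negative, then normalise via the
    # clipping engine (nonzero fill keeps every covered lobe)
    rings <- c(list(ring_orient(ext, positive = TRUE)),
               lapply(hole_rings, ring_orient, positive = FALSE))
    rings <- polyclip::polysimplify(rings, filltype = "nonzero")
  }
  area <- ringset_area(rings)
  if (length(rings) == 0L || area <= 1e-12) {
    stop(sprintf("degenerate region '%s': repaired geometry is empty", region$region_id))
  }
  attr(region, "rings") <- rings
  attr(region, "area") <- area
  region
}

#' @keywords internal
#' @noRd
region_rings <- function(region) {
  r <- validate_region(region)
  attr(r, "rings")
}

#' Area of a validated region (exterior minus holes), px^2
#' @param region An [annotated_region()].
#' @return Numeric area.
#' @export
region_area <- function(region) {
  r <- validate_region(region)
  attr(r, "area")
}

#' Parse an annotation file into level-0 polygon regions
#'
#' Supported dialects:
#' \describe{
#'   \item{`asap_xml`}{ASAP / CAMELYON16 XML: `<Annotations><Annotation
#'     PartOfGroup=..><Coordinates><Coordinate Order= X= Y=/>`.  Vertices are
#'     sorted by `Order`; `PartOfGroup` (falling back to `Name`) is the label.}
#'   \item{`geojson`}{A FeatureCollection of Polygon / MultiPolygon features;
#'     the label is read from `properties.classification.name`, falling back
#'     to `properties.label`.  Interior rings become holes.}
#'   \item{`plain_json`}{`{"slide_id": str, "regions": [{"label": str,
#'     "exterior": [[x,y],...], "holes": [[[x,y],...],...]}]}` — the neutral
#'     interchange written by [write_annotations_json()].}
#' }
#' `auto` sniffs the dialect from the file extension, then from content.
#' Coordinates are taken verbatim (assumed level-0 pixels).  A region with
#' fewer than 3 vertices is dropped with a warning, not an error.
#'
#' @param path Annotation file path.
#' @param dialect One of `"auto"`, `"asap_xml"`, `"geojson"`, `"plain_json"`.
#' @return An [annotation_set()].
#' @export
parse_annotations <- function(path, dialect = c("auto", "asap_xml", "geojson", "plain_json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  if (dialect == "auto") dialect <- sniff_dialect(path)
  out <- switch(dialect,
    asap_xml   = parse_asap_xml(path),
    geojson    = parse_geojson(path),
    plain_json = parse_plain_json(path)
  )
  out
}

#' @keywords internal
#' @noRd
sniff_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xml") return("asap_xml")
  if (ext == "geojson") return("geojson")
  head <- paste(readLines(path, n = 5L, warn = FALSE), collapse = " ")
  if (grepl("^\\s*<", head)) return("asap_xml")
  if (grepl("FeatureCollection|\"features\"", head)) return("geojson")
  if (grepl("\"regions\"", head) ||
      grepl("\"regions\"", paste(readLines(path, warn = FALSE), collapse = " "))) {
    return("plain_json")
  }
  if (ext == "json") return("plain_json")
  stop(sprintf("cannot determine annotation dialect of %s", path))
}

#' @keywords internal
#' @noRd
parse_asap_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf("asap_xml parse error in %s: %s",
                                                   path, conditionMessage(e))))
  nodes <- xml2::xml_find_all(doc, ".//Annotation")
  regions <- list()
  for (nd in nodes) {
    name <- xml2::xml_attr(nd, "Name")
    group <- xml2::xml_attr(nd, "PartOfGroup")
    label <- if (!is.na(group) && nzchar(group) && group != "None") group else name
    coords <- xml2::xml_find_all(nd, ".//Coordinate")
    if (length(coords) == 0L) next
    ord <- as.numeric(xml2::xml_attr(coords, "Order"))
    xs <- as.numeric(xml2::xml_attr(coords, "X"))
    ys <- as.numeric(xml2::xml_attr(coords, "Y"))
    o <- order(ord)
    m <- cbind(xs[o], ys[o])
    if (nrow(unique(m)) < 3L) {
      warning(sprintf("dropping region '%s': fewer than 3 distinct vertices", name))
      next
    }
    regions <- c(regions, list(annotated_region(label, m, region_id = name)))
  }
  annotation_set(slide_id_from_path(path), regions)
}

#' @keywords internal
#' @noRd
parse_geojson <- function(path) {
  js <- tryCatch(jsonlite::read_json(path),
                 error = function(e) stop(sprintf("geojson parse error in %s: %s",
                                                  path, conditionMessage(e))))
  feats <- if (identical(js$type, "FeatureCollection")) js$features else list(js)
  ring_mat <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    # GeoJSON rings repeat the first vertex; drop the closing copy
    if (nrow(m) > 1L && all(m[1L, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  }
  regions <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geom <- f$geometry
    if (is.null(geom)) next
    label <- f$properties$classification$name
    if (is.null(label)) label <- f$properties$label
    if (is.null(label)) label <- "unlabeled"
    id <- f$id
    if (is.null(id)) id <- sprintf("feature_%d", i)
    polys <- switch(geom$type,
                    Polygon = list(geom$coordinates),
                    MultiPolygon = geom$coordinates,
                    NULL)
    if (is.null(polys)) next
    for (p in polys) {
      ext <- ring_mat(p[[1]])
      if (nrow(unique(ext)) < 3L) {
        warning(sprintf("dropping region '%s': fewer than 3 distinct vertices", id))
        next
      }
      holes <- lapply(p[-1L], ring_mat)
      regions <- c(regions, list(annotated_region(label, ext, holes, region_id = as.character(id))))
    }
  }
  annotation_set(slide_id_from_path(path), regions)
}

#' @keywords internal
#' @noRd
parse_plain_json <- function(path) {
  js <- tryCatch(jsonlite::read_json(path),
                 error = function(e) stop(sprintf("plain_json parse error in %s: %s",
                                                  path, conditionMessage(e))))
  if (is.null(js$regions)) stop(sprintf("plain_json parse error in %s: no 'regions' field", path))
  ring_mat <- function(ring) do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  regions <- list()
  for (i in seq_along(js$regions)) {
    r <- js$regions[[i]]
    ext <- ring_mat(r$exterior)
    id <- if (!is.null(r$region_id)) r$region_id else sprintf("region_%d", i)
    if (nrow(unique(ext)) < 3L) {
      warning(sprintf("dropping region '%s': fewer than 3 distinct vertices", id))
      next
    }
    holes <- if (is.null(r$holes)) list() else lapply(r$holes, ring_mat)
    regions <- c(regions, list(annotated_region(r$label, ext, holes, region_id = id)))
  }
  sid <- if (!is.null(js$slide_id)) js$slide_id else slide_id_from_path(path)
  annotation_set(sid, regions)
}

#' @keywords internal
#' @noRd
slide_id_from_path <- function(path) {
  tools::file_path_sans_ext(basename(path))
}

#' Write an annotation set as plain JSON
#'
#' The inverse of [parse_annotations()]'s `plain_json` dialect; a round trip
#' preserves labels, vertex counts and coordinates exactly.
#'
#' @param annots An [annotation_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations_json <- function(annots, path) {
  stopifnot(inherits(annots, "annotation_set"))
  regions <- lapply(annots$regions, function(r) {
    out <- list(label = r$label,
                region_id = r$region_id,
                exterior = unname(apply(r$exterior, 1L, function(p) c(p[1], p[2]),
                                        simplify = FALSE)))
    out$holes <- lapply(r$holes, function(h) {
      unname(apply(h, 1L, function(p) c(p[1], p[2]), simplify = FALSE))
    })
    out
  })
  jsonlite::write_json(list(slide_id = annots$slide_id, regions = regions),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
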