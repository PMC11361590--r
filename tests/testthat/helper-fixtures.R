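# Generated fixtures are deterministic, so build each case once per session.
.fx_cache <- new.env(parent = emptyenv())

get_fixture <- function(case) {
  if (!is.null(.fx_cache[[case]])) return(.fx_cache[[case]])
  fx <- generate_fixture(fixture_case(case), file.path(tempdir(), paste0("fx_", case)),
                         slide_id = case)
  .fx_cache[[case]] <- fx
  fx
}

get_slide <- function(case) open_slide(get_fixture(case)$slide_path)

# single-region helper: a union from one exterior ring (+ optional holes)
make_union <- function(exterior, holes = list(), label = "tumor") {
  reg <- annotated_region(label, exterior, holes = holes)
  region_union(annotation_set("test", list(reg)), label)
}

rect_ring <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# independent shoelace area for test expectations
shoelace <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  abs(0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y))
}

# random star-shaped polygon around a center (always simple)
random_star_poly <- function(cx, cy, rmin, rmax, n = 12) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, rmin, rmax)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# true crescent ring: disc minus an overlapping disc, built independently of
# the package geometry path via the Clipper difference
crescent_ring <- function(cx, cy, r_outer, bite_dx, bite_r, n = 96) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  outer <- list(x = cx + r_outer * cos(th), y = cy + r_outer * sin(th))
  bite <- list(x = cx + bite_dx + bite_r * cos(th), y = cy + bite_r * sin(th))
  d <- polyclip::polyclip(list(outer), list(bite), op = "minus")
  cbind(d[[1]]$x, d[[1]]$y)
}
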