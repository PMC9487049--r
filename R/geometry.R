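# Field geometry: tumor nests as simple polygons inside a rectangular imaging
# field. Coordinates are micrometres with the origin at the field top-left
# corner (x right, y down); densities convert um^2 to mm^2 by /1e6.

#' Polygonized disc
#'
#' Regular n-gon inscribed in a circle, used to represent tumor nests.
#'
#' @param cx,cy center (um).
#' @param r radius (um).
#' @param n_vertices number of polygon vertices.
#' @return numeric matrix with columns x, y (vertices in order, not closed).
#' @export
disc_polygon <- function(cx, cy, r, n_vertices = 64L) {
  stopifnot(r > 0, n_vertices >= 3L)
  theta <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  cbind(x = cx + r * cos(theta), y = cy + r * sin(theta))
}

# Sutherland-Hodgman clip of a simple polygon to [0,w] x [0,h].
clip_polygon_rect <- function(poly, width, height) {
  clip_edge <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- vector("list", 2L * n)
    k <- 0L
    prev <- pts[n, ]
    prev_in <- inside(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      cur_in <- inside(cur)
      if (cur_in) {
        if (!prev_in) {
          k <- k + 1L; out[[k]] <- intersect(prev, cur)
        }
        k <- k + 1L; out[[k]] <- cur
      } else if (prev_in) {
        k <- k + 1L; out[[k]] <- intersect(prev, cur)
      }
      prev <- cur
      prev_in <- cur_in
    }
    if (k == 0L) return(poly[0, , drop = FALSE])
    do.call(rbind, out[seq_len(k)])
  }
  ix <- function(a, vertical) function(p, q) {
    if (vertical) {
      t <- (a - p[1]) / (q[1] - p[1])
      c(a, p[2] + t * (q[2] - p[2]))
    } else {
      t <- (a - p[2]) / (q[2] - p[2])
      c(p[1] + t * (q[1] - p[1]), a)
    }
  }
  poly <- clip_edge(poly, function(p) p[1] >= 0, ix(0, TRUE))
  poly <- clip_edge(poly, function(p) p[1] <= width, ix(width, TRUE))
  poly <- clip_edge(poly, function(p) p[2] >= 0, ix(0, FALSE))
  poly <- clip_edge(poly, function(p) p[2] <= height, ix(height, FALSE))
  colnames(poly) <- c("x", "y")
  poly
}

#' Polygon area (shoelace formula)
#'
#' @param poly vertex matrix (x, y), unclosed.
#' @return area in the square of the coordinate unit (um^2 here).
#' @export
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Point-in-polygon test (boundary inclusive)
#'
#' Crossing-number test, vectorized over points, with points lying on a
#' polygon edge (within `eps`) counted as inside. Boundary inclusivity is the
#' declared compartment convention: cells on a nest border are intra-tumoral.
#'
#' @param px,py point coordinates (um).
#' @param poly vertex matrix.
#' @param eps boundary tolerance (um).
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- length(px)
  inside <- logical(n)
  on_edge <- logical(n)
  nv <- nrow(poly)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((px - xi) * dx + (py - yi) * dy) / len2
      t <- pmin(1, pmax(0, t))
      ex <- xi + t * dx - px
      ey <- yi + t * dy - py
      on_edge <- on_edge | (ex * ex + ey * ey <= eps * eps)
    } else {
      on_edge <- on_edge | ((px - xi)^2 + (py - yi)^2 <= eps * eps)
    }
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside | on_edge
}

#' Field geometry
#'
#' A rectangular imaging field with its tumor-nest mask. Nest polygons are
#' clipped to the field rectangle at construction; the tumor compartment is
#' the union of the nests and the stroma the remainder, so tumor area plus
#' stroma area equals the field area by construction. Nests are assumed
#' pairwise disjoint (the generator guarantees this); overlapping nests would
#' double-count tumor area.
#'
#' @param field_id field identifier.
#' @param width,height field dimensions (um). Default 650 x 500 um.
#' @param nests list of vertex matrices (um).
#' @return object of class `field_geometry`.
#' @export
field_geometry <- function(field_id, width = 650, height = 500, nests = list()) {
  if (width <= 0 || height <= 0) .err("field width and height must be positive")
  nests <- lapply(nests, function(p) {
    p <- as.matrix(p)
    if (nrow(p) < 3L) .err("a nest polygon needs at least 3 vertices")
    clip_polygon_rect(p, width, height)
  })
  nests <- Filter(function(p) nrow(p) >= 3L, nests)
  structure(
    list(field_id = as.character(field_id), width = width, height = height,
         nests = nests),
    class = "field_geometry"
  )
}

#' @export
print.field_geometry <- function(x, ...) {
  a <- compartment_areas(x)
  cat(sprintf("<field_geometry> %s: %g x %g um, %d nest(s), tumor fraction %.2f\n",
              x$field_id, x$width, x$height, length(x$nests),
              a[["tumor"]] / (a[["tumor"]] + a[["stroma"]])))
  invisible(x)
}

#' Compartment areas of a field
#'
#' @param geom a `field_geometry`.
#' @return named numeric `c(tumor=, stroma=)` in um^2.
#' @export
compartment_areas <- function(geom) {
  stopifnot(inherits(geom, "field_geometry"))
  tumor <- sum(vapply(geom$nests, polygon_area, numeric(1)))
  total <- geom$width * geom$height
  c(tumor = tumor, stroma = total - tumor)
}

#' Which points fall inside any tumor nest
#'
#' @param geom a `field_geometry`.
#' @param px,py coordinates (um).
#' @return logical vector (boundary inclusive).
#' @export
point_in_nests <- function(geom, px, py) {
  inside <- logical(length(px))
  for (poly in geom$nests) {
    # bounding-box pre-filter keeps the edge loop off distant points
    todo <- which(!inside &
                    px >= min(poly[, 1]) & px <= max(poly[, 1]) &
                    py >= min(poly[, 2]) & py <= max(poly[, 2]))
    if (!length(todo)) next
    inside[todo] <- point_in_polygon(px[todo], py[todo], poly)
  }
  inside
}
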