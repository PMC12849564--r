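# planar polygon primitives (µm coordinates, image convention: y down)
#
# Polygons are closed implicitly: an n x 2 matrix of vertices without the
# repeated first point. These helpers back vessel tiling and the synthetic
# vessel geometry; they assume simple (non-self-intersecting) rings.

#' Signed and absolute polygon area (shoelace formula)
#' @param poly Numeric matrix with columns x, y.
#' @return Area in squared input units.
#' @keywords internal
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Polygon centroid (area-weighted)
#' @keywords internal
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) {
    return(c(mean(x), mean(y)))
  }
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

# even-odd ray casting; px, py vectors
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Sutherland-Hodgman clip of a simple polygon against an axis-aligned
# rectangle; returns NULL when the intersection is empty.
clip_polygon_rect <- function(poly, xmin, xmax, ymin, ymax) {
  clip_halfplane <- function(pts, inside_fn, intersect_fn) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    prev <- pts[n, ]
    prev_in <- inside_fn(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      cur_in <- inside_fn(cur)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, intersect_fn(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, intersect_fn(prev, cur))
      }
      prev <- cur
      prev_in <- cur_in
    }
    out
  }
  lerp_x <- function(p, q, x) c(x, p[2] + (q[2] - p[2]) * (x - p[1]) / (q[1] - p[1]))
  lerp_y <- function(p, q, y) c(p[1] + (q[1] - p[1]) * (y - p[2]) / (q[2] - p[2]), y)
  pts <- poly
  pts <- clip_halfplane(pts, function(p) p[1] >= xmin, function(p, q) lerp_x(p, q, xmin))
  pts <- clip_halfplane(pts, function(p) p[1] <= xmax, function(p, q) lerp_x(p, q, xmax))
  pts <- clip_halfplane(pts, function(p) p[2] >= ymin, function(p, q) lerp_y(p, q, ymin))
  pts <- clip_halfplane(pts, function(p) p[2] <= ymax, function(p, q) lerp_y(p, q, ymax))
  if (nrow(pts) < 3L || polygon_area(pts) < .Machine$double.eps) NULL else pts
}

# axis-aligned ribbon rotated by `angle` around its center: a rectangle of
# given length x width; returns a 4 x 2 vertex matrix
rect_ribbon <- function(cx, cy, length, width, angle) {
  hx <- length / 2; hy <- width / 2
  base <- rbind(c(-hx, -hy), c(hx, -hy), c(hx, hy), c(-hx, hy))
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(base %*% t(rot), 2, c(cx, cy), "+")
}

# crude simplicity check: a simple closed ring has positive area and no
# duplicated consecutive vertices
check_polygon <- function(poly, id = "?") {
  if (!is.matrix(poly) || ncol(poly) != 2 || nrow(poly) < 3) {
    abort(paste0("Vessel feature ", id, " is not a polygon with >= 3 vertices."))
  }
  if (!all(is.finite(poly))) {
    abort(paste0("Vessel feature ", id, " has non-finite coordinates."))
  }
  if (polygon_area(poly) <= 0) {
    abort(paste0("Vessel feature ", id, " has zero area."))
  }
  invisible(poly)
}

#' Build a vessel geometry table
#'
#' @param polygons List of n x 2 vertex matrices (µm).
#' @param source `"annotation"` or `"synthetic"`.
#' @return A tibble with columns `vessel_id`, `source` and list-column
#'   `polygon`.
#' @export
vessel_geometry <- function(polygons, source = "annotation") {
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    colnames(p) <- c("x", "y")
    p
  })
  for (i in seq_along(polygons)) check_polygon(polygons[[i]], id = i)
  tibble(
    vessel_id = seq_along(polygons),
    source = rep(source, length(polygons)),
    polygon = polygons
  )
}
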