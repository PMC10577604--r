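# Polygon primitives shared by the compartment and spatial modules.
# Polygons are two-column matrices (x, y) in micrometres, vertices in order,
# not closed (first vertex is not repeated at the end).

#' Polygon area by the shoelace formula
#'
#' @param poly Two-column numeric matrix of vertices (x, y), in order.
#' @return Absolute area in the square of the coordinate unit.
#' @export
poly_area <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  j <- c(seq_len(nrow(poly))[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || nrow(poly) < 3L)
    stop("a polygon needs a two-column matrix with at least 3 vertices")
  if (!all(is.finite(poly))) stop("polygon vertices must be finite")
  # drop a closing vertex if the caller supplied one
  n <- nrow(poly)
  if (all(poly[1L, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  unname(poly)
}

#' Test points for inclusion in a polygon
#'
#' Ray-casting with the closed-set convention: points on an edge or vertex
#' count as inside. Vectorized over points.
#'
#' @param x,y Numeric vectors of point coordinates.
#' @param poly Two-column vertex matrix.
#' @param eps Tolerance for the on-boundary test, same unit as coordinates.
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, poly, eps = 1e-9) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  px <- poly[, 1L]; py <- poly[, 2L]
  qx <- poly[c(2:n, 1L), 1L]; qy <- poly[c(2:n, 1L), 2L]
  inside <- logical(length(x))
  boundary <- logical(length(x))
  for (i in seq_len(n)) {
    x1 <- px[i]; y1 <- py[i]; x2 <- qx[i]; y2 <- qy[i]
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    # distance from point to segment
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    t <- if (L2 > 0) pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / L2)) else 0
    d2 <- (x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2
    boundary <- boundary | d2 <= eps * eps
  }
  inside | boundary
}

#' Membership of points in any polygon of a list
#'
#' @param x,y Point coordinates.
#' @param polys List of vertex matrices.
#' @return Integer vector: index of the first containing polygon, 0 if none.
#' @export
point_in_polygons <- function(x, y, polys) {
  hit <- integer(length(x))
  for (k in seq_along(polys)) {
    todo <- hit == 0L
    if (!any(todo)) break
    p <- polys[[k]]
    bb <- apply(p, 2L, range)
    cand <- todo & x >= bb[1L, 1L] & x <= bb[2L, 1L] &
      y >= bb[1L, 2L] & y <= bb[2L, 2L]
    if (any(cand))
      hit[cand][point_in_polygon(x[cand], y[cand], p)] <- k
  }
  hit
}

#' Discretize an ellipse as a polygon
#'
#' @param cx,cy Center. @param a,b Semi-axes (micrometres).
#' @param angle Rotation in radians. @param n Number of vertices.
#' @return Two-column vertex matrix.
#' @export
ellipse_polygon <- function(cx, cy, a, b, angle = 0, n = 64L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ex <- a * cos(t); ey <- b * sin(t)
  cbind(x = cx + ex * cos(angle) - ey * sin(angle),
        y = cy + ex * sin(angle) + ey * cos(angle))
}

segments_intersect <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2); d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) & ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

polygon_self_intersects <- function(poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  idx <- cbind(seq_len(n), c(2:n, 1L))
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the wrap-around
      if (segments_intersect(poly[idx[i, 1L], ], poly[idx[i, 2L], ],
                             poly[idx[j, 1L], ], poly[idx[j, 2L], ])) return(TRUE)
    }
  }
  FALSE
}

polygons_overlap <- function(p1, p2) {
  any(point_in_polygon(p1[, 1L], p1[, 2L], p2)) ||
    any(point_in_polygon(p2[, 1L], p2[, 2L], p1))
}

#' Write polygons as a GeoJSON FeatureCollection
#'
#' Coordinates are in micrometres; the unit is declared in each feature's
#' properties so round-trips are unambiguous.
#'
#' @param polys List of two-column vertex matrices.
#' @param path Output file.
#' @param properties Optional list (one element per polygon) of property lists.
#' @export
write_polygons_geojson <- function(polys, path, properties = NULL) {
  feats <- lapply(seq_along(polys), function(i) {
    p <- as_polygon(polys[[i]])
    ring <- rbind(p, p[1L, , drop = FALSE])  # GeoJSON rings are closed
    props <- c(list(unit = "micrometre"),
               if (!is.null(properties)) properties[[i]] else NULL)
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) ring[k, ]))))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  # digits = I(17) keeps coordinate round-trips bit-exact
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read polygons from a GeoJSON FeatureCollection
#'
#' Validates each polygon ring: closed, >= 3 distinct vertices, not
#' self-intersecting (a degenerate repair by vertex deduplication is
#' attempted first). Overlapping polygons are kept as distinct features;
#' \code{\link{load_follicles}} applies the union semantics.
#'
#' @param path GeoJSON file.
#' @return List of two-column vertex matrices.
#' @export
read_polygons_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection")) stop("not a FeatureCollection")
  lapply(fc$features, function(f) {
    geom <- f$geometry
    if (!identical(geom$type, "Polygon")) stop("only Polygon features supported")
    ring <- do.call(rbind, lapply(geom$coordinates[[1L]], function(v)
      c(as.numeric(v[[1L]]), as.numeric(v[[2L]]))))
    poly <- as_polygon(ring)
    poly <- poly[!duplicated(poly), , drop = FALSE]  # repair duplicate vertices
    if (nrow(poly) < 3L) stop("degenerate polygon in ", path)
    if (polygon_self_intersects(poly))
      stop("self-intersecting polygon in ", path, " could not be repaired")
    colnames(poly) <- c("x", "y")
    poly
  })
}

#' Rasterize polygons onto a pixel mask
#'
#' Pixel centers falling inside any polygon (closed-set convention) are set
#' to TRUE. The grid has origin at the tile's top-left corner and follows
#' the image convention (rows = y increasing downward).
#'
#' @param polys List of polygons (micrometre coordinates).
#' @param width_um,height_um Tile size.
#' @param um_per_px Pixel pitch.
#' @return Logical matrix (rows = y, columns = x).
#' @export
rasterize_polygons <- function(polys, width_um, height_um, um_per_px) {
  nx <- max(1L, round(width_um / um_per_px))
  ny <- max(1L, round(height_um / um_per_px))
  mask <- matrix(FALSE, nrow = ny, ncol = nx)
  cx <- (seq_len(nx) - 0.5) * um_per_px
  cy <- (seq_len(ny) - 0.5) * um_per_px
  for (p in polys) {
    bb <- apply(as_polygon(p), 2L, range)
    ix <- which(cx >= bb[1L, 1L] - um_per_px & cx <= bb[2L, 1L] + um_per_px)
    iy <- which(cy >= bb[1L, 2L] - um_per_px & cy <= bb[2L, 2L] + um_per_px)
    if (!length(ix) || !length(iy)) next
    g <- expand.grid(y = iy, x = ix)
    ins <- point_in_polygon(cx[g$x], cy[g$y], p)
    mask[cbind(g$y[ins], g$x[ins])] <- TRUE
  }
  mask
}
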