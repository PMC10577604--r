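# Spatial structure per compartment: Voronoi quadrat tessellation on a
# hexagonal seed lattice, Morisita-Horn co-localization, nearest-neighbor
# phenotype profiles.

hex_seeds <- function(width_um, height_um, spacing) {
  dy <- spacing * sqrt(3) / 2
  ys <- seq(dy / 2, height_um + spacing, by = dy)
  xs_base <- seq(-spacing, width_um + spacing, by = spacing)
  out <- do.call(rbind, lapply(seq_along(ys), function(r) {
    off <- if (r %% 2 == 0) spacing / 2 else 0
    cbind(x = xs_base + off, y = ys[r])
  }))
  structure(out, lattice = list(spacing = spacing, dy = dy,
                                x0 = xs_base[1L], y0 = ys[1L],
                                n_row = length(ys), n_col = length(xs_base)))
}

# analytic nearest-seed lookup on the hexagonal lattice: only the 3x3
# neighborhood of the rounded lattice coordinates can contain the minimum
nearest_hex <- function(x, y, lat) {
  best <- rep(Inf, length(x)); idx <- integer(length(x))
  r0 <- round((y - lat$y0) / lat$dy) + 1
  for (dr in -1:1) {
    r <- pmin(lat$n_row, pmax(1, r0 + dr))
    off <- ifelse(r %% 2 == 0, lat$spacing / 2, 0)
    sy <- lat$y0 + (r - 1) * lat$dy
    c0 <- round((x - lat$x0 - off) / lat$spacing) + 1
    for (dc in -1:1) {
      cc <- pmin(lat$n_col, pmax(1, c0 + dc))
      sx <- lat$x0 + off + (cc - 1) * lat$spacing
      d2 <- (x - sx)^2 + (y - sy)^2
      upd <- d2 < best
      best[upd] <- d2[upd]
      idx[upd] <- (r[upd] - 1) * lat$n_col + cc[upd]
    }
  }
  idx
}

nearest_seed <- function(x, y, seeds) {
  if (!length(x)) return(integer(0))
  out <- integer(length(x))
  # chunked to bound the distance-matrix size
  for (b in split(seq_along(x), ceiling(seq_along(x) / 20000L))) {
    d2 <- outer(x[b], seeds[, 1L], `-`)^2 + outer(y[b], seeds[, 2L], `-`)^2
    out[b] <- max.col(-d2, ties.method = "first")
  }
  out
}

hexagon_polygon <- function(cx, cy, spacing) {
  r <- spacing / sqrt(3)  # circumradius of the hexagonal Voronoi cell
  t <- pi / 6 + (0:5) * pi / 3
  cbind(x = cx + r * cos(t), y = cy + r * sin(t))
}

#' Voronoi quadrat tessellation of a compartment
#'
#' Seeds are placed on a hexagonal lattice (pitch `seed_spacing`), whose
#' Voronoi diagram is a honeycomb; alternatively an explicit seed matrix can
#' be supplied (e.g. cell positions). The compartment's raster mask is
#' partitioned by nearest-seed assignment, so quadrat areas sum exactly to
#' the compartment area; quadrats receiving no mask pixel are dropped.
#'
#' @param geometry An `fl_geometry`.
#' @param compartment `"intra"` or `"inter"`.
#' @param seed_spacing Lattice pitch in micrometres (> 0).
#' @param seeds Optional explicit seed matrix (columns x, y), overriding the
#'   lattice.
#' @return Object of class `fl_tessellation`: kept `seeds`, `areas_um2`,
#'   `polygons` (unclipped hexagons for lattice seeds), compartment name and
#'   spacing.
#' @export
tessellate_compartment <- function(geometry, compartment = c("inter", "intra"),
                                   seed_spacing = 50, seeds = NULL) {
  compartment <- match.arg(compartment)
  stopifnot(seed_spacing > 0)
  mask <- geometry[[paste0(compartment, "_mask")]]
  if (!any(mask)) stop("compartment ", compartment, " is empty")
  mpp <- geometry$um_per_px
  lattice <- is.null(seeds)
  if (lattice)
    seeds <- hex_seeds(geometry$width_um, geometry$height_um, seed_spacing)
  idx <- which(mask, arr.ind = TRUE)
  px <- (idx[, 2L] - 0.5) * mpp
  py <- (idx[, 1L] - 0.5) * mpp
  lat <- attr(seeds, "lattice")
  assign <- if (lattice) nearest_hex(px, py, lat)
            else nearest_seed(px, py, seeds)
  tab <- tabulate(assign, nbins = nrow(seeds))
  kept <- which(tab > 0L)
  if (length(kept) == 1L)
    warning("compartment smaller than one quadrat; single-quadrat tessellation")
  areas <- tab[kept] * mpp^2
  polys <- if (lattice)
    lapply(kept, function(k) hexagon_polygon(seeds[k, 1L], seeds[k, 2L],
                                             seed_spacing))
  else NULL
  structure(list(seeds = seeds[kept, , drop = FALSE], areas_um2 = areas,
                 kept = kept, lattice = if (lattice) lat else NULL,
                 polygons = polys, compartment = compartment,
                 seed_spacing = seed_spacing,
                 area_total_um2 = sum(areas)),
            class = "fl_tessellation")
}

#' @export
print.fl_tessellation <- function(x, ...) {
  cat(sprintf("Voronoi quadrat tessellation: %d quadrats (%s compartment)\n",
              nrow(x$seeds), x$compartment))
  cat(sprintf("  pitch %g um; area %.0f um^2; median quadrat %.0f um^2\n",
              x$seed_spacing, x$area_total_um2, stats::median(x$areas_um2)))
  invisible(x)
}

#' Per-quadrat counts of a phenotype
#'
#' Cells are assigned to the quadrat of their nearest seed; every cell gets
#' exactly one quadrat, so counts sum to the number of cells supplied.
#'
#' @param tess An `fl_tessellation`.
#' @param cells Cell data frame (x_um, y_um), already restricted to the
#'   tessellated compartment.
#' @return Integer vector of length `nrow(tess$seeds)`.
#' @export
quadrat_counts <- function(tess, cells) {
  if (!nrow(cells)) return(integer(nrow(tess$seeds)))
  if (!is.null(tess$lattice)) {
    full <- nearest_hex(cells$x_um, cells$y_um, tess$lattice)
    a <- match(full, tess$kept)
    # a cell whose nearest lattice seed received no mask pixel (boundary
    # rasterization) falls back to the nearest kept seed
    miss <- which(is.na(a))
    if (length(miss))
      a[miss] <- nearest_seed(cells$x_um[miss], cells$y_um[miss], tess$seeds)
  } else {
    a <- nearest_seed(cells$x_um, cells$y_um, tess$seeds)
  }
  tabulate(a, nbins = nrow(tess$seeds))
}

#' Morisita-Horn index of two count vectors
#'
#' `mh = 2 * sum(x_i * y_i) / ((sum(x_i^2)/X^2 + sum(y_i^2)/Y^2) * X * Y)`
#' with `X = sum(x)`, `Y = sum(y)`. Ranges from 0 (disjoint support) to 1
#' (identical relative distributions); symmetric and invariant to rescaling
#' either vector.
#'
#' @param x,y Non-negative count vectors of equal length.
#' @return The index, or `NA` (with a `reason` attribute) when either
#'   vector sums to zero.
#' @export
morisita_horn <- function(x, y) {
  if (length(x) != length(y)) stop("count vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  X <- sum(x); Y <- sum(y)
  if (X == 0 || Y == 0) {
    out <- NA_real_
    attr(out, "reason") <- "empty_phenotype"
    return(out)
  }
  # (X * Y) grouped so the value is exactly symmetric in the pair order
  2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * (X * Y))
}

#' Spatial co-localization of two phenotypes
#'
#' Quadrat counts of the two phenotypes are computed on each tile's
#' tessellation and concatenated across tiles (keeping the quadrat scale
#' constant) before a single Morisita-Horn index is taken, giving one
#' per-patient value.
#'
#' @param cells Cell map with `tile_id`, `compartment` and marker columns.
#' @param phenotype_a,phenotype_b Phenotype labels.
#' @param tessellations Named list: tile_id -> `fl_tessellation` (all built
#'   on the same compartment).
#' @param markers Panel marker vector.
#' @return Object of class `fl_mh`: `mh`, `pair`, `compartment`,
#'   `n_quadrats`, totals `X` and `Y`; `mh` is `NA` with a reason when a
#'   phenotype is absent from the compartment.
#' @export
colocalization <- function(cells, phenotype_a, phenotype_b, tessellations,
                           markers = panel_markers()) {
  comp <- unique(vapply(tessellations, `[[`, "", "compartment"))
  if (length(comp) != 1L)
    stop("tessellations mix compartments: ", paste(comp, collapse = ", "))
  if (is.null(cells$tile_id)) cells$tile_id <- names(tessellations)[1L]
  xs <- ys <- integer(0)
  for (tid in names(tessellations)) {
    tess <- tessellations[[tid]]
    sub <- cells[cells$tile_id == tid & cells$compartment == comp, ,
                 drop = FALSE]
    xs <- c(xs, quadrat_counts(tess, sub[match_phenotype(sub, phenotype_a,
                                                         markers), ]))
    ys <- c(ys, quadrat_counts(tess, sub[match_phenotype(sub, phenotype_b,
                                                         markers), ]))
  }
  structure(list(mh = morisita_horn(xs, ys),
                 pair = c(phenotype_a, phenotype_b), compartment = comp,
                 n_quadrats = length(xs), X = sum(xs), Y = sum(ys)),
            class = "fl_mh")
}

#' @export
print.fl_mh <- function(x, ...) {
  cat(sprintf("Morisita-Horn co-localization %s : %s (%s compartment)\n",
              x$pair[1L], x$pair[2L], x$compartment))
  if (is.na(x$mh))
    cat("  not computable:", attr(x$mh, "reason"), "\n")
  else
    cat(sprintf("  mh = %.4f over %d quadrats (X = %d, Y = %d cells)\n",
                x$mh, x$n_quadrats, x$X, x$Y))
  invisible(x)
}

#' Nearest-neighbor phenotype profile
#'
#' For every reference-phenotype cell, the nearest candidate cell of any of
#' the candidate phenotypes (Euclidean distance, same tile, self excluded,
#' ties broken by lowest cell id) is identified, and per-candidate-phenotype
#' distance distributions are summarized. A candidate cell matching several
#' candidate labels is labelled by the first match in the declared order.
#'
#' @param cells Cell map with cell_id, x_um, y_um, tile_id (optional),
#'   compartment, marker columns.
#' @param reference Reference phenotype label.
#' @param candidates Character vector of candidate phenotype labels.
#' @param compartment Compartment to analyze.
#' @param markers Panel marker vector.
#' @return Object of class `fl_nn`: `pairs` (one row per reference cell:
#'   nn phenotype, distance) and `summary` (per candidate phenotype:
#'   n, median and IQR of distances), or `NULL` fields when no reference or
#'   candidate cells exist.
#' @export
nearest_neighbor_profile <- function(cells, reference, candidates,
                                     compartment = "inter",
                                     markers = panel_markers()) {
  cells <- cells[cells$compartment == compartment, , drop = FALSE]
  if (is.null(cells$tile_id)) cells$tile_id <- "tile"
  is_ref <- match_phenotype(cells, reference, markers)
  cand_label <- rep(NA_character_, nrow(cells))
  for (cl in rev(candidates))  # first match in declared order wins
    cand_label[match_phenotype(cells, cl, markers)] <- cl
  rows <- list()
  for (tid in unique(cells$tile_id)) {
    in_tile <- cells$tile_id == tid
    ref <- cells[in_tile & is_ref, , drop = FALSE]
    cand <- cells[in_tile & !is.na(cand_label), , drop = FALSE]
    clab <- cand_label[in_tile][!is.na(cand_label[in_tile])]
    if (!nrow(ref) || !nrow(cand)) next
    ord <- order(cand$cell_id)  # which.min then breaks ties by lowest id
    cand <- cand[ord, , drop = FALSE]; clab <- clab[ord]
    d2 <- outer(ref$x_um, cand$x_um, `-`)^2 + outer(ref$y_um, cand$y_um, `-`)^2
    self <- outer(ref$cell_id, cand$cell_id, `==`)
    d2[self] <- Inf
    ok <- apply(d2, 1L, function(r) any(is.finite(r)))
    if (!any(ok)) next
    j <- apply(d2[ok, , drop = FALSE], 1L, which.min)
    rows[[length(rows) + 1L]] <- data.frame(
      tile_id = tid, cell_id = ref$cell_id[ok],
      nn_phenotype = clab[j],
      nn_cell_id = cand$cell_id[j],
      distance_um = sqrt(d2[cbind(which(ok), j)]))
  }
  if (!length(rows))
    return(structure(list(reference = reference, candidates = candidates,
                          compartment = compartment, pairs = NULL,
                          summary = NULL), class = "fl_nn"))
  pairs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(candidates, function(cl) {
    d <- pairs$distance_um[pairs$nn_phenotype == cl]
    data.frame(phenotype = cl, n = length(d),
               median_um = if (length(d)) stats::median(d) else NA_real_,
               iqr_um = if (length(d)) stats::IQR(d) else NA_real_)
  }))
  structure(list(reference = reference, candidates = candidates,
                 compartment = compartment, pairs = pairs, summary = summ),
            class = "fl_nn")
}

#' @export
print.fl_nn <- function(x, ...) {
  cat(sprintf("Nearest-neighbor profile of %s (%s compartment)\n",
              x$reference, x$compartment))
  if (is.null(x$pairs)) { cat("  no reference or candidate cells\n") }
  else print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a tessellation to GeoJSON
#'
#' @param tess An `fl_tessellation` built on lattice seeds.
#' @param path Output file.
#' @export
write_tessellation_geojson <- function(tess, path) {
  if (is.null(tess$polygons))
    stop("tessellation built on explicit seeds has no polygon representation")
  write_polygons_geojson(
    tess$polygons, path,
    properties = lapply(seq_along(tess$polygons), function(i)
      list(quadrat = i, area_um2 = tess$areas_um2[i],
           compartment = tess$compartment)))
}
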