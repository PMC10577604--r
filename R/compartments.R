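# Tissue and follicle geometry: tissue segmentation from the DAPI plane,
# follicle annotation ingestion, compartment assignment and cell densities.

#' Segment tissue from a DAPI image
#'
#' Otsu intensity threshold, binary closing, hole filling and small-object
#' removal. A near-constant bright image yields a full-tile mask; an image
#' in which no component survives the minimum-area filter raises an error.
#'
#' @param img Single-channel matrix with intensities in [0, 1].
#' @param um_per_px Pixel pitch.
#' @param min_area_um2 Minimum connected-component area kept.
#' @param close_radius_um Radius of the closing brush.
#' @param bright_floor Mean intensity above which a near-constant image is
#'   treated as all-tissue.
#' @return Object of class `fl_tissue_mask`: logical matrix `mask`,
#'   `area_um2`, `um_per_px`.
#' @export
segment_tissue <- function(img, um_per_px = 1, min_area_um2 = 500,
                           close_radius_um = 5, bright_floor = 0.2) {
  stopifnot(is.matrix(img))
  px_area <- um_per_px^2
  if (diff(range(img)) < 1e-3) {
    if (mean(img) >= bright_floor) {
      mask <- matrix(TRUE, nrow(img), ncol(img))
      return(structure(list(mask = mask, area_um2 = length(mask) * px_area,
                            um_per_px = um_per_px), class = "fl_tissue_mask"))
    }
    stop("no tissue detected (constant dark image)")
  }
  thr <- EBImage::otsu(EBImage::Image(t(img)), range = c(0, 1))
  bw <- img > thr
  # Otsu always splits; demand the foreground to be genuinely bright
  if (!any(bw) || mean(img[bw]) < bright_floor)
    stop("no tissue detected (foreground below brightness floor)")
  r_px <- max(1L, round(close_radius_um / um_per_px))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  eb <- EBImage::Image(t(bw))
  eb <- EBImage::closing(eb, brush)
  eb <- EBImage::fillHull(eb)
  lab <- EBImage::bwlabel(eb)
  sizes <- table(as.integer(lab))
  sizes <- sizes[names(sizes) != "0"]
  keep <- as.integer(names(sizes)[sizes * px_area >= min_area_um2])
  mask <- t(matrix(as.integer(lab) %in% keep, nrow(lab), ncol(lab)))
  if (!any(mask)) stop("no tissue detected")
  structure(list(mask = mask, area_um2 = sum(mask) * px_area,
                 um_per_px = um_per_px), class = "fl_tissue_mask")
}

#' @export
print.fl_tissue_mask <- function(x, ...) {
  cat(sprintf("Tissue mask: %d x %d px at %g um/px, area %.0f um^2 (%.1f%% of tile)\n",
              nrow(x$mask), ncol(x$mask), x$um_per_px, x$area_um2,
              100 * mean(x$mask)))
  invisible(x)
}

#' Load follicle annotations from GeoJSON
#'
#' Polygons are validated (closed rings, no self-intersection after a
#' vertex-deduplication repair). Overlapping follicles are kept but flagged
#' with a warning; membership tests treat them as their union, so
#' overlapping regions are not double counted in areas.
#'
#' @param path GeoJSON FeatureCollection with Polygon features in
#'   micrometre coordinates.
#' @return List of two-column vertex matrices.
#' @export
load_follicles <- function(path) {
  polys <- read_polygons_geojson(path)
  if (length(polys) > 1L) {
    for (i in seq_len(length(polys) - 1L)) for (j in (i + 1L):length(polys)) {
      if (polygons_overlap(polys[[i]], polys[[j]])) {
        warning("overlapping follicle annotations detected; ",
                "treated as their union")
        i <- length(polys); break
      }
    }
  }
  polys
}

#' Build the compartment geometry of a tile
#'
#' The intra-follicular region is the union of the follicle polygons
#' intersected with the tissue; the inter-follicular region is the tissue
#' minus the follicles. Areas are computed on the tissue raster so that
#' intra + inter equals the tissue area exactly.
#'
#' @param tissue An `fl_tissue_mask` (or NULL: whole tile is tissue).
#' @param follicles List of follicle polygons (micrometre coordinates).
#' @param width_um,height_um Tile size (required when `tissue` is NULL).
#' @param um_per_px Raster pitch when `tissue` is NULL.
#' @return Object of class `fl_geometry`: masks and areas per compartment.
#' @export
compartment_geometry <- function(tissue = NULL, follicles = list(),
                                 width_um = NULL, height_um = NULL,
                                 um_per_px = 2) {
  if (is.null(tissue)) {
    stopifnot(!is.null(width_um), !is.null(height_um))
    mask <- matrix(TRUE, round(height_um / um_per_px),
                   round(width_um / um_per_px))
    tissue <- structure(list(mask = mask, area_um2 = sum(mask) * um_per_px^2,
                             um_per_px = um_per_px), class = "fl_tissue_mask")
  }
  mpp <- tissue$um_per_px
  ny <- nrow(tissue$mask); nx <- ncol(tissue$mask)
  fmask <- if (length(follicles))
    rasterize_polygons(follicles, nx * mpp, ny * mpp, mpp)
  else matrix(FALSE, ny, nx)
  intra <- tissue$mask & fmask
  inter <- tissue$mask & !fmask
  structure(list(tissue = tissue, follicles = follicles,
                 intra_mask = intra, inter_mask = inter,
                 um_per_px = mpp,
                 width_um = nx * mpp, height_um = ny * mpp,
                 areas_um2 = c(tissue = tissue$area_um2,
                               intra = sum(intra) * mpp^2,
                               inter = sum(inter) * mpp^2)),
            class = "fl_geometry")
}

#' @export
print.fl_geometry <- function(x, ...) {
  a <- x$areas_um2
  cat(sprintf("Compartment geometry: %d follicles\n", length(x$follicles)))
  cat(sprintf("  tissue %.0f um^2; intra %.0f (%.1f%%), inter %.0f (%.1f%%)\n",
              a[["tissue"]], a[["intra"]], 100 * a[["intra"]] / a[["tissue"]],
              a[["inter"]], 100 * a[["inter"]] / a[["tissue"]]))
  invisible(x)
}

#' Assign cells to compartments
#'
#' A cell inside any follicle polygon (boundary counts as inside) is
#' `intra`; inside tissue but not in a follicle, `inter`; outside the
#' tissue mask, `excluded` (kept in the table, flagged, and reported).
#' Follicle membership is evaluated on the polygons, tissue membership on
#' the mask raster.
#'
#' @param cells Cell map data frame with x_um, y_um.
#' @param geometry An `fl_geometry`.
#' @param warn_exclusion_rate Warn when the excluded fraction exceeds this.
#' @return `cells` with a `compartment` factor column.
#' @export
assign_compartments <- function(cells, geometry,
                                warn_exclusion_rate = 0.2) {
  n <- nrow(cells)
  comp <- rep("inter", n)
  if (n) {
    mpp <- geometry$um_per_px
    mask <- geometry$tissue$mask
    ci <- pmin(nrow(mask), pmax(1L, floor(cells$y_um / mpp) + 1L))
    cj <- pmin(ncol(mask), pmax(1L, floor(cells$x_um / mpp) + 1L))
    in_tissue <- mask[cbind(ci, cj)]
    in_foll <- point_in_polygons(cells$x_um, cells$y_um,
                                 geometry$follicles) > 0L
    comp[in_foll] <- "intra"
    comp[!in_tissue] <- "excluded"
    n_exc <- sum(!in_tissue)
    if (n_exc / n > warn_exclusion_rate)
      warning(sprintf("%.1f%% of cells fall outside the tissue mask",
                      100 * n_exc / n))
  }
  cells$compartment <- factor(comp, levels = c("intra", "inter", "excluded"))
  cells
}

#' Phenotype density per compartment, pooled per patient
#'
#' Density = 1000 x (cells of the phenotype in the compartment, summed over
#' the patient's tiles) / (compartment area in um^2, summed over tiles).
#' Counts and areas are pooled before the ratio, which keeps the estimate
#' unbiased when tiles carry unequal tissue content.
#'
#' @param cells Cell map (may span several tiles; must carry `compartment`).
#' @param geometries List of `fl_geometry`, one per tile of the patient.
#' @param phenotype Phenotype label.
#' @param compartment `"intra"` or `"inter"`.
#' @param markers Panel marker vector.
#' @return Density in cells per 1000 um^2, or `NA` when the pooled area is 0.
#' @export
cell_density <- function(cells, geometries, phenotype,
                         compartment = c("inter", "intra"),
                         markers = panel_markers()) {
  compartment <- match.arg(compartment)
  if (inherits(geometries, "fl_geometry")) geometries <- list(geometries)
  area <- sum(vapply(geometries, function(g) g$areas_um2[[compartment]], 0))
  if (area <= 0) return(NA_real_)
  sel <- match_phenotype(cells, phenotype, markers) &
    cells$compartment == compartment
  1000 * sum(sel) / area
}

#' Polygonal outline(s) of a tissue mask
#'
#' Traces the boundary contour of each connected tissue component
#' (EBImage::ocontour) and returns polygons in micrometre coordinates.
#'
#' @param tissue An `fl_tissue_mask`.
#' @return List of two-column vertex matrices.
#' @export
tissue_outline <- function(tissue) {
  lab <- EBImage::bwlabel(EBImage::Image(t(tissue$mask)))
  oc <- EBImage::ocontour(lab)
  lapply(oc, function(m) {
    # ocontour works in the transposed (x = row) frame; map back to um
    cbind(x = (m[, 1L] + 0.5) * tissue$um_per_px,
          y = (m[, 2L] + 0.5) * tissue$um_per_px)
  })
}

#' Write a binary mask as a single-page TIFF
#'
#' @param mask Logical matrix (or an `fl_tissue_mask`).
#' @param path Output file.
#' @export
write_mask_tiff <- function(mask, path) {
  if (inherits(mask, "fl_tissue_mask")) mask <- mask$mask
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}
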