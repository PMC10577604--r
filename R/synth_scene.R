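# Synthetic tile generator: ground-truth cell maps with controlled spatial
# structure (per-compartment Poisson intensities, Thomas-style parent/
# offspring coupling) and rendered per-marker "deconvoluted" images.

#' Configuration of a synthetic tile scene
#'
#' Densities are in cells per 1000 square micrometres, given separately for
#' the intra-follicular and inter-follicular compartments. Phenotype labels
#' follow [parse_phenotype()]; markers not named in a label are negative for
#' cells of that phenotype. `coupling` entries place a fraction `kappa` of
#' the offspring phenotype's cells as Gaussian displacements (scale
#' `sigma_um`) of random parent-phenotype cells in the same compartment,
#' giving a Thomas-process-style spatial association.
#'
#' @param width_um,height_um Tile size in micrometres.
#' @param um_per_px Pixel pitch used when rendering.
#' @param markers Marker panel (vector or panel name; see [panel_markers()]).
#' @param phenotypes Named list: label -> c(intra = d1, inter = d2) densities.
#' @param n_follicles Number of follicles to place.
#' @param follicle_radius_range Range of the follicle major semi-axis (um).
#' @param coupling List of `list(parent=, offspring=, kappa=, sigma_um=)`.
#' @param background Mean background intensity of rendered images in [0, 1].
#' @param blob_radius_um Nominal cell blob radius for rendering.
#' @param noise_sd Additive Gaussian pixel noise standard deviation.
#' @param intensity_jitter Relative jitter of per-cell peak intensity.
#' @param seed Integer seed; the whole scene is deterministic given it.
#' @return An object of class `fl_scene_config`.
#' @export
scene_config <- function(width_um = 1338, height_um = 1000, um_per_px = 1,
                         markers = "immune_t",
                         phenotypes = list("CD8+" = c(intra = 0.5, inter = 1)),
                         n_follicles = 3L,
                         follicle_radius_range = c(80, 160),
                         coupling = list(),
                         background = 0.05, blob_radius_um = 3,
                         noise_sd = 0.02, intensity_jitter = 0.1,
                         seed = 1L) {
  markers <- panel_markers(markers)
  stopifnot(width_um > 0, height_um > 0, um_per_px > 0,
            n_follicles >= 0, background >= 0, noise_sd >= 0,
            blob_radius_um > 0, length(follicle_radius_range) == 2L,
            follicle_radius_range[1L] <= follicle_radius_range[2L])
  for (ph in names(phenotypes)) {
    d <- phenotypes[[ph]]
    if (length(d) != 2L || any(d < 0) || any(!is.finite(d)))
      stop("phenotype ", ph, ": densities must be two non-negative numbers")
    parse_phenotype(ph, markers)  # validates the label
  }
  for (cp in coupling) {
    stopifnot(all(c("parent", "offspring", "kappa", "sigma_um") %in% names(cp)))
    if (cp$kappa < 0 || cp$kappa > 1) stop("coupling kappa must lie in [0, 1]")
    if (cp$sigma_um <= 0) stop("coupling sigma_um must be positive")
    if (!all(c(cp$parent, cp$offspring) %in% names(phenotypes)))
      stop("coupling references a phenotype without a density entry")
  }
  structure(list(width_um = width_um, height_um = height_um,
                 um_per_px = um_per_px, markers = markers,
                 phenotypes = phenotypes, n_follicles = as.integer(n_follicles),
                 follicle_radius_range = follicle_radius_range,
                 coupling = coupling, background = background,
                 blob_radius_um = blob_radius_um, noise_sd = noise_sd,
                 intensity_jitter = intensity_jitter, seed = as.integer(seed)),
            class = "fl_scene_config")
}

in_ellipse <- function(x, y, e) {
  dx <- x - e$cx; dy <- y - e$cy
  u <- (dx * cos(e$angle) + dy * sin(e$angle)) / e$a
  v <- (-dx * sin(e$angle) + dy * cos(e$angle)) / e$b
  u * u + v * v <= 1
}

in_any_ellipse <- function(x, y, ells) {
  hit <- logical(length(x))
  for (e in ells) hit <- hit | in_ellipse(x, y, e)
  hit
}

place_follicles <- function(config, max_attempts = 500L) {
  ells <- list()
  rr <- config$follicle_radius_range
  for (k in seq_len(config$n_follicles)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      a <- stats::runif(1, rr[1L], rr[2L])
      b <- a * stats::runif(1, 0.7, 1.0)
      ang <- stats::runif(1, 0, pi)
      if (2 * a > min(config$width_um, config$height_um)) next
      cx <- stats::runif(1, a, config$width_um - a)
      cy <- stats::runif(1, a, config$height_um - a)
      cand <- list(cx = cx, cy = cy, a = a, b = b, angle = ang)
      ok <- TRUE
      for (e in ells) {
        if (sqrt((cx - e$cx)^2 + (cy - e$cy)^2) < a + e$a) { ok <- FALSE; break }
      }
      if (ok) { ells[[k]] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop("could not place ", config$n_follicles, " non-overlapping follicles; ",
           "follicle specification infeasible for this tile")
  }
  for (k in seq_along(ells))
    ells[[k]]$poly <- ellipse_polygon(ells[[k]]$cx, ells[[k]]$cy,
                                      ells[[k]]$a, ells[[k]]$b, ells[[k]]$angle)
  ells
}

sample_in_ellipse <- function(n, e) {
  r <- sqrt(stats::runif(n)); t <- stats::runif(n, 0, 2 * pi)
  u <- e$a * r * cos(t); v <- e$b * r * sin(t)
  cbind(x = e$cx + u * cos(e$angle) - v * sin(e$angle),
        y = e$cy + u * sin(e$angle) + v * cos(e$angle))
}

sample_in_compartment <- function(n, compartment, config, ells) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  if (compartment == "intra") {
    areas <- vapply(ells, function(e) pi * e$a * e$b, 0)
    which_f <- sample.int(length(ells), n, replace = TRUE, prob = areas)
    out <- matrix(0, n, 2L, dimnames = list(NULL, c("x", "y")))
    for (k in unique(which_f)) {
      idx <- which(which_f == k)
      out[idx, ] <- sample_in_ellipse(length(idx), ells[[k]])
    }
    out
  } else {
    out <- matrix(NA_real_, 0L, 2L)
    while (nrow(out) < n) {
      m <- max(2L * (n - nrow(out)), 16L)
      x <- stats::runif(m, 0, config$width_um)
      y <- stats::runif(m, 0, config$height_um)
      keep <- !in_any_ellipse(x, y, ells)
      out <- rbind(out, cbind(x[keep], y[keep]))
    }
    out <- out[seq_len(n), , drop = FALSE]
    colnames(out) <- c("x", "y")
    out
  }
}

#' Generate a ground-truth cell map for one tile
#'
#' Follicles are placed by rejection sampling as non-overlapping ellipses
#' (axis ratio uniform on 0.7-1.0). Each phenotype is a homogeneous Poisson
#' process within each compartment at its configured density; coupled
#' phenotype pairs then have a fraction kappa of the offspring cells
#' re-positioned as Gaussian displacements of random parents in the same
#' compartment. Deterministic given `config$seed`.
#'
#' @param config A [scene_config()].
#' @return An `fl_scene`: list with `cells` (data frame: cell_id, x_um, y_um,
#'   phenotype, compartment, `<marker>_pos` logicals), `follicles` (list of
#'   ellipse parameters with `$poly` vertex matrices), `areas_um2`
#'   (tile/intra/inter) and the config.
#' @export
generate_cell_map <- function(config) {
  stopifnot(inherits(config, "fl_scene_config"))
  withr::with_seed(config$seed, {
    ells <- place_follicles(config)
    tile_area <- config$width_um * config$height_um
    intra_area <- sum(vapply(ells, function(e) pi * e$a * e$b, 0))
    inter_area <- tile_area - intra_area
    areas <- c(tile = tile_area, intra = intra_area, inter = inter_area)

    rows <- list()
    for (ph in names(config$phenotypes)) {
      d <- config$phenotypes[[ph]]
      for (comp in c("intra", "inter")) {
        if (comp == "intra" && length(ells) == 0L) next
        lambda <- d[[comp]] * areas[[comp]] / 1000
        n <- stats::rpois(1L, lambda)
        if (n == 0L) next
        xy <- sample_in_compartment(n, comp, config, ells)
        rows[[length(rows) + 1L]] <-
          data.frame(x_um = xy[, 1L], y_um = xy[, 2L],
                     phenotype = ph, compartment = comp)
      }
    }
    cells <- if (length(rows)) do.call(rbind, rows) else
      data.frame(x_um = numeric(0), y_um = numeric(0),
                 phenotype = character(0), compartment = character(0))

    # Thomas-style coupling: move a fraction kappa of offspring next to parents
    for (cp in config$coupling) {
      if (cp$kappa == 0) next
      for (comp in c("intra", "inter")) {
        par_idx <- which(cells$phenotype == cp$parent & cells$compartment == comp)
        off_idx <- which(cells$phenotype == cp$offspring & cells$compartment == comp)
        n_off <- round(cp$kappa * length(off_idx))
        if (!length(par_idx) || n_off == 0L) next
        move <- sample(off_idx, n_off)
        parents <- sample(par_idx, n_off, replace = TRUE)
        for (i in seq_len(n_off)) {
          px <- cells$x_um[parents[i]]; py <- cells$y_um[parents[i]]
          for (try in 1:100) {
            nx <- px + stats::rnorm(1, 0, cp$sigma_um)
            ny <- py + stats::rnorm(1, 0, cp$sigma_um)
            inside_tile <- nx >= 0 && nx <= config$width_um &&
              ny >= 0 && ny <= config$height_um
            if (!inside_tile) next
            same_comp <- in_any_ellipse(nx, ny, ells) == (comp == "intra")
            if (same_comp) {
              cells$x_um[move[i]] <- nx; cells$y_um[move[i]] <- ny
              break
            }
          }
        }
      }
    }

    if (nrow(cells)) {
      ord <- order(cells$y_um, cells$x_um)
      cells <- cells[ord, , drop = FALSE]
      cells <- cbind(cell_id = seq_len(nrow(cells)), cells)
      rownames(cells) <- NULL
      phs <- unique(cells$phenotype)
      pos_by_ph <- t(vapply(phs,
                            function(ph) phenotype_to_positivity(ph, config$markers),
                            logical(length(config$markers))))
      pos <- pos_by_ph[match(cells$phenotype, phs), , drop = FALSE]
      colnames(pos) <- paste0(config$markers, "_pos")
      cells <- cbind(cells, as.data.frame(pos))
    } else {
      cells <- cbind(data.frame(cell_id = integer(0)), cells)
      for (mk in config$markers) cells[[paste0(mk, "_pos")]] <- logical(0)
    }
    structure(list(cells = cells, follicles = ells,
                   areas_um2 = areas, config = config),
              class = "fl_scene")
  })
}

#' @export
print.fl_scene <- function(x, ...) {
  cat("Synthetic M-IF tile scene:", nrow(x$cells), "cells,",
      length(x$follicles), "follicles\n")
  cat(sprintf("  tile %g x %g um; intra area %.0f um^2 (%.1f%%)\n",
              x$config$width_um, x$config$height_um, x$areas_um2[["intra"]],
              100 * x$areas_um2[["intra"]] / x$areas_um2[["tile"]]))
  if (nrow(x$cells)) print(table(x$cells$phenotype, x$cells$compartment))
  invisible(x)
}

paint_blobs <- function(img, x_um, y_um, peak, sigma_um, um_per_px) {
  if (!length(x_um)) return(img)
  ny <- nrow(img); nx <- ncol(img)
  s_px <- sigma_um / um_per_px
  w <- ceiling(3 * s_px)
  for (i in seq_along(x_um)) {
    cxp <- x_um[i] / um_per_px + 0.5  # pixel-center coordinates
    cyp <- y_um[i] / um_per_px + 0.5
    ix <- max(1L, floor(cxp - w)):min(nx, ceiling(cxp + w))
    iy <- max(1L, floor(cyp - w)):min(ny, ceiling(cyp + w))
    if (!length(ix) || !length(iy)) next
    gx <- exp(-((ix - cxp)^2) / (2 * s_px^2))
    gy <- exp(-((iy - cyp)^2) / (2 * s_px^2))
    img[iy, ix] <- pmax(img[iy, ix], peak[i] * outer(gy, gx))
  }
  img
}

#' Render per-marker deconvoluted images for a scene
#'
#' One two-channel image per marker: channel 1 is the positive ("brown")
#' stain, channel 2 the nuclear DAPI ("blue") channel. Every cell receives a
#' DAPI blob; marker-positive cells additionally receive a stain blob.
#' Gaussian blobs have standard deviation `blob_radius_um / 2`. With
#' `noise = TRUE`, background level plus additive Gaussian noise is applied
#' and intensities are clipped to [0, 1].
#'
#' @param scene An `fl_scene` from [generate_cell_map()].
#' @param noise Apply background/noise (FALSE gives the ground-truth render).
#' @return Named list (marker -> array height x width x 2).
#' @export
render_deconvoluted_tiles <- function(scene, noise = TRUE) {
  config <- scene$config
  if (config$blob_radius_um / config$um_per_px < 1)
    stop("blob radius below one pixel: cells would be unresolvable at this ",
         "pixel pitch")
  ny <- round(config$height_um / config$um_per_px)
  nx <- round(config$width_um / config$um_per_px)
  cells <- scene$cells
  withr::with_seed(config$seed + 1L, {
    peaks <- if (nrow(cells))
      pmin(1, pmax(0.3, 1 + stats::rnorm(nrow(cells), 0, config$intensity_jitter)))
    else numeric(0)
    sig <- config$blob_radius_um / 2
    dapi <- paint_blobs(matrix(0, ny, nx), cells$x_um, cells$y_um,
                        peaks, sig, config$um_per_px)
    out <- list()
    for (mk in config$markers) {
      posi <- which(cells[[paste0(mk, "_pos")]])
      stain <- paint_blobs(matrix(0, ny, nx), cells$x_um[posi], cells$y_um[posi],
                           peaks[posi], sig, config$um_per_px)
      img <- array(0, c(ny, nx, 2L))
      img[, , 1L] <- stain
      img[, , 2L] <- dapi
      if (noise) {
        img <- img + config$background +
          array(stats::rnorm(length(img), 0, config$noise_sd), dim(img))
        img[img < 0] <- 0; img[img > 1] <- 1
      }
      out[[mk]] <- img
    }
    out
  })
}

#' Write a scene to disk (tiles, cell map, follicles)
#'
#' Writes one two-channel TIFF per marker, the ground-truth cell table as
#' CSV and the follicle polygons as GeoJSON.
#'
#' @param scene An `fl_scene`.
#' @param dir Output directory (created if needed).
#' @param tile_id,patient_id Identifiers recorded in the outputs.
#' @param noise Passed to [render_deconvoluted_tiles()].
#' @return Invisibly, the list of written paths.
#' @export
write_scene <- function(scene, dir, tile_id = "tile01", patient_id = "P01",
                        noise = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  imgs <- render_deconvoluted_tiles(scene, noise = noise)
  paths <- list()
  for (mk in names(imgs)) {
    p <- file.path(dir, sprintf("%s_%s_%s.tiff", patient_id, tile_id, mk))
    tiff::writeTIFF(imgs[[mk]], p, bits.per.sample = 16L)
    paths[[paste0("tiff_", mk)]] <- p
  }
  cells <- cbind(patient_id = patient_id, tile_id = tile_id, scene$cells)
  cp <- file.path(dir, sprintf("%s_%s_cells.csv", patient_id, tile_id))
  utils::write.csv(cells, cp, row.names = FALSE)
  paths$cells <- cp
  fp <- file.path(dir, sprintf("%s_%s_follicles.geojson", patient_id, tile_id))
  write_polygons_geojson(lapply(scene$follicles, `[[`, "poly"), fp,
                         properties = lapply(seq_along(scene$follicles),
                                             function(i) list(id = i)))
  paths$follicles <- fp
  invisible(paths)
}
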