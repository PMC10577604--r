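test_that("zero-density phenotype yields no cells in that compartment", {
  cfg <- scene_config(width_um = 500, height_um = 500, n_follicles = 2L,
                      phenotypes = list("CD8+" = c(intra = 0, inter = 1)),
                      seed = 5L)
  sc <- generate_cell_map(cfg)
  expect_true(all(sc$cells$compartment == "inter"))
  inside <- folliscape:::in_any_ellipse(sc$cells$x_um, sc$cells$y_um,
                                        sc$follicles)
  expect_false(any(inside))
})

test_that("realized counts follow the configured Poisson intensity", {
  # 5 cells/1000 um^2 on a 1000x1000 tile, no follicles: mean 5000
  cfg <- scene_config(width_um = 1000, height_um = 1000, n_follicles = 0L,
                      phenotypes = list("CD8+" = c(intra = 0, inter = 5)),
                      seed = 7L)
  n <- nrow(generate_cell_map(cfg)$cells)
  expect_lt(abs(n - 5000), 3 * sqrt(5000))

  # per-compartment intensities over many seeds stay within 3 sigma of the
  # pooled expectation
  tot_intra <- tot_inter <- 0
  exp_intra <- exp_inter <- 0
  for (s in 1:50) {
    cfg <- scene_config(width_um = 400, height_um = 400, n_follicles = 1L,
                        follicle_radius_range = c(60, 100),
                        phenotypes = list("CD8+" = c(intra = 2, inter = 1)),
                        seed = s)
    sc <- generate_cell_map(cfg)
    tot_intra <- tot_intra + sum(sc$cells$compartment == "intra")
    tot_inter <- tot_inter + sum(sc$cells$compartment == "inter")
    exp_intra <- exp_intra + 2 * sc$areas_um2[["intra"]] / 1000
    exp_inter <- exp_inter + 1 * sc$areas_um2[["inter"]] / 1000
  }
  expect_lt(abs(tot_intra - exp_intra), 3 * sqrt(exp_intra))
  expect_lt(abs(tot_inter - exp_inter), 3 * sqrt(exp_inter))
})

test_that("identical seeds give bit-identical cell tables", {
  cfg <- scene_config(n_follicles = 2L,
                      phenotypes = list("CD8+" = c(intra = 0.5, inter = 1),
                                        "CD4+" = c(intra = 1, inter = 0.5)),
                      coupling = list(list(parent = "CD8+", offspring = "CD4+",
                                           kappa = 0.5, sigma_um = 20)),
                      seed = 99L)
  expect_identical(generate_cell_map(cfg)$cells, generate_cell_map(cfg)$cells)
})

test_that("infeasible follicle specification raises an explicit error", {
  cfg <- scene_config(width_um = 300, height_um = 300, n_follicles = 8L,
                      follicle_radius_range = c(100, 140), seed = 1L)
  expect_error(generate_cell_map(cfg), "infeasible")
})

test_that("follicles are pairwise non-overlapping ellipses", {
  cfg <- scene_config(width_um = 1200, height_um = 900, n_follicles = 4L,
                      seed = 3L)
  sc <- generate_cell_map(cfg)
  expect_length(sc$follicles, 4L)
  for (i in 1:3) for (j in (i + 1):4) {
    e1 <- sc$follicles[[i]]; e2 <- sc$follicles[[j]]
    expect_false(folliscape:::polygons_overlap(e1$poly, e2$poly))
  }
  ratios <- vapply(sc$follicles, function(e) e$b / e$a, 0)
  expect_true(all(ratios >= 0.7 & ratios <= 1))
})

test_that("rendered tiles place blobs where the cells are", {
  # zero cells: pure noise at the background level
  cfg0 <- scene_config(width_um = 64, height_um = 64, n_follicles = 0L,
                       phenotypes = list("CD8+" = c(intra = 0, inter = 0)),
                       background = 0.1, noise_sd = 0.02, seed = 2L)
  img0 <- render_deconvoluted_tiles(generate_cell_map(cfg0))$CD8
  expect_equal(mean(img0), 0.1, tolerance = 0.01)

  # single positive cell at the center: argmax within a blob radius
  cfg1 <- scene_config(width_um = 64, height_um = 64, n_follicles = 0L,
                       phenotypes = list("CD8+" = c(intra = 0, inter = 0)),
                       seed = 2L)
  sc1 <- generate_cell_map(cfg1)
  sc1$cells <- data.frame(cell_id = 1L, x_um = 32, y_um = 32,
                          phenotype = "CD8+", compartment = "inter",
                          CD4_pos = FALSE, CD8_pos = TRUE, FOXP3_pos = FALSE,
                          PD1_pos = FALSE)
  img1 <- render_deconvoluted_tiles(sc1, noise = FALSE)$CD8
  am <- which(img1[, , 1] == max(img1[, , 1]), arr.ind = TRUE)[1, ]
  expect_lt(sqrt((am[2] - 0.5 - 32)^2 + (am[1] - 0.5 - 32)^2),
            cfg1$blob_radius_um)
})

test_that("noiseless render has one DAPI blob per cell, one stain blob per positive", {
  # 100 well-separated cells on a grid, 40 marker-positive: the
  # ground-truth render must show exactly 100 DAPI and 40 stain blobs
  cfg <- scene_config(width_um = 310, height_um = 310, n_follicles = 0L,
                      phenotypes = list("CD8+" = c(intra = 0, inter = 0)),
                      seed = 31L)
  sc <- generate_cell_map(cfg)
  g <- expand.grid(x = seq(20, 290, by = 30), y = seq(20, 290, by = 30))
  pos <- rep(c(TRUE, FALSE), c(40, 60))
  sc$cells <- data.frame(cell_id = 1:100, x_um = g$x, y_um = g$y,
                         phenotype = ifelse(pos, "CD8+", "CD8-"),
                         compartment = "inter",
                         CD4_pos = FALSE, CD8_pos = pos, FOXP3_pos = FALSE,
                         PD1_pos = FALSE)
  img <- render_deconvoluted_tiles(sc, noise = FALSE)$CD8
  n_dapi <- max(EBImage::bwlabel(EBImage::Image(t(img[, , 2] > 0.2))))
  n_stain <- max(EBImage::bwlabel(EBImage::Image(t(img[, , 1] > 0.2))))
  expect_equal(n_dapi, 100L)
  expect_equal(n_stain, 40L)
})

test_that("sub-pixel blob radius is rejected", {
  cfg <- scene_config(um_per_px = 8, blob_radius_um = 3, seed = 1L,
                      n_follicles = 0L)
  sc <- generate_cell_map(cfg)
  expect_error(render_deconvoluted_tiles(sc), "unresolvable")
})

test_that("scene writer produces TIFF, CSV and GeoJSON artifacts", {
  cfg <- scene_config(width_um = 80, height_um = 80, n_follicles = 1L,
                      follicle_radius_range = c(20, 30),
                      phenotypes = list("CD8+" = c(intra = 2, inter = 2)),
                      seed = 4L)
  sc <- generate_cell_map(cfg)
  dir <- tempfile(); paths <- write_scene(sc, dir)
  expect_true(all(file.exists(unlist(paths))))
  # libtiff flags the 2-sample grayscale layout as extra samples; harmless
  img <- suppressWarnings(tiff::readTIFF(paths$tiff_CD8))
  expect_equal(dim(img), c(80, 80, 2))
  cells <- read.csv(paths$cells)
  expect_equal(nrow(cells), nrow(sc$cells))
  foll <- read_polygons_geojson(paths$follicles)
  expect_length(foll, 1L)
})
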