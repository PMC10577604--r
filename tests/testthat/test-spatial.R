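test_that("Morisita-Horn hand values and guard rails", {
  expect_equal(morisita_horn(c(3, 1, 2), c(3, 1, 2)), 1)
  expect_equal(morisita_horn(c(5, 0), c(0, 7)), 0)
  expect_equal(morisita_horn(c(2, 1), c(1, 2)), 0.8)
  expect_error(morisita_horn(1:3, 1:2), "equal length")
  out <- morisita_horn(c(0, 0), c(1, 2))
  expect_true(is.na(out))
  expect_equal(attr(out, "reason"), "empty_phenotype")
})

test_that("Morisita-Horn is symmetric, scale-invariant and bounded", {
  set.seed(101)
  for (rep in 1:1000) {
    n <- sample(2:30, 1)
    x <- rpois(n, sample(1:20, 1)); y <- rpois(n, sample(1:20, 1))
    if (sum(x) == 0 || sum(y) == 0) next
    mh <- morisita_horn(x, y)
    expect_gte(mh, 0); expect_lte(mh, 1 + 1e-12)
    expect_identical(mh, morisita_horn(y, x))
    expect_equal(morisita_horn(x * 7, y), mh, tolerance = 1e-12)
  }
})

test_that("hexagonal quadrats partition the compartment and conserve counts", {
  set.seed(55)
  for (rep in 1:20) {
    w <- runif(1, 200, 600); h <- runif(1, 150, 500)
    nf <- sample(0:2, 1)
    foll <- list()
    if (nf > 0) foll <- lapply(seq_len(nf), function(k)
      ellipse_polygon(runif(1, 60, w - 60), runif(1, 60, h - 60),
                      runif(1, 30, 55), runif(1, 25, 50), runif(1, 0, pi)))
    g <- compartment_geometry(follicles = foll, width_um = w, height_um = h,
                              um_per_px = 2)
    tess <- tessellate_compartment(g, "inter", seed_spacing = 60)
    # raster partition is exact by construction
    expect_equal(tess$area_total_um2, g$areas_um2[["inter"]])
    expect_lt(abs(tess$area_total_um2 - g$areas_um2[["inter"]]) /
                g$areas_um2[["inter"]], 0.005)
    cells <- data.frame(x_um = runif(300, 0, w), y_um = runif(300, 0, h))
    counts <- quadrat_counts(tess, cells)
    expect_equal(sum(counts), 300L)
  }
})

test_that("every cell lands in the quadrat of its nearest seed", {
  g <- compartment_geometry(width_um = 400, height_um = 300, um_per_px = 2)
  tess <- tessellate_compartment(g, "inter", seed_spacing = 50)
  set.seed(77)
  cells <- data.frame(x_um = runif(1000, 0, 400), y_um = runif(1000, 0, 300))
  counts <- quadrat_counts(tess, cells)
  # brute-force oracle on the kept seeds
  d2 <- outer(cells$x_um, tess$seeds[, 1], `-`)^2 +
    outer(cells$y_um, tess$seeds[, 2], `-`)^2
  oracle <- tabulate(max.col(-d2, ties.method = "first"),
                     nbins = nrow(tess$seeds))
  expect_equal(counts, oracle)
})

test_that("co-localization is 1 for cloned patterns and falls for segregation", {
  g <- compartment_geometry(width_um = 400, height_um = 400, um_per_px = 2)
  tess <- list(tile = tessellate_compartment(g, "inter", seed_spacing = 50))
  set.seed(9)
  xy <- data.frame(x_um = runif(200, 0, 400), y_um = runif(200, 0, 400))
  cells <- rbind(
    cbind(xy, CD8_pos = TRUE, FOXP3_pos = FALSE),
    cbind(xy, CD8_pos = FALSE, FOXP3_pos = TRUE))
  cells$tile_id <- "tile"; cells$compartment <- "inter"
  mh1 <- colocalization(cells, "CD8+", "FOXP3+", tess,
                        markers = c("CD8", "FOXP3"))
  expect_equal(mh1$mh, 1)

  # A on the left half, B on the right: mh near 0 at fine spacing
  seg <- rbind(
    data.frame(x_um = runif(200, 0, 180), y_um = runif(200, 0, 400),
               CD8_pos = TRUE, FOXP3_pos = FALSE),
    data.frame(x_um = runif(200, 220, 400), y_um = runif(200, 0, 400),
               CD8_pos = FALSE, FOXP3_pos = TRUE))
  seg$tile_id <- "tile"; seg$compartment <- "inter"
  tess2 <- list(tile = tessellate_compartment(g, "inter", seed_spacing = 40))
  mh0 <- colocalization(seg, "CD8+", "FOXP3+", tess2,
                        markers = c("CD8", "FOXP3"))
  expect_lt(mh0$mh, 0.05)

  # absent phenotype: missing value with a reason
  mhna <- colocalization(seg[seg$CD8_pos, ], "CD8+", "FOXP3+", tess2,
                         markers = c("CD8", "FOXP3"))
  expect_true(is.na(mhna$mh))
})

test_that("generator coupling raises the Morisita-Horn index monotonically", {
  mh_at <- function(kappa) {
    vals <- vapply(1:20, function(s) {
      cfg <- scene_config(
        width_um = 400, height_um = 400, n_follicles = 0L,
        phenotypes = list("CD8+FOXP3+" = c(intra = 0, inter = 0.6),
                          "CD4+CD8+" = c(intra = 0, inter = 0.6)),
        coupling = list(list(parent = "CD8+FOXP3+", offspring = "CD4+CD8+",
                             kappa = kappa, sigma_um = 20)),
        seed = 1000L + s)
      sc <- generate_cell_map(cfg)
      g <- compartment_geometry(width_um = 400, height_um = 400,
                                um_per_px = 4)
      cm <- assign_compartments(sc$cells, g)
      cm$tile_id <- "t"
      tess <- list(t = tessellate_compartment(g, "inter", seed_spacing = 50))
      colocalization(cm, "CD8+FOXP3+", "CD4+CD8+", tess)$mh
    }, 0)
    mean(vals)
  }
  curve <- vapply(c(0, 0.5, 1), mh_at, 0)
  expect_true(all(diff(curve) > 0))
})

test_that("independent CSR phenotypes give the documented mh range, rising with quadrat size", {
  g <- compartment_geometry(width_um = 500, height_um = 500, um_per_px = 4)
  mh_mean <- function(spacing) {
    tess <- list(t = tessellate_compartment(g, "inter",
                                            seed_spacing = spacing))
    vals <- vapply(1:50, function(s) {
      set.seed(4000 + s)
      # 2 cells / 1000 um^2 per phenotype, the package's default scale for
      # abundant subsets: a few cells per 50-um quadrat
      cells <- data.frame(
        x_um = runif(1000, 0, 500), y_um = runif(1000, 0, 500),
        CD8_pos = rep(c(TRUE, FALSE), each = 500),
        FOXP3_pos = rep(c(FALSE, TRUE), each = 500),
        tile_id = "t", compartment = "inter")
      colocalization(cells, "CD8+", "FOXP3+", tess,
                     markers = c("CD8", "FOXP3"))$mh
    }, 0)
    mean(vals)
  }
  m50 <- mh_mean(50); m100 <- mh_mean(100)
  expect_gt(m50, 0.6); expect_lt(m50, 1)
  expect_gt(m100, m50)
})

test_that("nearest-neighbor profile matches the exhaustive oracle", {
  mk <- c("A", "B", "C")
  # hand case: nearest candidate and self-exclusion
  cells <- data.frame(cell_id = 1:4,
                      x_um = c(0, 3, 4, 0), y_um = c(0, 0, 0, 0),
                      A_pos = c(TRUE, FALSE, FALSE, FALSE),
                      B_pos = c(FALSE, TRUE, FALSE, TRUE),
                      C_pos = c(FALSE, FALSE, TRUE, FALSE),
                      compartment = "inter")
  cells$x_um[4] <- 10
  nn <- nearest_neighbor_profile(cells, "A+", c("B+", "C+"), "inter", mk)
  expect_equal(nn$pairs$nn_phenotype, "B+")
  expect_equal(nn$pairs$distance_um, 3)

  # reference cells also candidates: self excluded, next-nearest returned
  both <- data.frame(cell_id = 1:2, x_um = c(0, 5), y_um = 0,
                     A_pos = TRUE, B_pos = FALSE, C_pos = FALSE,
                     compartment = "inter")
  nn2 <- nearest_neighbor_profile(both, "A+", "A+", "inter", mk)
  expect_equal(nn2$pairs$distance_um, c(5, 5))
  expect_true(all(nn2$pairs$distance_um > 0))

  # random instances against the O(n^2) oracle
  set.seed(303)
  for (rep in 1:3) {
    n <- 400
    cells <- data.frame(cell_id = sample(10 * n, n),
                        x_um = runif(n, 0, 300), y_um = runif(n, 0, 300),
                        A_pos = runif(n) < 0.3, B_pos = runif(n) < 0.4,
                        C_pos = FALSE, compartment = "inter")
    cells$C_pos <- !cells$A_pos & !cells$B_pos
    nn <- nearest_neighbor_profile(cells, "A+", c("B+", "C+"), "inter", mk)
    ref <- cells[match_phenotype(cells, "A+", mk), ]
    cand <- cells[match_phenotype(cells, "B+", mk) |
                    match_phenotype(cells, "C+", mk), ]
    ora <- nn_oracle(ref, cand)
    got <- nn$pairs[match(ref$cell_id, nn$pairs$cell_id), ]
    expect_equal(got$distance_um, ora$d)
    expect_equal(got$nn_cell_id, cand$cell_id[ora$nn])
  }
})

test_that("nearest-neighbor distances are invariant to rigid motions", {
  mk <- c("A", "B")
  set.seed(7)
  n <- 100
  cells <- data.frame(cell_id = 1:n, x_um = runif(n, 0, 200),
                      y_um = runif(n, 0, 200),
                      A_pos = runif(n) < 0.5, B_pos = FALSE,
                      compartment = "inter")
  cells$B_pos <- !cells$A_pos
  base <- nearest_neighbor_profile(cells, "A+", "B+", "inter", mk)
  th <- 0.6
  rot <- cells
  rot$x_um <- cells$x_um * cos(th) - cells$y_um * sin(th) + 50
  rot$y_um <- cells$x_um * sin(th) + cells$y_um * cos(th) - 20
  moved <- nearest_neighbor_profile(rot, "A+", "B+", "inter", mk)
  expect_equal(moved$pairs$distance_um, base$pairs$distance_um)
})

test_that("tessellation exports to GeoJSON", {
  g <- compartment_geometry(width_um = 200, height_um = 150, um_per_px = 2)
  tess <- tessellate_compartment(g, "inter", seed_spacing = 60)
  f <- tempfile(fileext = ".geojson")
  write_tessellation_geojson(tess, f)
  polys <- read_polygons_geojson(f)
  expect_equal(length(polys), nrow(tess$seeds))
})
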