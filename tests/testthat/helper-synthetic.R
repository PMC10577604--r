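# Shared fixtures: small synthetic scenes and lazily trained reference
# models (trained once per test run and reused across files).

.fl_cache <- new.env(parent = emptyenv())

easy_tile <- function(seed, width_um = 64, density = 2.5,
                      marker = "CD8", phenotypes = NULL) {
  if (is.null(phenotypes)) {
    phenotypes <- list(c(intra = 0, inter = density))
    names(phenotypes) <- paste0(marker, "+")
  }
  cfg <- scene_config(width_um = width_um, height_um = width_um,
                      n_follicles = 0L, phenotypes = phenotypes, seed = seed)
  sc <- generate_cell_map(cfg)
  list(scene = sc, img = render_deconvoluted_tiles(sc)[[marker]],
       cells = sc$cells)
}

# detector trained on 40 easy 64x64-um tiles (seed 0), reused by the
# detection benchmark and the end-to-end co-expression test
reference_detector <- function() {
  if (is.null(.fl_cache$detector)) {
    tiles <- lapply(1:40, easy_tile)
    .fl_cache$detector_train <- tiles
    .fl_cache$detector <- train_detector(lapply(tiles, `[[`, "img"),
                                         lapply(tiles, `[[`, "cells"),
                                         epochs = 30L, seed = 0L)
  }
  .fl_cache$detector
}

# patch set: positives centered on marker-positive cells, negatives on
# marker-negative (DAPI-only) cells, from easy two-phenotype tiles
classifier_patches <- function(n_tiles = 24L, seed_offset = 100L,
                               patch_px = 28L) {
  key <- paste0("patches_", n_tiles, "_", seed_offset)
  if (is.null(.fl_cache[[key]])) {
    pat <- list(); lab <- logical(0)
    for (s in seq_len(n_tiles)) {
      tl <- easy_tile(seed_offset + s, width_um = 96,
                      phenotypes = list("CD8+" = c(intra = 0, inter = 1.5),
                                        "CD4+" = c(intra = 0, inter = 1.5)))
      for (i in seq_len(nrow(tl$cells))) {
        pat[[length(pat) + 1L]] <-
          folliscape:::extract_patch(tl$img, tl$cells$x_um[i],
                                     tl$cells$y_um[i], 1, patch_px)
        lab <- c(lab, tl$cells$CD8_pos[i])
      }
    }
    .fl_cache[[key]] <- list(patches = simplify2array(pat), labels = lab)
  }
  .fl_cache[[key]]
}

reference_classifier <- function() {
  if (is.null(.fl_cache$classifier)) {
    ps <- classifier_patches()
    n <- length(ps$labels)
    train <- seq_len(floor(0.7 * n))
    .fl_cache$classifier_holdout <- list(
      patches = ps$patches[, , , -train, drop = FALSE],
      labels = ps$labels[-train])
    .fl_cache$classifier <- train_classifier(
      ps$patches[, , , train, drop = FALSE], ps$labels[train],
      epochs = 6L, seed = 0L)
  }
  .fl_cache$classifier
}

# area under the ROC curve via the rank (Mann-Whitney) statistic
auc_score <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# brute-force O(n^2) nearest-neighbor oracle (independent of the package's
# implementation path)
nn_oracle <- function(ref, cand) {
  out <- data.frame(nn = integer(nrow(ref)), d = numeric(nrow(ref)))
  for (i in seq_len(nrow(ref))) {
    best <- Inf; bj <- NA_integer_
    for (j in seq_len(nrow(cand))) {
      if (identical(ref$cell_id[i], cand$cell_id[j])) next
      d <- sqrt((ref$x_um[i] - cand$x_um[j])^2 +
                (ref$y_um[i] - cand$y_um[j])^2)
      if (d < best || (d == best && cand$cell_id[j] < cand$cell_id[bj])) {
        best <- d; bj <- j
      }
    }
    out$nn[i] <- bj; out$d[i] <- best
  }
  out
}

# exhaustive search vectorized per reference cell (independent tie-break
# route: explicit min over candidate ids among minimal distances)
nn_oracle_fast <- function(ref, cand) {
  nn <- integer(nrow(ref)); dd <- numeric(nrow(ref))
  for (i in seq_len(nrow(ref))) {
    d <- sqrt((ref$x_um[i] - cand$x_um)^2 + (ref$y_um[i] - cand$y_um)^2)
    d[cand$cell_id == ref$cell_id[i]] <- Inf
    dmin <- min(d)
    js <- which(d == dmin)
    j <- js[which.min(cand$cell_id[js])]
    nn[i] <- j; dd[i] <- dmin
  }
  data.frame(nn = nn, d = dd)
}

# exhaustive optimal one-to-one assignment (minimum total distance among
# maximum-cardinality matchings) for small instances
assignment_oracle <- function(pred, truth, radius) {
  d <- outer(pred$x_um, truth$x_um, `-`)^2 + outer(pred$y_um, truth$y_um, `-`)^2
  d[d > radius^2] <- Inf
  best <- list(n = -1L, cost = Inf)
  recurse <- function(i, used, n, cost) {
    if (i > nrow(d)) {
      if (n > best$n || (n == best$n && cost < best$cost))
        best <<- list(n = n, cost = cost)
      return(invisible())
    }
    recurse(i + 1L, used, n, cost)  # leave pred i unmatched
    for (j in seq_len(ncol(d))) {
      if (!used[j] && is.finite(d[i, j])) {
        used[j] <- TRUE
        recurse(i + 1L, used, n + 1L, cost + d[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(ncol(d)), 0L, 0)
  best
}
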