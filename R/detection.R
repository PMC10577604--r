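# Count-regularized convolutional cell detector: a small fully-convolutional
# network predicts a centroid heatmap; a global count head (heatmap mass
# divided by the mass of one target blob) is penalized against the true
# cell count, which regularizes the heatmap toward one unit of mass per cell.

#' Build the Gaussian-disk target heatmap for one tile
#' @keywords internal
detection_target <- function(cells, ny, nx, um_per_px, sigma_px = 3) {
  paint_blobs(matrix(0, ny, nx), cells$x_um, cells$y_um,
              rep(1, nrow(cells)), sigma_px * um_per_px, um_per_px)
}

gaussian_mass <- function(sigma_px = 3) {
  w <- ceiling(4 * sigma_px)
  g <- exp(-((-w:w)^2) / (2 * sigma_px^2))
  sum(outer(g, g))
}

detector_params <- function(filters = 12L, c_in = 2L) {
  list(W1 = glorot(c(3, 3, c_in, filters), 9 * c_in, 9 * filters),
       b1 = numeric(filters),
       W2 = glorot(c(3, 3, filters, filters), 9 * filters, 9 * filters),
       b2 = numeric(filters),
       W3 = glorot(c(3, 3, filters, 1), 9 * filters, 9),
       b3 = numeric(1))
}

detector_forward <- function(params, x, cache = FALSE) {
  c1 <- conv_fwd(x, params$W1, params$b1); a1 <- relu_fwd(c1$y)
  c2 <- conv_fwd(a1, params$W2, params$b2); a2 <- relu_fwd(c2$y)
  c3 <- conv_fwd(a2, params$W3, params$b3)
  h <- 1 / (1 + exp(-c3$y))
  if (!cache) return(h)
  # cols of each layer's *input* are needed for the weight gradients
  d <- dim(a2)
  cols3 <- im2col(a2, im2col_idx(d[1L], d[2L], d[3L]))
  list(h = h, x = x, c1 = c1, a1 = a1, c2 = c2, a2 = a2, cols3 = cols3)
}

detector_backward <- function(params, fw, dh) {
  dz3 <- dh * fw$h * (1 - fw$h)
  g3 <- conv_bwd(dz3, fw$a2, fw$cols3, params$W3)
  da2 <- relu_bwd(g3$dx, fw$a2)
  g2 <- conv_bwd(da2, fw$a1, fw$c2$cols, params$W2)
  da1 <- relu_bwd(g2$dx, fw$a1)
  g1 <- conv_bwd(da1, fw$x, fw$c1$cols, params$W1)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db, W3 = g3$dW, b3 = g3$db)
}

#' Train the count-regularized cell detector
#'
#' Trains a small fully-convolutional network (two hidden 3x3 conv layers)
#' on rendered marker tiles against Gaussian-disk centroid targets
#' (sigma = 3 px). The loss is a positively-weighted mean squared heatmap
#' error plus `lambda` times the squared relative error of the predicted
#' global cell count (heatmap mass / single-blob mass). `lambda = 0`
#' detaches the count head and reduces to plain heatmap regression.
#'
#' @param tiles List of tile images (arrays height x width x 2, stain+DAPI).
#' @param truths List of cell data frames (columns x_um, y_um), same length.
#' @param um_per_px Pixel pitch of the tiles.
#' @param epochs,lr,filters,lambda,pos_weight,sigma_px Hyperparameters.
#' @param seed Integer seed; training is deterministic given it.
#' @param verbose Print per-epoch loss.
#' @return An `fl_detector` with weights, config and per-epoch loss history.
#' @export
train_detector <- function(tiles, truths, um_per_px = 1, epochs = 40L,
                           lr = 5e-3, filters = 12L, lambda = 0.5,
                           pos_weight = 25, sigma_px = 3, seed = 0L,
                           verbose = FALSE) {
  if (!length(tiles)) stop("empty training set")
  if (length(tiles) != length(truths)) stop("tiles/truths length mismatch")
  if (!any(vapply(truths, nrow, 0L) > 0L))
    stop("training set contains no cells")
  gm <- gaussian_mass(sigma_px)
  tiles <- lapply(tiles, function(tl)
    center_input(array(tl, c(dim(tl)[1:2], 2L, 1L))))
  withr::with_seed(as.integer(seed), {
    params <- detector_params(filters)
    st <- adam_init(params)
    targets <- lapply(seq_along(tiles), function(i) {
      d <- dim(tiles[[i]])
      detection_target(truths[[i]], d[1L], d[2L], um_per_px, sigma_px)
    })
    history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(tiles))
      tot <- 0
      for (i in ord) {
        x <- tiles[[i]]
        t_hm <- targets[[i]]
        n_true <- nrow(truths[[i]])
        fw <- detector_forward(params, x, cache = TRUE)
        h <- fw$h[, , 1L, 1L]
        w <- 1 + pos_weight * t_hm
        sw <- sum(w)
        resid <- h - t_hm
        l_hm <- sum(w * resid^2) / sw
        c_hat <- sum(h) / gm
        m <- max(1, n_true)
        l_cnt <- ((c_hat - n_true) / m)^2
        loss <- l_hm + lambda * l_cnt
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", ep,
               " (tile ", i, "); lower the learning rate")
        tot <- tot + loss
        dh <- 2 * w * resid / sw
        if (lambda > 0)
          dh <- dh + lambda * 2 * (c_hat - n_true) / m^2 / gm
        dh <- array(dh, dim(fw$h))
        grads <- detector_backward(params, fw, dh)
        upd <- adam_step(params, grads, st, lr = lr)
        params <- upd$params; st <- upd$state
      }
      history[ep] <- tot / length(tiles)
      if (verbose) message(sprintf("epoch %d: loss %.5f", ep, history[ep]))
    }
    structure(list(params = params, um_per_px = um_per_px,
                   sigma_px = sigma_px, gaussian_mass = gm, lambda = lambda,
                   filters = filters, seed = as.integer(seed),
                   history = history),
              class = "fl_detector")
  })
}

#' @export
print.fl_detector <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf(
    "Count-regularized convolutional detector: %d parameters, %d epochs\n",
    np, length(x$history)))
  cat(sprintf("  final training loss %.5f (lambda = %g)\n",
              x$history[length(x$history)], x$lambda))
  invisible(x)
}

#' Predict the centroid heatmap and count for one tile
#'
#' @param model An `fl_detector`.
#' @param tile Array height x width x 2.
#' @return List with `heatmap` (matrix) and `count` (scalar count-head value).
#' @export
predict_heatmap <- function(model, tile, block_px = 160L, margin_px = 8L) {
  d <- dim(tile)
  # center on the whole tile so blocked and whole-tile paths agree
  tile <- center_input(array(tile, c(d[1:2], 2L, 1L)))[, , , 1L]
  if (max(d[1:2]) <= block_px) {
    x <- array(tile, c(d[1:2], 2L, 1L))
    h <- detector_forward(model$params, x)[, , 1L, 1L]
  } else {
    # process large tiles in overlapping blocks and stitch the interiors
    h <- matrix(0, d[1L], d[2L])
    ys <- seq(1L, d[1L], by = block_px)
    xs <- seq(1L, d[2L], by = block_px)
    for (y0 in ys) for (x0 in xs) {
      y1 <- min(d[1L], y0 + block_px - 1L)
      x1 <- min(d[2L], x0 + block_px - 1L)
      ye <- max(1L, y0 - margin_px):min(d[1L], y1 + margin_px)
      xe <- max(1L, x0 - margin_px):min(d[2L], x1 + margin_px)
      xb <- array(tile[ye, xe, ], c(length(ye), length(xe), 2L, 1L))
      hb <- detector_forward(model$params, xb)[, , 1L, 1L]
      h[y0:y1, x0:x1] <- hb[match(y0:y1, ye), match(x0:x1, xe)]
    }
  }
  list(heatmap = h, count = sum(h) / model$gaussian_mass)
}

#' Extract cell centroids from a tile
#'
#' Local maxima of the predicted heatmap above threshold `tau`, with greedy
#' non-maximum suppression at minimum separation `d_min_um`. Coordinates are
#' reported in micrometres (pixel centers).
#'
#' @param model An `fl_detector`.
#' @param tile Array height x width x 2 in the training channel convention.
#' @param tau Heatmap threshold in [0, 1].
#' @param d_min_um Minimum centroid separation.
#' @return Data frame: x_um, y_um, score (class `fl_detection`); zero rows
#'   for a blank tile.
#' @export
detect_cells <- function(model, tile, tau = 0.5, d_min_um = 5) {
  hp <- predict_heatmap(model, tile)
  h <- hp$heatmap
  mpp <- model$um_per_px
  # 3x3 local maxima above threshold
  ny <- nrow(h); nx <- ncol(h)
  pad <- matrix(-Inf, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- h
  is_max <- h >= tau
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    is_max <- is_max & (h >= pad[(2:(ny + 1L)) + di, (2:(nx + 1L)) + dj])
  }
  idx <- which(is_max, arr.ind = TRUE)
  out <- data.frame(x_um = numeric(0), y_um = numeric(0), score = numeric(0))
  if (nrow(idx)) {
    sc <- h[idx]
    ord <- order(-sc, idx[, 1L], idx[, 2L])
    idx <- idx[ord, , drop = FALSE]; sc <- sc[ord]
    x <- (idx[, 2L] - 0.5) * mpp
    y <- (idx[, 1L] - 0.5) * mpp
    keep <- logical(length(sc))
    for (i in seq_along(sc)) {
      if (i == 1L) { keep[1L] <- TRUE; next }
      kept <- which(keep)
      keep[i] <- all((x[i] - x[kept])^2 + (y[i] - y[kept])^2 >= d_min_um^2)
    }
    out <- data.frame(x_um = x[keep], y_um = y[keep], score = sc[keep])
    out <- out[order(out$y_um, out$x_um), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "count_head") <- hp$count
  class(out) <- c("fl_detection", class(out))
  out
}

#' Greedy one-to-one centroid matching
#'
#' Candidate pairs within `radius_um` are matched in ascending distance
#' order, each centroid used at most once.
#'
#' @param pred,truth Data frames with x_um, y_um.
#' @param radius_um Matching radius.
#' @return Integer matrix with columns `pred`, `truth` (matched index pairs).
#' @export
match_centroids <- function(pred, truth, radius_um) {
  stopifnot(radius_um > 0)
  if (!nrow(pred) || !nrow(truth))
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("pred", "truth"))))
  d2 <- outer(pred$x_um, truth$x_um, `-`)^2 + outer(pred$y_um, truth$y_um, `-`)^2
  cand <- which(d2 <= radius_um^2, arr.ind = TRUE)
  if (!nrow(cand))
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("pred", "truth"))))
  cand <- cand[order(d2[cand]), , drop = FALSE]
  used_p <- logical(nrow(pred)); used_t <- logical(nrow(truth))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (!used_p[i] && !used_t[j]) { keep[k] <- TRUE; used_p[i] <- TRUE; used_t[j] <- TRUE }
  }
  m <- cand[keep, , drop = FALSE]
  dimnames(m) <- list(NULL, c("pred", "truth"))
  m
}

#' Evaluate detections against ground truth
#'
#' One-to-one greedy matching within `radius_um`; matched predictions are
#' true positives, unmatched predictions false positives, unmatched truth
#' false negatives. When per-region counts are supplied, the Spearman
#' correlation between annotated and detected counts is reported.
#'
#' @param pred Data frame of detections (x_um, y_um).
#' @param truth Data frame of true centroids (x_um, y_um).
#' @param radius_um Matching radius (> 0).
#' @param region_counts Optional data frame with columns `annotated`,
#'   `detected` (one row per annotation region).
#' @return List of class `fl_detection_metrics`: precision, recall, f1,
#'   n_pred, n_truth, n_matched, `degenerate` flag (both sets empty), and
#'   optionally `count_cor` (estimate + p).
#' @export
evaluate_detection <- function(pred, truth, radius_um = 8,
                               region_counts = NULL) {
  degenerate <- nrow(pred) == 0L && nrow(truth) == 0L
  if (degenerate) {
    precision <- recall <- f1 <- 1
    n_matched <- 0L
  } else {
    m <- match_centroids(pred, truth, radius_um)
    n_matched <- nrow(m)
    precision <- if (nrow(pred)) n_matched / nrow(pred) else 0
    recall <- if (nrow(truth)) n_matched / nrow(truth) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
  }
  out <- list(precision = precision, recall = recall, f1 = f1,
              n_pred = nrow(pred), n_truth = nrow(truth),
              n_matched = n_matched, radius_um = radius_um,
              degenerate = degenerate)
  if (!is.null(region_counts)) {
    ct <- suppressWarnings(
      stats::cor.test(region_counts$annotated, region_counts$detected,
                      method = "spearman"))
    out$count_cor <- list(r = unname(ct$estimate), p = ct$p.value)
  }
  structure(out, class = "fl_detection_metrics")
}

#' @export
print.fl_detection_metrics <- function(x, ...) {
  cat(sprintf("Detection: precision %.3f, recall %.3f, F1 %.3f (radius %g um)\n",
              x$precision, x$recall, x$f1, x$radius_um))
  cat(sprintf("  %d predicted, %d annotated, %d matched%s\n", x$n_pred,
              x$n_truth, x$n_matched,
              if (x$degenerate) " [degenerate: both empty]" else ""))
  if (!is.null(x$count_cor))
    cat(sprintf("  count correlation: Spearman r = %.3f, p = %.3g\n",
                x$count_cor$r, x$count_cor$p))
  invisible(x)
}

#' Save / load a detector checkpoint as plain JSON
#'
#' @param model An `fl_detector`. @param path File path.
#' @export
write_detector <- function(model, path) {
  ser <- list(params = lapply(model$params, function(p)
    list(dim = dim(p) %||% length(p), data = as.numeric(p))),
    um_per_px = model$um_per_px, sigma_px = model$sigma_px,
    gaussian_mass = model$gaussian_mass, lambda = model$lambda,
    filters = model$filters, seed = model$seed, history = model$history)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_detector
#' @export
read_detector <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(ser$params, function(p)
    if (length(p$dim) > 1L) array(p$data, p$dim) else as.numeric(p$data))
  structure(list(params = params, um_per_px = ser$um_per_px,
                 sigma_px = ser$sigma_px, gaussian_mass = ser$gaussian_mass,
                 lambda = ser$lambda, filters = ser$filters, seed = ser$seed,
                 history = ser$history),
            class = "fl_detector")
}
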