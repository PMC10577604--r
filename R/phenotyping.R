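# Per-marker positive/negative patch classification and co-expression
# merging of positives across the deconvoluted planes into multi-marker
# phenotypes.

classifier_params <- function(c_in = 2L) {
  list(W1 = glorot(c(3, 3, c_in, 8L), 9 * c_in, 9 * 8), b1 = numeric(8L),
       W2 = glorot(c(3, 3, 8L, 8L), 72, 72),            b2 = numeric(8L),
       W3 = glorot(c(3, 3, 8L, 16L), 72, 144),          b3 = numeric(16L),
       W4 = glorot(c(7L * 7L * 16L, 32L), 784, 32),     b4 = numeric(32L),
       W5 = glorot(c(32L, 2L), 32, 2),                  b5 = numeric(2L))
}

classifier_forward <- function(params, x, cache = FALSE) {
  N <- dim(x)[4L]
  c1 <- conv_fwd(x, params$W1, params$b1); a1 <- relu_fwd(c1$y)
  c2 <- conv_fwd(a1, params$W2, params$b2); a2 <- relu_fwd(c2$y)
  p1 <- maxpool_fwd(a2)                                   # 28 -> 14
  c3 <- conv_fwd(p1$y, params$W3, params$b3); a3 <- relu_fwd(c3$y)
  p2 <- maxpool_fwd(a3)                                   # 14 -> 7
  fl <- matrix(aperm(p2$y, c(1L, 2L, 3L, 4L)), ncol = N)  # features x N
  z4 <- crossprod(params$W4, fl) + params$b4; a4 <- relu_fwd(z4)
  z5 <- crossprod(params$W5, a4) + params$b5              # 2 x N logits
  z5m <- sweep(z5, 2L, apply(z5, 2L, max))
  probs <- exp(z5m); probs <- sweep(probs, 2L, colSums(probs), `/`)
  if (!cache) return(probs)
  d2 <- dim(a2)
  cols3 <- im2col(p1$y, im2col_idx(dim(p1$y)[1L], dim(p1$y)[2L], dim(p1$y)[3L]))
  list(probs = probs, x = x, c1 = c1, a1 = a1, c2 = c2, a2 = a2, p1 = p1,
       c3 = c3, a3 = a3, p2 = p2, fl = fl, a4 = a4, cols3 = cols3)
}

classifier_backward <- function(params, fw, labels) {
  # labels: integer vector in {1, 2} (positive = 1); cross-entropy gradient
  N <- length(labels)
  dz5 <- fw$probs
  dz5[cbind(labels, seq_len(N))] <- dz5[cbind(labels, seq_len(N))] - 1
  dz5 <- dz5 / N
  dW5 <- fw$a4 %*% t(dz5); db5 <- rowSums(dz5)
  da4 <- params$W5 %*% dz5
  dz4 <- relu_bwd(da4, fw$a4)
  dW4 <- fw$fl %*% t(dz4); db4 <- rowSums(dz4)
  dfl <- params$W4 %*% dz4
  dp2 <- array(dfl, dim(fw$p2$y))
  da3 <- maxpool_bwd(dp2, fw$p2, dim(fw$a3))
  dz3 <- relu_bwd(da3, fw$a3)
  g3 <- conv_bwd(dz3, fw$p1$y, fw$cols3, params$W3)
  dp1 <- g3$dx
  da2 <- maxpool_bwd(dp1, fw$p1, dim(fw$a2))
  dz2 <- relu_bwd(da2, fw$a2)
  g2 <- conv_bwd(dz2, fw$a1, fw$c2$cols, params$W2)
  dz1 <- relu_bwd(g2$dx, fw$a1)
  g1 <- conv_bwd(dz1, fw$x, fw$c1$cols, params$W1)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db, W3 = g3$dW, b3 = g3$db,
       W4 = dW4, b4 = db4, W5 = dW5, b5 = db5)
}

#' Train the positive/negative patch classifier
#'
#' A small VGG-style stack (two 3x3 conv layers, max-pool, one more conv
#' layer, max-pool, dense, 2-way softmax) trained with cross-entropy on
#' patches centered on detected cells. Patches must be square with side a
#' multiple of 4 (default 28).
#'
#' @param patches Array `p x p x 2 x N` (stain + DAPI channels) or list of
#'   `p x p x 2` arrays.
#' @param labels Logical or 0/1 vector, TRUE/1 = positive; both classes
#'   must be present.
#' @param epochs,lr,batch_size Training hyperparameters.
#' @param seed Integer seed; training is deterministic given it.
#' @param verbose Print per-epoch loss.
#' @return An `fl_classifier` with weights and training history.
#' @export
train_classifier <- function(patches, labels, epochs = 6L, lr = 1e-3,
                             batch_size = 64L, seed = 0L, verbose = FALSE) {
  if (is.list(patches)) patches <- simplify2array(patches)
  stopifnot(length(dim(patches)) == 4L)
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop("training set must contain both positive and negative patches")
  if (dim(patches)[1L] %% 4L != 0L || dim(patches)[1L] != dim(patches)[2L])
    stop("patch side must be square and a multiple of 4")
  N <- dim(patches)[4L]
  y <- ifelse(labels, 1L, 2L)  # class index: 1 = positive, 2 = negative
  patches <- center_input(patches)
  withr::with_seed(as.integer(seed), {
    params <- classifier_params(dim(patches)[3L])
    st <- adam_init(params)
    history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      tot <- 0; nb <- 0L
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        x <- patches[, , , b, drop = FALSE]
        fw <- classifier_forward(params, x, cache = TRUE)
        pr <- pmax(fw$probs[cbind(y[b], seq_along(b))], 1e-12)
        loss <- -mean(log(pr))
        if (!is.finite(loss)) stop("non-finite classifier loss at epoch ", ep)
        tot <- tot + loss; nb <- nb + 1L
        grads <- classifier_backward(params, fw, y[b])
        upd <- adam_step(params, grads, st, lr = lr)
        params <- upd$params; st <- upd$state
      }
      history[ep] <- tot / nb
      if (verbose) message(sprintf("epoch %d: loss %.4f", ep, history[ep]))
    }
    structure(list(params = params, patch_px = dim(patches)[1L],
                   seed = as.integer(seed), history = history),
              class = "fl_classifier")
  })
}

#' @export
print.fl_classifier <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("VGG-style patch classifier: %d parameters, %d epochs, final loss %.4f\n",
              np, length(x$history), x$history[length(x$history)]))
  invisible(x)
}

#' Extract a zero-padded patch centered on a centroid
#' @keywords internal
extract_patch <- function(img, x_um, y_um, um_per_px, patch_px) {
  half_lo <- floor((patch_px - 1L) / 2)
  ci <- floor(y_um / um_per_px) + 1L
  cj <- floor(x_um / um_per_px) + 1L
  out <- array(0, c(patch_px, patch_px, dim(img)[3L]))
  ii <- (ci - half_lo):(ci - half_lo + patch_px - 1L)
  jj <- (cj - half_lo):(cj - half_lo + patch_px - 1L)
  ok_i <- ii >= 1L & ii <= dim(img)[1L]
  ok_j <- jj >= 1L & jj <= dim(img)[2L]
  out[which(ok_i), which(ok_j), ] <- img[ii[ok_i], jj[ok_j], , drop = FALSE]
  out
}

#' Classify detected cells on one marker plane
#'
#' Extracts a patch centered on each centroid (zero-padded at tile edges)
#' and applies the classifier. The class is positive when
#' `p_pos >= p_neg` (ties go to positive).
#'
#' @param model An `fl_classifier`.
#' @param tile Array height x width x 2.
#' @param centroids Data frame with x_um, y_um.
#' @param um_per_px Pixel pitch.
#' @return Data frame: x_um, y_um, p_pos, p_neg, positive (logical).
#' @export
classify_cells <- function(model, tile, centroids, um_per_px = 1) {
  n <- nrow(centroids)
  if (n == 0L)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      p_pos = numeric(0), p_neg = numeric(0),
                      positive = logical(0)))
  pp <- model$patch_px
  patches <- array(0, c(pp, pp, dim(tile)[3L], n))
  for (i in seq_len(n))
    patches[, , , i] <- extract_patch(tile, centroids$x_um[i],
                                      centroids$y_um[i], um_per_px, pp)
  probs <- classifier_probs(model, patches)
  data.frame(x_um = centroids$x_um, y_um = centroids$y_um,
             p_pos = probs[1L, ], p_neg = probs[2L, ],
             positive = probs[1L, ] >= probs[2L, ])
}

#' Class probabilities for a batch of patches
#'
#' Applies the model's input centering and returns the softmax output.
#'
#' @param model An `fl_classifier`.
#' @param patches Array `p x p x c x N`.
#' @return Matrix `2 x N`: rows p_pos, p_neg.
#' @export
classifier_probs <- function(model, patches) {
  patches <- center_input(patches)
  n <- dim(patches)[4L]
  probs <- matrix(0, 2L, n)
  for (b in split(seq_len(n), ceiling(seq_len(n) / 256L)))
    probs[, b] <- classifier_forward(model$params,
                                     patches[, , , b, drop = FALSE])
  rownames(probs) <- c("p_pos", "p_neg")
  probs
}

#' Decide the class from the two softmax probabilities
#'
#' @param p_pos,p_neg Probabilities (must sum to 1 within 1e-6).
#' @return Logical: positive class. Ties (`p_pos == p_neg`) are positive.
#' @export
classify_decision <- function(p_pos, p_neg) {
  if (any(abs(p_pos + p_neg - 1) > 1e-6))
    stop("p_pos + p_neg must sum to 1")
  p_pos >= p_neg
}

#' Merge per-plane positive centroids into multi-marker cells
#'
#' Centroids from different marker planes lying within `merge_radius_um`
#' are greedily merged (ascending pairwise distance, each centroid used
#' once per plane pair) into single cells carrying the union of marker
#' positivities. Duplicate centroids within one plane closer than
#' `d_min_um` are deduplicated with a warning. Every input centroid
#' contributes to exactly one output cell.
#'
#' @param planes Named list (marker -> data frame with x_um, y_um) of
#'   positive centroids per deconvoluted plane.
#' @param markers Panel marker vector (defines label order; defaults to the
#'   names of `planes`).
#' @param merge_radius_um Merge tolerance (default 5, about half a
#'   lymphocyte diameter).
#' @param d_min_um Within-plane deduplication distance.
#' @return Cell map data frame: cell_id, x_um, y_um, `<marker>_pos`
#'   logicals and the full `phenotype` signature.
#' @export
merge_across_planes <- function(planes, markers = names(planes),
                                merge_radius_um = 5, d_min_um = 5) {
  stopifnot(merge_radius_um > 0, length(planes) >= 1L)
  if (is.null(names(planes)) || any(names(planes) == ""))
    stop("planes must be a named list (marker -> centroid table)")
  planes <- lapply(planes, function(p) {
    p <- as.data.frame(p)[, c("x_um", "y_um")]
    if (nrow(p) > 1L) {
      dup <- integer(0)
      d2 <- as.matrix(stats::dist(p))^2
      diag(d2) <- Inf
      close <- which(d2 < d_min_um^2 & upper.tri(d2), arr.ind = TRUE)
      if (nrow(close)) {
        dup <- unique(close[, 2L])
        warning(length(dup), " duplicate centroid(s) within one plane ",
                "closer than d_min; deduplicated")
        p <- p[-dup, , drop = FALSE]
      }
    }
    p
  })
  # consolidated table: one row per cell, positivity per marker
  cells <- NULL
  for (mk in names(planes)) {
    pl <- planes[[mk]]
    if (is.null(cells)) {
      cells <- data.frame(x_um = pl$x_um, y_um = pl$y_um,
                          n_src = rep(1L, nrow(pl)))
      cells[[mk]] <- rep(TRUE, nrow(pl))
      next
    }
    cells[[mk]] <- rep(FALSE, nrow(cells))
    if (!nrow(pl)) next
    m <- match_centroids(pl, cells, merge_radius_um)
    if (nrow(m)) {
      j <- m[, "truth"]; i <- m[, "pred"]
      # running mean of the contributing centroid positions
      cells$x_um[j] <- (cells$x_um[j] * cells$n_src[j] + pl$x_um[i]) /
        (cells$n_src[j] + 1L)
      cells$y_um[j] <- (cells$y_um[j] * cells$n_src[j] + pl$y_um[i]) /
        (cells$n_src[j] + 1L)
      cells$n_src[j] <- cells$n_src[j] + 1L
      cells[[mk]][j] <- TRUE
    }
    rest <- setdiff(seq_len(nrow(pl)), if (nrow(m)) m[, "pred"] else integer(0))
    if (length(rest)) {
      new <- cells[rep(NA_integer_, length(rest)), , drop = FALSE]
      new$x_um <- pl$x_um[rest]; new$y_um <- pl$y_um[rest]; new$n_src <- 1L
      for (col in setdiff(names(cells), c("x_um", "y_um", "n_src")))
        new[[col]] <- FALSE
      new[[mk]] <- TRUE
      cells <- rbind(cells, new)
    }
  }
  full <- stats::setNames(
    lapply(markers, function(mk) if (mk %in% names(cells)) cells[[mk]]
           else rep(FALSE, nrow(cells))), paste0(markers, "_pos"))
  out <- cbind(data.frame(x_um = cells$x_um, y_um = cells$y_um),
               as.data.frame(full))
  out <- out[order(out$y_um, out$x_um), , drop = FALSE]
  out <- cbind(cell_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out$phenotype <- phenotype_signature(
    as.matrix(out[, paste0(markers, "_pos"), drop = FALSE]), markers)
  out
}

#' Fraction of a marker's cells carrying a phenotype
#'
#' Percentage of cells positive for `denominator_marker` that match the
#' `numerator` phenotype, e.g. the share of CD8-expressing cells that are
#' CD8+FOXP3+.
#'
#' @param cell_map Cell map with `<marker>_pos` columns.
#' @param numerator Phenotype label (see [parse_phenotype()]).
#' @param denominator_marker Single marker name.
#' @param markers Panel marker vector.
#' @return Percentage (0-100), or `NA` when no cell expresses the marker.
#' @export
phenotype_fractions <- function(cell_map, numerator, denominator_marker,
                                markers = panel_markers()) {
  den <- cell_map[[paste0(denominator_marker, "_pos")]]
  if (is.null(den)) stop("unknown marker: ", denominator_marker)
  if (!sum(den)) return(NA_real_)
  num <- match_phenotype(cell_map, numerator, markers)
  100 * sum(num & den) / sum(den)
}

#' Save / load a classifier checkpoint as plain JSON
#' @param model An `fl_classifier`. @param path File path.
#' @export
write_classifier <- function(model, path) {
  ser <- list(params = lapply(model$params, function(p)
    list(dim = dim(p) %||% length(p), data = as.numeric(p))),
    patch_px = model$patch_px, seed = model$seed, history = model$history)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(params = lapply(ser$params, function(p)
    if (length(p$dim) > 1L) array(p$data, p$dim) else as.numeric(p$data)),
                 patch_px = ser$patch_px, seed = ser$seed,
                 history = ser$history),
            class = "fl_classifier")
}
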