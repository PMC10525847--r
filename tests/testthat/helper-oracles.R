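# Independent oracles used across the suite. These deliberately use
# brute force (rasterization, pairwise enumeration, dense grids) so they
# stay independent of the implementation paths they check.

# IoU by rasterizing both boxes on a fine grid and counting covered
# cells. Exact when every box edge lies on the step grid, which
# random_box() guarantees.
raster_iou <- function(a, b, step = 0.05) {
  lo_x <- min(a[1], b[1]); hi_x <- max(a[3], b[3])
  lo_y <- min(a[2], b[2]); hi_y <- max(a[4], b[4])
  xs <- seq(lo_x + step / 2, hi_x, by = step)
  ys <- seq(lo_y + step / 2, hi_y, by = step)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  in_a <- gx >= a[1] & gx < a[3] & gy >= a[2] & gy < a[4]
  in_b <- gx >= b[1] & gx < b[3] & gy >= b[2] & gy < b[4]
  sum(in_a & in_b) / sum(in_a | in_b)
}

# square crop via "pad the whole canvas, then slice" -- shape-free of the
# clipping logic under test
pad_then_crop <- function(image, center, edge, fill = 0) {
  side <- floor(edge + 0.5)
  pad <- side + 128L # large enough for any center used in the tests
  h <- nrow(image); w <- ncol(image)
  big <- matrix(fill, h + 2L * pad, w + 2L * pad)
  big[pad + seq_len(h), pad + seq_len(w)] <- image
  x0 <- floor(center[1] - side / 2 + 0.5) + pad
  y0 <- floor(center[2] - side / 2 + 0.5) + pad
  big[(y0 + 1L):(y0 + side), (x0 + 1L):(x0 + side)]
}

# AUC by enumerating every positive-negative pair
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# best sensitivity x specificity over a dense threshold grid
grid_best_product <- function(scores, labels, step = 1e-4) {
  best <- -1
  for (t in seq(0, 1, by = step)) {
    pred <- scores > t
    tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
    tn <- sum(!pred & labels == 0); fp <- sum(pred & labels == 0)
    prod <- (tp / (tp + fn)) * (tn / (tn + fp))
    if (prod > best) best <- prod
  }
  best
}

# greedy NMS + bounds filter written independently with plain loops
filter_oracle <- function(df, w, h, thr) {
  inb <- which(df$x0 >= 0 & df$y0 >= 0 & df$x1 <= w & df$y1 <= h)
  df <- df[inb, , drop = FALSE]
  if (nrow(df) <= 1) return(df)
  ord <- order(-df$score)
  keep <- logical(nrow(df))
  for (i in ord) {
    ok <- TRUE
    for (j in which(keep)) {
      if (iou(as.numeric(df[i, c("x0", "y0", "x1", "y1")]),
              as.numeric(df[j, c("x0", "y0", "x1", "y1")])) > thr) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_box <- function(max_side = 10, origin = 10, grid = 0.05) {
  snap <- function(v) round(v / grid) * grid
  x0 <- snap(runif(1, 0, origin)); y0 <- snap(runif(1, 0, origin))
  c(x0, y0, x0 + snap(runif(1, 0.5, max_side)),
    y0 + snap(runif(1, 0.5, max_side)))
}

# small scene fixture with known labels
test_scene <- function(seed = 42, labels = c(1, 0, 0, 0, 1, 1),
                       image_size = 96) {
  cfg <- synthetic_config(image_size = image_size, seed = seed)
  set.seed(seed)
  render_scene(cfg, labels)
}

# tiny perfectly-learnable branch dataset: images whose mean intensity
# encodes the target labels (no spatial structure needed)
toy_branch_data <- function(n, seed = 1, size = 12) {
  set.seed(seed)
  labels <- matrix(rbinom(n * 6, 1, 0.5), n, 6,
                   dimnames = list(NULL, disease_names()))
  images <- lapply(seq_len(n), function(i) {
    base <- matrix(runif(size * size, 0.2, 0.3), size, size)
    # imprint each routed target as a bright quadrant
    if (labels[i, "erm"] == 1) base[1:(size / 2), 1:(size / 2)] <- 0.9
    if (labels[i, "amd"] == 1) base[1:(size / 2), (size / 2 + 1):size] <- 0.9
    if (labels[i, "gs"] == 1) base[(size / 2 + 1):size, 1:(size / 2)] <- 0.9
    base
  })
  list(images = images, labels = labels)
}
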