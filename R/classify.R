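# Label-routed classification branches.
#
# Three branches consume the three regions: the optic-disc crop detects
# glaucoma suspect (two-class softmax cross-entropy), the macula crop
# detects epiretinal membrane and macular degeneration (element-wise
# sigmoid binary cross-entropy), and the whole image detects diabetic
# retinopathy, retinal break and vein occlusion (same multi-label loss).
# A fourth configuration, the whole-image all-six-label baseline, is the
# ablation comparator. Training follows the published schedule: Adam,
# batch size 8, learning rate halved every 10 epochs, 60 epochs, with
# the checkpoint restored from the epoch of highest mean validation AUC.

#' Route a label vector to the three branches
#'
#' @param labels named 0/1 vector in [disease_names()] order.
#' @return list with `gs` (scalar), `mac` (`c(erm, amd)`) and `full`
#'   (`c(dr, rb, rvo)`). Concatenating `full`, `mac`, `gs` in canonical
#'   order reconstructs the input (see [combine_partitions()]).
#' @export
partition_labels <- function(labels) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == 6L, all(labels %in% 0:1))
  names(labels) <- disease_names()
  list(gs = labels[["gs"]],
       mac = labels[c("erm", "amd")],
       full = labels[c("dr", "rb", "rvo")])
}

#' Reassemble a label vector from branch parts
#'
#' @param parts list as returned by [partition_labels()].
#' @return named 0/1 vector in canonical order.
#' @export
combine_partitions <- function(parts) {
  out <- c(parts$full, parts$mac, gs = parts$gs)
  stats::setNames(as.integer(out), disease_names())
}

#' Draw online-augmentation parameters
#'
#' One draw per image per batch: a horizontal flip with probability 0.5
#' and a rotation angle uniform on `[-180, 180]` degrees.
#'
#' @return list with `flip` (logical) and `angle` (degrees).
#' @export
sample_augment_params <- function() {
  list(flip = stats::runif(1L) < 0.5,
       angle = stats::runif(1L, -180, 180))
}

#' Rotate an image about its center
#'
#' Nearest-neighbour rotation; pixels mapping outside the source are set
#' to `fill_value`. Angle 0 returns the input unchanged.
#'
#' @param image numeric matrix.
#' @param angle rotation in degrees (counter-clockwise).
#' @param fill_value intensity for unmapped pixels.
#' @return rotated matrix of the same size.
#' @export
rotate_image <- function(image, angle, fill_value = 0) {
  if (angle == 0) return(image)
  h <- nrow(image); w <- ncol(image)
  th <- angle * pi / 180
  cx <- w / 2; cy <- h / 2
  xs <- rep(seq_len(w) - 0.5 - cx, each = h)
  ys <- rep(seq_len(h) - 0.5 - cy, times = w)
  # inverse map: source coordinates for each destination pixel
  sx <- cos(th) * xs + sin(th) * ys + cx
  sy <- -sin(th) * xs + cos(th) * ys + cy
  ix <- floor(sx) + 1L
  iy <- floor(sy) + 1L
  ok <- ix >= 1L & ix <= w & iy >= 1L & iy <= h
  dest <- matrix(fill_value, h, w)
  dest_idx <- cbind(rep(seq_len(h), times = w)[ok],
                    rep(seq_len(w), each = h)[ok])
  dest[dest_idx] <- image[cbind(iy[ok], ix[ok])]
  dest
}

#' Apply online augmentation
#'
#' @param image numeric matrix.
#' @param params augmentation draw from [sample_augment_params()]; when
#'   `NULL` a fresh draw is taken from the current RNG stream.
#' @param fill_value intensity for pixels rotated in from outside.
#' @return augmented image.
#' @export
augment <- function(image, params = NULL, fill_value = 0) {
  if (is.null(params)) params <- sample_augment_params()
  if (isTRUE(params$flip)) image <- image[, rev(seq_len(ncol(image))), drop = FALSE]
  rotate_image(image, params$angle, fill_value)
}

#' Bilinear image resize
#'
#' @param image numeric matrix.
#' @param out_h,out_w output size in pixels.
#' @return `out_h x out_w` matrix.
#' @export
resize_bilinear <- function(image, out_h, out_w) {
  h <- nrow(image); w <- ncol(image)
  if (h == out_h && w == out_w) return(image)
  # map destination pixel centers to source coordinates
  sx <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  sy <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  x0 <- pmin(pmax(floor(sx), 0), w - 1L); x1 <- pmin(x0 + 1L, w - 1L)
  y0 <- pmin(pmax(floor(sy), 0), h - 1L); y1 <- pmin(y0 + 1L, h - 1L)
  fx <- pmin(pmax(sx - x0, 0), 1); fy <- pmin(pmax(sy - y0, 0), 1)
  A <- image[y0 + 1L, x0 + 1L, drop = FALSE]
  B <- image[y0 + 1L, x1 + 1L, drop = FALSE]
  C <- image[y1 + 1L, x0 + 1L, drop = FALSE]
  D <- image[y1 + 1L, x1 + 1L, drop = FALSE]
  FX <- matrix(fx, out_h, out_w, byrow = TRUE)
  FY <- matrix(fy, out_h, out_w)
  A * (1 - FX) * (1 - FY) + B * FX * (1 - FY) +
    C * (1 - FX) * FY + D * FX * FY
}

#' Resize and normalize an image for the classifier
#'
#' @param image numeric matrix.
#' @param input_size target side length in pixels.
#' @param norm_mean,norm_sd normalization constants; output is
#'   `(x - norm_mean) / norm_sd`.
#' @return `input_size x input_size` normalized matrix.
#' @export
preprocess <- function(image, input_size, norm_mean = 0.5, norm_sd = 0.5) {
  stopifnot(input_size >= 1)
  if (norm_sd == 0) stop("norm_sd must be non-zero")
  (resize_bilinear(image, input_size, input_size) - norm_mean) / norm_sd
}

.branch_defaults <- function() list(
  od_gs = list(region = "od_roi", targets = "gs",
               loss = "softmax2", lr_init = 1e-3),
  mac_erm_amd = list(region = "macula_roi", targets = c("erm", "amd"),
                     loss = "bce", lr_init = 1e-3),
  full_dr_rb_rvo = list(region = "full", targets = c("dr", "rb", "rvo"),
                        loss = "bce", lr_init = 1e-4),
  baseline_full6 = list(region = "full", targets = disease_names(),
                        loss = "bce", lr_init = 1e-4)
)

#' Branch configuration
#'
#' Defaults follow the published schedule: Adam, batch size 8, learning
#' rate 1e-3 for the two ROI branches and 1e-4 for the whole-image
#' branches, halved every 10 epochs, 60 epochs. Tests and the smoke
#' profile reduce `epochs`, never the schedule shape.
#'
#' @param branch_id one of `od_gs`, `mac_erm_amd`, `full_dr_rb_rvo`,
#'   `baseline_full6`.
#' @param backbone a name from [backbone_registry()].
#' @param input_size classifier input side length in pixels.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param lr_init initial learning rate (branch-dependent default).
#' @param lr_decay multiplicative decay factor.
#' @param lr_decay_every epochs between decays.
#' @param seed RNG seed controlling init, shuffling and augmentation.
#' @param augment apply online augmentation during training?
#' @return object of class `branch_config`.
#' @export
branch_config <- function(branch_id,
                          backbone = "tiny_mlp",
                          input_size = 48L,
                          batch_size = 8L,
                          epochs = 60L,
                          lr_init = NULL,
                          lr_decay = 0.5,
                          lr_decay_every = 10L,
                          seed = 1L,
                          augment = TRUE) {
  def <- .branch_defaults()[[branch_id]]
  if (is.null(def)) {
    stop("unknown branch_id: ", branch_id, " (expected one of ",
         paste(names(.branch_defaults()), collapse = ", "), ")")
  }
  if (!backbone %in% backbone_registry()) {
    stop("unregistered backbone: ", backbone)
  }
  lr <- if (is.null(lr_init)) def$lr_init else lr_init
  stopifnot(lr > 0, batch_size >= 1, epochs >= 1, input_size >= 4)
  structure(list(branch_id = branch_id, region = def$region,
                 targets = def$targets, loss = def$loss,
                 backbone = backbone, input_size = as.integer(input_size),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_init = lr,
                 lr_decay = lr_decay,
                 lr_decay_every = as.integer(lr_decay_every),
                 seed = as.integer(seed), augment = isTRUE(augment)),
            class = "branch_config")
}

#' Epoch of the best mean validation AUC
#'
#' Model selection rule: the checkpoint restored after training is the
#' one from the epoch maximizing the mean validation AUC over the
#' branch's targets; the earliest epoch wins ties.
#'
#' @param mean_auc numeric vector, one value per epoch.
#' @return integer epoch index.
#' @export
select_best_epoch <- function(mean_auc) {
  stopifnot(length(mean_auc) >= 1L, !anyNA(mean_auc))
  which.max(mean_auc)
}

# images: list of matrices; returns n x p design matrix
.design_matrix <- function(images, input_size, augmented = FALSE) {
  t(vapply(images, function(im) {
    if (augmented) im <- augment(im)
    as.numeric(preprocess(im, input_size))
  }, numeric(input_size^2)))
}

#' Train one classification branch
#'
#' `train` and `val` are lists with `images` (list of numeric matrices,
#' already cropped to the branch's region) and `labels` (`n x 6` 0/1
#' matrix with columns [disease_names()]). Optimization is Adam on the
#' branch loss (two-class softmax cross-entropy for `od_gs`, element-wise
#' sigmoid binary cross-entropy otherwise) with online augmentation drawn
#' fresh for every batch; after the final epoch the parameters from the
#' epoch of highest mean validation AUC are restored. Fully deterministic
#' given `config$seed`.
#'
#' @param train,val datasets as described above; every target must have
#'   at least one positive and one negative image in `val`.
#' @param config a [branch_config()].
#' @param val_metric_fn optional override used for model-selection tests:
#'   function `(epoch, params) -> per-target AUC vector` replacing the
#'   real validation pass.
#' @return object of class `branch_fit`: list with `params`, `config`,
#'   `best_epoch` and a per-epoch `history` data frame (epoch, lr,
#'   train_loss, one `val_auc_*` column per target, mean_val_auc).
#' @export
train_branch <- function(train, val, config, val_metric_fn = NULL) {
  stopifnot(inherits(config, "branch_config"),
            length(train$images) >= 1L, length(val$images) >= 1L)
  targets <- config$targets
  Ytr <- train$labels[, targets, drop = FALSE]
  Yva <- val$labels[, targets, drop = FALSE]
  if (is.null(val_metric_fn)) {
    pos <- colSums(Yva); neg <- nrow(Yva) - pos
    if (any(pos == 0L) || any(neg == 0L)) {
      bad <- targets[pos == 0L | neg == 0L]
      stop("degenerate validation split: target(s) ",
           paste(bad, collapse = ", "),
           " lack both a positive and a negative image")
    }
  }

  set.seed(config$seed)
  n_out <- if (config$loss == "softmax2") 2L else length(targets)
  params <- .net_init(config$backbone, config$input_size^2, n_out)
  opt <- .adam_init(params)
  Xva <- .design_matrix(val$images, config$input_size)

  n <- length(train$images)
  hist_rows <- vector("list", config$epochs)
  best_auc <- -Inf; best_epoch <- NA_integer_; best_params <- params
  for (epoch in seq_len(config$epochs)) {
    lr <- config$lr_init *
      config$lr_decay^((epoch - 1L) %/% config$lr_decay_every)
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      X <- .design_matrix(train$images[idx], config$input_size,
                          augmented = config$augment)
      fwd <- .net_forward(params, X)
      ls <- if (config$loss == "softmax2") {
        .loss_softmax2(fwd$logits, Ytr[idx, 1L])
      } else {
        .loss_bce_logits(fwd$logits, Ytr[idx, , drop = FALSE])
      }
      grads <- .net_backward(params, fwd, ls$grad)
      stepped <- .adam_step(params, grads, opt, lr)
      params <- stepped$params; opt <- stepped$state
      losses <- c(losses, ls$value)
    }
    aucs <- if (!is.null(val_metric_fn)) {
      val_metric_fn(epoch, params)
    } else {
      logits <- .net_forward(params, Xva)$logits
      scores <- if (config$loss == "softmax2") {
        matrix(softmax2_prob(logits), ncol = 1L)
      } else {
        sigmoid(logits)
      }
      vapply(seq_along(targets), function(j) {
        auc(scores[, j], Yva[, j])
      }, numeric(1L))
    }
    mean_auc <- mean(aucs)
    if (mean_auc > best_auc) {
      best_auc <- mean_auc; best_epoch <- epoch; best_params <- params
    }
    row <- data.frame(epoch = epoch, lr = lr, train_loss = mean(losses))
    for (j in seq_along(targets)) row[[paste0("val_auc_", targets[j])]] <- aucs[j]
    row$mean_val_auc <- mean_auc
    hist_rows[[epoch]] <- row
  }
  history <- do.call(rbind, hist_rows)
  stopifnot(identical(best_epoch, select_best_epoch(history$mean_val_auc)))
  structure(list(params = best_params, config = config,
                 best_epoch = best_epoch, history = history),
            class = "branch_fit")
}

#' Predict branch outputs
#'
#' @param fit a `branch_fit`.
#' @param images list of region crops matching the branch's region.
#' @return for a softmax branch an `n x 2` logit matrix; otherwise an
#'   `n x k` logit matrix with target column names.
#' @export
predict_branch <- function(fit, images) {
  X <- .design_matrix(images, fit$config$input_size)
  logits <- .net_forward(fit$params, X)$logits
  if (fit$config$loss != "softmax2") colnames(logits) <- fit$config$targets
  logits
}

#' Assemble the six-disease probability vector
#'
#' Combines the three branch outputs into canonical order: the glaucoma
#' probability is the two-class softmax score of the disease class; the
#' other five are element-wise sigmoid of their logits.
#'
#' @param outputs list with `od_gs` (`n x 2` logits), `mac_erm_amd`
#'   (`n x 2` logits, columns erm/amd) and `full_dr_rb_rvo` (`n x 3`
#'   logits, columns dr/rb/rvo).
#' @return `n x 6` probability matrix, columns [disease_names()].
#' @export
predict_assemble <- function(outputs) {
  need <- c("od_gs", "mac_erm_amd", "full_dr_rb_rvo")
  missing <- setdiff(need, names(outputs))
  if (length(missing)) {
    stop("missing branch output(s): ", paste(missing, collapse = ", "))
  }
  gs <- softmax2_prob(outputs$od_gs)
  mac <- sigmoid(outputs$mac_erm_amd)
  full <- sigmoid(outputs$full_dr_rb_rvo)
  probs <- cbind(full[, 1L], full[, 2L], full[, 3L],
                 mac[, 1L], mac[, 2L], gs)
  colnames(probs) <- disease_names()
  probs
}

#' Stratified train/validation split
#'
#' Greedy iterative stratification for multi-label data: images are
#' assigned so that each disease's positives split close to `ratio`
#' (the published split is approximately 9:1 per class). Images with no
#' positive label are distributed afterwards to preserve the overall
#' ratio. The two index sets are disjoint and exhaustive.
#'
#' @param labels `n x 6` 0/1 matrix, columns [disease_names()].
#' @param ratio training fraction in `(0, 1)`.
#' @param seed RNG seed for order shuffling and tie breaks.
#' @return list with integer index vectors `train` and `val`.
#' @export
split_dataset <- function(labels, ratio = 0.9, seed = 1L) {
  stopifnot(is.matrix(labels), ncol(labels) == 6L, ratio > 0, ratio < 1)
  colnames(labels) <- disease_names()
  pos_total <- colSums(labels)
  low <- pos_total[pos_total >= 1L & pos_total < 2L]
  if (length(low)) {
    stop("cannot stratify: class(es) with fewer than 2 positives: ",
         paste(names(low), collapse = ", "))
  }
  n <- nrow(labels)
  set.seed(seed)
  order_shuffled <- sample.int(n)

  # remaining desired positives per subset per class
  desire <- rbind(train = pos_total * ratio, val = pos_total * (1 - ratio))
  cap <- c(train = n * ratio, val = n * (1 - ratio))
  assign_to <- rep(NA_character_, n)
  remaining <- rep(TRUE, n)

  repeat {
    left <- colSums(labels[remaining, , drop = FALSE])
    active <- which(left > 0L)
    if (!length(active)) break
    cls <- active[which.min(left[active])]
    for (i in order_shuffled) {
      if (!remaining[i] || labels[i, cls] != 1L) next
      pick <- if (desire["train", cls] > desire["val", cls]) {
        "train"
      } else if (desire["val", cls] > desire["train", cls]) {
        "val"
      } else if (cap["train"] >= cap["val"]) "train" else "val"
      assign_to[i] <- pick
      remaining[i] <- FALSE
      desire[pick, ] <- desire[pick, ] - labels[i, ]
      cap[pick] <- cap[pick] - 1
    }
  }
  for (i in order_shuffled) {
    if (!remaining[i]) next
    pick <- if (cap["train"] >= cap["val"]) "train" else "val"
    assign_to[i] <- pick
    remaining[i] <- FALSE
    cap[pick] <- cap[pick] - 1
  }
  list(train = sort(which(assign_to == "train")),
       val = sort(which(assign_to == "val")))
}
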