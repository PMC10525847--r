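test_that("label routing partitions and reconstructs all 64 vectors", {
  for (code in 0:63) {
    lab <- as.integer(intToBits(code)[1:6])
    parts <- partition_labels(lab)
    expect_identical(unname(parts$gs), lab[6])
    expect_identical(unname(parts$mac), lab[4:5])
    expect_identical(unname(parts$full), lab[1:3])
    expect_identical(unname(combine_partitions(parts)), lab)
  }
})

test_that("augmentation draws match their stated distributions", {
  set.seed(77)
  n <- 10000L
  draws <- replicate(n, sample_augment_params(), simplify = FALSE)
  flips <- sum(vapply(draws, `[[`, logical(1), "flip"))
  # exact binomial 99% interval around p = 0.5
  expect_gte(flips, qbinom(0.005, n, 0.5))
  expect_lte(flips, qbinom(0.995, n, 0.5))
  angles <- vapply(draws, `[[`, numeric(1), "angle")
  ks <- suppressWarnings(ks.test(angles, "punif", -180, 180))
  expect_gt(ks$p.value, 0.01)
})

test_that("augmentation transforms behave at the identity and flip paths", {
  set.seed(5)
  img <- matrix(runif(64), 8, 8)
  expect_identical(augment(img, list(flip = FALSE, angle = 0)), img)
  flipped <- augment(img, list(flip = TRUE, angle = 0))
  expect_equal(flipped, img[, 8:1])
  # rotation by 90 degrees preserves content up to the grid mapping
  rot <- rotate_image(img, 90)
  expect_identical(dim(rot), dim(img))
  expect_equal(sort(as.numeric(rot)), sort(as.numeric(img)))
  # full turn restores the image
  expect_equal(rotate_image(img, 360), img, tolerance = 1e-12)
})

test_that("preprocess resizes and normalizes", {
  img <- matrix(runif(64 * 64), 64, 64)
  out <- preprocess(img, 128, norm_mean = 0, norm_sd = 1)
  expect_identical(dim(out), c(128L, 128L))
  # identity normalization preserves values at the same resolution
  expect_equal(preprocess(img, 64, 0, 1), img)
  # constant image at its own mean maps to zero
  expect_equal(preprocess(matrix(0.37, 10, 10), 16, 0.37, 1),
               matrix(0, 16, 16))
  expect_error(preprocess(img, 32, 0.5, 0), "norm_sd")
})

test_that("branch losses match hand-computed closed forms", {
  # sigmoid BCE on fixed logits/targets
  z <- matrix(c(0, 1, -2, 3), 2, 2)
  y <- matrix(c(1, 0, 1, 1), 2, 2)
  manual <- mean(-(y * log(1 / (1 + exp(-z))) +
                     (1 - y) * log(1 - 1 / (1 + exp(-z)))))
  got <- fundusroi:::.loss_bce_logits(z, y)
  expect_equal(got$value, manual, tolerance = 1e-6)
  expect_equal(got$grad, (1 / (1 + exp(-z)) - y) / 4, tolerance = 1e-12)

  # two-class softmax cross-entropy
  z2 <- rbind(c(1, 3), c(0, 0))
  y2 <- c(1, 0)
  manual2 <- mean(c(-log(exp(3) / (exp(1) + exp(3))), -log(0.5)))
  got2 <- fundusroi:::.loss_softmax2(z2, y2)
  expect_equal(got2$value, manual2, tolerance = 1e-9)

  # probability mapping: logits (1, 3) -> e^3 / (e^1 + e^3)
  expect_equal(softmax2_prob(rbind(c(1, 3))),
               exp(3) / (exp(1) + exp(3)), tolerance = 1e-9)
  expect_equal(softmax2_prob(rbind(c(0, 0))), 0.5)
})

test_that("assembled prediction vectors sit in canonical order", {
  out <- list(od_gs = rbind(c(0, 0)),
              mac_erm_amd = rbind(c(0.3, -0.3)),
              full_dr_rb_rvo = rbind(c(0, 2, -2)))
  p <- predict_assemble(out)
  expect_identical(colnames(p), disease_names())
  expect_equal(unname(p[1, "gs"]), 0.5)
  expect_equal(unname(p[1, "dr"]), 0.5)
  expect_equal(unname(p[1, "rb"]), 1 / (1 + exp(-2)))
  expect_equal(unname(p[1, "erm"]), 1 / (1 + exp(-0.3)))
  out$od_gs <- NULL
  expect_error(predict_assemble(out), "missing branch")
})

test_that("the stratified split hits per-class ratios", {
  # 100 single-label images per class -> exactly 90/10 each
  labels <- matrix(0L, 600, 6)
  for (j in 1:6) labels[((j - 1) * 100 + 1):(j * 100), j] <- 1L
  sp <- split_dataset(labels, 0.9, seed = 1)
  expect_identical(sort(c(sp$train, sp$val)), 1:600) # disjoint, exhaustive
  expect_identical(length(intersect(sp$train, sp$val)), 0L)
  for (j in 1:6) {
    expect_identical(sum(labels[sp$train, j]), 90L)
    expect_identical(sum(labels[sp$val, j]), 10L)
  }

  # multi-label set of 200 images: every class's val share in [5%, 15%]
  set.seed(2)
  ml <- matrix(rbinom(200 * 6, 1, 0.3), 200, 6)
  sp <- split_dataset(ml, 0.9, seed = 3)
  expect_identical(sort(c(sp$train, sp$val)), 1:200)
  share <- colSums(ml[sp$val, , drop = FALSE]) / colSums(ml)
  expect_true(all(share >= 0.05 & share <= 0.15))

  # a class with a single positive cannot be stratified
  bad <- matrix(0L, 20, 6); bad[1, 1] <- 1L; bad[, 2] <- 1L
  bad[1:2, 3] <- 1L
  expect_error(split_dataset(bad, 0.9, 1), "fewer than 2 positives")
})

test_that("training overfits a tiny batch and restores the best epoch", {
  toy <- toy_branch_data(8, seed = 9)
  cfg <- branch_config("mac_erm_amd", input_size = 12, epochs = 25,
                       batch_size = 8, seed = 1, augment = FALSE)
  fit <- train_branch(toy, toy, cfg)
  expect_lt(fit$history$train_loss[25], fit$history$train_loss[1])
  expect_identical(fit$best_epoch,
                   select_best_epoch(fit$history$mean_val_auc))

  # determinism: identical seed, identical history and parameters
  fit2 <- train_branch(toy, toy, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params, fit2$params)
})

test_that("model selection restores the checkpoint of the injected peak epoch", {
  toy <- toy_branch_data(12, seed = 3)
  fake_auc <- c(0.5, 0.6, 0.9, 0.7, 0.65) # peak at epoch 3
  inject <- function(epoch, params) fake_auc[epoch]
  cfg5 <- branch_config("od_gs", input_size = 12, epochs = 5,
                        batch_size = 4, seed = 11)
  fit <- train_branch(toy, toy, cfg5, val_metric_fn = inject)
  expect_identical(fit$best_epoch, 3L)

  # the restored parameters equal those of an identical run stopped at
  # the peak epoch (same seed -> same batch and augmentation stream)
  cfg3 <- branch_config("od_gs", input_size = 12, epochs = 3,
                        batch_size = 4, seed = 11)
  # increasing metric -> the truncated run keeps its final epoch
  fit3 <- train_branch(toy, toy, cfg3, val_metric_fn = function(e, p) e / 10)
  expect_equal(fit$params, fit3$params, tolerance = 1e-12)
})

test_that("degenerate validation classes are rejected before training", {
  toy <- toy_branch_data(8, seed = 9)
  val <- toy
  val$labels[, "erm"] <- 1L # all-positive target
  cfg <- branch_config("mac_erm_amd", input_size = 12, epochs = 2, seed = 1)
  expect_error(train_branch(toy, val, cfg), "degenerate validation.*erm")
})

test_that("learning-rate schedule halves every decay period", {
  toy <- toy_branch_data(6, seed = 2)
  cfg <- branch_config("od_gs", input_size = 12, epochs = 12, batch_size = 6,
                       seed = 1, lr_decay_every = 5L, augment = FALSE)
  fit <- train_branch(toy, toy, cfg)
  expect_equal(fit$history$lr[1:5], rep(1e-3, 5))
  expect_equal(fit$history$lr[6:10], rep(5e-4, 5))
  expect_equal(fit$history$lr[11:12], rep(2.5e-4, 2))
})
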