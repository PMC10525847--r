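# End-to-end orchestration and ablation harnesses.
#
# run_end_to_end() executes generate -> detect -> extract ROIs -> split
# -> train branches -> tune thresholds on validation -> evaluate, with
# every stage seeded from the configuration so re-running reproduces the
# report byte for byte. The ablation harnesses mirror the published
# experiment design: an ROI-edge sweep including an "Entire UFI" row,
# and a per-group backbone comparison selecting the argmax of the group
# mean AUC.

#' Pipeline configuration
#'
#' @param synth a [synthetic_config()] describing the dataset.
#' @param n_images number of scenes to generate.
#' @param detector detector name for [get_detector()].
#' @param jitter_sd detector jitter in pixels (0 = exact oracle).
#' @param detector_cfg a [detector_config()].
#' @param roi a [roi_config()].
#' @param branches named list of [branch_config()]s for `od_gs`,
#'   `mac_erm_amd` and `full_dr_rb_rvo`; missing entries get defaults
#'   with `epochs`/`input_size` from `...` untouched.
#' @param include_baseline also train the whole-image six-label baseline?
#' @param split_ratio training fraction (default 0.9).
#' @param n_runs number of repeated runs (the published protocol uses 5).
#' @param seeds integer vector, one seed per run (length >= `n_runs`).
#' @param epochs training epochs applied to default branch configs.
#' @param workdir optional directory for reports, logs and (optionally)
#'   the rendered dataset.
#' @param write_images write the dataset as PNGs under `workdir`?
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synthetic_config(),
                            n_images = 200L,
                            detector = "oracle",
                            jitter_sd = 0,
                            detector_cfg = detector_config(),
                            roi = roi_config(),
                            branches = NULL,
                            include_baseline = FALSE,
                            split_ratio = 0.9,
                            n_runs = 1L,
                            seeds = seq_len(n_runs),
                            epochs = 5L,
                            workdir = NULL,
                            write_images = FALSE) {
  stopifnot(n_images >= 1, split_ratio > 0, split_ratio < 1, n_runs >= 1)
  if (length(seeds) < n_runs) stop("need at least n_runs seeds")
  ids <- c("od_gs", "mac_erm_amd", "full_dr_rb_rvo")
  br <- list()
  for (id in ids) {
    br[[id]] <- if (!is.null(branches[[id]])) {
      branches[[id]]
    } else {
      branch_config(id, epochs = epochs)
    }
  }
  if (include_baseline) {
    br[["baseline_full6"]] <- if (!is.null(branches[["baseline_full6"]])) {
      branches[["baseline_full6"]]
    } else {
      branch_config("baseline_full6", epochs = epochs)
    }
  }
  structure(list(synth = synth, n_images = as.integer(n_images),
                 detector = detector, jitter_sd = jitter_sd,
                 detector_cfg = detector_cfg, roi = roi,
                 branches = br, include_baseline = include_baseline,
                 split_ratio = split_ratio, n_runs = as.integer(n_runs),
                 seeds = as.integer(seeds), workdir = workdir,
                 write_images = write_images),
            class = "pipeline_config")
}

.log_stage <- function(log, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  if (!is.null(log)) cat(line, "\n", file = log, sep = "", append = TRUE)
  invisible(line)
}

# render scenes, detect landmarks, extract region sets; the shared
# front-end of the pipeline and the ablation harnesses
.prepare_regions <- function(config, log = NULL) {
  .log_stage(log, "generate", sprintf("rendering %d scenes (seed %d)",
                                      config$n_images, config$synth$seed))
  scenes <- generate_scenes(config$synth, config$n_images)
  if (config$write_images && !is.null(config$workdir)) {
    generate_dataset(config$synth, config$n_images,
                     file.path(config$workdir, "dataset"), overwrite = TRUE)
  }
  detector <- get_detector(config$detector, config$jitter_sd)
  set.seed(config$synth$seed + 1L) # detector jitter stream
  labels <- do.call(rbind, lapply(scenes, `[[`, "labels"))
  rois <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    dets <- filter_proposals(detector(scenes[[i]]),
                             config$synth$image_size,
                             config$synth$image_size,
                             config$detector_cfg)
    lm <- select_landmarks(dets)
    rois[[i]] <- make_rois(scenes[[i]]$image, lm, config$roi)
  }
  .log_stage(log, "detect",
             sprintf("landmarks + ROIs extracted for %d images",
                     length(scenes)))
  list(scenes = scenes, labels = labels, rois = rois)
}

.region_images <- function(rois, region) lapply(rois, `[[`, region)

# train every configured branch on one split and evaluate on validation
.run_once <- function(prep, config, seed, log = NULL) {
  split <- split_dataset(prep$labels, config$split_ratio, seed)
  .log_stage(log, "split", sprintf(
    "seed %d: %d train / %d val", seed, length(split$train),
    length(split$val)))
  fits <- list()
  for (id in names(config$branches)) {
    bc <- config$branches[[id]]
    bc$seed <- seed
    region <- bc$region
    fits[[id]] <- train_branch(
      train = list(images = .region_images(prep$rois[split$train], region),
                   labels = prep$labels[split$train, , drop = FALSE]),
      val = list(images = .region_images(prep$rois[split$val], region),
                 labels = prep$labels[split$val, , drop = FALSE]),
      config = bc)
    .log_stage(log, "train", sprintf(
      "%s: best epoch %d (mean val AUC %.4f)", id, fits[[id]]$best_epoch,
      max(fits[[id]]$history$mean_val_auc)))
  }
  val_labels <- prep$labels[split$val, , drop = FALSE]
  outputs <- list(
    od_gs = predict_branch(fits$od_gs,
                           .region_images(prep$rois[split$val], "od_roi")),
    mac_erm_amd = predict_branch(
      fits$mac_erm_amd, .region_images(prep$rois[split$val], "macula_roi")),
    full_dr_rb_rvo = predict_branch(
      fits$full_dr_rb_rvo, .region_images(prep$rois[split$val], "full")))
  probs <- predict_assemble(outputs)
  thresholds <- tune_thresholds(probs, val_labels)
  report <- metrics_report(probs, val_labels, thresholds)
  .log_stage(log, "evaluate", sprintf(
    "seed %d: micro accuracy %.4f", seed, report$micro$micro_accuracy))
  out <- list(seed = seed, split = split, fits = fits, probs = probs,
              labels = val_labels, thresholds = thresholds, report = report)
  if (config$include_baseline) {
    base_probs <- sigmoid(predict_branch(
      fits$baseline_full6, .region_images(prep$rois[split$val], "full")))
    colnames(base_probs) <- disease_names()
    base_thr <- tune_thresholds(base_probs, val_labels)
    out$baseline <- list(
      probs = base_probs,
      report = metrics_report(base_probs, val_labels, base_thr))
  }
  out
}

#' Run the full pipeline
#'
#' Executes every stage from data generation to evaluation, `n_runs`
#' times with the configured seeds, and aggregates per-metric repeated-run
#' 95% confidence intervals when `n_runs >= 2`. When `config$workdir` is
#' set, writes `report.json`, `per_class.csv`, `thresholds.csv` and a
#' stage-tagged `pipeline.log`; re-running with the same configuration
#' reproduces those files byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_result`: list with `runs` (per-run
#'   results incl. a [metrics_report()] each), `summary` (data frame
#'   metric/class/mean/half_width) and `config`.
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- NULL
  if (!is.null(config$workdir)) {
    dir.create(config$workdir, recursive = TRUE, showWarnings = FALSE)
    log <- file.path(config$workdir, "pipeline.log")
    cat("", file = log) # truncate
  }
  prep <- .prepare_regions(config, log)
  runs <- lapply(config$seeds[seq_len(config$n_runs)], function(s) {
    .run_once(prep, config, s, log)
  })

  # long table of every metric over runs
  collect <- function(run) {
    pc <- run$report$per_class
    rows <- do.call(rbind, lapply(seq_len(nrow(pc)), function(j) {
      data.frame(class = pc$class[j],
                 metric = c("auc", "accuracy", "sensitivity", "specificity"),
                 value = as.numeric(pc[j, c("auc", "accuracy",
                                            "sensitivity", "specificity")]),
                 stringsAsFactors = FALSE)
    }))
    rbind(rows,
          data.frame(class = "micro",
                     metric = c("accuracy", "sensitivity", "specificity"),
                     value = as.numeric(run$report$micro),
                     stringsAsFactors = FALSE),
          data.frame(class = "normal",
                     metric = c("accuracy", "sensitivity", "specificity"),
                     value = as.numeric(run$report$normal),
                     stringsAsFactors = FALSE))
  }
  longs <- lapply(runs, collect)
  key <- paste(longs[[1]]$class, longs[[1]]$metric, sep = ".")
  summary <- data.frame(class = longs[[1]]$class, metric = longs[[1]]$metric,
                        stringsAsFactors = FALSE)
  vals <- sapply(longs, `[[`, "value")
  vals <- matrix(vals, nrow = length(key))
  summary$mean <- rowMeans(vals)
  summary$half_width <- if (config$n_runs >= 2L) {
    apply(vals, 1L, function(v) run_ci(v)$half_width)
  } else {
    NA_real_
  }
  result <- structure(list(runs = runs, summary = summary, config = config),
                      class = "pipeline_result")
  if (!is.null(config$workdir)) {
    utils::write.csv(summary, file.path(config$workdir, "per_class.csv"),
                     row.names = FALSE)
    thr <- do.call(rbind, lapply(runs, function(r) {
      as.data.frame(as.list(r$thresholds))
    }))
    thr <- cbind(seed = config$seeds[seq_len(config$n_runs)], thr)
    utils::write.csv(thr, file.path(config$workdir, "thresholds.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(n_runs = config$n_runs,
           seeds = config$seeds[seq_len(config$n_runs)],
           summary = summary),
      file.path(config$workdir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    .log_stage(log, "report", "written report.json / per_class.csv")
  }
  result
}

#' ROI-size ablation sweep
#'
#' Retrains the affected branch identically except for the ROI edge
#' multiplier, over a list of multipliers that may include the sentinel
#' `"entire"` (whole-image input, the ablation comparator row). Emits one
#' row per multiplier with the branch's per-target validation AUC,
#' averaged over runs.
#'
#' @param config a [pipeline_config()].
#' @param multipliers numeric vector, optionally with the string
#'   `"entire"` appended (accepts a list).
#' @param branch `"mac_erm_amd"` (sweeps beta) or `"od_gs"` (sweeps alpha).
#' @return data frame: `multiplier`, one AUC column per target, `average`.
#' @export
ablate_roi_size <- function(config, multipliers, branch = "mac_erm_amd") {
  stopifnot(branch %in% c("mac_erm_amd", "od_gs"), length(multipliers) >= 1)
  bc0 <- config$branches[[branch]]
  targets <- bc0$targets
  prep0 <- .prepare_regions(config)
  rows <- lapply(multipliers, function(m) {
    entire <- identical(m, "entire")
    res <- tryCatch({
      cfg <- config
      if (!entire) {
        m <- as.numeric(m)
        if (branch == "mac_erm_amd") cfg$roi$beta <- m else cfg$roi$alpha <- m
        prep <- .prepare_regions(cfg)
        region <- bc0$region
      } else {
        prep <- prep0
        region <- "full"
      }
      aucs <- matrix(NA_real_, config$n_runs, length(targets))
      for (r in seq_len(config$n_runs)) {
        seed <- config$seeds[r]
        split <- split_dataset(prep$labels, config$split_ratio, seed)
        bc <- bc0
        bc$seed <- seed
        bc$region <- region
        fit <- train_branch(
          train = list(images = .region_images(prep$rois[split$train], region),
                       labels = prep$labels[split$train, , drop = FALSE]),
          val = list(images = .region_images(prep$rois[split$val], region),
                     labels = prep$labels[split$val, , drop = FALSE]),
          config = bc)
        logits <- predict_branch(
          fit, .region_images(prep$rois[split$val], region))
        scores <- if (bc$loss == "softmax2") {
          matrix(softmax2_prob(logits), ncol = 1L)
        } else {
          sigmoid(logits)
        }
        aucs[r, ] <- vapply(seq_along(targets), function(j) {
          auc(scores[, j], prep$labels[split$val, targets[j]])
        }, numeric(1L))
      }
      colMeans(aucs)
    }, error = function(e) {
      warning("sweep cell '", format(m), "' failed: ", conditionMessage(e))
      rep(NA_real_, length(targets))
    })
    row <- data.frame(multiplier = if (entire) "entire" else format(m),
                      stringsAsFactors = FALSE)
    for (j in seq_along(targets)) row[[paste0("auc_", targets[j])]] <- res[j]
    row$average <- mean(res)
    row
  })
  do.call(rbind, rows)
}

#' Backbone comparison harness
#'
#' Trains one branch per registered backbone identifier and reports the
#' per-target validation AUC and the group mean; the backbone with the
#' highest group mean is flagged as selected.
#'
#' @param config a [pipeline_config()].
#' @param backbones character vector of names from [backbone_registry()]
#'   (length >= 2).
#' @param branch branch id to compare on (default `mac_erm_amd`).
#' @return data frame: `backbone`, per-target AUC columns, `average`,
#'   `selected` flag.
#' @export
compare_backbones <- function(config, backbones, branch = "mac_erm_amd") {
  stopifnot(length(backbones) >= 2L)
  unknown <- setdiff(backbones, backbone_registry())
  if (length(unknown)) {
    stop("unregistered backbone(s): ", paste(unknown, collapse = ", "))
  }
  bc0 <- config$branches[[branch]]
  targets <- bc0$targets
  prep <- .prepare_regions(config)
  rows <- lapply(backbones, function(bk) {
    aucs <- matrix(NA_real_, config$n_runs, length(targets))
    for (r in seq_len(config$n_runs)) {
      seed <- config$seeds[r]
      split <- split_dataset(prep$labels, config$split_ratio, seed)
      bc <- bc0
      bc$seed <- seed
      bc$backbone <- bk
      fit <- train_branch(
        train = list(images = .region_images(prep$rois[split$train], bc$region),
                     labels = prep$labels[split$train, , drop = FALSE]),
        val = list(images = .region_images(prep$rois[split$val], bc$region),
                   labels = prep$labels[split$val, , drop = FALSE]),
        config = bc)
      logits <- predict_branch(
        fit, .region_images(prep$rois[split$val], bc$region))
      scores <- if (bc$loss == "softmax2") {
        matrix(softmax2_prob(logits), ncol = 1L)
      } else {
        sigmoid(logits)
      }
      aucs[r, ] <- vapply(seq_along(targets), function(j) {
        auc(scores[, j], prep$labels[split$val, targets[j]])
      }, numeric(1L))
    }
    row <- data.frame(backbone = bk, stringsAsFactors = FALSE)
    m <- colMeans(aucs)
    for (j in seq_along(targets)) row[[paste0("auc_", targets[j])]] <- m[j]
    row$average <- mean(m)
    row
  })
  out <- do.call(rbind, rows)
  out$selected <- seq_len(nrow(out)) == which.max(out$average)
  out
}
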