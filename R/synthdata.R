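# Synthetic widefield fundus scenes.
#
# The generator emulates the spatial structure the classification method
# exploits: a circular retinal field, a bright optic disc with a central
# cup, a darker macula temporal to the disc, and lesions whose placement
# regime is disease-specific (global scatter, macula-concentrated, or
# peridiscal). Appearance is deliberately minimal: small Gaussian-profile
# blobs, because the downstream pipeline consumes only spatial signal.

#' Canonical disease order
#'
#' The six target diseases in fixed order: diabetic retinopathy (dr),
#' retinal break (rb), retinal vein occlusion (rvo), epiretinal membrane
#' (erm), age-related macular degeneration (amd), glaucoma suspect (gs).
#' "Normal" is the derived all-zero state, not a seventh label.
#'
#' @return character vector of length 6.
#' @export
disease_names <- function() c("dr", "rb", "rvo", "erm", "amd", "gs")

.default_spread <- function() {
  data.frame(
    disease = disease_names(),
    regime  = c("global", "global", "global", "macular", "macular", "peridiscal"),
    radius_d = c(NA, NA, NA, 2.0, 2.0, 1.0),
    stringsAsFactors = FALSE
  )
}

# per-disease blob amplitude and width (fraction of image size)
.lesion_appearance <- function() {
  data.frame(
    disease = disease_names(),
    amplitude = c(-0.30, 0.30, -0.25, 0.22, -0.22, 0.15),
    sigma_frac = c(0.016, 0.016, 0.020, 0.014, 0.014, 0.010),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic fundus generator
#'
#' @param image_size pixels per side of the square canvas.
#' @param field_radius_frac radius of the circular retinal field as a
#'   fraction of half the image side.
#' @param disc_center_frac optic-disc center as `(x, y)` fractions of the
#'   image side (default places the disc nasally, right of center).
#' @param disc_radius_frac optic-disc radius as a fraction of the image side.
#' @param macula_offset_frac macula-center displacement from the disc
#'   center, `(dx, dy)` fractions of the image side (default temporal,
#'   i.e. toward the image center).
#' @param macula_radius_frac macular blob radius fraction.
#' @param prevalence six marginal disease probabilities in `[0, 1]`,
#'   order `disease_names()`. Labels are independent Bernoulli draws.
#' @param lesion_rate mean lesion count per active disease (Poisson).
#' @param spread data frame with columns `disease`, `regime`
#'   (`global` | `macular` | `peridiscal`) and `radius_d` (concentration
#'   radius in units of the optic-disc box diagonal `d`; `NA` for global).
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param seed integer RNG seed used by [generate_dataset()].
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(image_size = 128L,
                             field_radius_frac = 0.95,
                             disc_center_frac = c(0.70, 0.50),
                             disc_radius_frac = 0.05,
                             macula_offset_frac = c(-0.28, 0.0),
                             macula_radius_frac = 0.07,
                             prevalence = rep(0.3, 6L),
                             lesion_rate = 8,
                             spread = .default_spread(),
                             noise_sd = 0.02,
                             seed = 1L) {
  stopifnot(image_size >= 16)
  fracs <- c(field_radius_frac, disc_radius_frac, macula_radius_frac)
  if (any(fracs <= 0) || any(fracs > 1)) {
    stop("all size fractions must lie in (0, 1]")
  }
  if (length(prevalence) != 6L || any(prevalence < 0) || any(prevalence > 1)) {
    stop("prevalence must be six probabilities in [0, 1]")
  }
  if (lesion_rate < 0) stop("lesion_rate must be >= 0")
  stopifnot(is.data.frame(spread),
            all(c("disease", "regime", "radius_d") %in% names(spread)),
            setequal(spread$disease, disease_names()),
            all(spread$regime %in% c("global", "macular", "peridiscal")))
  s <- as.integer(image_size)
  half <- s / 2
  ctr <- disc_center_frac * s
  mac <- ctr + macula_offset_frac * s
  R <- field_radius_frac * half
  inside <- function(p) sqrt((p[1] - half)^2 + (p[2] - half)^2) < R
  if (!inside(ctr) || !inside(mac)) {
    stop("disc center and macula center must both lie inside the retinal field")
  }
  structure(list(
    image_size = s,
    field_radius_frac = field_radius_frac,
    disc_center_frac = disc_center_frac,
    disc_radius_frac = disc_radius_frac,
    macula_offset_frac = macula_offset_frac,
    macula_radius_frac = macula_radius_frac,
    prevalence = as.numeric(prevalence),
    lesion_rate = lesion_rate,
    spread = spread,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Sample a six-disease label vector
#'
#' Independent Bernoulli draws per disease from the current RNG stream.
#' The all-zero vector is the Normal state.
#'
#' @param prevalence six probabilities in `[0, 1]`.
#' @return named integer vector of 0/1 flags in canonical order.
#' @export
sample_label_vector <- function(prevalence) {
  if (length(prevalence) != 6L || any(prevalence < 0) || any(prevalence > 1) ||
      anyNA(prevalence)) {
    stop("prevalence must be six probabilities in [0, 1]")
  }
  stats::setNames(as.integer(stats::runif(6L) < prevalence), disease_names())
}

# additive Gaussian blob over a local window, in place
.add_blob <- function(img, x, y, sigma, amplitude) {
  s <- nrow(img)
  r <- ceiling(3 * sigma)
  xlo <- max(1L, floor(x + 1 - r)); xhi <- min(s, ceiling(x + 1 + r))
  ylo <- max(1L, floor(y + 1 - r)); yhi <- min(s, ceiling(y + 1 + r))
  if (xlo > xhi || ylo > yhi) return(img)
  xs <- xlo:xhi
  ys <- ylo:yhi
  dx2 <- ((xs - 0.5) - x)^2
  dy2 <- ((ys - 0.5) - y)^2
  img[ys, xs] <- img[ys, xs] +
    amplitude * exp(-(outer(dy2, dx2, "+")) / (2 * sigma^2))
  img
}

# sample one lesion center per the disease's regime; all coordinates are
# continuous, 0-based pixel positions
.sample_lesion <- function(regime, radius, field_center, field_radius,
                           anchor) {
  if (regime == "global") {
    r <- field_radius * sqrt(stats::runif(1))
    th <- stats::runif(1, 0, 2 * pi)
    return(field_center + r * c(cos(th), sin(th)))
  }
  # truncated Gaussian around the anchor (macula or disc center)
  sd <- radius / 2.5
  for (i in 1:100) {
    p <- anchor + stats::rnorm(2L, 0, sd)
    if (sqrt(sum((p - anchor)^2)) <= radius) return(p)
  }
  anchor
}

#' Render one synthetic fundus scene
#'
#' Draws the retinal field, optic disc (with cup), macula and, for every
#' active disease, `Poisson(lesion_rate)` lesions placed according to the
#' disease's spatial regime: uniform over the field (dr/rb/rvo-like),
#' truncated Gaussian around the macula center (erm/amd-like), or a
#' peridiscal ring plus a cup-enlargement / ring-brightness perturbation
#' of the disc itself (gs-like). The scene is fully determined by the
#' configuration, the label vector and the RNG state.
#'
#' @param config a [synthetic_config()].
#' @param labels named 0/1 vector in `disease_names()` order.
#' @return an object of class `scene_record`: list with `image` (matrix in
#'   `[0, 1]`), `labels`, `disc_box`, `macula_box` (each
#'   `c(x0, y0, x1, y1)`, 0-based, min-inclusive/max-exclusive),
#'   `lesion_centers` (data frame `disease`, `x`, `y`) and `d_true`
#'   (ground-truth disc-box diagonal in pixels).
#' @export
render_scene <- function(config, labels) {
  stopifnot(inherits(config, "synthetic_config"))
  labels <- as.integer(labels)
  if (length(labels) != 6L || any(!labels %in% c(0L, 1L))) {
    stop("labels must be six 0/1 flags")
  }
  names(labels) <- disease_names()
  s <- config$image_size
  half <- s / 2
  R <- config$field_radius_frac * half

  # pixel-center coordinate grids (0-based continuous)
  xc <- matrix(rep(seq_len(s) - 0.5, each = s), nrow = s)
  yc <- matrix(rep(seq_len(s) - 0.5, times = s), nrow = s)
  r_field <- sqrt((xc - half)^2 + (yc - half)^2)

  img <- matrix(0.02, s, s)
  infield <- r_field <= R
  img[infield] <- 0.50 - 0.20 * (r_field[infield] / R)^2

  disc <- config$disc_center_frac * s
  rd <- config$disc_radius_frac * s
  mac <- disc + config$macula_offset_frac * s
  rm_ <- config$macula_radius_frac * s

  r_disc <- sqrt((xc - disc[1])^2 + (yc - disc[2])^2)
  # bright disc with soft rim
  img <- img + 0.32 / (1 + exp((r_disc - rd) / (0.15 * rd)))
  # central cup: enlarged and brighter under the glaucoma-suspect state,
  # with an extra bright peripapillary ring -- the signal is confined to
  # the disc neighbourhood by construction
  cup_ratio <- if (labels[["gs"]] == 1L) 0.78 else 0.45
  cup_gain <- if (labels[["gs"]] == 1L) 0.22 else 0.12
  img <- img + cup_gain / (1 + exp((r_disc - cup_ratio * rd) / (0.12 * rd)))
  if (labels[["gs"]] == 1L) {
    ring <- r_disc >= 1.05 * rd & r_disc <= 1.7 * rd
    img[ring] <- img[ring] + 0.08
  }
  # darker macula
  r_mac2 <- (xc - mac[1])^2 + (yc - mac[2])^2
  img <- img - 0.18 * exp(-r_mac2 / (2 * rm_^2))

  # ground-truth boxes
  hb <- 1.15 * rd
  disc_box <- c(x0 = disc[1] - hb, y0 = disc[2] - hb,
                x1 = disc[1] + hb, y1 = disc[2] + hb)
  hm <- 1.3 * rm_
  macula_box <- c(x0 = mac[1] - hm, y0 = mac[2] - hm,
                  x1 = mac[1] + hm, y1 = mac[2] + hm)
  d_true <- sqrt(sum((disc_box[c("x1", "y1")] - disc_box[c("x0", "y0")])^2))

  spread <- config$spread
  looks <- .lesion_appearance()
  centers <- list()
  for (dis in disease_names()) {
    if (labels[[dis]] != 1L) next
    n <- stats::rpois(1L, config$lesion_rate)
    if (n == 0L) next
    row <- spread[spread$disease == dis, ]
    look <- looks[looks$disease == dis, ]
    radius <- row$radius_d * d_true
    anchor <- if (identical(row$regime, "peridiscal")) disc else mac
    if (!is.na(radius) && radius > R) {
      warning("concentration radius for '", dis,
              "' exceeds the retinal field; clipping to the field")
      radius <- R
    }
    pts <- t(vapply(seq_len(n), function(i) {
      .sample_lesion(row$regime, radius, c(half, half), R, anchor)
    }, numeric(2L)))
    for (i in seq_len(n)) {
      img <- .add_blob(img, pts[i, 1], pts[i, 2],
                       look$sigma_frac * s, look$amplitude)
    }
    centers[[dis]] <- data.frame(disease = dis, x = pts[, 1], y = pts[, 2],
                                 stringsAsFactors = FALSE)
  }
  lesion_centers <- if (length(centers)) {
    do.call(rbind, c(centers, list(make.row.names = FALSE)))
  } else {
    data.frame(disease = character(0), x = numeric(0), y = numeric(0))
  }

  if (config$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(s * s, 0, config$noise_sd), s, s)
  }
  img <- pmin(pmax(img, 0), 1)

  structure(list(
    image = img,
    labels = labels,
    disc_box = disc_box,
    macula_box = macula_box,
    lesion_centers = lesion_centers,
    d_true = d_true,
    image_path = NA_character_
  ), class = "scene_record")
}

#' Generate a list of scenes in memory
#'
#' Seeds the RNG from `config$seed`, draws `n` label vectors from the
#' configured prevalences and renders each scene. Used by the pipeline
#' and the test-suite; [generate_dataset()] additionally writes files.
#'
#' @param config a [synthetic_config()].
#' @param n number of scenes.
#' @param labels optional `n x 6` 0/1 matrix overriding the label draws.
#' @return list of `scene_record` objects.
#' @export
generate_scenes <- function(config, n, labels = NULL) {
  stopifnot(n >= 1)
  set.seed(config$seed)
  lapply(seq_len(n), function(i) {
    lab <- if (is.null(labels)) {
      sample_label_vector(config$prevalence)
    } else {
      labels[i, ]
    }
    render_scene(config, lab)
  })
}

#' Write a synthetic dataset to disk
#'
#' Renders `n_images` scenes (seeded from `config$seed`), writes each as a
#' grayscale PNG under `out_dir/images/`, and writes `manifest.csv`
#' (columns `image, dr, rb, rvo, erm, amd, gs, disc_x0, disc_y0, disc_x1,
#' disc_y1, mac_x0, mac_y0, mac_x1, mac_y1`), a `lesions.csv` sidecar with
#' every lesion center, and `config.json` recording the full configuration
#' and seed. Two runs with the same configuration produce byte-identical
#' outputs.
#'
#' @param config a [synthetic_config()].
#' @param n_images number of images (>= 1).
#' @param out_dir output directory (created if missing).
#' @param overwrite overwrite an existing manifest? Default `FALSE`.
#' @return path to `manifest.csv`, invisibly.
#' @export
generate_dataset <- function(config, n_images, out_dir, overwrite = FALSE) {
  stopifnot(n_images >= 1)
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite) {
    stop("output manifest already exists: ", manifest_path,
         " (use overwrite = TRUE)")
  }
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir)) stop("cannot create output directory: ", img_dir)

  scenes <- generate_scenes(config, n_images)
  rows <- vector("list", n_images)
  lesions <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    rec <- scenes[[i]]
    rel <- file.path("images", sprintf("img_%05d.png", i))
    write_png(rec$image, file.path(out_dir, rel))
    rows[[i]] <- data.frame(
      image = rel,
      dr = rec$labels[["dr"]], rb = rec$labels[["rb"]],
      rvo = rec$labels[["rvo"]], erm = rec$labels[["erm"]],
      amd = rec$labels[["amd"]], gs = rec$labels[["gs"]],
      disc_x0 = rec$disc_box[["x0"]], disc_y0 = rec$disc_box[["y0"]],
      disc_x1 = rec$disc_box[["x1"]], disc_y1 = rec$disc_box[["y1"]],
      mac_x0 = rec$macula_box[["x0"]], mac_y0 = rec$macula_box[["y0"]],
      mac_x1 = rec$macula_box[["x1"]], mac_y1 = rec$macula_box[["y1"]],
      stringsAsFactors = FALSE
    )
    if (nrow(rec$lesion_centers)) {
      lesions[[i]] <- cbind(image = rel, rec$lesion_centers)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  les <- do.call(rbind, lesions)
  if (is.null(les)) {
    les <- data.frame(image = character(0), disease = character(0),
                      x = numeric(0), y = numeric(0))
  }
  utils::write.csv(les, file.path(out_dir, "lesions.csv"),
                   row.names = FALSE, quote = FALSE)
  sidecar <- unclass(config)
  sidecar$spread <- config$spread
  jsonlite::write_json(sidecar, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest_path)
}

#' Read a dataset manifest
#'
#' @param path path to a `manifest.csv` written by [generate_dataset()].
#' @return data frame with one row per image.
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Rebuild a scene record from a manifest row
#'
#' Loads the PNG and ground-truth boxes; lesion centers are not restored.
#'
#' @param row one-row data frame from [read_manifest()].
#' @param base_dir directory the manifest's image paths are relative to.
#' @return a `scene_record` (without `lesion_centers` detail).
#' @export
load_scene <- function(row, base_dir) {
  stopifnot(nrow(row) == 1L)
  img <- read_png(file.path(base_dir, row$image))
  labs <- stats::setNames(as.integer(row[disease_names()]), disease_names())
  disc_box <- c(x0 = row$disc_x0, y0 = row$disc_y0,
                x1 = row$disc_x1, y1 = row$disc_y1)
  macula_box <- c(x0 = row$mac_x0, y0 = row$mac_y0,
                  x1 = row$mac_x1, y1 = row$mac_y1)
  structure(list(
    image = img, labels = labs, disc_box = disc_box,
    macula_box = macula_box,
    lesion_centers = data.frame(disease = character(0),
                                x = numeric(0), y = numeric(0)),
    d_true = sqrt((row$disc_x1 - row$disc_x0)^2 +
                    (row$disc_y1 - row$disc_y0)^2),
    image_path = row$image
  ), class = "scene_record")
}
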