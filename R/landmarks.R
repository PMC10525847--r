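# Optic-disc and macula localization.
#
# Boxes are axis-aligned pixel rectangles c(x0, y0, x1, y1), continuous,
# 0-based, min-inclusive/max-exclusive. Detections are data frames with
# columns cls ("optic_disc" | "macula"), score in [0, 1] and the four box
# coordinates. The trained two-stage detector of the original method is
# behind an interface; the default implementation is an oracle fed by
# synthetic ground truth, so the downstream geometry and classification
# stages carry the method's substance.

.check_box <- function(b) {
  b <- as.numeric(b)
  if (length(b) != 4L || anyNA(b)) stop("a box is c(x0, y0, x1, y1)")
  if (b[3] <= b[1] || b[4] <= b[2]) {
    stop("degenerate box: need x1 > x0 and y1 > y0")
  }
  names(b) <- c("x0", "y0", "x1", "y1")
  b
}

#' Intersection over union of two boxes
#'
#' @param a,b boxes `c(x0, y0, x1, y1)` with `x1 > x0`, `y1 > y0`.
#' @return overlap ratio in `[0, 1]`; 0 for disjoint boxes.
#' @export
iou <- function(a, b) {
  a <- .check_box(a); b <- .check_box(b)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  unname(inter / union)
}

#' Detector configuration
#'
#' Mirrors the proposal stage of a two-stage detector: number of anchor
#' shapes per feature-map location, the proposal cap, and the IoU level
#' above which overlapping proposals are eliminated.
#'
#' @param anchors_per_location anchor shapes per location (default 9).
#' @param max_proposals proposal cap after filtering (default 256).
#' @param iou_elimination overlap threshold in `(0, 1)` (default 0.7).
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(anchors_per_location = 9L,
                            max_proposals = 256L,
                            iou_elimination = 0.7) {
  stopifnot(anchors_per_location >= 1, max_proposals >= 1,
            iou_elimination > 0, iou_elimination < 1)
  structure(list(anchors_per_location = as.integer(anchors_per_location),
                 max_proposals = as.integer(max_proposals),
                 iou_elimination = iou_elimination),
            class = "detector_config")
}

#' Build a detection table
#'
#' @param cls character vector, each `"optic_disc"` or `"macula"` (free
#'   class names are allowed for raw proposals).
#' @param score numeric scores in `[0, 1]`.
#' @param boxes matrix or data frame with columns x0, y0, x1, y1.
#' @return data frame with columns `cls`, `score`, `x0`, `y0`, `x1`, `y1`.
#' @export
detections <- function(cls, score, boxes) {
  boxes <- as.data.frame(boxes)
  names(boxes) <- c("x0", "y0", "x1", "y1")
  if (any(score < 0 | score > 1)) stop("scores must lie in [0, 1]")
  for (i in seq_len(nrow(boxes))) .check_box(as.numeric(boxes[i, ]))
  data.frame(cls = as.character(cls), score = as.numeric(score), boxes,
             stringsAsFactors = FALSE)
}

#' Filter region proposals
#'
#' Applies the proposal post-processing contract: proposals crossing the
#' image boundary (any extent outside `[0, W) x [0, H)`) are removed;
#' among overlapping pairs with IoU above `config$iou_elimination` the
#' lower-score proposal is eliminated (greedy non-maximum suppression in
#' descending score order, ties by input order); the survivors are
#' truncated to `config$max_proposals` by score.
#'
#' @param proposals detection data frame (see [detections()]).
#' @param image_w,image_h canvas size in pixels.
#' @param config a [detector_config()].
#' @return filtered detection data frame.
#' @export
filter_proposals <- function(proposals, image_w, image_h,
                             config = detector_config()) {
  if (is.null(proposals) || nrow(proposals) == 0L) return(proposals)
  inb <- proposals$x0 >= 0 & proposals$y0 >= 0 &
    proposals$x1 <= image_w & proposals$y1 <= image_h
  kept <- proposals[inb, , drop = FALSE]
  if (nrow(kept) <= 1L) return(utils::head(kept, config$max_proposals))
  ord <- order(-kept$score)
  keep_idx <- integer(0)
  for (i in ord) {
    bi <- as.numeric(kept[i, c("x0", "y0", "x1", "y1")])
    clash <- any(vapply(keep_idx, function(j) {
      iou(bi, as.numeric(kept[j, c("x0", "y0", "x1", "y1")])) >
        config$iou_elimination
    }, logical(1L)))
    if (!clash) keep_idx <- c(keep_idx, i)
  }
  # keep_idx is in descending-score order; truncate by score, then restore
  # input order
  keep_idx <- utils::head(keep_idx, config$max_proposals)
  out <- kept[sort(keep_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the final optic-disc and macula landmarks
#'
#' There is exactly one optic disc and one macula per image, so per class
#' the single highest-score detection is kept (ties broken by earliest
#' input position). Returns the two box centers and the optic-disc box
#' diagonal `d`, the scale unit for ROI extraction.
#'
#' @param dets detection data frame with at least one `optic_disc` and one
#'   `macula` row.
#' @return object of class `landmarks`: list with `O` (disc center
#'   `c(x, y)`), `M` (macula center) and `d` (disc-box diagonal, pixels).
#' @export
select_landmarks <- function(dets) {
  pick <- function(cls) {
    rows <- dets[dets$cls == cls, , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop("landmark not found: no '", cls, "' detection")
    }
    rows[which.max(rows$score), , drop = FALSE]
  }
  od <- pick("optic_disc")
  mac <- pick("macula")
  center <- function(r) c(x = (r$x0 + r$x1) / 2, y = (r$y0 + r$y1) / 2)
  d <- sqrt((od$x1 - od$x0)^2 + (od$y1 - od$y0)^2)
  structure(list(O = center(od), M = center(mac), d = d,
                 od_box = as.numeric(od[c("x0", "y0", "x1", "y1")]),
                 macula_box = as.numeric(mac[c("x0", "y0", "x1", "y1")])),
            class = "landmarks")
}

#' Oracle detector backed by ground truth
#'
#' Stands in for the trained detector: returns the scene's ground-truth
#' disc and macula boxes with score 1.0, each corner perturbed by
#' independent Gaussian jitter of standard deviation `jitter_sd` pixels
#' (0 gives the exact boxes). Degenerate jittered boxes are re-ordered so
#' `x1 > x0`, `y1 > y0`.
#'
#' @param record a `scene_record` with ground-truth boxes.
#' @param jitter_sd corner jitter standard deviation in pixels.
#' @return detection data frame with one `optic_disc` and one `macula` row.
#' @export
oracle_detect <- function(record, jitter_sd = 0) {
  jit <- function(b) {
    b <- as.numeric(b) + stats::rnorm(4L, 0, jitter_sd)
    c(min(b[1], b[3] - 1e-6), min(b[2], b[4] - 1e-6),
      max(b[3], b[1] + 1e-6), max(b[4], b[2] + 1e-6))
  }
  db <- jit(record$disc_box)
  mb <- jit(record$macula_box)
  detections(cls = c("optic_disc", "macula"),
             score = c(1, 1),
             boxes = rbind(db, mb))
}

#' Look up a detector implementation by name
#'
#' The detector interface maps a scene record to a detection data frame.
#' Only the ground-truth oracle is registered; a trained detector can be
#' added under a new name without touching downstream stages.
#'
#' @param name detector identifier (`"oracle"`).
#' @param jitter_sd jitter passed through to [oracle_detect()].
#' @return function `(record) -> detections`.
#' @export
get_detector <- function(name = "oracle", jitter_sd = 0) {
  switch(name,
         oracle = function(record) oracle_detect(record, jitter_sd),
         stop("unknown detector: ", name))
}

#' Write / read detections as JSON
#'
#' @param dets detection data frame.
#' @param path JSON file path.
#' @return `path` (write) or the detection data frame (read).
#' @export
write_detections <- function(dets, path) {
  jsonlite::write_json(dets, path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
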