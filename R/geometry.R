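#' Construct a set of axis-aligned bounding boxes
#'
#' Boxes use 0-based, half-open, real-valued pixel coordinates: a box spans
#' `[xmin, xmax) x [ymin, ymax)`, so its width is `xmax - xmin` with no "+1".
#' This matches the COCO convention and keeps areas and IoU continuous.
#'
#' @param xmin,ymin,xmax,ymax Numeric vectors of equal length (recycled by
#'   `data.frame`). Each box must satisfy `xmax > xmin` and `ymax > ymin`
#'   (strictly positive area).
#' @return A `data.frame` with columns `xmin`, `ymin`, `xmax`, `ymax`.
#' @examples
#' bbox(0, 0, 60, 60)
#' @export
bbox <- function(xmin = numeric(), ymin = numeric(), xmax = numeric(),
                 ymax = numeric()) {
  b <- data.frame(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
                  xmax = as.numeric(xmax), ymax = as.numeric(ymax))
  validate_boxes(b)
  b
}

validate_boxes <- function(b) {
  stopifnot(is.data.frame(b),
            all(c("xmin", "ymin", "xmax", "ymax") %in% names(b)))
  if (nrow(b) == 0) return(invisible(b))
  bad <- b$xmax <= b$xmin | b$ymax <= b$ymin
  if (any(is.na(bad)) || any(bad))
    stop("degenerate bounding box: xmax > xmin and ymax > ymin required",
         call. = FALSE)
  invisible(b)
}

#' Box areas
#'
#' @param b A box data frame from [bbox()].
#' @return Numeric vector of areas in square pixels.
#' @export
box_area <- function(b) {
  (b$xmax - b$xmin) * (b$ymax - b$ymin)
}

#' Construct detections
#'
#' A detection is a bounding box plus a confidence score in `[0, 1]` and a
#' category label. The task is single-class, so the label defaults to
#' `"insect"`.
#'
#' @param boxes A box data frame from [bbox()].
#' @param score Numeric vector of confidences in `[0, 1]`.
#' @param label Character label(s), recycled.
#' @return A `data.frame` with the box columns plus `score` and `label`.
#' @export
detection <- function(boxes, score, label = "insect") {
  validate_boxes(boxes)
  score <- as.numeric(score)
  if (nrow(boxes) == 0 && length(score) == 0) return(empty_detections())
  if (any(is.na(score)) || any(score < 0 | score > 1))
    stop("detection scores must lie in [0, 1]", call. = FALSE)
  cbind(boxes[, c("xmin", "ymin", "xmax", "ymax"), drop = FALSE],
        data.frame(score = score, label = label))
}

empty_detections <- function() {
  data.frame(xmin = numeric(), ymin = numeric(), xmax = numeric(),
             ymax = numeric(), score = numeric(), label = character())
}

#' Intersection over union of two boxes
#'
#' IoU is the overlap area divided by the union area: symmetric, 0 for
#' disjoint boxes, 1 iff the boxes are identical.
#'
#' @param a,b Single-row box data frames (or 1-row slices of detections).
#' @return A number in `[0, 1]`.
#' @examples
#' iou(bbox(0, 0, 2, 2), bbox(1, 1, 3, 3)) # 1/7
#' @export
iou <- function(a, b) {
  validate_boxes(a); validate_boxes(b)
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  iou_matrix(a, b)[1, 1]
}

#' Pairwise IoU matrix
#'
#' @param a,b Box data frames with `m` and `n` rows.
#' @return An `m x n` numeric matrix of IoU values.
#' @export
iou_matrix <- function(a, b) {
  m <- nrow(a); n <- nrow(b)
  if (m == 0 || n == 0) return(matrix(numeric(), m, n))
  ix <- pmin(outer(a$xmax, b$xmax, pmin) - outer(a$xmin, b$xmin, pmax),
             Inf)
  iy <- pmin(outer(a$ymax, b$ymax, pmin) - outer(a$ymin, b$ymin, pmax),
             Inf)
  inter <- pmax(ix, 0) * pmax(iy, 0)
  un <- outer(box_area(a), box_area(b), "+") - inter
  inter / un
}

#' Greedy non-maximum suppression
#'
#' Repeatedly keeps the highest-scoring remaining detection and discards all
#' remaining detections whose IoU with it exceeds `iou_threshold` (strict
#' `>`: a pair exactly at the threshold survives). Score ties are broken by
#' input order, earlier wins. Used globally after stitching to eliminate
#' duplicate detections of one insect seen in the overlap region of two
#' windows.
#'
#' @param dets Detection data frame (see [detection()]).
#' @param iou_threshold Suppression threshold in `[0, 1]`; default 0.5.
#' @return The surviving detections, sorted by score descending. A subset of
#'   the input; no two survivors have mutual IoU above the threshold.
#' @export
nms <- function(dets, iou_threshold = 0.5) {
  stopifnot(is.numeric(iou_threshold), length(iou_threshold) == 1,
            iou_threshold >= 0, iou_threshold <= 1)
  if (nrow(dets) == 0) return(dets)
  ord <- order(-dets$score)        # stable: ties keep input order
  d <- dets[ord, , drop = FALSE]
  n <- nrow(d)
  alive <- rep(TRUE, n)
  keep <- logical(n)
  iom <- iou_matrix(d, d)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    sup <- iom[i, ] > iou_threshold
    sup[i] <- FALSE
    alive[alive & sup] <- FALSE
    alive[i] <- FALSE
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
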