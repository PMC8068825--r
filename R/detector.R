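# Pluggable detector interface. A detector is an S3 object; detect() returns
# tile-local detections. The trained CNN detectors that motivated this
# contract are represented only by the interface: any object with a detect()
# method that returns in-bounds boxes with scores in [0, 1], deterministically
# given the tile and its fixed configuration/seed, can drive the pipeline.

#' Run a detector on one image tile
#'
#' @param detector A detector object ([blob_detector()] or
#'   [oracle_detector()]).
#' @param tile A numeric matrix or `h x w x channels` array in `[0, 1]`.
#' @param w The grid-window row the tile was cut from (offsets are used to
#'   localize ground truth and to derive per-window random streams); may be
#'   `NULL` for a free-standing tile, which is then treated as a whole image
#'   at offset (0, 0).
#' @return A detection data frame in tile-local coordinates.
#' @export
detect <- function(detector, tile, w = NULL) UseMethod("detect")

#' Reference intensity-blob detector
#'
#' A deterministic, trained-weight-free detector for synthetic trap images:
#' grayscale conversion, intensity threshold (dark foreground on the bright
#' yellow trap), connected-component labelling, and area filtering. Each
#' surviving component becomes a detection whose box is the component's
#' bounding rectangle and whose score is the component's mean contrast
#' against the tile background, clipped to `[0, 1]` (any monotone confidence
#' works for threshold calibration).
#'
#' Insects that overlap in a cluster merge into one connected component and
#' would otherwise be counted once. With `split_touching = TRUE` (the
#' default) the detector estimates each component's multiplicity from its
#' area -- `k = round(area / unit)`, where the unit is the median component
#' area in the tile, dominated by isolated insects -- and splits a
#' multi-insect component's bounding rectangle into `k` boxes along its
#' longer side. Insect-to-insect size variation is far below 2x in area, so
#' isolated insects are never split.
#'
#' @param threshold Grayscale threshold below which a pixel is foreground
#'   (default 0.5), or `"otsu"` for per-tile Otsu thresholding.
#' @param min_area,max_area Component area bounds in pixels; components
#'   outside `[min_area, max_area]` are discarded.
#' @param split_touching Estimate component multiplicity from area and
#'   split merged clusters (default `TRUE`).
#' @param unit_area Area of a single insect in pixels, used as the
#'   multiplicity unit. `NULL` (default) estimates it per tile as the
#'   median area of components clear of the tile border; sparse tiles make
#'   that estimate noisy, so when the insect scale is known -- e.g.
#'   measured once on a calibration trap with [calibrate_unit_area()] --
#'   passing it fixed is more reliable.
#' @return A detector object for [detect()].
#' @export
blob_detector <- function(threshold = 0.5, min_area = 20, max_area = Inf,
                          split_touching = TRUE, unit_area = NULL) {
  if (!identical(threshold, "otsu"))
    stopifnot(is.numeric(threshold), threshold > 0, threshold < 1)
  structure(list(threshold = threshold, min_area = min_area,
                 max_area = max_area,
                 split_touching = isTRUE(split_touching),
                 unit_area = unit_area),
            class = c("blob_detector", "detector"))
}

#' @export
detect.blob_detector <- function(detector, tile, w = NULL) {
  gray <- to_gray(tile)
  thr <- detector$threshold
  if (identical(thr, "otsu"))
    thr <- EBImage::otsu(EBImage::Image(gray), range = c(0, 1))
  mask <- gray < thr
  if (!any(mask)) return(empty_detections())
  lab <- EBImage::bwlabel(mask)
  idx <- which(lab > 0)
  labs <- lab[idx]
  rc <- arrayInd(idx, dim(gray))
  area <- tabulate(labs)
  keep_lab <- which(area >= detector$min_area & area <= detector$max_area)
  if (length(keep_lab) == 0) return(empty_detections())
  sel <- labs %in% keep_lab
  labs <- labs[sel]; rc <- rc[sel, , drop = FALSE]; px <- gray[idx][sel]
  f <- factor(labs, levels = keep_lab)
  # half-open boxes from 1-based pixel indices: pixel (row r, col c) covers
  # [c-1, c) x [r-1, r)
  xmin <- tapply(rc[, 2], f, min) - 1
  xmax <- tapply(rc[, 2], f, max)
  ymin <- tapply(rc[, 1], f, min) - 1
  ymax <- tapply(rc[, 1], f, max)
  bg <- stats::median(gray[lab == 0])
  contrast <- bg - tapply(px, f, mean)
  score <- pmin(pmax(contrast / max(bg, 1e-6), 0), 1)
  comp_area <- area[keep_lab]
  out <- detection(bbox(xmin, ymin, xmax, ymax), score)
  if (detector$split_touching && nrow(out) > 0) {
    # components cut by the tile border have truncated areas; exclude them
    # from the unit-area estimate (the edge filter discards them later)
    interior <- out$xmin > 1 & out$ymin > 1 &
      out$xmax < ncol(gray) - 1 & out$ymax < nrow(gray) - 1
    unit <- detector$unit_area
    if (is.null(unit) && any(interior))
      unit <- stats::median(comp_area[interior])
    if (!is.null(unit)) {
      mult <- pmax(1, round(comp_area / unit))
      mult[!interior] <- 1
      if (any(mult > 1)) out <- split_components(out, mult)
    }
  }
  out[order(-out$score), , drop = FALSE]
}

#' Measure the single-insect blob area on a calibration image
#'
#' Thresholds and labels the whole image and returns the median area of
#' connected components clear of the image border. Run on a calibration
#' trap (ideally one without dense clusters) to obtain a stable
#' `unit_area` for [blob_detector()] multiplicity splitting.
#'
#' @param image Calibration trap image.
#' @param threshold,min_area As in [blob_detector()].
#' @return Median component area in pixels.
#' @export
calibrate_unit_area <- function(image, threshold = 0.5, min_area = 20) {
  gray <- to_gray(image)
  mask <- gray < threshold
  if (!any(mask)) stop("no foreground on the calibration image",
                       call. = FALSE)
  lab <- EBImage::bwlabel(mask)
  idx <- which(lab > 0)
  labs <- lab[idx]
  rc <- arrayInd(idx, dim(gray))
  area <- tabulate(labs)
  r1 <- tapply(rc[, 1], labs, min); r2 <- tapply(rc[, 1], labs, max)
  c1 <- tapply(rc[, 2], labs, min); c2 <- tapply(rc[, 2], labs, max)
  ok <- area >= min_area & r1 > 1 & c1 > 1 &
    r2 < nrow(gray) & c2 < ncol(gray)
  if (!any(ok)) stop("no interior components on the calibration image",
                     call. = FALSE)
  stats::median(area[ok])
}

# split each multi-insect component's box into `mult` equal boxes along its
# longer side
split_components <- function(dets, mult) {
  pieces <- lapply(seq_len(nrow(dets)), function(i) {
    k <- mult[i]
    d <- dets[i, , drop = FALSE]
    if (k == 1) return(d)
    w <- d$xmax - d$xmin; h <- d$ymax - d$ymin
    if (w >= h) {
      cuts <- d$xmin + w * (0:k) / k
      b <- bbox(cuts[-(k + 1)], rep(d$ymin, k), cuts[-1], rep(d$ymax, k))
    } else {
      cuts <- d$ymin + h * (0:k) / k
      b <- bbox(rep(d$xmin, k), cuts[-(k + 1)], rep(d$xmax, k), cuts[-1])
    }
    detection(b, rep(d$score, k), rep(d$label, k))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Noisy-oracle detector
#'
#' A detector that "sees" the ground truth with controllable error rates,
#' used to exercise the stitching and evaluation stages with known error
#' structure (missed insects, spurious wing-like detections, sloppy
#' localization). With all noise parameters zero it reproduces the truth
#' exactly with scores 1.0 (the perfect oracle).
#'
#' For each grid window, truth boxes intersecting the window are clipped to
#' it and emitted in local coordinates -- so an insect cut by a window border
#' yields a partial box in that window, exactly the duplicate structure the
#' interior-edge filter exists to remove. Each visible truth box is
#' independently dropped with probability `miss_rate`, its coordinates
#' jittered by up to `jitter` px, and scored from the true-score law;
#' `Poisson(fp_rate)` spurious boxes per tile are added with scores from the
#' spurious law. Output is reproducible: the random stream of each window is
#' derived from `seed` and the window's grid indices, so results do not
#' depend on processing order.
#'
#' @param truth Ground-truth boxes in global image coordinates.
#' @param miss_rate Probability of dropping each visible truth box.
#' @param fp_rate Expected number of spurious boxes per tile.
#' @param jitter Maximum absolute perturbation per box coordinate, px.
#' @param score_true,score_false Ranges `c(lo, hi)` of the uniform score laws
#'   for true and spurious boxes.
#' @param fp_size Side-length range of spurious boxes, px.
#' @param seed Integer seed for the detector's random stream.
#' @return A detector object for [detect()].
#' @export
oracle_detector <- function(truth, miss_rate = 0, fp_rate = 0, jitter = 0,
                            score_true = c(1, 1), score_false = c(0.05, 0.5),
                            fp_size = c(10, 30), seed = 1L) {
  validate_boxes(truth)
  stopifnot(miss_rate >= 0, miss_rate <= 1, fp_rate >= 0, jitter >= 0)
  structure(list(truth = truth, miss_rate = miss_rate, fp_rate = fp_rate,
                 jitter = jitter, score_true = score_true,
                 score_false = score_false, fp_size = fp_size,
                 seed = as.integer(seed)),
            class = c("oracle_detector", "detector"))
}

#' @export
detect.oracle_detector <- function(detector, tile, w = NULL) {
  dm <- dim(tile)
  if (is.null(w))
    w <- data.frame(col_index = 0L, row_index = 0L, x_offset = 0,
                    y_offset = 0, width = dm[2], height = dm[1])
  local <- clip_boxes_to_window(detector$truth, w)
  ws <- (detector$seed + 7919 * w$row_index + 104729 * w$col_index) %%
    .Machine$integer.max
  with_seed(ws, oracle_emit(detector, local, w$width, w$height))
}

# truth handling shared by detect.oracle_detector and oracle_detect
clip_boxes_to_window <- function(truth, w) {
  if (nrow(truth) == 0) return(truth)
  xmin <- pmax(truth$xmin, w$x_offset)
  ymin <- pmax(truth$ymin, w$y_offset)
  xmax <- pmin(truth$xmax, w$x_offset + w$width)
  ymax <- pmin(truth$ymax, w$y_offset + w$height)
  vis <- xmax > xmin & ymax > ymin
  data.frame(xmin = xmin[vis] - w$x_offset, ymin = ymin[vis] - w$y_offset,
             xmax = xmax[vis] - w$x_offset, ymax = ymax[vis] - w$y_offset)
}

oracle_emit <- function(det, local_truth, width, height) {
  n <- nrow(local_truth)
  out <- empty_detections()
  if (n > 0) {
    kept <- stats::runif(n) >= det$miss_rate
    tb <- local_truth[kept, , drop = FALSE]
    m <- nrow(tb)
    if (m > 0) {
      if (det$jitter > 0) {
        j <- function() stats::runif(m, -det$jitter, det$jitter)
        tb$xmin <- tb$xmin + j(); tb$ymin <- tb$ymin + j()
        tb$xmax <- tb$xmax + j(); tb$ymax <- tb$ymax + j()
        tb <- repair_boxes(tb, width, height)
      }
      sc <- stats::runif(m, det$score_true[1], det$score_true[2])
      out <- detection(tb, sc)
    }
  }
  nfp <- stats::rpois(1, det$fp_rate)
  if (nfp > 0) {
    sw <- stats::runif(nfp, det$fp_size[1], min(det$fp_size[2], width))
    sh <- stats::runif(nfp, det$fp_size[1], min(det$fp_size[2], height))
    x0 <- stats::runif(nfp, 0, width - sw)
    y0 <- stats::runif(nfp, 0, height - sh)
    sc <- stats::runif(nfp, det$score_false[1], det$score_false[2])
    out <- rbind(out, detection(bbox(x0, y0, x0 + sw, y0 + sh), sc))
  }
  out[order(-out$score), , drop = FALSE]
}

# clip jittered boxes back into the tile and keep them non-degenerate
repair_boxes <- function(b, width, height) {
  b$xmin <- pmin(pmax(b$xmin, 0), width - 1)
  b$ymin <- pmin(pmax(b$ymin, 0), height - 1)
  b$xmax <- pmax(pmin(b$xmax, width), b$xmin + 1)
  b$ymax <- pmax(pmin(b$ymax, height), b$ymin + 1)
  b
}

#' One-shot noisy-oracle detection on a tile
#'
#' Functional form of the oracle: supply tile-local truth directly.
#'
#' @param tile Raster tile (used only for its dimensions).
#' @param truth Truth boxes in tile-local coordinates.
#' @param ... Passed to [oracle_detector()] (noise configuration).
#' @return Tile-local detections.
#' @export
oracle_detect <- function(tile, truth, ...) {
  detect(oracle_detector(truth, ...), tile, w = NULL)
}

to_gray <- function(img) {
  if (length(dim(img)) == 2) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# evaluate code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
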