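#' Match detections to ground truth at an IoU threshold
#'
#' Greedy matching in score-descending order (ties broken by input order):
#' each detection is matched to the still-unmatched truth box of highest IoU
#' if that IoU reaches the threshold (a true positive), otherwise it counts
#' as a false positive. IoU ties between truth boxes are broken toward the
#' lower truth index. Truth boxes left unmatched are false negatives. Each
#' detection and each truth box appears in at most one match.
#'
#' @param dets Detection data frame (scores required).
#' @param truth Ground-truth boxes.
#' @param iou_threshold Minimum IoU for a correct localization, in `(0, 1]`.
#' @return A `match_result`: list with counts `TP`, `FP`, `FN`, the
#'   `matches` data frame (`det`, `truth`, `iou`; indices into the inputs),
#'   `det_order` (input indices in processing order), `det_tp` (logical, TP
#'   flag per detection in processing order), `scores` (in processing
#'   order), and `iou_threshold`.
#' @export
match_detections <- function(dets, truth, iou_threshold = 0.5) {
  stopifnot(iou_threshold > 0, iou_threshold <= 1)
  nd <- nrow(dets); nt <- nrow(truth)
  ord <- if (nd > 0) order(-dets$score) else integer()
  tp <- logical(nd)
  matches <- data.frame(det = integer(), truth = integer(), iou = numeric())
  if (nd > 0 && nt > 0) {
    iom <- iou_matrix(dets, truth)
    truth_free <- rep(TRUE, nt)
    for (k in seq_len(nd)) {
      i <- ord[k]
      ious <- iom[i, ]
      ious[!truth_free] <- -1
      j <- which.max(ious)            # ties -> lower truth index
      if (ious[j] >= iou_threshold) {
        tp[k] <- TRUE
        truth_free[j] <- FALSE
        matches <- rbind(matches,
                         data.frame(det = i, truth = j, iou = ious[j]))
      }
    }
  }
  structure(
    list(TP = sum(tp), FP = nd - sum(tp), FN = nt - sum(tp),
         matches = matches, det_order = ord, det_tp = tp,
         scores = if (nd > 0) dets$score[ord] else numeric(),
         iou_threshold = iou_threshold),
    class = "match_result"
  )
}

#' Precision and recall of a match result, in percent
#'
#' `precision = TP / (TP + FP) * 100` and `recall = TP / (TP + FN) * 100`.
#' An empty denominator makes the corresponding value undefined: it is
#' returned as `NA` (never silently 0).
#'
#' @param m A `match_result` from [match_detections()].
#' @return Named numeric vector `c(precision = , recall = )` in percent.
#' @examples
#' m <- list(TP = 9, FP = 1, FN = 0)
#' class(m) <- "match_result"
#' precision_recall(m) # 90, 100
#' @export
precision_recall <- function(m) {
  prec <- if (m$TP + m$FP > 0) 100 * m$TP / (m$TP + m$FP) else NA_real_
  rec <- if (m$TP + m$FN > 0) 100 * m$TP / (m$TP + m$FN) else NA_real_
  c(precision = prec, recall = rec)
}

#' Precision-recall curve over the score sweep
#'
#' Sweeps the operating point over the distinct detection scores (all-point
#' sweep, highest score first): at each distinct score the detections at or
#' above it are matched and a (recall, precision) point recorded. Greedy
#' score-order matching is prefix-consistent, so the sweep is computed from
#' one full match's cumulative TP counts.
#'
#' @inheritParams match_detections
#' @return Data frame with columns `score`, `recall`, `precision` (percent),
#'   one row per distinct score, recall non-decreasing.
#' @export
pr_curve <- function(dets, truth, iou_threshold = 0.5) {
  if (nrow(truth) == 0)
    stop("PR curve undefined without ground-truth boxes", call. = FALSE)
  m <- match_detections(dets, truth, iou_threshold)
  n <- length(m$det_tp)
  if (n == 0)
    return(data.frame(score = numeric(), recall = numeric(),
                      precision = numeric()))
  cum_tp <- cumsum(m$det_tp)
  # operating points: the last position of each distinct score (a threshold
  # exactly at a tied score keeps all of its ties)
  last <- cumsum(rle(m$scores)$lengths)
  data.frame(score = m$scores[last],
             recall = 100 * cum_tp[last] / nrow(truth),
             precision = 100 * cum_tp[last] / last)
}

#' Average precision at a fixed IoU threshold
#'
#' Area under the monotone precision envelope of the all-point
#' precision-recall curve (the right-to-left running maximum of precision,
#' integrated over recall). Returned in `[0, 1]`.
#'
#' @inheritParams match_detections
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(dets, truth, iou_threshold = 0.5) {
  if (nrow(truth) == 0)
    stop("average precision undefined without ground-truth boxes",
         call. = FALSE)
  pc <- pr_curve(dets, truth, iou_threshold)
  ap_from_points(pc$recall / 100, pc$precision / 100)
}

# exact area under the monotone (right-to-left max) precision envelope;
# recall/precision as proportions
ap_from_points <- function(recall, precision) {
  if (length(recall) == 0) return(0)
  env <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * env)
}

#' Dataset-pooled average precision
#'
#' Detections from several traps are matched within their own trap, then
#' pooled by score across traps to form one PR curve, the convention used
#' for test-set AP reporting.
#'
#' @param dets_list List of detection data frames, one per trap.
#' @param truth_list List of truth box data frames, same order.
#' @param iou_threshold IoU matching threshold.
#' @return Pooled AP in `[0, 1]`.
#' @export
dataset_average_precision <- function(dets_list, truth_list,
                                      iou_threshold = 0.5) {
  stopifnot(length(dets_list) == length(truth_list))
  n_truth <- sum(vapply(truth_list, nrow, integer(1)))
  if (n_truth == 0)
    stop("average precision undefined without ground-truth boxes",
         call. = FALSE)
  ms <- mapply(function(d, t) match_detections(d, t, iou_threshold),
               dets_list, truth_list, SIMPLIFY = FALSE)
  scores <- unlist(lapply(ms, `[[`, "scores"))
  flags <- unlist(lapply(ms, `[[`, "det_tp"))
  if (length(scores) == 0) return(0)
  ord <- order(-scores)
  scores <- scores[ord]; flags <- flags[ord]
  cum_tp <- cumsum(flags)
  last <- cumsum(rle(scores)$lengths)
  ap_from_points(cum_tp[last] / n_truth, cum_tp[last] / last)
}

#' Counting error across traps, in percent
#'
#' Mean absolute per-trap relative deviation between the manual count `C_i`
#' and the pipeline count `Chat_i`:
#' `(1/N) * sum_i |C_i - Chat_i| / C_i * 100`.
#' Counting accuracy is 100 minus this value. A signed variant (over- and
#' under-counts cancelling) is available with `signed = TRUE`.
#'
#' @param manual Vector of manual counts `C_i` (all > 0).
#' @param predicted Vector of pipeline counts `Chat_i`, same length.
#' @param signed If `TRUE`, drop the absolute value (signed mean deviation).
#' @return The counting error in percent.
#' @examples
#' counting_error(100, 90) # 10
#' counting_error(c(200, 400, 600), c(190, 420, 570)) # 5
#' @export
counting_error <- function(manual, predicted, signed = FALSE) {
  stopifnot(length(manual) == length(predicted), length(manual) >= 1)
  if (any(manual <= 0))
    stop("counting error undefined for traps with manual count 0; ",
         "exclude them upstream", call. = FALSE)
  dev <- (manual - predicted) / manual
  if (!signed) dev <- abs(dev)
  mean(dev) * 100
}

#' Build a per-trap counting report
#'
#' @param trap_id Trap identifiers.
#' @param manual,predicted Per-trap manual and pipeline counts.
#' @param signed Passed to [counting_error()].
#' @return A `counting_report`: list with the per-trap data frame `traps`,
#'   `N`, and `counting_error` (percent).
#' @export
counting_report <- function(trap_id, manual, predicted, signed = FALSE) {
  structure(
    list(traps = data.frame(trap_id = trap_id, manual = manual,
                            predicted = predicted),
         N = length(manual),
         counting_error = counting_error(manual, predicted, signed = signed)),
    class = "counting_report"
  )
}

#' @export
print.counting_report <- function(x, ...) {
  cat(sprintf("counting report: %d traps, counting error %.3f%%\n",
              x$N, x$counting_error))
  invisible(x)
}

#' Calibrate the detection score threshold on held-out traps
#'
#' The detector's score threshold controls how many boxes are retained and
#' hence the count; it is chosen on a calibration subset of traps (10 of the
#' 30 in the original design) to minimize the counting error, and then
#' applied unchanged to the evaluation traps. Because the threshold acts
#' after NMS, each calibration trap is stitched once and simply re-counted
#' at every candidate threshold.
#'
#' @param detections List of stitched detection data frames, one per
#'   calibration trap (e.g. the `detections` element of [count_trap()] run
#'   with `score_threshold = 0`).
#' @param manual Vector of manual counts for the same traps.
#' @param thresholds Candidate thresholds in `[0, 1]`; default a 0.05 grid
#'   from 0.05 to 0.95.
#' @param signed Passed to [counting_error()].
#' @return List with `threshold` (the minimizer; ties broken toward the
#'   higher threshold) and `errors`, a data frame of candidate thresholds
#'   and their calibration counting errors.
#' @export
calibrate_threshold <- function(detections, manual,
                                thresholds = seq(0.05, 0.95, by = 0.05),
                                signed = FALSE) {
  stopifnot(length(detections) == length(manual), length(manual) >= 1)
  if (length(thresholds) == 0)
    stop("empty threshold grid", call. = FALSE)
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  errs <- vapply(thresholds, function(t) {
    counts <- vapply(detections, function(d) sum(d$score >= t) + 0,
                     numeric(1))
    counting_error(manual, counts, signed = signed)
  }, numeric(1))
  best <- max(thresholds[errs == min(errs)])
  list(threshold = best,
       errors = data.frame(threshold = thresholds, counting_error = errs))
}

#' Calibrate the score threshold directly from trap images
#'
#' Convenience wrapper: runs the counting pipeline once per calibration
#' image (keeping all stitched detections) and calls
#' [calibrate_threshold()].
#'
#' @param images List of trap images.
#' @param manual Manual counts, same order.
#' @param detector Detector object.
#' @param ... Grid/stitching parameters passed to [count_trap()].
#' @param thresholds,signed Passed to [calibrate_threshold()].
#' @return As [calibrate_threshold()].
#' @export
calibrate_threshold_images <- function(images, manual, detector, ...,
                                       thresholds = seq(0.05, 0.95,
                                                        by = 0.05),
                                       signed = FALSE) {
  dets <- lapply(images, function(img)
    count_trap(img, detector, score_threshold = 0, ...)$detections)
  calibrate_threshold(dets, manual, thresholds = thresholds, signed = signed)
}
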