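#' Remove detections cut by interior window borders
#'
#' An object cut at the edge of one window is detected as a partial box
#' there and as a full box in the neighbouring window; the two have low
#' mutual IoU, so NMS alone does not remove the duplicate. Following the
#' counting algorithm's edge rule, any detection with a coordinate within
#' `tolerance` px of a window border is removed -- EXCEPT at borders that
#' coincide with the image boundary, where an object at the trap's edge
#' appears cut in every window and would otherwise be uncountable.
#'
#' @param dets Detections in window-local coordinates.
#' @param w One row of `grid$windows`.
#' @param grid The `window_grid` the window belongs to (supplies the image
#'   extent, which decides which borders are interior).
#' @param tolerance Distance from a border, in px, within which a box
#'   coordinate counts as "at the end of the window" (default 1).
#' @return The surviving detections, unchanged.
#' @export
filter_edge_boxes <- function(dets, w, grid, tolerance = 1) {
  if (nrow(dets) == 0) return(dets)
  interior_left <- w$x_offset > 0
  interior_top <- w$y_offset > 0
  interior_right <- w$x_offset + w$width < grid$image_width
  interior_bottom <- w$y_offset + w$height < grid$image_height
  cut <- (interior_left & dets$xmin <= tolerance) |
    (interior_right & dets$xmax >= w$width - tolerance) |
    (interior_top & dets$ymin <= tolerance) |
    (interior_bottom & dets$ymax >= w$height - tolerance)
  out <- dets[!cut, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge per-window detections into one trap-level detection set
#'
#' Per window: drop boxes cut by interior borders ([filter_edge_boxes()]),
#' translate to global coordinates ([to_global()]); then pool all windows
#' and apply global NMS to collapse duplicate detections of one insect seen
#' in the overlap region of adjacent windows.
#'
#' @param per_window A list of `list(window = <grid row>, detections =
#'   <local detections>)` entries, one per scanned window.
#' @param grid The `window_grid` used for scanning.
#' @param nms_iou Global NMS IoU threshold (default 0.5).
#' @param tolerance Edge-filter tolerance in px; see [filter_edge_boxes()].
#' @param filter_edges Set `FALSE` to skip the edge filter and rely on NMS
#'   alone (reproduces the cut-object duplicate failure mode; for study
#'   only).
#' @return Global detections sorted by score descending.
#' @export
stitch <- function(per_window, grid, nms_iou = 0.5, tolerance = 1,
                   filter_edges = TRUE) {
  pooled <- lapply(per_window, function(pw) {
    w <- pw$window
    if (is.null(w) || !all(c("x_offset", "y_offset", "width") %in% names(w)))
      stop("each per_window entry needs a grid window row", call. = FALSE)
    if (w$x_offset + w$width > grid$image_width ||
        w$y_offset + w$height > grid$image_height)
      stop("window does not belong to the supplied grid", call. = FALSE)
    d <- pw$detections
    if (filter_edges) d <- filter_edge_boxes(d, w, grid, tolerance)
    to_global(d, w)
  })
  pooled <- do.call(rbind, c(list(empty_detections()), pooled))
  nms(pooled, nms_iou)
}

#' Count insects on one trap image
#'
#' The full counting pipeline for a single trap: compute the sliding-window
#' grid, run the detector on every window crop, stitch the per-window
#' detections (edge filter, global coordinates, global NMS), then discard
#' detections below the score threshold and count the survivors.
#'
#' @param image Trap image: numeric matrix or `h x w x 3` array in `[0, 1]`.
#' @param detector A detector object; see [detect()].
#' @param window_size,overlap Scanning-grid parameters, px (defaults 500 and
#'   100, the trap-counting operating point; 1000/100 is the coarser
#'   alternative).
#' @param score_threshold Minimum confidence retained for counting; applied
#'   after NMS, matching how the threshold is calibrated downstream of a
#'   fixed detection stage. Default 0.5.
#' @param nms_iou,edge_tolerance Stitching parameters; see [stitch()].
#' @param filter_edges See [stitch()].
#' @param trap_id Identifier recorded in the result.
#' @return A `trap_count` object: list with `trap_id`, `detections` (all
#'   stitched detections, any score), `count` (number with score >=
#'   threshold), `score_threshold`, and `grid`.
#' @export
count_trap <- function(image, detector, window_size = 500, overlap = 100,
                       score_threshold = 0.5, nms_iou = 0.5,
                       edge_tolerance = 1, filter_edges = TRUE,
                       trap_id = "trap") {
  dm <- dim(image)
  grid <- compute_grid(dm[2], dm[1], window_size, overlap)
  per_window <- lapply(seq_len(nrow(grid$windows)), function(i) {
    w <- grid$windows[i, , drop = FALSE]
    tile <- extract_tile(image, w)
    list(window = w, detections = detect(detector, tile, w))
  })
  stitched <- stitch(per_window, grid, nms_iou = nms_iou,
                     tolerance = edge_tolerance, filter_edges = filter_edges)
  structure(
    list(trap_id = trap_id, detections = stitched,
         count = sum(stitched$score >= score_threshold),
         score_threshold = score_threshold, grid = grid),
    class = "trap_count"
  )
}

#' @export
print.trap_count <- function(x, ...) {
  cat(sprintf("trap %s: %d insects (score >= %.2f; %d x %d windows of %d px)\n",
              x$trap_id, x$count, x$score_threshold, x$grid$n_cols,
              x$grid$n_rows, x$grid$window_size))
  invisible(x)
}

#' Re-count a stitched result at a different score threshold
#'
#' The stitched detection set is independent of the score threshold, so a
#' trap can be re-counted without re-running the detector.
#'
#' @param result A `trap_count` object.
#' @param score_threshold New threshold.
#' @return The updated `trap_count`.
#' @export
recount <- function(result, score_threshold) {
  result$count <- sum(result$detections$score >= score_threshold)
  result$score_threshold <- score_threshold
  result
}
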