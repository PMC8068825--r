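# Independent brute-force references used to check the package's geometry
# and evaluation code, plus small fixture builders. Everything here is
# written from the definitions, not from the package's implementation.

rand_boxes <- function(n, W = 100, H = 100, min_side = 5, max_side = 30) {
  x0 <- stats::runif(n, 0, W - max_side)
  y0 <- stats::runif(n, 0, H - max_side)
  w <- stats::runif(n, min_side, max_side)
  h <- stats::runif(n, min_side, max_side)
  bbox(x0, y0, x0 + w, y0 + h)
}

rand_dets <- function(n, ...) {
  if (n == 0) return(detection(bbox(), numeric()))
  detection(rand_boxes(n, ...), stats::runif(n))
}

# IoU from the definition, scalar boxes as c(xmin, ymin, xmax, ymax)
ref_iou <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) +
             (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

box_vec <- function(d, i) as.numeric(d[i, c("xmin", "ymin", "xmax", "ymax")])

# explicit O(n^2) simulation of greedy score-descending suppression
ref_nms <- function(dets, thr) {
  remaining <- seq_len(nrow(dets))
  kept <- integer()
  while (length(remaining) > 0) {
    best <- remaining[which.max(dets$score[remaining])] # ties: input order
    kept <- c(kept, best)
    remaining <- setdiff(remaining, best)
    if (length(remaining) > 0) {
      drop <- vapply(remaining, function(i)
        ref_iou(box_vec(dets, best), box_vec(dets, i)) > thr, logical(1))
      remaining <- remaining[!drop]
    }
  }
  out <- dets[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# greedy score-order matching from the definition; returns TP/FP/FN counts
ref_match <- function(dets, truth, thr) {
  used <- rep(FALSE, nrow(truth))
  tp <- 0L
  for (i in order(-dets$score)) {
    if (nrow(truth) == 0) break
    ious <- vapply(seq_len(nrow(truth)), function(j)
      ref_iou(box_vec(dets, i), box_vec(truth, j)), numeric(1))
    ious[used] <- -1
    j <- which.max(ious)
    if (ious[j] >= thr) {
      tp <- tp + 1L
      used[j] <- TRUE
    }
  }
  list(TP = tp, FP = nrow(dets) - tp, FN = nrow(truth) - tp)
}

# AP by exhaustive enumeration: re-match the score-thresholded subset from
# scratch at every distinct score, then integrate the monotone envelope
ref_ap <- function(dets, truth, thr) {
  if (nrow(dets) == 0) return(0)
  sc <- sort(unique(dets$score), decreasing = TRUE)
  rec <- prec <- numeric(length(sc))
  for (k in seq_along(sc)) {
    sub <- dets[dets$score >= sc[k], , drop = FALSE]
    m <- ref_match(sub, truth, thr)
    rec[k] <- m$TP / nrow(truth)
    prec[k] <- m$TP / nrow(sub)
  }
  env <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * env)
}

# small separable scene at 1/10 linear scale (50-px window, 10-px overlap
# keep the full-scale insect:window ratio)
small_scene <- function(seed, n_insects = 40, ...) {
  generate_scene(scene_config(n_insects = n_insects, scale = 0.1,
                              cluster_fraction = 0, n_distractors = 0,
                              seed = seed, ...))
}

small_grid_pars <- list(window_size = 50, overlap = 10)

blank_tile <- function(w) matrix(0, w$height, w$width)
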