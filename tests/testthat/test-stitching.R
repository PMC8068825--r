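# image 250 x 150: window 150 / overlap 50 gives two windows, offsets 0 and
# 100, with one interior vertical border at x = 150
two_window_grid <- function() compute_grid(250, 150, 150, 50)

test_that("interior-edge boxes are removed, image-boundary boxes kept", {
  g <- compute_grid(1000, 1000, 500, 100)
  w_interior <- g$windows[g$windows$x_offset == 400 &
                            g$windows$y_offset == 400, ][1, ]
  w_origin <- g$windows[1, ]
  d_left <- detection(bbox(0, 100, 60, 160), 0.9)
  d_inside <- detection(bbox(200, 200, 260, 260), 0.9)
  # touches the left border of an interior window: cut duplicate, removed
  expect_equal(nrow(filter_edge_boxes(d_left, w_interior, g)), 0)
  expect_equal(nrow(filter_edge_boxes(d_inside, w_interior, g)), 1)
  # same local box, but the window's left border IS the image's left edge
  expect_equal(nrow(filter_edge_boxes(d_left, w_origin, g)), 1)
  # ... while its right/bottom borders are interior
  d_right <- detection(bbox(440, 100, 500, 160), 0.9)
  expect_equal(nrow(filter_edge_boxes(d_right, w_origin, g)), 0)
})

test_that("one object in the overlap region stitches to one detection", {
  g <- two_window_grid()
  truth <- bbox(110, 60, 140, 90)   # wholly inside both windows
  per_window <- lapply(seq_len(nrow(g$windows)), function(i) {
    w <- g$windows[i, ]
    list(window = w,
         detections = detect(oracle_detector(truth), blank_tile(w), w))
  })
  out <- stitch(per_window, g)
  expect_equal(nrow(out), 1)
  expect_equal(out[1, 1:4], truth, ignore_attr = TRUE)
})

test_that("a cut object needs the edge filter, not just NMS", {
  g <- two_window_grid()
  truth <- bbox(140, 60, 160, 80)   # straddles the interior border x = 150
  per_window <- lapply(seq_len(nrow(g$windows)), function(i) {
    w <- g$windows[i, ]
    list(window = w,
         detections = detect(oracle_detector(truth), blank_tile(w), w))
  })
  with_filter <- stitch(per_window, g)
  expect_equal(nrow(with_filter), 1)
  expect_equal(with_filter[1, 1:4], truth, ignore_attr = TRUE)
  # the partial box survives NMS alone: its IoU with the full box is low
  without_filter <- stitch(per_window, g, filter_edges = FALSE)
  expect_equal(nrow(without_filter), 2)
})

test_that("stitch validates windows and never creates detections", {
  g <- two_window_grid()
  alien <- data.frame(col_index = 0, row_index = 0, x_offset = 400,
                      y_offset = 0, width = 150, height = 150)
  expect_error(stitch(list(list(window = alien,
                                detections = empty <- detection(bbox(), numeric()))),
                      g), "grid")
  set.seed(5)
  per_window <- lapply(seq_len(nrow(g$windows)), function(i) {
    w <- g$windows[i, ]
    list(window = w, detections = rand_dets(8, W = 150, H = 150,
                                            min_side = 5, max_side = 30))
  })
  out <- stitch(per_window, g)
  expect_lte(nrow(out), sum(vapply(per_window,
                                   function(p) nrow(p$detections),
                                   integer(1))))
})

test_that("stitching is independent of window processing order", {
  sc <- small_scene(31)
  g <- compute_grid(600, 400, 50, 10)
  det <- oracle_detector(sc$truth, score_true = c(0.6, 1), seed = 9)
  mk <- function(idx) lapply(idx, function(i) {
    w <- g$windows[i, ]
    list(window = w, detections = detect(det, blank_tile(w), w))
  })
  a <- stitch(mk(seq_len(nrow(g$windows))), g)
  set.seed(8)
  b <- stitch(mk(sample(nrow(g$windows))), g)
  expect_equal(a[order(a$xmin, a$ymin), ], b[order(b$xmin, b$ymin), ],
               ignore_attr = TRUE)
})

test_that("count_trap is exact with a perfect oracle and monotone in threshold", {
  expect_equal(count_trap(array(0.8, c(100, 120, 3)), blob_detector(),
                          window_size = 60, overlap = 20)$count, 0)
  sc <- small_scene(17, n_insects = 35)
  res <- count_trap(sc$image, oracle_detector(sc$truth),
                    window_size = 50, overlap = 10, score_threshold = 0.5)
  expect_equal(res$count, 35)
  # recounting at increasing thresholds never increases the count
  det <- oracle_detector(sc$truth, score_true = c(0.2, 1), seed = 4)
  res2 <- count_trap(sc$image, det, window_size = 50, overlap = 10,
                     score_threshold = 0)
  counts <- vapply(seq(0, 1, by = 0.1),
                   function(t) recount(res2, t)$count, integer(1))
  expect_true(all(diff(counts) <= 0))
})
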