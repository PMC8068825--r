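test_that("matching handles the hand-worked cases", {
  t1 <- bbox(0, 0, 10, 10)
  m <- match_detections(detection(t1, 0.9), t1, 0.5)
  expect_equal(c(m$TP, m$FP, m$FN), c(1, 0, 0))

  m0 <- match_detections(detection(bbox(), numeric()),
                         rand_boxes(5), 0.5)
  expect_equal(c(m0$TP, m0$FP, m0$FN), c(0, 0, 5))

  # two detections on one truth: the higher-scoring one takes the match
  d <- detection(bbox(c(0, 0), c(0, 0), c(10, 10), c(10, 16)),
                 c(0.9, 0.6))
  m2 <- match_detections(d, t1, 0.5)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(1, 1, 0))
  expect_equal(m2$matches$det, 1)
})

test_that("match bookkeeping identities hold on random instances", {
  set.seed(12)
  for (rep in 1:25) {
    nd <- sample(0:12, 1); nt <- sample(0:6, 1)
    d <- rand_dets(nd, W = 60, H = 60, min_side = 10, max_side = 35)
    tr <- rand_boxes(nt, W = 60, H = 60, min_side = 10, max_side = 35)
    thr <- sample(c(0.3, 0.5), 1)
    m <- match_detections(d, tr, thr)
    expect_equal(m$TP + m$FN, nt)
    expect_equal(m$TP + m$FP, nd)
    expect_true(!anyDuplicated(m$matches$det))
    expect_true(!anyDuplicated(m$matches$truth))
    expect_true(all(m$matches$iou >= thr))
    ref <- ref_match(d, tr, thr)
    expect_equal(m$TP, ref$TP)
  }
})

test_that("precision and recall reproduce the worked examples", {
  mk <- function(TP, FP, FN) structure(list(TP = TP, FP = FP, FN = FN),
                                       class = "match_result")
  expect_equal(precision_recall(mk(9, 1, 0)),
               c(precision = 90, recall = 100))
  expect_equal(precision_recall(mk(50, 10, 25)),
               c(precision = 100 * 50 / 60, recall = 100 * 50 / 75))
  pr <- precision_recall(mk(0, 0, 3))
  expect_true(is.na(pr["precision"]))
  expect_equal(unname(pr["recall"]), 0)
})

test_that("AP trivial cases", {
  t1 <- bbox(0, 0, 10, 10)
  expect_equal(average_precision(detection(t1, 0.8), t1, 0.5), 1)
  far <- detection(bbox(90, 90, 99, 99), 0.8)
  expect_equal(average_precision(far, t1, 0.5), 0)
  expect_equal(average_precision(detection(bbox(), numeric()), t1, 0.5), 0)
  expect_error(average_precision(far, bbox(), 0.5), "undefined")
})

test_that("AP equals the exhaustive sweep oracle on random instances", {
  set.seed(23)
  for (rep in 1:40) {
    nd <- sample(1:10, 1); nt <- sample(1:5, 1)
    d <- rand_dets(nd, W = 50, H = 50, min_side = 10, max_side = 30)
    tr <- rand_boxes(nt, W = 50, H = 50, min_side = 10, max_side = 30)
    for (thr in c(0.3, 0.5))
      expect_equal(average_precision(d, tr, thr), ref_ap(d, tr, thr))
  }
  # tied scores: operating points exist only at distinct score values
  t2 <- bbox(c(0, 30), c(0, 30), c(10, 40), c(10, 40))
  d2 <- detection(bbox(c(0, 90), c(0, 90), c(10, 99), c(10, 99)),
                  c(0.7, 0.7))
  expect_equal(average_precision(d2, t2, 0.5), ref_ap(d2, t2, 0.5))
})

test_that("AP is invariant to monotone score transforms and IoU-ordered", {
  set.seed(37)
  for (rep in 1:10) {
    d <- rand_dets(12, W = 60, H = 60, min_side = 10, max_side = 30)
    tr <- rand_boxes(6, W = 60, H = 60, min_side = 10, max_side = 30)
    d_sq <- d; d_sq$score <- d$score^2      # monotone transform
    expect_equal(average_precision(d, tr, 0.5),
                 average_precision(d_sq, tr, 0.5))
    expect_gte(average_precision(d, tr, 0.3),
               average_precision(d, tr, 0.5))
  }
})

test_that("counting error reproduces the worked examples and properties", {
  expect_equal(counting_error(c(10, 20), c(10, 20)), 0)
  expect_equal(counting_error(100, 90), 10)
  expect_equal(counting_error(c(200, 400, 600), c(190, 420, 570)), 5)
  expect_error(counting_error(c(100, 0), c(90, 0)), "0")
  # scale invariance
  expect_equal(counting_error(c(2, 4, 6) * 50, c(3, 4, 5) * 50),
               counting_error(c(2, 4, 6), c(3, 4, 5)))
  # signed variant lets over- and under-counts cancel
  expect_equal(counting_error(c(100, 100), c(90, 110), signed = TRUE), 0)
  expect_equal(counting_error(c(100, 100), c(90, 110)), 10)
})

test_that("threshold calibration recovers the separating threshold", {
  set.seed(41)
  mk_trap <- function(n_true, n_fp) {
    rbind(detection(rand_boxes(n_true, W = 400, H = 400),
                    runif(n_true, 0.9, 1)),
          detection(rand_boxes(n_fp, W = 400, H = 400),
                    runif(n_fp, 0.05, 0.3)))
  }
  manual <- c(30, 45, 60)
  dets <- lapply(manual, function(n) mk_trap(n, sample(5:15, 1)))
  cal <- calibrate_threshold(dets, manual)
  expect_gt(cal$threshold, 0.3)
  expect_lte(cal$threshold, 0.9 + 1e-9)
  expect_equal(min(cal$errors$counting_error), 0)
  # held-out traps built the same way count exactly at that threshold
  held_manual <- c(25, 50)
  held <- lapply(held_manual, function(n) mk_trap(n, 8))
  held_counts <- vapply(held, function(d)
    sum(d$score >= cal$threshold) + 0, numeric(1))
  expect_equal(counting_error(held_manual, held_counts), 0)
  # degenerate grids
  expect_equal(calibrate_threshold(dets, manual,
                                   thresholds = 0.4)$threshold, 0.4)
  expect_error(calibrate_threshold(dets, manual, thresholds = numeric()),
               "empty")
})

test_that("calibrated counting beats the grid extremes on separated scores", {
  set.seed(53)
  manual <- c(40, 55)
  dets <- lapply(manual, function(n)
    rbind(detection(rand_boxes(n, W = 400, H = 400), runif(n, 0.9, 1)),
          detection(rand_boxes(12, W = 400, H = 400),
                    runif(12, 0.05, 0.3))))
  cal <- calibrate_threshold(dets, manual)
  err_at <- function(t) counting_error(manual, vapply(dets, function(d)
    sum(d$score >= t) + 0, numeric(1)))
  expect_lte(err_at(cal$threshold), err_at(0.05))
  expect_lte(err_at(cal$threshold), err_at(0.95))
})
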