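test_that("scene generation is an exact, reproducible census", {
  cfg <- scene_config(n_insects = 30, scale = 0.1, n_distractors = 4,
                      seed = 77)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$truth), 30)
  # boxes strictly inside the image
  W <- cfg$image_width; H <- cfg$image_height
  expect_true(all(a$truth$xmin >= 0 & a$truth$xmax <= W &
                    a$truth$ymin >= 0 & a$truth$ymax <= H))
  expect_equal(dim(a$image), c(H, W, 3))

  empty <- generate_scene(scene_config(n_insects = 0, scale = 0.1,
                                       seed = 1))
  expect_equal(nrow(empty$truth), 0)
  # blank background: nothing darker than the insect threshold
  expect_gt(min(empty$image[, , 1]), 0.5)
})

test_that("insect boxes average the configured size", {
  sc <- generate_scene(scene_config(n_insects = 250, scale = 0.25,
                                    seed = 5))
  side <- (sc$truth$xmax - sc$truth$xmin +
             sc$truth$ymax - sc$truth$ymin) / 2
  # configured 60 px at 1/4 scale: 15 +/- 1.25 (the +/- 5 px band scaled)
  expect_gt(mean(side), 15 - 1.25)
  expect_lt(mean(side), 15 + 1.25)
})

test_that("infeasible densities are rejected", {
  expect_error(generate_scene(scene_config(n_insects = 5000, scale = 0.1)),
               "infeasible")
})

test_that("separable scenes are counted exactly by the blob detector", {
  for (s in c(3, 14)) {
    sc <- generate_scene(scene_config(n_insects = 100, scale = 0.25,
                                      cluster_fraction = 0, seed = s))
    res <- count_trap(sc$image, blob_detector(), window_size = 125,
                      overlap = 25, score_threshold = 0.5)
    expect_equal(res$count, 100)
  }
})

test_that("clustering degrades blob counting monotonically in expectation", {
  err_at <- function(cf) {
    errs <- vapply(1:3, function(s) {
      sc <- generate_scene(scene_config(n_insects = 150, scale = 0.25,
                                        cluster_fraction = cf, seed = s))
      res <- count_trap(sc$image, blob_detector(), window_size = 125,
                        overlap = 25, score_threshold = 0.5)
      counting_error(150, res$count)
    }, numeric(1))
    mean(errs)
  }
  e0 <- err_at(0); e2 <- err_at(0.2); e5 <- err_at(0.5)
  expect_lte(e0, e2 + 1e-9)
  expect_lte(e2, e5 + 1e-9)
})

test_that("wing-like distractors are rendered but never annotated", {
  cfg <- scene_config(n_insects = 10, scale = 0.1, n_distractors = 30,
                      seed = 9)
  sc <- generate_scene(cfg)
  expect_equal(nrow(sc$truth), 10)
  # distractors brighten the scene above the background ceiling
  bare <- generate_scene(scene_config(n_insects = 10, scale = 0.1,
                                      n_distractors = 0, seed = 9))
  expect_gt(mean(sc$image[, , 3] > 0.6), mean(bare$image[, , 3] > 0.6))
})

test_that("the stratified benchmark respects its density bands", {
  bench <- generate_benchmark(n_per_band = 2, seed = 4, scale = 0.1,
                              bands = list(low = c(20, 40),
                                           mid = c(41, 60),
                                           high = c(61, 80)))
  expect_equal(nrow(bench$counts), 6)
  expect_equal(as.character(bench$counts$band),
               rep(c("low", "mid", "high"), each = 2))
  for (i in seq_len(6)) {
    id <- bench$counts$trap_id[i]
    expect_equal(nrow(bench$scenes[[id]]$truth), bench$counts$n_insects[i])
  }
  rng <- range(bench$counts$n_insects[bench$counts$band == "low"])
  expect_true(rng[1] >= 20 && rng[2] <= 40)
})

test_that("density bands follow the population stratification", {
  expect_equal(as.character(density_band(c(120, 299, 300, 500, 501, 700))),
               c("low", "low", "mid", "mid", "high", "high"))
})

test_that("a benchmark written to disk round-trips through the readers", {
  dir <- withr::local_tempdir()
  bench <- generate_benchmark(n_per_band = 1, seed = 6, scale = 0.1,
                              bands = list(low = c(10, 15),
                                           mid = c(16, 20),
                                           high = c(21, 25)),
                              dir = dir)
  pngs <- list.files(dir, pattern = "\\.png$")
  expect_length(pngs, 3)
  id <- bench$counts$trap_id[1]
  img <- read_image(file.path(dir, paste0(id, ".png")))
  expect_equal(dim(img), dim(bench$scenes[[id]]$image))
  rec <- read_annotations(file.path(dir, paste0(id, ".xml")))[[1]]
  expect_equal(nrow(rec$boxes), bench$counts$n_insects[1])
  expect_equal(rec$boxes$xmin, bench$scenes[[id]]$truth$xmin,
               tolerance = 1e-6)
  counts <- read.csv(file.path(dir, "counts.csv"))
  expect_equal(counts$n_insects, bench$counts$n_insects)
})
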