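# Seeded synthetic sticky-trap scenes: a bright yellow noisy background,
# dark rotated-ellipse insects (~60 px boxes at full scale), optional
# overlapping clusters, and bright elongated wing-like distractors that are
# rendered but never annotated. The generator is its own census: the truth
# list is exact, so generated scenes serve as ground truth for every
# pipeline stage.

#' Configure a synthetic trap scene
#'
#' Defaults emulate the original study's traps: 6000 x 4000 px images whose
#' insects have ground-truth boxes of 60 x 60 px on average. `scale` shrinks
#' the whole geometry (image, insects, margins) for fast tests while
#' preserving the insect:window ratio; 0.25 gives 1500 x 1000 images with
#' 15-px insects.
#'
#' @param n_insects Number of insects; the emitted truth has exactly this
#'   many boxes.
#' @param image_width,image_height Image size in px (before scaling).
#' @param insect_size Mean ground-truth box side, px (before scaling);
#'   default 60.
#' @param insect_size_sd Box-side standard deviation, px; default 4.
#' @param aspect_range Range of the insect ellipse minor:major axis ratio.
#' @param cluster_fraction Fraction of insects placed within one
#'   insect-diameter of a previously placed mate, producing overlapping
#'   clusters (the dominant source of missed insects). Insects outside
#'   clusters are placed with disjoint boxes, so `cluster_fraction = 0`
#'   gives fully separable scenes.
#' @param n_distractors Number of bright elongated wing-like shapes,
#'   rendered beneath the insects and never annotated.
#' @param background RGB of the yellow trap surface, each in `[0, 1]`.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param insect_colour Mean RGB of an insect body.
#' @param boundary_margin Minimum distance from any truth box to the image
#'   border, px (before scaling).
#' @param scale Linear scale factor applied to all geometry; default 1.
#' @param seed Integer seed; two scenes with the same configuration and
#'   seed are bit-identical.
#' @return A `scene_config` list.
#' @export
scene_config <- function(n_insects = 250,
                         image_width = 6000, image_height = 4000,
                         insect_size = 60, insect_size_sd = 4,
                         aspect_range = c(0.65, 0.95),
                         cluster_fraction = 0, n_distractors = 0,
                         background = c(0.98, 0.82, 0.15),
                         noise_sd = 0.02,
                         insect_colour = c(0.13, 0.09, 0.06),
                         boundary_margin = 8, scale = 1, seed = 1L) {
  stopifnot(n_insects >= 0, scale > 0,
            cluster_fraction >= 0, cluster_fraction <= 1,
            n_distractors >= 0, insect_size > 0)
  cfg <- list(
    n_insects = as.integer(n_insects),
    image_width = as.integer(round(image_width * scale)),
    image_height = as.integer(round(image_height * scale)),
    insect_size = insect_size * scale,
    insect_size_sd = insect_size_sd * scale,
    aspect_range = aspect_range,
    cluster_fraction = cluster_fraction,
    n_distractors = as.integer(n_distractors),
    background = background, noise_sd = noise_sd,
    insect_colour = insect_colour,
    boundary_margin = max(2, boundary_margin * scale),
    scale = scale, seed = as.integer(seed)
  )
  class(cfg) <- "scene_config"
  cfg
}

#' Density band of an insect count
#'
#' The evaluation traps are stratified by population: fewer than 300,
#' 300 to 500, and more than 500 insects per trap.
#'
#' @param n Insect count(s).
#' @return Factor with levels `low`, `mid`, `high`.
#' @export
density_band <- function(n) {
  cut(n, c(-Inf, 299.5, 500.5, Inf), labels = c("low", "mid", "high"))
}

#' Generate one synthetic trap scene
#'
#' @param config A [scene_config()].
#' @return A `trap_scene`: list with `image` (`h x w x 3` array in
#'   `[0, 1]`), `truth` (box data frame, one row per insect, all boxes
#'   inside the image), and `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, render_scene(config))
}

render_scene <- function(cfg) {
  W <- cfg$image_width; H <- cfg$image_height
  if (cfg$n_insects * cfg$insect_size^2 > 0.35 * W * H)
    stop("requested insect density is infeasible for the image area",
         call. = FALSE)
  img <- array(rep(cfg$background, each = W * H), dim = c(H, W, 3))

  # wing-like distractors first, so insect bodies always overwrite them
  if (cfg$n_distractors > 0) {
    for (i in seq_len(cfg$n_distractors)) {
      len <- stats::runif(1, 1.0, 1.8) * cfg$insect_size
      wid <- stats::runif(1, 0.25, 0.4) * cfg$insect_size
      th <- stats::runif(1, 0, pi)
      hw <- ellipse_half_extents(len / 2, wid / 2, th)
      cx <- stats::runif(1, hw[1], W - hw[1])
      cy <- stats::runif(1, hw[2], H - hw[2])
      img <- draw_ellipse(img, cx, cy, len / 2, wid / 2, th,
                          c(0.99, 0.99, 0.92))
    }
  }

  n <- cfg$n_insects
  truth <- data.frame(xmin = numeric(n), ymin = numeric(n),
                      xmax = numeric(n), ymax = numeric(n))
  if (n > 0) {
    n_cluster <- round(cfg$cluster_fraction * n)
    n_free <- n - n_cluster
    if (n_free == 0 && n_cluster > 0) { n_free <- 1; n_cluster <- n - 1 }
    geo <- insect_geometry(n, cfg)
    centres <- matrix(NA_real_, n, 2)
    m <- cfg$boundary_margin
    for (i in seq_len(n_free)) {
      hw <- geo$hw[i]; hh <- geo$hh[i]
      placed <- FALSE
      for (try in seq_len(400)) {
        cx <- stats::runif(1, m + hw, W - m - hw)
        cy <- stats::runif(1, m + hh, H - m - hh)
        # keep free insects' boxes disjoint (2 px gap) so isolated bodies
        # never merge into one blob
        if (i == 1 || !any(
          abs(cx - centres[seq_len(i - 1), 1]) <
            hw + geo$hw[seq_len(i - 1)] + 2 &
          abs(cy - centres[seq_len(i - 1), 2]) <
            hh + geo$hh[seq_len(i - 1)] + 2, na.rm = TRUE)) {
          centres[i, ] <- c(cx, cy); placed <- TRUE; break
        }
      }
      if (!placed)
        stop("requested insect density is infeasible for the image area",
             call. = FALSE)
    }
    if (n_cluster > 0) {
      d <- cfg$insect_size
      for (i in n_free + seq_len(n_cluster)) {
        hw <- geo$hw[i]; hh <- geo$hh[i]
        anchor <- centres[sample.int(i - 1, 1), ]
        for (try in seq_len(100)) {
          ang <- stats::runif(1, 0, 2 * pi)
          r <- stats::runif(1, 0.35, 1) * d
          cx <- min(max(anchor[1] + r * cos(ang), m + hw), W - m - hw)
          cy <- min(max(anchor[2] + r * sin(ang), m + hh), H - m - hh)
          if (is.finite(cx) && is.finite(cy)) break
        }
        centres[i, ] <- c(cx, cy)
      }
    }
    shade <- stats::runif(n, 0.8, 1.2)
    for (i in seq_len(n)) {
      img <- draw_ellipse(img, centres[i, 1], centres[i, 2],
                          geo$a[i], geo$b[i], geo$theta[i],
                          pmin(cfg$insect_colour * shade[i], 1))
      truth[i, ] <- c(centres[i, 1] - geo$hw[i], centres[i, 2] - geo$hh[i],
                      centres[i, 1] + geo$hw[i], centres[i, 2] + geo$hh[i])
    }
  }

  if (cfg$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, cfg$noise_sd), dim(img))
  img[img < 0] <- 0; img[img > 1] <- 1
  structure(list(image = img, truth = truth, config = cfg),
            class = "trap_scene")
}

# per-insect ellipse geometry: sizes drawn around the configured mean box
# side; semi-axes scaled so each insect's rotated-ellipse bounding box has
# (width + height)/2 equal to its drawn size
insect_geometry <- function(n, cfg) {
  s <- stats::rnorm(n, cfg$insect_size, cfg$insect_size_sd)
  s <- pmin(pmax(s, 0.5 * cfg$insect_size), 1.5 * cfg$insect_size)
  r <- stats::runif(n, cfg$aspect_range[1], cfg$aspect_range[2])
  theta <- stats::runif(n, 0, pi)
  ct <- cos(theta); st <- sin(theta)
  g <- sqrt(ct^2 + r^2 * st^2) + sqrt(st^2 + r^2 * ct^2)
  a <- s / g
  b <- r * a
  hw <- sqrt(a^2 * ct^2 + b^2 * st^2)
  hh <- sqrt(a^2 * st^2 + b^2 * ct^2)
  list(a = a, b = b, theta = theta, hw = hw, hh = hh)
}

ellipse_half_extents <- function(a, b, theta) {
  c(sqrt(a^2 * cos(theta)^2 + b^2 * sin(theta)^2),
    sqrt(a^2 * sin(theta)^2 + b^2 * cos(theta)^2))
}

# paint a filled rotated ellipse; pixel centres at (col - 0.5, row - 0.5)
# in 0-based image coordinates
draw_ellipse <- function(img, cx, cy, a, b, theta, colour) {
  H <- dim(img)[1]; W <- dim(img)[2]
  he <- ellipse_half_extents(a, b, theta)
  rows <- max(1, floor(cy - he[2])):min(H, ceiling(cy + he[2]) + 1)
  cols <- max(1, floor(cx - he[1])):min(W, ceiling(cx + he[1]) + 1)
  dx <- outer(rep(1, length(rows)), cols - 0.5 - cx)
  dy <- outer(rows - 0.5 - cy, rep(1, length(cols)))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  if (any(inside)) {
    ri <- row(inside)[inside]; ci <- col(inside)[inside]
    for (ch in 1:3)
      img[cbind(rows[ri], cols[ci], ch)] <- colour[ch]
  }
  img
}

#' Generate a stratified synthetic benchmark
#'
#' Emits a trap set stratified by population density -- `n_per_band` traps
#' in each of the low (< 300), mid (300-500) and high (> 500) bands,
#' mirroring the 10/10/10 design of the original counting evaluation -- with
#' per-trap manual-count surrogates equal to the generated insect number.
#' Rendered at 1/4 linear scale by default so a full benchmark builds in
#' seconds; pass `scale = 1` in `template` arguments for full 6000 x 4000
#' traps.
#'
#' @param n_per_band Traps per density band.
#' @param bands Named list of `c(min, max)` insect-count ranges.
#' @param seed Master seed; per-trap seeds are derived from it.
#' @param dir Optional output directory: writes `<trap>.png`, Pascal-VOC
#'   `<trap>.xml`, and `counts.csv`.
#' @param ... Overrides passed to [scene_config()] (e.g. `scale`,
#'   `cluster_fraction`, `n_distractors`).
#' @return A `trap_benchmark`: list with `scenes` (list of `trap_scene`)
#'   and `counts` (data frame `trap_id`, `band`, `n_insects`).
#' @export
generate_benchmark <- function(n_per_band = 10,
                               bands = list(low = c(150, 299),
                                            mid = c(300, 500),
                                            high = c(501, 650)),
                               seed = 1L, dir = NULL, ...) {
  args <- list(...)
  if (is.null(args$scale)) args$scale <- 0.25
  master <- as.integer(seed)
  scenes <- list()
  counts <- data.frame(trap_id = character(), band = character(),
                       n_insects = integer())
  idx <- 0
  for (band in names(bands)) {
    rng <- bands[[band]]
    ns <- with_seed((master + 613 * idx) %% .Machine$integer.max,
                    sample(rng[1]:rng[2], n_per_band, replace = TRUE))
    for (k in seq_len(n_per_band)) {
      idx <- idx + 1
      trap_id <- sprintf("trap_%s_%02d", band, k)
      cfg_args <- c(list(n_insects = ns[k],
                         seed = (master + 104729 * idx) %%
                           .Machine$integer.max),
                    args)
      sc <- generate_scene(do.call(scene_config, cfg_args))
      scenes[[trap_id]] <- sc
      counts <- rbind(counts,
                      data.frame(trap_id = trap_id, band = band,
                                 n_insects = ns[k]))
    }
  }
  out <- structure(list(scenes = scenes, counts = counts),
                   class = "trap_benchmark")
  if (!is.null(dir)) write_benchmark(out, dir)
  out
}

write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (trap_id in names(bench$scenes)) {
    sc <- bench$scenes[[trap_id]]
    write_image(sc$image, file.path(dir, paste0(trap_id, ".png")))
    rec <- annotation_record(trap_id, dim(sc$image)[2], dim(sc$image)[1],
                             sc$truth)
    write_annotations(rec, file.path(dir, paste0(trap_id, ".xml")),
                      format = "voc")
  }
  utils::write.csv(bench$counts, file.path(dir, "counts.csv"),
                   row.names = FALSE)
  invisible(dir)
}
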