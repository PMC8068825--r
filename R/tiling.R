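#' Compute the overlap-aware sliding-window grid over a large image
#'
#' Along each axis of length `L` the grid places windows of the configured
#' size every `stride = window_size - overlap` pixels; the final window is
#' clamped to end exactly at the image edge (offset `L - window_size`), so
#' every window has the full configured size and no padding is ever needed.
#' The number of windows per axis is `ceiling((L - window_size)/stride) + 1`.
#'
#' With the operating point used for trap counting (overlap 100 px, window
#' 500 or 1000 px) a 6000 x 4000 trap image is scanned by a 15 x 10 grid of
#' 150 windows, or a 7 x 5 grid of 35 windows. The 100-px overlap exceeds
#' the ~60-px insect size, so an insect cut at the edge of one window is
#' always fully contained in an adjacent window.
#'
#' @param image_width,image_height Image dimensions in pixels.
#' @param window_size Side of the square scanning window, in pixels.
#' @param overlap Minimum overlap between consecutive windows, in pixels
#'   (default 100). Must satisfy `0 <= overlap < window_size`.
#' @return A `window_grid` object: a list with `image_width`, `image_height`,
#'   `window_size`, `overlap`, `n_cols`, `n_rows`, and `windows`, a row-major
#'   data frame (rows outer, columns inner) with 0-based `col_index`,
#'   `row_index`, pixel `x_offset`, `y_offset`, `width`, `height`.
#' @examples
#' g <- compute_grid(6000, 4000, 500, 100)
#' g$n_cols * g$n_rows # 150
#' @export
compute_grid <- function(image_width, image_height, window_size,
                         overlap = 100) {
  stopifnot(image_width >= 1, image_height >= 1, window_size >= 1)
  if (window_size > min(image_width, image_height))
    stop("window_size (", window_size, ") exceeds the image (",
         image_width, " x ", image_height, ")", call. = FALSE)
  if (overlap < 0 || overlap >= window_size)
    stop("overlap must satisfy 0 <= overlap < window_size ",
         "(stride would be non-positive)", call. = FALSE)
  stride <- window_size - overlap
  axis_offsets <- function(L) {
    n <- ceiling((L - window_size) / stride) + 1
    off <- (seq_len(n) - 1) * stride
    off[n] <- L - window_size   # clamp the final window to the image edge
    off
  }
  xs <- axis_offsets(image_width)
  ys <- axis_offsets(image_height)
  windows <- data.frame(
    col_index = rep(seq_along(xs) - 1L, times = length(ys)),
    row_index = rep(seq_along(ys) - 1L, each = length(xs)),
    x_offset = rep(xs, times = length(ys)),
    y_offset = rep(ys, each = length(xs)),
    width = window_size, height = window_size
  )
  structure(
    list(image_width = image_width, image_height = image_height,
         window_size = window_size, overlap = overlap,
         n_cols = length(xs), n_rows = length(ys), windows = windows),
    class = "window_grid"
  )
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf(
    "window grid: %d x %d windows of %d px (overlap %d) over a %d x %d image\n",
    x$n_cols, x$n_rows, x$window_size, x$overlap,
    x$image_width, x$image_height))
  invisible(x)
}

#' @export
as.data.frame.window_grid <- function(x, ...) x$windows

#' Serialize a window grid to JSON
#'
#' Written into run logs so the scanning structure (e.g. 15 x 10 or 7 x 5)
#' of every processed image is auditable.
#'
#' @param grid A `window_grid`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
grid_to_json <- function(grid, path = NULL) {
  js <- jsonlite::toJSON(unclass(grid), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Extract one window's crop from an image
#'
#' @param image A numeric matrix (grayscale) or `h x w x channels` array with
#'   values in `[0, 1]`, as returned by [read_image()] or [generate_scene()].
#' @param w One row of `grid$windows`.
#' @return The `height x width` crop at the window's offset, same type as
#'   the input.
#' @export
extract_tile <- function(image, w) {
  dm <- dim(image)
  h <- dm[1]; wd <- dm[2]
  if (w$x_offset < 0 || w$y_offset < 0 ||
      w$x_offset + w$width > wd || w$y_offset + w$height > h)
    stop("window [", w$x_offset, ",", w$y_offset, "] + ", w$width, "x",
         w$height, " lies outside the ", wd, " x ", h, " image", call. = FALSE)
  rows <- (w$y_offset + 1):(w$y_offset + w$height)
  cols <- (w$x_offset + 1):(w$x_offset + w$width)
  if (length(dm) == 2) image[rows, cols, drop = FALSE]
  else image[rows, cols, , drop = FALSE]
}

#' Map window-local boxes to global image coordinates
#'
#' @param local A box or detection data frame in window-local coordinates.
#' @param w One row of `grid$windows`.
#' @return The same data frame translated by the window offset.
#' @export
to_global <- function(local, w) {
  local$xmin <- local$xmin + w$x_offset
  local$xmax <- local$xmax + w$x_offset
  local$ymin <- local$ymin + w$y_offset
  local$ymax <- local$ymax + w$y_offset
  local
}

#' Map global boxes to window-local coordinates
#'
#' Inverse of [to_global()].
#'
#' @inheritParams to_global
#' @param global A box or detection data frame in global image coordinates.
#' @export
to_local <- function(global, w) {
  global$xmin <- global$xmin - w$x_offset
  global$xmax <- global$xmax - w$x_offset
  global$ymin <- global$ymin - w$y_offset
  global$ymax <- global$ymax - w$y_offset
  global
}
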