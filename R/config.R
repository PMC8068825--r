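#' Pipeline configuration
#'
#' Bundles every tunable of the counting pipeline. The defaults reproduce
#' the trap-counting operating point: 500-px windows with 100-px overlap
#' (the fine scanning condition; `window_size = 1000` is the coarse one),
#' AP evaluation at IoU 0.5 and 0.3.
#'
#' @param window_size Scanning window side, px (500 or 1000 in the original
#'   design).
#' @param overlap Window overlap, px; default 100, chosen larger than the
#'   insect so an insect cut at one window's edge is whole in the next.
#' @param nms_iou Global NMS threshold.
#' @param edge_tolerance Interior-edge filter tolerance, px.
#' @param score_threshold Numeric threshold, or `"calibrate"` to fit it on
#'   calibration traps.
#' @param detector List: `type` (`"blob"` or `"oracle"`) plus that
#'   detector's parameters.
#' @param ap_iou IoU thresholds for AP reporting.
#' @param seed Integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(window_size = 500, overlap = 100,
                            nms_iou = 0.5, edge_tolerance = 1,
                            score_threshold = 0.5,
                            detector = list(type = "blob"),
                            ap_iou = c(0.3, 0.5), seed = 1L) {
  if (!identical(score_threshold, "calibrate"))
    stopifnot(is.numeric(score_threshold), score_threshold >= 0,
              score_threshold <= 1)
  stopifnot(overlap >= 0, overlap < window_size)
  structure(list(window_size = window_size, overlap = overlap,
                 nms_iou = nms_iou, edge_tolerance = edge_tolerance,
                 score_threshold = score_threshold, detector = detector,
                 ap_iou = ap_iou, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

#' Build a detector from a pipeline configuration
#'
#' @param config A `pipeline_config`.
#' @param truth Global truth boxes; required when `detector$type` is
#'   `"oracle"`.
#' @return A detector object.
#' @export
config_detector <- function(config, truth = NULL) {
  d <- config$detector
  type <- if (is.null(d$type)) "blob" else d$type
  pars <- d[setdiff(names(d), "type")]
  if (type == "blob") {
    do.call(blob_detector, pars)
  } else if (type == "oracle") {
    if (is.null(truth))
      stop("the oracle detector needs ground-truth boxes", call. = FALSE)
    if (is.null(pars$seed)) pars$seed <- config$seed
    do.call(oracle_detector, c(list(truth = truth), pars))
  } else {
    stop("unknown detector type: ", type, call. = FALSE)
  }
}

resolved_config_json <- function(config, extra = list()) {
  jsonlite::toJSON(c(unclass(config), extra), auto_unbox = TRUE,
                   digits = NA)
}
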