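#' Read a raster image
#'
#' PNG is read natively; TIFF/JPEG fall back to EBImage's readers.
#'
#' @param path Image file path.
#' @return Numeric `h x w x 3` array (or matrix for grayscale) in `[0, 1]`;
#'   an alpha channel, if present, is dropped.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else {
    a <- EBImage::imageData(EBImage::readImage(path))
    img <- if (length(dim(a)) == 2) t(a) else aperm(a, c(2, 1, 3))
  }
  if (length(dim(img)) == 3 && dim(img)[3] > 3)
    img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an image as PNG
#'
#' @param image Numeric matrix or `h x w x 3` array in `[0, 1]`.
#' @param path Output path.
#' @export
write_image <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' Create an annotation record
#'
#' One annotated image: identifier, pixel extent, and labelled ground-truth
#' boxes in the package's 0-based half-open convention.
#'
#' @param image_id Image identifier (file stem).
#' @param width,height Image extent in px.
#' @param boxes Box data frame.
#' @param label Category label(s), recycled over boxes.
#' @return An `annotation_record` list.
#' @export
annotation_record <- function(image_id, width, height, boxes,
                              label = "insect") {
  validate_boxes(boxes)
  if (nrow(boxes) > 0 &&
      (any(boxes$xmin < 0) || any(boxes$ymin < 0) ||
       any(boxes$xmax > width) || any(boxes$ymax > height)))
    stop("annotation boxes fall outside the ", width, " x ", height,
         " image", call. = FALSE)
  boxes <- boxes[, c("xmin", "ymin", "xmax", "ymax"), drop = FALSE]
  if (nrow(boxes) > 0) boxes$label <- label
  else boxes$label <- character(0)
  structure(list(image_id = as.character(image_id), width = width,
                 height = height, boxes = boxes),
            class = "annotation_record")
}

#' Write annotations
#'
#' `"voc"` writes one Pascal-VOC-style XML file per record using the
#' conventional 1-based inclusive pixel coordinates (`xmin + 1`, `ymin + 1`,
#' `xmax`, `ymax`); `"coco"` writes one COCO-style JSON file holding all
#' records with 0-based `[x, y, width, height]` boxes. Reading either file
#' back reproduces the records exactly.
#'
#' @param records An `annotation_record` or list of them.
#' @param path Output file (VOC: a single record's XML; COCO: the JSON).
#' @param format `"voc"` or `"coco"`.
#' @export
write_annotations <- function(records, path, format = c("voc", "coco")) {
  format <- match.arg(format)
  if (inherits(records, "annotation_record")) records <- list(records)
  if (format == "voc") {
    if (length(records) != 1)
      stop("VOC XML holds one image per file; write records separately",
           call. = FALSE)
    write_voc_xml(records[[1]], path)
  } else {
    write_coco_json(records, path)
  }
  invisible(path)
}

write_voc_xml <- function(rec, path) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", rec$image_id)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", format(rec$width))
  xml2::xml_add_child(size, "height", format(rec$height))
  xml2::xml_add_child(size, "depth", "3")
  b <- rec$boxes
  for (i in seq_len(nrow(b))) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", b$label[i])
    bb <- xml2::xml_add_child(obj, "bndbox")
    # VOC dialect: 1-based inclusive corners
    xml2::xml_add_child(bb, "xmin", num_str(b$xmin[i] + 1))
    xml2::xml_add_child(bb, "ymin", num_str(b$ymin[i] + 1))
    xml2::xml_add_child(bb, "xmax", num_str(b$xmax[i]))
    xml2::xml_add_child(bb, "ymax", num_str(b$ymax[i]))
  }
  xml2::write_xml(doc, path)
}

num_str <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

write_coco_json <- function(records, path) {
  images <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    list(id = i, file_name = r$image_id, width = r$width, height = r$height)
  })
  anns <- list(); aid <- 0
  labels <- sort(unique(unlist(lapply(records,
                                      function(r) r$boxes$label))))
  if (length(labels) == 0) labels <- "insect"
  for (i in seq_along(records)) {
    b <- records[[i]]$boxes
    for (k in seq_len(nrow(b))) {
      aid <- aid + 1
      anns[[aid]] <- list(
        id = aid, image_id = i,
        category_id = match(b$label[k], labels),
        bbox = c(b$xmin[k], b$ymin[k],
                 b$xmax[k] - b$xmin[k], b$ymax[k] - b$ymin[k]),
        area = (b$xmax[k] - b$xmin[k]) * (b$ymax[k] - b$ymin[k]),
        iscrowd = 0)
    }
  }
  cats <- lapply(seq_along(labels),
                 function(i) list(id = i, name = labels[i]))
  jsonlite::write_json(list(images = images, annotations = anns,
                            categories = cats),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Read annotations
#'
#' Coordinates are normalized to the package's 0-based half-open convention
#' whatever the source dialect: VOC's 1-based inclusive corners become
#' `(xmin - 1, ymin - 1, xmax, ymax)`; COCO's `[x, y, w, h]` become corner
#' coordinates directly.
#'
#' @param path Annotation file (`.xml` for VOC, `.json` for COCO).
#' @param format `"auto"` (by extension), `"voc"`, or `"coco"`.
#' @return A list of `annotation_record` objects (VOC files yield one).
#' @export
read_annotations <- function(path, format = c("auto", "voc", "coco")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "xml") "voc" else "coco"
  recs <- if (format == "voc") list(read_voc_xml(path))
          else read_coco_json(path)
  for (r in recs) {
    if (nrow(r$boxes) > 0 &&
        (any(r$boxes$xmax > r$width) || any(r$boxes$ymax > r$height) ||
         any(r$boxes$xmin < 0) || any(r$boxes$ymin < 0)))
      stop("annotation boxes outside image bounds in ", path, " (image ",
           r$image_id, ")", call. = FALSE)
  }
  recs
}

read_voc_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed VOC XML at ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  num_field <- function(node, what) {
    v <- suppressWarnings(as.numeric(xml2::xml_text(
      xml2::xml_find_first(node, what))))
    if (is.na(v))
      stop("malformed VOC record in ", path, ": missing or non-numeric <",
           what, ">", call. = FALSE)
    v
  }
  size <- xml2::xml_find_first(doc, "size")
  width <- num_field(size, "width"); height <- num_field(size, "height")
  objs <- xml2::xml_find_all(doc, "object")
  boxes <- data.frame(xmin = numeric(), ymin = numeric(), xmax = numeric(),
                      ymax = numeric(), label = character())
  for (o in objs) {
    bb <- xml2::xml_find_first(o, "bndbox")
    boxes <- rbind(boxes, data.frame(
      xmin = num_field(bb, "xmin") - 1,   # 1-based inclusive -> 0-based
      ymin = num_field(bb, "ymin") - 1,
      xmax = num_field(bb, "xmax"),
      ymax = num_field(bb, "ymax"),
      label = xml2::xml_text(xml2::xml_find_first(o, "name"))))
  }
  rec <- annotation_record(
    xml2::xml_text(xml2::xml_find_first(doc, "filename")),
    width, height, boxes[, 1:4, drop = FALSE],
    label = if (nrow(boxes)) boxes$label else "insect")
  rec
}

read_coco_json <- function(path) {
  j <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop("malformed COCO JSON at ", path,
                                         ": ", conditionMessage(e),
                                         call. = FALSE))
  cats <- stats::setNames(
    vapply(j$categories, function(c) c$name, character(1)),
    vapply(j$categories, function(c) as.character(c$id), character(1)))
  lapply(j$images, function(im) {
    anns <- Filter(function(a) a$image_id == im$id, j$annotations)
    boxes <- data.frame(xmin = numeric(), ymin = numeric(),
                        xmax = numeric(), ymax = numeric())
    labels <- character()
    for (a in anns) {
      bb <- unlist(a$bbox)
      boxes <- rbind(boxes, data.frame(xmin = bb[1], ymin = bb[2],
                                       xmax = bb[1] + bb[3],
                                       ymax = bb[2] + bb[4]))
      labels <- c(labels, cats[[as.character(a$category_id)]])
    }
    annotation_record(im$file_name, im$width, im$height, boxes,
                      label = if (nrow(boxes)) labels else "insect")
  })
}

#' Write detections as COCO-style results JSON
#'
#' The interchange format is the COCO results convention: a flat array of
#' `{image_id, category_id, bbox = [x, y, width, height], score}`.
#'
#' @param dets Detection data frame.
#' @param path Output path.
#' @param image_id Image identifier stored with every detection.
#' @export
write_detections <- function(dets, path, image_id = "trap") {
  res <- lapply(seq_len(nrow(dets)), function(i) {
    list(image_id = image_id, category_id = 1,
         bbox = c(dets$xmin[i], dets$ymin[i],
                  dets$xmax[i] - dets$xmin[i],
                  dets$ymax[i] - dets$ymin[i]),
         score = dets$score[i])
  })
  jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO-style results JSON into a detection data frame
#'
#' @param path Detections JSON path.
#' @return Detection data frame (corner coordinates plus `score`, `label`).
#' @export
read_detections <- function(path) {
  j <- jsonlite::read_json(path)
  if (length(j) == 0) return(empty_detections())
  rows <- lapply(j, function(d) {
    bb <- unlist(d$bbox)
    data.frame(xmin = bb[1], ymin = bb[2], xmax = bb[1] + bb[3],
               ymax = bb[2] + bb[4], score = d$score, label = "insect")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a per-trap counts CSV
#'
#' @param results List of `trap_count` objects, or a data frame with at
#'   least `trap_id` and `count`.
#' @param path Output path.
#' @export
write_counts_csv <- function(results, path) {
  df <- if (is.data.frame(results)) results else
    do.call(rbind, lapply(results, function(r)
      data.frame(trap_id = r$trap_id, count = r$count,
                 score_threshold = r$score_threshold,
                 window_size = r$grid$window_size,
                 overlap = r$grid$overlap,
                 n_cols = r$grid$n_cols, n_rows = r$grid$n_rows)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
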