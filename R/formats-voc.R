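#' Read a Pascal VOC XML annotation file
#'
#' VOC stores boxes as 1-based inclusive pixel coordinates. They are converted
#' to the internal 0-based half-open convention on the way in:
#' `x_min = xmin_voc - 1`, `x_max = xmax_voc` (and likewise for y), so a VOC
#' box `xmin=1, ymin=1, xmax=10, ymax=10` becomes the internal
#' `Box(0, 0, 10, 10)` of area 100.
#'
#' @param path Path to a VOC XML file.
#' @param class_table Named character vector mapping label strings to
#'   `"focal"`/`"gfp"`; see [default_class_table()]. Unknown labels are an
#'   error listing the offending names.
#' @return A [worm_annotation()].
#' @seealso [write_voc_xml()] for the exact inverse.
#' @export
read_voc_xml <- function(path, class_table = default_class_table()) {
  doc <- xml2::read_xml(path)
  image_id <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  if (is.na(image_id) || !nzchar(image_id)) {
    image_id <- tools::file_path_sans_ext(basename(path))
  }
  width <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "./size/width")))
  height <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "./size/height")))
  if (is.na(width) || is.na(height)) {
    stop("VOC file ", path, " is missing <size><width>/<height>")
  }
  objs <- xml2::xml_find_all(doc, "./object")
  if (length(objs) == 0L) {
    return(worm_annotation(image_id, width, height))
  }
  num <- function(node, tag) {
    as.numeric(xml2::xml_text(xml2::xml_find_first(node, paste0("./bndbox/", tag))))
  }
  labels <- vapply(objs, function(o) {
    xml2::xml_text(xml2::xml_find_first(o, "./name"))
  }, character(1))
  objects <- data.frame(
    x_min = vapply(objs, num, numeric(1), tag = "xmin") - 1,
    y_min = vapply(objs, num, numeric(1), tag = "ymin") - 1,
    x_max = vapply(objs, num, numeric(1), tag = "xmax"),
    y_max = vapply(objs, num, numeric(1), tag = "ymax"),
    class = map_class_names(labels, class_table),
    stringsAsFactors = FALSE
  )
  worm_annotation(image_id, width, height, objects)
}

#' Write a Pascal VOC XML annotation file
#'
#' Writes the exact inverse conversion of [read_voc_xml()]
#' (`xmin_voc = x_min + 1`, `xmax_voc = x_max`), so a read/write round trip
#' reproduces boxes exactly.
#'
#' @param ann A [worm_annotation()].
#' @param path Output file path.
#' @param class_names Named character vector giving the label string to write
#'   for each internal class.
#' @return `path`, invisibly.
#' @export
write_voc_xml <- function(ann, path,
                          class_names = c(focal = "focal", gfp = "gfp")) {
  stopifnot(inherits(ann, "worm_annotation"))
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", ann$image_id)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", format(ann$width))
  xml2::xml_add_child(size, "height", format(ann$height))
  xml2::xml_add_child(size, "depth", "1")
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  for (i in seq_len(nrow(ann$objects))) {
    o <- ann$objects[i, ]
    node <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(node, "name", class_names[[o$class]])
    xml2::xml_add_child(node, "difficult", "0")
    bb <- xml2::xml_add_child(node, "bndbox")
    xml2::xml_add_child(bb, "xmin", fmt(o$x_min + 1))
    xml2::xml_add_child(bb, "ymin", fmt(o$y_min + 1))
    xml2::xml_add_child(bb, "xmax", fmt(o$x_max))
    xml2::xml_add_child(bb, "ymax", fmt(o$y_max))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
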