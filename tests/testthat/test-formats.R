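make_ann <- function(id = "img_a", n = 2) {
  objects <- data.frame(
    x_min = c(0, 40), y_min = c(0, 50), x_max = c(10, 70), y_max = c(10, 90),
    class = c("focal", "gfp")
  )[seq_len(n), , drop = FALSE]
  worm_annotation(id, 200, 150, objects)
}

test_that("VOC coordinates convert between 1-based inclusive and half-open", {
  path <- withr::local_tempfile(fileext = ".xml")
  xml2::write_xml(xml2::read_xml(paste0(
    "<annotation><filename>v1</filename>",
    "<size><width>100</width><height>80</height></size>",
    "<object><name>elegans</name><bndbox>",
    "<xmin>1</xmin><ymin>1</ymin><xmax>10</xmax><ymax>10</ymax>",
    "</bndbox></object></annotation>"
  )), path)
  ann <- read_voc_xml(path)
  expect_equal(ann$objects$x_min, 0)
  expect_equal(ann$objects$y_min, 0)
  expect_equal(ann$objects$x_max, 10)
  expect_equal(ann$objects$y_max, 10)
  expect_equal(box_area(ann$objects), 100)
  expect_equal(ann$objects$class, "focal")
})

test_that("VOC write/read round-trips boxes exactly, including empty files", {
  path <- withr::local_tempfile(fileext = ".xml")
  ann <- make_ann()
  write_voc_xml(ann, path)
  back <- read_voc_xml(path)
  expect_equal(back$objects, ann$objects)
  expect_equal(back$image_id, ann$image_id)
  # internal Box(0,0,10,10) is written as VOC xmin=1, xmax=10
  doc <- xml2::read_xml(path)
  expect_equal(xml2::xml_text(xml2::xml_find_first(doc, "//bndbox/xmin")), "1")
  expect_equal(xml2::xml_text(xml2::xml_find_first(doc, "//bndbox/xmax")), "10")
  expect_equal(length(xml2::xml_find_all(doc, "//object")), 2L)

  empty <- worm_annotation("none", 50, 50)
  write_voc_xml(empty, path)
  expect_equal(nrow(read_voc_xml(path)$objects), 0L)
})

test_that("unknown VOC class names fail loudly, naming the offenders", {
  path <- withr::local_tempfile(fileext = ".xml")
  xml2::write_xml(xml2::read_xml(paste0(
    "<annotation><filename>v2</filename>",
    "<size><width>100</width><height>80</height></size>",
    "<object><name>mystery</name><bndbox>",
    "<xmin>1</xmin><ymin>1</ymin><xmax>10</xmax><ymax>10</ymax>",
    "</bndbox></object></annotation>"
  )), path)
  expect_error(read_voc_xml(path), "mystery")
  # but a custom table can map it
  ann <- read_voc_xml(path, class_table = c(mystery = "gfp"))
  expect_equal(ann$objects$class, "gfp")
})

test_that("COCO bbox [x, y, w, h] maps to Box(x, y, x+w, y+h) and round-trips", {
  path <- withr::local_tempfile(fileext = ".json")
  anns <- list(make_ann("c1"), make_ann("c2", n = 1))
  write_coco_json(anns, path)
  back <- read_coco_json(path)
  expect_length(back, 2L)
  expect_equal(back[["c1"]]$objects, anns[[1]]$objects)
  expect_equal(back[["c2"]]$objects, anns[[2]]$objects)
  expect_equal(sum(vapply(back, function(a) nrow(a$objects), integer(1))), 3L)
  # idempotent round trip
  path2 <- withr::local_tempfile(fileext = ".json")
  write_coco_json(back, path2)
  expect_equal(read_coco_json(path2), back)
  # raw bbox check
  coco <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  bb <- as.numeric(unlist(coco$annotations[[1]]$bbox))
  expect_equal(bb, c(0, 0, 10, 10))
})

test_that("the same boxes read through VOC and COCO are identical", {
  ann <- make_ann("both")
  voc <- withr::local_tempfile(fileext = ".xml")
  coco <- withr::local_tempfile(fileext = ".json")
  write_voc_xml(ann, voc)
  write_coco_json(list(ann), coco)
  expect_equal(read_voc_xml(voc)$objects, read_coco_json(coco)[[1]]$objects)
})

test_that("COCO annotations referencing a missing image id are an error", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    images = list(list(id = 1, file_name = "a", width = 10, height = 10)),
    annotations = list(list(id = 1, image_id = 99, category_id = 1,
                            bbox = c(0, 0, 2, 2))),
    categories = list(list(id = 1, name = "focal"))
  ), path, auto_unbox = TRUE)
  expect_error(read_coco_json(path), "99")
})

test_that("counts CSV round-trips and rejects duplicate image ids", {
  path <- withr::local_tempfile(fileext = ".csv")
  counts <- data.frame(image = c("img1", "img2"), focal = c(3L, 0L),
                       gfp = c(1L, 7L))
  write_counts_csv(counts, path)
  expect_equal(readLines(path)[1:2], c("image,focal,gfp", "img1,3,1"))
  expect_equal(read_counts_csv(path), counts)
  expect_error(
    write_counts_csv(data.frame(image = c("x", "x"), focal = 1, gfp = 1), path),
    "duplicate"
  )
})

test_that("detections CSV round-trips all fields exactly on integer boxes", {
  path <- withr::local_tempfile(fileext = ".csv")
  det <- worm_detections("img9", data.frame(
    class = c("focal", "gfp", "focal", "gfp", "focal"),
    x_min = c(0, 10, 20, 30, 40), y_min = c(1, 11, 21, 31, 41),
    x_max = c(5, 15, 25, 35, 45), y_max = c(6, 16, 26, 36, 46),
    confidence = c(0.5, 0.75, 1.0, 0.9, 0.625)
  ))
  write_detections_csv(det, path)
  back <- read_detections_csv(path)
  expect_length(back, 1L)
  expect_equal(back[["img9"]]$detections, det$detections)
  expect_identical(back[["img9"]]$detections$confidence[3], 1.0)
})

test_that("instance masks are written one per worm and read back losslessly", {
  cfg <- sim_config(n_worms = 3, image_width = 200, image_height = 160,
                    focal_fraction = 1, cluster_fraction = 0, seed = 11)
  scene <- sample_scene(cfg, image_id = "m1")
  dir <- withr::local_tempdir()
  paths <- write_instance_masks(scene, dir)
  expect_length(paths, 3L)
  m <- read_instance_mask(paths[[2]])
  expect_equal(dim(m), c(160, 200))
  expect_equal(sum(m), length(scene$worms[[2]]$mask_idx))
  expect_equal(which(m), scene$worms[[2]]$mask_idx)
  # empty selection writes nothing
  expect_length(write_instance_masks(scene, dir, which = integer(0)), 0L)
  # non-rasterised scenes cannot provide masks
  scene2 <- sample_scene(cfg, rasterize = FALSE)
  expect_error(write_instance_masks(scene2, dir), "rasteris")
})
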