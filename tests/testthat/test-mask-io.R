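test_that("COCO JSON round-trips instances losslessly", {
  sc <- generate_scene(3, seed = 11, image_size = c(140, 180),
                       length_range = c(30, 60), radius_range = c(3, 5))
  f <- withr::local_tempfile(fileext = ".json")
  write_instances(sc$instances, f, "coco_json")
  back <- read_instances(f, "coco_json")
  expect_length(back, 3L)
  expect_true(all(vapply(back, function(b) b$image_id == "scene", logical(1))))
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$mask, sc$instances[[i]]$mask)
    expect_equal(back[[i]]$bbox, sc$instances[[i]]$bbox)
  }
})

test_that("mask-folder dialect preserves amodal overlaps", {
  sc <- generate_scene(4, overlap_fraction = 0.5, seed = 21,
                       image_size = c(150, 190),
                       length_range = c(35, 60), radius_range = c(3.5, 5))
  shared <- sum(sc$instances[[1]]$mask & sc$instances[[2]]$mask)
  expect_gt(shared, 0)  # the designated pair overlaps
  d <- withr::local_tempdir()
  write_instances(sc$instances, d, "mask_folder")
  back <- read_instances(d, "mask_folder")
  expect_length(back, 4L)
  expect_identical(sum(back[[1]]$mask & back[[2]]$mask), shared)
  for (i in seq_along(back))
    expect_identical(back[[i]]$mask, sc$instances[[i]]$mask)
})

test_that("instance counts are conserved across dialect conversion", {
  sc <- generate_scene(5, seed = 31, image_size = c(150, 190),
                       length_range = c(30, 55), radius_range = c(3, 5))
  d <- withr::local_tempdir()
  f <- file.path(d, "coco.json")
  write_instances(sc$instances, f, "coco_json")
  md <- file.path(d, "masks")
  write_instances(read_instances(f, "coco_json"), md, "mask_folder")
  f2 <- file.path(d, "coco2.json")
  write_instances(read_instances(md, "mask_folder"), f2, "coco_json")
  expect_length(read_instances(f2, "coco_json"), 5L)
})

test_that("a stored bbox that misses foreground pixels is recomputed", {
  m <- matrix(0L, 20, 20)
  m[5:10, 5:15] <- 1L
  expect_warning(
    inst <- instance_mask(m, "a", bbox = c(4, 4, 10, 6)),  # misses col 16
    "recomputed")
  expect_equal(unname(inst$bbox), c(4, 4, 11, 6))
  # a correct enclosing (even loose) bbox is kept
  expect_silent(inst2 <- instance_mask(m, "b", bbox = c(3, 3, 14, 9)))
  expect_equal(inst2$bbox, c(3, 3, 14, 9))
})

test_that("empty and malformed inputs are reported, not silently dropped", {
  expect_error(read_instances(tempfile(), "coco_json"), "does not exist")
  expect_error(instance_mask(matrix(0L, 4, 4), "e"), "no foreground")
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(read_instances(bad, "coco_json"), "malformed JSON")
  # an annotation decoding to an empty mask warns and is skipped
  doc <- list(
    images = list(list(id = "im", height = 4L, width = 4L)),
    annotations = list(
      list(id = "ok", image_id = "im",
           segmentation = list(size = c(4L, 4L), counts = c(5L, 2L, 9L))),
      list(id = "empty", image_id = "im",
           segmentation = list(size = c(4L, 4L), counts = c(16L)))))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_warning(out <- read_instances(f, "coco_json"), "empty")
  expect_length(out, 1L)
  expect_identical(out[[1]]$instance_id, "ok")
})

test_that("compressed RLE strings and polygons decode", {
  # string codec round-trips arbitrary count vectors
  withr::with_seed(1, {
    for (k in 1:25) {
      counts <- c(sample(0:3, 1), sample(1:5000, sample(1:25, 1)))
      s <- siliquant:::rle_string_encode(counts)
      expect_equal(as.numeric(siliquant:::rle_string_decode(s)),
                   as.numeric(counts))
    }
  })
  # a mask survives encode -> string -> decode
  m <- generate_capsule(straight_capsule(30, 3))$instance$mask
  r <- siliquant:::mask_to_rle(m)
  dec <- siliquant:::rle_to_mask(
    siliquant:::rle_string_decode(siliquant:::rle_string_encode(r$counts)),
    r$size)
  expect_identical(dec, m)
  # an axis-aligned polygon fills the expected pixel block
  doc <- list(
    images = list(list(id = "im", height = 10L, width = 10L)),
    annotations = list(list(
      id = "poly", image_id = "im",
      segmentation = list(list(c(2, 3, 7, 3, 7, 6, 2, 6))))))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  inst <- read_instances(f, "coco_json")[[1]]
  # half-open fill: pixel centres x in [2, 7), y in [3, 6)
  expect_equal(unname(inst$bbox), c(2, 3, 5, 3))
  expect_equal(sum(inst$mask), 15)
})

test_that("manifest validation enforces the treatment vocabulary and dpi", {
  d <- withr::local_tempdir()
  f <- file.path(d, "m.csv")
  base <- data.frame(sample_id = c("s1", "s2"), genotype = c("g1", "g2"),
                     treatment = c("isolation", "group"), batch = 1:2)
  write.csv(base, f, row.names = FALSE)
  expect_warning(m <- read_manifest(f), "300 dpi")
  expect_equal(m$dpi, c(300, 300))

  base$dpi <- c(300, NA)
  write.csv(base, f, row.names = FALSE)
  expect_warning(m <- read_manifest(f), "blank dpi")
  expect_equal(m$dpi, c(300, 300))

  bad <- base; bad$dpi <- 300; bad$treatment[2] <- "triplet"
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_manifest(f), "row\\(s\\) 2")

  dup <- base; dup$dpi <- 300; dup$sample_id <- c("s1", "s1")
  write.csv(dup, f, row.names = FALSE)
  expect_error(read_manifest(f), "duplicate sample_id")
})

test_that("trait tables round-trip, keep rejected rows, and handle 0 records", {
  rows <- data.frame(
    instance_id = sprintf("i%02d", 1:10), image_id = "im",
    sample_id = "s1", score = round(runif(10), 4),
    qc_status = c(rep("accepted", 8), "rejected", "rejected"),
    qc_reason = c(rep(NA, 8), "multi_component", "residual_spur"),
    area_mm2 = c(runif(8, 5, 20), NA, NA),
    length_mm = c(runif(8, 8, 16), NA, NA),
    diameter_mm = c(runif(8, 0.5, 1.5), NA, NA),
    volume_mm3 = c(runif(8, 3, 12), NA, NA))
  f <- withr::local_tempfile(fileext = ".csv")
  write_traits_table(rows, f)
  back <- read_traits_table(f)
  expect_equal(nrow(back), 10L)
  for (cc in c("area_mm2", "length_mm", "diameter_mm", "volume_mm3"))
    expect_equal(back[[cc]], rows[[cc]], tolerance = 1e-6)
  expect_equal(back$qc_reason[9:10], c("multi_component", "residual_spur"))
  expect_true(all(is.na(back$area_mm2[9:10])))

  empty <- rows[0, ]
  write_traits_table(empty, f)
  back0 <- read_traits_table(f)
  expect_equal(nrow(back0), 0L)
  expect_true(all(c("instance_id", "qc_reason", "volume_mm3") %in% names(back0)))
})
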