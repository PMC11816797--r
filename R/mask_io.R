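# Instance mask I/O: COCO-style instance JSON, per-instance mask folders,
# sample manifests, and trait tables.

#' Construct an instance mask
#'
#' An `instance_mask` holds one detected or annotated silique: a full-frame
#' binary raster, its tight bounding box, a confidence score, and linkage to
#' the image it came from. Masks are amodal: overlapping instances may share
#' foreground pixels, which is why each instance carries its own raster
#' rather than a shared label image.
#'
#' @param mask binary matrix (`[row, col]`, row = y + 1); nonzero = foreground.
#' @param instance_id,image_id identifiers (coerced to character).
#' @param bbox optional 0-based `(x, y, w, h)` box. If absent, or if it fails
#'   to enclose every foreground pixel, the tight pixel bounds are
#'   (re)computed (with a warning in the latter case).
#' @param score confidence in `[0, 1]`; ground-truth annotations use 1.
#' @param category class label; this study has the single class `"silique"`.
#' @return an object of class `instance_mask`.
#' @export
instance_mask <- function(mask, instance_id, image_id = "image", bbox = NULL,
                          score = 1.0, category = "silique") {
  mask <- as_binary_matrix(mask)
  if (!any(mask == 1L)) stop("instance mask has no foreground pixels")
  if (!is.numeric(score) || length(score) != 1L || is.na(score) ||
      score < 0 || score > 1)
    stop("score must be a single value in [0, 1]")
  tight <- mask_bbox(mask)
  if (is.null(bbox)) {
    bbox <- tight
  } else {
    bbox <- as.numeric(bbox)
    if (length(bbox) != 4L) stop("bbox must be (x, y, w, h)")
    if (!bbox_contains_mask(bbox, mask)) {
      warning("stored bbox does not enclose the mask; recomputed from pixels")
      bbox <- tight
    }
  }
  structure(list(instance_id = as.character(instance_id),
                 image_id = as.character(image_id),
                 mask = mask,
                 bbox = as.numeric(bbox),
                 score = as.numeric(score),
                 category = as.character(category)),
            class = "instance_mask")
}

#' @export
print.instance_mask <- function(x, ...) {
  cat(sprintf("<instance_mask %s @ %s: %d px, bbox (%g, %g, %g, %g), score %.3f>\n",
              x$instance_id, x$image_id, sum(x$mask), x$bbox[1], x$bbox[2],
              x$bbox[3], x$bbox[4], x$score))
  invisible(x)
}

## ---- COCO run-length encoding --------------------------------------------

# COCO RLE flattens the h x w mask in column-major order (identical to R's
# own layout) and stores alternating background/foreground run lengths,
# always starting with background.

rle_to_mask <- function(counts, size) {
  h <- size[1L]; w <- size[2L]
  counts <- as.numeric(counts)
  if (sum(counts) != h * w)
    stop("RLE counts sum to ", sum(counts), ", expected ", h * w)
  vals <- rep(rep_len(c(0L, 1L), length(counts)), counts)
  matrix(vals, nrow = h, ncol = w)
}

mask_to_rle <- function(mask) {
  r <- rle(as.integer(mask))
  counts <- r$lengths
  if (length(r$values) > 0L && r$values[1L] == 1L) counts <- c(0L, counts)
  list(size = c(nrow(mask), ncol(mask)), counts = as.integer(counts))
}

# Compressed COCO RLE strings: each run length (delta-coded against the
# count two places back, from the third count on) is stored as a signed
# varint in 5-bit chunks offset into printable ASCII by 48; bit 0x20 is the
# continuation flag and bit 0x10 of the final chunk carries the sign.
rle_string_decode <- function(s) {
  bytes <- as.integer(charToRaw(s)) - 48L
  counts <- numeric(0)
  p <- 1L; m <- 0L
  while (p <= length(bytes)) {
    x <- 0; k <- 0L
    repeat {
      ch <- bytes[p]
      x <- x + (ch %% 32L) * 32^k
      p <- p + 1L; k <- k + 1L
      if (ch < 32L) {                    # no continuation bit
        if (ch %% 32L >= 16L) x <- x - 32^k
        break
      }
    }
    m <- m + 1L
    if (m > 2L) x <- x + counts[m - 2L]
    counts[m] <- x
  }
  counts
}

rle_string_encode <- function(counts) {
  bytes <- integer(0)
  m <- length(counts)
  for (i in seq_len(m)) {
    x <- as.numeric(counts[i])
    if (i > 2L) x <- x - as.numeric(counts[i - 2L])
    repeat {
      ch <- x %% 32                      # low 5 bits, two's-complement style
      x <- (x - ch) / 32                 # arithmetic shift right by 5
      more <- if (ch >= 16) x != -1 else x != 0
      if (more) ch <- ch + 32
      bytes <- c(bytes, ch + 48)
      if (!more) break
    }
  }
  rawToChar(as.raw(bytes))
}

# Even-odd scanline fill of a COCO polygon ring ([x1, y1, x2, y2, ...]) onto
# an h x w grid; a pixel is foreground when its centre lies inside the ring.
polygon_to_mask <- function(xy, h, w) {
  xs <- xy[seq(1L, length(xy), 2L)]
  ys <- xy[seq(2L, length(xy), 2L)]
  n <- length(xs)
  mask <- matrix(0L, h, w)
  rows <- max(1L, floor(min(ys)) + 1L):min(h, ceiling(max(ys)) + 1L)
  x2 <- c(xs[-1L], xs[1L]); y2 <- c(ys[-1L], ys[1L])
  for (row in rows) {
    yc <- row - 1L # pixel-centre y
    crosses <- (ys <= yc & y2 > yc) | (y2 <= yc & ys > yc)
    if (!any(crosses)) next
    xi <- xs[crosses] + (yc - ys[crosses]) *
      (x2[crosses] - xs[crosses]) / (y2[crosses] - ys[crosses])
    xi <- sort(xi)
    for (k in seq(1L, length(xi) - 1L, by = 2L)) {
      c1 <- ceiling(xi[k]) + 1L       # first centre strictly inside
      c2 <- floor(xi[k + 1L]) + 1L
      if (xi[k + 1L] == floor(xi[k + 1L])) c2 <- c2 - 1L # half-open right edge
      if (xi[k] == ceiling(xi[k])) c1 <- c1 # left edge inclusive
      c1 <- max(1L, c1); c2 <- min(w, c2)
      if (c1 <= c2) mask[row, c1:c2] <- 1L
    }
  }
  mask
}

decode_segmentation <- function(seg, h, w) {
  if (is.list(seg) && !is.null(seg$counts)) {
    size <- as.integer(unlist(seg$size))
    counts <- seg$counts
    if (is.character(counts)) counts <- rle_string_decode(counts)
    rle_to_mask(unlist(counts), size)
  } else {
    # one or more polygon rings; union them
    rings <- if (is.list(seg)) seg else list(seg)
    mask <- matrix(0L, h, w)
    for (ring in rings) {
      mask <- pmax(mask, polygon_to_mask(as.numeric(unlist(ring)), h, w))
    }
    mask
  }
}

## ---- readers -------------------------------------------------------------

#' Read instance masks
#'
#' Reads per-instance silique masks from either a COCO-format instance JSON
#' file (`annotations` array with RLE or polygon segmentations; detection
#' `results` arrays are also accepted) or a mask-folder layout with one
#' binary PNG per instance (`<image_id>/<instance_id>.png`) and a
#' `metadata.json` sidecar. Overlapping (amodal) masks are preserved: a
#' pixel may belong to several instances.
#'
#' @param path file (COCO JSON) or directory (mask folder).
#' @param dialect `"coco_json"` or `"mask_folder"`.
#' @return list of [instance_mask()] objects.
#' @export
read_instances <- function(path, dialect = c("coco_json", "mask_folder")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("path does not exist: ", path)
  switch(dialect,
         coco_json = read_instances_coco(path),
         mask_folder = read_instances_folder(path))
}

read_instances_coco <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed JSON in ", path, ": ",
                                           conditionMessage(e)))
  if (!is.null(doc$annotations)) {
    anns <- doc$annotations
    sizes <- list()
    for (img in doc$images)
      sizes[[as.character(img$id)]] <- c(img$height, img$width)
  } else {
    anns <- doc
    sizes <- NULL
  }
  out <- list()
  for (i in seq_along(anns)) {
    a <- anns[[i]]
    iid <- as.character(a$id %||% i)
    img <- as.character(a$image_id %||% "image")
    hw <- if (!is.null(sizes) && !is.null(sizes[[img]])) sizes[[img]] else {
      if (is.list(a$segmentation) && !is.null(a$segmentation$size))
        as.integer(unlist(a$segmentation$size))
      else stop("annotation ", iid, ": image size unknown and not in RLE")
    }
    mask <- tryCatch(decode_segmentation(a$segmentation, hw[1L], hw[2L]),
                     error = function(e)
                       stop("annotation ", iid, ": ", conditionMessage(e)))
    if (!any(mask == 1L)) {
      warning("annotation ", iid, " decodes to an empty mask; skipped")
      next
    }
    out[[length(out) + 1L]] <- instance_mask(
      mask, instance_id = iid, image_id = img,
      bbox = if (!is.null(a$bbox)) as.numeric(unlist(a$bbox)) else NULL,
      score = a$score %||% 1.0,
      category = as.character(a$category %||% a$category_id %||% "silique"))
  }
  out
}

read_instances_folder <- function(path) {
  metafile <- file.path(path, "metadata.json")
  if (!file.exists(metafile)) stop("mask folder lacks metadata.json: ", path)
  meta <- jsonlite::fromJSON(metafile, simplifyVector = FALSE)
  out <- list()
  for (rec in meta$instances) {
    f <- file.path(path, as.character(rec$image_id),
                   paste0(as.character(rec$instance_id), ".png"))
    if (!file.exists(f)) stop("missing mask raster: ", f)
    px <- tryCatch(png::readPNG(f),
                   error = function(e) stop("unreadable raster ", f, ": ",
                                            conditionMessage(e)))
    if (length(dim(px)) == 3L) px <- px[, , 1L]
    mask <- matrix(as.integer(px > 0.5), nrow(px), ncol(px))
    if (!any(mask == 1L)) {
      warning("instance ", rec$instance_id, " has an empty raster; skipped")
      next
    }
    out[[length(out) + 1L]] <- instance_mask(
      mask, instance_id = as.character(rec$instance_id),
      image_id = as.character(rec$image_id),
      score = rec$score %||% 1.0,
      category = as.character(rec$category %||% "silique"))
  }
  out
}

## ---- writers -------------------------------------------------------------

#' Write instance masks
#'
#' Serialises instances either as COCO instance JSON (uncompressed RLE
#' segmentations, one annotation per instance, with `score` carried as an
#' extra field) or as the mask-folder layout read by [read_instances()].
#'
#' @param instances list of [instance_mask()].
#' @param path output file (COCO) or directory (mask folder).
#' @inheritParams read_instances
#' @return `path`, invisibly.
#' @export
write_instances <- function(instances, path,
                            dialect = c("coco_json", "mask_folder")) {
  dialect <- match.arg(dialect)
  if (dialect == "coco_json") {
    imgs <- list(); seen <- character(0)
    anns <- vector("list", length(instances))
    for (i in seq_along(instances)) {
      inst <- instances[[i]]
      if (!(inst$image_id %in% seen)) {
        seen <- c(seen, inst$image_id)
        imgs[[length(imgs) + 1L]] <- list(id = inst$image_id,
                                          height = nrow(inst$mask),
                                          width = ncol(inst$mask))
      }
      anns[[i]] <- list(id = inst$instance_id, image_id = inst$image_id,
                        category_id = 1L,
                        segmentation = mask_to_rle(inst$mask),
                        bbox = inst$bbox, area = sum(inst$mask),
                        score = inst$score, iscrowd = 0L)
    }
    doc <- list(images = imgs, annotations = anns,
                categories = list(list(id = 1L, name = "silique")))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    recs <- vector("list", length(instances))
    imgs <- list(); seen <- character(0)
    for (i in seq_along(instances)) {
      inst <- instances[[i]]
      d <- file.path(path, inst$image_id)
      dir.create(d, showWarnings = FALSE)
      png::writePNG(matrix(as.numeric(inst$mask), nrow(inst$mask)),
                    file.path(d, paste0(inst$instance_id, ".png")))
      recs[[i]] <- list(instance_id = inst$instance_id,
                        image_id = inst$image_id, score = inst$score,
                        category = inst$category)
      if (!(inst$image_id %in% seen)) {
        seen <- c(seen, inst$image_id)
        imgs[[length(imgs) + 1L]] <- list(image_id = inst$image_id,
                                          height = nrow(inst$mask),
                                          width = ncol(inst$mask))
      }
    }
    meta <- list(format = "siliquant-mask-folder", format_version = 1L,
                 images = imgs, instances = recs)
    jsonlite::write_json(meta, file.path(path, "metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

## ---- sample manifest -----------------------------------------------------

#' Read a sample manifest
#'
#' A manifest maps each sample (a pot of one or more plants, scanned as one
#' or more images) to its genotype line, treatment, batch and scan
#' resolution. Required columns: `sample_id`, `genotype`, `treatment`,
#' `batch`. Optional: `dpi` (defaults to 300, the study's flatbed scanner
#' setting, with a warning), `images` (semicolon-separated image ids),
#' `excluded` (logical) and `exclusion_reason`.
#'
#' @param path CSV file.
#' @return data.frame with one row per sample.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(df)
}

validate_manifest <- function(df) {
  req <- c("sample_id", "genotype", "treatment", "batch")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0L)
    stop("manifest lacks required columns: ", paste(missing, collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0L)
    stop("duplicate sample_id in manifest: ", paste(unique(dup), collapse = ", "))
  bad <- which(!(df$treatment %in% c("isolation", "group")))
  if (length(bad) > 0L)
    stop("unknown treatment label in manifest row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(df$treatment[bad]), collapse = ", "),
         " (expected 'isolation' or 'group')")
  if (is.null(df$dpi)) {
    warning("manifest has no dpi column; assuming 300 dpi")
    df$dpi <- 300
  } else {
    blank <- is.na(df$dpi)
    if (any(blank)) {
      warning(sum(blank), " manifest row(s) with blank dpi; assuming 300 dpi")
      df$dpi[blank] <- 300
    }
  }
  if (any(df$dpi <= 0)) stop("manifest dpi must be > 0")
  if (is.null(df$images)) df$images <- df$sample_id
  if (is.null(df$excluded)) df$excluded <- FALSE
  if (is.null(df$exclusion_reason)) df$exclusion_reason <- ""
  df
}

#' Map image ids to sample ids from a manifest
#'
#' @param manifest data.frame from [read_manifest()].
#' @return named character vector: `map[image_id] == sample_id`.
#' @export
manifest_image_map <- function(manifest) {
  ids <- strsplit(as.character(manifest$images), ";", fixed = TRUE)
  setNames(rep(manifest$sample_id, lengths(ids)), trimws(unlist(ids)))
}

## ---- trait tables --------------------------------------------------------

TRAIT_COLS <- c("area_mm2", "length_mm", "diameter_mm", "volume_mm3")

#' Write / read an instance-level trait table
#'
#' One row per instance, accepted or not: rejected instances keep their row
#' with empty trait cells and a QC reason code, so that rejection rates can
#' be recomputed from the table alone. Values round-trip through
#' [read_traits_table()] to at least 1e-6.
#'
#' @param records data.frame as produced by [extract_traits_batch()], with
#'   columns `instance_id`, `image_id`, `sample_id`, `score`, `qc_status`,
#'   `qc_reason`, `area_mm2`, `length_mm`, `diameter_mm`, `volume_mm3`.
#' @param path CSV file.
#' @return `path` invisibly (writer); data.frame (reader).
#' @export
write_traits_table <- function(records, path) {
  cols <- c("instance_id", "image_id", "sample_id", "score",
            "qc_status", "qc_reason", TRAIT_COLS)
  if (nrow(records) == 0L) {
    records <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    for (cc in setdiff(cols, names(records))) records[[cc]] <- NA
    records <- records[, cols]
  }
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_traits_table
#' @export
read_traits_table <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(instance_id = "character",
                                image_id = "character",
                                sample_id = "character"))
  for (cc in TRAIT_COLS) df[[cc]] <- as.numeric(df[[cc]])
  df
}
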