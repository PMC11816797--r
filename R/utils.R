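# Internal helpers shared across modules. Masks are stored as integer
# matrices indexed [row, col] with row = y + 1, col = x + 1 (0-based pixel
# coordinates, origin top-left), matching the COCO convention.

# Coerce an EBImage Image / logical / numeric matrix to a 0/1 integer matrix.
as_binary_matrix <- function(mask) {
  if (inherits(mask, "Image")) mask <- EBImage::imageData(mask)
  if (!is.matrix(mask)) stop("mask must be a matrix")
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  m
}

# Tight 0-based bbox (x, y, w, h) of foreground pixels.
mask_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no bounding box")
  r <- range(idx[, 1L]); c <- range(idx[, 2L])
  c(x = c[1L] - 1L, y = r[1L] - 1L, w = c[2L] - c[1L] + 1L, h = r[2L] - r[1L] + 1L)
}

bbox_contains_mask <- function(bbox, mask) {
  tb <- mask_bbox(mask)
  bbox[1L] <= tb[1L] && bbox[2L] <= tb[2L] &&
    bbox[1L] + bbox[3L] >= tb[1L] + tb[3L] &&
    bbox[2L] + bbox[4L] >= tb[2L] + tb[4L]
}

# Crop mask to its foreground bbox plus a `pad`-pixel background ring.
# Returns list(mask, row0, col0) where row0/col0 are offsets such that
# cropped [i, j] corresponds to full [i + row0, j + col0].
crop_to_bbox <- function(mask, pad = 1L) {
  bb <- mask_bbox(mask)
  r1 <- bb[["y"]] + 1L; r2 <- bb[["y"]] + bb[["h"]]
  c1 <- bb[["x"]] + 1L; c2 <- bb[["x"]] + bb[["w"]]
  sub <- mask[r1:r2, c1:c2, drop = FALSE]
  if (pad > 0L) {
    out <- matrix(0L, nrow(sub) + 2L * pad, ncol(sub) + 2L * pad)
    out[(pad + 1L):(pad + nrow(sub)), (pad + 1L):(pad + ncol(sub))] <- sub
    list(mask = out, row0 = r1 - pad - 1L, col0 = c1 - pad - 1L)
  } else {
    list(mask = sub, row0 = r1 - 1L, col0 = c1 - 1L)
  }
}

# Shift a matrix by (dr, dc), zero-filling vacated cells.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) > 0L && length(cs) > 0L)
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

NEIGH8 <- cbind(dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
                dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))

# Per-pixel count of foreground 8-neighbours.
neighbor_count8 <- function(m) {
  acc <- matrix(0L, nrow(m), ncol(m))
  for (k in seq_len(8L)) acc <- acc + shift_mat(m, NEIGH8[k, 1L], NEIGH8[k, 2L])
  acc
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Trapezoidal integration over possibly non-uniform abscissae.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n]) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
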