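# Instance-level mask quality control: connected-component filter and
# skeletonization (Zhang-Suen thinning) with small-spur pruning. All
# adjacency is 8-connected: thin diagonal structures such as silique
# skeletons disconnect under 4-connectivity, and the thinning operator
# itself is defined on the 8-neighbourhood.

#' Label 8-connected foreground components
#'
#' `EBImage::bwlabel()` labels 4-connected components; diagonal-only
#' contacts are then merged with a union-find pass over the four diagonal
#' shift directions, yielding 8-connected labels.
#'
#' @param mask binary matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  mask <- as_binary_matrix(mask)
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (d in list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))) {
    sh <- shift_mat(lab, d[1L], d[2L])
    sel <- lab > 0L & sh > 0L & lab != sh
    if (!any(sel)) next
    pairs <- unique(cbind(lab[sel], sh[sel]))
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Count 8-connected foreground components
#'
#' @param mask binary matrix (or [instance_mask()]).
#' @return integer; 0 for an empty mask.
#' @export
component_count <- function(mask) {
  if (inherits(mask, "instance_mask")) mask <- mask$mask
  mask <- as_binary_matrix(mask)
  if (!any(mask == 1L)) return(0L)
  cr <- crop_to_bbox(mask)
  max(label_components(cr$mask))
}

## ---- Zhang-Suen thinning -------------------------------------------------

# One parallel thinning sub-iteration. Neighbours x1..x8 run
# counterclockwise from east (x1 = E, x2 = NE, ..., x8 = SE). A foreground
# pixel is deleted when the Hilditch crossing number XH(p) is 1, the
# connectivity measure min(n1, n2) lies in [2, 3], and the sub-iteration's
# directional condition holds: the two-subcycle conditions of Guo & Hall
# (1989) as tabulated by Lam, Lee & Suen (1992). This is the
# connectivity-safe form of Zhang-Suen-style parallel thinning used by
# mainstream image libraries; the textbook Zhang-Suen subcycle conditions
# delete both pixels of a 2-px diagonal pair in one pass and can erase
# diagonal limbs outright.
thin_pass <- function(m, sub) {
  x1 <- shift_mat(m, 0L, -1L)   # E
  x2 <- shift_mat(m, 1L, -1L)   # NE
  x3 <- shift_mat(m, 1L, 0L)    # N
  x4 <- shift_mat(m, 1L, 1L)    # NW
  x5 <- shift_mat(m, 0L, 1L)    # W
  x6 <- shift_mat(m, -1L, 1L)   # SW
  x7 <- shift_mat(m, -1L, 0L)   # S
  x8 <- shift_mat(m, -1L, -1L)  # SE
  XH <- (x1 == 0L) * (x2 | x3) + (x3 == 0L) * (x4 | x5) +
        (x5 == 0L) * (x6 | x7) + (x7 == 0L) * (x8 | x1)
  n1 <- (x1 | x2) + (x3 | x4) + (x5 | x6) + (x7 | x8)
  n2 <- (x2 | x3) + (x4 | x5) + (x6 | x7) + (x8 | x1)
  nmin <- pmin(n1, n2)
  del <- m == 1L & XH == 1L & nmin >= 2L & nmin <= 3L
  if (sub == 1L) {
    del <- del & !((x2 | x3 | !x8) & x1)
  } else {
    del <- del & !((x6 | x7 | !x4) & x5)
  }
  m[del] <- 0L
  list(m = m, changed = any(del))
}

#' Parallel binary thinning to a one-pixel spinal line
#'
#' Iteratively peels the boundary of a binary mask with a two-subiteration
#' parallel thinning scheme (the Zhang-Suen family, using the
#' connectivity-preserving subcycle conditions of Guo and Hall as
#' standardised by Lam, Lee and Suen and used by mainstream image
#' libraries) until only a one-pixel-wide medial line remains.
#'
#' @param mask binary matrix.
#' @return binary matrix of the same dimensions containing the skeleton.
#' @export
binary_thin <- function(mask) {
  mask <- as_binary_matrix(mask)
  cr <- crop_to_bbox(mask, pad = 1L)
  m <- cr$mask
  repeat {
    s1 <- thin_pass(m, 1L)
    s2 <- thin_pass(s1$m, 2L)
    m <- s2$m
    if (!s1$changed && !s2$changed) break
  }
  out <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(m == 1L, arr.ind = TRUE)
  out[cbind(idx[, 1L] + cr$row0, idx[, 2L] + cr$col0)] <- 1L
  out
}

## ---- skeleton graph analysis ---------------------------------------------

skeleton_degrees <- function(skel) neighbor_count8(skel) * skel

skel_neighbors <- function(skel, rc) {
  nb <- cbind(rc[1L] + NEIGH8[, 1L], rc[2L] + NEIGH8[, 2L])
  keep <- nb[, 1L] >= 1L & nb[, 1L] <= nrow(skel) &
          nb[, 2L] >= 1L & nb[, 2L] <= ncol(skel)
  nb <- nb[keep, , drop = FALSE]
  nb[skel[nb] == 1L, , drop = FALSE]
}

# Walk from an endpoint until hitting a branch point (excluded) or running
# out of unvisited pixels. Returns the branch pixels in order.
trace_terminal_branch <- function(skel, deg, start) {
  path <- matrix(start, ncol = 2L)
  prev <- c(NA_integer_, NA_integer_)
  cur <- start
  repeat {
    nb <- skel_neighbors(skel, cur)
    if (!any(is.na(prev)))
      nb <- nb[!(nb[, 1L] == prev[1L] & nb[, 2L] == prev[2L]), , drop = FALSE]
    if (nrow(nb) == 0L) return(list(pixels = path, hit_branch = FALSE))
    # at a fork we have arrived next to a branch point
    nxt <- nb[1L, ]
    if (deg[nxt[1L], nxt[2L]] >= 3L)
      return(list(pixels = path, hit_branch = TRUE,
                  branch_point = c(nxt[1L], nxt[2L])))
    if (nrow(nb) > 1L) {
      # ambiguous continuation without a branch point: treat as a fork
      return(list(pixels = path, hit_branch = TRUE, branch_point = NULL))
    }
    prev <- cur; cur <- c(nxt[1L], nxt[2L])
    path <- rbind(path, cur)
  }
}

#' Skeletonize a mask and prune small spurs
#'
#' Applies parallel thinning ([binary_thin()]), then iteratively deletes every terminal
#' branch (endpoint-to-branch-point path) whose length, excluding the
#' branch point, is at most `max_spur_px` pixels — shortest spur first,
#' recomputing the skeleton graph after each deletion until stable. Spurs
#' longer than the threshold are left in place; their surviving branch
#' points mark the mask for rejection downstream ([qc_filter()]).
#'
#' The default threshold of 5 px encodes the rule that only side branches
#' exceeding 5 pixels are "significant": anything smaller is a thinning
#' artifact, not evidence of a malformed mask.
#'
#' @param mask binary matrix or [instance_mask()]; must be a single
#'   connected component.
#' @param max_spur_px prune terminal branches of at most this many pixels.
#' @return an object of class `silique_skeleton`: list with `pixels`
#'   (n x 2 row/col matrix), `skel` (binary matrix), `endpoints`,
#'   `branch_points`, `spurs_pruned` (lengths, px), and `clean` (exactly 2
#'   endpoints, no branch points).
#' @export
skeletonize_and_prune <- function(mask, max_spur_px = 5L) {
  if (inherits(mask, "instance_mask")) mask <- mask$mask
  skel <- binary_thin(mask)
  spurs <- numeric(0)
  repeat {
    deg <- skeleton_degrees(skel)
    if (!any(deg >= 3L)) break
    eps <- which(skel == 1L & deg == 1L, arr.ind = TRUE)
    if (nrow(eps) == 0L) break
    branches <- list()
    for (i in seq_len(nrow(eps))) {
      br <- trace_terminal_branch(skel, deg, c(eps[i, 1L], eps[i, 2L]))
      if (br$hit_branch) branches[[length(branches) + 1L]] <- br
    }
    if (length(branches) == 0L) break
    lens <- vapply(branches, function(b) nrow(b$pixels), integer(1L))
    ord <- order(lens)
    shortest <- branches[[ord[1L]]]
    if (nrow(shortest$pixels) > max_spur_px) break
    skel[shortest$pixels] <- 0L
    spurs <- c(spurs, nrow(shortest$pixels))
    # deleting a spur can leave a one-pixel bump where the junction was
    # (the former branch point keeps diagonal contacts with the through
    # path); a re-thin pass absorbs it back into the line
    skel <- binary_thin(skel)
  }
  deg <- skeleton_degrees(skel)
  pixels <- which(skel == 1L, arr.ind = TRUE)
  endpoints <- which(skel == 1L & deg == 1L, arr.ind = TRUE)
  branch_points <- which(skel == 1L & deg >= 3L, arr.ind = TRUE)
  structure(list(skel = skel,
                 pixels = unname(pixels),
                 endpoints = unname(endpoints),
                 branch_points = unname(branch_points),
                 spurs_pruned = spurs,
                 clean = nrow(branch_points) == 0L && nrow(endpoints) == 2L &&
                         nrow(pixels) >= 2L),
            class = "silique_skeleton")
}

#' @export
print.silique_skeleton <- function(x, ...) {
  cat(sprintf(
    "<silique_skeleton: %d px, %d endpoints, %d branch points, %d spur(s) pruned%s>\n",
    nrow(x$pixels), nrow(x$endpoints), nrow(x$branch_points),
    length(x$spurs_pruned), if (x$clean) ", clean" else ""))
  invisible(x)
}

#' Instance-level mask quality control
#'
#' Applies the two structural filters used before trait extraction:
#' a mask must be a single 8-connected shape, and its pruned skeleton must
#' be a single continuous line (two endpoints, no residual branch points).
#' Masks failing either test — typically predictions covering more than one
#' silique, or fragmented detections — are rejected with a reason code.
#'
#' @param instance [instance_mask()] or binary matrix.
#' @param max_spur_px spur-pruning threshold, see [skeletonize_and_prune()].
#' @return list with `status` (`"accepted"`/`"rejected"`), `reason`
#'   (`NA`, `"empty_mask"`, `"multi_component"`, `"residual_spur"` or
#'   `"degenerate_skeleton"`), and `skeleton` (when one was computed).
#' @export
qc_filter <- function(instance, max_spur_px = 5L) {
  mask <- if (inherits(instance, "instance_mask")) instance$mask else
    as_binary_matrix(instance)
  if (!any(mask == 1L))
    return(list(status = "rejected", reason = "empty_mask", skeleton = NULL))
  nc <- component_count(mask)
  if (nc != 1L)
    return(list(status = "rejected", reason = "multi_component", skeleton = NULL))
  sk <- skeletonize_and_prune(mask, max_spur_px = max_spur_px)
  if (nrow(sk$branch_points) > 0L)
    return(list(status = "rejected", reason = "residual_spur", skeleton = sk))
  if (!sk$clean)
    return(list(status = "rejected", reason = "degenerate_skeleton", skeleton = sk))
  list(status = "accepted", reason = NA_character_, skeleton = sk)
}
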