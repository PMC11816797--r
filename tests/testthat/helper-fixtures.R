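# Shared fixtures: all built in code, nothing read from disk.

# Straight capsule with sub-pixel placement (unbiased rasterisation).
straight_capsule <- function(length = 100, radius = 5, y = 10.5, x0 = 0.3,
                             angle = 0) {
  p2 <- c(x0 + length * cos(angle), y + length * sin(angle))
  capsule_spec(rbind(c(x0, y), p2), radius = radius)
}

# A rectangle instance in a given frame (fast fixtures for the matcher).
rect_instance <- function(frame, x, y, w, h, id = "r", image_id = "img",
                          score = 1.0) {
  m <- matrix(0L, frame[1], frame[2])
  m[(y + 1):(y + h), (x + 1):(x + w)] <- 1L
  instance_mask(m, instance_id = id, image_id = image_id, score = score)
}

# Independent brute-force matcher: enumerates every one-to-one assignment
# (each prediction -> one unmatched ground truth with IoU >= thr, or none)
# and keeps the lexicographically best IoU vector in descending-score
# order (ties: lower ground-truth index). TP/FP/FN from the winner.
brute_force_match <- function(ioumat, scores, thr) {
  np <- nrow(ioumat); ng <- ncol(ioumat)
  ord <- order(-scores)
  best <- NULL
  better <- function(a, b) {
    # a, b: list(iou = vec, gt = vec)
    d <- which(a$iou != b$iou)
    if (length(d) > 0) return(a$iou[d[1]] > b$iou[d[1]])
    d <- which(a$gt != b$gt)
    if (length(d) > 0) return(a$gt[d[1]] < b$gt[d[1]])
    FALSE
  }
  rec <- function(k, used, iou_vec, gt_vec) {
    if (k > np) {
      cand <- list(iou = iou_vec, gt = gt_vec)
      if (is.null(best) || better(cand, best)) best <<- cand
      return(invisible(NULL))
    }
    i <- ord[k]
    for (j in which(!used & ioumat[i, ] >= thr)) {
      u <- used; u[j] <- TRUE
      rec(k + 1, u, c(iou_vec, ioumat[i, j]), c(gt_vec, j))
    }
    rec(k + 1, used, c(iou_vec, -1), c(gt_vec, ng + 1L))
  }
  rec(1L, rep(FALSE, ng), numeric(0), integer(0))
  tp <- sum(best$iou >= 0)
  list(tp = tp, fp = np - tp, fn = ng - tp)
}

# Random tiny "scene" of rectangles with jittered predictions, for the
# matcher-oracle equivalence tests. Returns prediction/GT instance lists.
random_rect_scene <- function(n_gt, frame = c(60, 80)) {
  gt <- lapply(seq_len(n_gt), function(i) {
    rect_instance(frame,
                  x = sample(0:(frame[2] - 16), 1),
                  y = sample(0:(frame[1] - 12), 1),
                  w = sample(6:14, 1), h = sample(5:10, 1),
                  id = paste0("g", i))
  })
  preds <- list()
  for (i in seq_len(n_gt)) {
    if (runif(1) < 0.15) next  # missed detection
    b <- gt[[i]]$bbox
    dx <- sample(-4:4, 1); dy <- sample(-3:3, 1)
    dw <- sample(-2:2, 1); dh <- sample(-2:2, 1)
    x <- max(0, b[1] + dx); y <- max(0, b[2] + dy)
    w <- max(2, b[3] + dw); h <- max(2, b[4] + dh)
    w <- min(w, frame[2] - x); h <- min(h, frame[1] - y)
    preds[[length(preds) + 1]] <-
      rect_instance(frame, x, y, w, h, id = paste0("p", i),
                    score = round(runif(1, 0.3, 1), 3))
  }
  if (runif(1) < 0.4 && length(preds) > 0) {   # spurious duplicate
    d <- preds[[sample(length(preds), 1)]]
    preds[[length(preds) + 1]] <-
      instance_mask(d$mask, instance_id = "dup", image_id = d$image_id,
                    score = round(runif(1, 0.2, 0.9), 3))
  }
  list(predictions = preds, ground_truth = gt)
}

# Capsule batch used by the recovery tests (deterministic under seed).
capsule_recovery_errors <- function(n, seed = 42) {
  withr::with_seed(seed, {
    out <- data.frame(sl = numeric(n), sd = numeric(n), sa = numeric(n),
                      sv = numeric(n), r = numeric(n))
    for (i in seq_len(n)) {
      sp <- random_capsule_spec(profile = if (i %% 2) "constant" else "bulged")
      cap <- generate_capsule(sp)
      qc <- qc_filter(cap$instance)
      stopifnot(qc$status == "accepted")
      sk <- qc$skeleton
      m <- cap$instance$mask
      dpi <- 25.4  # 1 mm per px: trait values are in px units
      tr <- cap$truth
      out$sl[i] <- silique_length(sk, dpi) - tr$digital_length_px
      out$sd[i] <- silique_diameter(m, sk, dpi) - 2 * tr$max_radius_px
      out$sa[i] <- silique_area(m, dpi) / tr$area_px2 - 1
      out$sv[i] <- silique_volume(m, sk, dpi) / tr$volume_px3 - 1
      out$r[i] <- tr$max_radius_px
    }
    out
  })
}
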