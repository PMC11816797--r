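# Detection / instance-segmentation evaluation: IoU computation, greedy
# score-ordered matching, precision-recall sweeps, and AP/AR summaries at
# IoU thresholds 0.5, 0.75 and 0.5:0.05:0.95 for boxes and masks.

#' Intersection over union
#'
#' For `mode = "bbox"`, rectangles `(x, y, w, h)` with half-open extents;
#' for `mode = "mask"`, pixelwise `|A n B| / |A u B|` of two full-frame
#' binary masks. Symmetric; two empty inputs have IoU 0 by convention.
#'
#' @param a,b [instance_mask()] objects, or bbox vectors (`bbox` mode) /
#'   binary matrices (`mask` mode).
#' @param mode `"bbox"` or `"mask"`.
#' @return scalar in `[0, 1]`.
#' @export
iou <- function(a, b, mode = c("bbox", "mask")) {
  mode <- match.arg(mode)
  if (mode == "bbox") {
    if (inherits(a, "instance_mask")) a <- a$bbox
    if (inherits(b, "instance_mask")) b <- b$bbox
    ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    uni <- a[3] * a[4] + b[3] * b[4] - inter
    if (uni <= 0) return(0)
    inter / uni
  } else {
    if (inherits(a, "instance_mask")) a <- a$mask
    if (inherits(b, "instance_mask")) b <- b$mask
    if (!identical(dim(a), dim(b)))
      stop("mask IoU requires rasters in the same image frame")
    inter <- sum(a == 1L & b == 1L)
    uni <- sum(a == 1L | b == 1L)
    if (uni == 0L) return(0)
    inter / uni
  }
}

# IoU matrix between prediction and ground-truth lists (same image frame).
iou_matrix <- function(predictions, ground_truth, mode = c("bbox", "mask")) {
  mode <- match.arg(mode)
  m <- matrix(0, length(predictions), length(ground_truth))
  for (i in seq_along(predictions))
    for (j in seq_along(ground_truth))
      m[i, j] <- iou(predictions[[i]], ground_truth[[j]], mode = mode)
  m
}

#' Greedy score-ordered matching at one IoU threshold
#'
#' Predictions are processed in descending confidence (ties broken by
#' stable input order); each claims the unmatched ground truth with the
#' highest IoU at or above the threshold (ties: lowest ground-truth
#' index). Matching is one-to-one: leftover predictions are false
#' positives, leftover ground truths false negatives.
#'
#' @param predictions,ground_truth lists of [instance_mask()] from one
#'   image.
#' @param thr IoU threshold.
#' @inheritParams iou
#' @param ioumat optional precomputed [iou_matrix()].
#' @return list with `tp`, `fp`, `fn` counts and `assignment` (data.frame
#'   of matches: `pred`, `gt`, `iou`, `score`).
#' @export
match_at_threshold <- function(predictions, ground_truth, thr,
                               mode = c("bbox", "mask"), ioumat = NULL) {
  mode <- match.arg(mode)
  if (is.null(ioumat)) ioumat <- iou_matrix(predictions, ground_truth, mode)
  scores <- vapply(predictions, `[[`, numeric(1L), "score")
  ord <- order(-scores)          # stable: ties keep input order
  matched_gt <- rep(FALSE, length(ground_truth))
  rows <- list()
  for (i in ord) {
    cand <- which(!matched_gt & ioumat[i, ] >= thr)
    if (length(cand) == 0L) next
    j <- cand[which.max(ioumat[i, cand])]
    matched_gt[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(pred = i, gt = j,
                                            iou = ioumat[i, j],
                                            score = scores[i])
  }
  assignment <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(pred = integer(0), gt = integer(0),
               iou = numeric(0), score = numeric(0))
  tp <- nrow(assignment)
  list(tp = tp, fp = length(predictions) - tp,
       fn = length(ground_truth) - tp, assignment = assignment)
}

# Group instances by image id.
split_by_image <- function(instances) {
  ids <- vapply(instances, `[[`, character(1L), "image_id")
  split(instances, ids)
}

# Score-ordered TP labels pooled over images at one threshold.
pooled_detections <- function(predictions, ground_truth, thr, mode) {
  pimgs <- split_by_image(predictions)
  gimgs <- split_by_image(ground_truth)
  imgs <- union(names(pimgs), names(gimgs))
  score <- numeric(0); is_tp <- logical(0); n_gt <- 0L
  for (im in imgs) {
    p <- pimgs[[im]] %||% list()
    g <- gimgs[[im]] %||% list()
    n_gt <- n_gt + length(g)
    if (length(p) == 0L) next
    if (length(g) == 0L) {
      score <- c(score, vapply(p, `[[`, numeric(1L), "score"))
      is_tp <- c(is_tp, rep(FALSE, length(p)))
      next
    }
    m <- match_at_threshold(p, g, thr, mode = mode)
    lab <- rep(FALSE, length(p))
    lab[m$assignment$pred] <- TRUE
    score <- c(score, vapply(p, `[[`, numeric(1L), "score"))
    is_tp <- c(is_tp, lab)
  }
  ord <- order(-score)
  list(is_tp = is_tp[ord], n_gt = n_gt)
}

#' Average precision at one IoU threshold
#'
#' Sweeps the precision-recall curve over the confidence-ranked pooled
#' detections and summarises it with interpolated precision (at each
#' recall level, the maximum precision at that recall or beyond). The
#' default follows the 101-point benchmark convention (recall grid 0,
#' 0.01, ..., 1); `interpolation = "all"` averages over every achieved
#' recall step instead.
#'
#' @inheritParams match_at_threshold
#' @param interpolation `"101point"` or `"all"`.
#' @return AP in `[0, 1]`; `NA` if there is no ground truth.
#' @export
average_precision <- function(predictions, ground_truth, thr,
                              mode = c("bbox", "mask"),
                              interpolation = c("101point", "all")) {
  mode <- match.arg(mode)
  interpolation <- match.arg(interpolation)
  pool <- pooled_detections(predictions, ground_truth, thr, mode)
  if (pool$n_gt == 0L) return(NA_real_)
  if (length(pool$is_tp) == 0L) return(0)
  ctp <- cumsum(pool$is_tp)
  cfp <- cumsum(!pool$is_tp)
  recall <- ctp / pool$n_gt
  precision <- ctp / (ctp + cfp)
  # interpolated precision: running max from the right
  p_interp <- rev(cummax(rev(precision)))
  if (interpolation == "101point") {
    grid <- seq(0, 1, by = 0.01)
    vals <- vapply(grid, function(r) {
      k <- which(recall >= r)
      if (length(k) == 0L) 0 else p_interp[k[1L]]
    }, numeric(1L))
    mean(vals)
  } else {
    # area under the interpolated step curve over achieved recall
    r_prev <- c(0, recall[-length(recall)])
    sum((recall - r_prev) * p_interp)
  }
}

#' Recall of the greedy matching at one IoU threshold
#'
#' `TP / (TP + FN)` over all images with every detection considered (no
#' per-image detection cap).
#'
#' @inheritParams match_at_threshold
#' @return recall in `[0, 1]`; `NA` if there is no ground truth.
#' @export
recall_at_threshold <- function(predictions, ground_truth, thr,
                                mode = c("bbox", "mask")) {
  mode <- match.arg(mode)
  pool <- pooled_detections(predictions, ground_truth, thr, mode)
  if (pool$n_gt == 0L) return(NA_real_)
  sum(pool$is_tp) / pool$n_gt
}

#' Evaluate predictions against ground truth
#'
#' Computes, for boxes (detection) and masks (segmentation): AP at IoU
#' 0.5 and 0.75, AP averaged over IoU 0.5:0.05:0.95, and AR (mean recall
#' over the same thresholds), all reported as percentages, together with
#' per-threshold TP/FP/FN counts.
#'
#' @param predictions,ground_truth nonempty lists of [instance_mask()].
#' @param modes tasks to evaluate.
#' @param thresholds IoU thresholds for the averaged metrics.
#' @inheritParams average_precision
#' @return object of class `silique_eval_report`: per mode a list with
#'   `ap50`, `ap75`, `ap`, `ar` (percent) and `by_threshold`
#'   (data.frame: thr, tp, fp, fn, precision, recall).
#' @export
evaluate_detections <- function(predictions, ground_truth,
                                modes = c("bbox", "mask"),
                                thresholds = seq(0.5, 0.95, by = 0.05),
                                interpolation = c("101point", "all")) {
  if (length(predictions) == 0L || length(ground_truth) == 0L)
    stop("need nonempty prediction and ground-truth sets")
  interpolation <- match.arg(interpolation)
  out <- list()
  for (mode in modes) {
    aps <- vapply(thresholds, function(th)
      average_precision(predictions, ground_truth, th, mode = mode,
                        interpolation = interpolation), numeric(1L))
    rec <- vapply(thresholds, function(th)
      recall_at_threshold(predictions, ground_truth, th, mode = mode),
      numeric(1L))
    counts <- t(vapply(thresholds, function(th) {
      pool <- pooled_detections(predictions, ground_truth, th, mode)
      tp <- sum(pool$is_tp)
      c(tp = tp, fp = length(pool$is_tp) - tp, fn = pool$n_gt - tp)
    }, numeric(3L)))
    by_thr <- data.frame(thr = thresholds, counts)
    by_thr$precision <- ifelse(by_thr$tp + by_thr$fp > 0,
                               by_thr$tp / (by_thr$tp + by_thr$fp), NA)
    by_thr$recall <- by_thr$tp / (by_thr$tp + by_thr$fn)
    out[[mode]] <- list(
      ap50 = 100 * average_precision(predictions, ground_truth, 0.5,
                                     mode = mode, interpolation = interpolation),
      ap75 = 100 * average_precision(predictions, ground_truth, 0.75,
                                     mode = mode, interpolation = interpolation),
      ap = 100 * mean(aps),
      ar = 100 * mean(rec),
      by_threshold = by_thr)
  }
  structure(out, class = "silique_eval_report")
}

#' @export
print.silique_eval_report <- function(x, ...) {
  task <- c(bbox = "Detection", mask = "Segmentation")
  cat(sprintf("%-14s %6s %6s %6s %6s\n", "", "AP50", "AP75", "AP", "AR"))
  for (mode in names(x)) {
    cat(sprintf("%-14s %6.1f %6.1f %6.1f %6.1f\n",
                task[[mode]] %||% mode, x[[mode]]$ap50, x[[mode]]$ap75,
                x[[mode]]$ap, x[[mode]]$ar))
  }
  invisible(x)
}

#' Write an evaluation report as JSON plus a summary CSV
#'
#' The CSV has one row per task with columns `task`, `AP50`, `AP75`,
#' `AP`, `AR` (percent).
#'
#' @param report `silique_eval_report` from [evaluate_detections()].
#' @param dir output directory.
#' @return invisible character vector of the file paths.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jfile <- file.path(dir, "eval_report.json")
  cfile <- file.path(dir, "eval_report.csv")
  jsonlite::write_json(unclass(report), jfile, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  task <- c(bbox = "detection", mask = "segmentation")
  df <- do.call(rbind, lapply(names(report), function(mode)
    data.frame(task = task[[mode]] %||% mode,
               AP50 = report[[mode]]$ap50, AP75 = report[[mode]]$ap75,
               AP = report[[mode]]$ap, AR = report[[mode]]$ar)))
  write.csv(df, cfile, row.names = FALSE)
  invisible(c(jfile, cfile))
}
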