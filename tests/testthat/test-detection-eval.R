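test_that("IoU matches hand-computed values", {
  f <- c(20, 20)
  a <- rect_instance(f, 0, 0, 2, 2)
  b <- rect_instance(f, 1, 1, 2, 2)
  expect_equal(iou(a, b, "bbox"), 1 / 7)   # union 4 + 4 - 1
  expect_equal(iou(a, b, "mask"), 1 / 7)
  expect_equal(iou(a, a, "bbox"), 1)
  expect_equal(iou(a, a, "mask"), 1)
  c_ <- rect_instance(f, 10, 10, 3, 3)
  expect_equal(iou(a, c_, "bbox"), 0)
  expect_equal(iou(a, c_, "mask"), 0)
  expect_equal(iou(matrix(0L, 4, 4), matrix(0L, 4, 4), "mask"), 0)
  # symmetry
  expect_equal(iou(a, b, "bbox"), iou(b, a, "bbox"))
})

test_that("greedy matching crosses thresholds and is one-to-one", {
  f <- c(30, 30)
  gt <- list(rect_instance(f, 5, 5, 10, 6, id = "g1"))
  # one prediction shifted a row: IoU 50/70
  pred <- list(rect_instance(f, 5, 6, 10, 6, id = "p1", score = 0.9))
  i_pg <- iou(pred[[1]], gt[[1]], "mask")
  expect_gt(i_pg, 0.5); expect_lt(i_pg, 0.75)
  m1 <- match_at_threshold(pred, gt, 0.5, "mask")
  expect_equal(c(m1$tp, m1$fp, m1$fn), c(1, 0, 0))
  m2 <- match_at_threshold(pred, gt, 0.75, "mask")
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0, 1, 1))
  # two predictions over one truth: only the higher score matches
  two <- list(rect_instance(f, 5, 6, 10, 6, id = "hi", score = 0.9),
              rect_instance(f, 5, 4, 10, 6, id = "lo", score = 0.8))
  m3 <- match_at_threshold(two, gt, 0.5, "mask")
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(1, 1, 0))
  expect_equal(m3$assignment$pred, 1L)
})

test_that("average precision follows the ranked precision-recall sweep", {
  f <- c(30, 30)
  gt <- list(rect_instance(f, 5, 5, 10, 6, id = "g1"))
  rank_tp_first <- list(
    rect_instance(f, 5, 5, 10, 6, id = "hit", score = 0.9),
    rect_instance(f, 20, 20, 6, 6, id = "miss", score = 0.5))
  rank_fp_first <- list(
    rect_instance(f, 20, 20, 6, 6, id = "miss", score = 0.9),
    rect_instance(f, 5, 5, 10, 6, id = "hit", score = 0.5))
  expect_equal(average_precision(rank_tp_first, gt, 0.5, "mask"), 1.0)
  expect_equal(average_precision(rank_fp_first, gt, 0.5, "mask"), 0.5)
  # all-point interpolation agrees on these degenerate curves
  expect_equal(average_precision(rank_fp_first, gt, 0.5, "mask",
                                 interpolation = "all"), 0.5)
})

test_that("perfect predictions score 100 on every metric", {
  sc <- generate_scene(5, seed = 41, image_size = c(150, 200),
                       length_range = c(30, 55), radius_range = c(3, 5))
  preds <- perturb_instances(sc$instances, "identity",
                             scores = seq(1, 0.6, length.out = 5))
  rep <- evaluate_detections(preds, sc$instances)
  for (mode in c("bbox", "mask"))
    for (metric in c("ap50", "ap75", "ap", "ar"))
      expect_equal(rep[[mode]][[metric]], 100)
})

test_that("uniform erosion drops AP75 to 0 while AP50 stays 100", {
  sc <- generate_scene(6, seed = 43, image_size = c(220, 260),
                       length_range = c(60, 90), radius_range = c(5.5, 7))
  pe <- perturb_instances(sc$instances, "erode", px = 2,
                          scores = seq(0.95, 0.7, length.out = 6))
  ious <- vapply(seq_along(pe),
                 function(i) iou(pe[[i]], sc$instances[[i]], "mask"),
                 numeric(1))
  expect_true(all(ious > 0.5 & ious < 0.75))  # construction validity
  rep <- evaluate_detections(pe, sc$instances, modes = "mask")
  expect_equal(rep$mask$ap50, 100)
  expect_equal(rep$mask$ap75, 0)
  expect_gte(rep$mask$ap50, rep$mask$ap)
})

test_that("box metrics ignore mask-only changes", {
  sc <- generate_scene(4, seed = 47, image_size = c(150, 200),
                       length_range = c(35, 60), radius_range = c(4, 6))
  scores <- seq(0.9, 0.6, length.out = 4)
  p1 <- perturb_instances(sc$instances, "identity", scores = scores)
  # replace each mask by its filled bbox: same boxes, different masks
  p2 <- lapply(p1, function(inst) {
    b <- round(inst$bbox)
    m <- matrix(0L, nrow(inst$mask), ncol(inst$mask))
    m[(b[2] + 1):(b[2] + b[4]), (b[1] + 1):(b[1] + b[3])] <- 1L
    instance_mask(m, inst$instance_id, inst$image_id, bbox = inst$bbox,
                  score = inst$score)
  })
  r1 <- evaluate_detections(p1, sc$instances, modes = "bbox")
  r2 <- evaluate_detections(p2, sc$instances, modes = "bbox")
  expect_equal(r1$bbox, r2$bbox)
})

test_that("greedy matcher agrees with exhaustive assignment on random scenes", {
  withr::with_seed(101, {
    thresholds <- seq(0.5, 0.95, by = 0.05)
    for (s in 1:100) {
      sc <- random_rect_scene(sample(2:6, 1))
      if (length(sc$predictions) == 0) next
      for (mode in c("bbox", "mask")) {
        ioumat <- siliquant:::iou_matrix(sc$predictions, sc$ground_truth, mode)
        scores <- vapply(sc$predictions, `[[`, numeric(1), "score")
        for (thr in thresholds) {
          got <- match_at_threshold(sc$predictions, sc$ground_truth, thr,
                                    mode, ioumat = ioumat)
          want <- brute_force_match(ioumat, scores, thr)
          expect_equal(c(got$tp, got$fp, got$fn),
                       c(want$tp, want$fp, want$fn))
        }
      }
    }
  })
})

test_that("duplicates never add true positives and order does not matter", {
  withr::with_seed(53, {
    sc <- random_rect_scene(4)
    preds <- sc$predictions
    gt <- sc$ground_truth
    base <- match_at_threshold(preds, gt, 0.5, "mask")
    dup <- preds[[1]]
    dup$score <- dup$score / 2
    with_dup <- match_at_threshold(c(preds, list(dup)), gt, 0.5, "mask")
    expect_equal(with_dup$tp, base$tp)
    expect_equal(with_dup$fp, base$fp + 1)
    # shuffling input order (distinct scores) leaves AP and AR unchanged
    perm <- sample(length(preds))
    expect_equal(average_precision(preds[perm], gt, 0.5, "mask"),
                 average_precision(preds, gt, 0.5, "mask"))
    expect_equal(recall_at_threshold(preds[perm], gt, 0.5, "mask"),
                 recall_at_threshold(preds, gt, 0.5, "mask"))
  })
})

test_that("reports serialise to JSON and a summary CSV", {
  sc <- generate_scene(3, seed = 59, image_size = c(140, 180),
                       length_range = c(30, 50), radius_range = c(3, 5))
  preds <- perturb_instances(sc$instances, "dilate", px = 1,
                             scores = c(0.9, 0.8, 0.7))
  rep <- evaluate_detections(preds, sc$instances)
  d <- withr::local_tempdir()
  files <- write_eval_report(rep, d)
  df <- read.csv(file.path(d, "eval_report.csv"))
  expect_equal(df$task, c("detection", "segmentation"))
  expect_equal(names(df), c("task", "AP50", "AP75", "AP", "AR"))
  expect_true(all(df$AP50 >= df$AP - 1e-9))
  j <- jsonlite::fromJSON(file.path(d, "eval_report.json"))
  expect_equal(j$mask$ap50, rep$mask$ap50)
})
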