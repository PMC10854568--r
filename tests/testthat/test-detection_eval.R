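test_that("IoU matches hand-computed values and basic geometry", {
  b <- function(...) as.data.frame(setNames(as.list(c(...)),
                                            c("x_min", "y_min", "x_max", "y_max")))
  expect_equal(box_iou(b(0, 0, 2, 2), b(0, 0, 2, 2)), 1.0)
  expect_equal(box_iou(b(0, 0, 2, 2), b(5, 5, 7, 7)), 0.0)
  # unit-cell enumeration: boxes (0,0,2,2) and (1,0,3,2) share 2 of 6 cells
  expect_equal(box_iou(b(0, 0, 2, 2), b(1, 0, 3, 2)), 1 / 3)
  # symmetric and vectorised over the second argument
  many <- rbind(b(0, 0, 2, 2), b(1, 0, 3, 2), b(10, 10, 12, 12))
  expect_equal(box_iou(b(1, 0, 3, 2), many), c(1 / 3, 1, 0))
})

test_that("NMS keeps the highest-scoring of overlapping boxes", {
  one <- data.frame(x_min = 0, y_min = 0, x_max = 2, y_max = 2, score = 0.5)
  expect_equal(nms(one), one)
  dup <- rbind(one, one)
  dup$score <- c(0.9, 0.8)
  expect_equal(nrow(nms(dup)), 1)
  expect_equal(nms(dup)$score, 0.9)
  # chain: A suppresses B; C survives because its only link was through B
  chain <- data.frame(
    x_min = c(0, 0, 0), y_min = c(0, 10, 20),
    x_max = c(30, 30, 30), y_max = c(20, 30, 40),
    score = c(0.9, 0.8, 0.7)
  )
  kept <- nms(chain, iou_thresh = 0.3)
  expect_equal(kept$score, c(0.9, 0.7))
})

test_that("NMS equals the brute-force oracle on random instances", {
  set.seed(42)
  for (rep in 1:300) {
    n <- sample(1:12, 1)
    dets <- rand_boxes(n)
    thr <- sample(c(0.1, 0.3, 0.5), 1)
    kept <- nms(dets, iou_thresh = thr)
    expect_equal(sort(match(do.call(paste, kept[1:4]),
                            do.call(paste, dets[1:4]))),
                 oracle_nms_keep(dets, thr))
  }
})

test_that("greedy matching follows the score-ordered highest-IoU rule", {
  gt <- data.frame(x_min = 0, y_min = 0, x_max = 32, y_max = 32)
  d_exact <- data.frame(x_min = 0, y_min = 0, x_max = 32, y_max = 32,
                        score = 0.9)
  o <- match_detections(d_exact, gt)
  expect_equal(c(o$tp, o$fp_n, o$fn_n), c(1, 0, 0))
  expect_true(all(o$tp_pairs$iou >= 0.5))

  # IoU 0.4 detection: both an FP and an FN
  d_off <- data.frame(x_min = 13.7, y_min = 0, x_max = 45.7, y_max = 32,
                      score = 0.9)
  stopifnot(abs(box_iou(d_off, gt) - 0.4) < 0.01)
  o <- match_detections(d_off, gt)
  expect_equal(c(o$tp, o$fp_n, o$fn_n), c(0, 1, 1))

  # two detections on one GT: higher score wins, the other is an FP
  d2 <- data.frame(x_min = c(0, 2), y_min = c(0, 0),
                   x_max = c(32, 34), y_max = c(32, 32),
                   score = c(0.9, 0.6))
  o <- match_detections(d2, gt)
  expect_equal(c(o$tp, o$fp_n, o$fn_n), c(1, 1, 0))
  expect_equal(o$tp_pairs$det_idx, 1L)
})

test_that("greedy matching equals its oracle and count identities hold", {
  set.seed(99)
  for (rep in 1:300) {
    dets <- rand_boxes(sample(0:12, 1))
    gts <- rand_boxes(sample(0:8, 1), scores = FALSE)
    o <- match_detections(dets, gts)
    expect_equal(c(tp = o$tp, fp = o$fp_n, fn = o$fn_n),
                 oracle_match_counts(dets, gts, 0.5))
    # TP + FN = |GT|, TP + FP = |dets|, every det/gt used at most once
    expect_equal(o$tp + o$fn_n, nrow(gts))
    expect_equal(o$tp + o$fp_n, nrow(dets))
    expect_false(any(duplicated(o$tp_pairs$det_idx)))
    expect_false(any(duplicated(o$tp_pairs$gt_idx)))
  }
})

test_that("metrics follow the defining identities, zero-denominator = 0", {
  m <- compute_metrics(590, 229, 20)
  expect_equal(round_half_up(m$sensitivity, 3), 0.967)
  expect_equal(round_half_up(m$precision, 3), 0.720)
  expect_equal(round_half_up(m$f1, 3), 0.826)
  expect_equal(m$f1, 2 * 590 / (2 * 590 + 229 + 20), tolerance = 1e-12)
  expect_equal(unlist(compute_metrics(0, 0, 10)[c("sensitivity", "precision", "f1")]),
               c(sensitivity = 0, precision = 0, f1 = 0))
  expect_equal(unlist(compute_metrics(0, 0, 0)[c("sensitivity", "precision", "f1")]),
               c(sensitivity = 0, precision = 0, f1 = 0))
  expect_error(compute_metrics(-1, 0, 0), "non-negative")
})

test_that("aggregation is a micro-average over patches, never a mean of F1s", {
  o1 <- match_detections(
    data.frame(x_min = 0, y_min = 0, x_max = 32, y_max = 32, score = 0.9),
    data.frame(x_min = 0, y_min = 0, x_max = 32, y_max = 32))
  expect_equal(aggregate_global(list(o1)),
               compute_metrics(o1$tp, o1$fp_n, o1$fn_n))
  # patch A: (1,0,0); patch B: (0,1,1)  ->  pooled F1 = 2/(2+1+1) = 0.5
  o2 <- match_detections(
    data.frame(x_min = 100, y_min = 0, x_max = 132, y_max = 32, score = 0.8),
    data.frame(x_min = 200, y_min = 0, x_max = 232, y_max = 32))
  agg <- aggregate_global(list(o1, o2))
  expect_equal(agg$f1, 0.5)
  expect_equal(aggregate_global(list())$f1, 0)
})

test_that("threshold sweep rematches at each t with the keep rule score >= t", {
  gts <- data.frame(x_min = c(0, 100), y_min = 0, x_max = c(32, 132),
                    y_max = 32)
  dets <- data.frame(
    x_min = c(0, 100, 200), y_min = 0, x_max = c(32, 132, 232), y_max = 32,
    score = c(0.9, 0.8, 0.3)
  )
  curve <- threshold_curve(dets, gts)
  expect_s3_class(curve, "threshold_curve")
  expect_equal(nrow(curve), 100)
  # t=0.01 equals unthresholded; t=1.0 keeps nothing here
  o_all <- match_detections(dets, gts)
  expect_equal(curve$f1[curve$t == 0.01],
               compute_metrics(o_all$tp, o_all$fp_n, o_all$fn_n)$f1)
  expect_equal(curve$tp[curve$t == 1.00], 0)
  # hand enumeration: at t=0.5 counts (2,0,0); at t=0.85 counts (1,0,1)
  expect_equal(curve$f1[curve$t == 0.50], 1.0)
  expect_equal(curve$f1[curve$t == 0.85], 2 / 3)
  # kept detections and TP non-increasing, FN non-decreasing in t
  expect_true(all(diff(curve$tp) <= 0))
  expect_true(all(diff(curve$fn) >= 0))
  expect_true(all(diff(curve$tp + curve$fp) <= 0))
})

test_that("threshold monotonicity holds over random score sets", {
  set.seed(7)
  for (rep in 1:20) {
    patches <- make_patch_lattice(4)
    gts <- make_gt_on_patches(patches, 3)
    dets <- simulate_detections(gts, detector_model(), patches, seed = rep)
    curve <- threshold_curve(dets, gts)
    expect_true(all(diff(curve$tp) <= 0))
    expect_true(all(diff(curve$fn) >= 0))
    expect_true(all(diff(curve$tp + curve$fp) <= 0))
  }
})

test_that("optimal threshold maximizes F1 with largest-t tie-break", {
  gts <- data.frame(x_min = c(0, 100), y_min = 0, x_max = c(32, 132),
                    y_max = 32)
  dets <- data.frame(
    x_min = c(0, 100, 200), y_min = 0, x_max = c(32, 132, 232), y_max = 32,
    score = c(1.0, 1.0, 0.3)
  )
  curve <- threshold_curve(dets, gts)
  op <- optimal_threshold(curve)
  # F1 is 1 for every t in (0.30, 1.00]; the tie-break takes the top
  expect_equal(op$T, 1.00)
  expect_equal(op$f1_at_T, 1.0)
  # exhaustive-scan oracle on random curves
  set.seed(11)
  for (rep in 1:50) {
    dd <- rand_boxes(sample(1:10, 1))
    gg <- rand_boxes(sample(1:6, 1), scores = FALSE)
    cv <- threshold_curve(dd, gg)
    best <- max(cv$f1)
    scan <- if (best > 0) max(cv$t[cv$f1 == best]) else 1.00
    expect_equal(suppressWarnings(optimal_threshold(cv))$T, scan)
  }
  # no detections: degenerate all-zero curve
  none <- threshold_curve(dets[0, ], gts)
  expect_warning(op0 <- optimal_threshold(none), "zero")
  expect_equal(op0$T, 1.00)
  expect_equal(op0$f1_at_T, 0)
})

test_that("threshold sweep at unique scores only agrees at the optimum", {
  set.seed(23)
  patches <- make_patch_lattice(6)
  gts <- make_gt_on_patches(patches, 3)
  dets <- simulate_detections(gts, detector_model(), patches, seed = 5)
  full <- threshold_curve(dets, gts)
  sparse_grid <- sort(unique(c(0.01, dets$score, 1.00)))
  sparse <- threshold_curve(dets, gts, grid = sparse_grid)
  # the exact score values index every achievable kept-set, so the sparse
  # sweep attains the full grid's optimum (and possibly a finer one)
  expect_gte(max(sparse$f1), max(full$f1) - 1e-12)
  expect_true(any(abs(sparse$f1 - max(full$f1)) < 1e-12))
})

test_that("operating point keeps scores >= T and drops low-confidence FPs", {
  dets <- data.frame(x_min = 0, y_min = 0, x_max = 32, y_max = 32,
                     score = c(0.97, 0.95, 0.053))
  expect_equal(apply_operating_point(dets, 0.96)$score, 0.97)
  expect_equal(nrow(apply_operating_point(dets, 0.01)), 3)
  # a 5.3%-confidence FP candidate is dismissed at every threshold selected
  # on validation in practice (all far above 0.1)
  for (T in c(0.96, 0.84, 0.91)) {
    expect_false(0.053 %in% apply_operating_point(dets, T)$score)
  }
})

test_that("per-fold experiment report averages the rounded fold metrics", {
  set.seed(31)
  mk_fold <- function(seed) {
    patches <- make_patch_lattice(8)
    gts_v <- make_gt_on_patches(patches[1:4, ], 3)
    gts_t <- make_gt_on_patches(patches[5:8, ], 3)
    list(
      val_dets = simulate_detections(gts_v, detector_model(),
                                     patches[1:4, ], seed = seed),
      test_dets = simulate_detections(gts_t, detector_model(),
                                      patches[5:8, ], seed = seed + 50),
      val_gts = gts_v, test_gts = gts_t
    )
  }
  folds <- list(fold1 = mk_fold(1), fold2 = mk_fold(2), fold3 = mk_fold(3))
  res <- evaluate_experiment(folds)
  rep <- res$report
  expect_equal(nrow(rep), 16)  # 4 rows per fold + 4 mean rows
  mean_opt_test <- rep[rep$Fold == "Average (mean)" &
                         rep$Threshold == "Optimised" & rep$Set == "Test", ]
  per_fold <- rep[rep$Fold != "Average (mean)" & rep$Threshold != "None" &
                    rep$Set == "Test", ]
  expect_equal(mean_opt_test$F1, round_half_up(mean(per_fold$F1), 3))
  # identical folds: the mean row equals each fold
  same <- list(fold1 = folds$fold1, fold2 = folds$fold1)
  rep2 <- evaluate_experiment(same)$report
  f1s <- rep2[rep2$Threshold == "None" & rep2$Set == "Val", "F1"]
  expect_equal(f1s[1], f1s[2])
  expect_equal(f1s[3], f1s[1])
  expect_error(evaluate_experiment(list(fold1 = list(val_dets = NULL))),
               "missing split")
})
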