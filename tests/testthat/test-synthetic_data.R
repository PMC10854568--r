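test_that("slide simulation is deterministic and respects its config", {
  cfg <- tiny_slide_config(seed = 3, n_mitoses = 25)
  s1 <- simulate_slide(cfg)
  s2 <- simulate_slide(cfg)
  expect_identical(s1$thumbnail, s2$thumbnail)
  expect_identical(s1$centroids, s2$centroids)
  expect_equal(nrow(s1$centroids), 25)
  # every centroid lies inside rendered tissue
  f <- cfg$factor
  cell_r <- floor(s1$centroids$y / f) + 1
  cell_c <- floor(s1$centroids$x / f) + 1
  expect_true(all(s1$mask$grid[cbind(cell_r, cell_c)]))
  # tissue darker than glass in the thumbnail
  expect_lt(mean(s1$thumbnail[s1$mask$grid]), mean(s1$thumbnail[!s1$mask$grid]))
  # zero mitoses: empty centroids, nonempty mask
  s0 <- simulate_slide(tiny_slide_config(seed = 3, n_mitoses = 0))
  expect_equal(nrow(s0$centroids), 0)
  expect_gt(sum(s0$mask$grid), 0)
})

test_that("configured tissue area matches the rendered mask fraction", {
  # ellipse with pi * rx * ry = half the slide area
  w <- 16000; h <- 16000
  ry <- 0.4 * h
  rx <- 0.5 * w * h / (pi * ry)
  cfg <- slide_sim_config("A", w, h,
                          tissue = list(list(cx = w / 2, cy = h / 2,
                                             rx = rx, ry = ry,
                                             noise_amp = 0)),
                          n_mitoses = 0, seed = 1)
  s <- simulate_slide(cfg)
  expect_equal(mean(s$mask$grid), 0.5, tolerance = 0.05 / 0.5)
  # a region poking out of the slide is rejected up front
  expect_error(
    slide_sim_config("B", 1000, 1000,
                     tissue = list(list(cx = 900, cy = 500, rx = 200,
                                        ry = 100, noise_amp = 0)),
                     n_mitoses = 0),
    "bounds")
})

test_that("annotator simulation follows sensitivity, jitter and FP rates", {
  sl <- simulate_slide(tiny_slide_config(seed = 5, n_mitoses = 40))
  perfect <- list(annotator_model("a1", 1, 0, 0),
                  annotator_model("a2", 1, 0, 0))
  ann <- simulate_annotators(sl$centroids, perfect, sl, seed = 2)
  expect_equal(ann$a1$x, sl$centroids$x)
  expect_equal(ann$a2$y, sl$centroids$y)
  # sensitivity 0: only Poisson false marks remain
  blind <- list(annotator_model("a1", 0, 0, 2),
                annotator_model("a2", 0, 0, 0))
  ann0 <- simulate_annotators(sl$centroids, blind, sl, seed = 2)
  expect_equal(nrow(ann0$a2), 0)
  expect_true(all(ann0$a1$x >= 0 & ann0$a1$x <= sl$config$width_px))
  # binomial expectation: mean marks over seeds within 3 SD of n * p
  sl_big <- simulate_slide(tiny_slide_config(seed = 6, n_mitoses = 500))
  mod <- list(annotator_model("a1", 0.8, 2, 0))
  marks <- vapply(1:20, function(s) {
    nrow(simulate_annotators(sl_big$centroids, mod, sl_big, seed = s)$a1)
  }, numeric(1))
  expect_lt(abs(mean(marks) - 400), 3 * sqrt(500 * 0.8 * 0.2) / sqrt(20))
  # determinism
  expect_identical(simulate_annotators(sl$centroids, perfect, sl, seed = 9),
                   simulate_annotators(sl$centroids, perfect, sl, seed = 9))
})

test_that("detector simulation produces exact TPs and well-separated FPs", {
  set.seed(1)
  patches <- make_patch_lattice(4)
  gts <- make_gt_on_patches(patches, 3)
  # noiseless detector: one IoU-1 detection per GT
  exact <- detector_model(sensitivity = 1, box_jitter_sigma_px = 0,
                          fp_per_patch = 0)
  d <- simulate_detections(gts, exact, patches, seed = 4)
  expect_equal(nrow(d), nrow(gts))
  o <- match_detections(d, gts, iou_min = 0.999)
  expect_equal(o$tp, nrow(gts))
  # Poisson expectation for FP counts over seeds
  fp_only <- detector_model(sensitivity = 0, fp_per_patch = 3)
  patches100 <- make_patch_lattice(100)
  fp_counts <- vapply(1:20, function(s) {
    nrow(simulate_detections(gts[0, ], fp_only, patches100, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(fp_counts) - 300), 3 * sqrt(300) / sqrt(20))
  # every simulated FP is a genuine FP under IoU-0.5 matching
  dd <- simulate_detections(gts, detector_model(), patches, seed = 8)
  oo <- match_detections(dd[!dd$is_tp, , drop = FALSE], gts)
  expect_equal(oo$tp, 0)
  # scores separate: mean TP score > mean FP score (Beta 0.8 vs 0.2)
  big <- simulate_detections(make_gt_on_patches(patches100, 3),
                             detector_model(), patches100, seed = 3)
  expect_gt(mean(big$score[big$is_tp]), mean(big$score[!big$is_tp]))
  expect_true(all(big$score > 0 & big$score <= 1))
  expect_identical(simulate_detections(gts, detector_model(), patches, seed = 5),
                   simulate_detections(gts, detector_model(), patches, seed = 5))
})

test_that("the expected-F1 oracle handles sharp, FP-free and symmetric cases", {
  # point-mass scores: all mass at 0.9 (TP) and 0.1 (FP)
  sharp <- detector_model(sensitivity = 0.9,
                          tp_score_dist = score_dist_fixed(0.9),
                          fp_score_dist = score_dist_fixed(0.1))
  expect_equal(expected_f1_threshold_oracle(sharp, 100, 100), 0.90)
  # no FPs: any threshold only loses TPs, so the grid minimum wins
  expect_equal(expected_f1_threshold_oracle(detector_model(), 100, 0), 0.01)
  # symmetric distributions: equals an inline exhaustive grid scan
  sym <- detector_model(sensitivity = 0.9,
                        tp_score_dist = score_dist_beta(2, 2),
                        fp_score_dist = score_dist_beta(2, 2))
  grid <- threshold_grid()
  tp <- 100 * 0.9 * (1 - pbeta(grid, 2, 2))
  fp <- 50 * (1 - pbeta(grid, 2, 2))
  f1 <- 2 * tp / (2 * tp + fp + (100 - tp))
  expect_equal(expected_f1_threshold_oracle(sym, 100, 50),
               grid[max(which(f1 == max(f1)))])
  expect_error(expected_f1_threshold_oracle(detector_model(), 0, 10), "n_gt")
})

test_that("slide artifacts round-trip through the on-disk formats", {
  sl <- simulate_slide(tiny_slide_config(seed = 13, n_mitoses = 10))
  dir <- tempfile()
  paths <- write_slide_sim(sl, dir)
  expect_true(all(file.exists(unlist(paths))))
  thumb <- png::readPNG(paths$thumbnail)
  expect_equal(dim(thumb), dim(sl$thumbnail))
  back <- read.csv(paths$centroids)
  expect_equal(back$x, sl$centroids$x, tolerance = 1e-6)
  manifest <- jsonlite::read_json(paths$manifest)
  expect_equal(manifest$n_mitoses, 10)
})
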