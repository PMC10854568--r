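#' Configuration for a synthetic slide
#'
#' Describes a slide as one or more blobby elliptical tissue regions on a
#' glass background, with true mitosis centroids scattered uniformly inside
#' tissue. Geometry is in level-0 (full magnification) pixels; the rendered
#' thumbnail is produced directly at the stated downsample factor, since only
#' the downsized mask is ever used downstream.
#'
#' @param slide_id identifier
#' @param width_px,height_px slide dimensions in level-0 pixels
#' @param tissue list of regions, each a list with `cx`, `cy` (centre),
#'   `rx`, `ry` (radii), `noise_amp` (relative radial boundary-noise
#'   amplitude, e.g. 0.05)
#' @param n_mitoses number of true mitosis centroids
#' @param stain_foreground,glass_background grayscale levels in `[0,1]`
#'   (tissue must be darker than glass)
#' @param factor thumbnail downsample factor (default 32)
#' @param seed RNG seed for this slide
#' @return validated config of class `slide_sim_config`
#' @export
slide_sim_config <- function(slide_id, width_px, height_px, tissue,
                             n_mitoses, stain_foreground = 0.55,
                             glass_background = 0.92, factor = 32,
                             seed = 1L) {
  if (width_px <= 0 || height_px <= 0) stop("slide dimensions must be > 0", call. = FALSE)
  if (n_mitoses < 0) stop("n_mitoses must be >= 0", call. = FALSE)
  if (stain_foreground >= glass_background) {
    stop("tissue must be darker than glass (stain_foreground < glass_background)",
         call. = FALSE)
  }
  for (reg in tissue) {
    stopifnot(all(c("cx", "cy", "rx", "ry") %in% names(reg)))
    amp <- if (is.null(reg$noise_amp)) 0 else reg$noise_amp
    reach_x <- reg$rx * (1 + amp)
    reach_y <- reg$ry * (1 + amp)
    if (reg$cx - reach_x < 0 || reg$cx + reach_x > width_px ||
        reg$cy - reach_y < 0 || reg$cy + reach_y > height_px) {
      stop("tissue region exceeds slide bounds", call. = FALSE)
    }
  }
  structure(
    list(slide_id = slide_id, width_px = width_px, height_px = height_px,
         tissue = tissue, n_mitoses = n_mitoses,
         stain_foreground = stain_foreground,
         glass_background = glass_background,
         factor = factor, seed = seed),
    class = "slide_sim_config"
  )
}

#' Render a synthetic slide thumbnail, tissue mask, and true centroids
#'
#' The thumbnail is rendered at the configured downsample factor: each
#' thumbnail pixel is tissue if its level-0 centre falls inside one of the
#' (noise-perturbed) elliptical regions. Tissue pixels take the foreground
#' stain level and glass pixels the background level, each with mild
#' Gaussian texture. True mitosis centroids are placed uniformly over tissue
#' (a uniformly chosen tissue cell plus a uniform offset within it), so every
#' centroid lies inside the returned mask. Deterministic given the config
#' seed.
#'
#' @param config a [slide_sim_config()]
#' @return object of class `slide_sim`: list with `slide_id`, `thumbnail`
#'   (numeric matrix, rows = y), `mask` (a `tissue_mask`), `centroids`
#'   (data.frame `slide_id`, `x`, `y` in level-0 pixels), `config`
#' @export
simulate_slide <- function(config) {
  stopifnot(inherits(config, "slide_sim_config"))
  with_seed(config$seed, {
    f <- config$factor
    nx <- ceiling(config$width_px / f)
    ny <- ceiling(config$height_px / f)
    # per-region radial boundary noise: low-order random harmonics
    regions <- lapply(config$tissue, function(reg) {
      amp <- if (is.null(reg$noise_amp)) 0 else reg$noise_amp
      k <- 3:5
      reg$harm_amp <- if (amp > 0) amp * stats::runif(length(k)) / length(k) * 2 else rep(0, length(k))
      reg$harm_phase <- stats::runif(length(k), 0, 2 * pi)
      reg$harm_k <- k
      reg
    })
    cx0 <- (seq_len(nx) - 0.5) * f       # level-0 x of thumbnail pixel centres
    cy0 <- (seq_len(ny) - 0.5) * f
    xg <- matrix(cx0, nrow = ny, ncol = nx, byrow = TRUE)
    yg <- matrix(cy0, nrow = ny, ncol = nx)
    inside <- matrix(FALSE, ny, nx)
    for (reg in regions) {
      u <- (xg - reg$cx) / reg$rx
      v <- (yg - reg$cy) / reg$ry
      theta <- atan2(v, u)
      rho <- 1
      for (h in seq_along(reg$harm_k)) {
        rho <- rho + reg$harm_amp[h] * sin(reg$harm_k[h] * theta + reg$harm_phase[h])
      }
      inside <- inside | (u^2 + v^2 <= rho^2)
    }
    thumb <- matrix(
      stats::rnorm(ny * nx, config$glass_background, 0.01), ny, nx)
    thumb[inside] <- stats::rnorm(sum(inside), config$stain_foreground, 0.02)
    thumb[] <- pmin(1, pmax(thumb, 0))
    # centroids: uniform over tissue cells, uniform offset within a cell,
    # clamped to the slide so boundary cells cannot spill over
    tissue_cells <- which(inside, arr.ind = TRUE)
    if (config$n_mitoses > 0 && nrow(tissue_cells) == 0) {
      stop("no tissue to place mitoses in", call. = FALSE)
    }
    if (config$n_mitoses > 0) {
      pick <- sample.int(nrow(tissue_cells), config$n_mitoses, replace = TRUE)
      x <- (tissue_cells[pick, 2] - 1) * f + stats::runif(config$n_mitoses, 0, f)
      y <- (tissue_cells[pick, 1] - 1) * f + stats::runif(config$n_mitoses, 0, f)
      centroids <- data.frame(slide_id = config$slide_id,
                              x = pmin(x, config$width_px - 1e-6),
                              y = pmin(y, config$height_px - 1e-6))
    } else {
      centroids <- data.frame(slide_id = character(0),
                              x = numeric(0), y = numeric(0))
    }
    mask <- structure(list(slide_id = config$slide_id, factor = f,
                           grid = inside),
                      class = "tissue_mask")
    structure(list(slide_id = config$slide_id, thumbnail = thumb,
                   mask = mask, centroids = centroids, config = config),
              class = "slide_sim")
  })
}

#' Annotator behaviour model
#'
#' An annotator marks each true mitosis independently with probability
#' `sensitivity`, displaces the mark by isotropic Gaussian jitter, and adds
#' spurious marks at a Poisson rate per slide, placed uniformly in tissue.
#'
#' @param annotator_id identifier
#' @param sensitivity per-mitosis marking probability in `[0,1]`
#' @param jitter_sigma_px localization jitter SD in level-0 pixels (>= 0)
#' @param false_annotation_rate expected spurious marks per slide (>= 0)
#' @return validated model of class `annotator_model`
#' @export
annotator_model <- function(annotator_id, sensitivity = 0.85,
                            jitter_sigma_px = 4,
                            false_annotation_rate = 5) {
  if (sensitivity < 0 || sensitivity > 1) stop("sensitivity must be in [0,1]", call. = FALSE)
  if (jitter_sigma_px < 0 || false_annotation_rate < 0 ||
      !is.finite(jitter_sigma_px) || !is.finite(false_annotation_rate)) {
    stop("jitter and rates must be finite and >= 0", call. = FALSE)
  }
  structure(list(annotator_id = annotator_id, sensitivity = sensitivity,
                 jitter_sigma_px = jitter_sigma_px,
                 false_annotation_rate = false_annotation_rate),
            class = "annotator_model")
}

# uniform points in tissue: uniform tissue cell + uniform offset within it
sample_in_tissue <- function(n, mask, width_px, height_px) {
  f <- mask$factor
  cells <- which(mask$grid, arr.ind = TRUE)
  if (nrow(cells) == 0) stop("mask has no tissue", call. = FALSE)
  pick <- sample.int(nrow(cells), n, replace = TRUE)
  data.frame(
    x = pmin((cells[pick, 2] - 1) * f + stats::runif(n, 0, f), width_px - 1e-6),
    y = pmin((cells[pick, 1] - 1) * f + stats::runif(n, 0, f), height_px - 1e-6)
  )
}

#' Simulate independent annotators marking true mitoses
#'
#' @param true_centroids data.frame with `slide_id`, `x`, `y` (level-0)
#' @param models list of [annotator_model()]s
#' @param slide a `slide_sim` (or list with `mask`, `config`) providing the
#'   tissue mask and slide bounds for placing false marks
#' @param seed RNG seed
#' @return named list (by annotator_id) of centroid data.frames with columns
#'   `slide_id`, `annotator_id`, `x`, `y`
#' @export
simulate_annotators <- function(true_centroids, models, slide, seed = 1L) {
  stopifnot_cols(true_centroids, c("x", "y"))
  with_seed(seed, {
    w <- slide$config$width_px; h <- slide$config$height_px
    sid <- slide$slide_id
    out <- list()
    for (m in models) {
      stopifnot(inherits(m, "annotator_model"))
      n <- nrow(true_centroids)
      marked <- which(stats::runif(n) < m$sensitivity)
      x <- true_centroids$x[marked]
      y <- true_centroids$y[marked]
      if (m$jitter_sigma_px > 0 && length(marked) > 0) {
        x <- x + stats::rnorm(length(marked), 0, m$jitter_sigma_px)
        y <- y + stats::rnorm(length(marked), 0, m$jitter_sigma_px)
      }
      x <- pmin(pmax(x, 0), w - 1e-6)
      y <- pmin(pmax(y, 0), h - 1e-6)
      n_false <- stats::rpois(1, m$false_annotation_rate)
      if (n_false > 0) {
        fp <- sample_in_tissue(n_false, slide$mask, w, h)
        x <- c(x, fp$x); y <- c(y, fp$y)
      }
      out[[m$annotator_id]] <- data.frame(
        slide_id = rep(sid, length(x)),
        annotator_id = rep(m$annotator_id, length(x)),
        x = x, y = y, stringsAsFactors = FALSE
      )
    }
    out
  })
}

#' Score distributions for the simulated detector
#'
#' `score_dist_beta(a, b)` draws from a Beta(a, b); `score_dist_fixed(v)` is
#' a point mass at `v` (useful for sharp oracle tests). Draws are clamped
#' into (0, 1].
#'
#' @param shape1,shape2 Beta shape parameters (> 0)
#' @return a `score_dist` object
#' @export
score_dist_beta <- function(shape1, shape2) {
  if (shape1 <= 0 || shape2 <= 0) stop("Beta parameters must be > 0", call. = FALSE)
  structure(list(type = "beta", shape1 = shape1, shape2 = shape2),
            class = "score_dist")
}

#' @rdname score_dist_beta
#' @param value fixed score in (0, 1]
#' @export
score_dist_fixed <- function(value) {
  if (value <= 0 || value > 1) stop("fixed score must be in (0,1]", call. = FALSE)
  structure(list(type = "fixed", value = value), class = "score_dist")
}

draw_scores <- function(dist, n) {
  s <- switch(dist$type,
              beta = stats::rbeta(n, dist$shape1, dist$shape2),
              fixed = rep(dist$value, n))
  pmin(pmax(s, 1e-9), 1)
}

# P(score >= t)
score_survival <- function(dist, t) {
  switch(dist$type,
         beta = 1 - stats::pbeta(t, dist$shape1, dist$shape2),
         fixed = as.numeric(dist$value >= t))
}

#' Detector behaviour model
#'
#' Stands in for a trained object detector: each ground-truth box yields a
#' true-positive detection with probability `sensitivity` (box centre
#' jittered, score drawn from `tp_score_dist`), and each patch contributes
#' Poisson(`fp_per_patch`) false-positive boxes with scores from
#' `fp_score_dist`, placed away from all ground truth. A realistic
#' configuration gives true positives systematically higher scores than
#' false positives.
#'
#' @param sensitivity per-ground-truth detection probability
#' @param tp_score_dist,fp_score_dist [score_dist_beta()] /
#'   [score_dist_fixed()] objects; defaults Beta(8, 2) and Beta(2, 8)
#' @param fp_per_patch Poisson mean of false positives per patch
#' @param box_jitter_sigma_px SD of the true-positive box-centre jitter
#' @param box_size_px side of false-positive boxes
#' @return validated model of class `detector_model`
#' @export
detector_model <- function(sensitivity = 0.9,
                           tp_score_dist = score_dist_beta(8, 2),
                           fp_per_patch = 3,
                           fp_score_dist = score_dist_beta(2, 8),
                           box_jitter_sigma_px = 2,
                           box_size_px = 32) {
  if (sensitivity < 0 || sensitivity > 1) stop("sensitivity must be in [0,1]", call. = FALSE)
  if (fp_per_patch < 0) stop("fp_per_patch must be >= 0", call. = FALSE)
  stopifnot(inherits(tp_score_dist, "score_dist"),
            inherits(fp_score_dist, "score_dist"))
  structure(list(sensitivity = sensitivity, tp_score_dist = tp_score_dist,
                 fp_per_patch = fp_per_patch, fp_score_dist = fp_score_dist,
                 box_jitter_sigma_px = box_jitter_sigma_px,
                 box_size_px = box_size_px),
            class = "detector_model")
}

#' Simulate scored detections over a set of patches
#'
#' Ground-truth boxes and patches share one coordinate frame (slide pixels at
#' one level); each detection carries the `patch_id` of its patch as `ref`.
#' False positives are rejection-sampled at least one box diagonal away from
#' every ground-truth centre, so under the usual IoU-0.5 matching rule every
#' simulated false positive really is false. Deterministic given `seed`.
#'
#' @param gt_boxes box data.frame with a `ref` column naming the patch of
#'   each box (as from [assign_gt_to_patches()], kept in slide coordinates)
#' @param model a [detector_model()]
#' @param patches patch data.frame ([extract_patch_grid()] / [tile_hpf()])
#' @param seed RNG seed
#' @return detection data.frame: `ref`, `x_min`, `y_min`, `x_max`, `y_max`,
#'   `score`, `is_tp` (generator truth flag, for diagnostics only)
#' @export
simulate_detections <- function(gt_boxes, model, patches, seed = 1L) {
  stopifnot(inherits(model, "detector_model"))
  stopifnot_cols(gt_boxes, c("x_min", "y_min", "x_max", "y_max", "ref"))
  with_seed(seed, {
    rows <- list()
    n_gt <- nrow(gt_boxes)
    if (n_gt > 0) {
      hit <- stats::runif(n_gt) < model$sensitivity
      idx <- which(hit)
      if (length(idx) > 0) {
        dx <- stats::rnorm(length(idx), 0, model$box_jitter_sigma_px)
        dy <- stats::rnorm(length(idx), 0, model$box_jitter_sigma_px)
        rows[[1]] <- data.frame(
          ref = gt_boxes$ref[idx],
          x_min = gt_boxes$x_min[idx] + dx, y_min = gt_boxes$y_min[idx] + dy,
          x_max = gt_boxes$x_max[idx] + dx, y_max = gt_boxes$y_max[idx] + dy,
          score = draw_scores(model$tp_score_dist, length(idx)),
          is_tp = TRUE, stringsAsFactors = FALSE
        )
      }
    }
    gt_cx <- (gt_boxes$x_min + gt_boxes$x_max) / 2
    gt_cy <- (gt_boxes$y_min + gt_boxes$y_max) / 2
    min_dist <- sqrt(2) * model$box_size_px
    half <- model$box_size_px / 2
    for (p in seq_len(nrow(patches))) {
      n_fp <- stats::rpois(1, model$fp_per_patch)
      if (n_fp == 0) next
      placed <- 0L
      cxs <- numeric(0); cys <- numeric(0)
      tries <- 0L
      while (placed < n_fp && tries < 200L * n_fp) {
        tries <- tries + 1L
        cx <- stats::runif(1, patches$x[p] + half, patches$x[p] + patches$size[p] - half)
        cy <- stats::runif(1, patches$y[p] + half, patches$y[p] + patches$size[p] - half)
        if (n_gt > 0 && min(sqrt((gt_cx - cx)^2 + (gt_cy - cy)^2)) < min_dist) next
        placed <- placed + 1L
        cxs <- c(cxs, cx); cys <- c(cys, cy)
      }
      if (placed > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          ref = patches$patch_id[p],
          x_min = cxs - half, y_min = cys - half,
          x_max = cxs + half, y_max = cys + half,
          score = draw_scores(model$fp_score_dist, placed),
          is_tp = FALSE, stringsAsFactors = FALSE
        )
      }
    }
    if (length(rows) == 0) {
      return(data.frame(ref = character(0), x_min = numeric(0),
                        y_min = numeric(0), x_max = numeric(0),
                        y_max = numeric(0), score = numeric(0),
                        is_tp = logical(0)))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Expected-F1 threshold oracle for a simulated detector
#'
#' Closed-form counterpart of the empirical threshold sweep, used in tests to
#' check that the pipeline recovers the operating point implied by the score
#' distributions. At threshold t the expected counts are
#' `TP(t) = n_gt * sensitivity * P(tp score >= t)`,
#' `FP(t) = n_fp_expected * P(fp score >= t)`, `FN(t) = n_gt - TP(t)`,
#' and the oracle returns the grid threshold maximizing the implied F1, ties
#' broken by the largest threshold (the same tie-break as
#' [optimal_threshold()]).
#'
#' @param model a [detector_model()]
#' @param n_gt number of ground-truth boxes (> 0)
#' @param n_fp_expected expected total number of false positives
#' @param grid threshold grid (default [threshold_grid()])
#' @return the oracle threshold, a value on the grid
#' @export
expected_f1_threshold_oracle <- function(model, n_gt, n_fp_expected,
                                         grid = threshold_grid()) {
  stopifnot(inherits(model, "detector_model"))
  if (n_gt <= 0) stop("n_gt must be > 0", call. = FALSE)
  tp <- n_gt * model$sensitivity * score_survival(model$tp_score_dist, grid)
  fp <- n_fp_expected * score_survival(model$fp_score_dist, grid)
  fn <- n_gt - tp
  f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), 0)
  grid[max(which(f1 == max(f1)))]
}

#' Write synthetic-slide artifacts to disk
#'
#' Writes the thumbnail and truth mask as PNG, the true centroids as CSV,
#' and a small JSON manifest of the configuration. All coordinates are
#' level-0 pixels, 0-based.
#'
#' @param slide a `slide_sim`
#' @param dir output directory (created if needed)
#' @return invisibly, the named list of file paths written
#' @export
write_slide_sim <- function(slide, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    thumbnail = file.path(dir, paste0(slide$slide_id, "_thumb.png")),
    mask = file.path(dir, paste0(slide$slide_id, "_mask.png")),
    centroids = file.path(dir, paste0(slide$slide_id, "_truth_centroids.csv")),
    manifest = file.path(dir, paste0(slide$slide_id, "_manifest.json"))
  )
  png::writePNG(slide$thumbnail, paths$thumbnail)
  png::writePNG(slide$mask$grid * 1, paths$mask)
  utils::write.csv(slide$centroids, paths$centroids, row.names = FALSE)
  cfg <- slide$config
  jsonlite::write_json(
    list(slide_id = cfg$slide_id, width_px = cfg$width_px,
         height_px = cfg$height_px, n_mitoses = cfg$n_mitoses,
         factor = cfg$factor, seed = cfg$seed),
    paths$manifest, auto_unbox = TRUE)
  invisible(paths)
}
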