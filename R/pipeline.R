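#' Pipeline configuration
#'
#' Bundles every tunable constant of the workflow: geometry (pyramid level,
#' patch size, mask downsample factor), evaluation rules (NMS IoU, matching
#' IoU, threshold grid), annotation handling (agreement radius, ground-truth
#' box size), the cross-validation fold layout, and the synthetic cohort
#' description used when no real data is supplied.
#'
#' @param out_dir output directory for all stage artifacts
#' @param seed master seed; per-slide and per-fold seeds are derived from it
#' @param level working pyramid level for patches/boxes (default 1 = 20x)
#' @param patch_size patch side in pixels (default 512)
#' @param min_tissue minimum tissue fraction for keeping a patch (0.75)
#' @param mask_factor thumbnail/mask downsample factor (32)
#' @param nms_iou NMS suppression IoU (0.1)
#' @param match_iou true-positive matching IoU (0.5)
#' @param grid score-threshold grid (default [threshold_grid()])
#' @param agreement_radius_px annotator agreement radius, level-0 px (25)
#' @param gt_box_size_px ground-truth box side at `level` (32)
#' @param n_folds number of cross-validation folds (3); validation slides
#'   are assigned to folds round-robin at the slide (patient) level
#' @param trainval_slides,test_slides synthetic cohort slide descriptions:
#'   data.frames with `slide_id`, `width_px`, `height_px`, `n_mitoses`
#' @param hpf_width,hpf_height test-region (10-HPF) dimensions at `level`
#' @param annotators list of two [annotator_model()]s
#' @param detector a [detector_model()]
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir, seed = 1L, level = 1, patch_size = 512,
                            min_tissue = 0.75, mask_factor = 32,
                            nms_iou = 0.1, match_iou = 0.5,
                            grid = threshold_grid(),
                            agreement_radius_px = 25, gt_box_size_px = 32,
                            n_folds = 3,
                            trainval_slides = default_trainval_slides(),
                            test_slides = default_test_slides(),
                            hpf_width = 4096, hpf_height = 2560,
                            annotators = list(
                              annotator_model("anno1", 0.85, 4, 5),
                              annotator_model("anno2", 0.80, 4, 4)),
                            detector = detector_model()) {
  stopifnot(min_tissue >= 0, min_tissue <= 1, nms_iou >= 0, nms_iou <= 1,
            match_iou > 0, match_iou <= 1, n_folds >= 1)
  if (length(annotators) != 2) stop("exactly two annotators are modelled", call. = FALSE)
  overlap <- intersect(trainval_slides$slide_id, test_slides$slide_id)
  if (length(overlap) > 0) {
    stop("slide(s) in both train/val and test: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  if (nrow(trainval_slides) < n_folds) {
    stop("need at least one validation slide per fold", call. = FALSE)
  }
  folds <- split(trainval_slides$slide_id,
                 rep_len(seq_len(n_folds), nrow(trainval_slides)))
  names(folds) <- paste0("fold", seq_len(n_folds))
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), level = level,
         patch_size = patch_size, min_tissue = min_tissue,
         mask_factor = mask_factor, nms_iou = nms_iou,
         match_iou = match_iou, grid = grid,
         agreement_radius_px = agreement_radius_px,
         gt_box_size_px = gt_box_size_px, n_folds = n_folds,
         folds = folds, trainval_slides = trainval_slides,
         test_slides = test_slides,
         hpf_width = hpf_width, hpf_height = hpf_height,
         annotators = annotators, detector = detector),
    class = "pipeline_config"
  )
}

#' Default synthetic cohorts
#'
#' Six training/validation slides and three hold-out test slides, each 12.6 x
#' 8.4 mm at level 0 (about 1/4 the linear extent of a typical scanned
#' specimen, keeping the workflow desk-scale), with mitosis burdens spanning
#' the order-of-magnitude range seen across real slides.
#'
#' @return data.frame with `slide_id`, `width_px`, `height_px`, `n_mitoses`
#' @export
default_trainval_slides <- function() {
  data.frame(
    slide_id = sprintf("TV-%02d", 1:6),
    width_px = 55000, height_px = 36000,
    n_mitoses = c(260, 120, 45, 180, 75, 150),
    stringsAsFactors = FALSE
  )
}

#' @rdname default_trainval_slides
#' @export
default_test_slides <- function() {
  data.frame(
    slide_id = sprintf("TE-%02d", 1:3),
    width_px = 55000, height_px = 36000,
    n_mitoses = c(300, 200, 400),
    stringsAsFactors = FALSE
  )
}

# derived seed, kept inside 32-bit integer range (arithmetic in double)
derive_seed <- function(seed, k) {
  m <- 2000000011
  as.integer(((as.numeric(seed) %% m) * 1009 + as.numeric(k) * 97) %% m)
}

default_slide_tissue <- function(width_px, height_px) {
  list(list(cx = width_px * 0.5, cy = height_px * 0.5,
            rx = width_px * 0.36, ry = height_px * 0.38,
            noise_amp = 0.08))
}

#' Run the full evaluation workflow on synthetic data
#'
#' Stages, in order: `simulate` (slides, annotators), `agree` (two-annotator
#' matching and the agreement table), `extract` (tissue masks, patch grids
#' for train/val slides, 10-HPF tiling for test slides, ground-truth boxes
#' assigned to patches), `evaluate` (simulated detections, NMS, IoU matching,
#' unthresholded global metrics per fold), `optimize` (validation threshold
#' curves, F1-optimal operating points, thresholded re-evaluation),
#' `review` (false-positive export, simulated consensus review against the
#' generator's truth, updated dataset version, re-evaluation on the updated
#' ground truth). Each stage writes its artifacts as CSV/JSON/PNG under the
#' config's `out_dir`, and a run manifest records the configuration and
#' seed. Later stages require earlier ones in the same call.
#'
#' @param config a [pipeline_config()]
#' @param stages character vector of stages to run (default: all, in order)
#' @return invisibly, a list with the in-memory results of each stage
#'   (`slides`, `agreement`, `patches`, `gt`, `evaluation`, `optimized`,
#'   `review`) plus `files` (paths written)
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "agree", "extract",
                                    "evaluate", "optimize", "review")) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "agree", "extract", "evaluate", "optimize",
                  "review")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stages <- all_stages[all_stages %in% stages]
  # stage dependency check: a requested stage needs all its predecessors
  need_idx <- match(stages, all_stages)
  if (length(need_idx) > 0 && !identical(need_idx, seq_len(max(need_idx)))) {
    first_missing <- all_stages[setdiff(seq_len(max(need_idx)), need_idx)][1]
    stop("stage '", stages[which(need_idx > match(first_missing, all_stages))[1]],
         "' requires upstream stage '", first_missing, "'", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list(files = list())
  for (st in stages) {
    message("stage ", st, " ...")
    state <- switch(st,
      simulate = stage_simulate(config, state),
      agree = stage_agree(config, state),
      extract = stage_extract(config, state),
      evaluate = stage_evaluate(config, state),
      optimize = stage_optimize(config, state),
      review = stage_review(config, state)
    )
  }
  manifest <- file.path(config$out_dir, "run_manifest.json")
  cfg_json <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(config_summary(config), cfg_json, auto_unbox = TRUE,
                       pretty = TRUE)
  jsonlite::write_json(
    list(seed = config$seed, stages = stages,
         config_md5 = unname(tools::md5sum(cfg_json)),
         r_version = as.character(getRversion())),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  state$files$manifest <- manifest
  invisible(state)
}

config_summary <- function(config) {
  list(seed = config$seed, level = config$level,
       patch_size = config$patch_size, min_tissue = config$min_tissue,
       mask_factor = config$mask_factor, nms_iou = config$nms_iou,
       match_iou = config$match_iou,
       agreement_radius_px = config$agreement_radius_px,
       gt_box_size_px = config$gt_box_size_px, n_folds = config$n_folds,
       folds = config$folds,
       trainval_slides = config$trainval_slides,
       test_slides = config$test_slides)
}

all_slide_rows <- function(config) {
  tv <- config$trainval_slides; tv$role <- "trainval"
  te <- config$test_slides; te$role <- "test"
  rbind(tv, te)
}

stage_simulate <- function(config, state) {
  slides <- list()
  annos <- list()
  rows <- all_slide_rows(config)
  for (k in seq_len(nrow(rows))) {
    r <- rows[k, ]
    cfg <- slide_sim_config(
      slide_id = r$slide_id, width_px = r$width_px, height_px = r$height_px,
      tissue = default_slide_tissue(r$width_px, r$height_px),
      n_mitoses = r$n_mitoses, factor = config$mask_factor,
      seed = derive_seed(config$seed, k)
    )
    sl <- simulate_slide(cfg)
    slides[[r$slide_id]] <- sl
    annos[[r$slide_id]] <- simulate_annotators(
      sl$centroids, config$annotators, sl,
      seed = derive_seed(config$seed, 1000L + k))
    sdir <- file.path(config$out_dir, "slides")
    write_slide_sim(sl, sdir)
    for (a in annos[[r$slide_id]]) {
      utils::write.csv(a, file.path(
        sdir, paste0(r$slide_id, "_", a$annotator_id[1] %||% "anno", ".csv")),
        row.names = FALSE)
    }
  }
  state$slides <- slides
  state$annotations <- annos
  state$slide_roles <- rows
  state
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

stage_agree <- function(config, state) {
  if (is.null(state$annotations)) {
    stop("missing upstream artifact: annotations (run stage 'simulate' first)",
         call. = FALSE)
  }
  agreed <- list()
  counts <- list()
  for (sid in names(state$annotations)) {
    anns <- state$annotations[[sid]]
    m <- match_annotator_centroids(anns[[1]], anns[[2]],
                                   radius_px = config$agreement_radius_px)
    agreed[[sid]] <- m$agreed
    counts[[sid]] <- data.frame(
      slide_id = sid, n_anno1 = nrow(anns[[1]]), n_anno2 = nrow(anns[[2]]),
      n_agreed = nrow(m$agreed), stringsAsFactors = FALSE
    )
  }
  # the agreement table describes the training/validation annotation effort
  tv_ids <- config$trainval_slides$slide_id
  summ <- agreement_summary(do.call(rbind, counts[tv_ids]))
  path <- file.path(config$out_dir, "agreement.csv")
  write_agreement_csv(summ, path)
  state$agreed <- agreed
  state$agreement <- summ
  state$files$agreement <- path
  state
}

stage_extract <- function(config, state) {
  if (is.null(state$slides)) {
    stop("missing upstream artifact: simulated slides (run stage 'simulate')",
         call. = FALSE)
  }
  if (is.null(state$agreed)) {
    stop("missing upstream artifact: agreed centroids (run stage 'agree')",
         call. = FALSE)
  }
  lvl <- config$level
  patches <- list(); gt <- list(); truth <- list()
  for (k in seq_len(nrow(state$slide_roles))) {
    r <- state$slide_roles[k, ]
    sid <- r$slide_id
    sl <- state$slides[[sid]]
    dims_l <- c(floor(r$width_px / 2^lvl), floor(r$height_px / 2^lvl))
    mask <- build_tissue_mask(sl$thumbnail, factor = config$mask_factor,
                              slide_id = sid)
    if (r$role == "trainval") {
      p <- extract_patch_grid(dims_l, lvl, mask, size = config$patch_size,
                              min_tissue = config$min_tissue)
    } else {
      # hold-out test: one 10-HPF region centred on the tissue
      region <- list(
        slide_id = sid, level = lvl,
        x = round((dims_l[1] - config$hpf_width) / 2 / config$patch_size) *
          config$patch_size,
        y = round((dims_l[2] - config$hpf_height) / 2 / config$patch_size) *
          config$patch_size,
        width = config$hpf_width, height = config$hpf_height
      )
      p <- tile_hpf(region, size = config$patch_size)
    }
    gt_boxes <- centroids_to_boxes(state$agreed[[sid]],
                                   box_size_px = config$gt_box_size_px,
                                   level = lvl, from_level = 0,
                                   slide_dims = dims_l)
    gt_boxes$slide_id <- rep(sid, nrow(gt_boxes))
    truth_boxes <- centroids_to_boxes(sl$centroids,
                                      box_size_px = config$gt_box_size_px,
                                      level = lvl, from_level = 0,
                                      slide_dims = dims_l)
    truth_boxes$slide_id <- rep(sid, nrow(truth_boxes))
    asg <- assign_gt_to_patches(gt_boxes, p)
    if (r$role == "trainval") {
      p <- filter_patches_with_mitosis(p, asg)
      asg <- assign_gt_to_patches(gt_boxes, p)
    }
    # keep gt in slide coords but tag the owning patch
    gt_boxes <- gt_boxes[asg$assigned$gt_idx, , drop = FALSE]
    gt_boxes$ref <- asg$assigned$patch_id
    tasg <- assign_gt_to_patches(truth_boxes, p)
    truth_boxes <- truth_boxes[tasg$assigned$gt_idx, , drop = FALSE]
    truth_boxes$ref <- tasg$assigned$patch_id
    patches[[sid]] <- p
    gt[[sid]] <- gt_boxes
    truth[[sid]] <- truth_boxes
  }
  pm <- do.call(rbind, patches)
  rownames(pm) <- NULL
  path <- file.path(config$out_dir, "patch_manifest.csv")
  utils::write.csv(pm, path, row.names = FALSE)
  state$patches <- patches
  state$gt <- gt
  state$truth_boxes <- truth
  state$files$patch_manifest <- path
  state
}

# simulate + post-process detections for a set of slides in one fold
fold_detections <- function(config, state, slide_ids, seed) {
  dets <- list()
  for (sid in slide_ids) {
    d <- simulate_detections(state$truth_boxes[[sid]], config$detector,
                             state$patches[[sid]],
                             seed = derive_seed(seed, match(sid, names(state$patches))))
    if (nrow(d) > 0) d$slide_id <- sid
    dets[[sid]] <- d
  }
  dets <- do.call(rbind, dets)
  if (is.null(dets) || nrow(dets) == 0) {
    return(data.frame(ref = character(0), x_min = numeric(0),
                      y_min = numeric(0), x_max = numeric(0),
                      y_max = numeric(0), score = numeric(0),
                      is_tp = logical(0), slide_id = character(0)))
  }
  # NMS within each patch
  out <- do.call(rbind, lapply(split(dets, dets$ref), nms,
                               iou_thresh = config$nms_iou))
  rownames(out) <- NULL
  out
}

stage_evaluate <- function(config, state) {
  if (is.null(state$patches)) {
    stop("missing upstream artifact: patches (run stage 'extract')", call. = FALSE)
  }
  test_ids <- config$test_slides$slide_id
  folds <- list()
  for (fi in seq_along(config$folds)) {
    fname <- names(config$folds)[fi]
    val_ids <- config$folds[[fi]]
    folds[[fname]] <- list(
      val_dets = fold_detections(config, state, val_ids,
                                 derive_seed(config$seed, 5000L + fi)),
      test_dets = fold_detections(config, state, test_ids,
                                  derive_seed(config$seed, 6000L + fi)),
      val_gts = do.call(rbind, state$gt[val_ids]),
      test_gts = do.call(rbind, state$gt[test_ids])
    )
  }
  rows <- list()
  for (fname in names(folds)) {
    fd <- folds[[fname]]
    for (set in c("Val", "Test")) {
      dd <- if (set == "Val") fd$val_dets else fd$test_dets
      gg <- if (set == "Val") fd$val_gts else fd$test_gts
      m <- aggregate_global(match_by_ref(dd, gg, iou_min = config$match_iou))
      rows[[length(rows) + 1]] <- cbind(
        data.frame(Fold = fname, Data = "Initial", Set = set), m)
    }
  }
  initial_metrics <- do.call(rbind, rows)
  path <- file.path(config$out_dir, "metrics_initial.csv")
  write_metrics_csv(initial_metrics, path)
  state$folds <- folds
  state$initial_metrics <- initial_metrics
  state$files$metrics_initial <- path
  state
}

stage_optimize <- function(config, state) {
  if (is.null(state$folds)) {
    stop("missing upstream artifact: fold detections (run stage 'evaluate')",
         call. = FALSE)
  }
  res <- evaluate_experiment(state$folds, grid = config$grid,
                             iou_min = config$match_iou)
  path <- file.path(config$out_dir, "metrics_thresholded.csv")
  utils::write.csv(res$report, path, row.names = FALSE, na = "")
  for (fname in names(state$folds)) {
    curve <- threshold_curve(state$folds[[fname]]$val_dets,
                             state$folds[[fname]]$val_gts,
                             grid = config$grid, iou_min = config$match_iou)
    cpath <- file.path(config$out_dir,
                       paste0("threshold_curve_", fname, ".csv"))
    utils::write.csv(
      data.frame(t = curve$t,
                 sensitivity = round_half_up(curve$sensitivity, 3),
                 precision = round_half_up(curve$precision, 3),
                 f1 = round_half_up(curve$f1, 3)),
      cpath, row.names = FALSE)
    state$files[[paste0("curve_", fname)]] <- cpath
  }
  state$optimized <- res
  state$files$metrics_thresholded <- path
  state
}

stage_review <- function(config, state) {
  if (is.null(state$folds)) {
    stop("missing upstream artifact: fold detections (run stage 'evaluate')",
         call. = FALSE)
  }
  # unthresholded FP candidates from every fold's validation and test splits
  outcomes <- list(); det_sets <- list(); splits <- character(0)
  for (fname in names(state$folds)) {
    fd <- state$folds[[fname]]
    for (set in c("val", "test")) {
      dd <- if (set == "val") fd$val_dets else fd$test_dets
      gg <- if (set == "val") fd$val_gts else fd$test_gts
      per_ref <- match_by_ref(dd, gg, iou_min = config$match_iou)
      refs <- union(unique(dd$ref), unique(gg$ref))
      for (ri in seq_along(refs)) {
        outcomes[[length(outcomes) + 1]] <- per_ref[[ri]]
        det_sets[[length(det_sets) + 1]] <-
          dd[dd$ref == refs[ri], , drop = FALSE]
        splits <- c(splits, paste0(fname, "_", set))
      }
    }
  }
  manifest <- export_fp_review(outcomes, det_sets, splits)
  mpath <- file.path(config$out_dir, "fp_review_manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  # simulated consensus review: a candidate is a genuine (missed) mitosis iff
  # it overlaps the generator's truth (IoU > 0.5) - both reviewers agree
  truth_all <- do.call(rbind, state$truth_boxes)
  verdicts <- vapply(seq_len(nrow(manifest)), function(i) {
    hit <- any(same_box(manifest[i, , drop = FALSE], truth_all))
    if (hit) "mitosis" else "not_mitosis"
  }, character(1))
  decisions <- rbind(
    data.frame(candidate_id = manifest$candidate_id, verdict = verdicts,
               reviewer_id = "anno1", stringsAsFactors = FALSE),
    data.frame(candidate_id = manifest$candidate_id, verdict = verdicts,
               reviewer_id = "anno2", stringsAsFactors = FALSE)
  )
  dpath <- file.path(config$out_dir, "review_decisions.csv")
  utils::write.csv(decisions, dpath, row.names = FALSE)
  initial <- dataset_version("initial", do.call(rbind, state$gt))
  updated <- apply_review_decisions(initial, decisions, manifest)
  diff <- dataset_diff(initial, updated)
  utils::write.csv(diff$per_slide,
                   file.path(config$out_dir, "dataset_diff.csv"),
                   row.names = FALSE)
  # re-evaluate every fold against the updated ground truth
  upd_boxes <- updated$boxes
  upd_boxes$ref <- assign_ref_from_patches(upd_boxes, state$patches)
  upd_boxes <- upd_boxes[!is.na(upd_boxes$ref), , drop = FALSE]
  rows <- list()
  test_ids <- config$test_slides$slide_id
  for (fi in seq_along(config$folds)) {
    fname <- names(config$folds)[fi]
    fd <- state$folds[[fname]]
    val_ids <- config$folds[[fi]]
    for (set in c("Val", "Test")) {
      ids <- if (set == "Val") val_ids else test_ids
      dd <- if (set == "Val") fd$val_dets else fd$test_dets
      gg <- upd_boxes[upd_boxes$slide_id %in% ids, , drop = FALSE]
      m <- aggregate_global(match_by_ref(dd, gg, iou_min = config$match_iou))
      rows[[length(rows) + 1]] <- cbind(
        data.frame(Fold = fname, Data = "Updated", Set = set), m)
    }
  }
  updated_metrics <- do.call(rbind, rows)
  both <- rbind(state$initial_metrics, updated_metrics)
  both <- both[order(both$Fold, both$Set, both$Data), ]
  upath <- file.path(config$out_dir, "metrics_initial_vs_updated.csv")
  write_metrics_csv(both, upath)
  state$review <- list(manifest = manifest, decisions = decisions,
                       initial = initial, updated = updated, diff = diff,
                       updated_metrics = updated_metrics)
  state$files$fp_manifest <- mpath
  state$files$decisions <- dpath
  state$files$metrics_updated <- upath
  state
}

assign_ref_from_patches <- function(boxes, patches_by_slide) {
  ref <- rep(NA_character_, nrow(boxes))
  for (sid in unique(boxes$slide_id)) {
    idx <- which(boxes$slide_id == sid)
    p <- patches_by_slide[[sid]]
    if (is.null(p)) next
    asg <- assign_gt_to_patches(boxes[idx, , drop = FALSE], p)
    ref[idx[asg$assigned$gt_idx]] <- asg$assigned$patch_id
  }
  ref
}

#' Write the agreement table as CSV
#'
#' Column order mirrors the published agreement table: slide, the two
#' annotator counts, the agreed count, and the two percentages; the final
#' row carries the totals and the unweighted average percentages.
#'
#' @param summ an [agreement_summary()] result
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_agreement_csv <- function(summ, path) {
  tab <- summ$table
  n <- nrow(tab)
  tab$pct_agree_anno1 <- format(tab$pct_agree_anno1, nsmall = 2)
  tab$pct_agree_anno2 <- format(tab$pct_agree_anno2, nsmall = 2)
  tab$pct_agree_anno1[n] <- paste0("Avg: ", format(summ$avg[1], nsmall = 2))
  tab$pct_agree_anno2[n] <- paste0("Avg: ", format(summ$avg[2], nsmall = 2))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a metrics table as CSV with 3-decimal metrics and integer counts
#'
#' @param metrics data.frame with metric columns `sensitivity`, `precision`,
#'   `f1` plus count columns `tp`, `fp`, `fn` (any leading id columns kept)
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_metrics_csv <- function(metrics, path) {
  out <- metrics
  for (col in c("sensitivity", "precision", "f1")) {
    out[[col]] <- format(round_half_up(out[[col]], 3), nsmall = 3)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
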