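#' Intersection over union of axis-aligned boxes
#'
#' Boxes are half-open `[x_min, x_max) x [y_min, y_max)` in pixel coordinates.
#' `a` may be a single box (one-row data.frame or named list) and `b` a box
#' data.frame, in which case the IoU of `a` against every row of `b` is
#' returned.
#'
#' @param a box: list or data.frame with `x_min`, `y_min`, `x_max`, `y_max`
#' @param b box or box data.frame with the same columns
#' @return numeric vector of IoU values in `[0, 1]`
#' @export
box_iou <- function(a, b) {
  ix <- pmax(0, pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min))
  iy <- pmax(0, pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min))
  inter <- ix * iy
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  inter / (area_a + area_b - inter)
}

#' Greedy non-maximum suppression
#'
#' Repeatedly keeps the highest-scoring remaining detection and discards all
#' remaining detections whose IoU with it exceeds `iou_thresh`. Score ties are
#' broken by input order (earlier row wins). This is the standard
#' post-processing step used to remove redundant overlapping candidate boxes
#' before matching against ground truth; an aggressive overlap threshold of
#' 0.1 is the default used throughout this workflow.
#'
#' @param dets data.frame of detections with box columns and `score`
#' @param iou_thresh suppress a detection when its IoU with a kept,
#'   higher-scoring detection is strictly greater than this value
#' @return the kept detections, sorted by descending score (ties input order)
#' @export
nms <- function(dets, iou_thresh = 0.1) {
  stopifnot_cols(dets, c("x_min", "y_min", "x_max", "y_max", "score"))
  if (nrow(dets) == 0) return(dets)
  if (any(dets$score <= 0 | dets$score > 1)) {
    stop("detection scores must lie in (0, 1]", call. = FALSE)
  }
  x1 <- dets$x_min; y1 <- dets$y_min; x2 <- dets$x_max; y2 <- dets$y_max
  area <- (x2 - x1) * (y2 - y1)
  ord <- order(-dets$score, seq_len(nrow(dets)))
  alive <- rep(TRUE, nrow(dets))
  keep <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    alive[i] <- FALSE
    cand <- which(alive)
    if (length(cand) > 0) {
      ix <- pmax(0, pmin(x2[i], x2[cand]) - pmax(x1[i], x1[cand]))
      iy <- pmax(0, pmin(y2[i], y2[cand]) - pmax(y1[i], y1[cand]))
      inter <- ix * iy
      ious <- inter / (area[i] + area[cand] - inter)
      alive[cand[ious > iou_thresh]] <- FALSE
    }
  }
  dets[keep, , drop = FALSE]
}

#' Match detections to ground truth at an IoU threshold
#'
#' Detections are processed in descending score order (ties by input order);
#' each is matched to the not-yet-matched ground-truth box with the highest
#' IoU, provided that IoU is at least `iou_min`, and is otherwise a false
#' positive. Ground-truth boxes left unmatched are false negatives. Each
#' detection and each ground-truth box is used at most once.
#'
#' @param dets detection data.frame (box columns + `score`), normally already
#'   NMS-processed and optionally score-thresholded
#' @param gts ground-truth box data.frame in the same coordinate frame
#' @param iou_min minimum IoU for a true positive (default 0.5)
#' @return an object of class `match_outcome`: list with `tp_pairs`
#'   (det_idx, gt_idx, iou), `fp` (detection row indices), `fn` (ground-truth
#'   row indices), and the counts `tp`, `fp_n`, `fn_n`
#' @export
match_detections <- function(dets, gts, iou_min = 0.5) {
  stopifnot_cols(dets, c("x_min", "y_min", "x_max", "y_max", "score"))
  stopifnot_cols(gts, c("x_min", "y_min", "x_max", "y_max"))
  n_det <- nrow(dets)
  n_gt <- nrow(gts)
  dx1 <- dets$x_min; dy1 <- dets$y_min; dx2 <- dets$x_max; dy2 <- dets$y_max
  gx1 <- gts$x_min; gy1 <- gts$y_min; gx2 <- gts$x_max; gy2 <- gts$y_max
  d_area <- (dx2 - dx1) * (dy2 - dy1)
  g_area <- (gx2 - gx1) * (gy2 - gy1)
  gt_used <- rep(FALSE, n_gt)
  tp_det <- integer(0); tp_gt <- integer(0); tp_iou <- numeric(0)
  fp <- integer(0)
  ord <- if (n_det > 0) order(-dets$score, seq_len(n_det)) else integer(0)
  for (i in ord) {
    best_gt <- 0L
    best_iou <- -1
    if (n_gt > 0) {
      ix <- pmax(0, pmin(dx2[i], gx2) - pmax(dx1[i], gx1))
      iy <- pmax(0, pmin(dy2[i], gy2) - pmax(dy1[i], gy1))
      inter <- ix * iy
      ious <- inter / (d_area[i] + g_area - inter)
      ious[gt_used] <- -1
      best_gt <- which.max(ious)       # ties: lowest gt index
      best_iou <- ious[best_gt]
    }
    if (best_iou >= iou_min) {
      gt_used[best_gt] <- TRUE
      tp_det <- c(tp_det, i); tp_gt <- c(tp_gt, best_gt)
      tp_iou <- c(tp_iou, best_iou)
    } else {
      fp <- c(fp, i)
    }
  }
  structure(
    list(
      tp_pairs = data.frame(det_idx = tp_det, gt_idx = tp_gt, iou = tp_iou),
      fp = fp,
      fn = which(!gt_used),
      tp = length(tp_det),
      fp_n = length(fp),
      fn_n = sum(!gt_used)
    ),
    class = "match_outcome"
  )
}

#' Detection metrics from confusion counts
#'
#' Sensitivity (recall) is `TP / (TP + FN)`, precision is `TP / (TP + FP)`,
#' and F1 is their harmonic mean, `2 * sens * prec / (sens + prec)`, which
#' equals `2 TP / (2 TP + FP + FN)`. A ratio with a zero denominator is
#' defined as 0, and F1 is 0 when sensitivity + precision is 0; this keeps
#' degenerate splits (no ground truth or no detections) well defined.
#'
#' @param tp,fp,fn non-negative integer counts
#' @return one-row data.frame with `tp`, `fp`, `fn`, `sensitivity`,
#'   `precision`, `f1` (full precision, not rounded)
#' @export
compute_metrics <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative", call. = FALSE)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0
  data.frame(tp = tp, fp = fp, fn = fn,
             sensitivity = sens, precision = prec, f1 = f1)
}

#' Micro-averaged metrics over per-patch match outcomes
#'
#' Sums TP/FP/FN across all patches of a split before computing the metrics
#' (a global, micro-averaged F1). Per-patch F1 values are never averaged.
#'
#' @param outcomes list of `match_outcome` objects (one per patch)
#' @return one-row metrics data.frame as from [compute_metrics()]
#' @export
aggregate_global <- function(outcomes) {
  tp <- sum(vapply(outcomes, function(o) o$tp, integer(1)))
  fp <- sum(vapply(outcomes, function(o) o$fp_n, integer(1)))
  fn <- sum(vapply(outcomes, function(o) o$fn_n, integer(1)))
  compute_metrics(tp, fp, fn)
}

#' Match detections to ground truth within reference groups
#'
#' Groups both inputs by a reference column (patch or slide id) and runs
#' [match_detections()] within each group. Groups present in only one of the
#' two inputs still count: their unmatched detections are false positives
#' and their unmatched ground truth false negatives.
#'
#' @param dets,gts detection / ground-truth data.frames with `ref_col`
#' @param iou_min matching IoU threshold
#' @param ref_col grouping column name (default `"ref"`)
#' @return list of `match_outcome` objects, one per reference group
#' @export
match_by_ref <- function(dets, gts, iou_min = 0.5, ref_col = "ref") {
  refs <- union(unique(dets[[ref_col]]), unique(gts[[ref_col]]))
  d_split <- split(dets, factor(dets[[ref_col]], levels = refs))
  g_split <- split(gts, factor(gts[[ref_col]], levels = refs))
  lapply(refs, function(r) {
    match_detections(d_split[[r]], g_split[[r]], iou_min = iou_min)
  })
}

#' Metrics as a function of the score threshold
#'
#' For each threshold `t` on the grid, detections with `score >= t` are kept,
#' matched afresh against the ground truth, and globally aggregated. The
#' default grid is t = 0.01, 0.02, ..., 1.00.
#'
#' @param dets NMS-processed detection data.frame; if it has a `ref` column
#'   matching is done per `ref` group and aggregated
#' @param gts ground-truth box data.frame
#' @param grid increasing vector of thresholds
#' @param iou_min IoU threshold for matching
#' @return data.frame of class `threshold_curve` with column `t` plus the
#'   metric columns, one row per grid point
#' @export
threshold_curve <- function(dets, gts, grid = threshold_grid(), iou_min = 0.5) {
  if (length(grid) == 0) stop("threshold grid must be nonempty", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("threshold grid must be strictly increasing", call. = FALSE)
  }
  per_ref <- "ref" %in% names(dets) && "ref" %in% names(gts)
  if (per_ref) {
    refs <- union(unique(dets$ref), unique(gts$ref))
    dets_by_ref <- split(dets, factor(dets$ref, levels = refs))
    gts_by_ref <- split(gts, factor(gts$ref, levels = refs))
  }
  rows <- lapply(grid, function(t) {
    m <- if (per_ref) {
      aggregate_global(lapply(refs, function(r) {
        d <- dets_by_ref[[r]]
        match_detections(d[d$score >= t, , drop = FALSE], gts_by_ref[[r]],
                         iou_min = iou_min)
      }))
    } else {
      o <- match_detections(dets[dets$score >= t, , drop = FALSE], gts,
                            iou_min = iou_min)
      compute_metrics(o$tp, o$fp_n, o$fn_n)
    }
    cbind(data.frame(t = t), m)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_curve", class(out))
  out
}

#' The default probability-threshold grid
#'
#' @return thresholds 0.01, 0.02, ..., 1.00 (step 0.01)
#' @export
threshold_grid <- function() round((1:100) / 100, 2)

#' F1-optimal operating point on a threshold curve
#'
#' Selects `T = argmax_t F1(t)` over the grid. Ties are broken by the LARGEST
#' maximizing threshold: among equally good operating points the one keeping
#' the fewest detections is preferred, since the purpose of thresholding here
#' is false-positive reduction. An all-zero F1 curve returns t = 1.00 with a
#' warning.
#'
#' @param curve a [threshold_curve()] result
#' @return list of class `operating_point` with `T` and `f1_at_T`
#' @export
optimal_threshold <- function(curve) {
  if (nrow(curve) == 0) stop("empty threshold curve", call. = FALSE)
  best <- max(curve$f1)
  if (best <= 0) {
    warning("F1 is zero over the whole grid; returning the top of the grid")
    idx <- nrow(curve)
  } else {
    idx <- max(which(curve$f1 == best))
  }
  structure(list(T = curve$t[idx], f1_at_T = curve$f1[idx]),
            class = "operating_point")
}

#' Apply an operating point to a detection set
#'
#' Keeps detections whose score is at least the selected threshold `T`
#' (chosen on the validation split and applied unchanged to held-out data).
#'
#' @param dets detection data.frame
#' @param op an `operating_point` (or a bare numeric threshold)
#' @return the detections with `score >= T`
#' @export
apply_operating_point <- function(dets, op) {
  T <- if (inherits(op, "operating_point")) op$T else as.numeric(op)
  dets[dets$score >= T, , drop = FALSE]
}

#' Full per-fold evaluation with validation-selected thresholds
#'
#' For each fold: compute unthresholded validation and test metrics, select
#' the F1-optimal threshold on the validation split, and re-evaluate both
#' splits at that threshold. Metrics in the report are rounded half-up to 3
#' decimals; the mean rows are the arithmetic mean of the rounded per-fold
#' values (matching the convention used in published summary tables).
#'
#' @param folds named list; each element is a list with `val_dets`,
#'   `test_dets` (detection data.frames with a `ref` column), `val_gts`,
#'   `test_gts` (box data.frames with `ref`)
#' @param grid threshold grid (default [threshold_grid()])
#' @param iou_min matching IoU (default 0.5)
#' @return list with `report` (data.frame with columns Fold, Threshold, Set,
#'   Sensitivity, Precision, F1, TP, FP, FN including `Average (mean)` rows)
#'   and `operating_points` (named list per fold)
#' @export
evaluate_experiment <- function(folds, grid = threshold_grid(), iou_min = 0.5) {
  if (length(folds) == 0) stop("no folds supplied", call. = FALSE)
  need <- c("val_dets", "test_dets", "val_gts", "test_gts")
  for (f in names(folds)) {
    missing <- setdiff(need, names(folds[[f]]))
    if (length(missing) > 0) {
      stop("fold ", f, " is missing split(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  eval_split <- function(dets, gts) {
    aggregate_global(match_by_ref(dets, gts, iou_min = iou_min))
  }
  row_of <- function(fold, thr, set, m) {
    data.frame(
      Fold = fold, Threshold = thr, Set = set,
      Sensitivity = round_half_up(m$sensitivity, 3),
      Precision = round_half_up(m$precision, 3),
      F1 = round_half_up(m$f1, 3),
      TP = m$tp, FP = m$fp, FN = m$fn,
      stringsAsFactors = FALSE
    )
  }
  ops <- list()
  rows <- list()
  for (f in names(folds)) {
    fd <- folds[[f]]
    curve <- threshold_curve(fd$val_dets, fd$val_gts, grid = grid,
                             iou_min = iou_min)
    op <- optimal_threshold(curve)
    ops[[f]] <- op
    thr <- format(op$T, nsmall = 2)
    rows[[length(rows) + 1]] <- row_of(f, "None", "Val",
                                       eval_split(fd$val_dets, fd$val_gts))
    rows[[length(rows) + 1]] <- row_of(
      f, thr, "Val",
      eval_split(apply_operating_point(fd$val_dets, op), fd$val_gts))
    rows[[length(rows) + 1]] <- row_of(f, "None", "Test",
                                       eval_split(fd$test_dets, fd$test_gts))
    rows[[length(rows) + 1]] <- row_of(
      f, thr, "Test",
      eval_split(apply_operating_point(fd$test_dets, op), fd$test_gts))
  }
  report <- do.call(rbind, rows)
  # mean rows: arithmetic mean of the rounded per-fold values
  mean_rows <- list()
  for (thr_kind in c("None", "Optimised")) {
    for (set in c("Val", "Test")) {
      sel <- report$Set == set &
        (if (thr_kind == "None") report$Threshold == "None"
         else report$Threshold != "None")
      sub <- report[sel, , drop = FALSE]
      mean_rows[[length(mean_rows) + 1]] <- data.frame(
        Fold = "Average (mean)", Threshold = thr_kind, Set = set,
        Sensitivity = round_half_up(mean(sub$Sensitivity), 3),
        Precision = round_half_up(mean(sub$Precision), 3),
        F1 = round_half_up(mean(sub$F1), 3),
        TP = NA_integer_, FP = NA_integer_, FN = NA_integer_,
        stringsAsFactors = FALSE
      )
    }
  }
  report <- rbind(report, do.call(rbind, mean_rows))
  rownames(report) <- NULL
  list(report = report, operating_points = ops)
}
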