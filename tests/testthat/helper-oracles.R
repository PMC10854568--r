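# Independent brute-force oracles and small fixture builders.
# Oracles are written directly from the definitions, separately from the
# package implementations they check.

# O(n^2) NMS oracle: walk detections in descending score (ties: input
# order); keep one iff its IoU with every previously kept box is <= thresh.
oracle_nms_keep <- function(dets, iou_thresh) {
  ord <- order(-dets$score, seq_len(nrow(dets)))
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (pair_iou(dets[i, ], dets[j, ]) > iou_thresh) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

pair_iou <- function(a, b) {
  ix <- max(0, min(a$x_max, b$x_max) - max(a$x_min, b$x_min))
  iy <- max(0, min(a$y_max, b$y_max) - max(a$y_min, b$y_min))
  inter <- ix * iy
  inter / ((a$x_max - a$x_min) * (a$y_max - a$y_min) +
             (b$x_max - b$x_min) * (b$y_max - b$y_min) - inter)
}

# score-ordered greedy matching oracle built on an explicit IoU matrix
oracle_match_counts <- function(dets, gts, iou_min) {
  n_det <- nrow(dets); n_gt <- nrow(gts)
  if (n_det == 0) return(c(tp = 0L, fp = 0L, fn = n_gt))
  M <- matrix(0, n_det, n_gt)
  for (i in seq_len(n_det)) {
    for (j in seq_len(n_gt)) M[i, j] <- pair_iou(dets[i, ], gts[j, ])
  }
  used <- rep(FALSE, max(n_gt, 1))
  tp <- 0L
  for (i in order(-dets$score, seq_len(n_det))) {
    if (n_gt == 0) next
    best <- -1; best_j <- 0L
    for (j in seq_len(n_gt)) {
      if (!used[j] && M[i, j] > best) { best <- M[i, j]; best_j <- j }
    }
    if (best_j > 0 && best >= iou_min) { used[best_j] <- TRUE; tp <- tp + 1L }
  }
  c(tp = tp, fp = n_det - tp, fn = n_gt - sum(used[seq_len(n_gt)]))
}

# exhaustive maximum-cardinality point matching within a radius (<= ~6 pts)
oracle_max_matching <- function(a, b, radius) {
  na <- nrow(a); nb <- nrow(b)
  d <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2)
  best <- 0L
  recurse <- function(i, used_b, count) {
    if (i > na) { best <<- max(best, count); return(invisible()) }
    recurse(i + 1L, used_b, count)       # leave a_i unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && d[i, j] <= radius) {
        used_b[j] <- TRUE
        recurse(i + 1L, used_b, count + 1L)
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nb), 0L)
  best
}

rand_boxes <- function(n, extent = 100, min_side = 5, max_side = 30,
                       scores = TRUE) {
  x <- runif(n, 0, extent)
  y <- runif(n, 0, extent)
  w <- runif(n, min_side, max_side)
  h <- runif(n, min_side, max_side)
  df <- data.frame(x_min = x, y_min = y, x_max = x + w, y_max = y + h)
  if (scores) df$score <- round(runif(n, 0.01, 1), 3)
  df
}

# patch lattice + GT boxes for detector-simulation scenarios
make_patch_lattice <- function(n_patches, size = 512, per_row = 20,
                               slide_id = "S1") {
  i <- (seq_len(n_patches) - 1L) %% per_row
  j <- (seq_len(n_patches) - 1L) %/% per_row
  data.frame(
    slide_id = slide_id,
    patch_id = sprintf("%s_L1_%d_%d", slide_id, i * size, j * size),
    level = 1L, x = i * size, y = j * size, size = size,
    tissue_fraction = 1, stringsAsFactors = FALSE
  )
}

make_gt_on_patches <- function(patches, per_patch, box = 32, margin = 40) {
  rows <- lapply(seq_len(nrow(patches)), function(p) {
    cx <- runif(per_patch, patches$x[p] + margin,
                patches$x[p] + patches$size[p] - margin)
    cy <- runif(per_patch, patches$y[p] + margin,
                patches$y[p] + patches$size[p] - margin)
    data.frame(ref = patches$patch_id[p],
               x_min = cx - box / 2, y_min = cy - box / 2,
               x_max = cx + box / 2, y_max = cy + box / 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

tiny_slide_config <- function(seed = 7, n_mitoses = 30,
                              width = 16384, height = 16384) {
  slide_sim_config(
    slide_id = "SYN-1", width_px = width, height_px = height,
    tissue = list(list(cx = width / 2, cy = height / 2,
                       rx = width * 0.35, ry = height * 0.35,
                       noise_amp = 0.05)),
    n_mitoses = n_mitoses, seed = seed
  )
}
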