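#' Binary tissue mask from a slide thumbnail
#'
#' Thumbnails are rendered at a fixed downsample of the full-resolution slide
#' (factor 32 by default) and show stained tissue darker than the glass
#' background. The mask is produced by Otsu thresholding the inverted
#' luminance, followed by a 3x3 morphological closing and removal of
#' connected components smaller than `min_component_px` mask pixels.
#' A constant thumbnail admits no Otsu split: it is classified wholesale by a
#' mid-gray cutoff (all tissue if darker than 0.5, all background otherwise)
#' with a warning.
#'
#' @param thumbnail numeric matrix (grayscale, `[0,1]`, rows = y) or 3-d
#'   array (rows x cols x RGB)
#' @param factor integer downsample factor of the thumbnail relative to
#'   level 0 (default 32)
#' @param slide_id optional identifier carried on the result
#' @param min_component_px connected components smaller than this many mask
#'   pixels are removed (default 10)
#' @return object of class `tissue_mask`: list with `slide_id`, `factor`,
#'   and `grid`, a logical matrix (TRUE = tissue) with the thumbnail's shape
#' @export
build_tissue_mask <- function(thumbnail, factor = 32, slide_id = NULL,
                              min_component_px = 10) {
  if (factor < 1) stop("factor must be >= 1", call. = FALSE)
  lum <- if (length(dim(thumbnail)) == 3) {
    0.2126 * thumbnail[, , 1] + 0.7152 * thumbnail[, , 2] +
      0.0722 * thumbnail[, , 3]
  } else {
    thumbnail
  }
  rng <- range(lum)
  if (diff(rng) < 1e-8) {
    warning("constant thumbnail: no tissue/glass contrast, classifying by mid-gray cutoff")
    grid <- matrix(rng[1] < 0.5, nrow = nrow(lum), ncol = ncol(lum))
  } else {
    inv <- 1 - lum                       # tissue darker than glass -> brighter inverted
    thr <- EBImage::otsu(EBImage::Image(inv), range = c(0, 1))
    img <- EBImage::Image((inv > thr) * 1)
    img <- EBImage::closing(img, EBImage::makeBrush(3, shape = "box"))
    labels <- EBImage::imageData(EBImage::bwlabel(img))
    sizes <- tabulate(labels[labels > 0])
    small <- which(sizes < min_component_px)
    if (length(small) > 0) labels[labels %in% small] <- 0
    grid <- matrix(labels > 0, nrow = nrow(lum), ncol = ncol(lum))
  }
  structure(list(slide_id = slide_id, factor = factor, grid = grid),
            class = "tissue_mask")
}

# mask-cell index range (1-based, inclusive) covering a half-open pixel
# interval [lo, hi) at `level`, for a mask at `factor` relative to level 0
mask_cell_range <- function(lo, hi, level, factor) {
  lo0 <- lo * 2^level
  hi0 <- hi * 2^level
  seq.int(floor(lo0 / factor) + 1, ceiling(hi0 / factor))
}

#' Tissue-filtered non-overlapping patch grid
#'
#' Tiles the slide with non-overlapping `size x size` patches anchored at
#' (0, 0) (stride = size; partial edge tiles dropped) and keeps a patch iff
#' the tissue fraction over the mask cells covering its footprint is at
#' least `min_tissue`. The published rule dismisses patches with *less than*
#' 75% tissue, so a fraction of exactly `min_tissue` is kept.
#'
#' @param slide_dims `c(width, height)` in pixels at `level`
#' @param level pyramid level of the patch coordinates
#' @param mask a [build_tissue_mask()] result (factor relative to level 0)
#' @param size patch side in pixels (default 512)
#' @param min_tissue minimum tissue fraction to keep a patch (default 0.75)
#' @return data.frame of kept patches: `slide_id`, `patch_id`, `level`, `x`,
#'   `y`, `size`, `tissue_fraction`
#' @export
extract_patch_grid <- function(slide_dims, level, mask, size = 512,
                               min_tissue = 0.75) {
  stopifnot(inherits(mask, "tissue_mask"))
  exp_cols <- ceiling(slide_dims[1] * 2^level / mask$factor)
  exp_rows <- ceiling(slide_dims[2] * 2^level / mask$factor)
  if (nrow(mask$grid) != exp_rows || ncol(mask$grid) != exp_cols) {
    stop("mask dimensions (", nrow(mask$grid), "x", ncol(mask$grid),
         ") do not match slide dimensions at the stated level (expected ",
         exp_rows, "x", exp_cols, ")", call. = FALSE)
  }
  nx <- floor(slide_dims[1] / size)
  ny <- floor(slide_dims[2] / size)
  rows <- list()
  for (j in seq_len(ny) - 1L) {
    for (i in seq_len(nx) - 1L) {
      x <- i * size; y <- j * size
      cc <- mask_cell_range(x, x + size, level, mask$factor)
      rr <- mask_cell_range(y, y + size, level, mask$factor)
      frac <- mean(mask$grid[rr, cc])
      if (frac >= min_tissue) {
        rows[[length(rows) + 1]] <- data.frame(
          slide_id = if (is.null(mask$slide_id)) NA_character_ else mask$slide_id,
          patch_id = sprintf("%s_L%d_%d_%d",
                             if (is.null(mask$slide_id)) "slide" else mask$slide_id,
                             level, x, y),
          level = level, x = x, y = y, size = size,
          tissue_fraction = frac,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(slide_id = character(0), patch_id = character(0),
                      level = integer(0), x = integer(0), y = integer(0),
                      size = integer(0), tissue_fraction = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Tile a high-powered-field region into patches
#'
#' A 10-HPF test region (4096 x 2560 pixels at 20x, loosely covering the
#' conventional 2 mm^2 counting area) tiles into exactly 40 non-overlapping
#' 512 x 512 patches. Tiles are emitted row-major; partial tiles at the
#' right/bottom edge are dropped.
#'
#' @param region list with `x`, `y`, `width`, `height`, `level`, and
#'   optionally `slide_id`
#' @param size tile side in pixels (default 512)
#' @return patch data.frame as in [extract_patch_grid()] (tissue_fraction NA)
#' @export
tile_hpf <- function(region, size = 512) {
  stopifnot(all(c("x", "y", "width", "height", "level") %in% names(region)))
  nx <- floor(region$width / size)
  ny <- floor(region$height / size)
  if (nx < 1 || ny < 1) {
    warning("HPF region smaller than tile size; no tiles")
    return(data.frame(slide_id = character(0), patch_id = character(0),
                      level = integer(0), x = integer(0), y = integer(0),
                      size = integer(0), tissue_fraction = numeric(0)))
  }
  sid <- if (is.null(region$slide_id)) "slide" else region$slide_id
  grid <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)
  grid <- grid[order(grid$j, grid$i), ]     # row-major
  x <- region$x + grid$i * size
  y <- region$y + grid$j * size
  data.frame(
    slide_id = sid,
    patch_id = sprintf("%s_L%d_%d_%d", sid, region$level, x, y),
    level = region$level, x = x, y = y, size = size,
    tissue_fraction = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Assign ground-truth boxes to patches by centre containment
#'
#' Each ground-truth box belongs to the unique patch whose half-open
#' footprint `[x, x+size) x [y, y+size)` contains the box centre (a centre
#' lying exactly on a shared edge therefore goes to the higher-index tile).
#' Assigned boxes are translated to patch-local coordinates and clipped to
#' the patch. Boxes whose centre falls in no kept patch are reported
#' unassigned.
#'
#' @param gt_boxes box data.frame at the patches' level (optionally with
#'   `slide_id`, matched against the patch `slide_id` when both are present)
#' @param patches patch data.frame from [extract_patch_grid()] / [tile_hpf()]
#' @return list with `assigned` (data.frame: `gt_idx`, `patch_id`, local
#'   `x_min`, `y_min`, `x_max`, `y_max`) and `unassigned` (row indices of
#'   `gt_boxes`)
#' @export
assign_gt_to_patches <- function(gt_boxes, patches) {
  stopifnot_cols(gt_boxes, c("x_min", "y_min", "x_max", "y_max"))
  n <- nrow(gt_boxes)
  assigned <- list()
  unassigned <- integer(0)
  use_slide <- !is.null(gt_boxes$slide_id) && !all(is.na(patches$slide_id))
  for (k in seq_len(n)) {
    cx <- (gt_boxes$x_min[k] + gt_boxes$x_max[k]) / 2
    cy <- (gt_boxes$y_min[k] + gt_boxes$y_max[k]) / 2
    cand <- patches$x <= cx & cx < patches$x + patches$size &
      patches$y <= cy & cy < patches$y + patches$size
    if (use_slide) cand <- cand & patches$slide_id == gt_boxes$slide_id[k]
    idx <- which(cand)
    if (length(idx) == 0) {
      unassigned <- c(unassigned, k)
      next
    }
    p <- patches[idx[1], ]
    assigned[[length(assigned) + 1]] <- data.frame(
      gt_idx = k, patch_id = p$patch_id,
      x_min = max(0, gt_boxes$x_min[k] - p$x),
      y_min = max(0, gt_boxes$y_min[k] - p$y),
      x_max = min(p$size, gt_boxes$x_max[k] - p$x),
      y_max = min(p$size, gt_boxes$y_max[k] - p$y),
      stringsAsFactors = FALSE
    )
  }
  assigned <- if (length(assigned) > 0) {
    do.call(rbind, assigned)
  } else {
    data.frame(gt_idx = integer(0), patch_id = character(0),
               x_min = numeric(0), y_min = numeric(0),
               x_max = numeric(0), y_max = numeric(0))
  }
  list(assigned = assigned, unassigned = unassigned)
}

#' Keep only patches containing at least one ground-truth mitosis
#'
#' Training and validation use only mitosis-bearing patches; test-mode
#' callers evaluate all extracted patches and skip this filter.
#'
#' @param patches patch data.frame
#' @param assignment result of [assign_gt_to_patches()]
#' @return the subset of `patches` with >= 1 assigned ground-truth box
#' @export
filter_patches_with_mitosis <- function(patches, assignment) {
  keep <- patches$patch_id %in% unique(assignment$assigned$patch_id)
  patches[keep, , drop = FALSE]
}
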