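#' Read centroid mitosis annotations
#'
#' Supports two dialects: `"csv"` — plain CSV with columns
#' `slide_id, annotator_id, x, y` — and `"asap_xml"` — point ("Dot")
#' annotations exported by the ASAP slide viewer, where each
#' `<Annotation Type="Dot">` holds a single `<Coordinate X=".." Y="..">`.
#' Coordinates are level-0 (full magnification) pixels.
#'
#' @param path file path
#' @param dialect `"csv"` or `"asap_xml"`
#' @param slide_id,annotator_id identifiers to attach when the file carries
#'   none (required for `asap_xml`; override the file for `csv` if given)
#' @return data.frame with columns `slide_id`, `annotator_id`, `x`, `y`
#' @export
parse_centroids <- function(path, dialect = c("csv", "asap_xml"),
                            slide_id = NULL, annotator_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "csv") {
    if (file.size(path) == 0) {
      warning("empty annotation file: ", path)
      return(data.frame(slide_id = character(0), annotator_id = character(0),
                        x = numeric(0), y = numeric(0)))
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot_cols(df, c("x", "y"), what = path)
    if (!is.null(slide_id)) df$slide_id <- slide_id
    if (!is.null(annotator_id)) df$annotator_id <- annotator_id
    stopifnot_cols(df, c("slide_id", "annotator_id"), what = path)
    if (any(!is.finite(df$x)) || any(!is.finite(df$y))) {
      stop("non-numeric coordinate in ", path, call. = FALSE)
    }
    df[, c("slide_id", "annotator_id", "x", "y")]
  } else {
    if (is.null(slide_id) || is.null(annotator_id)) {
      stop("asap_xml carries no slide/annotator metadata; pass slide_id and annotator_id",
           call. = FALSE)
    }
    doc <- xml2::read_xml(path)
    dots <- xml2::xml_find_all(doc, "//Annotation[@Type='Dot']")
    if (length(dots) == 0) {
      warning("no Dot annotations in ", path)
      return(data.frame(slide_id = character(0), annotator_id = character(0),
                        x = numeric(0), y = numeric(0)))
    }
    coords <- lapply(dots, function(a) {
      c_node <- xml2::xml_find_first(a, ".//Coordinate")
      if (inherits(c_node, "xml_missing")) {
        stop("Annotation '", xml2::xml_attr(a, "Name"),
             "' has no Coordinate element in ", path, call. = FALSE)
      }
      x <- as.numeric(xml2::xml_attr(c_node, "X"))
      y <- as.numeric(xml2::xml_attr(c_node, "Y"))
      if (is.na(x) || is.na(y)) {
        stop("non-numeric X/Y on Annotation '", xml2::xml_attr(a, "Name"),
             "' in ", path, call. = FALSE)
      }
      c(x, y)
    })
    m <- do.call(rbind, coords)
    data.frame(slide_id = slide_id, annotator_id = annotator_id,
               x = m[, 1], y = m[, 2])
  }
}

#' Pair centroid annotations from two annotators
#'
#' Two point annotations agree when their Euclidean distance is at most
#' `radius_px`. Pairing is one-to-one and greedy in ascending distance order:
#' the closest eligible pair is committed first, then the next closest among
#' still-unpaired points, and so on; distance ties are broken by lower index
#' in `list_a`, then lower index in `list_b`. Annotations left unpaired carry
#' no agreement and are returned separately (in the study workflow they are
#' dismissed from the ground truth).
#'
#' @param list_a,list_b centroid data.frames for the same slide
#'   (columns `x`, `y`, optionally `slide_id`)
#' @param radius_px agreement radius in pixels (default 25 at level 0,
#'   about 5.75 um at 0.23 um/px)
#' @return list with `agreed` (data.frame: consensus `x`, `y` = midpoint of
#'   the pair, `a_idx`, `b_idx`, `dist`), `unmatched_a`, `unmatched_b`
#'   (row indices)
#' @export
match_annotator_centroids <- function(list_a, list_b, radius_px = 25) {
  stopifnot_cols(list_a, c("x", "y"), "list_a")
  stopifnot_cols(list_b, c("x", "y"), "list_b")
  if (radius_px <= 0) stop("radius_px must be > 0", call. = FALSE)
  sids <- unique(c(list_a$slide_id, list_b$slide_id))
  if (length(sids) > 1) {
    stop("annotations from mixed slides: ", paste(sids, collapse = ", "),
         call. = FALSE)
  }
  na <- nrow(list_a); nb <- nrow(list_b)
  if (na == 0 || nb == 0) {
    return(list(
      agreed = data.frame(x = numeric(0), y = numeric(0),
                          a_idx = integer(0), b_idx = integer(0),
                          dist = numeric(0)),
      unmatched_a = seq_len(na), unmatched_b = seq_len(nb)
    ))
  }
  dx <- outer(list_a$x, list_b$x, "-")
  dy <- outer(list_a$y, list_b$y, "-")
  d <- sqrt(dx^2 + dy^2)
  cand <- which(d <= radius_px, arr.ind = TRUE)
  ord <- order(d[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  a_used <- rep(FALSE, na); b_used <- rep(FALSE, nb)
  a_idx <- integer(0); b_idx <- integer(0); dd <- numeric(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (a_used[i] || b_used[j]) next
    a_used[i] <- TRUE; b_used[j] <- TRUE
    a_idx <- c(a_idx, i); b_idx <- c(b_idx, j); dd <- c(dd, d[i, j])
  }
  agreed <- data.frame(
    x = (list_a$x[a_idx] + list_b$x[b_idx]) / 2,
    y = (list_a$y[a_idx] + list_b$y[b_idx]) / 2,
    a_idx = a_idx, b_idx = b_idx, dist = dd
  )
  if (!is.null(list_a$slide_id) && nrow(agreed) > 0) {
    agreed$slide_id <- list_a$slide_id[agreed$a_idx]
    agreed <- agreed[, c("slide_id", setdiff(names(agreed), "slide_id"))]
  }
  list(agreed = agreed,
       unmatched_a = which(!a_used), unmatched_b = which(!b_used))
}

#' Per-slide and average two-annotator agreement statistics
#'
#' For each slide, reports the two annotators' counts, the number of agreed
#' mitoses, and the percentage of each annotator's count that was agreed
#' (`100 * n_agreed / n_anno_i`, rounded half-up to 2 decimals). A `Total:`
#' row sums the counts, and the average percentage per annotator is the
#' unweighted mean over slides of the per-slide percentages. Slides where an
#' annotator marked nothing have that percentage undefined: it is reported as
#' `NA` and excluded from the average, with a message.
#'
#' @param counts data.frame with columns `slide_id`, `n_anno1`, `n_anno2`,
#'   `n_agreed` (one row per slide), e.g. built from
#'   [match_annotator_centroids()] results
#' @return list with `table` (per-slide rows plus the totals row;
#'   columns `slide_id`, `n_anno1`, `n_anno2`, `n_agreed`, `pct_agree_anno1`,
#'   `pct_agree_anno2`) and `avg` (named vector of the two average
#'   percentages, rounded half-up to 2 decimals)
#' @export
agreement_summary <- function(counts) {
  stopifnot_cols(counts, c("slide_id", "n_anno1", "n_anno2", "n_agreed"))
  if (nrow(counts) == 0) stop("need at least one slide", call. = FALSE)
  bad <- counts$n_agreed > pmin(counts$n_anno1, counts$n_anno2)
  if (any(bad)) {
    stop("n_agreed exceeds an annotator count for slide(s): ",
         paste(counts$slide_id[bad], collapse = ", "), call. = FALSE)
  }
  pct <- function(agreed, n) ifelse(n > 0, round_half_up(100 * agreed / n, 2), NA_real_)
  tab <- data.frame(
    slide_id = counts$slide_id,
    n_anno1 = counts$n_anno1, n_anno2 = counts$n_anno2,
    n_agreed = counts$n_agreed,
    pct_agree_anno1 = pct(counts$n_agreed, counts$n_anno1),
    pct_agree_anno2 = pct(counts$n_agreed, counts$n_anno2),
    stringsAsFactors = FALSE
  )
  if (anyNA(tab$pct_agree_anno1) || anyNA(tab$pct_agree_anno2)) {
    message("slide(s) with a zero annotation count: percentage omitted and excluded from the average")
  }
  avg <- c(
    pct_agree_anno1 = round_half_up(mean(tab$pct_agree_anno1, na.rm = TRUE), 2),
    pct_agree_anno2 = round_half_up(mean(tab$pct_agree_anno2, na.rm = TRUE), 2)
  )
  total <- data.frame(
    slide_id = "Total:",
    n_anno1 = sum(tab$n_anno1), n_anno2 = sum(tab$n_anno2),
    n_agreed = sum(tab$n_agreed),
    pct_agree_anno1 = NA_real_, pct_agree_anno2 = NA_real_,
    stringsAsFactors = FALSE
  )
  list(table = rbind(tab, total), avg = avg)
}

#' Expand agreed centroids into square ground-truth boxes
#'
#' A centroid is a weak annotation: it marks the centre of a mitotic figure
#' without delineating it. For box-based detection evaluation each consensus
#' centroid is expanded to a square box of side `box_size_px` centred on the
#' (level-rescaled) point, clipped to the slide bounds. A box fully clipped
#' away (zero area) is dropped with a warning.
#'
#' @param agreed data.frame with columns `x`, `y` (and optionally `slide_id`)
#'   at level `from_level`
#' @param box_size_px even, positive box side in pixels at `level`
#' @param level pyramid level of the output boxes (default 1, i.e. 20x)
#' @param from_level level of the input centroids (default 0, i.e. 40x)
#' @param slide_dims optional `c(width, height)` at `level` for clipping
#' @return box data.frame (half-open corners) with any `slide_id` carried over
#' @export
centroids_to_boxes <- function(agreed, box_size_px = 32, level = 1,
                               from_level = 0, slide_dims = NULL) {
  stopifnot_cols(agreed, c("x", "y"))
  if (box_size_px <= 0 || box_size_px %% 2 != 0) {
    stop("box_size_px must be even and > 0", call. = FALSE)
  }
  if (nrow(agreed) == 0) return(empty_box_df())
  p <- rescale_point(agreed$x, agreed$y, from_level, level)
  half <- box_size_px / 2
  x_min <- p$x - half; x_max <- p$x + half
  y_min <- p$y - half; y_max <- p$y + half
  if (!is.null(slide_dims)) {
    x_min <- pmax(0, x_min); y_min <- pmax(0, y_min)
    x_max <- pmin(slide_dims[1], x_max); y_max <- pmin(slide_dims[2], y_max)
  } else {
    x_min <- pmax(0, x_min); y_min <- pmax(0, y_min)
  }
  keep <- x_max > x_min & y_max > y_min
  if (any(!keep)) {
    warning(sum(!keep), " box(es) clipped to zero area and dropped")
  }
  out <- data.frame(x_min = x_min, y_min = y_min,
                    x_max = x_max, y_max = y_max)[keep, , drop = FALSE]
  if (!is.null(agreed$slide_id)) out$slide_id <- agreed$slide_id[keep]
  rownames(out) <- NULL
  out
}

#' Rescale a point between pyramid levels
#'
#' Level `l + 1` halves the resolution of level `l`, so coordinates are
#' divided by `2^(to_level - from_level)`.
#'
#' @param x,y numeric coordinates at `from_level`
#' @param from_level,to_level non-negative pyramid levels
#' @return list with rescaled `x`, `y`
#' @export
rescale_point <- function(x, y, from_level, to_level) {
  if (from_level < 0 || to_level < 0) stop("levels must be >= 0", call. = FALSE)
  f <- 2^(to_level - from_level)
  list(x = x / f, y = y / f)
}
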