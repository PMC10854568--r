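#' A versioned ground-truth dataset
#'
#' The review cycle produces dataset versions: the `initial` set built from
#' annotator agreement, and an `updated` set where expert-confirmed
#' false-positive candidates have been promoted to ground truth.
#'
#' @param version_tag e.g. `"initial"` or `"updated"`
#' @param boxes ground-truth box data.frame with a `slide_id` column
#' @param provenance character vector of applied decision identifiers
#' @param added_ids candidate ids already promoted into this version
#' @return object of class `dataset_version`
#' @export
dataset_version <- function(version_tag, boxes,
                            provenance = character(),
                            added_ids = character()) {
  stopifnot_cols(boxes, c("slide_id", "x_min", "y_min", "x_max", "y_max"))
  structure(list(version_tag = version_tag, boxes = boxes,
                 provenance = provenance, added_ids = added_ids),
            class = "dataset_version")
}

# same-slide box identity: IoU > 0.5
same_box <- function(box, others) {
  if (nrow(others) == 0) return(logical(0))
  sl <- others$slide_id == box$slide_id
  iou <- box_iou(box, others)
  sl & iou > 0.5
}

#' Export false-positive candidates for expert review
#'
#' Collects every false-positive detection from a set of match outcomes into
#' a review manifest — all of them, regardless of confidence score, since the
#' point of the review is to find ground truth the annotators missed, not to
#' triage by model confidence. Candidates appearing in more than one
#' evaluation (e.g. the same box flagged in two folds) are deduplicated by
#' same-slide IoU > 0.5 identity. The manifest is sorted by slide then
#' position, and candidate ids are assigned after sorting so they are stable
#' for a given input.
#'
#' @param outcomes list of `match_outcome` objects
#' @param detections list of detection data.frames parallel to `outcomes`
#'   (each with `slide_id` or `ref`, box columns, `score`)
#' @param splits character vector (recycled) naming the fold/split of origin
#' @return manifest data.frame: `candidate_id`, `slide_id`, box columns,
#'   `score`, `split`
#' @export
export_fp_review <- function(outcomes, detections,
                             splits = rep("val", length(outcomes))) {
  stopifnot(length(outcomes) == length(detections))
  splits <- rep_len(splits, length(outcomes))
  rows <- list()
  for (k in seq_along(outcomes)) {
    o <- outcomes[[k]]
    d <- detections[[k]]
    if (length(o$fp) == 0) next
    fp <- d[o$fp, , drop = FALSE]
    sid <- if (!is.null(fp$slide_id)) fp$slide_id else fp$ref
    rows[[length(rows) + 1]] <- data.frame(
      slide_id = sid,
      x_min = fp$x_min, y_min = fp$y_min,
      x_max = fp$x_max, y_max = fp$y_max,
      score = fp$score, split = splits[k],
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(candidate_id = character(0), slide_id = character(0),
                      x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      score = numeric(0), split = character(0)))
  }
  all_fp <- do.call(rbind, rows)
  kept <- all_fp[0, , drop = FALSE]
  for (i in seq_len(nrow(all_fp))) {
    if (!any(same_box(all_fp[i, , drop = FALSE], kept))) {
      kept <- rbind(kept, all_fp[i, , drop = FALSE])
    }
  }
  kept <- kept[order(kept$slide_id, kept$x_min, kept$y_min), , drop = FALSE]
  kept <- cbind(candidate_id = sprintf("fp_%05d", seq_len(nrow(kept))), kept,
                stringsAsFactors = FALSE)
  rownames(kept) <- NULL
  kept
}

#' Apply expert review decisions to a ground-truth dataset
#'
#' Candidates with a `"mitosis"` verdict are promoted verbatim into the
#' ground truth; `"not_mitosis"` candidates are ignored. Every decision must
#' reference a manifest candidate, and reviewers must agree: conflicting
#' verdicts for the same candidate are an error (the workflow requires
#' consensus, mirroring the two-annotator agreement rule used to build the
#' initial set). Re-applying the same decisions is a no-op.
#'
#' @param initial a [dataset_version()]
#' @param decisions data.frame with `candidate_id`, `verdict`
#'   (`"mitosis"` / `"not_mitosis"`), `reviewer_id`
#' @param items the review manifest from [export_fp_review()]
#' @param decision_tag identifier for the decision file (provenance)
#' @return a new `dataset_version` with tag `"updated"`
#' @export
apply_review_decisions <- function(initial, decisions, items,
                                   decision_tag = "review-1") {
  stopifnot(inherits(initial, "dataset_version"))
  stopifnot_cols(decisions, c("candidate_id", "verdict", "reviewer_id"))
  bad_verdict <- !decisions$verdict %in% c("mitosis", "not_mitosis")
  if (any(bad_verdict)) {
    stop("unknown verdict(s): ",
         paste(unique(decisions$verdict[bad_verdict]), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(decisions$candidate_id, items$candidate_id)
  if (length(unknown) > 0) {
    stop("decision(s) for unknown candidate id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n_verdicts <- tapply(decisions$verdict, decisions$candidate_id,
                       function(v) length(unique(v)))
  conflict <- names(n_verdicts)[n_verdicts > 1]
  if (length(conflict) > 0) {
    stop("conflicting reviewer verdicts (consensus required) for: ",
         paste(conflict, collapse = ", "), call. = FALSE)
  }
  accepted <- unique(decisions$candidate_id[decisions$verdict == "mitosis"])
  new_ids <- setdiff(accepted, initial$added_ids)
  add <- items[items$candidate_id %in% new_ids,
               c("slide_id", "x_min", "y_min", "x_max", "y_max"),
               drop = FALSE]
  boxes <- rbind(initial$boxes[, c("slide_id", "x_min", "y_min",
                                   "x_max", "y_max"), drop = FALSE], add)
  rownames(boxes) <- NULL
  dataset_version(
    version_tag = "updated",
    boxes = boxes,
    provenance = unique(c(initial$provenance, decision_tag)),
    added_ids = c(initial$added_ids, new_ids)
  )
}

#' Difference between two ground-truth dataset versions
#'
#' Counts, per slide and in total, the boxes present in `v2` but not in `v1`
#' (same-slide IoU > 0.5 identity). In the review workflow `v2` extends
#' `v1`; boxes of `v1` missing from `v2` are reported as removals with a
#' warning, since the refinement cycle only ever adds ground truth.
#'
#' @param v1,v2 [dataset_version()] objects
#' @return list with `per_slide` (data.frame `slide_id`, `added`, `removed`)
#'   and `total_added`, `total_removed`
#' @export
dataset_diff <- function(v1, v2) {
  stopifnot(inherits(v1, "dataset_version"), inherits(v2, "dataset_version"))
  slides <- sort(unique(c(v1$boxes$slide_id, v2$boxes$slide_id)))
  count_new <- function(from, into) {
    # boxes in `from` with no IoU>0.5 partner in `into`
    if (nrow(from) == 0) return(0L)
    sum(vapply(seq_len(nrow(from)), function(i) {
      !any(same_box(from[i, , drop = FALSE], into))
    }, logical(1)))
  }
  per_slide <- do.call(rbind, lapply(slides, function(s) {
    b1 <- v1$boxes[v1$boxes$slide_id == s, , drop = FALSE]
    b2 <- v2$boxes[v2$boxes$slide_id == s, , drop = FALSE]
    data.frame(slide_id = s,
               added = count_new(b2, b1),
               removed = count_new(b1, b2),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_slide)) {
    per_slide <- data.frame(slide_id = character(0), added = integer(0),
                            removed = integer(0))
  }
  if (sum(per_slide$removed) > 0) {
    warning("boxes of v1 are missing from v2; the review workflow should only add ground truth")
  }
  list(per_slide = per_slide,
       total_added = sum(per_slide$added),
       total_removed = sum(per_slide$removed))
}
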