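#' Match detections to simulator ground truth
#'
#' Greedily pairs detected objects with ground-truth objects of the same well
#' by centroid distance (closest pairs first, each object used once, pairs
#' beyond `match_radius` discarded). Used as the test oracle: it separates
#' genuine class errors from vulva-class false positives caused by
#' confounder speckles, which truthfully carry vulva-like area and intensity.
#'
#' @param objects labeled detections for one well ([detect_well()]).
#' @param truth a `ground_truth` object (or its `object_table`).
#' @param match_radius maximum centroid distance (px) for a match.
#' @return list with `pairs` (detection index, truth index, classes,
#'   distance), `per_class` (for each countable class: n_true, n_detected,
#'   n_matched_same_class), `speckle_detections` (detections matched to true
#'   speckles, by label), `unmatched_detections` and `missed_truth` counts.
#' @export
evaluate_detections <- function(objects, truth, match_radius = 8) {
  tt <- if (inherits(truth, "ground_truth")) truth$object_table else truth
  pairs <- list()
  det_match <- rep(NA_integer_, nrow(objects))
  tru_match <- rep(NA_integer_, nrow(tt))
  for (k in unique(c(objects$field, tt$field))) {
    di <- which(objects$field == k)
    ti <- which(tt$field == k)
    if (!length(di) || !length(ti)) next
    d <- sqrt(outer(objects$x[di], tt$x[ti], "-")^2 +
              outer(objects$y[di], tt$y[ti], "-")^2)
    cand <- which(d <= match_radius, arr.ind = TRUE)
    if (!nrow(cand)) next
    cand <- cand[order(d[cand]), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- di[cand[r, 1]]; j <- ti[cand[r, 2]]
      if (!is.na(det_match[i]) || !is.na(tru_match[j])) next
      det_match[i] <- j; tru_match[j] <- i
      pairs[[length(pairs) + 1]] <- data.frame(
        det = i, truth = j, det_label = objects$label[i],
        true_class = tt$class[j], dist = d[cand[r, 1], cand[r, 2]])
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(det = integer(0), truth = integer(0),
               det_label = character(0), true_class = character(0),
               dist = numeric(0))
  per_class <- do.call(rbind, lapply(DETECT_CLASSES, function(cl) {
    data.frame(class = cl,
               n_true = sum(tt$class == cl),
               n_detected = sum(objects$label == cl),
               n_matched_same_class = sum(pairs$det_label == cl &
                                          pairs$true_class == cl))
  }))
  spk <- pairs[pairs$true_class == "speckle", , drop = FALSE]
  list(pairs = pairs, per_class = per_class,
       speckle_detections = table(factor(spk$det_label,
                                         levels = c(DETECT_CLASSES, "rejected"))),
       unmatched_detections = sum(is.na(det_match)),
       missed_truth = sum(is.na(tru_match) & tt$class != "speckle"))
}

#' Aggregate per-class detection accuracy over many wells
#'
#' Sums [evaluate_detections()] results across wells and reports, per class,
#' the aggregate relative count error with speckle-attributed detections
#' removed from the vulva channel, plus the speckle-driven vulva false
#' positives as their own figure.
#'
#' @param evals list of [evaluate_detections()] results.
#' @return data frame per class: n_true, n_detected, n_speckle_attributed,
#'   count_error (|detected - speckle-attributed - true| / true).
#' @export
summarize_detection_accuracy <- function(evals) {
  per <- lapply(DETECT_CLASSES, function(cl) {
    n_true <- sum(vapply(evals, function(e)
      e$per_class$n_true[e$per_class$class == cl], numeric(1)))
    n_det <- sum(vapply(evals, function(e)
      e$per_class$n_detected[e$per_class$class == cl], numeric(1)))
    n_spk <- sum(vapply(evals, function(e)
      as.numeric(e$speckle_detections[[cl]]), numeric(1)))
    data.frame(class = cl, n_true = n_true, n_detected = n_det,
               n_speckle_attributed = n_spk,
               count_error = if (n_true > 0)
                 abs(n_det - n_spk - n_true) / n_true else NA_real_)
  })
  do.call(rbind, per)
}
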