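# Evaluation metrics: confusion matrix (rows = truth, columns =
# prediction, fixed label order), per-class accuracy, weighted overall
# accuracy (class-support-weighted mean of per-class accuracies, which
# equals trace/total), tracker binary accuracy, and an end-to-end
# report bundling the pipeline's quality measures.

#' Confusion matrix over the five action classes
#'
#' @param true_labels,pred_labels Character vectors of equal length.
#' @return 5 x 5 integer matrix; rows are true labels, columns predicted,
#'   both in [action_labels()] order.
#' @export
confusion <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels))
    stop("label vectors must have equal length")
  labs <- action_labels()
  bad <- setdiff(unique(c(true_labels, pred_labels)), labs)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  tf <- factor(true_labels, levels = labs)
  pf <- factor(pred_labels, levels = labs)
  cm <- table(true = tf, predicted = pf)
  matrix(as.integer(cm), nrow = length(labs),
         dimnames = list(true = labs, predicted = labs))
}

#' Per-class accuracy from a confusion matrix
#'
#' Diagonal over row sum; classes with zero support are reported as NA
#' (and excluded from the weighting in
#' [weighted_overall_accuracy()], where their zero support removes them
#' anyway).
#'
#' @param cm Confusion matrix (rows = truth).
#' @return Named numeric vector of per-class accuracies.
#' @export
per_class_accuracy <- function(cm) {
  support <- rowSums(cm)
  acc <- ifelse(support > 0, diag(cm) / support, NA_real_)
  setNames(acc, rownames(cm))
}

#' Weighted overall accuracy
#'
#' Class-support-weighted mean of the per-class accuracies,
#' `sum(support_c * acc_c) / sum(support_c)`, which is identically
#' `trace(cm) / total`. The weighting accounts for class imbalance:
#' each class contributes in proportion to its support.
#'
#' @param cm Confusion matrix (rows = truth).
#' @return Accuracy in `[0, 1]`.
#' @export
weighted_overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

#' Evaluate tracking on a simulated scenario
#'
#' Runs the cascaded tracker on a scenario from [generate_scenario()]
#' and scores it against the simulator's ground truth: per-tracklet
#' binary classification accuracy (target vs non-target) and the
#' fraction of the target's visible frames covered by the fused track
#' with the target's own detection.
#'
#' The reference tracklet is chosen as the surviving tracklet with the
#' most ground-truth target detections (the stand-in for the human
#' picking a reference in real data).
#'
#' @param scenario Result of [generate_scenario()].
#' @param config A [pipeline_config()].
#' @return List: `tracklet_accuracy`, `coverage`, `n_tracklets`,
#'   `n_pruned`, `track`, `tracklet_table` (with truth column),
#'   `reference_id`.
#' @export
evaluate_tracking <- function(scenario, config = pipeline_config()) {
  tracklets <- build_tracklets(scenario$stream, config$iou_threshold)
  pruned <- prune_tracklets(tracklets, config$min_tracklet_length,
                            config$min_mean_kp_conf)
  gt <- scenario$ground_truth
  gt_key <- paste(gt$frame, gt$det_index)
  actor_of <- setNames(gt$actor_id, gt_key)
  target_id <- scenario$config$actors[[
    which(vapply(scenario$config$actors, `[[`, logical(1),
                 "is_target"))]]$actor_id

  tr_target_count <- vapply(pruned, function(tr) {
    keys <- vapply(tr$detections, function(d)
      paste(d$frame, d$det_index), character(1))
    sum(actor_of[keys] == target_id, na.rm = TRUE)
  }, numeric(1))
  tr_len <- vapply(pruned, `[[`, integer(1), "length")
  truth <- tr_target_count > tr_len / 2
  if (!any(truth))
    stop("no target tracklet survived pruning; relax the pruning ",
         "thresholds")
  ref_id <- pruned[[which.max(tr_target_count)]]$id

  track <- fuse_to_track(pruned, ref_id, config$affinity_threshold)
  tt <- track$tracklet_table
  tt$truth <- truth[match(tt$tracklet_id,
                          vapply(pruned, `[[`, integer(1), "id"))]
  acc <- tracklet_classification_accuracy(tt$accepted, tt$truth)

  # coverage: target-visible frames where the fused track holds the
  # target's own detection
  target_rows <- gt[gt$actor_id == target_id, ]
  track_keys <- vapply(track$detections, function(d)
    paste(d$frame, d$det_index), character(1))
  covered <- paste(target_rows$frame, target_rows$det_index) %in%
    track_keys
  list(tracklet_accuracy = acc, coverage = mean(covered),
       n_tracklets = length(tracklets), n_pruned = length(pruned),
       track = track, tracklet_table = tt, reference_id = ref_id)
}

#' End-to-end pipeline report
#'
#' Bundles the tracking metrics, the clip inventory and the classifier
#' metrics of one pipeline run into a single serializable report.
#'
#' @param tracking Result of [evaluate_tracking()] (or NULL).
#' @param clips Clip data.frame from [segment_clips()] (or NULL).
#' @param true_labels,pred_labels Classifier truth/predictions on the
#'   evaluation set (or NULL).
#' @param config The [pipeline_config()] used.
#' @return List of class `"poseaction_report"`.
#' @export
end_to_end_report <- function(tracking = NULL, clips = NULL,
                              true_labels = NULL, pred_labels = NULL,
                              config = pipeline_config()) {
  rep <- list(config_hash = config_hash(config), seed = config$seed)
  if (!is.null(tracking)) {
    rep$tracklet_accuracy <- tracking$tracklet_accuracy
    rep$track_coverage <- tracking$coverage
    rep$n_tracklets <- tracking$n_tracklets
    rep$n_pruned_tracklets <- tracking$n_pruned
  }
  if (!is.null(clips)) {
    counts <- table(factor(clips$label, levels = action_labels()))
    rep$clip_counts <- as.list(setNames(as.integer(counts),
                                        names(counts)))
  }
  if (!is.null(true_labels)) {
    cm <- confusion(true_labels, pred_labels)
    rep$confusion <- unname(apply(cm, 1, as.integer, simplify = FALSE))
    rep$per_class_accuracy <- as.list(per_class_accuracy(cm))
    rep$weighted_overall_accuracy <- weighted_overall_accuracy(cm)
  }
  structure(rep, class = "poseaction_report")
}

#' Write / read an end-to-end report as JSON
#' @param report A `"poseaction_report"`.
#' @param path JSON path.
#' @return `path` (write) or the report list (read).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE)
  structure(rep, class = "poseaction_report")
}
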