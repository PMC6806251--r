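# End-to-end orchestration: simulate -> track -> clips -> featurize ->
# train -> evaluate, the same composition the CLI's `run-all` command
# and the vignette use.

#' Run the full pipeline on a simulated scene
#'
#' Simulates a multi-actor scenario, tracks the target through it,
#' segments the target's annotation into clips, featurizes them, and
#' scores a classifier (trained on an independently simulated, balanced
#' clip corpus) on the scenario's clips. Returns an
#' [end_to_end_report()].
#'
#' @param scenario_config A [scenario_config()].
#' @param config A [pipeline_config()].
#' @param train_clips_per_class Clips per class simulated for classifier
#'   training (0 skips the classifier stage).
#' @param clip_len_frames Frames per training clip.
#' @param verbose Print stage progress.
#' @return List with the report and the intermediate artifacts
#'   (`scenario`, `tracking`, `clips`, `model`).
#' @export
run_pipeline <- function(scenario_config, config = pipeline_config(),
                         train_clips_per_class = 100,
                         clip_len_frames = 60, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("simulating scenario (", scenario_config$n_frames, " frames, ",
      length(scenario_config$actors), " actors)")
  scenario <- generate_scenario(scenario_config)

  say("tracking target")
  tracking <- evaluate_tracking(scenario, config)

  say("segmenting clips")
  clips <- segment_clips(scenario$annotations, fps = config$fps)

  model <- NULL
  true_labels <- NULL
  pred_labels <- NULL
  if (train_clips_per_class > 0 && nrow(clips) > 0) {
    grid_H <- as.integer(ceiling(scenario_config$frame_size[1] *
                                   config$downscale))
    grid_W <- as.integer(ceiling(scenario_config$frame_size[2] *
                                   config$downscale))
    say("simulating training corpus (", train_clips_per_class,
        " clips/class)")
    corpus <- generate_clip_dataset(train_clips_per_class,
                                    clip_len_frames, fps = config$fps,
                                    frame_size = scenario_config$frame_size,
                                    seed = config$seed + 1L)
    Xtr <- featurize_clips(corpus, C = config$C, H = grid_H, W = grid_W,
                           sigma = config$heatmap_sigma,
                           downscale = config$downscale)
    # subject-wise validation split
    subjects <- unique(attr(Xtr, "subjects"))
    val_sub <- subjects[seq_len(max(1L, round(0.1 * length(subjects))))]
    is_val <- attr(Xtr, "subjects") %in% val_sub
    cfg <- model_config(C = config$C, H = grid_H, W = grid_W,
                        seed = config$seed)
    cls <- config$classifier
    for (k in names(cls)) cfg[[k]] <- cls[[k]]
    model <- build_model(cfg)
    say("training classifier")
    model <- train_classifier(model, Xtr[, !is_val, drop = FALSE],
                              attr(Xtr, "labels")[!is_val],
                              Xtr[, is_val, drop = FALSE],
                              attr(Xtr, "labels")[is_val],
                              verbose = verbose)

    say("featurizing scenario clips")
    scen_clips <- extract_clip_keypoints(tracking$track, clips)
    Xte <- featurize_clips(scen_clips, C = config$C, H = grid_H,
                           W = grid_W, sigma = config$heatmap_sigma,
                           downscale = config$downscale)
    true_labels <- attr(Xte, "labels")
    pred_labels <- predict_labels(model, Xte)
  }

  report <- end_to_end_report(tracking = tracking, clips = clips,
                              true_labels = true_labels,
                              pred_labels = pred_labels, config = config)
  list(report = report, scenario = scenario, tracking = tracking,
       clips = clips, model = model)
}
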