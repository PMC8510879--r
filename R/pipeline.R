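# Declarative end-to-end pipeline: simulate -> train classifier -> train
# U-Net -> tune thresholds -> segment -> evaluate, with one root seed fanned
# out to per-stage seeds by fixed offsets so stages are individually
# reproducible.

PIPELINE_STAGES <- c("simulate", "train_classifier", "train_unet", "tune",
                     "segment", "evaluate")
SEGMENT_METHODS <- c(CAM_METHODS, "global", "unet")

#' Run the weakly supervised segmentation pipeline
#'
#' Executes the requested stages in canonical order on a phantom cohort.
#' The configuration is a plain named list (or the path of a YAML file with
#' the same structure): top-level `seed`, `out_dir`, `stages`, `methods`,
#' plus per-stage parameter blocks `phantom`, `classifier_train`,
#' `unet` passed to [phantom_config()], [train_config()] and
#' [unet_config()]. Every stage logs its parameters, seed and outputs;
#' tabular artifacts (slice labels, training histories, tuning grids,
#' per-subject reports, ICC table) are written as CSV under `out_dir`.
#' Re-running with the same config reproduces all outputs.
#'
#' @param config named list or path to a YAML file.
#' @return (invisibly) a list with the in-memory artifacts of the executed
#'   stages: `cohort`, `classifier`, `unet`, `tuning`, `pred`, `reports`,
#'   `icc`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% "."
  stages <- config$stages %||% PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad))
    stop(sprintf("unknown stage(s) %s; valid stages: %s",
                 paste(bad, collapse = ", "), paste(PIPELINE_STAGES, collapse = ", ")),
         call. = FALSE)
  methods <- config$methods %||% SEGMENT_METHODS
  bad <- setdiff(methods, SEGMENT_METHODS)
  if (length(bad))
    stop(sprintf("unknown method(s) %s; valid methods: %s",
                 paste(bad, collapse = ", "), paste(SEGMENT_METHODS, collapse = ", ")),
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) message(sprintf("[camseg %s] ", format(Sys.time(), "%H:%M:%S")),
                                    sprintf(...))
  log_line("config hash %s, root seed %d", rlang::hash(config), seed)

  art <- list()
  need <- function(what, stage_hint) {
    if (is.null(art[[what]]))
      stop(sprintf("missing upstream artifact '%s'; run stage '%s' first", what, stage_hint),
           call. = FALSE)
    art[[what]]
  }

  if ("simulate" %in% stages) {
    pcfg <- do.call(phantom_config,
                    utils::modifyList(list(seed = seed), config$phantom %||% list()))
    log_line("simulate: %d subjects, %s grid", pcfg$n_subjects,
             paste(c(pcfg$slice_shape, pcfg$slices_per_subject), collapse = "x"))
    art$cohort <- generate_cohort(pcfg)
    art$slices <- extract_slices(art$cohort)
    readr::write_csv(slice_label_table(art$cohort), file.path(out_dir, "slice_labels.csv"))
    if (isTRUE(config$write_volumes)) {
      vdir <- file.path(out_dir, "volumes")
      for (v in art$cohort$volume) write_volume_sample(v, vdir)
      log_line("simulate: volumes written to %s", vdir)
    }
  }

  split_slices <- function(sp) {
    sl <- need("slices", "simulate")
    sl[sl$split == sp, ]
  }

  if ("train_classifier" %in% stages) {
    shp <- dim(need("slices", "simulate")$pet[[1]])
    ccfg <- classifier_config(input_shape = shp)
    tcfg <- do.call(train_config,
                    utils::modifyList(list(epochs = 6L, seed = seed + 1L),
                                      config$classifier_train %||% list()))
    log_line("train_classifier: %d epochs, lr %g, w+ %g", tcfg$epochs,
             tcfg$learning_rate, tcfg$positive_class_weight)
    art$classifier <- train_classifier(split_slices("train"), split_slices("val"),
                                       ccfg, tcfg)
    readr::write_csv(art$classifier$history, file.path(out_dir, "classifier_history.csv"))
  }

  if ("train_unet" %in% stages && "unet" %in% methods) {
    shp <- dim(need("slices", "simulate")$pet[[1]])
    ucfg <- do.call(unet_config,
                    utils::modifyList(list(epochs = 8L, input_shape = shp, seed = seed + 2L),
                                      config$unet %||% list()))
    tr <- split_slices("train")
    log_line("train_unet: %d epochs on %d slices", ucfg$epochs, nrow(tr))
    art$unet <- train_unet(tr, split_slices("val"), ucfg)
    readr::write_csv(art$unet$history, file.path(out_dir, "unet_history.csv"))
  }

  if ("tune" %in% stages) {
    model <- need("classifier", "train_classifier")
    val <- split_slices("val")
    art$tuning <- list()
    for (m in setdiff(methods, "unet")) {
      tg <- if (m == "global") tune_global_threshold(model, val)
            else tune_thresholds(model, m, val)
      art$tuning[[m]] <- tg
      b <- attr(tg, "best")
      log_line("tune %s: best %s q_m = %.3g (median Dice %.3f)", m,
               if (!is.null(b$t_m)) sprintf("t_m = %.3g,", b$t_m) else "", b$q_m,
               b$median_dice)
      readr::write_csv(tibble::as_tibble(tg), file.path(out_dir, paste0("tuning_", gsub("\\+", "p", m), ".csv")))
    }
  }

  if ("segment" %in% stages) {
    model <- need("classifier", "train_classifier")
    test <- split_slices("test")
    art$pred <- list()
    for (m in methods) {
      params <- if (m == "unet") {
        need("unet", "train_unet")
      } else if (m == "global") {
        list(q = attr(need("tuning", "tune")[[m]], "best")$q_m)
      } else {
        b <- attr(need("tuning", "tune")[[m]], "best")
        cam_params(m, b$t_m, b$q_m)
      }
      art$pred[[m]] <- lapply(split(test, test$subject_id), segment_subject,
                              model = model, method = m, params = params)
      log_line("segment %s: %d test subjects", m, length(art$pred[[m]]))
    }
  }

  if ("evaluate" %in% stages) {
    cohort <- need("cohort", "simulate")
    vols <- stats::setNames(cohort$volume, cohort$subject_id)
    reports <- evaluate_cohort(need("pred", "segment"), vols)
    art$reports <- reports
    art$icc <- icc_table(reports)
    readr::write_csv(reports, file.path(out_dir, "subject_reports.csv"))
    readr::write_csv(art$icc, file.path(out_dir, "icc_table.csv"))
    summary_tb <- reports |>
      dplyr::group_by(.data$method) |>
      dplyr::summarise(median_dice = stats::median(.data$dice),
                       iqr_dice = stats::IQR(.data$dice, type = 7),
                       median_mtv_dev = stats::median(.data$mtv_dev),
                       median_tlg_dev = stats::median(.data$tlg_dev))
    readr::write_csv(summary_tb, file.path(out_dir, "cohort_summary.csv"))
    art$summary <- summary_tb
    log_line("evaluate: %s", paste(sprintf("%s %.2f", summary_tb$method,
                                           summary_tb$median_dice), collapse = ", "))
  }
  invisible(art)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the desk-scale phantom study
#'
#' One complete replicate of the scaled-down phantom experiment: generate a
#' cohort, train the slice classifier, tune `(t_m, q_m)` for every CAM
#' method and the global percentile on the validation split, train the
#' supervised U-Net, segment the test subjects with every method, and
#' evaluate per-subject 3D Dice, MTV and TLG against ground truth. All
#' randomness derives from `seed`.
#'
#' Desk-scale training recipes (documented in the methods vignette): the
#' classifier trains with Adam (lr 5e-3, batch 64) for `classifier_epochs`
#' on all training slices; the U-Net trains with Adam (lr 3e-3, batch 8)
#' for `unet_epochs` on the positive training slices plus an equal number of
#' the highest-uptake negatives.
#'
#' @param seed root seed of the replicate.
#' @param n_subjects cohort size.
#' @param classifier_epochs,unet_epochs training lengths.
#' @param methods segmentation methods to evaluate.
#' @param verbose print stage progress.
#' @return list with `summary` (per-method median/IQR Dice and deviations),
#'   `icc` (method x biomarker ICC table), `tuned` (selected thresholds),
#'   `reports` (per subject x method), `classifier_metrics`, and `timings`.
#' @export
run_phantom_study <- function(seed = 1L, n_subjects = 100L,
                              classifier_epochs = 5L, unet_epochs = 4L,
                              methods = SEGMENT_METHODS, verbose = FALSE) {
  t0 <- proc.time()[3]
  tick <- function() round(proc.time()[3] - t0, 1)
  say <- function(...) if (verbose) message(sprintf(...))
  timings <- c()
  cfg <- phantom_config(n_subjects = n_subjects, seed = seed)
  co <- generate_cohort(cfg)
  sl <- extract_slices(co)
  tr <- sl[sl$split == "train", ]
  va <- sl[sl$split == "val", ]
  te <- sl[sl$split == "test", ]
  timings["simulate"] <- tick()
  say("cohort: %d subjects, %.1f%% positive slices [%ss]",
      n_subjects, 100 * mean(sl$label), tick())

  m <- train_classifier(tr, va, classifier_config(input_shape = dim(tr$pet[[1]])),
                        train_config(epochs = classifier_epochs, learning_rate = 5e-3,
                                     batch_size = 64L, optimizer = "adam",
                                     seed = seed + 1L))
  pr_te <- predict(m, te)
  clf_metrics <- tibble::tibble(
    accuracy = mean(pr_te$pred_label == te$label),
    recall = mean(pr_te$pred_label[te$label == 1] == 1),
    fpr = mean(pr_te$pred_label[te$label == 0] == 1))
  timings["classifier"] <- tick()
  say("classifier: acc %.3f recall %.3f fpr %.3f [%ss]",
      clf_metrics$accuracy, clf_metrics$recall, clf_metrics$fpr, tick())

  pred_va <- predict(m, va)$pred_label
  params <- list(); tuned <- list()
  for (meth in setdiff(methods, c("unet", "global"))) {
    tg <- tune_thresholds(m, meth, va, pred_labels = pred_va)
    tuned[[meth]] <- glance(tg)
    b <- attr(tg, "best")
    params[[meth]] <- cam_params(meth, b$t_m, b$q_m)
  }
  if ("global" %in% methods) {
    tg <- tune_global_threshold(m, va, pred_labels = pred_va)
    tuned$global <- glance(tg)
    params$global <- list(q = attr(tg, "best")$q_m)
  }
  timings["tune"] <- tick()
  say("tuned: %s [%ss]", paste(sprintf("%s q=%.2g", names(tuned),
      vapply(tuned, function(g) g$q_m, numeric(1))), collapse = ", "), tick())

  if ("unet" %in% methods) {
    posi <- which(tr$label == 1)
    negi <- which(tr$label == 0)
    negi <- negi[order(-vapply(tr$pet[negi], max, numeric(1)))]
    negi <- negi[seq_len(min(length(posi), length(negi)))]
    sub <- tr[sort(c(posi, negi)), ]
    params$unet <- train_unet(sub, va,
                              unet_config(input_shape = dim(tr$pet[[1]]),
                                          epochs = unet_epochs, learning_rate = 3e-3,
                                          batch_size = 8L, seed = seed + 2L))
    timings["unet"] <- tick()
    say("unet trained on %d slices [%ss]", nrow(sub), tick())
  }

  tes <- split(te, te$subject_id)
  pred_te <- split(pr_te$pred_label, te$subject_id)
  pred <- list()
  for (meth in methods) {
    pred[[meth]] <- lapply(names(tes), function(sid)
      segment_subject(tes[[sid]], m, meth, params[[meth]],
                      pred_labels = if (meth != "unet") pred_te[[sid]]))
    names(pred[[meth]]) <- names(tes)
  }
  timings["segment"] <- tick()

  vols <- stats::setNames(co$volume, co$subject_id)
  reports <- evaluate_cohort(pred, vols)
  summary_tb <- reports |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(median_dice = stats::median(.data$dice),
                     iqr_dice = stats::IQR(.data$dice, type = 7),
                     median_mtv_dev = stats::median(.data$mtv_dev),
                     median_tlg_dev = stats::median(.data$tlg_dev))
  timings["evaluate"] <- tick()
  say("done: %s [%ss]", paste(sprintf("%s %.2f", summary_tb$method,
      summary_tb$median_dice), collapse = ", "), tick())
  list(summary = summary_tb, icc = icc_table(reports),
       tuned = dplyr::bind_rows(tuned), reports = reports,
       classifier_metrics = clf_metrics, classifier = m, timings = timings)
}
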