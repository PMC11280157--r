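#' Predict, clean and merge respiratory-muscle masks for one CT
#'
#' Runs the two inference models of the workflow: the binary
#' respiratory-muscle segmentation network, connected-component noise
#' filtering, then the classification network on the cleaned mask; class
#' labels are kept only inside the binary mask (the classifier categorizes
#' the segmented region).
#'
#' @param seg_model binary-head `aunet_model`.
#' @param cls_model softmax-head `aunet_model`.
#' @param ct a [ct_volume].
#' @param min_component_px minimum surviving component size for
#'   [remove_small_components].
#' @param connectivity 4 or 8.
#' @return list with `binary` and `multiclass` [muscle_mask] objects.
#' @export
predict_subject <- function(seg_model, cls_model, ct, min_component_px = 10L,
                            connectivity = 8L) {
  bin <- predict(seg_model, ct, input_builder = "segmentation")
  bin <- remove_small_components(bin, min_component_px, connectivity)
  bin$pixel_spacing_mm <- ct$pixel_spacing_mm
  bin$slice_thickness_mm <- ct$slice_thickness_mm
  cls <- predict(cls_model, ct, respiratory_mask = bin,
                 input_builder = "classification")
  cls$voxels[bin$voxels == 0L] <- 0L
  cls$pixel_spacing_mm <- ct$pixel_spacing_mm
  cls$slice_thickness_mm <- ct$slice_thickness_mm
  list(binary = bin, multiclass = cls)
}

.log_line <- function(con, event, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                event = event), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  flush(con)
}

.require_keys <- function(cfg, keys, where) {
  missing <- setdiff(keys, names(cfg))
  if (length(missing))
    stop("config section '", where, "' is missing required key(s): ",
         paste(missing, collapse = ", "))
}

#' Run the full three-stage pipeline from a YAML config
#'
#' Executes the workflow end to end: obtain a cohort (generate phantoms or
#' load a directory), split subjects 8:2, train the muscle-tissue
#' segmentation stage, fine-tune it into the respiratory-muscle
#' segmentation stage with frozen encoder levels (optionally growing the
#' pool by active learning on held-back "unlabeled" subjects), train the
#' classification stage, predict and post-process the test cohort,
#' quantify volumes and densities, and correlate them with the PFT table.
#' Every step appends a line-oriented JSON record (seeds, config hash,
#' subject lists) to `pipeline.log.jsonl`; artifacts are written as each
#' stage completes so failures keep partial results.
#'
#' Required config keys: `seed`, `out_dir`, and either
#' `data: {dir: ...}` or `data: {phantom: {n_subjects: ...}}`; optional
#' sections `network`, `stages` (per-stage overrides), `postprocess`,
#' `correlation`, `active_learning`.
#'
#' @param config_path YAML configuration file.
#' @return invisibly, a list with the trained models, metrics data frame,
#'   correlation table and output directory.
#' @export
run_pipeline <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  .require_keys(cfg, c("seed", "out_dir", "data"), "<top level>")
  if (is.null(cfg$data$dir) && is.null(cfg$data$phantom))
    stop("config section 'data' is missing required key(s): dir or phantom")
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "pipeline.log.jsonl"), "a")
  on.exit(close(log_con))
  .log_line(log_con, "start",
            package_version = as.character(utils::packageVersion("respmuscle")),
            r_version = as.character(getRversion()),
            config = normalizePath(config_path),
            config_md5 = unname(tools::md5sum(config_path)),
            seed = cfg$seed)

  step <- function(name, expr) {
    .log_line(log_con, "stage_begin", stage = name)
    res <- tryCatch(expr, error = function(e) {
      .log_line(log_con, "stage_failed", stage = name,
                message = conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    .log_line(log_con, "stage_done", stage = name)
    res
  }

  cohort <- step("data", {
    if (!is.null(cfg$data$dir)) load_cohort(cfg$data$dir)
    else {
      ph <- cfg$data$phantom
      .require_keys(ph, "n_subjects", "data.phantom")
      spec <- phantom_spec(
        image_size = rep(ph$size %||% 64L, 2L),
        n_slices = ph$slices %||% 12L,
        rng_seed = cfg$seed)
      dir <- file.path(out_dir, "phantom")
      generate_cohort(spec, ph$n_subjects, seed = cfg$seed, dir = dir)
      load_cohort(dir)
    }
  })

  subs <- cohort$subjects
  split <- split_dataset(subs, c(0.8, 0.2), seed = cfg$seed)
  .log_line(log_con, "split", train = split$train, test = split$test)
  in_train <- vapply(subs, function(s) s$subject_id %in% split$train, TRUE)
  train_subs <- subs[in_train]
  test_subs <- subs[!in_train]

  net <- cfg$network %||% list()
  ncfg_bin <- network_config(depth = net$depth %||% 4L,
                             base_channels = net$base_channels %||% 8L,
                             out_mode = "binary_sigmoid")
  ncfg_cls <- network_config(depth = net$depth %||% 4L,
                             base_channels = net$base_channels %||% 8L,
                             out_mode = "multiclass_softmax", n_classes = 4L)

  scfg <- function(stage) {
    ov <- cfg$stages[[stage]] %||% list()
    ov$rng_seed <- ov$rng_seed %||% cfg$seed
    do.call(stage_config, c(list(stage = stage), ov))
  }

  al_cfg <- cfg$active_learning %||% list(unlabeled_fraction = 0)
  n_unlab <- floor((al_cfg$unlabeled_fraction %||% 0) * length(train_subs))
  labeled <- if (n_unlab > 0) train_subs[seq_len(length(train_subs) - n_unlab)]
             else train_subs
  unlabeled <- if (n_unlab > 0)
    train_subs[length(train_subs) - n_unlab + seq_len(n_unlab)] else list()

  tissue <- step("tissue_seg", {
    samp <- build_stage_samples(labeled, "tissue_seg")
    tr <- train_stage(build_aunet(ncfg_bin, seed = cfg$seed), samp,
                      scfg("tissue_seg"))
    save_model(tr$model, file.path(out_dir, "tissue_seg.rds"))
    write_train_log(tr$log, file.path(out_dir, "tissue_seg_log.csv"),
                    file.path(out_dir, "tissue_seg_log.json"))
    tr$model
  })

  seg <- step("resp_seg", {
    samp <- build_stage_samples(labeled, "resp_seg")
    tr <- train_stage(tissue, samp, scfg("resp_seg"))
    model <- tr$model
    if (length(unlabeled)) {
      refine <- function(pred_mask, probs, subject) {
        true <- Filter(function(s) s$subject_id == subject$subject_id,
                       subs)[[1]]$mask
        v <- true$voxels
        v[v != 0L] <- 1L
        muscle_mask(v, "binary", true$pixel_spacing_mm,
                    true$slice_thickness_mm)
      }
      al <- run_active_learning(model, labeled, unlabeled, refine,
                                scfg("resp_seg"), base_model = tissue)
      model <- al$model
    }
    save_model(model, file.path(out_dir, "resp_seg.rds"))
    write_train_log(tr$log, file.path(out_dir, "resp_seg_log.csv"),
                    file.path(out_dir, "resp_seg_log.json"))
    model
  })

  cls <- step("resp_cls", {
    samp <- build_stage_samples(train_subs, "resp_cls")
    tr <- train_stage(build_aunet(ncfg_cls, seed = cfg$seed + 1L), samp,
                      scfg("resp_cls"))
    save_model(tr$model, file.path(out_dir, "resp_cls.rds"))
    write_train_log(tr$log, file.path(out_dir, "resp_cls_log.csv"),
                    file.path(out_dir, "resp_cls_log.json"))
    tr$model
  })

  pp <- cfg$postprocess %||% list()
  metrics <- step("predict_quantify", {
    mets <- list()
    for (s in test_subs) {
      pred <- predict_subject(seg, cls, s$ct,
                              min_component_px = pp$min_component_px %||% 10L,
                              connectivity = pp$connectivity %||% 8L)
      write_mask(pred$multiclass,
                 file.path(out_dir, paste0("pred_", s$subject_id, ".nii.gz")))
      m <- suppressWarnings(
        muscle_metrics(pred$multiclass, s$ct, subject_id = s$subject_id,
                       sex = s$sex, age_years = s$age_years))
      m$ct_date <- as.character(s$ct_date)
      mets[[s$subject_id]] <- m
    }
    df <- metrics_table(mets)
    write.csv(df, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    for (g in c("sex", "age_decade"))
      write.csv(cohort_summary(df, g),
                file.path(out_dir, paste0("summary_", g, ".csv")),
                row.names = FALSE)
    df
  })

  corr <- step("correlate", {
    cc <- cfg$correlation %||% list()
    paired <- pair_ct_with_pft(metrics, cohort$pft_df,
                               window_days = cc$window_days %||% 90L)
    if (nrow(paired) >= 3L) {
      tab <- build_correlation_table(paired)
      write.csv(as.data.frame(tab), file.path(out_dir, "correlations.csv"),
                row.names = FALSE)
      tab
    } else {
      .log_line(log_con, "note",
                message = "fewer than 3 paired subjects; correlation skipped")
      NULL
    }
  })

  .log_line(log_con, "done")
  invisible(list(tissue_model = tissue, seg_model = seg, cls_model = cls,
                 metrics = metrics, correlations = corr, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
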