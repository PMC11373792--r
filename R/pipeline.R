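# One-command orchestration: generate/ingest -> reconstruct -> segment ->
# augment -> split -> train -> evaluate. Stages communicate only through
# files and CSV manifests inside the workspace; completed stages are
# skipped when their config/input hash is unchanged.

#' Default pipeline configuration
#'
#' Returns the packaged synthetic three-class configuration: a small
#' corpus of synthetic scenes, the 188-83-41 band triple, default
#' segmentation/augmentation, a 7:2:1 grouped split, and the scaled-down
#' SE-residual classifier.
#'
#' @param workspace Workspace directory (created on demand).
#' @param rng_seed Global seed; stage seeds derive from it.
#' @return Nested configuration list (class `pipeline_config`).
#' @export
default_pipeline_config <- function(workspace = tempfile("hyperseed_ws_"),
                                    rng_seed = 1L) {
  structure(list(
    workspace = workspace,
    rng_seed = as.integer(rng_seed),
    generate = list(skip = FALSE, n_scenes = 6L, n_classes = 3L,
                    seeds_per_class = 5L, image_size = c(150L, 200L),
                    band_count = 462L, noise_sd = 0.02),
    reconstruct = list(skip = FALSE, triple = c(188L, 83L, 41L)),
    segment = list(skip = FALSE, min_area = 20L, opening_radius = 1L,
                   pad = 4L, out_size = 32L),
    augment = list(skip = FALSE, brightness = 1.3, color = 1.3, contrast = 1.3),
    split = list(skip = FALSE, ratios = c(7, 2, 1), group_by_parent = TRUE),
    train = list(skip = FALSE, family = "se_resnet_small", base_channels = 8L,
                 input_size = 32L, learning_rate = 0.01, momentum = 0.9,
                 weight_decay = 0.01, batch_size = 8L, epochs = 10L),
    evaluate = list(skip = FALSE)), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_pipeline_config()]; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown pipeline config keys: ", paste(bad, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      bad2 <- setdiff(names(user[[nm]]), names(cfg[[nm]]))
      if (length(bad2))
        stop(sprintf("unknown keys in pipeline config section '%s': %s",
                     nm, paste(bad2, collapse = ", ")))
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    } else cfg[[nm]] <- user[[nm]]
  }
  cfg
}

# stage-skip bookkeeping: a stage is current if its recorded hash matches
.stage_hash <- function(cfg_part, inputs = character()) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(list(cfg = cfg_part,
               inputs = if (length(inputs)) unname(tools::md5sum(inputs)) else character()),
          tmp, version = 2)
  unname(tools::md5sum(tmp))
}

.stage_current <- function(dir, hash, outputs) {
  hf <- file.path(dir, ".stage_hash")
  file.exists(hf) && readLines(hf, warn = FALSE)[1] == hash &&
    all(file.exists(outputs))
}

.stage_done <- function(dir, hash) writeLines(hash, file.path(dir, ".stage_hash"))

#' Run the full pipeline
#'
#' Executes the configured stages in order, each writing a manifest the
#' next consumes. Re-running with an unchanged configuration and inputs
#' skips completed stages via content hashes. A failing stage halts the
#' run with its name; artifacts of earlier stages are preserved.
#'
#' @param config A `pipeline_config` (list), or a path to a YAML file.
#' @param verbose Print stage progress.
#' @return List with `metrics` (a `metrics_report`), `confusion`
#'   (a [confusion_matrix()]), `history` (training history), and
#'   `workspace`. When every stage is skipped, returns the workspace
#'   only.
#' @export
run_pipeline <- function(config = default_pipeline_config(), verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  ws <- config$workspace
  dir.create(ws, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  run_stage <- function(name, fun) {
    tryCatch(fun, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- generate ------------------------------------------------------------
  gen_dir <- file.path(ws, "scenes")
  scene_csv <- file.path(gen_dir, "scenes.csv")
  if (!config$generate$skip) {
    g <- config$generate
    sp <- scene_spec(n_classes = g$n_classes, seeds_per_class = g$seeds_per_class,
                     image_size = g$image_size, band_count = g$band_count,
                     noise_sd = g$noise_sd, rng_seed = config$rng_seed)
    h <- .stage_hash(g)
    if (!.stage_current(gen_dir, h, scene_csv)) {
      say("stage generate: %d scenes", g$n_scenes)
      dir.create(gen_dir, showWarnings = FALSE)
      run_stage("generate", {
        rows <- NULL
        for (k in seq_len(g$n_scenes)) {
          spk <- sp; spk$rng_seed <- sp$rng_seed + k
          sc <- generate_scene(spk)
          stem <- file.path(gen_dir, sprintf("scene%02d", k))
          write_envi_cube(sc$cube, paste0(stem, ".hdr"))
          write_ground_truth(sc$truth, stem)
          rows <- rbind(rows, data.frame(scene = sprintf("scene%02d", k),
                                         header = paste0(stem, ".hdr"),
                                         instances = paste0(stem, "_instances.json")))
        }
        utils::write.csv(rows, scene_csv, row.names = FALSE)
        .stage_done(gen_dir, h)
      })
    } else say("stage generate: up to date")
  }

  # --- reconstruct ---------------------------------------------------------
  rgb_dir <- file.path(ws, "rgb")
  rgb_csv <- file.path(rgb_dir, "rgb.csv")
  if (!config$reconstruct$skip) {
    r <- config$reconstruct
    h <- .stage_hash(r, scene_csv)
    if (!.stage_current(rgb_dir, h, rgb_csv)) {
      say("stage reconstruct: triple %s", paste(r$triple, collapse = "-"))
      dir.create(rgb_dir, showWarnings = FALSE)
      run_stage("reconstruct", {
        scenes <- utils::read.csv(scene_csv)
        tri <- band_triple(r$triple[1], r$triple[2], r$triple[3])
        rows <- NULL
        for (i in seq_len(nrow(scenes))) {
          cube <- read_envi_cube(scenes$header[i])
          img <- compose_rgb(cube, tri, scene_id = scenes$scene[i])
          p <- file.path(rgb_dir, sprintf("%s_%d-%d-%d.png", scenes$scene[i],
                                          tri$r, tri$g, tri$b))
          write_image_png(img, p)
          rows <- rbind(rows, data.frame(scene = scenes$scene[i], path = p,
                                         instances = scenes$instances[i]))
        }
        utils::write.csv(rows, rgb_csv, row.names = FALSE)
        .stage_done(rgb_dir, h)
      })
    } else say("stage reconstruct: up to date")
  }

  # --- segment -------------------------------------------------------------
  crop_dir <- file.path(ws, "crops")
  crop_csv <- file.path(crop_dir, "crops.csv")
  if (!config$segment$skip) {
    s <- config$segment
    h <- .stage_hash(s, rgb_csv)
    if (!.stage_current(crop_dir, h, crop_csv)) {
      say("stage segment")
      dir.create(crop_dir, showWarnings = FALSE)
      run_stage("segment", {
        rgbs <- utils::read.csv(rgb_csv)
        rows <- NULL
        for (i in seq_len(nrow(rgbs))) {
          img <- read_image_png(rgbs$path[i])
          gray <- to_grayscale(img)
          bw <- fill_holes(binarize(gray))
          masks <- extract_seed_masks(bw, min_area = s$min_area,
                                      opening_radius = s$opening_radius)
          # label crops from the ground-truth instance table when present
          inst <- NULL
          if (!is.na(rgbs$instances[i]) && file.exists(rgbs$instances[i])) {
            inst <- jsonlite::read_json(rgbs$instances[i], simplifyVector = TRUE)
            mask_png <- sub("_instances\\.json$", "_mask.png", rgbs$instances[i])
            lab_mask <- round(png::readPNG(mask_png) * 255)
          }
          for (mk in masks) {
            label <- NA_character_
            if (!is.null(inst) && nrow(inst)) {
              ids <- lab_mask[mk$mask]
              ids <- ids[ids > 0]
              if (length(ids))
                label <- inst$class[match(as.integer(names(which.max(table(ids)))),
                                          inst$instance_id)]
            }
            cr <- crop_seed(img, mk, pad = s$pad, out_size = s$out_size,
                            label = label, scene_id = rgbs$scene[i])
            p <- file.path(crop_dir, sprintf("%s_seed%02d.png", rgbs$scene[i],
                                             mk$component_id))
            write_image_png(cr$pixels, p)
            rows <- rbind(rows, data.frame(
              path = p, label = label, scene_id = rgbs$scene[i],
              component_id = mk$component_id, area = mk$area,
              parent_id = sprintf("%s_seed%02d", rgbs$scene[i], mk$component_id)))
          }
        }
        rows <- rows[!is.na(rows$label), , drop = FALSE]
        utils::write.csv(rows, crop_csv, row.names = FALSE)
        .stage_done(crop_dir, h)
      })
    } else say("stage segment: up to date")
  }

  # --- augment -------------------------------------------------------------
  aug_dir <- file.path(ws, "augmented")
  aug_csv <- file.path(aug_dir, "augmented.csv")
  if (!config$augment$skip) {
    a <- config$augment
    h <- .stage_hash(a, crop_csv)
    if (!.stage_current(aug_dir, h, aug_csv)) {
      say("stage augment")
      dir.create(aug_dir, showWarnings = FALSE)
      run_stage("augment", {
        crops <- utils::read.csv(crop_csv)
        params <- augmentation_params(brightness_factor = a$brightness,
                                      color_factor = a$color,
                                      contrast_factor = a$contrast)
        out <- expand_dataset(crops, params, out_dir = aug_dir)
        out$parent_id <- rep(crops$parent_id, each = 7L)
        utils::write.csv(out, aug_csv, row.names = FALSE)
        .stage_done(aug_dir, h)
      })
    } else say("stage augment: up to date")
  }

  # --- split ---------------------------------------------------------------
  split_csv <- file.path(ws, "split.csv")
  if (!config$split$skip) {
    sp <- config$split
    h <- .stage_hash(sp, aug_csv)
    if (!.stage_current(ws, h, split_csv)) {
      say("stage split")
      run_stage("split", {
        man <- utils::read.csv(aug_csv)
        spec <- split_spec(ratios = sp$ratios, rng_seed = config$rng_seed,
                           group_by_parent = sp$group_by_parent)
        man <- assign_split(man, spec)
        utils::write.csv(man, split_csv, row.names = FALSE)
        .stage_done(ws, h)
      })
    } else say("stage split: up to date")
  }

  # --- train ---------------------------------------------------------------
  ckpt <- file.path(ws, "model.rds")
  hist_csv <- file.path(ws, "history.csv")
  model <- NULL
  if (!config$train$skip) {
    t <- config$train
    h <- .stage_hash(t, split_csv)
    if (!.stage_current(ws, h, c(ckpt, hist_csv))) {
      say("stage train: %s", t$family)
      run_stage("train", {
        man <- utils::read.csv(split_csv)
        classes <- sort(unique(man$label))
        mc <- model_config(family = t$family, num_classes = length(classes),
                           input_size = t$input_size,
                           base_channels = t$base_channels,
                           rng_seed = config$rng_seed)
        model <- build_classifier(mc)
        tc <- train_config(learning_rate = t$learning_rate, momentum = t$momentum,
                           weight_decay = t$weight_decay, batch_size = t$batch_size,
                           epochs = t$epochs, rng_seed = config$rng_seed)
        model <- train(model, man[man$split == "train", ],
                        man[man$split == "val", ], tc, verbose = verbose)
        save_checkpoint(model, ckpt)
        utils::write.csv(model$history, hist_csv, row.names = FALSE)
        .stage_done(ws, h)
      })
    } else {
      say("stage train: up to date")
      model <- load_checkpoint(ckpt)
      model$history <- utils::read.csv(hist_csv)
    }
  }

  # --- evaluate ------------------------------------------------------------
  if (!config$evaluate$skip) {
    say("stage evaluate")
    res <- run_stage("evaluate", {
      if (is.null(model)) model <- load_checkpoint(ckpt)
      man <- utils::read.csv(split_csv)
      test <- man[man$split == "test", ]
      cm <- evaluate(model, test)
      rep <- metrics_from_cm(cm)
      utils::write.csv(as.data.frame(unclass(cm)), file.path(ws, "confusion.csv"))
      jsonlite::write_json(
        list(accuracy = rep$accuracy, macro_precision = rep$macro_precision,
             macro_recall = rep$macro_recall,
             macro_specificity = rep$macro_specificity, macro_f1 = rep$macro_f1,
             per_class = rep$per_class),
        file.path(ws, "metrics.json"), auto_unbox = TRUE, digits = NA)
      list(metrics = rep, confusion = cm)
    })
    return(list(metrics = res$metrics, confusion = res$confusion,
                history = if (!is.null(model)) model$history else NULL,
                workspace = ws))
  }
  list(workspace = ws)
}
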