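# End-to-end orchestration on the synthetic herd: simulate frame
# sequences, deduplicate, build balanced splits, train per-view reference
# classifiers, evaluate, fuse view pairs, run the cascade policy and emit
# a structured report. Every stage writes its outputs under the run
# directory and a manifest records the configuration, seeds and output
# checksums; deterministic stages are byte-identical across reruns with
# the same config.

#' Configure a pipeline run
#'
#' The defaults describe a small herd so a full run completes in well
#' under a minute; they scale up by argument.
#'
#' @param n_identities Herd size.
#' @param views View labels to simulate.
#' @param frames_per_class Frames per (identity, view) sequence.
#' @param dup_rate Planted near-duplicate rate in the simulated sequences.
#' @param interval Frame-extraction interval (1 keeps every simulated
#'   frame; raw video work uses 30).
#' @param dhash_threshold,ssim_threshold Deduplication thresholds.
#' @param test_per_class,target_per_class,val_fraction Dataset-builder
#'   parameters.
#' @param image_size Rendered image side length.
#' @param train Training config, a [train_config()].
#' @param weights_from Split whose accuracies become fusion weights:
#'   `"val"` (default; keeps the test set untouched) or `"test"`.
#' @param policy_episodes Episodes for the policy stage.
#' @param seed Master seed; stage seeds are derived from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_identities = 6L, views = c("S", "B", "F", "L", "R"),
                       frames_per_class = 26L, dup_rate = 0.15,
                       interval = 1L, dhash_threshold = 5L,
                       ssim_threshold = 0.7, test_per_class = 5L,
                       target_per_class = 30L, val_fraction = 0.2,
                       image_size = 64L,
                       train = train_config(feature = 12L, epochs = 40L),
                       weights_from = c("val", "test"),
                       policy_episodes = 300L, seed = 1L) {
  weights_from <- match.arg(weights_from)
  stopifnot(n_identities >= 2, frames_per_class >= 1,
            test_per_class >= 0, target_per_class >= 1)
  structure(list(n_identities = as.integer(n_identities), views = views,
                 frames_per_class = as.integer(frames_per_class),
                 dup_rate = dup_rate, interval = as.integer(interval),
                 dhash_threshold = as.integer(dhash_threshold),
                 ssim_threshold = ssim_threshold,
                 test_per_class = as.integer(test_per_class),
                 target_per_class = as.integer(target_per_class),
                 val_fraction = val_fraction,
                 image_size = as.integer(image_size), train = train,
                 weights_from = weights_from,
                 policy_episodes = as.integer(policy_episodes), seed = seed),
            class = "run_config")
}

PIPELINE_STAGES <- c("simulate", "prep", "build", "train", "eval", "fuse",
                     "policy", "report")

#' Run the identification pipeline end to end
#'
#' Executes the requested stages in canonical order, reading each stage's
#' inputs from the outputs of its predecessors under `out_dir`. Missing
#' dependencies raise a `stage-order-error`. A `run_manifest.json` records
#' the configuration, master seed and md5 checksums of every written file.
#'
#' @param out_dir Run directory (created if needed).
#' @param cfg A [run_config()].
#' @param stages Subset of
#'   `simulate, prep, build, train, eval, fuse, policy, report`.
#' @return Invisibly, a list with the run manifest and the paths written.
#' @export
run_pipeline <- function(out_dir, cfg = run_config(),
                         stages = PIPELINE_STAGES) {
  if (!all(stages %in% PIPELINE_STAGES))
    stop("config-error: unknown stage(s) ",
         paste(setdiff(stages, PIPELINE_STAGES), collapse = ", "), call. = FALSE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  need <- function(path, stage, dep) {
    if (!file.exists(path))
      stop("stage-order-error: stage '", stage, "' needs output of '", dep,
           "' (", basename(path), ")", call. = FALSE)
    path
  }
  written <- character(0)
  note <- function(p) { written <<- unique(c(written, p)); p }
  paths <- list(
    raw_manifest = file.path(out_dir, "raw_manifest.csv"),
    prep_manifest = file.path(out_dir, "prep_manifest.csv"),
    built_manifest = file.path(out_dir, "built_manifest.csv"),
    accuracies = file.path(out_dir, "view_accuracies.json"),
    fused = file.path(out_dir, "fused_metrics.csv"),
    episodes = file.path(out_dir, "policy_episodes.csv"),
    report = file.path(out_dir, "report.json")
  )
  profile <- default_view_profile()[cfg$views]

  if ("simulate" %in% stages) {
    bank <- make_identity_bank(cfg$n_identities, seed = cfg$seed)
    rows <- list()
    for (v in cfg$views) for (i in seq_len(cfg$n_identities)) {
      id <- identity_labels(cfg$n_identities)[i]
      seq_seed <- seed_from(cfg$seed, paste0("seq-", v, "-", id))
      sq <- generate_frame_sequence(bank, i, profile[[v]],
                                    n_frames = cfg$frames_per_class,
                                    dup_rate = cfg$dup_rate, seed = seq_seed,
                                    size = cfg$image_size)
      dir.create(file.path(out_dir, "raw", v, id), recursive = TRUE,
                 showWarnings = FALSE)
      rel <- sprintf("raw/%s/%s/%03d.png", v, id,
                     seq_along(sq$frames))
      for (k in seq_along(sq$frames))
        write_frame_png(sq$frames[[k]], file.path(out_dir, rel[k]))
      rows[[length(rows) + 1L]] <- data.frame(
        path = rel, identity = id, view = v, split = "unassigned",
        is_augmented = FALSE, source_path = NA_character_,
        op = NA_character_, duplicate_flag = sq$duplicate,
        stringsAsFactors = FALSE)
    }
    write.csv(do.call(rbind, rows), note(paths$raw_manifest),
              row.names = FALSE)
  }

  if ("prep" %in% stages) {
    raw <- read.csv(need(paths$raw_manifest, "prep", "simulate"),
                    stringsAsFactors = FALSE,
                    colClasses = c(identity = "character"))
    keep_all <- logical(nrow(raw))
    for (g in unique(paste(raw$view, raw$identity))) {
      idx <- which(paste(raw$view, raw$identity) == g)
      idx <- idx[order(raw$path[idx])]
      frames <- lapply(raw$path[idx],
                       function(p) read_frame_png(file.path(out_dir, p)))
      sub <- extract_frames(seq_along(frames), cfg$interval)
      d1 <- dedup_by_dhash(frames[sub], cfg$dhash_threshold)
      d2 <- dedup_by_ssim(d1$frames, cfg$ssim_threshold)
      kept <- sub[which(d1$keep)][which(d2$keep)]
      keep_all[idx[kept]] <- TRUE
    }
    raw$retained <- keep_all
    write.csv(raw, note(paths$prep_manifest), row.names = FALSE)
  }

  if ("build" %in% stages) {
    prep <- read.csv(need(paths$prep_manifest, "build", "prep"),
                     stringsAsFactors = FALSE,
                     colClasses = c(identity = "character"))
    man <- prep[prep$retained, setdiff(names(prep),
                                       c("retained", "duplicate_flag"))]
    man <- make_test_split(man, per_class = cfg$test_per_class,
                           seed = seed_from(cfg$seed, "test-split"))
    acfg <- augmentation_config(target_per_class = cfg$target_per_class,
                                seed = seed_from(cfg$seed, "augment"))
    man <- balance_manifest(man, acfg)
    man <- make_train_val_split(man, val_fraction = cfg$val_fraction,
                                seed = seed_from(cfg$seed, "val-split"))
    write.csv(man, note(paths$built_manifest), row.names = FALSE)
  }

  if (any(c("train", "eval") %in% stages)) {
    man <- read.csv(need(paths$built_manifest, "train", "build"),
                    stringsAsFactors = FALSE,
                    colClasses = c(identity = "character"))
    dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
  }
  if ("train" %in% stages) {
    tcfg <- cfg$train
    for (v in cfg$views) {
      tcfg$seed <- seed_from(cfg$seed, paste0("train-", v))
      model <- train_view_classifier(man, v, tcfg, root = out_dir)
      save_classifier(model, note(file.path(out_dir, "models",
                                            paste0(v, ".json"))))
    }
  }

  if ("eval" %in% stages) {
    acc <- list()
    for (v in cfg$views) {
      model <- load_classifier(need(file.path(out_dir, "models",
                                              paste0(v, ".json")),
                                    "eval", "train"))
      for (split in c("val", "test")) {
        ev <- evaluate_view_model(model, man, split, root = out_dir)
        write.csv(ev$dump,
                  note(file.path(out_dir, sprintf("dump_%s_%s.csv", split, v))),
                  row.names = FALSE)
        acc[[split]][[v]] <- ev$accuracy
      }
    }
    jsonlite::write_json(acc, note(paths$accuracies), digits = NA,
                         auto_unbox = TRUE)
  }

  if (any(c("fuse", "policy", "report") %in% stages)) {
    acc <- jsonlite::read_json(need(paths$accuracies, "fuse", "eval"),
                               simplifyVector = TRUE)
    weights <- unlist(acc[[cfg$weights_from]])
  }

  if ("fuse" %in% stages) {
    dumps <- lapply(setNames(cfg$views, cfg$views), function(v)
      read.csv(file.path(out_dir, sprintf("dump_test_%s.csv", v)),
               stringsAsFactors = FALSE, check.names = FALSE,
               colClasses = c(true_identity = "character")))
    pairs <- utils::combn(cfg$views, 2L, simplify = FALSE)
    rows <- lapply(pairs, function(pr) {
      fd <- fuse_dumps(dumps[pr], weights)
      rep <- metrics_report(fd)
      data.frame(combination = paste(pr, collapse = "-"),
                 top1_acc = rep$top1_acc, top5_acc = rep$top5_acc,
                 mean_precision = rep$mean_precision,
                 mean_recall = rep$mean_recall, mean_f1 = rep$mean_f1)
    })
    write.csv(do.call(rbind, rows), note(paths$fused), row.names = FALSE)
  }

  if ("policy" %in% stages) {
    chance <- 1 / cfg$n_identities
    sim_acc <- pmax(pmin(weights[cfg$views], 1), chance + 1e-3)
    sim_cfg <- confidence_sim_config(cfg$n_identities, sim_acc,
                                     seed = seed_from(cfg$seed, "policy-sim"))
    pcfg <- policy_config(view_order = cfg$views, weights = sim_acc)
    log <- simulate_policy_episodes(cfg$policy_episodes, sim_cfg, pcfg,
                                    mode = "multi",
                                    seed = seed_from(cfg$seed, "policy-ep"))
    write.csv(log, note(paths$episodes), row.names = FALSE)
  }

  if ("report" %in% stages) {
    fused <- read.csv(need(paths$fused, "report", "fuse"),
                      stringsAsFactors = FALSE)
    log <- read.csv(need(paths$episodes, "report", "policy"),
                    stringsAsFactors = FALSE)
    report <- list(
      per_view = acc,
      per_pair = fused,
      cascade = list(
        accuracy = mean(log$correct),
        accepted_accuracy = if (any(log$status == "accepted"))
          mean(log$correct[log$status == "accepted"]) else NA,
        mean_views_used = mean(log$images_consumed),
        episodes = nrow(log))
    )
    jsonlite::write_json(report, note(paths$report), digits = NA,
                         auto_unbox = TRUE, dataframe = "rows")
  }

  manifest <- list(
    config = unclass(cfg)[setdiff(names(unclass(cfg)), "train")],
    train = unclass(cfg$train),
    stages = stages, seed = cfg$seed,
    checksums = as.list(tools::md5sum(written[file.exists(written)]))
  )
  names(manifest$checksums) <-
    sub(paste0("^", out_dir, "/?"), "", names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(manifest = manifest, written = written))
}
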