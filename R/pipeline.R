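#' Pipeline run configuration
#'
#' Validates and normalizes a configuration for [run_pipeline()]. A config is
#' a named list (or a JSON/YAML file path) with a mandatory `seed` and
#' `output_dir`, plus optional blocks mirroring the stage parameters.
#'
#' @param config Named list, or path to a JSON (or YAML, if the `yaml`
#'   package is available) file.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configs requires the yaml package", call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop("config must be a named list or a file path", call. = FALSE)
  problems <- character()
  if (is.null(config$seed) || !is.numeric(config$seed)) {
    problems <- c(problems, "seed: a numeric seed is mandatory")
  }
  if (is.null(config$output_dir) || !is.character(config$output_dir)) {
    problems <- c(problems, "output_dir: an output directory is mandatory")
  }
  config$n <- config$n %||% 97
  if (config$n < 1) problems <- c(problems, "n: must be >= 1")
  config$profile <- config$profile %||% "desk"
  if (!config$profile %in% c("desk", "full")) {
    problems <- c(problems, "profile: must be 'desk' or 'full'")
  }
  if (length(problems)) {
    stop("invalid run config:\n  ", paste(problems, collapse = "\n  "), call. = FALSE)
  }
  config$phantom <- config$phantom %||% list()
  config$motion <- config$motion %||% list()
  config$train <- config$train %||% list()
  config$evaluate <- config$evaluate %||% list()
  structure(config, class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config[order(names(config))], f, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(f))
}

stage_manifest_path <- function(out, stage) {
  file.path(out, stage, "stage_manifest.json")
}

write_stage_manifest <- function(out, stage, hash, seed, outputs) {
  dir.create(file.path(out, stage), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(stage = stage, config_hash = hash, seed = seed,
         outputs = outputs, time = format(Sys.time(), tz = "UTC")),
    stage_manifest_path(out, stage), auto_unbox = TRUE)
}

stage_done <- function(out, stage, hash) {
  mp <- stage_manifest_path(out, stage)
  if (!file.exists(mp)) return(FALSE)
  m <- jsonlite::read_json(mp)
  identical(m$config_hash, hash) &&
    all(file.exists(file.path(out, stage, unlist(m$outputs))))
}

#' Run the simulate/train/evaluate pipeline
#'
#' Orchestrates the stages `simulate` (synthetic paired dataset),
#' `preprocess` (artefact localization index), `train` (adversarial model),
#' `correct` (apply the generator to the test split), `evaluate` (metrics
#' table and paired statistics) and `report` (human-readable summary). Each
#' stage writes its outputs plus a manifest recording the config hash and
#' seed; a completed stage with an unchanged hash is skipped unless `force`.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @param stages Character subset of the stages above, in any order; they are
#'   executed in pipeline order.
#' @param force Re-run stages whose manifests are already up to date.
#' @return Invisibly, a named list with the key artifacts of the executed
#'   stages.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "preprocess", "train",
                                    "correct", "evaluate", "report"),
                         force = FALSE) {
  cfg <- run_config(config)
  all_stages <- c("simulate", "preprocess", "train", "correct", "evaluate", "report")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(all_stages, collapse = ", "), ")", call. = FALSE)
  }
  stages <- all_stages[all_stages %in% stages]
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass(cfg))
  res <- list()

  ds_dir <- file.path(out, "simulate", "dataset")
  if ("simulate" %in% stages) {
    if (stage_done(out, "simulate", hash) && !force) {
      message("simulate: up to date, skipping")
    } else {
      ph <- do.call(phantom_params, cfg$phantom)
      ds <- generate_dataset(
        cfg$n, params = ph,
        amplitude = cfg$motion$amplitude %||% c(2, 8),
        direction = cfg$motion$direction,
        decay = cfg$motion$decay %||% 0.5,
        seed = cfg$seed)
      write_paired_dataset(ds, ds_dir)
      write_stage_manifest(out, "simulate", hash, cfg$seed, "dataset/manifest.csv")
    }
    res$dataset_dir <- ds_dir
  }

  read_ds <- local({
    cache <- NULL
    function() {
      if (is.null(cache)) cache <<- read_paired_dataset(ds_dir)
      cache
    }
  })

  if ("preprocess" %in% stages) {
    if (stage_done(out, "preprocess", hash) && !force) {
      message("preprocess: up to date, skipping")
    } else {
      ds <- read_ds()
      idx <- do.call(rbind, lapply(ds$samples, function(s) {
        det <- locate_artifact_centroid(s$artefact, s$reference)
        data.frame(sample_id = s$sample_id, detected = det$detected,
                   centroid_row = det$centroid[1] %||% NA_real_,
                   centroid_col = det$centroid[2] %||% NA_real_)
      }))
      dir.create(file.path(out, "preprocess"), recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(idx, file.path(out, "preprocess", "roi_index.csv"),
                       row.names = FALSE)
      write_stage_manifest(out, "preprocess", hash, cfg$seed, "roi_index.csv")
    }
    res$roi_index <- file.path(out, "preprocess", "roi_index.csv")
  }

  ck_path <- file.path(out, "train", "model.rds")
  if ("train" %in% stages) {
    if (stage_done(out, "train", hash) && !force) {
      message("train: up to date, skipping")
    } else {
      ds <- read_ds()
      train_ids <- ds$manifest$sample_id[ds$manifest$split == "train"]
      tr <- ds$samples[vapply(ds$samples, function(s) s$sample_id %in% train_ids, logical(1))]
      tcfg <- do.call(train_config, utils::modifyList(
        list(profile = cfg$profile, seed = cfg$seed,
             checkpoint_dir = file.path(out, "train")),
        cfg$train))
      fit <- train_gan(tr, tcfg)
      save_checkpoint(ck_path, fit$generator, fit$discriminator,
                      adam_init(fit$generator$layers),
                      adam_init(fit$discriminator$layers),
                      max(fit$history$step), max(fit$history$epoch),
                      fit$history, tcfg)
      write_stage_manifest(out, "train", hash, cfg$seed, "model.rds")
    }
    res$model <- ck_path
  }

  load_gen <- function() {
    if (!file.exists(ck_path)) return(NULL)
    model_from_state(readRDS(ck_path)$generator, "generator")
  }

  if ("correct" %in% stages) {
    if (stage_done(out, "correct", hash) && !force) {
      message("correct: up to date, skipping")
    } else {
      ds <- read_ds()
      gen <- load_gen()
      if (is.null(gen)) stop("correct: no trained model at ", ck_path, call. = FALSE)
      test_ids <- ds$manifest$sample_id[ds$manifest$split == "test"]
      corrected <- lapply(ds$samples, function(s) {
        if (!s$sample_id %in% test_ids) return(NULL)
        xn <- normalize_hu(s$artefact)
        list(sample_id = s$sample_id,
             corrected_hu = denormalize_hu(correct_image(gen, xn)))
      })
      corrected <- corrected[!vapply(corrected, is.null, logical(1))]
      dir.create(file.path(out, "correct"), recursive = TRUE, showWarnings = FALSE)
      saveRDS(corrected, file.path(out, "correct", "corrected.rds"))
      write_stage_manifest(out, "correct", hash, cfg$seed, "corrected.rds")
    }
    res$corrected <- file.path(out, "correct", "corrected.rds")
  }

  metrics_path <- file.path(out, "evaluate", "metrics.csv")
  if ("evaluate" %in% stages) {
    if (stage_done(out, "evaluate", hash) && !force) {
      message("evaluate: up to date, skipping")
    } else {
      ds <- read_ds()
      gen <- load_gen()
      test_ids <- ds$manifest$sample_id[ds$manifest$split == "test"]
      te <- ds$samples[vapply(ds$samples, function(s) s$sample_id %in% test_ids, logical(1))]
      mt <- evaluate_pairs(te, gen,
                           upsample = cfg$evaluate$upsample %||% 4)
      dir.create(file.path(out, "evaluate"), showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(as.data.frame(mt), metrics_path, row.names = FALSE)
      jsonlite::write_json(summary(mt), file.path(out, "evaluate", "summary.json"),
                           dataframe = "rows", digits = NA)
      write_stage_manifest(out, "evaluate", hash, cfg$seed,
                           c("metrics.csv", "summary.json"))
    }
    res$metrics <- metrics_path
  }

  if ("report" %in% stages) {
    mt <- utils::read.csv(metrics_path, stringsAsFactors = FALSE)
    class(mt) <- c("metrics_table", "data.frame")
    cmps <- tryCatch(compare_metrics(mt), error = function(e) NULL)
    lines <- c("Motion-artefact correction report",
               sprintf("samples evaluated: %d (detected: %d)", nrow(mt), sum(mt$detected)),
               "")
    for (nm in names(cmps)) {
      cc <- cmps[[nm]]
      lines <- c(lines, sprintf(
        "%s: corrected %s vs raw %s — %s, p = %.4g (%s)", nm,
        cc$summary_a, cc$summary_b, cc$test, cc$p_value,
        if (cc$significant) "significant" else "not significant"))
    }
    if (is.null(cmps)) {
      lines <- c(lines, "paired comparisons not computed (fewer than 5 usable samples)")
      cmps <- list()
    }
    dir.create(file.path(out, "report"), showWarnings = FALSE, recursive = TRUE)
    writeLines(lines, file.path(out, "report", "report.txt"))
    jsonlite::write_json(
      lapply(cmps, function(cc) cc[c("test", "statistic", "p_value",
                                     "significant", "summary_a", "summary_b")]),
      file.path(out, "report", "report.json"), auto_unbox = TRUE, digits = NA)
    write_stage_manifest(out, "report", hash, cfg$seed,
                         c("report.txt", "report.json"))
    res$report <- file.path(out, "report", "report.txt")
  }
  invisible(res)
}
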