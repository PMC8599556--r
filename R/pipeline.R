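# End-to-end pipeline driver: QC -> train -> CV -> transfer -> EWAS from a
# single flat config, with a content-hashed manifest so reruns are
# auditable for bit-identity.

#' Run the full clock pipeline from a config
#'
#' Stages run in dependency order; any stage can be toggled off. All
#' randomness is funneled through named per-stage seeds recorded in the
#' manifest, and every output file is listed with its MD5 hash, so two
#' runs of the same config produce byte-identical outputs and manifests
#' (manifest paths are relative to the output directory).
#'
#' Config keys (YAML or a named list): `matrix`, `sheet`,
#' `species_params`, `annotation` (paths); `out_dir`; `seed`; `stages`
#' (named logicals `qc`, `train`, `cv`, `transfer`, `ewas`); `clocks` — a
#' list of `{name, target, species}` entries (species being the training
#' subset); `cv: {scheme: loo|kfold, k}`; `ewas: {species, p_threshold,
#' cap}`; `transfer: {clock, species}`.
#'
#' @param config path to a YAML config or an equivalent named list.
#' @return invisibly, the manifest list (also written as
#'   `manifest.json` in the output directory).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (key in c("matrix", "sheet", "species_params", "out_dir")) {
    if (is.null(config[[key]]))
      stop("config missing required key: ", key, call. = FALSE)
  }
  for (key in c("matrix", "sheet", "species_params")) {
    if (!file.exists(config[[key]]))
      stop("input file not found: ", config[[key]], call. = FALSE)
  }
  stages <- utils::modifyList(
    list(qc = TRUE, train = TRUE, cv = TRUE, transfer = FALSE, ewas = TRUE),
    config$stages %||% list())
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_line <- function(...) message("[clockforge] ", ...)

  mat <- read_beta_matrix(config$matrix)
  sheet <- read_sample_sheet(config$sheet)
  species_params <- read_species_params(config$species_params)
  aligned <- align_samples(mat, sheet)
  mat <- aligned$matrix; sheet <- aligned$sheet
  annotation <- if (!is.null(config$annotation))
    read_probe_annotation(config$annotation) else NULL

  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)
  run_stage <- function(name, expr) {
    log_line("stage ", name, " ...")
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (isTRUE(stages$qc)) {
    run_stage("qc", {
      rep <- qc_report(mat, sheet, seed = seed)
      write_qc_report(rep, file.path(out_dir, "qc_report.json"),
                      newick_path = file.path(out_dir, "qc_dendrogram.nwk"))
      emit("qc_report.json"); emit("qc_dendrogram.nwk")
    })
  }

  clock_specs <- config$clocks %||% list(
    list(name = "clock_raw", target = "raw_age",
         species = unique(sheet$species)[1]))
  models <- list()
  if (isTRUE(stages$train)) {
    run_stage("train", {
      for (cs in clock_specs) {
        sp <- cs$species %||% unique(sheet$species)
        keep <- sheet$species %in% sp
        m <- train_clock(mat[keep, , drop = FALSE],
                         sheet[keep, , drop = FALSE],
                         species_params, target = cs$target, seed = seed)
        models[[cs$name]] <- m
        fn <- paste0(cs$name, ".tsv")
        write_clock(m, file.path(out_dir, fn))
        emit(fn)
      }
      models <<- models
    })
  }

  if (isTRUE(stages$cv)) {
    run_stage("cv", {
      cv_cfg <- config$cv %||% list(scheme = "kfold", k = 10L)
      metrics_all <- list()
      for (cs in clock_specs) {
        sp <- cs$species %||% unique(sheet$species)
        keep <- sheet$species %in% sp
        res <- if (identical(cv_cfg$scheme, "loo")) {
          loocv(mat[keep, , drop = FALSE], sheet[keep, , drop = FALSE],
                species_params, target = cs$target, seed = seed)
        } else {
          kfold_cv(mat[keep, , drop = FALSE], sheet[keep, , drop = FALSE],
                   species_params, target = cs$target,
                   k = as.integer(cv_cfg$k %||% 10L), seed = seed)
        }
        fn <- paste0(cs$name, "_cv_predictions.tsv")
        .write_tsv(res$predictions, file.path(out_dir, fn))
        emit(fn)
        metrics_all[[cs$name]] <- res$metrics
      }
      jsonlite::write_json(metrics_all,
                           file.path(out_dir, "cv_metrics.json"),
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      emit("cv_metrics.json")
    })
  }

  if (isTRUE(stages$transfer)) {
    run_stage("transfer", {
      tcfg <- config$transfer
      if (is.null(tcfg$clock) || is.null(models[[tcfg$clock]]))
        stop("transfer stage needs a trained clock name", call. = FALSE)
      keep <- sheet$species %in% tcfg$species
      rep <- transfer_evaluate(models[[tcfg$clock]],
                               mat[keep, , drop = FALSE],
                               sheet[keep, , drop = FALSE], species_params)
      jsonlite::write_json(as.data.frame(rep),
                           file.path(out_dir, "transfer_report.json"),
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      emit("transfer_report.json")
    })
  }

  if (isTRUE(stages$ewas)) {
    run_stage("ewas", {
      ecfg <- config$ewas %||% list()
      sp <- ecfg$species %||% unique(sheet$species)[1]
      keep <- sheet$species %in% sp
      recs <- ewas_screen(mat[keep, , drop = FALSE], sheet$age[keep])
      write_ewas_table(recs, file.path(out_dir, "ewas_table.tsv"))
      emit("ewas_table.tsv")
      top <- select_top_cpgs(recs,
                             p_threshold = ecfg$p_threshold %||% 1e-8,
                             cap = ecfg$cap %||% 500L)
      topdf <- data.frame(
        probe_id = c(top$hyper, top$hypo),
        direction = c(rep("hyper", length(top$hyper)),
                      rep("hypo", length(top$hypo))),
        stringsAsFactors = FALSE)
      .write_tsv(topdf, file.path(out_dir, "ewas_top_cpgs.tsv"))
      emit("ewas_top_cpgs.tsv")
      if (!is.null(annotation)) {
        rs <- region_summary(top, annotation)
        .write_tsv(rs, file.path(out_dir, "ewas_region_summary.tsv"))
        emit("ewas_region_summary.tsv")
      }
    })
  }

  outputs <- sort(unique(outputs))
  hashes <- unname(tools::md5sum(file.path(out_dir, outputs)))
  manifest <- list(
    pipeline = "clockforge",
    seed = seed,
    stages = stages[order(names(stages))],
    outputs = data.frame(path = outputs, md5 = hashes,
                         stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  log_line("done; ", length(outputs), " outputs in ", out_dir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create a self-contained demo dataset and pipeline config
#'
#' Generates a small two-species (cat + human) panel with default effect
#' sizes, writes its tables, and emits a ready-to-run pipeline config
#' sized so the full pipeline completes in about a minute.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for the panel.
#' @return path to the written `config.yaml`.
#' @export
make_demo <- function(dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- generator_config(
    species = list(
      species_spec("cat", n_samples = 40, age_range = c(0.2, 21),
                   max_lifespan = 30, maturity = 1),
      species_spec("human", n_samples = 60, age_range = c(0, 93),
                   max_lifespan = 122, maturity = 15)),
    n_probes = 600L, n_age_probes = 120L, n_sex_probes = 20L,
    n_species_marker_probes = 40L, seed = seed)
  panel <- generate_panel(cfg)
  write_panel(panel, dir)
  pipe_cfg <- list(
    matrix = file.path(dir, "matrix.tsv"),
    sheet = file.path(dir, "sheet.tsv"),
    species_params = file.path(dir, "species_params.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    out_dir = file.path(dir, "out"),
    seed = as.integer(seed),
    stages = list(qc = TRUE, train = TRUE, cv = TRUE, transfer = FALSE,
                  ewas = TRUE),
    clocks = list(
      list(name = "cat_clock", target = "raw_age", species = "cat"),
      list(name = "dual_chrono", target = "loglinear",
           species = c("cat", "human")),
      list(name = "dual_relative", target = "relative",
           species = c("cat", "human"))),
    cv = list(scheme = "kfold", k = 5L),
    ewas = list(species = "cat", p_threshold = 1e-8, cap = 500L))
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(pipe_cfg, path)
  path
}
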