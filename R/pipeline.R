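pipeline_defaults <- function() {
  list(
    output = list(dir = "connstab_out"),
    input = list(cohort_dir = NULL),   # real-data path; NULL = synthetic
    synthetic = list(),                # overrides for synth_config()
    features = list(types = c("ss_link_weight", "ss_log_degree"),
                    threshold = 0.7, block_dims = c(4, 4, 3),
                    min_fill = 0.5, absolute = FALSE),
    stats = list(alpha = 0.05, stat_maps = FALSE),
    stability = list(k_grid = NULL),
    classify = list(families = "linear_svm", k_grid = c(10, 30),
                    seed = 1L, params = list()),
    scales = list(target_grid = c(50, 100, 300, 500, 700),
                  lambda2_grid = c(0.01, 0.1, 1.0), alpha = 0.05)
  )
}

#' Validate a pipeline configuration
#'
#' Loads a YAML file (or takes a list), checks every section and key
#' against the known schema (unknown keys are rejected), and fills in
#' defaults.
#'
#' @param config path to a YAML config file, or a named list.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (sec == "synthetic") bad <- setdiff(names(config[[sec]]),
                                           names(formals(synth_config)))
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
    defaults[[sec]] <- modifyList(defaults[[sec]], config[[sec]])
  }
  ft <- defaults$features$types
  ok <- c("degree", "log_degree", "ss_log_degree", "link_weight",
          "ss_link_weight")
  if (!all(ft %in% ok)) stop("unknown feature type(s): ",
                             paste(setdiff(ft, ok), collapse = ", "))
  if (!all(defaults$classify$families %in% classifier_families))
    stop("unknown classifier familie(s): ",
         paste(setdiff(defaults$classify$families, classifier_families),
               collapse = ", "))
  structure(defaults, class = "pipeline_config")
}

log_line <- function(out_dir, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
  cat(msg, "\n", sep = "", file = file.path(out_dir, "connstab.log"),
      append = TRUE)
}

timed <- function(out_dir, stage, expr) {
  t0 <- Sys.time()
  log_line(out_dir, "[", stage, "] start")
  res <- force(expr)
  log_line(out_dir, "[", stage, "] done in ",
           sprintf("%.1fs", as.numeric(difftime(Sys.time(), t0, "secs"))))
  res
}

features_csv <- function(out_dir, type) {
  file.path(out_dir, paste0("features_", type, ".csv"))
}

write_features <- function(fm, out_dir, type) {
  vals <- tibble::as_tibble(as.data.frame(fm$values),
                            .name_repair = ~ paste0("f", seq_along(.x)))
  readr::write_csv(dplyr::bind_cols(fm$samples, vals),
                   features_csv(out_dir, type))
  readr::write_csv(fm$descriptors,
                   file.path(out_dir, paste0("features_", type,
                                             "_descriptors.csv")))
}

read_features <- function(out_dir, type) {
  path <- features_csv(out_dir, type)
  if (!file.exists(path))
    stop("missing feature table ", path,
         "; run the 'extract' stage first")
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  fcols <- grep("^f[0-9]+$", names(tbl))
  desc <- readr::read_csv(file.path(out_dir, paste0("features_", type,
                                                    "_descriptors.csv")),
                          show_col_types = FALSE)
  structure(list(values = as.matrix(tbl[, fcols]),
                 feature_type = sub("^ss_", "", type),
                 descriptors = desc,
                 samples = tbl[, -fcols, drop = FALSE],
                 threshold = NA_real_, block_dims = NULL),
            class = "conn_features")
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages — `simulate` (or real-data ingest), `extract`,
#' `univariate`, `stability`, `classify`, `scales`, `report` — writing
#' CSV tables, a JSON run manifest, and a timing log under the configured
#' output directory. Each stage reads its inputs from the artifacts of
#' the previous stages, so stages can be re-run individually.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @param stages which stages to run, in order.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "extract", "univariate",
                                    "stability", "classify", "scales",
                                    "report")) {
  cfg <- if (inherits(config, "pipeline_config")) config
    else pipeline_config(config)
  out <- cfg$output$dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- match.arg(stages, several.ok = TRUE)

  if ("simulate" %in% stages) timed(out, "simulate", cmd_simulate(cfg))
  if ("extract" %in% stages) timed(out, "extract", cmd_extract(cfg))
  if ("univariate" %in% stages) timed(out, "univariate", cmd_univariate(cfg))
  if ("stability" %in% stages) timed(out, "stability", cmd_stability(cfg))
  if ("classify" %in% stages) timed(out, "classify", cmd_classify(cfg))
  if ("scales" %in% stages) timed(out, "scales", cmd_scales(cfg))
  if ("report" %in% stages) timed(out, "report", cmd_report(cfg))
  invisible(out)
}

cohort_dir <- function(cfg) {
  cfg$input$cohort_dir %||% file.path(cfg$output$dir, "cohort")
}

#' Pipeline stage: simulate a synthetic cohort
#' @param cfg a [pipeline_config()].
#' @return Invisibly, the cohort directory.
#' @export
cmd_simulate <- function(cfg) {
  sc <- do.call(synth_config, cfg$synthetic)
  cohort <- generate_cohort(sc)
  write_cohort(cohort, file.path(cfg$output$dir, "cohort"))
  invisible(file.path(cfg$output$dir, "cohort"))
}

#' Pipeline stage: extract feature matrices
#' @inheritParams cmd_simulate
#' @return Invisibly, the output directory.
#' @export
cmd_extract <- function(cfg) {
  cdir <- cohort_dir(cfg)
  if (!file.exists(file.path(cdir, "metadata.tsv")))
    stop("missing cohort at ", cdir, "; run the 'simulate' stage ",
         "or point input$cohort_dir at real data")
  cohort <- read_cohort(cdir)
  fs <- cfg$features
  for (type in fs$types) {
    fm <- extract_features(cohort, type, threshold = fs$threshold,
                           block_dims = fs$block_dims,
                           min_fill = fs$min_fill, absolute = fs$absolute)
    write_features(fm, cfg$output$dir, type)
  }
  invisible(cfg$output$dir)
}

#' Pipeline stage: mass-univariate tests
#' @inheritParams cmd_simulate
#' @return Invisibly, the output directory.
#' @export
cmd_univariate <- function(cfg) {
  for (type in cfg$features$types) {
    fm <- read_features(cfg$output$dir, type)
    res <- univariate_ttest(fm, alpha = cfg$stats$alpha)
    out <- dplyr::left_join(tibble::as_tibble(res), fm$descriptors,
                            by = "feature")
    readr::write_csv(out, file.path(cfg$output$dir,
                                    paste0("univariate_", type, ".csv")))
    if (isTRUE(cfg$stats$stat_maps) && all(c("x", "y", "z") %in%
                                           names(fm$descriptors))) {
      dims <- apply(fm$descriptors[, c("x", "y", "z")], 2, max) + 1L
      write_stat_map(res$t, fm$descriptors, dims,
                     file.path(cfg$output$dir, paste0("tmap_", type,
                                                      ".nii.gz")))
    }
  }
  invisible(cfg$output$dir)
}

# per-LOSO-fold p-value vectors for one feature matrix
per_fold_pvalues <- function(fm, alpha = 0.05) {
  folds <- make_loso_folds(fm$samples)
  lapply(folds$train_rows, function(tr)
    univariate_ttest(fm$values[tr, , drop = FALSE],
                     fm$samples$group[tr], alpha = alpha)$p)
}

#' Pipeline stage: feature-selection stability
#' @inheritParams cmd_simulate
#' @return Invisibly, the output directory.
#' @export
cmd_stability <- function(cfg) {
  for (type in cfg$features$types) {
    fm <- read_features(cfg$output$dir, type)
    pv <- per_fold_pvalues(fm, cfg$stats$alpha)
    curve <- stability_curve(pv, cfg$stability$k_grid, feature_type = type)
    readr::write_csv(tibble::as_tibble(curve),
                     file.path(cfg$output$dir,
                               paste0("stability_", type, ".csv")))
    masks <- lapply(pv, bonferroni_mask, alpha = cfg$stats$alpha)
    stable <- stable_bonferroni(masks)
    readr::write_csv(
      dplyr::semi_join(fm$descriptors, tibble::tibble(feature = stable),
                       by = "feature"),
      file.path(cfg$output$dir, paste0("stable_bonferroni_", type, ".csv")))
  }
  invisible(cfg$output$dir)
}

#' Pipeline stage: LOSO classification
#' @inheritParams cmd_simulate
#' @return Invisibly, the output directory.
#' @export
cmd_classify <- function(cfg) {
  for (type in cfg$features$types) {
    fm <- read_features(cfg$output$dir, type)
    res <- dplyr::bind_rows(lapply(cfg$classify$families, function(fam) {
      cv <- run_cv(fm, fam, k_grid = cfg$classify$k_grid,
                   params = cfg$classify$params, seed = cfg$classify$seed)
      dplyr::mutate(cv$summary, classifier = fam, .before = 1)
    }))
    readr::write_csv(res, file.path(cfg$output$dir,
                                    paste0("classification_", type, ".csv")))
  }
  invisible(cfg$output$dir)
}

#' Pipeline stage: symptom-scale prediction
#' @inheritParams cmd_simulate
#' @return Invisibly, the output directory.
#' @export
cmd_scales <- function(cfg) {
  type <- grep("link_weight", cfg$features$types, value = TRUE)[1]
  if (is.na(type))
    stop("scale prediction needs a link_weight feature type in ",
         "features$types")
  fm <- read_features(cfg$output$dir, type)
  rep <- scale_prediction_report(fm,
                                 target_grid = cfg$scales$target_grid,
                                 lambda2_grid = cfg$scales$lambda2_grid,
                                 alpha = cfg$scales$alpha)
  tbl <- dplyr::select(rep$table, -dplyr::any_of(c("supports",
                                                   "stable_support")))
  readr::write_csv(tbl, file.path(cfg$output$dir, "scales_configs.csv"))
  readr::write_csv(rep$best_per_scale,
                   file.path(cfg$output$dir, "scales_summary.csv"))
  if (nrow(rep$chosen))
    readr::write_csv(dplyr::select(rep$chosen,
                                   -dplyr::any_of(c("supports",
                                                    "stable_support"))),
                     file.path(cfg$output$dir, "scales_chosen.csv"))
  invisible(cfg$output$dir)
}

#' Pipeline stage: run manifest
#'
#' Writes a JSON manifest of the exact configuration (including seeds and
#' the package version) that reproduces every table in the output
#' directory.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the manifest path.
#' @export
cmd_report <- function(cfg) {
  manifest <- list(
    package = "connstab",
    version = as.character(utils::packageVersion("connstab")),
    config = unclass(cfg),
    artifacts = sort(setdiff(list.files(cfg$output$dir),
                             c("connstab.log", "manifest.json"))))
  path <- file.path(cfg$output$dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
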