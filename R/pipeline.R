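#' Pipeline configuration
#'
#' One structured config drives all pipeline commands. It can be built in
#' code or read from YAML with [read_pipeline_config()]. Any field left NULL
#' takes the package default.
#'
#' @param eem_dir Directory holding (or receiving) the EEM-CSV files.
#' @param manifest Path of the manifest CSV.
#' @param out_dir Directory for command outputs.
#' @param seed Integer seed; every stochastic step derives from it.
#' @param design A [study_design()] for `cmd_simulate`.
#' @param scatter A [scatter_params()].
#' @param atld An [atld_config()].
#' @param n_range Candidate component numbers for the CORCONDIA scan.
#' @param classifier List: `method` (`"knn"`, `"rf"`, `"plsda"`), method
#'   parameters, `label` (`"origin"` or `"species"`), `scheme`
#'   (`"loo"` or `"stratified"`).
#' @param clip Clip negative intensities after preprocessing?
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(eem_dir, manifest = file.path(eem_dir, "manifest.csv"),
                            out_dir = eem_dir, seed = 42,
                            design = NULL, scatter = scatter_params(),
                            atld = atld_config(), n_range = 1:8,
                            classifier = list(method = "rf", label = "origin",
                                              scheme = "loo"),
                            clip = FALSE) {
  if (is.null(design)) design <- study_design(seed = seed)
  structure(list(eem_dir = eem_dir, manifest = manifest, out_dir = out_dir,
                 seed = as.integer(seed), design = design, scatter = scatter,
                 atld = atld, n_range = n_range, classifier = classifier,
                 clip = clip),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()], [study_design()],
#' [scatter_params()] and [atld_config()]; unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  take <- function(lst, fn, extra = list()) {
    allowed <- names(formals(fn))
    unknown <- setdiff(names(lst), allowed)
    if (length(unknown))
      stop(sprintf("config error: unknown key(s) %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    do.call(fn, c(lst, extra))
  }
  seed <- if (is.null(raw$seed)) 42L else as.integer(raw$seed)
  design <- if (is.null(raw$design)) study_design(seed = seed) else
    take(raw$design, study_design)
  scatter <- if (is.null(raw$scatter)) scatter_params() else
    take(raw$scatter, scatter_params)
  atld <- if (is.null(raw$atld)) atld_config() else take(raw$atld, atld_config)
  pipeline_config(eem_dir = raw$eem_dir,
                  manifest = if (is.null(raw$manifest))
                    file.path(raw$eem_dir, "manifest.csv") else raw$manifest,
                  out_dir = if (is.null(raw$out_dir)) raw$eem_dir else raw$out_dir,
                  seed = seed, design = design, scatter = scatter, atld = atld,
                  n_range = if (is.null(raw$n_range)) 1:8 else
                    eval(parse(text = raw$n_range)),
                  classifier = if (is.null(raw$classifier))
                    list(method = "rf", label = "origin", scheme = "loo") else
                    raw$classifier,
                  clip = isTRUE(raw$clip))
}

log_line <- function(...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  sprintf(...)))
}

#' Simulate a dataset to disk
#'
#' Runs [simulate_dataset()] with the config's design and writes one EEM-CSV
#' per sample, the manifest, and a ground-truth sidecar (true concentrations)
#' under `eem_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest path.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$eem_dir, showWarnings = FALSE, recursive = TRUE)
  log_line("simulate: seed %d", config$design$seed)
  sim <- simulate_dataset(config$design)
  files <- character(length(sim$samples))
  for (i in seq_along(sim$samples)) {
    s <- sim$samples[[i]]
    files[i] <- paste0(s$sample_id, ".csv")
    write_eem(s, file.path(config$eem_dir, files[i]))
  }
  manifest <- sim$truth$labels
  manifest$file <- files
  manifest <- manifest[, c("sample_id", "file", "origin", "species", "role")]
  manifest[is.na(manifest)] <- ""
  utils::write.csv(manifest, config$manifest, row.names = FALSE)
  utils::write.csv(data.frame(sample_id = rownames(sim$truth$concentrations),
                              sim$truth$concentrations),
                   file.path(config$eem_dir, "ground_truth_concentrations.csv"),
                   row.names = FALSE)
  log_line("simulate: wrote %d EEM files + manifest", length(files))
  invisible(config$manifest)
}

load_dataset <- function(config) {
  manifest <- load_manifest(config$manifest)
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    s <- read_eem(file.path(config$eem_dir, manifest$file[i]))
    s$sample_id <- manifest$sample_id[i]
    s$origin <- manifest$origin[i]
    s$species <- manifest$species[i]
    s$role <- manifest$role[i]
    s
  })
  list(manifest = manifest, samples = samples)
}

#' Preprocess a dataset on disk
#'
#' Loads the manifest and EEM files, applies [preprocess_pipeline()]
#' (crop, blank subtraction, scatter interpolation, optional clipping), and
#' writes corrected EEM-CSVs plus a copy of the manifest under
#' `out_dir/corrected`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the corrected-data directory.
#' @export
cmd_preprocess <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ds <- load_dataset(config)
  is_blank <- ds$manifest$role == "blank"
  if (!any(is_blank))
    stop("cmd_preprocess: no blank samples in manifest", call. = FALSE)
  out_dir <- file.path(config$out_dir, "corrected")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  corrected <- preprocess_pipeline(ds$samples[!is_blank],
                                   blanks = ds$samples[is_blank],
                                   params = config$scatter, clip = config$clip,
                                   verbose = TRUE)
  for (s in corrected)
    write_eem(s, file.path(out_dir, paste0(s$sample_id, ".csv")))
  manifest <- ds$manifest[!is_blank, ]
  manifest$file <- paste0(manifest$sample_id, ".csv")
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  log_line("preprocess: corrected %d samples", length(corrected))
  invisible(out_dir)
}

#' Decompose a corrected dataset
#'
#' Stacks the corrected training + validation samples into a tensor, scans
#' component numbers by CORCONDIA, fits ATLD at the selected N, and exports
#' loadings, scores, the residual trace and the scan table under
#' `out_dir/decomposition`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the `scan`, the fitted `model`, and the
#'   corrected-data `manifest`.
#' @export
cmd_decompose <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  corr <- config
  corr$eem_dir <- file.path(config$out_dir, "corrected")
  corr$manifest <- file.path(corr$eem_dir, "manifest.csv")
  ds <- load_dataset(corr)
  tensor <- stack_tensor(ds$samples)
  log_line("decompose: scanning N over %s", paste(range(config$n_range),
                                                  collapse = ".."))
  scan <- scan_components(tensor, config$n_range, config$atld)
  model <- atld_fit(tensor, scan$selected, config$atld)
  out_dir <- file.path(config$out_dir, "decomposition")
  export_model(model, out_dir)
  utils::write.csv(scan$results, file.path(out_dir, "corcondia_scan.csv"),
                   row.names = FALSE)
  log_line("decompose: selected N=%d (fit %.4f)", scan$selected,
           model$explained_variance)
  invisible(list(scan = scan, model = model, manifest = ds$manifest))
}

#' Classify samples from decomposition scores
#'
#' Builds the feature table from the ATLD scores and manifest labels, runs
#' the configured classifier with cross-validation on the training samples
#' and external validation on the held-out samples, and writes the reports
#' (confusion matrices, per-class metric tables, kNN neighbour table) under
#' `out_dir/classification`.
#'
#' @param config A [pipeline_config()].
#' @param decomposition Optional result of [cmd_decompose()] (rerun if
#'   omitted).
#' @return Invisibly, a list with `cv_report`, `external_report`, and for
#'   kNN the `neighbors` table.
#' @export
cmd_classify <- function(config, decomposition = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(decomposition)) decomposition <- cmd_decompose(config)
  model <- decomposition$model
  manifest <- decomposition$manifest
  idx <- match(model$sample_ids, manifest$sample_id)
  label_col <- if (identical(config$classifier$label, "species"))
    "species" else "origin"
  labels <- manifest[[label_col]][idx]
  roles <- manifest$role[idx]
  spec <- config$classifier
  spec$label <- NULL
  scheme <- if (is.null(spec$scheme)) "loo" else spec$scheme
  spec$scheme <- NULL
  if (is.null(spec$seed)) spec$seed <- config$seed

  is_train <- roles == "train"
  train <- feature_table(model$sample_ids[is_train], labels[is_train],
                         model$scores[is_train, , drop = FALSE])
  cv_report <- cross_validate(train, spec, scheme = scheme, seed = config$seed)
  external_report <- NULL
  neighbors <- NULL
  if (any(!is_train)) {
    holdout <- feature_table(model$sample_ids[!is_train], labels[!is_train],
                             model$scores[!is_train, , drop = FALSE])
    external_report <- external_validate(train, holdout, spec)
    if (spec$method == "knn")
      neighbors <- knn_classify(train, holdout,
                                k = if (is.null(spec$k)) 3 else spec$k)$neighbors
  }
  out_dir <- file.path(config$out_dir, "classification")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- paste0(spec$method, "_", label_col)
  utils::write.csv(as.data.frame(cv_report$confusion),
                   file.path(out_dir, paste0(prefix, "_cv_confusion.csv")),
                   row.names = FALSE)
  utils::write.csv(cv_report$metrics,
                   file.path(out_dir, paste0(prefix, "_cv_metrics.csv")),
                   row.names = FALSE)
  if (!is.null(external_report))
    utils::write.csv(external_report$metrics,
                     file.path(out_dir, paste0(prefix, "_external_metrics.csv")),
                     row.names = FALSE)
  if (!is.null(neighbors))
    utils::write.csv(neighbors,
                     file.path(out_dir, paste0(prefix, "_neighbors.csv")),
                     row.names = FALSE)
  log_line("classify: %s on %s labels, CV accuracy %.1f%%", spec$method,
           label_col, cv_report$accuracy)
  invisible(list(cv_report = cv_report, external_report = external_report,
                 neighbors = neighbors))
}

#' Run the full pipeline end to end
#'
#' `simulate -> preprocess -> decompose -> classify` from one config; all
#' randomness flows from the single config seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the [cmd_classify()] result.
#' @export
run_pipeline <- function(config) {
  cmd_simulate(config)
  cmd_preprocess(config)
  dec <- cmd_decompose(config)
  invisible(cmd_classify(config, dec))
}
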