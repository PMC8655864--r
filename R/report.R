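run_config_defaults <- function() {
  list(
    leak_threshold_uA = 1,
    rectification_ratio = 5,
    noise_floor_uA = 0.05,
    normalizer = "rms",
    candidates = c("exactly_4", "at_least_3", "at_least_2", "at_least_1",
                   "no_mixing"),
    weights = "none",
    fit_residual = FALSE,
    bootstrap_B = 0L,
    seed = 1L
  )
}

#' Read and validate a run configuration
#'
#' Accepts a YAML file path or a named list; unspecified fields take the
#' package defaults (1 uA leak threshold, rectification ratio 5, RMS
#' percent-deviation normalizer, the five-member tetramer candidate set,
#' unweighted fitting, no bootstrap).
#'
#' @param config NULL (all defaults), a named list, or a YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(config = NULL) {
  cfg <- run_config_defaults()
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.null(config)) {
    if (!is.list(config)) stop("'config' must be a list or a YAML path",
                               call. = FALSE)
    unknown <- setdiff(names(config), names(cfg))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(config)] <- config
  }
  if (cfg$leak_threshold_uA <= 0 || cfg$rectification_ratio <= 0)
    stop("QC thresholds must be positive", call. = FALSE)
  if (length(cfg$candidates) < 1L)
    stop("candidate model set must be non-empty", call. = FALSE)
  cfg$bootstrap_B <- as.integer(cfg$bootstrap_B)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Build stoichiometry models from labels
#'
#' @param labels Character labels such as `"exactly_4"`, `"at_least_2"`,
#'   `"no_mixing"`.
#' @param n_subunits Subunits per channel.
#' @param residual Mutant residual activity for every model.
#' @return A named list of [stoich_model()] objects.
#' @export
candidates_from_labels <- function(labels, n_subunits = 4L, residual = 0) {
  out <- lapply(labels, function(lb) {
    if (lb == "no_mixing")
      return(stoich_model("no_mixing", n_subunits = n_subunits,
                          residual = residual))
    m <- regmatches(lb, regexec("^(exactly|at_least)_([0-9]+)$", lb))[[1]]
    if (length(m) != 3L)
      stop("unrecognized model label: '", lb, "'", call. = FALSE)
    stoich_model(paste0(m[2], "_n"), as.integer(m[3]), n_subunits, residual)
  })
  names(out) <- vapply(out, model_label, character(1))
  out
}

as_table <- function(path_or_df, what) {
  if (is.null(path_or_df)) return(NULL)
  if (is.data.frame(path_or_df)) return(path_or_df)
  if (!is.character(path_or_df) || !file.exists(path_or_df))
    stop("cannot read ", what, ": ", path_or_df, call. = FALSE)
  utils::read.csv(path_or_df, stringsAsFactors = FALSE)
}

#' Simulate a dataset and write it to disk
#'
#' Wraps [simulate_dataset()] and [write_dataset()]; the effective
#' configuration (including the seed) is echoed to `config_echo.json` in the
#' output directory so any run can be reproduced exactly.
#'
#' @param config A [sim_config()], a named list of its fields, or a YAML file
#'   path with those fields (`truth_model` given as a mapping with `rule`,
#'   `n_required`, `n_subunits`, `residual`).
#' @param out_dir Output directory.
#' @param seed Optional integer overriding the config seed.
#' @return The simulated `oocyte_dataset`, invisibly.
#' @export
run_simulate <- function(config = sim_config(), out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!inherits(config, "sim_config")) {
    if (!is.list(config))
      stop("'config' must be a sim_config, list, or YAML path", call. = FALSE)
    defaults <- config_to_list(sim_config())
    full <- defaults
    full[names(config)] <- config
    if (!is.list(full$truth_model))
      stop("'truth_model' must be a mapping with a 'rule' field",
           call. = FALSE)
    tm <- full$truth_model
    defaults_tm <- defaults$truth_model
    defaults_tm[names(tm)] <- tm
    full$truth_model <- defaults_tm
    config <- config_from_list(full)
  }
  if (!is.null(seed)) {
    lst <- config_to_list(config)
    lst$seed <- as.integer(seed)
    config <- config_from_list(lst)
  }
  dataset <- simulate_dataset(config)
  write_dataset(dataset, out_dir)
  jsonlite::write_json(config_to_list(config),
                       file.path(out_dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dataset)
}

#' Run the full analysis pipeline and write a fit report
#'
#' Extraction with QC ([extract_all()]), batch normalization
#' ([normalize_by_batch()]), model ranking ([fit_stoichiometry()]) and, if
#' configured, bootstrap selection frequencies ([bootstrap_ranking()]).
#' Writes `fit_report.json` (validated by [validate_report()]) and a plain
#' text `summary.txt` when `out_dir` is given.
#'
#' @param measurements Long measurements table or CSV path (columns
#'   `batch_id, oocyte_id, wt_fraction, rna_ng_total, solution, holding_mV,
#'   current_uA`).
#' @param ramps Optional ramp table or CSV path.
#' @param design Optional design table or CSV path; cross-checked against the
#'   measurements when given.
#' @param config Run configuration ([read_run_config()]): list, YAML path or
#'   NULL for defaults.
#' @param out_dir Optional output directory for the report files.
#' @param verbose Emit per-stage counts via [message()].
#' @return The report, an object of class `fit_report` (a list with elements
#'   `version, seed, config, qc, groups, fits, bootstrap, best_model`),
#'   invisibly when `out_dir` is given.
#' @export
run_fit <- function(measurements, ramps = NULL, design = NULL, config = NULL,
                    out_dir = NULL, verbose = interactive()) {
  cfg <- read_run_config(config)
  measurements <- as_table(measurements, "measurements")
  ramps <- as_table(ramps, "ramps")
  design <- as_table(design, "design")
  if (!is.null(design)) {
    extra <- setdiff(unique(measurements$oocyte_id), design$oocyte_id)
    if (length(extra))
      stop("measurements reference oocytes absent from the design: ",
           paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }

  extracted <- extract_all(measurements, ramps,
                           leak_threshold_uA = cfg$leak_threshold_uA,
                           r_min = cfg$rectification_ratio,
                           noise_floor_uA = cfg$noise_floor_uA)
  qc <- as.list(attr(extracted, "qc_counts"))
  if (verbose)
    message(sprintf("QC: %d/%d oocytes included (%d leaky, %d not rectifying)",
                    qc$included, qc$total, qc$leaky, qc$not_rectifying))
  if (qc$included == 0L)
    stop("no oocytes survived QC; nothing to fit", call. = FALSE)

  groups <- normalize_by_batch(extracted)
  if (verbose)
    message("normalized groups at p = ",
            paste(groups$wt_fraction, collapse = ", "),
            if (length(attr(groups, "dropped_batches")))
              paste("; dropped batches:",
                    paste(attr(groups, "dropped_batches"), collapse = ", "))
            else "")
  points <- to_points(groups)

  candidates <- candidates_from_labels(cfg$candidates)
  weights <- if (identical(cfg$weights, "none")) NULL else cfg$weights
  fit <- fit_stoichiometry(points, candidates, cfg$normalizer, weights,
                           cfg$fit_residual)

  boot <- NULL
  if (cfg$bootstrap_B > 0L) {
    boot <- bootstrap_ranking(extracted, candidates, cfg$bootstrap_B,
                              cfg$seed, cfg$normalizer, weights,
                              cfg$fit_residual)
    attr(boot, "skipped") <- NULL
  }

  report <- structure(list(
    version = as.character(utils::packageVersion("kirstoich")),
    seed = cfg$seed,
    config = unclass(cfg),
    qc = c(qc, list(dropped_batches = as.list(attr(groups,
                                                   "dropped_batches")))),
    groups = groups,
    fits = fit$results,
    bootstrap = boot,
    best_model = fit$results$label[1]
  ), class = "fit_report")

  if (!is.null(out_dir)) {
    ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
    jsonlite::write_json(unclass_report(report),
                         file.path(out_dir, "fit_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(report_text(report), file.path(out_dir, "summary.txt"))
    return(invisible(report))
  }
  report
}

unclass_report <- function(report) {
  out <- unclass(report)
  out$groups <- as.data.frame(out$groups)
  attr(out$groups, "oocytes") <- NULL
  attr(out$groups, "dropped_batches") <- NULL
  out$fits <- as.data.frame(out$fits)
  attr(out$fits, "models") <- NULL
  out
}

#' Render a fit report as human-readable text
#'
#' @param report A `fit_report` from [run_fit()], or a path to a directory
#'   containing `fit_report.json` (or to the file itself).
#' @return A character vector of lines.
#' @export
report_text <- function(report) {
  if (is.character(report)) {
    path <- if (dir.exists(report)) file.path(report, "fit_report.json")
            else report
    if (!file.exists(path)) stop("report not found: ", path, call. = FALSE)
    report <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  g <- as.data.frame(report$groups)
  f <- as.data.frame(report$fits)
  lines <- c(
    sprintf("kirstoich fit report (package %s, seed %s)", report$version,
            report$seed),
    sprintf("QC: %g/%g oocytes included; %g leaky, %g not rectifying",
            report$qc$included, report$qc$total, report$qc$leaky,
            report$qc$not_rectifying),
    "",
    "Normalized groups (mean +/- sem vs WT fraction p):",
    sprintf("  p=%-4g  n=%-3d  %.4f +/- %.4f", g$wt_fraction, g$n_oocytes,
            g$mean_normalized, g$sem_normalized),
    "",
    "Model ranking by percent deviation from the data:",
    sprintf("  %d. %-10s rmsd=%.5f  deviation=%.2f%%", f$rank, f$label,
            f$rmsd, f$percent_deviation),
    "",
    sprintf("Best-supported rule: %s", report$best_model)
  )
  if (!is.null(report$bootstrap)) {
    b <- as.data.frame(report$bootstrap)
    lines <- c(lines, "",
               "Bootstrap rank-1 frequencies:",
               sprintf("  %-10s %.3f", b$label, b$freq_rank1))
  }
  lines
}

#' Validate a fit report against the shipped schema
#'
#' Checks the report against the JSON schema installed at
#' `inst/schema/fit_report.schema.json`: required keys must be present and of
#' the schema's primitive types (a lightweight structural check, not a full
#' JSON-Schema engine).
#'
#' @param report A `fit_report`, a parsed report list, or a path to
#'   `fit_report.json`.
#' @return TRUE invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report))
    report <- jsonlite::read_json(report, simplifyVector = TRUE)
  schema <- jsonlite::read_json(
    system.file("schema", "fit_report.schema.json", package = "kirstoich",
                mustWork = TRUE),
    simplifyVector = FALSE)
  check_node <- function(node, value, where) {
    type <- node[["type"]]
    ok <- switch(type,
      object  = is.list(value) && !is.data.frame(value),
      array   = is.list(value) || is.data.frame(value) ||
                (is.atomic(value) && is.null(dim(value))),
      string  = is.character(value) && length(value) == 1L,
      integer = is.numeric(value) && length(value) == 1L,
      number  = is.numeric(value) && length(value) == 1L,
      TRUE)
    if (!ok)
      stop("report field '", where, "' is not of schema type '", type, "'",
           call. = FALSE)
    if (type == "object" && !is.null(node$required)) {
      for (key in node$required) {
        if (is.null(value[[key]]))
          stop("report is missing required field '",
               paste(c(where, key), collapse = "."), "'", call. = FALSE)
        if (!is.null(node$properties[[key]]))
          check_node(node$properties[[key]], value[[key]],
                     paste(c(where, key), collapse = "."))
      }
    }
  }
  check_node(schema, unclass_report_safe(report), character(0))
  invisible(TRUE)
}

unclass_report_safe <- function(report) {
  if (inherits(report, "fit_report")) unclass_report(report)
  else report
}
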