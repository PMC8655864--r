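# Lognormal draws parameterized by arithmetic mean and coefficient of
# variation; a CV of 0 degenerates to the mean. Expression levels in oocytes
# are positive and right-skewed, which this matches.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (mean == 0) return(rep(0, n))
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Configuration for a synthetic oocyte co-expression experiment
#'
#' Defines the design and noise structure of a simulated two-electrode
#' voltage-clamp experiment: batches of Xenopus oocytes injected with
#' WT/mutant mRNA mixes, with lognormal expression variability within and
#' between batches, additive ohmic leak, a Ba2+-insensitive endogenous
#' outward component at positive potentials, and a known ground-truth
#' assembly rule.
#'
#' Defaults emulate the study conditions: design points p = 1, 0.8, 0.5, 0
#' (pure WT, the 4:1 and 1:1 WT:mutant co-injections, pure mutant), about ten
#' oocytes per group, 30% within-batch expression CV, a stronger 50%
#' batch-to-batch scale CV (oocyte batches are notoriously variable, which is
#' what the batch normalization corrects), a few-microampere pure-WT Kir
#' current at -50 mV in high K+, and a 10% rate of over-leaky oocytes.
#'
#' @param n_batches Number of oocyte batches (donor frogs).
#' @param oocytes_per_group Oocytes per (batch, WT-fraction) cell.
#' @param wt_fractions Injected WT mRNA mass fractions, each in \[0, 1\];
#'   taken directly as the WT subunit fraction p (equal translation
#'   efficiency and random co-assembly assumed).
#' @param truth_model Ground-truth [stoich_model()] generating the data.
#' @param wt_only_mean_current Mean magnitude (uA) of the Kir-specific inward
#'   current at -50 mV in high K+ for pure-WT oocytes.
#' @param expression_cv Lognormal CV of per-oocyte expression.
#' @param batch_scale_cv Lognormal CV of the per-batch expression scale.
#' @param leak_mean,leak_cv Mean (uA at -50 mV) and lognormal CV of the
#'   ohmic leak current magnitude.
#' @param endogenous_outward_mean Magnitude (uA at +50 mV) of the
#'   Ba2+-insensitive endogenous outward component.
#' @param leaky_fraction Probability an oocyte is "too leaky" (its leak is
#'   redrawn large enough that outward ramp current at positive potentials
#'   exceeds the 1 uA QC threshold).
#' @param rna_ng_total Total injected mRNA mass (ng), recorded as metadata.
#' @param seed Integer RNG seed; the full dataset is deterministic given the
#'   configuration including this seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_batches = 3L, oocytes_per_group = 10L,
                       wt_fractions = c(1, 0.8, 0.5, 0),
                       truth_model = stoich_model("exactly_n", 4),
                       wt_only_mean_current = 5, expression_cv = 0.3,
                       batch_scale_cv = 0.5, leak_mean = 0.1, leak_cv = 0.5,
                       endogenous_outward_mean = 0.2, leaky_fraction = 0.1,
                       rna_ng_total = 2, seed = 1L) {
  n_batches <- as.integer(n_batches)
  oocytes_per_group <- as.integer(oocytes_per_group)
  if (is.na(n_batches) || n_batches < 1L)
    stop("'n_batches' must be >= 1", call. = FALSE)
  if (is.na(oocytes_per_group) || oocytes_per_group < 1L)
    stop("'oocytes_per_group' must be >= 1", call. = FALSE)
  if (!is.numeric(wt_fractions) || length(wt_fractions) < 1L ||
      anyNA(wt_fractions) || any(wt_fractions < 0 | wt_fractions > 1))
    stop("'wt_fractions' must all lie in [0, 1]", call. = FALSE)
  if (!inherits(truth_model, "stoich_model"))
    stop("'truth_model' must be a stoich_model", call. = FALSE)
  for (nm in c("wt_only_mean_current", "expression_cv", "batch_scale_cv",
               "leak_mean", "leak_cv", "endogenous_outward_mean",
               "rna_ng_total")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("'", nm, "' must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(leaky_fraction) || length(leaky_fraction) != 1L ||
      is.na(leaky_fraction) || leaky_fraction < 0 || leaky_fraction >= 1)
    stop("'leaky_fraction' must be in [0, 1)", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer", call. = FALSE)
  structure(
    list(n_batches = n_batches, oocytes_per_group = oocytes_per_group,
         wt_fractions = as.numeric(wt_fractions), truth_model = truth_model,
         wt_only_mean_current = wt_only_mean_current,
         expression_cv = expression_cv, batch_scale_cv = batch_scale_cv,
         leak_mean = leak_mean, leak_cv = leak_cv,
         endogenous_outward_mean = endogenous_outward_mean,
         leaky_fraction = leaky_fraction, rna_ng_total = rna_ng_total,
         seed = seed),
    class = "sim_config"
  )
}

ramp_voltages <- function() seq(-50, 50, by = 2)

#' Synthesize a current-voltage ramp for one oocyte in one bath solution
#'
#' Builds the current response to a -50 to +50 mV voltage ramp from three
#' components: an ohmic leak through the origin; a strongly inwardly
#' rectifying Kir component conducting in the high-K+ solution only (reversal
#' at 0 mV in symmetric K+, open fraction falling sigmoidally with
#' depolarization), scaled so the Kir current at -50 mV equals `-kir_uA`
#' exactly; and an endogenous outward component at positive potentials that
#' is present in every solution, including Ba2+, because it is not carried by
#' Kir channels. Currents are signed: inward negative, in uA.
#'
#' @param kir_uA Magnitude (uA, positive) of the oocyte's Kir-specific inward
#'   current at -50 mV in high K+.
#' @param leak_uA Magnitude (uA, positive) of the ohmic leak at -50 mV.
#' @param endo_uA Magnitude (uA, positive) of the endogenous outward current
#'   at +50 mV.
#' @param solution One of `"low_k"`, `"high_k"`, `"ba"`. The Kir component
#'   conducts only in `"high_k"`: in low K+ it is negligible at -50 mV and in
#'   Ba2+ it is fully blocked.
#' @param voltages Ramp voltage grid (mV), non-decreasing, covering -50..+50.
#' @param v_slope Steepness (mV) of the rectification gate.
#' @return A data.frame with columns `voltage_mV`, `current_uA`.
#' @export
synth_ramp <- function(kir_uA, leak_uA, endo_uA, solution,
                       voltages = ramp_voltages(), v_slope = 10) {
  if (!solution %in% c("low_k", "high_k", "ba"))
    stop("unknown solution label: '", solution, "'", call. = FALSE)
  i_leak <- leak_uA / 50 * voltages
  i_endo <- endo_uA * (pmax(voltages, 0) / 50)^2
  i_kir <- 0
  if (solution == "high_k" && kir_uA > 0) {
    shape <- voltages * stats::plogis(-voltages / v_slope)
    i_kir <- kir_uA * shape / (50 * stats::plogis(50 / v_slope))
  }
  data.frame(voltage_mV = voltages, current_uA = i_leak + i_endo + i_kir)
}

#' Simulate a full oocyte co-expression dataset with known ground truth
#'
#' For each oocyte, the Kir-specific current magnitude is
#' `batch_scale x oocyte_expression x wt_only_mean_current x
#' expected_activity(p, truth_model)`. Steady currents at -50 mV are then
#' `I_lowK = -leak`, `I_highK = I_lowK - Kir`, `I_Ba = I_lowK` (complete
#' Ba2+ block), all signed with inward negative. Oocytes flagged leaky have
#' their leak redrawn in 1.5..3 uA so the positive-potential ramp current
#' crosses the QC threshold. Deterministic given the seed in `config`.
#'
#' @param config A [sim_config()].
#' @param include_ramps Generate per-solution voltage ramps for every oocyte
#'   (default TRUE). Ramp synthesis is deterministic given the measurements,
#'   so disabling it changes no currents and no random draws; it only skips
#'   the bulkiest output for large simulation sweeps.
#' @return An object of class `oocyte_dataset`: a list with elements
#'   `design`, `measurements`, `ramps` (NULL if not generated) and `truth`
#'   (seed, config echo, truth model, per-oocyte latent scales).
#' @export
simulate_dataset <- function(config = sim_config(), include_ramps = TRUE) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be a sim_config", call. = FALSE)
  set.seed(config$seed)

  batch_ids <- sprintf("b%02d", seq_len(config$n_batches))
  design <- expand.grid(
    slot = seq_len(config$oocytes_per_group),
    wt_fraction = config$wt_fractions,
    batch_id = batch_ids,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  design <- design[order(design$batch_id, -design$wt_fraction, design$slot), ]
  n <- nrow(design)
  design$oocyte_id <- paste0(design$batch_id, sprintf("_o%03d",
                             stats::ave(seq_len(n), design$batch_id,
                                        FUN = seq_along)))
  design$rna_ng_total <- config$rna_ng_total
  design <- design[, c("batch_id", "oocyte_id", "wt_fraction",
                       "rna_ng_total")]
  rownames(design) <- NULL

  batch_scale <- rlnorm_mean_cv(config$n_batches, 1, config$batch_scale_cv)
  names(batch_scale) <- batch_ids
  expression_scale <- rlnorm_mean_cv(n, 1, config$expression_cv)
  leak <- rlnorm_mean_cv(n, config$leak_mean, config$leak_cv)
  leaky <- stats::runif(n) < config$leaky_fraction
  if (any(leaky)) leak[leaky] <- stats::runif(sum(leaky), 1.5, 3)

  activity <- expected_activity(design$wt_fraction, config$truth_model)
  kir_mag <- batch_scale[design$batch_id] * expression_scale *
    config$wt_only_mean_current * activity
  i_low <- -leak
  i_high <- i_low - kir_mag
  i_ba <- i_low

  solutions <- c("low_k", "high_k", "ba")
  measurements <- data.frame(
    batch_id = rep(design$batch_id, each = 3L),
    oocyte_id = rep(design$oocyte_id, each = 3L),
    wt_fraction = rep(design$wt_fraction, each = 3L),
    rna_ng_total = rep(design$rna_ng_total, each = 3L),
    solution = rep(solutions, times = n),
    holding_mV = -50,
    current_uA = as.vector(rbind(i_low, i_high, i_ba)),
    stringsAsFactors = FALSE
  )

  ramps <- NULL
  if (include_ramps) {
    v <- ramp_voltages()
    ramp_list <- vector("list", n * 3L)
    k <- 0L
    for (i in seq_len(n)) {
      for (sol in solutions) {
        r <- synth_ramp(kir_mag[i], leak[i], config$endogenous_outward_mean,
                        sol, v)
        k <- k + 1L
        ramp_list[[k]] <- data.frame(
          batch_id = design$batch_id[i], oocyte_id = design$oocyte_id[i],
          solution = sol, voltage_mV = r$voltage_mV,
          current_uA = r$current_uA, stringsAsFactors = FALSE)
      }
    }
    ramps <- do.call(rbind, ramp_list)
    rownames(ramps) <- NULL
  }

  truth <- list(
    seed = config$seed,
    config = config_to_list(config),
    truth_model = unclass(config$truth_model),
    scales = data.frame(
      batch_id = design$batch_id, oocyte_id = design$oocyte_id,
      batch_scale = unname(batch_scale[design$batch_id]),
      expression_scale = expression_scale, leak_uA = leak, leaky = leaky,
      stringsAsFactors = FALSE)
  )

  structure(list(design = design, measurements = measurements, ramps = ramps,
                 truth = truth),
            class = "oocyte_dataset")
}

#' @export
print.oocyte_dataset <- function(x, ...) {
  cat(sprintf(
    "<oocyte_dataset: %d oocytes, %d batches, p in {%s}%s>\n",
    nrow(x$design), length(unique(x$design$batch_id)),
    paste(sort(unique(x$design$wt_fraction), decreasing = TRUE),
          collapse = ", "),
    if (is.null(x$ramps)) ", no ramps" else ""))
  invisible(x)
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$truth_model <- unclass(config$truth_model)
  out
}

config_from_list <- function(lst) {
  tm <- lst$truth_model
  model <- stoich_model(tm$rule,
                        n_required = if (is.null(tm$n_required) ||
                                         is.na(tm$n_required)) 4L
                                     else tm$n_required,
                        n_subunits = tm$n_subunits, residual = tm$residual)
  sim_config(
    n_batches = lst$n_batches, oocytes_per_group = lst$oocytes_per_group,
    wt_fractions = lst$wt_fractions, truth_model = model,
    wt_only_mean_current = lst$wt_only_mean_current,
    expression_cv = lst$expression_cv, batch_scale_cv = lst$batch_scale_cv,
    leak_mean = lst$leak_mean, leak_cv = lst$leak_cv,
    endogenous_outward_mean = lst$endogenous_outward_mean,
    leaky_fraction = lst$leaky_fraction, rna_ng_total = lst$rna_ng_total,
    seed = lst$seed)
}

# Full-precision numeric formatting so CSVs round-trip losslessly.
fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  gsub(" ", "", out, fixed = TRUE)
}

write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `measurements.csv`, `ramps.csv`, `design.csv` and `truth.json` into
#' `out_dir`. Numeric columns are written at full double precision so that
#' [read_dataset()] round-trips every value exactly, and `truth.json` records
#' the seed and configuration so the dataset can be regenerated
#' byte-identically.
#'
#' @param dataset An `oocyte_dataset` from [simulate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "oocyte_dataset"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- file.path(out_dir,
                     c("measurements.csv", "ramps.csv", "design.csv",
                       "truth.json"))
  names(paths) <- c("measurements", "ramps", "design", "truth")
  write_csv_precise(dataset$measurements, paths["measurements"])
  ramps <- dataset$ramps
  if (is.null(ramps))
    ramps <- data.frame(batch_id = character(), oocyte_id = character(),
                        solution = character(), voltage_mV = double(),
                        current_uA = double(), stringsAsFactors = FALSE)
  write_csv_precise(ramps, paths["ramps"])
  write_csv_precise(dataset$design, paths["design"])
  jsonlite::write_json(dataset$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `measurements.csv`, `ramps.csv`,
#'   `design.csv` and optionally `truth.json`.
#' @return An `oocyte_dataset`; `truth` is NULL when `truth.json` is absent
#'   (as for real recordings).
#' @export
read_dataset <- function(dir) {
  req <- file.path(dir, c("measurements.csv", "ramps.csv", "design.csv"))
  missing <- req[!file.exists(req)]
  if (length(missing))
    stop("missing dataset files: ", paste(missing, collapse = ", "),
         call. = FALSE)
  measurements <- utils::read.csv(req[1], stringsAsFactors = FALSE,
                                  colClasses = c(solution = "character"))
  ramps <- utils::read.csv(req[2], stringsAsFactors = FALSE)
  if (nrow(ramps) == 0L) ramps <- NULL
  design <- utils::read.csv(req[3], stringsAsFactors = FALSE)
  truth <- NULL
  tpath <- file.path(dir, "truth.json")
  if (file.exists(tpath)) {
    truth <- jsonlite::read_json(tpath, simplifyVector = TRUE)
    truth$scales <- as.data.frame(truth$scales, stringsAsFactors = FALSE)
  }
  structure(list(design = design, measurements = measurements, ramps = ramps,
                 truth = truth),
            class = "oocyte_dataset")
}
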