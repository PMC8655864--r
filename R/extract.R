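#' Kir-specific current at -50 mV
#'
#' The inward-rectifier current is isolated as the difference between the
#' steady current in the high-K+ bath and the current in the low-K+ bath at
#' the -50 mV holding potential. Leak and other K+-independent components
#' cancel in the difference; the result is negative (inward) for a
#' functional Kir channel in high external K+.
#'
#' @param m A data.frame with numeric columns `i_low_k` and `i_high_k`
#'   (signed currents in uA at -50 mV), one row per oocyte.
#' @return Signed Kir-specific currents (uA), one per row.
#' @export
kir_current <- function(m) {
  if (!all(c("i_low_k", "i_high_k") %in% names(m)))
    stop("'m' must have columns 'i_low_k' and 'i_high_k'", call. = FALSE)
  if (anyNA(m$i_low_k) || anyNA(m$i_high_k) ||
      any(!is.finite(m$i_low_k)) || any(!is.finite(m$i_high_k)))
    stop("solution currents must be finite", call. = FALSE)
  m$i_high_k - m$i_low_k
}

#' Fraction of the Kir-specific current blocked by Ba2+
#'
#' Barium occludes Kir channels, so the Ba2+-sensitive share of the
#' high-K+ minus low-K+ difference current,
#' `(i_high_k - i_ba) / (i_high_k - i_low_k)` clipped to \[0, 1\],
#' verifies that the extracted current is Kir-specific: 1 means a complete
#' block, 0 no block. Oocytes with no Kir current (zero denominator) return
#' `NA` rather than erroring; they are flagged downstream, not excluded.
#'
#' @param m A data.frame with numeric columns `i_low_k`, `i_high_k`, `i_ba`.
#' @return Fractions in \[0, 1\] (`NA` where the Kir current is zero).
#' @export
ba_sensitive_fraction <- function(m) {
  if (!all(c("i_low_k", "i_high_k", "i_ba") %in% names(m)))
    stop("'m' must have columns 'i_low_k', 'i_high_k' and 'i_ba'",
         call. = FALSE)
  denom <- m$i_high_k - m$i_low_k
  out <- ifelse(denom == 0, NA_real_, (m$i_high_k - m$i_ba) / denom)
  pmin(pmax(out, 0), 1)
}

#' Leak quality control from voltage ramps
#'
#' An oocyte is "too leaky" when any ramp, in any solution, shows an outward
#' (positive) current exceeding 1 uA at positive potentials. The threshold is
#' strict: exactly 1 uA passes.
#'
#' @param ramps A data.frame of ramp samples with columns `voltage_mV` and
#'   `current_uA` (rows from all solutions may be pooled).
#' @param threshold_uA Outward-current threshold (uA), default 1.
#' @return TRUE if leaky.
#' @export
leak_qc <- function(ramps, threshold_uA = 1) {
  if (is.null(ramps) || nrow(ramps) == 0L)
    stop("no ramp samples supplied", call. = FALSE)
  pos <- ramps$voltage_mV > 0
  any(pos & ramps$current_uA > threshold_uA)
}

#' Inward-rectification check on the Ba2+-sensitive component
#'
#' Verifies that the current removed by Ba2+ behaves like a Kir channel:
#' subtracting the Ba2+ ramp from the high-K+ ramp pointwise (interpolating
#' the Ba2+ ramp onto the high-K+ voltage grid) cancels leak and the
#' Ba2+-insensitive endogenous outward currents, leaving the Kir component.
#' The oocyte passes when the inward Ba2+-sensitive current at -50 mV exceeds
#' `r_min` times the Ba2+-sensitive outward current at +50 mV, or when the
#' outward component sits below the noise floor — the latter lets
#' zero-expression oocytes (e.g. pure loss-of-function mutant groups) pass
#' vacuously rather than be excluded for producing no current.
#'
#' @param ramp_high_k,ramp_ba Data.frames with columns `voltage_mV`,
#'   `current_uA` for the high-K+ and Ba2+ ramps.
#' @param r_min Required inward/outward ratio at -50/+50 mV (default 5).
#' @param noise_floor_uA Currents below this magnitude (uA) are treated as
#'   noise (default 0.05).
#' @return Logical flag, with the decision rationale in `attr(, "reason")`.
#' @export
rectification_check <- function(ramp_high_k, ramp_ba, r_min = 5,
                                noise_floor_uA = 0.05) {
  for (r in list(ramp_high_k, ramp_ba)) {
    if (is.null(r) || nrow(r) < 2L)
      stop("both high-K+ and Ba2+ ramps with >= 2 samples are required",
           call. = FALSE)
  }
  v <- ramp_high_k$voltage_mV
  ba_on_grid <- stats::approx(ramp_ba$voltage_mV, ramp_ba$current_uA,
                              xout = v, ties = mean)$y
  if (anyNA(ba_on_grid))
    stop("Ba2+ ramp does not cover the high-K+ voltage grid; ",
         "cannot interpolate", call. = FALSE)
  ba_sens <- ramp_high_k$current_uA - ba_on_grid
  at_m50 <- ba_sens[which.min(abs(v - (-50)))]
  at_p50 <- ba_sens[which.min(abs(v - 50))]
  if (min(abs(v + 50)) > 1 || min(abs(v - 50)) > 1)
    stop("ramp grid must cover -50 and +50 mV within 1 mV", call. = FALSE)
  outward <- max(at_p50, 0)
  if (outward <= noise_floor_uA) {
    flag <- TRUE
    attr(flag, "reason") <- "Ba-sensitive outward component below noise floor"
  } else {
    flag <- abs(at_m50) > r_min * outward
    attr(flag, "reason") <- sprintf(
      "inward/outward ratio %.3g %s threshold %g",
      abs(at_m50) / outward, if (flag) ">" else "<=", r_min)
  }
  flag
}

solution_levels <- c("low_k", "high_k", "ba")

# Pivot long measurements to one row per oocyte with one current per
# solution; errors name the offending oocyte and solution.
measurements_to_wide <- function(measurements) {
  req <- c("batch_id", "oocyte_id", "wt_fraction", "solution", "current_uA")
  miss <- setdiff(req, names(measurements))
  if (length(miss))
    stop("measurements table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- !measurements$solution %in% solution_levels
  if (any(bad))
    stop("unknown solution label(s) in measurements rows ",
         paste(utils::head(which(bad), 5), collapse = ", "), ": ",
         paste(unique(measurements$solution[bad]), collapse = ", "),
         call. = FALSE)
  dup <- duplicated(measurements[, c("oocyte_id", "solution")])
  if (any(dup))
    stop("duplicate (oocyte, solution) measurements: ",
         paste(utils::head(unique(measurements$oocyte_id[dup]), 5),
               collapse = ", "), call. = FALSE)
  ids <- unique(measurements$oocyte_id)
  wide <- data.frame(
    oocyte_id = ids,
    batch_id = measurements$batch_id[match(ids, measurements$oocyte_id)],
    wt_fraction = measurements$wt_fraction[match(ids,
                                                 measurements$oocyte_id)],
    stringsAsFactors = FALSE)
  cols <- c(low_k = "i_low_k", high_k = "i_high_k", ba = "i_ba")
  for (sol in solution_levels) {
    sel <- measurements$solution == sol
    idx <- match(wide$oocyte_id, measurements$oocyte_id[sel])
    if (anyNA(idx))
      stop("oocyte(s) missing a '", sol, "' measurement: ",
           paste(utils::head(wide$oocyte_id[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    wide[[cols[[sol]]]] <- measurements$current_uA[sel][idx]
  }
  wide
}

#' Reduce measurements and ramps to QC-annotated Kir currents per oocyte
#'
#' Runs the full per-oocyte reduction: the high-K+ minus low-K+ difference
#' current, the Ba2+-sensitive fraction, leak QC on the ramps, and the
#' rectification check on the Ba2+-sensitive ramp component. An oocyte is
#' included when it is not leaky and its Ba2+-sensitive component rectifies.
#' Oocytes without ramps are retained with a warning — the -50 mV three-bath
#' protocol alone determines the difference current; the ramps are a
#' verification step.
#'
#' @param measurements Long table (or path semantics via [run_fit()]) with
#'   columns `batch_id, oocyte_id, wt_fraction, solution, current_uA`,
#'   `solution` in `low_k`/`high_k`/`ba`, one row per oocyte and solution.
#' @param ramps Optional long ramp table with columns
#'   `oocyte_id, solution, voltage_mV, current_uA`. NULL skips ramp QC.
#' @param leak_threshold_uA Leak QC threshold, see [leak_qc()].
#' @param r_min,noise_floor_uA Rectification parameters, see
#'   [rectification_check()].
#' @return A data.frame, one row per oocyte, with columns `batch_id,
#'   oocyte_id, wt_fraction, kir_current, ba_fraction, leaky, rectifying,
#'   included, reasons`, plus an attribute `qc_counts` tallying exclusions.
#' @export
extract_all <- function(measurements, ramps = NULL, leak_threshold_uA = 1,
                        r_min = 5, noise_floor_uA = 0.05) {
  wide <- measurements_to_wide(measurements)
  n <- nrow(wide)
  out <- wide[, c("batch_id", "oocyte_id", "wt_fraction")]
  out$kir_current <- kir_current(wide)
  out$ba_fraction <- ba_sensitive_fraction(wide)

  leaky <- rep(NA, n)
  rectifying <- rep(NA, n)
  reasons <- character(n)
  if (!is.null(ramps) && nrow(ramps) > 0L) {
    orphan <- setdiff(unique(ramps$oocyte_id), wide$oocyte_id)
    if (length(orphan))
      stop("ramps reference unknown oocyte(s): ",
           paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
    bad_sol <- !ramps$solution %in% solution_levels
    if (any(bad_sol))
      stop("unknown solution label(s) in ramps: ",
           paste(unique(ramps$solution[bad_sol]), collapse = ", "),
           call. = FALSE)
    ramp_split <- split(ramps, ramps$oocyte_id)
    no_ramp <- setdiff(wide$oocyte_id, names(ramp_split))
    if (length(no_ramp))
      warning(length(no_ramp), " oocyte(s) have no ramps; leak/rectification",
              " QC not assessable, retained", call. = FALSE)
    for (i in seq_len(n)) {
      rs <- ramp_split[[wide$oocyte_id[i]]]
      if (is.null(rs)) {
        reasons[i] <- "QC not assessable: no ramps"
        next
      }
      leaky[i] <- leak_qc(rs, leak_threshold_uA)
      hk <- rs[rs$solution == "high_k", ]
      ba <- rs[rs$solution == "ba", ]
      if (nrow(hk) >= 2L && nrow(ba) >= 2L) {
        rc <- rectification_check(hk, ba, r_min, noise_floor_uA)
        rectifying[i] <- as.logical(rc)
        if (!rectifying[i])
          reasons[i] <- paste0("not rectifying (", attr(rc, "reason"), ")")
      } else {
        reasons[i] <- "rectification not assessable: high_k/ba ramp missing"
      }
      if (isTRUE(leaky[i]))
        reasons[i] <- trimws(paste("leaky: outward ramp current >",
                                   leak_threshold_uA, "uA;", reasons[i]))
    }
  } else {
    warning("no ramps supplied; leak/rectification QC not assessable, ",
            "all oocytes retained", call. = FALSE)
    reasons[] <- "QC not assessable: no ramps"
  }

  out$leaky <- leaky
  out$rectifying <- rectifying
  # missing QC information retains the oocyte (verification, not gate)
  out$included <- !(leaky %in% TRUE) & !(rectifying %in% FALSE)
  out$reasons <- reasons

  counts <- c(total = n, included = sum(out$included),
              leaky = sum(leaky %in% TRUE),
              not_rectifying = sum(rectifying %in% FALSE),
              qc_not_assessable = sum(is.na(leaky)))
  attr(out, "qc_counts") <- counts
  if (counts["included"] == 0L)
    warning("no oocytes passed QC", call. = FALSE)
  out
}
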