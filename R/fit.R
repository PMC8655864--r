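as_points <- function(points) {
  if (!is.data.frame(points) || !all(c("p", "y") %in% names(points)))
    stop("'points' must be a data.frame with columns 'p' and 'y'",
         call. = FALSE)
  if (nrow(points) == 0L) stop("no data points", call. = FALSE)
  check_p(points$p)
  if (anyNA(points$y) || any(points$y < 0))
    stop("'y' must be non-negative normalized current magnitudes",
         call. = FALSE)
  points
}

fit_weights <- function(points, weights) {
  if (is.null(weights) || identical(weights, "none")) return(NULL)
  if (identical(weights, "inv_sem2")) {
    if (is.null(points$sem) || any(points$sem <= 0))
      stop("'inv_sem2' weighting needs positive 'sem' for every point",
           call. = FALSE)
    return(1 / points$sem^2)
  }
  if (is.numeric(weights) && length(weights) == nrow(points) &&
      all(weights > 0)) return(weights)
  stop("'weights' must be NULL, \"none\", \"inv_sem2\" or positive numbers",
       call. = FALSE)
}

#' Root-mean-square deviation of data from a model curve
#'
#' \eqn{\sqrt{\mathrm{mean}_i (y_i - \hat y(p_i))^2}} between observed
#' normalized currents and the curve predicted by a stoichiometry rule.
#' Unweighted by default; optional `1/sem^2` weighting.
#'
#' @param points Data.frame with columns `p`, `y` (and `sem` if weighting).
#' @param model A [stoich_model()].
#' @param weights NULL/"none" (default), "inv_sem2", or a positive numeric
#'   vector, one per point.
#' @return The (weighted) RMSD, dimensionless.
#' @export
rmsd <- function(points, model, weights = NULL) {
  points <- as_points(points)
  resid <- points$y - predicted_current(points$p, model)
  w <- fit_weights(points, weights)
  if (is.null(w)) sqrt(mean(resid^2)) else sqrt(sum(w * resid^2) / sum(w))
}

#' Percent deviation of data from a model curve
#'
#' The RMSD expressed as a percentage of the overall scale of the data,
#' `100 * rmsd / normalizer(y)`. The default normalizer is the root mean
#' square of the observed values, which makes the quantity scale-free and
#' equal to `100 * rmsd` when the data are normalized so the largest value is
#' near 1; `"mean"` and `"max"` are available since the field's convention is
#' not fixed.
#'
#' @inheritParams rmsd
#' @param normalizer `"rms"` (default), `"mean"` or `"max"` of the `y`
#'   values.
#' @return Percent deviation (>= 0; 0 iff the fit is perfect).
#' @export
percent_deviation <- function(points, model,
                              normalizer = c("rms", "mean", "max"),
                              weights = NULL) {
  points <- as_points(points)
  normalizer <- match.arg(normalizer)
  scale <- switch(normalizer,
                  rms = sqrt(mean(points$y^2)),
                  mean = mean(points$y),
                  max = max(points$y))
  if (!is.finite(scale) || scale <= 0)
    stop("percent deviation normalizer undefined: data are all zero",
         call. = FALSE)
  100 * rmsd(points, model, weights) / scale
}

#' Fit the mutant residual activity of a stoichiometry rule
#'
#' Bounded one-dimensional least squares: minimizes the RMSD over the mutant
#' residual activity r in \[0, 1\] while keeping the assembly rule fixed.
#' The bounds and the r = 0 endpoint are checked explicitly so a boundary
#' optimum is returned exactly.
#'
#' @inheritParams rmsd
#' @param tol Convergence tolerance on r passed to [stats::optimize()].
#' @return A list with elements `r` (the argmin), `rmsd` (objective at the
#'   optimum, never exceeding the r = 0 RMSD) and `model` (the input model
#'   with `residual` set to the fit).
#' @export
fit_residual <- function(points, model, weights = NULL, tol = 1e-9) {
  points <- as_points(points)
  stopifnot(inherits(model, "stoich_model"))
  if (nrow(points) < 2L)
    stop("residual fitting needs at least 2 points", call. = FALSE)
  with_r <- function(r) {
    m <- model
    m$residual <- r
    m
  }
  objective <- function(r) rmsd(points, with_r(r), weights)
  opt <- stats::optimize(objective, interval = c(0, 1), tol = tol)
  # candidate set includes both bounds so boundary optima are exact
  cand_r <- c(opt$minimum, 0, 1)
  cand_f <- c(opt$objective, objective(0), objective(1))
  best <- which.min(cand_f)
  list(r = cand_r[best], rmsd = cand_f[best], model = with_r(cand_r[best]))
}

#' Rank candidate stoichiometry models against normalized-current data
#'
#' Computes RMSD and percent deviation of the data from each candidate
#' model's predicted curve and ranks candidates by ascending percent
#' deviation. Ties are broken deterministically: fewer fitted parameters
#' first, then lexicographic model label. Rank 1 is the best-supported rule.
#'
#' @inheritParams percent_deviation
#' @param candidates List of [stoich_model()] objects
#'   (default [default_candidates()]). Order does not affect the ranking.
#' @param fit_r Also fit the mutant residual activity of each candidate
#'   ([fit_residual()]); the fitted model then carries one free parameter in
#'   the tie-break.
#' @return A data.frame of fit results ordered by rank, with columns
#'   `rank, label, rule, n_required, n_subunits, residual, n_free, rmsd,
#'   percent_deviation, n_points`; the ranked models are attached as
#'   attribute `models`.
#' @export
rank_models <- function(points, candidates = default_candidates(),
                        normalizer = "rms", weights = NULL, fit_r = FALSE) {
  points <- as_points(points)
  if (!is.list(candidates) || length(candidates) < 1L ||
      !all(vapply(candidates, inherits, logical(1), "stoich_model")))
    stop("'candidates' must be a non-empty list of stoich_model objects",
         call. = FALSE)
  rows <- vector("list", length(candidates))
  models <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    m <- candidates[[i]]
    n_free <- 0L
    if (fit_r) {
      fr <- fit_residual(points, m, weights)
      m <- fr$model
      n_free <- 1L
    }
    rows[[i]] <- data.frame(
      label = model_label(m), rule = m$rule, n_required = m$n_required,
      n_subunits = m$n_subunits, residual = m$residual, n_free = n_free,
      rmsd = rmsd(points, m, weights),
      percent_deviation = percent_deviation(points, m, normalizer, weights),
      n_points = nrow(points), stringsAsFactors = FALSE)
    models[[i]] <- m
  }
  res <- do.call(rbind, rows)
  ord <- order(res$percent_deviation, res$n_free, res$label)
  res <- res[ord, , drop = FALSE]
  res <- cbind(rank = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  attr(res, "models") <- models[ord]
  res
}

#' Infer how many mutant subunits disable a tetrameric channel
#'
#' The package's central fit: given batch-normalized current means at several
#' injected WT subunit fractions, ranks the binomial subunit-assembly model
#' family (exactly-n WT, at-least-n WT, no co-assembly) by percent deviation
#' from the data. With the default tetramer candidates, a rank-1 `exactly_4`
#' means a single mutant subunit suffices to silence the channel — the
#' dominant-negative mechanism.
#'
#' @param points A data.frame of normalized points with columns `p` (WT
#'   subunit fraction), `y` (mean normalized current) and optionally `sem`,
#'   `n`, e.g. from [to_points()]; or an [extract_all()] table, in which case
#'   [normalize_by_batch()] is applied first.
#' @inheritParams rank_models
#' @return An object of class `stoich_fit` with components `points`,
#'   `results` (the ranked table from [rank_models()]), `models` (ranked
#'   model objects), `best` (the rank-1 model), `normalizer`, `weights` and
#'   `call`. Supports `print`, `summary`, `coef`, `predict`, `residuals` and
#'   `plot`.
#' @examples
#' # the dominant-negative signature: current collapses far below the
#' # no-mixing diagonal as mutant subunits are mixed in
#' pts <- data.frame(p = c(1, 0.8, 0.5, 0), y = c(1, 0.40, 0.05, 0))
#' fit <- fit_stoichiometry(pts)
#' fit$results$label[1]   # "exactly_4"
#' @export
fit_stoichiometry <- function(points, candidates = default_candidates(),
                              normalizer = "rms", weights = NULL,
                              fit_r = FALSE) {
  if (is.data.frame(points) && "kir_current" %in% names(points))
    points <- to_points(normalize_by_batch(points))
  points <- as_points(points)
  res <- rank_models(points, candidates, normalizer, weights, fit_r)
  models <- attr(res, "models")
  structure(
    list(points = points, results = res, models = models,
         best = models[[1]], normalizer = normalizer, weights = weights,
         call = match.call()),
    class = "stoich_fit")
}

#' @export
print.stoich_fit <- function(x, digits = 4, ...) {
  cat("Subunit stoichiometry model ranking (",
      x$best$n_subunits, "-mer channel)\n", sep = "")
  cat(sprintf("Best model: %s (percent deviation %.3g%%)\n\n",
              model_label(x$best), x$results$percent_deviation[1]))
  print(format(x$results[, c("rank", "label", "rmsd", "percent_deviation",
                             "residual")], digits = digits),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.stoich_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.stoich_fit")
}

#' @export
print.summary.stoich_fit <- function(x, digits = 4, ...) {
  fit <- x$fit
  print(fit, digits = digits)
  cat("\nData points (normalized current vs WT fraction):\n")
  print(format(fit$points, digits = digits), row.names = FALSE)
  cat("\nResiduals from the best model:\n")
  print(signif(residuals(fit), digits))
  cat("\nPercent-deviation normalizer:", fit$normalizer, "\n")
  invisible(x)
}

#' @export
coef.stoich_fit <- function(object, ...) {
  b <- object$best
  c(n_subunits = b$n_subunits,
    n_required = if (is.na(b$n_required)) NA_real_ else b$n_required,
    residual = b$residual)
}

#' Predicted normalized currents from a stoichiometry fit
#'
#' @param object A `stoich_fit`.
#' @param newdata Optional data.frame with column `p` (or a numeric vector of
#'   WT fractions); defaults to the fitted points.
#' @param model `"best"` (default) for the rank-1 model, or a model label
#'   from the results table.
#' @param ... Unused.
#' @return Predicted normalized currents.
#' @export
predict.stoich_fit <- function(object, newdata = NULL, model = "best", ...) {
  p <- if (is.null(newdata)) object$points$p
       else if (is.numeric(newdata)) newdata
       else newdata$p
  m <- if (identical(model, "best")) object$best else {
    idx <- match(model, object$results$label)
    if (is.na(idx)) stop("unknown model label: ", model, call. = FALSE)
    object$models[[idx]]
  }
  predicted_current(p, m)
}

#' @export
residuals.stoich_fit <- function(object, ...) {
  r <- object$points$y - predict(object)
  names(r) <- paste0("p=", object$points$p)
  r
}

#' Plot a stoichiometry fit
#'
#' Normalized-current data (mean +/- s.e.m.) against the WT subunit fraction,
#' overlaid with every candidate model curve; the best model is drawn bold.
#'
#' @param x A `stoich_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.stoich_fit <- function(x, ...) {
  grid <- seq(0, 1, by = 0.01)
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1.05),
                 xlab = "WT subunit fraction p",
                 ylab = "normalized current", ...)
  cols <- seq_along(x$models) + 1L
  for (i in rev(seq_along(x$models))) {
    graphics::lines(grid, predicted_current(grid, x$models[[i]]),
                    col = cols[i], lwd = if (i == 1L) 3 else 1,
                    lty = if (x$models[[i]]$rule == "no_mixing") 3 else 1)
  }
  graphics::points(x$points$p, x$points$y, pch = 19)
  if (!is.null(x$points$sem))
    graphics::arrows(x$points$p, x$points$y - x$points$sem,
                     x$points$p, x$points$y + x$points$sem,
                     angle = 90, code = 3, length = 0.03)
  graphics::legend("topleft", legend = x$results$label, col = cols,
                   lwd = c(3, rep(1, length(cols) - 1L)), bty = "n",
                   cex = 0.8)
  invisible(x)
}

#' Bootstrap model-selection frequencies
#'
#' Resamples oocytes with replacement within each (batch, WT fraction) cell —
#' respecting the batch-normalization structure, since resampling across
#' batches would mix normalization denominators — then reruns normalization
#' and model ranking, and reports the fraction of replicates in which each
#' candidate ranks first. Replicates whose resampled normalization fails
#' (e.g. a batch losing all usable WT controls) are skipped and counted.
#'
#' @param extracted Per-oocyte table from [extract_all()].
#' @inheritParams rank_models
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed; frequencies are deterministic given it.
#' @return A data.frame with columns `label` and `freq_rank1`, sorted by
#'   descending frequency; skipped-replicate count in attribute `skipped`.
#' @export
bootstrap_ranking <- function(extracted, candidates = default_candidates(),
                              B = 200L, seed = 1L, normalizer = "rms",
                              weights = NULL, fit_r = FALSE) {
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("'B' must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  keep <- extracted[extracted$included %in% TRUE, , drop = FALSE]
  if (nrow(keep) == 0L) stop("no QC-passed oocytes", call. = FALSE)
  cells <- split(seq_len(nrow(keep)),
                 paste(keep$batch_id, keep$wt_fraction, sep = "\r"))
  labels <- vapply(candidates, model_label, character(1))
  wins <- stats::setNames(numeric(length(labels)), labels)
  skipped <- 0L
  for (b in seq_len(B)) {
    idx <- unlist(lapply(cells, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]),
      use.names = FALSE)
    rep_tab <- keep[idx, , drop = FALSE]
    winner <- tryCatch({
      pts <- to_points(suppressWarnings(normalize_by_batch(rep_tab)))
      rank_models(pts, candidates, normalizer, weights, fit_r)$label[1]
    }, error = function(e) NA_character_)
    if (is.na(winner)) skipped <- skipped + 1L else
      wins[winner] <- wins[winner] + 1
  }
  used <- B - skipped
  if (skipped > 0.1 * B)
    warning(skipped, " of ", B, " bootstrap replicates skipped",
            call. = FALSE)
  out <- data.frame(label = names(wins),
                    freq_rank1 = if (used > 0) unname(wins) / used
                                 else rep(NA_real_, length(wins)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$freq_rank1, out$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
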