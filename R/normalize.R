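#' Batch-anchored normalization of Kir currents
#'
#' Oocyte batches vary strongly in expression level, so raw current
#' magnitudes are comparable only within a batch. Each QC-passed oocyte's
#' Kir-current magnitude is divided by the mean magnitude of the WT-only
#' (p = 1) oocytes of its own batch; normalized values are then pooled across
#' batches per injected WT fraction, and summarized as mean +/- s.e.m.
#' (sample SD divided by sqrt(n)). Normalizing per oocyte, rather than
#' normalizing group means after the fact, preserves per-oocyte dispersion
#' for the s.e.m. and for bootstrap resampling.
#'
#' Batches lacking a QC-passed WT-only control cannot be anchored: all their
#' oocytes are dropped with a logged reason. If no batch has WT controls the
#' function errors.
#'
#' @param extracted Per-oocyte table from [extract_all()] (columns
#'   `batch_id, oocyte_id, wt_fraction, kir_current, included`).
#' @return A data.frame of group summaries, one row per WT fraction, with
#'   columns `wt_fraction, n_oocytes, mean_current, sem_current,
#'   mean_normalized, sem_normalized, batches_used`, sorted by descending
#'   `wt_fraction`. The per-oocyte normalized values are attached as
#'   attribute `oocytes`; batches dropped for missing WT controls as
#'   attribute `dropped_batches`.
#' @export
normalize_by_batch <- function(extracted) {
  req <- c("batch_id", "wt_fraction", "kir_current", "included")
  miss <- setdiff(req, names(extracted))
  if (length(miss))
    stop("extracted table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  keep <- extracted[extracted$included %in% TRUE, , drop = FALSE]
  if (nrow(keep) == 0L)
    stop("no QC-passed oocytes to normalize", call. = FALSE)
  keep$magnitude <- abs(keep$kir_current)

  wt_rows <- keep[keep$wt_fraction == 1, , drop = FALSE]
  wt_mean <- tapply(wt_rows$magnitude, wt_rows$batch_id, mean)
  batches <- unique(keep$batch_id)
  anchored <- batches[batches %in% names(wt_mean) &
                        !is.na(wt_mean[batches]) & wt_mean[batches] > 0]
  dropped <- setdiff(batches, anchored)
  if (length(anchored) == 0L)
    stop("no batch contains a usable WT-only (p = 1) control group",
         call. = FALSE)
  if (length(dropped))
    warning("batch(es) without WT-only controls dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  keep <- keep[keep$batch_id %in% anchored, , drop = FALSE]
  keep$normalized <- keep$magnitude / unname(wt_mean[keep$batch_id])

  groups <- lapply(split(keep, keep$wt_fraction), function(g) {
    n <- nrow(g)
    data.frame(
      wt_fraction = g$wt_fraction[1],
      n_oocytes = n,
      mean_current = mean(g$magnitude),
      sem_current = if (n > 1) stats::sd(g$magnitude) / sqrt(n) else 0,
      mean_normalized = mean(g$normalized),
      sem_normalized = if (n > 1) stats::sd(g$normalized) / sqrt(n) else 0,
      batches_used = paste(sort(unique(g$batch_id)), collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, groups)
  out <- out[order(-out$wt_fraction), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "oocytes") <- keep
  attr(out, "dropped_batches") <- dropped
  out
}

#' Convert group summaries to model-fitting points
#'
#' @param summaries Group summaries from [normalize_by_batch()] (or any
#'   data.frame with columns `wt_fraction, mean_normalized, sem_normalized,
#'   n_oocytes`).
#' @return A data.frame with columns `p, y, sem, n` sorted by descending `p`
#'   — the input to [fit_stoichiometry()]. Duplicate `p` values are merged by
#'   oocyte-weighted pooled mean with a warning.
#' @export
to_points <- function(summaries) {
  if (is.null(summaries) || nrow(summaries) == 0L)
    stop("no group summaries to convert", call. = FALSE)
  pts <- data.frame(p = summaries$wt_fraction,
                    y = summaries$mean_normalized,
                    sem = summaries$sem_normalized,
                    n = summaries$n_oocytes)
  if (anyDuplicated(pts$p)) {
    warning("duplicate WT fractions merged by pooled mean", call. = FALSE)
    merged <- lapply(split(pts, pts$p), function(g) {
      ntot <- sum(g$n)
      data.frame(p = g$p[1],
                 y = sum(g$y * g$n) / ntot,
                 sem = sqrt(sum((g$sem * g$n)^2)) / ntot,
                 n = ntot)
    })
    pts <- do.call(rbind, merged)
  }
  pts <- pts[order(-pts$p), , drop = FALSE]
  rownames(pts) <- NULL
  pts
}
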