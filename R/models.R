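#' Candidate stoichiometry rules for a multimeric channel
#'
#' A `stoich_model` encodes one hypothesis about how many wild-type (WT)
#' subunits a channel of `n_subunits` randomly co-assembled subunits needs in
#' order to conduct. Channels meeting the rule conduct at full unitary
#' activity (1); channels failing it conduct at the mutant residual activity
#' `residual` (0 for a complete loss-of-function mutant). The `no_mixing`
#' rule is the null hypothesis that WT and mutant subunits never co-assemble,
#' so normalized current is simply the injected WT fraction.
#'
#' @param rule One of `"exactly_n"` (channel functional only with exactly
#'   `n_required` WT subunits), `"at_least_n"` (functional with `n_required`
#'   or more), or `"no_mixing"` (WT and mutant subunits form separate
#'   homotetramers; `n_required` is ignored).
#' @param n_required Number of WT subunits required by the rule
#'   (1..`n_subunits`). With the default tetramer, `exactly_n` with
#'   `n_required = 4` is the dominant-negative hypothesis that a single
#'   mutant subunit silences the whole channel.
#' @param n_subunits Subunits per channel; 4 for Kir2.1 tetramers.
#' @param residual Activity of channels failing the WT rule, a fraction of
#'   full activity in \[0, 1\]. Default 0 (complete loss of function).
#' @return An object of class `stoich_model`.
#' @examples
#' stoich_model("exactly_n", 4)           # dominant-negative tetramer rule
#' stoich_model("at_least_n", 1)          # one WT subunit rescues the channel
#' stoich_model("no_mixing")              # independent homotetramer pools
#' @export
stoich_model <- function(rule = c("exactly_n", "at_least_n", "no_mixing"),
                         n_required = 4L, n_subunits = 4L, residual = 0) {
  rule <- match.arg(rule)
  n_subunits <- as.integer(n_subunits)
  if (length(n_subunits) != 1L || is.na(n_subunits) || n_subunits < 1L)
    stop("'n_subunits' must be a single integer >= 1", call. = FALSE)
  if (rule != "no_mixing") {
    n_required <- as.integer(n_required)
    if (length(n_required) != 1L || is.na(n_required) ||
        n_required < 1L || n_required > n_subunits)
      stop("'n_required' must be in 1..n_subunits for rule '", rule, "'",
           call. = FALSE)
  } else {
    n_required <- NA_integer_
  }
  if (!is.numeric(residual) || length(residual) != 1L || is.na(residual) ||
      residual < 0 || residual > 1)
    stop("'residual' must be a single value in [0, 1]", call. = FALSE)
  structure(
    list(rule = rule, n_required = n_required, n_subunits = n_subunits,
         residual = as.numeric(residual)),
    class = "stoich_model"
  )
}

#' @export
print.stoich_model <- function(x, ...) {
  desc <- switch(x$rule,
    exactly_n  = sprintf("functional iff exactly %d of %d subunits are WT",
                         x$n_required, x$n_subunits),
    at_least_n = sprintf("functional iff at least %d of %d subunits are WT",
                         x$n_required, x$n_subunits),
    no_mixing  = "WT and mutant subunits do not co-assemble")
  cat(sprintf("<stoich_model %s: %s; mutant residual activity %g>\n",
              model_label(x), desc, x$residual))
  invisible(x)
}

#' Short label for a stoichiometry model
#'
#' @param model A [stoich_model()].
#' @return A string such as `"exactly_4"`, `"at_least_2"` or `"no_mixing"`.
#' @export
model_label <- function(model) {
  stopifnot(inherits(model, "stoich_model"))
  switch(model$rule,
    exactly_n  = sprintf("exactly_%d", model$n_required),
    at_least_n = sprintf("at_least_%d", model$n_required),
    no_mixing  = "no_mixing")
}

#' Default candidate model set for a tetramer
#'
#' The five hypotheses compared against co-expression data: the
#' dominant-negative rule (all four subunits WT), the three at-least-n rules
#' for n = 3, 2, 1, and the no-co-assembly null. All with zero mutant
#' residual activity.
#'
#' @param n_subunits Subunits per channel (default 4).
#' @param residual Mutant residual activity shared by all candidates.
#' @return A named list of [stoich_model()] objects.
#' @export
default_candidates <- function(n_subunits = 4L, residual = 0) {
  N <- as.integer(n_subunits)
  cands <- c(
    list(stoich_model("exactly_n", N, N, residual)),
    lapply(seq(N - 1L, 1L), function(n)
      stoich_model("at_least_n", n, N, residual)),
    list(stoich_model("no_mixing", n_subunits = N, residual = residual))
  )
  names(cands) <- vapply(cands, model_label, character(1))
  cands
}

check_p <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop("'p' must be numeric in [0, 1]", call. = FALSE)
  as.numeric(p)
}

#' Binomial probability of exactly n wild-type subunits
#'
#' With random co-assembly from a subunit pool containing WT fraction `p`,
#' the number of WT subunits in a channel of `N` subunits is binomial, so the
#' probability of a channel carrying exactly `n` WT subunits is
#' \deqn{P_n = \binom{N}{n} p^n (1-p)^{N-n}.}
#'
#' @param n Number of WT subunits (0..`N`).
#' @param p WT subunit fraction in \[0, 1\]; vectorized.
#' @param N Subunits per channel (default 4).
#' @return Probabilities, one per element of `p`.
#' @examples
#' p_exact(4, 0.8)   # 0.4096: fraction of all-WT tetramers at a 4:1 mix
#' @export
p_exact <- function(n, p, N = 4L) {
  p <- check_p(p)
  N <- as.integer(N)
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 0L || n > N)
    stop("'n' must be a single integer in 0..N", call. = FALSE)
  # 0^0 == 1 in R, so the endpoints p = 0, 1 are exact
  choose(N, n) * p^n * (1 - p)^(N - n)
}

#' Binomial probability of at least n wild-type subunits
#'
#' Upper tail of the subunit-composition distribution:
#' \eqn{\sum_{k=n}^{N} P_k}. Non-decreasing in `p`, non-increasing in `n`.
#'
#' @inheritParams p_exact
#' @return Probabilities, one per element of `p`.
#' @examples
#' p_at_least(1, 0.5)   # 0.9375 = 1 - (1/2)^4
#' @export
p_at_least <- function(n, p, N = 4L) {
  p <- check_p(p)
  N <- as.integer(N)
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 0L || n > N)
    stop("'n' must be a single integer in 0..N", call. = FALSE)
  out <- numeric(length(p))
  for (k in n:N) out <- out + p_exact(k, p, N)
  pmin(out, 1)
}

#' Predicted normalized current under a stoichiometry rule
#'
#' Population-mean current, as a fraction of the pure-WT current, of a
#' channel pool assembled randomly from WT fraction `p`: channels satisfying
#' the rule contribute activity 1, the rest contribute the mutant residual
#' `r`, so the prediction is \eqn{f(p) + (1 - f(p)) r} where `f` is the rule
#' probability (`P_n`, the upper tail, or `p` itself for no co-assembly).
#' Always in \[r, 1\], and exactly 1 at `p = 1`.
#'
#' @param p WT subunit fraction in \[0, 1\]; vectorized.
#' @param model A [stoich_model()].
#' @return Predicted normalized currents, one per element of `p`.
#' @examples
#' predicted_current(0.5, stoich_model("exactly_n", 4))  # 0.5^4 = 0.0625
#' predicted_current(0.8, stoich_model("no_mixing"))     # 0.8
#' @export
predicted_current <- function(p, model) {
  stopifnot(inherits(model, "stoich_model"))
  p <- check_p(p)
  f <- switch(model$rule,
    exactly_n  = p_exact(model$n_required, p, model$n_subunits),
    at_least_n = p_at_least(model$n_required, p, model$n_subunits),
    no_mixing  = p)
  f + (1 - f) * model$residual
}

#' Expected channel activity for a given WT subunit fraction
#'
#' Alias of [predicted_current()] used by the synthetic-data generator: the
#' mean fraction of maximal current produced by an oocyte whose subunit pool
#' contains WT fraction `p` under a ground-truth assembly rule. Composition
#' sampling noise across the millions of channels per oocyte is negligible,
#' so only this binomial expectation enters the simulation.
#'
#' @inheritParams predicted_current
#' @return Expected activity in \[0, 1\], one per element of `p`.
#' @export
expected_activity <- function(p, model) predicted_current(p, model)

#' Predicted curve for a stoichiometry model
#'
#' @param object A [stoich_model()].
#' @param p WT subunit fractions at which to evaluate the model.
#' @param ... Unused.
#' @return Predicted normalized currents.
#' @export
predict.stoich_model <- function(object, p = seq(0, 1, by = 0.01), ...) {
  predicted_current(p, object)
}
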