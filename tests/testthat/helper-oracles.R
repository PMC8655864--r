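# Independent oracles, deliberately implemented without calling the package's
# own closed forms.

# Exact enumeration over all ordered subunit assignments of a channel with N
# positions, at rational WT fraction p = p_num / p_den. Each assignment is
# weighted p_num^(#WT) * (p_den - p_num)^(#mutant); the result is an exact
# integer numerator over p_den^N.
enum_exact_prob <- function(n_wt, p_num, p_den, N) {
  grid <- as.matrix(expand.grid(rep(list(c(1L, 0L)), N)))
  num <- 0
  for (i in seq_len(nrow(grid))) {
    wt <- sum(grid[i, ])
    if (wt == n_wt)
      num <- num + p_num^wt * (p_den - p_num)^(N - wt)
  }
  num / p_den^N
}

enum_at_least_prob <- function(n_wt, p_num, p_den, N) {
  sum(vapply(n_wt:N, enum_exact_prob, numeric(1), p_num = p_num,
             p_den = p_den, N = N))
}

# Direct-summation prediction via base R binomial distribution functions --
# an implementation route independent of the package's explicit closed form.
oracle_predicted <- function(p, model) {
  f <- switch(model$rule,
    exactly_n  = stats::dbinom(model$n_required, model$n_subunits, p),
    at_least_n = 1 - stats::pbinom(model$n_required - 1, model$n_subunits, p),
    no_mixing  = p)
  f + (1 - f) * model$residual
}

oracle_rmsd <- function(points, model) {
  s <- 0
  for (i in seq_len(nrow(points)))
    s <- s + (points$y[i] - oracle_predicted(points$p[i], model))^2
  sqrt(s / nrow(points))
}

oracle_percent_deviation <- function(points, model) {
  rms <- sqrt(sum(points$y^2) / nrow(points))
  100 * oracle_rmsd(points, model) / rms
}
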