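# Reported normalized-current points for the two loss-of-function variants:
# pure WT, the 4:1 and 1:1 WT:mutant co-injections, pure mutant.
p186q_points <- function() {
  data.frame(p = c(1, 0.8, 0.5, 0), y = c(1.00, 0.40, 0.05, 0.00))
}

r82w_points <- function() {
  data.frame(p = c(1, 0.8, 0.5, 0), y = c(1.00, 0.40, 0.20, 0.00))
}

# A deterministic (all-noise-off) simulation configuration.
noisefree_config <- function(truth = stoich_model("exactly_n", 4), ...) {
  sim_config(n_batches = 2, oocytes_per_group = 5,
             truth_model = truth, expression_cv = 0, batch_scale_cv = 0,
             leak_mean = 0.1, leak_cv = 0, endogenous_outward_mean = 0,
             leaky_fraction = 0, seed = 11L, ...)
}

# Hand-built measurements table: one oocyte per row spec, long format.
make_measurements <- function(batch_id, oocyte_id, wt_fraction,
                              i_low, i_high, i_ba) {
  n <- length(oocyte_id)
  data.frame(
    batch_id = rep(batch_id, each = 3L)[seq_len(3L * n)],
    oocyte_id = rep(oocyte_id, each = 3L),
    wt_fraction = rep(wt_fraction, each = 3L),
    rna_ng_total = 2,
    solution = rep(c("low_k", "high_k", "ba"), times = n),
    holding_mV = -50,
    current_uA = as.vector(rbind(i_low, i_high, i_ba)),
    stringsAsFactors = FALSE)
}

# Minimal extracted-style table that skips extract_all().
make_extracted <- function(batch_id, wt_fraction, kir_current,
                           included = TRUE) {
  n <- length(kir_current)
  data.frame(batch_id = rep_len(batch_id, n),
             oocyte_id = sprintf("o%03d", seq_len(n)),
             wt_fraction = rep_len(wt_fraction, n),
             kir_current = kir_current,
             included = rep_len(included, n),
             stringsAsFactors = FALSE)
}
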