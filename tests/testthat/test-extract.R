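test_that("the difference current isolates the Kir component", {
  m <- data.frame(i_low_k = c(-0.1, -2), i_high_k = c(-5.1, -2),
                  i_ba = c(-0.1, -2))
  expect_equal(kir_current(m), c(-5.0, 0))
  expect_error(kir_current(data.frame(i_low_k = NA_real_, i_high_k = 1)),
               "finite")

  # linearity: scaling every solution current scales the Kir current
  set.seed(1)
  for (i in 1:20) {
    row <- data.frame(i_low_k = rnorm(1), i_high_k = rnorm(1),
                      i_ba = rnorm(1))
    c0 <- runif(1, 0.1, 10)
    expect_equal(kir_current(row * c0), c0 * kir_current(row),
                 tolerance = 1e-12)
  }
})

test_that("the Ba2+-sensitive fraction measures block completeness", {
  expect_equal(ba_sensitive_fraction(
    data.frame(i_low_k = -0.1, i_high_k = -4.1, i_ba = -0.1)), 1)
  expect_equal(ba_sensitive_fraction(
    data.frame(i_low_k = -0.1, i_high_k = -4.1, i_ba = -4.1)), 0)
  expect_equal(ba_sensitive_fraction(
    data.frame(i_low_k = -0.1, i_high_k = -4.1, i_ba = -1.1)), 0.75)
  # zero Kir current is flagged NA, not an exception
  expect_true(is.na(ba_sensitive_fraction(
    data.frame(i_low_k = -1, i_high_k = -1, i_ba = -1))))
  # invariant under a constant leak added to all three solutions
  set.seed(2)
  for (i in 1:20) {
    row <- data.frame(i_low_k = -0.1, i_high_k = -4.1, i_ba = -1.6)
    leak <- rnorm(1)
    expect_equal(ba_sensitive_fraction(row + leak),
                 ba_sensitive_fraction(row), tolerance = 1e-12)
  }
})

test_that("leak QC applies the 1 uA outward threshold strictly", {
  ramp <- function(peak) data.frame(voltage_mV = c(-50, 0, 40, 50),
                                    current_uA = c(-peak, 0, peak, peak))
  expect_true(leak_qc(ramp(1.5)))
  expect_false(leak_qc(ramp(0.2)))
  expect_false(leak_qc(ramp(1.0)))   # boundary: strictly greater than
  # inward currents at negative potentials never count as leak
  expect_false(leak_qc(data.frame(voltage_mV = -50, current_uA = -8)))
  expect_error(leak_qc(NULL), "no ramp")
})

test_that("rectification check separates Kir-like from ohmic Ba-sensitive currents", {
  v <- seq(-50, 50, by = 2)
  leak_line <- function(g) data.frame(voltage_mV = v, current_uA = g * v)

  # synthetic pure-Kir ramp rectifies
  hk <- synth_ramp(10, 0.2, 0, "high_k", v)
  ba <- synth_ramp(10, 0.2, 0, "ba", v)
  expect_true(as.logical(rectification_check(hk, ba)))

  # an ohmic Ba-sensitive component does not
  flag <- rectification_check(leak_line(0.03), leak_line(0.005))
  expect_false(as.logical(flag))

  # zero-conductance oocytes pass vacuously with the noise-floor reason
  flag0 <- rectification_check(leak_line(0.01), leak_line(0.01))
  expect_true(as.logical(flag0))
  expect_match(attr(flag0, "reason"), "noise floor")

  # Ba2+ ramp must cover the high-K+ grid
  expect_error(
    rectification_check(leak_line(0.03),
                        data.frame(voltage_mV = c(-10, 10),
                                   current_uA = c(-0.1, 0.1))),
    "interpolate")
})

test_that("extract_all filters leaky oocytes and keeps per-reason counts", {
  cfg <- sim_config(n_batches = 1, oocytes_per_group = 10, wt_fractions = 1,
                    leaky_fraction = 0, seed = 3L)
  ds <- simulate_dataset(cfg)
  ex <- extract_all(ds$measurements, ds$ramps)
  expect_identical(sum(ex$included), 10L)   # leaky_fraction 0: all retained

  # force exactly one leaky oocyte by inflating one ramp
  ramps <- ds$ramps
  one <- ds$design$oocyte_id[1]
  sel <- ramps$oocyte_id == one & ramps$voltage_mV > 0
  ramps$current_uA[sel] <- ramps$current_uA[sel] + 2
  ex1 <- extract_all(ds$measurements, ramps)
  expect_identical(sum(ex1$included), 9L)
  expect_match(ex1$reasons[ex1$oocyte_id == one], "leaky")
  expect_identical(unname(attr(ex1, "qc_counts")["leaky"]), 1L)

  # all leaky: empty inclusion with a warning, not an exception
  ramps_all <- ds$ramps
  sel <- ramps_all$voltage_mV > 0
  ramps_all$current_uA[sel] <- ramps_all$current_uA[sel] + 2
  expect_warning(ex_all <- extract_all(ds$measurements, ramps_all),
                 "no oocytes passed QC")
  expect_identical(sum(ex_all$included), 0L)
})

test_that("QC never depends on the injected WT fraction", {
  ds <- simulate_dataset(sim_config(n_batches = 2, oocytes_per_group = 6,
                                    leaky_fraction = 0.3, seed = 13L))
  ex <- extract_all(ds$measurements, ds$ramps)
  shuffled <- ds$measurements
  set.seed(99)
  perm <- sample(unique(shuffled$oocyte_id))
  names(perm) <- unique(shuffled$oocyte_id)
  remap <- ds$design$wt_fraction[match(perm[shuffled$oocyte_id],
                                       ds$design$oocyte_id)]
  shuffled$wt_fraction <- remap
  ex_perm <- extract_all(shuffled, ds$ramps)
  expect_identical(ex$included, ex_perm$included)
  expect_identical(ex$leaky, ex_perm$leaky)
})

test_that("extracted Kir currents equal the generator's configured values", {
  cfg <- noisefree_config(wt_fractions = c(1, 0.8, 0.5, 0))
  ds <- simulate_dataset(cfg)
  ex <- extract_all(ds$measurements, ds$ramps)
  truth <- 5 * expected_activity(ex$wt_fraction, cfg$truth_model)
  expect_true(all(abs(abs(ex$kir_current) - truth) < 1e-9))
})

test_that("schema violations are reported with identities", {
  ds <- simulate_dataset(sim_config(n_batches = 1, oocytes_per_group = 2,
                                    wt_fractions = 1, seed = 2L))
  bad <- ds$measurements
  bad$solution[2] <- "wash"
  expect_error(extract_all(bad, NULL), "unknown solution")

  missing <- ds$measurements[-2, ]   # drop one oocyte's high_k row
  expect_error(suppressWarnings(extract_all(missing, NULL)),
               "missing a 'high_k'")

  orphan <- ds$ramps
  orphan$oocyte_id[1] <- "b99_o999"
  expect_error(extract_all(ds$measurements, orphan), "unknown oocyte")

  # no ramps at all: retained with a warning, QC marked not assessable
  expect_warning(ex <- extract_all(ds$measurements, NULL), "not assessable")
  expect_true(all(ex$included))
  expect_true(all(is.na(ex$leaky)))
})
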