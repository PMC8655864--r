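test_that("rmsd matches hand-computable cases and the constant-shift property", {
  m4 <- stoich_model("exactly_n", 4)
  # data generated exactly on a candidate curve fit that candidate perfectly
  al1 <- stoich_model("at_least_n", 1)
  p <- c(1, 0.8, 0.5, 0.2, 0)
  on_curve <- data.frame(p = p, y = predicted_current(p, al1))
  expect_equal(rmsd(on_curve, al1), 0)

  expect_equal(rmsd(data.frame(p = 0.5, y = 0.05), m4), 0.0125)

  set.seed(4)
  for (i in 1:10) {
    m <- default_candidates()[[sample(5, 1)]]
    pp <- runif(6)
    c0 <- runif(1, -0.2, 0.2)
    pts <- data.frame(p = pp, y = pmax(predicted_current(pp, m) + c0, 0))
    if (all(predicted_current(pp, m) + c0 >= 0))
      expect_equal(rmsd(pts, m), abs(c0), tolerance = 1e-12)
  }
  expect_error(rmsd(data.frame(p = numeric(), y = numeric()), m4),
               "no data")
})

test_that("rmsd and percent deviation agree with a direct-summation oracle", {
  set.seed(8)
  cands <- default_candidates()
  for (i in 1:100) {
    k <- sample(2:10, 1)
    pts <- data.frame(p = runif(k), y = runif(k))
    m <- cands[[sample(5, 1)]]
    expect_equal(rmsd(pts, m), oracle_rmsd(pts, m), tolerance = 1e-12)
    expect_equal(percent_deviation(pts, m),
                 oracle_percent_deviation(pts, m), tolerance = 1e-12)
  }
})

test_that("percent deviation is scale-free and guards its normalizer", {
  m4 <- stoich_model("exactly_n", 4)
  pts <- p186q_points()
  expect_equal(percent_deviation(pts, m4),
               100 * rmsd(pts, m4) / sqrt(mean(pts$y^2)))
  # alternative normalizers
  expect_equal(percent_deviation(pts, m4, "mean"),
               100 * rmsd(pts, m4) / mean(pts$y))
  expect_equal(percent_deviation(pts, m4, "max"), 100 * rmsd(pts, m4))
  # perfect fit is 0%
  on_curve <- data.frame(p = pts$p, y = predicted_current(pts$p, m4))
  expect_equal(percent_deviation(on_curve, m4), 0)
  expect_error(percent_deviation(data.frame(p = c(0, 0.5), y = c(0, 0)), m4),
               "normalizer undefined")
})

test_that("the dominant-negative rule wins on both variants' reported points", {
  for (pts in list(p186q_points(), r82w_points())) {
    res <- rank_models(pts)
    expect_identical(res$label[res$rank == 1], "exactly_4")
    expect_lt(res$percent_deviation[res$label == "exactly_4"],
              res$percent_deviation[res$label == "no_mixing"])
  }
})

test_that("ranking recovers a perfectly sampled no-mixing line and ignores input order", {
  nm <- stoich_model("no_mixing")
  p <- c(1, 0.8, 0.5, 0)
  pts <- data.frame(p = p, y = predicted_current(p, nm))
  res <- rank_models(pts)
  expect_identical(res$label[1], "no_mixing")
  expect_equal(res$percent_deviation[1], 0)

  set.seed(10)
  shuffled <- default_candidates()[sample(5)]
  res2 <- rank_models(pts, shuffled)
  expect_identical(res$label, res2$label)
  expect_equal(res$percent_deviation, res2$percent_deviation)
})

test_that("residual-activity fitting recovers the truth and respects bounds", {
  truth <- stoich_model("exactly_n", 4, residual = 0.1)
  p <- c(1, 0.8, 0.5, 0.2, 0)
  pts <- data.frame(p = p, y = predicted_current(p, truth))
  fr <- fit_residual(pts, stoich_model("exactly_n", 4))
  expect_equal(fr$r, 0.1, tolerance = 1e-6)
  expect_lt(fr$rmsd, 1e-6)

  # zero-residual data give the exact boundary solution
  pts0 <- data.frame(p = p, y = predicted_current(p, stoich_model("exactly_n", 4)))
  fr0 <- fit_residual(pts0, stoich_model("exactly_n", 4))
  expect_identical(fr0$r, 0)

  # the fitted rmsd never exceeds the r = 0 rmsd
  set.seed(12)
  for (i in 1:20) {
    noisy <- data.frame(p = p, y = pmax(predicted_current(p, truth) +
                                          rnorm(5, 0, 0.05), 0))
    m <- default_candidates()[[sample(4, 1)]]
    expect_lte(fit_residual(noisy, m)$rmsd, rmsd(noisy, m) + 1e-12)
  }
})

test_that("fit_stoichiometry returns a full-featured model object", {
  fit <- fit_stoichiometry(p186q_points())
  expect_s3_class(fit, "stoich_fit")
  expect_identical(model_label(fit$best), "exactly_4")
  expect_equal(unname(coef(fit)), c(4, 4, 0))
  expect_equal(predict(fit, 0.5), 0.0625)
  expect_equal(predict(fit, 0.8, model = "no_mixing"), 0.8)
  expect_equal(unname(residuals(fit)),
               p186q_points()$y - predicted_current(c(1, 0.8, 0.5, 0),
                                                    fit$best))
  expect_output(print(fit), "exactly_4")
  expect_output(print(summary(fit)), "Residuals")
  # plot renders headlessly without error
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))

  # an extract_all-style table is normalized on the fly
  ex <- make_extracted(batch_id = "b01", wt_fraction = c(1, 1, 0.5, 0.5),
                       kir_current = -c(4, 6, 0.3, 0.325))
  fit2 <- fit_stoichiometry(ex)
  expect_equal(fit2$points$y[fit2$points$p == 1], 1)
})

test_that("bootstrap ranking is deterministic and concentrates on the truth", {
  cfg <- sim_config(n_batches = 2, oocytes_per_group = 8,
                    expression_cv = 0.1, batch_scale_cv = 0.3,
                    leaky_fraction = 0, seed = 31L)
  ds <- simulate_dataset(cfg, include_ramps = FALSE)
  ex <- suppressWarnings(extract_all(ds$measurements, NULL))
  b1 <- bootstrap_ranking(ex, B = 50, seed = 7L)
  b2 <- bootstrap_ranking(ex, B = 50, seed = 7L)
  expect_identical(b1, b2)
  expect_gte(b1$freq_rank1[b1$label == "exactly_4"], 0.9)

  # single-oocyte cells force identity resampling: all mass on the winner
  ex1 <- make_extracted(batch_id = "b01", wt_fraction = c(1, 0.8, 0.5, 0),
                        kir_current = -c(5, 2, 0.25, 0))
  bb <- bootstrap_ranking(ex1, B = 1, seed = 1L)
  full <- rank_models(to_points(normalize_by_batch(ex1)))
  expect_equal(bb$freq_rank1[bb$label == full$label[1]], 1)
})
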