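test_that("generate_truth honors the silent fraction and the seed", {
  all_silent <- generate_truth(truth_model(n_genes = 50,
                                           silent_fraction = 1))
  expect_true(all(all_silent$lambda == 0))
  expect_true(all(!all_silent$expressed))

  none_silent <- generate_truth(truth_model(n_genes = 275,
                                            silent_fraction = 0))
  expect_equal(nrow(none_silent), 275L)
  expect_true(all(none_silent$lambda > 0))

  t1 <- generate_truth(truth_model(seed = 9))
  t2 <- generate_truth(truth_model(seed = 9))
  expect_identical(t1$lambda, t2$lambda)
  t3 <- generate_truth(truth_model(seed = 10))
  expect_false(identical(t1$lambda, t3$lambda))

  expect_error(truth_model(n_genes = 0), class = "txc_domain_error")
})

test_that("the noiseless limit reproduces the truth exactly", {
  truth <- generate_truth(truth_model(n_genes = 60, silent_fraction = 0.1,
                                      seed = 3))
  pm <- platform_model("short_read", efficiency = 1, noise_sd_log = 0,
                       dropout_d0 = 0, false_positive_rate = 0)
  tab <- observe_platform(truth, pm, seed = 3)
  expect_identical(tab$value, truth$lambda)
})

test_that("without false positives silent genes stay at zero", {
  truth <- generate_truth(truth_model(n_genes = 100, silent_fraction = 0.5,
                                      seed = 5))
  pm <- platform_model("long_read", false_positive_rate = 0)
  tab <- observe_platform(truth, pm, seed = 5)
  expect_true(all(tab$value[!truth$expressed] == 0))
  # hence silent genes are undetected at any cutoff
  expect_false(any(detect_genes(tab, 0)$gene_id %in%
                     truth$gene_id[!truth$expressed]))
})

test_that("observation streams are keyed by platform and batch", {
  truth <- generate_truth(truth_model(seed = 2))
  a1 <- observe_platform(truth, platform_model("short_read"), seed = 2)
  a2 <- observe_platform(truth, platform_model("short_read"), seed = 2)
  expect_identical(a1, a2)
  b <- observe_platform(truth, platform_model("long_read"), seed = 2)
  expect_false(identical(a1$value, b$value))
  # observing another platform does not perturb the first one's draws
  expect_identical(a1,
                   observe_platform(truth, platform_model("short_read"),
                                    seed = 2))
})

test_that("drift leaves silent genes silent and damps high abundances", {
  truth <- generate_truth(truth_model(n_genes = 200, silent_fraction = 0.25,
                                      seed = 8))
  pm <- platform_model("short_read", noise_sd_log = 0, dropout_d0 = 0,
                       false_positive_rate = 0)
  plain <- observe_platform(truth, pm, seed = 8, batch = "b2")
  drifted <- observe_platform(truth, pm, seed = 8, batch = "b2",
                              drift = batch_drift(extra_noise_sd_log = 0))
  expect_true(all(drifted$value[!truth$expressed] == 0))
  expect_true(all(drifted$value[truth$expressed] <
                    plain$value[truth$expressed]))
  # the top-quantile gene is scaled by exp(-decay_rate)
  top <- which.max(truth$lambda)
  expect_equal(drifted$value[top], plain$value[top] * exp(-0.2))
})

test_that("generate_dataset is deterministic end-to-end, files included", {
  ds1 <- generate_dataset(seed = 12)
  ds2 <- generate_dataset(seed = 12)
  expect_identical(ds1$tables, ds2$tables)
  expect_equal(dplyr::n_distinct(ds1$tables$platform), 3L)
  expect_equal(nrow(ds1$tables), 3L * 275L)

  d1 <- tempfile()
  d2 <- tempfile()
  write_dataset(ds1, d1)
  write_dataset(ds2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))))
  }
  # drifted datasets double the batches
  ds_drift <- generate_dataset(drift = batch_drift(), seed = 12)
  expect_equal(nrow(ds_drift$tables), 6L * 275L)
  expect_identical(
    ds_drift$tables[ds_drift$tables$batch == "b1", ]$value[
      ds_drift$tables$platform[ds_drift$tables$batch == "b1"] == "short_read"],
    ds1$tables$value[ds1$tables$platform == "short_read"])
})

test_that("the sub-cutoff signal fraction matches the closed-form
           observation law", {
  # P(observed value in (0, 0.1] | expressed) under the default short-read
  # model, by numerical integration over the abundance law (the oracle is
  # independent of the sampling path)
  tm <- truth_model()
  pm <- platform_model("short_read")
  integrand <- function(lam) {
    dlnorm(lam, tm$meanlog, tm$sdlog) *
      (1 - pm$dropout_d0 * exp(-lam / pm$dropout_lambda0)) *
      pnorm((log(0.1) - log(pm$efficiency * lam)) / pm$noise_sd_log)
  }
  p_expected <- integrate(integrand, 0, Inf, rel.tol = 1e-8)$value

  n_seeds <- 200
  phat <- vapply(seq_len(n_seeds), function(s) {
    truth <- generate_truth(truth_model(silent_fraction = 0), seed = s)
    tab <- observe_platform(truth, pm, seed = s)
    mean(tab$value > 0 & tab$value <= 0.1)
  }, numeric(1))
  se <- stats::sd(phat) / sqrt(n_seeds)
  expect_lt(abs(mean(phat) - p_expected), 3 * se + 1e-12)
})

test_that("empirical detection probability increases with abundance", {
  pm <- platform_model("short_read")
  hits <- matrix(0, nrow = 100, ncol = 3)
  for (s in 1:100) {
    truth <- generate_truth(truth_model(silent_fraction = 0), seed = s)
    tab <- observe_platform(truth, pm, seed = s)
    bins <- cut(truth$lambda, breaks = c(0, 0.5, 2, Inf))
    hits[s, ] <- tapply(tab$value > 0, bins, mean)
  }
  rates <- colMeans(hits)
  expect_true(all(diff(rates) > 0))
  # and the low bin tracks the model curve 1 - d0 * exp(-lambda / lambda0)
  expect_lt(rates[1], 1 - pm$dropout_d0 * exp(-0.5))
})
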