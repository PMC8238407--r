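three_platform_fixture <- function() {
  dplyr::bind_rows(
    expr_tbl(c(G1 = 8, G2 = 3, G3 = 0.5, G4 = 0.05), "short_read"),
    expr_tbl(c(G1 = 6, G2 = 0.8, G3 = 0.3, G5 = 0.02), "long_read"),
    expr_tbl(c(G1 = 12, G2 = 2, G4 = 1.5), "qpcr"))
}

test_that("sweep_concordance assembles a consistent per-cutoff report", {
  uni <- gene_universe(sprintf("G%d", 1:6))
  rep <- sweep_concordance(three_platform_fixture(), uni)
  s <- tidy(rep)
  expect_equal(nrow(s), 5L)
  expect_equal(s$cutoff, default_cutoffs())
  # tier counts sum to the union at every cutoff
  expect_equal(s$n_tier1 + s$n_tier2 + s$n_tier3, s$union_size)
  expect_equal(s$coverage, s$union_size / 6)
  expect_equal(s$n_undetected, 6L - s$union_size)
  # union and coverage are non-increasing in the cutoff
  expect_true(all(diff(s$union_size) <= 0))
  expect_true(all(diff(s$coverage) <= 0))
  # detection sets are nested across the ladder
  keys <- names(rep$per_cutoff)
  for (i in seq_along(keys)[-1]) {
    lo <- rep$per_cutoff[[keys[i - 1]]]
    hi <- rep$per_cutoff[[keys[i]]]
    expect_true(all(hi$tiers$gene_id %in% lo$tiers$gene_id))
  }
  expect_s3_class(rep$per_cutoff[["0"]]$venn, "venn_partition")
  expect_equal(attr(rep$per_cutoff[["0"]]$venn, "common_all"),
               s$common_all[1])
})

test_that("a platform compared against its duplicate has Tanimoto 1
           wherever sets are non-empty", {
  a <- expr_tbl(c(G1 = 5, G2 = 0.5), "short_read")
  b <- expr_tbl(c(G1 = 5, G2 = 0.5), "long_read")
  rep <- sweep_concordance(dplyr::bind_rows(a, b),
                           gene_universe(c("G1", "G2")))
  for (e in rep$per_cutoff) {
    expect_equal(e$tanimoto$tanimoto, 1.0)
  }
})

test_that("glance summarizes the sweep in one row", {
  uni <- gene_universe(sprintf("G%d", 1:6))
  g <- glance(sweep_concordance(three_platform_fixture(), uni))
  expect_equal(nrow(g), 1L)
  expect_equal(g$n_sets, 3L)
  expect_equal(g$universe_size, 6L)
  expect_equal(g$best_cutoff, 0)
})

test_that("sweep_concordance validates inputs", {
  uni <- gene_universe("G1")
  one <- expr_tbl(c(G1 = 1))
  expect_error(sweep_concordance(one, uni), class = "txc_validation_error")
  two <- dplyr::bind_rows(one, expr_tbl(c(G1 = 1), "long_read"))
  expect_error(sweep_concordance(two, uni, cutoffs = c(1, 0.5)),
               class = "txc_validation_error")
  expect_error(sweep_concordance(two, uni, cutoffs = c(-1, 0)),
               class = "txc_validation_error")
})

test_that("replicate concordance of identical batches is 1 at every cutoff", {
  a <- expr_tbl(c(G1 = 5, G2 = 0.5, G3 = 0.05), batch = "2017")
  b <- expr_tbl(c(G1 = 5, G2 = 0.5, G3 = 0.05), batch = "2020")
  rc <- replicate_concordance(a, b)
  expect_equal(rc$tanimoto, rep(1, 5))
  expect_true(all(rc$band == "identical"))
})

test_that("thresholding at zero is scale-invariant across batches", {
  a <- expr_tbl(c(G1 = 5, G2 = 0.5, G3 = 0.05), batch = "2017")
  b <- a
  b$batch <- "2020"
  b$value <- b$value * 2
  rc <- replicate_concordance(a, b)
  expect_equal(rc$tanimoto[rc$cutoff == 0], 1.0)
  # but not at interior cutoffs that split the doubled values
  expect_lt(rc$tanimoto[rc$cutoff == 5], 1.0)
})

test_that("replicate concordance rejects mismatched provenance", {
  a <- expr_tbl(c(G1 = 1), platform = "short_read", batch = "2017")
  b <- expr_tbl(c(G1 = 1), platform = "long_read", batch = "2020")
  expect_error(replicate_concordance(a, b), class = "txc_validation_error")
  same_batch <- expr_tbl(c(G1 = 1), batch = "2017")
  expect_error(replicate_concordance(a, same_batch),
               class = "txc_validation_error")
})
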