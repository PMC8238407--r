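test_that("venn_partition assigns genes to exclusive regions", {
  vp <- venn_partition(list(A = c("G1", "G2"), B = c("G2", "G3")))
  counts <- setNames(vp$n_genes, vp$region)
  expect_equal(counts[["A"]], 1L)
  expect_equal(counts[["B"]], 1L)
  expect_equal(counts[["A&B"]], 1L)
  expect_equal(attr(vp, "union_size"), 3L)
  expect_equal(attr(vp, "common_all"), 1L)

  vp3 <- venn_partition(list(A = "G1", B = "G1", C = "G1"))
  expect_equal(attr(vp3, "common_all"), 1L)
  expect_equal(attr(vp3, "union_size"), 1L)
  expect_equal(sum(vp3$n_genes), 1L)

  vp_empty <- venn_partition(list(A = "G1", B = character(0),
                                  C = character(0)))
  counts <- setNames(vp_empty$n_genes, vp_empty$region)
  expect_equal(counts[["A"]], 1L)
  expect_equal(sum(vp_empty$n_genes), 1L)
})

test_that("venn_partition validates its inputs", {
  expect_error(venn_partition(list(A = "G1")), class = "txc_validation_error")
  expect_error(venn_partition(list(A = "G1", A = "G2")),
               class = "txc_validation_error")
  five <- setNames(replicate(5, "G1", simplify = FALSE), paste0("S", 1:5))
  expect_error(venn_partition(five), class = "txc_validation_error")
})

test_that("region counts sum to the union and recover pairwise
           intersections", {
  universe <- sprintf("g%02d", 1:25)
  set.seed(23)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    sets <- random_sets(k, universe, p = stats::runif(1, 0.2, 0.8))
    vp <- venn_partition(sets)
    expect_equal(sum(vp$n_genes), attr(vp, "union_size"))
    expect_equal(attr(vp, "union_size"),
                 length(unique(unlist(sets, use.names = FALSE))))
    # every pairwise intersection is the sum of regions containing both sets
    nm <- names(sets)
    for (a in seq_len(k - 1)) for (b in seq.int(a + 1, k)) {
      parts <- strsplit(vp$region, "&", fixed = TRUE)
      in_both <- vapply(parts, function(p) all(nm[c(a, b)] %in% p),
                        logical(1))
      expect_equal(sum(vp$n_genes[in_both]),
                   length(intersect(sets[[a]], sets[[b]])))
    }
  }
})

test_that("reliability tiers count detecting platforms and match the
           partition grouped by degree", {
  tiers <- reliability_tiers(list(A = c("G1", "G2"), B = "G2", C = "G2"))
  expect_equal(setNames(tiers$tier, tiers$gene_id), c(G1 = 1L, G2 = 3L))

  same <- list(A = c("x", "y"), B = c("x", "y"), C = c("x", "y"))
  expect_true(all(reliability_tiers(same)$tier == 3L))

  universe <- sprintf("g%02d", 1:25)
  set.seed(31)
  for (i in 1:50) {
    sets <- random_sets(3, universe)
    vp <- venn_partition(sets)
    tiers <- reliability_tiers(sets)
    for (k in 1:3) {
      expect_equal(sum(tiers$tier == k), sum(vp$n_genes[vp$degree == k]))
    }
  }
})

test_that("platform-unique genes are the singleton regions", {
  u <- platform_unique(list(A = c("G1", "G2"), B = c("G2", "G3")))
  expect_equal(u$gene_id[u$set_id == "A"], "G1")
  expect_equal(u$gene_id[u$set_id == "B"], "G3")

  same <- list(A = "G1", B = "G1")
  expect_equal(nrow(platform_unique(same)), 0L)

  universe <- sprintf("g%02d", 1:25)
  set.seed(37)
  for (i in 1:25) {
    sets <- random_sets(3, universe)
    tiers <- reliability_tiers(sets)
    expect_equal(nrow(platform_unique(sets)), sum(tiers$tier == 1L))
  }
})

test_that("undetected genes complement the union within the universe", {
  uni <- gene_universe(c("G1", "G2", "G3", "G4"))
  sets <- list(A = "G1", B = "G2")
  expect_equal(undetected_genes(sets, uni)$gene_id, c("G3", "G4"))
  expect_equal(nrow(undetected_genes(list(A = uni$gene_id, B = "G1"), uni)),
               0L)
})

test_that("coverage is the detected fraction of the universe", {
  uni <- gene_universe(sprintf("G%03d", 1:275))
  sets <- list(A = sprintf("G%03d", 1:200), B = sprintf("G%03d", 150:273))
  expect_equal(coverage(sets, uni), 273 / 275)
  expect_equal(coverage(list(A = character(0), B = character(0)), uni), 0)
  sets_all <- list(A = uni$gene_id, B = c(uni$gene_id, "EXTRA"))
  expect_equal(coverage(sets_all, uni), 1)
  expect_error(coverage(sets, character(0)), class = "txc_domain_error")
})
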