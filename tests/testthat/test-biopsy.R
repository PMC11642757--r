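test_that("classification rules map counts to classes as stated", {
  expect_equal(as.character(classify_biopsy(0:5)),
               c("euploid", "mosaic", "mosaic", "mosaic", "aneuploid",
                 "aneuploid"))
  expect_equal(as.character(classify_biopsy(0:5, rule = "any_but_not_all")),
               c("euploid", "mosaic", "mosaic", "mosaic", "mosaic",
                 "aneuploid"))
  # the rules disagree only at 4 of 5
  expect_equal(classify_biopsy(3)[[1]], factor("mosaic", biopsy_class_levels())[[1]])
  expect_error(classify_biopsy(6), "0..biopsy_size")
})

test_that("biopsies of homogeneous embryos are certain", {
  g <- make_geometry(256)
  full <- place_aneuploid(g, 256, 1)
  none <- place_aneuploid(g, 0, 1)
  for (idx in c(1L, 77L, 256L)) {
    expect_equal(take_biopsy(full, idx)$aneuploid_count, 5L)
    expect_equal(take_biopsy(none, idx)$aneuploid_count, 0L)
  }
  b <- take_biopsy(full)
  expect_length(b$cell_ids[[1]], 5)
  expect_error(take_biopsy(full, index_cell = 300), "cell id")
})

test_that("at dispersal 1 biopsy counts are hypergeometric (TV < 0.01)", {
  set.seed(31)
  g <- make_geometry(256)
  k <- 64L
  n_rep <- 40000L
  counts <- mosaicabc:::cpp_two_biopsies(
    g$neighbor_order - 1L, biopsy_cells(g) - 1L, rep(k, n_rep), 1
  )[, 1]
  obs <- tabulate(counts + 1L, nbins = 6L)
  expect_lt(tv_distance(obs, hyper_pmf(k, 256, 5)), 0.01)
})

test_that("biopsy proportions are a simplex and degenerate rates are exact", {
  set.seed(32)
  cfg <- model_config(dispersal = 1)
  expect_equal(unname(simulate_biopsy_proportions(1, 0.3, cfg, 500)),
               c(0, 0, 1))
  expect_equal(unname(simulate_biopsy_proportions(0, 0, cfg, 500)),
               c(1, 0, 0))
  for (d in c(0, 0.5, 1)) {
    p <- simulate_biopsy_proportions(stats::runif(1), stats::runif(1, 0, 0.1),
                                     model_config(dispersal = d), 400)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("class lookup matches direct placement simulation", {
  set.seed(33)
  cfg <- model_config(dispersal = 0.5)
  g <- make_geometry(256)
  lk <- biopsy_class_lookup(cfg, n_rep = 3000)
  expect_equal(lk$p_euploid + lk$p_mosaic + lk$p_aneuploid, rep(1, 257))
  expect_equal(lk$p_euploid[1], 1)       # no aneuploid cells
  expect_equal(lk$p_aneuploid[257], 1)   # all aneuploid
  codes <- mosaicabc:::class_codes(5, "threshold_20_70")
  for (k in c(10L, 64L, 180L)) {
    direct <- mosaicabc:::cpp_two_biopsies(
      g$neighbor_order - 1L, biopsy_cells(g) - 1L, rep(k, 3000L), 0.5
    )[, 1]
    direct_probs <- vapply(1:3, function(cl) mean(codes[direct + 1L] == cl),
                           numeric(1))
    table_probs <- c(lk$p_euploid[k + 1], lk$p_mosaic[k + 1],
                     lk$p_aneuploid[k + 1])
    # both are Monte Carlo at 3000 reps; allow ~4 binomial SEs
    expect_lt(max(abs(direct_probs - table_probs)), 0.05)
  }
})

test_that("dispersal-1 lookup agrees with the exact hypergeometric classes", {
  set.seed(34)
  cfg <- model_config(dispersal = 1)
  lk <- biopsy_class_lookup(cfg, n_rep = 4000)
  codes <- mosaicabc:::class_codes(5, "threshold_20_70")
  for (k in c(20L, 64L, 128L, 220L)) {
    pmf <- hyper_pmf(k, 256, 5)
    exact <- vapply(1:3, function(cl) sum(pmf[codes == cl]), numeric(1))
    got <- c(lk$p_euploid[k + 1], lk$p_mosaic[k + 1], lk$p_aneuploid[k + 1])
    expect_lt(max(abs(got - exact)), 0.035)
  }
})
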