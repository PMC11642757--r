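test_that("embryo classification follows the any-but-not-all definition", {
  got <- classify_embryo(c(0L, 1L, 128L, 255L, 256L))
  expect_equal(as.character(got),
               c("fully_euploid", "mosaic", "mosaic", "mosaic",
                 "fully_aneuploid"))
  expect_error(classify_embryo(-1L), "0..n_cells")
  expect_error(classify_embryo(257L), "0..n_cells")
})

test_that("point-mass posteriors produce the embryos they promise", {
  cfg <- model_config(dispersal = 1)
  all_aneu <- simulate_predictive(point_posterior(1, 0.5), cfg,
                                  n_draws = 5, n_embryos_per_draw = 200,
                                  seed = 51)
  expect_true(all(all_aneu$embryo_type == "fully_aneuploid"))
  expect_true(all(all_aneu$biopsy1_class == "aneuploid"))
  expect_true(all(all_aneu$biopsy2_class == "aneuploid"))

  all_eu <- simulate_predictive(point_posterior(0, 0), cfg,
                                n_draws = 5, n_embryos_per_draw = 200,
                                seed = 52)
  expect_true(all(all_eu$embryo_type == "fully_euploid"))
  expect_true(all(all_eu$biopsy1_class == "euploid"))
})

test_that("biopsies cannot contradict homogeneous embryos", {
  set.seed(53)
  cfg <- model_config(dispersal = 0.5)
  pred <- simulate_predictive(point_posterior(0.4, 0.05), cfg,
                              n_draws = 20, n_embryos_per_draw = 200)
  eu <- pred[pred$embryo_type == "fully_euploid", ]
  an <- pred[pred$embryo_type == "fully_aneuploid", ]
  expect_true(all(eu$biopsy1_class == "euploid"))
  expect_true(all(eu$biopsy2_class == "euploid"))
  expect_true(all(an$biopsy1_class == "aneuploid"))
  expect_true(all(an$biopsy2_class == "aneuploid"))
})

test_that("fully-euploid predictive proportion matches the lineage closed form", {
  cfg <- model_config(dispersal = 1)
  m <- 0.58
  p <- 0.015
  pred <- simulate_predictive(point_posterior(m, p), cfg,
                              n_draws = 200, n_embryos_per_draw = 1000,
                              seed = 54)
  expected <- (1 - m) * (1 - p)^510
  phat <- mean(pred$n_aneuploid == 0L)
  expect_lt(abs(phat - expected), 3 * sqrt(expected / nrow(pred)))
})

test_that("second biopsies at dispersal 1 look hypergeometric and near-independent", {
  set.seed(55)
  g <- make_geometry(256)
  k <- 64L
  n_rep <- 30000L
  bb <- mosaicabc:::cpp_two_biopsies(
    g$neighbor_order - 1L, biopsy_cells(g) - 1L, rep(k, n_rep), 1
  )
  obs2 <- tabulate(bb[, 2] + 1L, nbins = 6L)
  expect_lt(tv_distance(obs2, hyper_pmf(k, 256, 5)), 0.01)
  # overlap is allowed and placements are uniform, so the two counts are
  # essentially uncorrelated
  expect_lt(abs(stats::cor(bb[, 1], bb[, 2])), 0.03)
})

test_that("predictive tables are internally consistent", {
  set.seed(56)
  cfg <- model_config(dispersal = 0.5)
  pred <- simulate_predictive(point_posterior(0.5, 0.03), cfg,
                              n_draws = 30, n_embryos_per_draw = 300)
  tab <- predictive_tables(pred)
  n_total <- nrow(pred)
  expect_equal(sum(tab$embryo_types$proportion), 1)
  expect_equal(sum(tab$embryo_types$n), n_total)
  expect_equal(sum(tab$aneuploid_fraction$n), n_total)
  expect_equal(sum(tab$biopsy_by_embryo$n), n_total)
  expect_equal(sum(tab$rebiopsy$n), n_total)
  # per-class shares sum to one where the class occurs
  shares <- tab$biopsy_by_embryo |>
    dplyr::group_by(biopsy_class) |>
    dplyr::summarise(s = sum(share_of_biopsy_class), n = sum(n))
  expect_true(all(abs(shares$s[shares$n > 0] - 1) < 1e-12))
  # concordance equals the diagonal share, recomputed directly
  for (cl in levels(pred$biopsy1_class)) {
    sel <- pred$biopsy1_class == cl
    if (any(sel)) {
      direct <- mean(pred$biopsy2_class[sel] == cl)
      expect_equal(
        tab$concordance$concordance[tab$concordance$first_class == cl],
        direct
      )
    }
  }
})
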