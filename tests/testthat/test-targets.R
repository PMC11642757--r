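test_that("the published catalog holds its frozen values", {
  cat <- published_targets()
  expect_equal(cat$study, c("capalbo", "clarke", "munne", "rodrigo"))
  expect_equal(cat$prop_euploid, c(0.232, 0.49, 0.53, 0.51))
  expect_equal(cat$prop_mosaic, c(0.187, 0.18, 0.15, 0.06))
  expect_equal(cat$prop_aneuploid, c(0.581, 0.33, 0.32, 0.43))
  expect_equal(cat$n_biopsies, c(6766L, NA, NA, NA))
  rounded <- published_targets(rounded = TRUE)
  expect_equal(rounded$prop_euploid[1], 0.23)
  expect_equal(rounded$prop_mosaic[1], 0.19)
  # every entry lies on the simplex within printed-rounding tolerance
  sums <- cat$prop_euploid + cat$prop_mosaic + cat$prop_aneuploid
  expect_true(all(abs(sums - 1) <= 0.005))
  # checksum over all stored proportions guards against silent edits
  expect_equal(sum(c(cat$prop_euploid, cat$prop_mosaic, cat$prop_aneuploid,
                     rounded$prop_euploid, rounded$prop_mosaic,
                     rounded$prop_aneuploid)), 8)
})

test_that("target validation renormalises printed rounding and rejects junk", {
  t <- target_proportions(0.23, 0.19, 0.58)
  expect_equal(t$prop_euploid + t$prop_mosaic + t$prop_aneuploid, 1)
  expect_error(target_proportions(0.5, 0.1, 0.2), "sum to")
  expect_error(target_proportions(-0.1, 0.5, 0.6), "non-negative")
})

test_that("synthetic targets hit degenerate truths exactly", {
  set.seed(71)
  cfg <- model_config(dispersal = 1)
  all_aneu <- generate_synthetic_target(1, 0.3, cfg, n_biopsies = 300)
  expect_equal(c(all_aneu$prop_euploid, all_aneu$prop_mosaic,
                 all_aneu$prop_aneuploid), c(0, 0, 1))
  all_eu <- generate_synthetic_target(0, 0, cfg, n_biopsies = 300)
  expect_equal(c(all_eu$prop_euploid, all_eu$prop_mosaic,
                 all_eu$prop_aneuploid), c(1, 0, 0))
  expect_equal(all_aneu$true_meiotic, 1)
})

test_that("finite-size synthetic targets show multinomial sampling noise", {
  set.seed(72)
  cfg <- model_config(dispersal = 1)
  n_b <- 6766L
  reps <- purrr::map_dfr(1:60, function(i) {
    generate_synthetic_target(0.45, 0.02, cfg, n_biopsies = n_b)
  })
  # the noise-free class probabilities, estimated once at large n
  big <- generate_synthetic_target(0.45, 0.02, cfg, n_biopsies = Inf)
  for (col in c("prop_euploid", "prop_mosaic", "prop_aneuploid")) {
    p <- big[[col]]
    se <- sqrt(p * (1 - p) / n_b)
    # observed spread consistent with multinomial sampling
    expect_lt(stats::sd(reps[[col]]), 3 * se)
    expect_gt(stats::sd(reps[[col]]), se / 3)
    # and centred on the noise-free value
    expect_lt(abs(mean(reps[[col]]) - p), 4 * se / sqrt(60))
  }
})

test_that("targets survive a file round trip", {
  path <- tempfile(fileext = ".tsv")
  write_target(published_targets(), path)
  back <- read_target(path)
  expect_equal(back$study, published_targets()$study)
  expect_equal(back$prop_euploid, published_targets()$prop_euploid,
               tolerance = 1e-6)
  bad <- tempfile(fileext = ".tsv")
  writeLines("study\tprop_euploid\tprop_mosaic\tprop_aneuploid\nx\t0.5\t0.1\t0.2",
             bad)
  expect_error(read_target(bad), "sum to")
})
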