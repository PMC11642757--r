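test_that("degenerate error rates give degenerate lineages", {
  set.seed(1)
  cfg <- model_config()
  all_meiotic <- simulate_lineages(200, 1, 0.5, cfg)
  expect_true(all(all_meiotic$n_aneuploid == 256L))
  expect_true(all(all_meiotic$meiotic_error))
  none <- simulate_lineages(200, 0, 0, cfg)
  expect_true(all(none$n_aneuploid == 0L))
  expect_false(any(none$meiotic_error))
})

test_that("per-daughter lineage matches its closed forms", {
  set.seed(42)
  cfg <- model_config()
  p <- 0.015
  lin <- simulate_lineages(1e5, 0, p, cfg)
  frac <- lin$n_aneuploid / 256

  # expected aneuploid fraction: 1 - (1 - p)^8
  expected_frac <- 1 - (1 - p)^8
  se <- stats::sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - expected_frac), 3 * se)

  # fully-euploid probability: (1 - p)^510 (510 daughter draws over 8 rounds)
  lin2 <- simulate_lineages(1e6, 0, p, cfg)
  p0 <- (1 - p)^510
  phat <- mean(lin2$n_aneuploid == 0L)
  expect_lt(abs(phat - p0), 3 * sqrt(p0 * (1 - p0) / 1e6))

  # with meiotic errors folded in: P(K = n_cells) >= meiotic
  set.seed(7)
  mixed <- simulate_lineages(2e4, 0.58, p, cfg)
  expect_gt(mean(mixed$n_aneuploid == 256L), 0.58 - 3 * sqrt(0.25 / 2e4))
  efrac <- 0.58 + 0.42 * expected_frac
  se2 <- stats::sd(mixed$n_aneuploid / 256) / sqrt(2e4)
  expect_lt(abs(mean(mixed$n_aneuploid / 256) - efrac), 3 * se2)
})

test_that("per-division convention keeps the per-cell marginal but errs as a unit", {
  set.seed(9)
  cfg <- model_config(mitotic_convention = "per_division_both_daughters")
  p <- 0.02
  lin <- simulate_lineages(1e5, 0, p, cfg)
  # same marginal expected fraction as per-daughter
  expected_frac <- 1 - (1 - p)^8
  se <- stats::sd(lin$n_aneuploid / 256) / sqrt(1e5)
  expect_lt(abs(mean(lin$n_aneuploid / 256) - expected_frac), 3 * se)
  # fully euploid iff none of the 255 euploid-cell divisions errs
  p0 <- (1 - p)^255
  expect_lt(abs(mean(lin$n_aneuploid == 0L) - p0), 3 * sqrt(p0 / 1e5))
  # aneuploid cells arrive in clones of at least two: counts are even
  expect_true(all(lin$n_aneuploid %% 2L == 0L))
})

test_that("binomial recursion is distributionally equivalent to the per-cell tree", {
  set.seed(11)
  n_rounds <- 4L
  cfg <- model_config(n_rounds = n_rounds, biopsy_size = 5)
  p <- 0.05
  n <- 4000L
  fast <- simulate_lineages(n, 0, p, cfg)$n_aneuploid
  slow <- tree_lineage_oracle(n, 0, p, n_rounds)
  # chi-square homogeneity across pooled count bins, alpha = 0.001
  bins <- c(-1, 0, 1, 2, 3, 4, 6, 8, 16)
  tab <- rbind(table(cut(fast, bins)), table(cut(slow, bins)))
  keep <- colSums(tab) > 0
  test <- suppressWarnings(stats::chisq.test(tab[, keep]))
  expect_gt(test$p.value, 0.001)
})

test_that("expected class proportions are monotone in the error rates", {
  set.seed(13)
  cfg <- model_config(dispersal = 1)
  lk <- biopsy_class_lookup(cfg, n_rep = 2000)
  n <- 3e4
  aneu_by_meiotic <- vapply(c(0.2, 0.5, 0.8), function(m) {
    simulate_biopsy_proportions(m, 0.02, cfg, n, lookup = lk)[["prop_aneuploid"]]
  }, numeric(1))
  expect_true(all(diff(aneu_by_meiotic) > 0))
  eu_by_mitotic <- vapply(c(0.005, 0.03, 0.1), function(p) {
    simulate_biopsy_proportions(0.3, p, cfg, n, lookup = lk)[["prop_euploid"]]
  }, numeric(1))
  expect_true(all(diff(eu_by_mitotic) < 0))
})
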