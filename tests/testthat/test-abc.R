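test_that("distance is Euclidean on raw proportions", {
  expect_equal(abc_distance(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 0)
  expect_equal(abc_distance(c(1, 0, 0), c(0, 1, 0)), sqrt(2))
  expect_equal(abc_distance(c(0.25, 0.17, 0.58), c(0.23, 0.19, 0.58)),
               sqrt(0.0004 + 0.0004))
  m <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(abc_distance(m, c(0, 1, 0)), c(sqrt(2), 0))
})

test_that("the sampler recovers a deterministic identity-simulator target", {
  post <- run_abc(
    c(0.3, 0.7), simulator = function(theta) theta,
    control = abc_config(n_particles = 400, max_iterations = 20),
    seed = 41
  )
  s <- posterior_summary(post)
  expect_lt(abs(s$mean[s$parameter == "meiotic"] - 0.3), 0.01)
  expect_lt(abs(s$mean[s$parameter == "mitotic"] - 0.7), 0.01)
  expect_lt(utils::tail(post$tolerance_history, 1), 0.01)
})

test_that("tolerances are nonincreasing and weights well-formed on a noisy run", {
  set.seed(42)
  cfg <- model_config(dispersal = 1)
  lk <- biopsy_class_lookup(cfg, n_rep = 1000)
  post <- run_abc(
    published_targets()[1, ], config = cfg,
    control = abc_config(n_particles = 200, n_embryos_per_trial = 100,
                         max_iterations = 8),
    lookup = lk
  )
  expect_true(all(diff(post$tolerance_history) <= 0))
  expect_equal(nrow(post$particles), 100L)  # ceiling(0.5 * 200)
  expect_true(all(post$particles$weight > 0))
  expect_equal(sum(post$particles$weight), 1)
  expect_true(all(post$particles$distance >= 0))
  expect_true(all(post$particles$meiotic > 0 & post$particles$meiotic < 1))
  expect_true(all(post$particles$mitotic > 0 & post$particles$mitotic < 1))
  # first-iteration retention leaves prior draws equally weighted, so any
  # surviving initial particles share one weight value
  expect_lte(length(unique(signif(post$particles$weight, 12))),
             nrow(post$particles))
})

test_that("posterior summaries use weighted means and interpolated quantiles", {
  single <- point_posterior(0.4, 0.05)
  s <- posterior_summary(single)
  expect_equal(s$mean, c(0.4, 0.05))
  expect_equal(s$ci_lower, s$mean)
  expect_equal(s$ci_upper, s$mean)

  two <- point_posterior(0.4, 0.05)
  two$particles <- tibble::tibble(
    meiotic = c(0.2, 0.6), mitotic = c(0.01, 0.03),
    distance = 0, weight = c(0.5, 0.5)
  )
  expect_equal(posterior_summary(two)$mean, c(0.4, 0.02))

  set.seed(43)
  unif <- point_posterior(0.5, 0.5)
  x <- stats::runif(1e4)
  unif$particles <- tibble::tibble(
    meiotic = x, mitotic = x, distance = 0, weight = rep(1e-4, 1e4)
  )
  s <- posterior_summary(unif)
  expect_lt(abs(s$mean[1] - 0.5), 0.02)
  expect_lt(abs(s$ci_lower[1] - 0.025), 0.01)
  expect_lt(abs(s$ci_upper[1] - 0.975), 0.01)
})

test_that("tidy and glance expose particles and run-level summaries", {
  post <- run_abc(
    c(0.25, 0.5), simulator = function(theta) theta,
    control = abc_config(n_particles = 100, max_iterations = 5),
    seed = 44
  )
  td <- tidy(post)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("meiotic", "mitotic", "distance", "weight"))
  gl <- glance(post)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_particles, 50L)
  expect_equal(gl$n_iterations, post$n_iterations)
  expect_lt(abs(gl$mean_meiotic - 0.25), 0.02)
})
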