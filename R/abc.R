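#' Settings for the adaptive population Monte Carlo ABC sampler
#'
#' @param n_particles Population size `N` (default 2000).
#' @param keep_fraction Fraction `alpha` of the population retained each
#'   iteration (default 0.5, so 1000 particles approximate the posterior at
#'   the default `N`).
#' @param p_acc_min Stopping threshold on the acceptance proportion: the
#'   sampler stops once the fraction of fresh proposals beating the previous
#'   tolerance drops to this value or below (default 0.05).
#' @param n_embryos_per_trial Embryos simulated per parameter pair when
#'   computing its summary statistic (default 1000).
#' @param max_iterations Safety cap on PMC iterations (default 30).
#' @param lookup_n_rep Placements per aneuploid count when the biopsy-class
#'   lookup is built internally (default 8000; see
#'   [biopsy_class_lookup()]).
#' @return An `abc_config` list.
#' @seealso [abc_preset()] for the full/desk presets.
#' @export
abc_config <- function(n_particles = 2000L, keep_fraction = 0.5,
                       p_acc_min = 0.05, n_embryos_per_trial = 1000L,
                       max_iterations = 30L, lookup_n_rep = 8000L) {
  n_particles <- as.integer(n_particles)
  if (is.na(n_particles) || n_particles < 4L) {
    stop("`n_particles` must be an integer >= 4.", call. = FALSE)
  }
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 ||
      keep_fraction >= 1) {
    stop("`keep_fraction` must be in (0, 1).", call. = FALSE)
  }
  if (ceiling(keep_fraction * n_particles) < 2L) {
    stop("Retained set would have fewer than 2 particles.", call. = FALSE)
  }
  structure(
    list(
      n_particles = n_particles,
      keep_fraction = keep_fraction,
      p_acc_min = p_acc_min,
      n_embryos_per_trial = as.integer(n_embryos_per_trial),
      max_iterations = as.integer(max_iterations),
      lookup_n_rep = as.integer(lookup_n_rep)
    ),
    class = "abc_config"
  )
}

#' ABC presets
#'
#' `"full"` mirrors the headline analysis (N = 2000 particles, 1000 embryos
#' per trial, 1000 retained particles); `"desk"` is a reduced preset
#' (N = 600, 200 embryos per trial) for quick exploratory runs and
#' sensitivity sweeps.
#'
#' @param preset `"full"` or `"desk"`.
#' @return An [abc_config()].
#' @export
abc_preset <- function(preset = c("full", "desk")) {
  preset <- match.arg(preset)
  switch(preset,
    full = abc_config(),
    desk = abc_config(n_particles = 600L, n_embryos_per_trial = 200L,
                      lookup_n_rep = 4000L)
  )
}

#' Euclidean distance between summary statistics
#'
#' The ABC discrepancy: the Euclidean distance between a simulated vector of
#' biopsy-class proportions and the target vector, on the raw proportion
#' scale (the three summaries share a scale, so no rescaling is applied).
#'
#' @param sim Numeric vector (or matrix with one row per simulation).
#' @param target Numeric vector of the same length as `sim` rows.
#' @return Non-negative distance(s).
#' @examples
#' abc_distance(c(1, 0, 0), c(0, 1, 0))  # sqrt(2)
#' @export
abc_distance <- function(sim, target) {
  if (is.matrix(sim)) {
    sqrt(colSums((t(sim) - target)^2))
  } else {
    sqrt(sum((sim - target)^2))
  }
}

# batch summary simulation: one row of class proportions per theta row
simulate_summaries_batch <- function(theta, n_embryos, config, lookup) {
  n <- nrow(theta)
  total <- n * n_embryos
  counts <- lineage_counts(
    total,
    rep(theta[, 1L], each = n_embryos),
    rep(theta[, 2L], each = n_embryos),
    config
  )
  cls <- sample_classes(counts, lookup)
  grp <- rep(seq_len(n), each = n_embryos)
  cbind(
    rowsum((cls == 1L) + 0, grp, reorder = FALSE),
    rowsum((cls == 2L) + 0, grp, reorder = FALSE),
    rowsum((cls == 3L) + 0, grp, reorder = FALSE)
  ) / n_embryos
}

#' Infer meiotic and mitotic error rates by adaptive PMC ABC
#'
#' Adaptive population Monte Carlo ABC with uniform(0, 1) priors on both
#' error rates. An initial population of `N` parameter pairs is drawn from
#' the prior and scored by simulating `n_embryos_per_trial` embryos each and
#' measuring the Euclidean distance between simulated and target
#' biopsy-class proportions; the best `ceiling(alpha * N)` pairs are
#' retained and the first tolerance is their largest distance. Each
#' subsequent iteration resamples retained particles by weight, perturbs
#' them with a Gaussian kernel whose per-coordinate variance is twice the
#' weighted empirical variance of the retained set (proposals outside
#' `(0, 1)^2` are redrawn), importance-weights the proposals against the
#' kernel mixture, merges them with the retained set, and keeps the
#' smallest-distance particles. Sampling stops when the fraction of fresh
#' proposals improving on the previous tolerance falls to `p_acc_min`.
#'
#' @param target A target: one row of [published_targets()], a
#'   [target_proportions()] / [generate_synthetic_target()] tibble, or a
#'   bare numeric triple of proportions. With a custom `simulator`, any
#'   numeric vector matching the simulator's summary dimension.
#' @param config A [model_config()]; fixes dispersal, biopsy model and
#'   classification rule for the run.
#' @param control An [abc_config()].
#' @param lookup Optional prebuilt [biopsy_class_lookup()] matching
#'   `config`; built internally when absent.
#' @param simulator Optional replacement simulator for testing:
#'   `function(theta_matrix)` returning one summary row per particle. When
#'   supplied, `config` and `lookup` are ignored.
#' @param seed Optional integer seed applied before any randomness.
#' @param verbose Print each iteration's tolerance and acceptance
#'   proportion.
#' @return An object of class `abc_posterior`: a list with `particles` (a
#'   tibble of `meiotic`, `mitotic`, `distance`, normalised `weight`),
#'   `tolerance_history`, `p_acc_history`, `n_iterations`, `target`,
#'   `control`, `model_config` and `seed`. Supports [tidy()], [glance()],
#'   [posterior_summary()] and [ggplot2::autoplot()].
#' @examples
#' # degenerate simulator: the identity map recovers its target exactly
#' post <- run_abc(c(0.3, 0.7), simulator = function(th) th,
#'                 control = abc_config(n_particles = 200,
#'                                      max_iterations = 8),
#'                 seed = 1)
#' posterior_summary(post)
#' @export
run_abc <- function(target, config = model_config(), control = abc_config(),
                    lookup = NULL, simulator = NULL, seed = NULL,
                    verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  n_total <- control$n_particles
  n_keep <- as.integer(ceiling(control$keep_fraction * n_total))

  if (is.null(simulator)) {
    check_model_config(config)
    target_vec <- as_target_vector(target)
    if (is.null(lookup)) {
      lookup <- biopsy_class_lookup(config, n_rep = control$lookup_n_rep)
    }
    sim_fun <- function(theta) {
      simulate_summaries_batch(theta, control$n_embryos_per_trial, config,
                               lookup)
    }
  } else {
    target_vec <- as.numeric(target)
    sim_fun <- simulator
    config <- NULL
  }

  # initial population from the uniform prior
  theta <- cbind(stats::runif(n_total), stats::runif(n_total))
  dist <- abc_distance(sim_fun(theta), target_vec)
  keep <- order(dist)[seq_len(n_keep)]
  theta <- theta[keep, , drop = FALSE]
  dist <- dist[keep]
  weight <- rep.int(1, n_keep)

  eps <- max(dist)
  tolerance_history <- eps
  p_acc_history <- numeric(0)
  iteration <- 1L
  if (verbose) {
    message(sprintf("iteration %d: epsilon = %.5f", iteration, eps))
  }

  while (iteration < control$max_iterations) {
    w_norm <- weight / sum(weight)
    sd_kernel <- sqrt(pmax(2 * weighted_var_cols(theta, w_norm), 1e-12))

    n_new <- n_total - n_keep
    parent <- sample.int(n_keep, n_new, replace = TRUE, prob = w_norm)
    proposal <- matrix(NA_real_, n_new, 2L)
    for (k in 1:2) {
      proposal[, k] <- stats::rnorm(n_new, theta[parent, k], sd_kernel[k])
    }
    # redraw perturbations that leave the prior support (same parent)
    outside <- which(proposal[, 1] <= 0 | proposal[, 1] >= 1 |
                     proposal[, 2] <= 0 | proposal[, 2] >= 1)
    while (length(outside) > 0L) {
      for (k in 1:2) {
        proposal[outside, k] <- stats::rnorm(length(outside),
                                             theta[parent[outside], k],
                                             sd_kernel[k])
      }
      outside <- outside[proposal[outside, 1] <= 0 |
                         proposal[outside, 1] >= 1 |
                         proposal[outside, 2] <= 0 |
                         proposal[outside, 2] >= 1]
    }

    # importance weight: uniform prior density over the weight-normalised
    # Gaussian kernel mixture evaluated at the proposal
    mix <- kernel_mixture_density(proposal, theta, w_norm, sd_kernel)
    new_weight <- 1 / mix
    if (any(!is.finite(new_weight))) {
      stop("Non-finite particle weight (kernel mixture density ",
           format(min(mix)), "); the retained set may have collapsed.",
           call. = FALSE)
    }

    new_dist <- abc_distance(sim_fun(proposal), target_vec)
    p_acc <- mean(new_dist < eps)

    all_theta <- rbind(theta, proposal)
    all_dist <- c(dist, new_dist)
    all_weight <- c(weight, new_weight)
    keep <- order(all_dist)[seq_len(n_keep)]
    theta <- all_theta[keep, , drop = FALSE]
    dist <- all_dist[keep]
    weight <- all_weight[keep]

    eps <- max(dist)
    iteration <- iteration + 1L
    tolerance_history <- c(tolerance_history, eps)
    p_acc_history <- c(p_acc_history, p_acc)
    if (verbose) {
      message(sprintf("iteration %d: epsilon = %.5f, p_acc = %.3f",
                      iteration, eps, p_acc))
    }
    if (p_acc <= control$p_acc_min) break
  }

  structure(
    list(
      particles = tibble::tibble(
        meiotic = theta[, 1],
        mitotic = theta[, 2],
        distance = dist,
        weight = weight / sum(weight)
      ),
      tolerance_history = tolerance_history,
      p_acc_history = p_acc_history,
      n_iterations = iteration,
      target = target_vec,
      control = control,
      model_config = config,
      seed = seed
    ),
    class = "abc_posterior"
  )
}

weighted_var_cols <- function(x, w) {
  mu <- colSums(x * w)
  colSums((x - rep(mu, each = nrow(x)))^2 * w)
}

# density of the weighted Gaussian kernel mixture at each proposal row
kernel_mixture_density <- function(proposal, centers, w_norm, sd_kernel) {
  n_new <- nrow(proposal)
  out <- numeric(n_new)
  for (i in seq_len(n_new)) {
    out[i] <- sum(
      w_norm *
        stats::dnorm(proposal[i, 1], centers[, 1], sd_kernel[1]) *
        stats::dnorm(proposal[i, 2], centers[, 2], sd_kernel[2])
    )
  }
  out
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat("<abc_posterior> ", nrow(x$particles), " weighted particles, ",
      x$n_iterations, " iterations, final tolerance ",
      format(utils::tail(x$tolerance_history, 1), digits = 4), "\n",
      sep = "")
  s <- posterior_summary(x)
  cat(sprintf("  %s: mean %.4f [%.4f, %.4f]\n", s$parameter, s$mean,
              s$ci_lower, s$ci_upper), sep = "")
  invisible(x)
}

#' Weighted posterior means and credible intervals
#'
#' @param posterior An [run_abc()] result.
#' @param level Credible level (default 0.95).
#' @return A tibble with one row per parameter: `parameter`, `mean`,
#'   `ci_lower`, `ci_upper` (weighted quantiles by cumulative-weight
#'   interpolation, lower tie index).
#' @export
posterior_summary <- function(posterior, level = 0.95) {
  if (!inherits(posterior, "abc_posterior")) {
    stop("`posterior` must be an abc_posterior.", call. = FALSE)
  }
  p <- posterior$particles
  if (nrow(p) == 0L) stop("Empty posterior.", call. = FALSE)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  purrr::map_dfr(c("meiotic", "mitotic"), function(par) {
    x <- p[[par]]
    q <- weighted_quantile(x, p$weight, probs)
    tibble::tibble(
      parameter = par,
      mean = sum(x * p$weight),
      ci_lower = q[1],
      ci_upper = q[2]
    )
  })
}

#' Weighted quantiles by cumulative-weight interpolation
#'
#' Sorts the sample, interpolates the cumulative normalised weight linearly
#' against the ordered values, and reads quantiles off that curve; exact
#' ties in cumulative weight resolve to the lower index. Used for posterior
#' credible intervals.
#'
#' @param x Numeric sample.
#' @param w Non-negative weights.
#' @param probs Quantile probabilities.
#' @return Numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  if (length(x) == 1L) return(rep(x, length(probs)))
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  stats::approx(cw, x[ord], xout = probs, ties = min, rule = 2)$y
}

#' A degenerate single-particle posterior
#'
#' Convenience constructor for a point-mass `abc_posterior` at known rates,
#' useful for predictive simulation at fixed parameters and in tests.
#'
#' @param meiotic,mitotic Error probabilities.
#' @return An `abc_posterior` with one particle of weight 1.
#' @export
point_posterior <- function(meiotic, mitotic) {
  check_prob(meiotic, "meiotic")
  check_prob(mitotic, "mitotic")
  structure(
    list(
      particles = tibble::tibble(
        meiotic = meiotic, mitotic = mitotic, distance = 0, weight = 1
      ),
      tolerance_history = numeric(0),
      p_acc_history = numeric(0),
      n_iterations = 0L,
      target = NULL,
      control = NULL,
      model_config = NULL,
      seed = NULL
    ),
    class = "abc_posterior"
  )
}
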