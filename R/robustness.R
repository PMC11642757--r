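#' Reassign a fraction of mosaic biopsies to model misclassification
#'
#' Models over-diagnosis of mosaicism: a fraction `rate` of the mosaic
#' biopsy proportion is removed and reassigned evenly to the euploid and
#' aneuploid classes (half to each). The adjusted proportions are exact:
#' `euploid + rate * mosaic / 2`, `mosaic * (1 - rate)`,
#' `aneuploid + rate * mosaic / 2`, and remain on the simplex.
#'
#' @param target A target (one-row tibble or numeric triple).
#' @param rate Misclassification rate in `[0, 1]`.
#' @return A one-row target tibble with study label suffixed
#'   `"+misclass<rate>"`.
#' @examples
#' adjust_target(c(0.232, 0.187, 0.581), rate = 0.5)
#' @export
adjust_target <- function(target, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0 ||
      rate > 1) {
    stop("`rate` must be a number in [0, 1].", call. = FALSE)
  }
  p <- as_target_vector(target)
  study <- if (is.data.frame(target)) target$study else "custom"
  tibble::tibble(
    study = paste0(study, "+misclass", format(rate)),
    prop_euploid = p[[1]] + rate * p[[2]] / 2,
    prop_mosaic = p[[2]] * (1 - rate),
    prop_aneuploid = p[[3]] + rate * p[[2]] / 2,
    n_biopsies = NA_integer_
  )
}

#' Misclassification sensitivity sweep
#'
#' For each misclassification rate and dispersal level: adjust the target
#' with [adjust_target()], re-run ABC against the adjusted target, draw a
#' posterior-predictive embryo sample, and record the inferred whole-embryo
#' type proportions alongside the posterior means. This reproduces the
#' robustness analysis in which mosaic biopsies are progressively assumed
#' to be technical false positives.
#'
#' @param target Base target (one-row tibble or numeric triple).
#' @param rates Misclassification rates (default `seq(0, 1, by = 0.1)`).
#' @param dispersals Dispersal levels (default `c(0, 0.5, 1)`).
#' @param control An [abc_config()]; the desk preset by default, since the
#'   sweep multiplies ABC runs.
#' @param n_draws,n_embryos_per_draw Predictive sample size per cell
#'   (default 1000 x 1000).
#' @param config Base [model_config()]; its dispersal field is overridden
#'   per sweep cell.
#' @param seed Optional integer seed applied once before the sweep.
#' @param verbose Print progress per cell.
#' @return A tibble with one row per rate x dispersal: the adjusted target
#'   proportions, posterior means `mean_meiotic` / `mean_mitotic`, and the
#'   predictive embryo-type proportions `prop_fully_euploid`,
#'   `prop_mosaic_embryo`, `prop_fully_aneuploid`.
#' @export
run_misclassification_sweep <- function(target,
                                        rates = seq(0, 1, by = 0.1),
                                        dispersals = c(0, 0.5, 1),
                                        control = abc_preset("desk"),
                                        n_draws = 1000L,
                                        n_embryos_per_draw = 1000L,
                                        config = model_config(),
                                        seed = NULL,
                                        verbose = FALSE) {
  if (anyNA(rates) || any(rates < 0) || any(rates > 1)) {
    stop("`rates` must lie in [0, 1].", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(dispersal = dispersals, rate = rates)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    dispersal <- grid$dispersal[i]
    rate <- grid$rate[i]
    if (verbose) {
      message(sprintf("sweep: dispersal %.1f, rate %.1f", dispersal, rate))
    }
    cfg <- replace_dispersal(config, dispersal)
    adjusted <- adjust_target(target, rate)
    fit <- run_abc(adjusted, config = cfg, control = control)
    cell_summary(fit, adjusted, cfg, n_draws, n_embryos_per_draw) |>
      dplyr::mutate(rate = rate, .before = 1)
  })
}

#' Multi-dataset inference battery
#'
#' Runs the full inference-plus-predictive pipeline for every study x
#' dispersal combination: ABC against each published (or custom) target,
#' then a posterior-predictive embryo sample tabulated into whole-embryo
#' type proportions. One row per combination, mirroring the published
#' summary table's column order.
#'
#' @param targets A target catalog tibble (default [published_targets()]);
#'   any subset of rows works.
#' @param dispersals Dispersal levels (default `c(0, 0.5, 1)`).
#' @param control An [abc_config()]; desk preset by default, with full-scale
#'   settings available via `abc_preset("full")`.
#' @param n_draws,n_embryos_per_draw Predictive sample size (default
#'   1000 x 1000).
#' @param config Base [model_config()]; dispersal overridden per row.
#' @param seed Optional integer seed applied once before the battery.
#' @param verbose Print progress per row.
#' @return A tibble with one row per study x dispersal: target proportions,
#'   posterior means, and predictive embryo-type proportions.
#' @export
run_dataset_battery <- function(targets = published_targets(),
                                dispersals = c(0, 0.5, 1),
                                control = abc_preset("desk"),
                                n_draws = 1000L,
                                n_embryos_per_draw = 1000L,
                                config = model_config(),
                                seed = NULL,
                                verbose = FALSE) {
  if (nrow(targets) < 1L) stop("Need at least one target.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(dispersal = dispersals,
                             row = seq_len(nrow(targets)))
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    dispersal <- grid$dispersal[i]
    target <- targets[grid$row[i], ]
    if (verbose) {
      message(sprintf("battery: %s, dispersal %.1f", target$study,
                      dispersal))
    }
    cfg <- replace_dispersal(config, dispersal)
    fit <- run_abc(target, config = cfg, control = control)
    cell_summary(fit, target, cfg, n_draws, n_embryos_per_draw)
  })
}

replace_dispersal <- function(config, dispersal) {
  model_config(
    n_rounds = config$n_rounds,
    biopsy_size = config$biopsy_size,
    dispersal = dispersal,
    classification_rule = config$classification_rule,
    mitotic_convention = config$mitotic_convention
  )
}

# one summary row: posterior means + predictive embryo-type proportions
cell_summary <- function(fit, target, config, n_draws, n_embryos_per_draw) {
  means <- posterior_summary(fit)
  pred <- simulate_predictive(fit, config, n_draws = n_draws,
                              n_embryos_per_draw = n_embryos_per_draw)
  types <- predictive_tables(pred)$embryo_types
  tibble::tibble(
    study = target$study,
    dispersal = config$dispersal,
    prop_euploid = target$prop_euploid,
    prop_mosaic = target$prop_mosaic,
    prop_aneuploid = target$prop_aneuploid,
    mean_meiotic = means$mean[means$parameter == "meiotic"],
    mean_mitotic = means$mean[means$parameter == "mitotic"],
    prop_fully_euploid =
      types$proportion[types$embryo_type == "fully_euploid"],
    prop_mosaic_embryo = types$proportion[types$embryo_type == "mosaic"],
    prop_fully_aneuploid =
      types$proportion[types$embryo_type == "fully_aneuploid"]
  )
}
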