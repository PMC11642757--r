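#' Classify whole embryos by aneuploid cell count
#'
#' An embryo is `fully_euploid` with zero aneuploid cells, `fully_aneuploid`
#' when every cell is aneuploid, and `mosaic` whenever any but not all cells
#' are aneuploid. Vectorised.
#'
#' @param n_aneuploid Integer vector of aneuploid cell counts.
#' @param n_cells Total cells per embryo (default 256).
#' @return Factor with levels `fully_euploid`, `mosaic`, `fully_aneuploid`.
#' @examples
#' classify_embryo(c(0, 1, 255, 256))
#' @export
classify_embryo <- function(n_aneuploid, n_cells = 256L) {
  if (anyNA(n_aneuploid) || any(n_aneuploid < 0) ||
      any(n_aneuploid > n_cells)) {
    stop("`n_aneuploid` must be in 0..n_cells.", call. = FALSE)
  }
  lev <- embryo_type_levels()
  factor(
    ifelse(n_aneuploid == 0L, lev[1],
           ifelse(n_aneuploid == n_cells, lev[3], lev[2])),
    levels = lev
  )
}

embryo_type_levels <- function() c("fully_euploid", "mosaic", "fully_aneuploid")

#' Posterior-predictive embryo sample with two biopsies per embryo
#'
#' Draws `n_draws` error-rate pairs from the posterior (weighted, with
#' replacement), simulates `n_embryos_per_draw` embryos for each, places
#' their aneuploid cells at the configured dispersal, and takes two 5-cell
#' biopsies per embryo: the first anchored at the default index cell, the
#' second at a uniformly drawn index cell (overlap with the first biopsy is
#' permitted — the embryo is re-biopsied intact). Both biopsies are
#' classified with the 20%/70% thresholds unless the configuration says
#' otherwise.
#'
#' The defaults (1000 draws x 1000 embryos) reproduce the million-embryo
#' predictive samples used to characterise whole-embryo karyotype
#' composition; scale down for exploratory runs.
#'
#' @param posterior An [run_abc()] or [point_posterior()] object.
#' @param config A [model_config()].
#' @param n_draws Number of posterior draws (default 1000).
#' @param n_embryos_per_draw Embryos per draw (default 1000).
#' @param geometry Optional geometry (defaults to the cached one).
#' @param seed Optional integer seed applied before any randomness.
#' @return A tibble of class `predictive_sample`, one row per embryo:
#'   `draw`, `meiotic`, `mitotic`, `n_aneuploid`, `embryo_type`,
#'   `biopsy1_count`, `biopsy1_class`, `biopsy2_count`, `biopsy2_class`.
#'   The configuration, draw counts and seed are attached as attribute
#'   `provenance`.
#' @export
simulate_predictive <- function(posterior, config = model_config(),
                                n_draws = 1000L, n_embryos_per_draw = 1000L,
                                geometry = NULL, seed = NULL) {
  if (!inherits(posterior, "abc_posterior")) {
    stop("`posterior` must be an abc_posterior.", call. = FALSE)
  }
  check_model_config(config)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(geometry)) geometry <- default_geometry(config$n_cells)
  n_draws <- as.integer(n_draws)
  n_embryos_per_draw <- as.integer(n_embryos_per_draw)

  p <- posterior$particles
  idx <- sample.int(nrow(p), n_draws, replace = TRUE, prob = p$weight)
  total <- n_draws * n_embryos_per_draw
  meiotic <- rep(p$meiotic[idx], each = n_embryos_per_draw)
  mitotic <- rep(p$mitotic[idx], each = n_embryos_per_draw)

  counts <- lineage_counts(total, meiotic, mitotic, config)
  biopsies <- cpp_two_biopsies(
    nbr0(geometry),
    biopsy_cells(geometry, biopsy_size = config$biopsy_size) - 1L,
    as.integer(counts),
    config$dispersal
  )
  codes <- class_codes(config$biopsy_size, config$classification_rule)
  lev <- biopsy_class_levels()

  out <- tibble::tibble(
    draw = rep(seq_len(n_draws), each = n_embryos_per_draw),
    meiotic = meiotic,
    mitotic = mitotic,
    n_aneuploid = as.integer(counts),
    embryo_type = classify_embryo(as.integer(counts), config$n_cells),
    biopsy1_count = biopsies[, 1L],
    biopsy1_class = factor(lev[codes[biopsies[, 1L] + 1L]], levels = lev),
    biopsy2_count = biopsies[, 2L],
    biopsy2_class = factor(lev[codes[biopsies[, 2L] + 1L]], levels = lev)
  )
  attr(out, "provenance") <- list(
    config = config, n_draws = n_draws,
    n_embryos_per_draw = n_embryos_per_draw, seed = seed
  )
  class(out) <- c("predictive_sample", class(out))
  out
}

#' Tabulate a posterior-predictive embryo sample
#'
#' Builds the four summary tables of a predictive sample: whole-embryo type
#' proportions, the aneuploid-cell-fraction histogram, the first-biopsy
#' class by embryo type cross-tabulation (with the share of each biopsy
#' class contributed by each embryo type), and the first-by-second biopsy
#' cross-tabulation with per-class concordance.
#'
#' @param sample A [simulate_predictive()] tibble.
#' @param hist_bins Number of equal-width bins for the exported
#'   aneuploid-fraction histogram summary (default 20; exact per-count
#'   tallies are always included).
#' @return A list of class `predictive_tables`:
#'   * `embryo_types`: tibble of `embryo_type`, `n`, `proportion`;
#'   * `aneuploid_fraction`: tibble of exact `n_aneuploid` tallies plus a
#'     `bin` column for the coarse histogram;
#'   * `biopsy_by_embryo`: long tibble of `biopsy_class`, `embryo_type`,
#'     `n`, `share_of_biopsy_class`;
#'   * `rebiopsy`: long tibble of `first_class`, `second_class`, `n`,
#'     `share_of_first_class`;
#'   * `concordance`: tibble of `first_class`, `concordance`;
#'   plus the sample's provenance.
#' @export
predictive_tables <- function(sample, hist_bins = 20L) {
  if (!inherits(sample, "predictive_sample")) {
    stop("`sample` must come from simulate_predictive().", call. = FALSE)
  }
  n_total <- nrow(sample)
  n_cells <- attr(sample, "provenance")$config$n_cells

  embryo_types <- sample |>
    dplyr::count(.data$embryo_type, .drop = FALSE, name = "n") |>
    dplyr::mutate(proportion = .data$n / n_total)

  aneuploid_fraction <- sample |>
    dplyr::count(.data$n_aneuploid, name = "n") |>
    dplyr::mutate(
      fraction = .data$n_aneuploid / n_cells,
      bin = pmin(floor(.data$fraction * hist_bins) + 1L, hist_bins)
    )

  biopsy_by_embryo <- sample |>
    dplyr::count(biopsy_class = .data$biopsy1_class,
                 .data$embryo_type, .drop = FALSE, name = "n") |>
    dplyr::group_by(.data$biopsy_class) |>
    dplyr::mutate(
      share_of_biopsy_class = if (sum(.data$n) > 0) {
        .data$n / sum(.data$n)
      } else {
        NA_real_
      }
    ) |>
    dplyr::ungroup()

  rebiopsy <- sample |>
    dplyr::count(first_class = .data$biopsy1_class,
                 second_class = .data$biopsy2_class,
                 embryo_type = .data$embryo_type,
                 .drop = FALSE, name = "n")

  concordance <- rebiopsy |>
    dplyr::group_by(.data$first_class) |>
    dplyr::summarise(
      concordance = {
        total <- sum(.data$n)
        if (total > 0) {
          sum(.data$n[.data$second_class == .data$first_class[1]]) / total
        } else {
          NA_real_
        }
      },
      n = sum(.data$n),
      .groups = "drop"
    )

  structure(
    list(
      embryo_types = embryo_types,
      aneuploid_fraction = aneuploid_fraction,
      biopsy_by_embryo = biopsy_by_embryo,
      rebiopsy = rebiopsy,
      concordance = concordance,
      provenance = attr(sample, "provenance")
    ),
    class = "predictive_tables"
  )
}

#' @export
print.predictive_tables <- function(x, ...) {
  cat("<predictive_tables>\n")
  cat("embryo types:\n")
  print(x$embryo_types)
  cat("rebiopsy concordance by first-biopsy class:\n")
  print(x$concordance)
  invisible(x)
}
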