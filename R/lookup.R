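#' Monte-Carlo lookup of biopsy-class probabilities by aneuploid cell count
#'
#' Biopsy class depends on the embryo only through its aneuploid cell count,
#' the dispersal level and the (fixed) geometry, so repeated simulation can
#' be accelerated by tabulating, once per dispersal, the probability of each
#' biopsy class for every possible aneuploid count. Each of the
#' `n_cells - 1` non-degenerate counts is placed `n_rep` times and biopsied
#' at the default index cell; the degenerate counts 0 and `n_cells` are
#' exact. ABC and synthetic-target generation sample biopsy classes from
#' this table; its agreement with direct placement-and-biopsy simulation is
#' within Monte-Carlo error (and exactly hypergeometric at dispersal 1).
#'
#' Building the table consumes the R random number stream, so a seeded
#' pipeline that builds it inline remains reproducible end to end.
#'
#' @param config A [model_config()]; supplies dispersal, biopsy size and the
#'   classification rule.
#' @param geometry Optional [make_geometry()]; defaults to the cached
#'   geometry for `config$n_cells`.
#' @param n_rep Placements per aneuploid count (default 8000).
#' @return A tibble of class `biopsy_class_lookup` with one row per
#'   aneuploid count `0..n_cells`: `n_aneuploid`, `p_euploid`, `p_mosaic`,
#'   `p_aneuploid`. The raw biopsy-count tallies are attached as attribute
#'   `count_table` ( `(n_cells + 1)` x `(biopsy_size + 1)` ).
#' @export
biopsy_class_lookup <- function(config = model_config(), geometry = NULL,
                                n_rep = 8000L) {
  check_model_config(config)
  if (is.null(geometry)) geometry <- default_geometry(config$n_cells)
  counts <- cpp_biopsy_count_table(
    nbr0(geometry),
    biopsy_cells(geometry, biopsy_size = config$biopsy_size) - 1L,
    config$dispersal,
    as.integer(n_rep)
  )
  probs <- class_probs_from_counts(counts, config)
  out <- tibble::tibble(
    n_aneuploid = 0:config$n_cells,
    p_euploid = probs[, 1],
    p_mosaic = probs[, 2],
    p_aneuploid = probs[, 3]
  )
  attr(out, "count_table") <- counts
  attr(out, "config") <- config
  class(out) <- c("biopsy_class_lookup", class(out))
  out
}

class_probs_from_counts <- function(counts, config) {
  codes <- class_codes(config$biopsy_size, config$classification_rule)
  probs <- vapply(
    1:3,
    function(k) rowSums(counts[, codes == k, drop = FALSE]),
    numeric(nrow(counts))
  )
  probs / rowSums(counts)
}

# cumulative class probabilities (euploid, euploid + mosaic) for fast
# inverse-CDF class sampling, indexed by n_aneuploid + 1
lookup_cum <- function(lookup) {
  cbind(lookup$p_euploid, lookup$p_euploid + lookup$p_mosaic)
}

#' Simulate biopsy-class proportions for one error-rate pair
#'
#' Runs the full generative chain — meiotic/mitotic lineage, spatial
#' placement at the configured dispersal, a single biopsy at the default
#' index cell, classification — for `n_embryos` embryos and returns the
#' proportions of euploid, mosaic and aneuploid biopsies (the ABC summary
#' statistic).
#'
#' @param meiotic,mitotic Error probabilities in `[0, 1]`.
#' @param config A [model_config()].
#' @param n_embryos Number of embryos (default 1000, one ABC trial).
#' @param lookup Optional [biopsy_class_lookup()] matching `config`; when
#'   supplied, biopsy classes are sampled from the lookup instead of placing
#'   every embryo, which is exact up to the lookup's Monte-Carlo error.
#' @param geometry Optional geometry (defaults to the cached one).
#' @return A named numeric vector `c(prop_euploid, prop_mosaic,
#'   prop_aneuploid)` summing to 1.
#' @examples
#' set.seed(1)
#' simulate_biopsy_proportions(0.58, 0.015, model_config(dispersal = 1),
#'                             n_embryos = 500)
#' @export
simulate_biopsy_proportions <- function(meiotic, mitotic,
                                        config = model_config(),
                                        n_embryos = 1000L,
                                        lookup = NULL, geometry = NULL) {
  check_model_config(config)
  check_prob(meiotic, "meiotic")
  check_prob(mitotic, "mitotic")
  n_embryos <- as.integer(n_embryos)
  if (is.na(n_embryos) || n_embryos < 1L) {
    stop("`n_embryos` must be a positive integer.", call. = FALSE)
  }
  counts <- lineage_counts(n_embryos, rep_len(meiotic, n_embryos),
                           rep_len(mitotic, n_embryos), config)
  if (is.null(lookup)) {
    if (is.null(geometry)) geometry <- default_geometry(config$n_cells)
    bcount <- cpp_two_biopsies(
      nbr0(geometry),
      biopsy_cells(geometry, biopsy_size = config$biopsy_size) - 1L,
      as.integer(counts),
      config$dispersal
    )[, 1]
    cls <- class_codes(config$biopsy_size,
                       config$classification_rule)[bcount + 1L]
  } else {
    cls <- sample_classes(counts, lookup)
  }
  props <- tabulate(cls, nbins = 3L) / n_embryos
  stats::setNames(props, paste0("prop_", biopsy_class_levels()))
}

# sample biopsy class codes (1/2/3) from a lookup given aneuploid counts
sample_classes <- function(n_aneuploid, lookup) {
  cum <- lookup_cum(lookup)
  u <- stats::runif(length(n_aneuploid))
  idx <- n_aneuploid + 1L
  1L + (u > cum[idx, 1L]) + (u > cum[idx, 2L])
}
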