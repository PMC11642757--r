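#' Simulate embryo lineages under meiotic and mitotic error rates
#'
#' A meiotic error (probability `meiotic` per meiosis) produces a zygote in
#' which every descendant cell is aneuploid. Otherwise the zygote is euploid
#' and the embryo grows through `n_rounds` synchronous divisions during which
#' euploid cells can found aneuploid clones by mitotic error; aneuploid cells
#' breed true. Under the default `per_daughter` convention each daughter of a
#' euploid division independently becomes aneuploid with probability
#' `mitotic`, so the euploid cell count follows the binomial recursion
#' `E_{r+1} ~ Binomial(2 E_r, 1 - mitotic)` from `E_0 = 1`. Under
#' `per_division_both_daughters` the division errs as a unit:
#' `E_{r+1} = 2 Binomial(E_r, 1 - mitotic)`.
#'
#' Closed forms under `per_daughter` (used as test oracles): an embryo is
#' fully euploid with probability
#' `(1 - meiotic) * (1 - mitotic)^(2 (2^n_rounds - 1))`, and the expected
#' aneuploid cell fraction is
#' `meiotic + (1 - meiotic) * (1 - (1 - mitotic)^n_rounds)`.
#'
#' @param n_embryos Number of embryos to simulate.
#' @param meiotic,mitotic Error probabilities in `[0, 1]`; either scalars or
#'   vectors of length `n_embryos` (one pair per embryo).
#' @param config A [model_config()].
#' @return A tibble with one row per embryo: `meiotic`, `mitotic` (the rates
#'   used), `meiotic_error` (logical) and `n_aneuploid` (integer in
#'   `0..n_cells`).
#' @examples
#' set.seed(1)
#' simulate_lineages(5, meiotic = 0.5, mitotic = 0.02, model_config())
#' @export
simulate_lineages <- function(n_embryos, meiotic, mitotic,
                              config = model_config()) {
  check_model_config(config)
  n_embryos <- as.integer(n_embryos)
  if (is.na(n_embryos) || n_embryos < 1L) {
    stop("`n_embryos` must be a positive integer.", call. = FALSE)
  }
  check_prob(meiotic, "meiotic", n_embryos)
  check_prob(mitotic, "mitotic", n_embryos)
  meiotic <- rep_len(meiotic, n_embryos)
  mitotic <- rep_len(mitotic, n_embryos)

  n_aneuploid <- lineage_counts(n_embryos, meiotic, mitotic, config)
  tibble::tibble(
    meiotic = meiotic,
    mitotic = mitotic,
    meiotic_error = attr(n_aneuploid, "is_meiotic"),
    n_aneuploid = as.integer(n_aneuploid)
  )
}

# vectorised core: returns the per-embryo aneuploid cell count, with the
# meiotic-error indicator attached as an attribute
lineage_counts <- function(n, meiotic, mitotic, config) {
  is_meiotic <- stats::runif(n) < meiotic
  euploid <- rep.int(1L, n)
  if (config$mitotic_convention == "per_daughter") {
    for (r in seq_len(config$n_rounds)) {
      euploid <- stats::rbinom(n, 2L * euploid, 1 - mitotic)
    }
  } else {
    for (r in seq_len(config$n_rounds)) {
      euploid <- 2L * stats::rbinom(n, euploid, 1 - mitotic)
    }
  }
  counts <- config$n_cells - euploid
  counts[is_meiotic] <- config$n_cells
  attr(counts, "is_meiotic") <- is_meiotic
  counts
}

check_prob <- function(p, name, n = NULL) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("`", name, "` must be probabilities in [0, 1].", call. = FALSE)
  }
  if (!is.null(n) && !(length(p) %in% c(1L, n))) {
    stop("`", name, "` must have length 1 or n_embryos.", call. = FALSE)
  }
  invisible(p)
}
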