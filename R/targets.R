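#' Published PGT-A biopsy-class proportions
#'
#' The four published clinical datasets used as inference targets, as
#' printed in their source reports: per-study proportions of euploid, mosaic
#' and aneuploid trophectoderm biopsies (whole-chromosome aneuploidies
#' only). The Capalbo et al. entry carries its precise proportions
#' (23.2% / 18.7% / 58.1% of 6,766 biopsies) by default; with
#' `rounded = TRUE` all studies are returned at two-decimal precision as
#' tabulated alongside the other three.
#'
#' These values are frozen constants; inference defaults to the most precise
#' form available per study.
#'
#' @param rounded Return two-decimal proportions for every study (default
#'   `FALSE`: most precise available).
#' @return A tibble with columns `study`, `prop_euploid`, `prop_mosaic`,
#'   `prop_aneuploid`, `n_biopsies` (NA where the source does not print a
#'   usable total).
#' @examples
#' published_targets()
#' @export
published_targets <- function(rounded = FALSE) {
  if (rounded) {
    tibble::tibble(
      study = c("capalbo", "clarke", "munne", "rodrigo"),
      prop_euploid = c(0.23, 0.49, 0.53, 0.51),
      prop_mosaic = c(0.19, 0.18, 0.15, 0.06),
      prop_aneuploid = c(0.58, 0.33, 0.32, 0.43),
      n_biopsies = c(6766L, NA_integer_, NA_integer_, NA_integer_)
    )
  } else {
    tibble::tibble(
      study = c("capalbo", "clarke", "munne", "rodrigo"),
      prop_euploid = c(0.232, 0.49, 0.53, 0.51),
      prop_mosaic = c(0.187, 0.18, 0.15, 0.06),
      prop_aneuploid = c(0.581, 0.33, 0.32, 0.43),
      n_biopsies = c(6766L, NA_integer_, NA_integer_, NA_integer_)
    )
  }
}

#' Construct and validate a target-proportion record
#'
#' @param prop_euploid,prop_mosaic,prop_aneuploid Biopsy-class proportions;
#'   must lie on the unit simplex within `tolerance` (printed values are
#'   renormalised to sum exactly to 1).
#' @param study Label for the target (default `"custom"`).
#' @param n_biopsies Optional biopsy count behind the proportions.
#' @param tolerance Allowed deviation of the printed sum from 1 (default
#'   0.005, printed-rounding slack).
#' @return A one-row tibble in the same shape as [published_targets()].
#' @export
target_proportions <- function(prop_euploid, prop_mosaic, prop_aneuploid,
                               study = "custom", n_biopsies = NA_integer_,
                               tolerance = 0.005) {
  p <- c(prop_euploid, prop_mosaic, prop_aneuploid)
  if (length(p) != 3L || anyNA(p) || any(p < 0)) {
    stop("Proportions must be three non-negative numbers.", call. = FALSE)
  }
  if (abs(sum(p) - 1) > tolerance) {
    stop("Proportions sum to ", format(sum(p)), "; expected 1 within ",
         tolerance, ".", call. = FALSE)
  }
  p <- p / sum(p)
  tibble::tibble(
    study = study,
    prop_euploid = p[1],
    prop_mosaic = p[2],
    prop_aneuploid = p[3],
    n_biopsies = as.integer(n_biopsies)
  )
}

# coerce a target (one-row tibble, named or bare length-3 numeric) to a
# renormalised numeric triple
as_target_vector <- function(target, tolerance = 0.005) {
  if (is.data.frame(target)) {
    if (nrow(target) != 1L) {
      stop("`target` must be a single target (one row).", call. = FALSE)
    }
    p <- c(target$prop_euploid, target$prop_mosaic, target$prop_aneuploid)
  } else {
    p <- as.numeric(target)
  }
  if (length(p) != 3L || anyNA(p) || any(p < 0)) {
    stop("`target` must supply three non-negative proportions.",
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > tolerance) {
    stop("Target proportions sum to ", format(sum(p)),
         "; expected 1 within ", tolerance, ".", call. = FALSE)
  }
  stats::setNames(p / sum(p), paste0("prop_", biopsy_class_levels()))
}

#' Generate a synthetic biopsy-proportion target from known error rates
#'
#' Simulates PGT-A-style targets with known ground truth for
#' parameter-recovery testing: `n_biopsies` embryos are generated at the
#' true rates, each biopsied once at the default index cell through the full
#' spatial chain, and the resulting class proportions are returned in the
#' same shape as [published_targets()] entries, so inference treats real and
#' synthetic targets interchangeably. `n_biopsies = Inf` requests the
#' noise-free limit, approximated with 100,000 embryos.
#'
#' @param meiotic,mitotic True error probabilities.
#' @param config A [model_config()] (fixes dispersal and the biopsy model).
#' @param n_biopsies Biopsies behind the target; finite for multinomial
#'   sampling noise at a realistic study size, `Inf` for (near) noise-free.
#' @param study Label stored with the target.
#' @return A one-row tibble: `study`, the three proportions, `n_biopsies`,
#'   plus the true rates as columns `true_meiotic`, `true_mitotic`.
#' @examples
#' set.seed(1)
#' generate_synthetic_target(0.45, 0.02, model_config(dispersal = 1),
#'                           n_biopsies = 2000)
#' @export
generate_synthetic_target <- function(meiotic, mitotic,
                                      config = model_config(),
                                      n_biopsies = Inf,
                                      study = "synthetic") {
  check_prob(meiotic, "meiotic")
  check_prob(mitotic, "mitotic")
  n <- if (is.infinite(n_biopsies)) 100000L else as.integer(n_biopsies)
  if (is.na(n) || n < 1L) {
    stop("`n_biopsies` must be a positive integer or Inf.", call. = FALSE)
  }
  props <- simulate_biopsy_proportions(meiotic, mitotic, config,
                                       n_embryos = n)
  out <- tibble::tibble(
    study = study,
    prop_euploid = props[[1]],
    prop_mosaic = props[[2]],
    prop_aneuploid = props[[3]],
    n_biopsies = if (is.infinite(n_biopsies)) NA_integer_ else n
  )
  out$true_meiotic <- meiotic
  out$true_mitotic <- mitotic
  out
}

#' Write or read target proportions as a tab-separated file
#'
#' @param target A one-row (or multi-row catalog) target tibble.
#' @param path File path.
#' @return `write_target()` returns `path` invisibly; `read_target()` a
#'   validated tibble.
#' @export
write_target <- function(target, path) {
  write_tsv_six(target, path)
  invisible(path)
}

#' @rdname write_target
#' @export
read_target <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE)
  out <- purrr::map_dfr(seq_len(nrow(raw)), function(i) {
    target_proportions(
      raw$prop_euploid[i], raw$prop_mosaic[i], raw$prop_aneuploid[i],
      study = if ("study" %in% names(raw)) raw$study[i] else "custom",
      n_biopsies = if ("n_biopsies" %in% names(raw)) raw$n_biopsies[i]
                   else NA_integer_
    )
  })
  out
}
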