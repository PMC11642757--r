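#' Embryo-model configuration
#'
#' Collects the structural parameters of the embryo and biopsy model: the
#' number of mitotic division rounds (8 rounds giving a 256-cell blastocyst),
#' the biopsy size (5 trophectoderm cells), the spatial dispersal of
#' aneuploid cells, the biopsy classification rule and the mitotic-error
#' convention.
#'
#' Dispersal controls how aneuploid clones are arranged on the embryo
#' surface: 0 grows a single contiguous patch, 1 scatters aneuploid cells as
#' a uniform random subset, and intermediate values seed
#' `round(dispersal * n_aneuploid)` clusters that grow outward.
#'
#' Two classification rules are supported for a biopsy with `a` of `b` cells
#' aneuploid: `"threshold_20_70"` (euploid if `a/b < 0.2`, mosaic if
#' `0.2 <= a/b <= 0.7`, aneuploid if `a/b > 0.7` — the clinical copy-number
#' thresholds) and `"any_but_not_all"` (euploid only at 0, aneuploid only at
#' `b`, mosaic otherwise). For 5-cell biopsies the rules disagree only at
#' 4/5 aneuploid cells.
#'
#' Two mitotic conventions are supported, sharing the same per-cell marginal
#' euploid probability `(1 - mitotic)^n_rounds` but differing in clone
#' correlation: `"per_daughter"` (each daughter of a euploid division
#' independently becomes aneuploid with the mitotic probability; the default)
#' and `"per_division_both_daughters"` (the division itself errs with that
#' probability, making both daughters aneuploid).
#'
#' @param n_rounds Number of division rounds; the final cell count is
#'   `2^n_rounds`. Default 8.
#' @param biopsy_size Cells per biopsy (default 5).
#' @param dispersal Spatial dispersal of aneuploid cells, in `[0, 1]`.
#' @param classification_rule Biopsy classification rule (see Details).
#' @param mitotic_convention Mitotic-error convention (see Details).
#' @return A `model_config` list with the validated fields plus `n_cells`.
#' @examples
#' model_config(dispersal = 1)
#' @export
model_config <- function(n_rounds = 8L,
                         biopsy_size = 5L,
                         dispersal = 1,
                         classification_rule = c("threshold_20_70",
                                                 "any_but_not_all"),
                         mitotic_convention = c("per_daughter",
                                                "per_division_both_daughters")) {
  n_rounds <- as.integer(n_rounds)
  biopsy_size <- as.integer(biopsy_size)
  classification_rule <- match.arg(classification_rule)
  mitotic_convention <- match.arg(mitotic_convention)
  if (is.na(n_rounds) || n_rounds < 1L) {
    stop("`n_rounds` must be a positive integer.", call. = FALSE)
  }
  n_cells <- as.integer(2^n_rounds)
  if (is.na(biopsy_size) || biopsy_size < 1L || biopsy_size > n_cells) {
    stop("`biopsy_size` must be in 1..n_cells.", call. = FALSE)
  }
  if (!is.numeric(dispersal) || length(dispersal) != 1L || is.na(dispersal) ||
      dispersal < 0 || dispersal > 1) {
    stop("`dispersal` must be a number in [0, 1].", call. = FALSE)
  }
  structure(
    list(
      n_rounds = n_rounds,
      n_cells = n_cells,
      biopsy_size = biopsy_size,
      dispersal = as.numeric(dispersal),
      classification_rule = classification_rule,
      mitotic_convention = mitotic_convention
    ),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  cat("  n_rounds:            ", x$n_rounds, " (", x$n_cells, " cells)\n",
      sep = "")
  cat("  biopsy_size:         ", x$biopsy_size, "\n", sep = "")
  cat("  dispersal:           ", x$dispersal, "\n", sep = "")
  cat("  classification_rule: ", x$classification_rule, "\n", sep = "")
  cat("  mitotic_convention:  ", x$mitotic_convention, "\n", sep = "")
  invisible(x)
}

check_model_config <- function(config) {
  if (!inherits(config, "model_config")) {
    stop("`config` must be created with model_config().", call. = FALSE)
  }
  config
}

#' Write or read a model configuration as plain `key: value` text
#'
#' The round trip is exact: `read_model_config(write_model_config(cfg, f))`
#' reproduces `cfg` field for field (dispersal is serialised at full
#' precision).
#'
#' @param config A [model_config()] object.
#' @param path File path.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns a `model_config`.
#' @export
write_model_config <- function(config, path) {
  check_model_config(config)
  fields <- c(
    n_rounds = as.character(config$n_rounds),
    biopsy_size = as.character(config$biopsy_size),
    dispersal = format(config$dispersal, digits = 17),
    classification_rule = config$classification_rule,
    mitotic_convention = config$mitotic_convention
  )
  writeLines(paste0(names(fields), ": ", fields), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  kv <- read_key_value(path)
  model_config(
    n_rounds = as.integer(kv[["n_rounds"]]),
    biopsy_size = as.integer(kv[["biopsy_size"]]),
    dispersal = as.numeric(kv[["dispersal"]]),
    classification_rule = kv[["classification_rule"]],
    mitotic_convention = kv[["mitotic_convention"]]
  )
}

read_key_value <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexpr(": ", lines, fixed = TRUE), invert = TRUE)
  bad <- lengths(m) != 2L
  if (any(bad)) {
    stop("Malformed `key: value` line in ", path, ": ", lines[bad][1],
         call. = FALSE)
  }
  stats::setNames(vapply(m, `[[`, "", 2L), vapply(m, `[[`, "", 1L))
}
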