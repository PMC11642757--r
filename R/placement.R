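#' Place aneuploid cells on the embryo surface at a given dispersal
#'
#' Arranges `n_aneuploid` aneuploid cells among the geometry's cells by a
#' seed-and-grow mechanism: `s = max(1, round(dispersal * n_aneuploid))`
#' seed cells are drawn uniformly without replacement (rounding half away
#' from zero, clamped to `n_aneuploid`), then clusters grow — a cluster is
#' chosen uniformly at random and its seed's nearest not-yet-aneuploid cell
#' is marked — until `n_aneuploid` cells are marked. Dispersal 0 therefore
#' yields a single spatially contiguous patch, dispersal 1 a uniform random
#' subset (every aneuploid cell its own seed), and intermediate values
#' moderate clustering.
#'
#' @param geometry An [make_geometry()] object.
#' @param n_aneuploid Number of aneuploid cells, in `0..n_cells`.
#' @param dispersal Dispersal in `[0, 1]`.
#' @return An object of class `embryo`: a list with `geometry`, a logical
#'   `aneuploid` label per cell, `n_aneuploid` and `dispersal`.
#' @examples
#' set.seed(1)
#' emb <- place_aneuploid(make_geometry(64), n_aneuploid = 10, dispersal = 0)
#' sum(emb$aneuploid)
#' @export
place_aneuploid <- function(geometry, n_aneuploid, dispersal) {
  n_aneuploid <- as.integer(n_aneuploid)
  if (is.na(n_aneuploid) || n_aneuploid < 0L ||
      n_aneuploid > geometry$n_cells) {
    stop("`n_aneuploid` must be in 0..", geometry$n_cells, ".", call. = FALSE)
  }
  if (!is.numeric(dispersal) || is.na(dispersal) || dispersal < 0 ||
      dispersal > 1) {
    stop("`dispersal` must be in [0, 1].", call. = FALSE)
  }
  labels <- cpp_place_labels(nbr0(geometry), n_aneuploid, dispersal)
  structure(
    list(
      geometry = geometry,
      aneuploid = as.logical(labels),
      n_aneuploid = n_aneuploid,
      dispersal = as.numeric(dispersal)
    ),
    class = "embryo"
  )
}

#' @export
print.embryo <- function(x, ...) {
  cat("<embryo> ", x$geometry$n_cells, " cells, ", x$n_aneuploid,
      " aneuploid, dispersal ", x$dispersal, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.embryo <- function(x, ...) {
  as.data.frame(tibble::as_tibble(x))
}

#' @export
as_tibble.embryo <- function(x, ...) {
  pos <- x$geometry$positions
  labels <- x$aneuploid
  tibble::tibble(
    cell = seq_len(nrow(pos)),
    x = pos[, 1],
    y = pos[, 2],
    z = pos[, 3],
    aneuploid = labels
  )
}

#' Take a spatially contiguous biopsy from an embryo
#'
#' Samples the index cell plus its `biopsy_size - 1` nearest cells (chordal
#' distance, ties broken by lowest id) and tallies how many are aneuploid.
#'
#' @param embryo An [place_aneuploid()] object.
#' @param index_cell Anchor cell id; defaults to the geometry's default
#'   index cell.
#' @param biopsy_size Number of cells sampled (default 5).
#' @return A one-row tibble: `index_cell`, `biopsy_size`, `cell_ids`
#'   (list-column of the sampled ids) and `aneuploid_count`.
#' @export
take_biopsy <- function(embryo, index_cell = NULL, biopsy_size = 5L) {
  if (!inherits(embryo, "embryo")) {
    stop("`embryo` must be created with place_aneuploid().", call. = FALSE)
  }
  ids <- biopsy_cells(embryo$geometry, index_cell, biopsy_size)
  tibble::tibble(
    index_cell = ids[1],
    biopsy_size = as.integer(biopsy_size),
    cell_ids = list(ids),
    aneuploid_count = as.integer(sum(embryo$aneuploid[ids]))
  )
}

#' Classify biopsies as euploid, mosaic or aneuploid
#'
#' Applies either the clinical 20%/70% copy-number thresholds (euploid below
#' 20% aneuploid cells, mosaic between 20% and 70% inclusive, aneuploid
#' above 70%) or the `any_but_not_all` rule (mosaic whenever the biopsy
#' mixes euploid and aneuploid cells). Vectorised over `aneuploid_count`.
#'
#' @param aneuploid_count Integer vector of aneuploid cells per biopsy.
#' @param biopsy_size Cells per biopsy (default 5).
#' @param rule Classification rule; see [model_config()].
#' @return Factor with levels `euploid`, `mosaic`, `aneuploid`.
#' @examples
#' classify_biopsy(0:5)
#' classify_biopsy(0:5, rule = "any_but_not_all")
#' @export
classify_biopsy <- function(aneuploid_count, biopsy_size = 5L,
                            rule = c("threshold_20_70", "any_but_not_all")) {
  rule <- match.arg(rule)
  if (anyNA(aneuploid_count) || any(aneuploid_count < 0) ||
      any(aneuploid_count > biopsy_size)) {
    stop("`aneuploid_count` must be in 0..biopsy_size.", call. = FALSE)
  }
  codes <- class_codes(biopsy_size, rule)[aneuploid_count + 1L]
  factor(biopsy_class_levels()[codes], levels = biopsy_class_levels())
}

biopsy_class_levels <- function() c("euploid", "mosaic", "aneuploid")

# class code (1 = euploid, 2 = mosaic, 3 = aneuploid) for each possible
# aneuploid count 0..biopsy_size
class_codes <- function(biopsy_size, rule) {
  prop <- (0:biopsy_size) / biopsy_size
  if (rule == "threshold_20_70") {
    ifelse(prop < 0.2, 1L, ifelse(prop <= 0.7, 2L, 3L))
  } else {
    c(1L, rep.int(2L, max(biopsy_size - 1L, 0L)), 3L)
  }
}
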