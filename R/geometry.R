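#' Deterministic spherical geometry for a blastocyst-stage embryo
#'
#' Places `n_cells` points on the unit sphere with a Fibonacci lattice — a
#' deterministic, near-uniform packing that stands in for the trophectoderm
#' shell of a blastocyst — and precomputes, for every cell, the ordering of
#' all other cells by increasing chordal distance (ties broken by lowest cell
#' id). Biopsies of spatially adjacent cells and the seed-and-grow placement
#' of aneuploid clones both read these orderings.
#'
#' The construction is fully deterministic: two calls with the same `n_cells`
#' return identical geometries.
#'
#' @param n_cells Number of cells (default 256, i.e. 8 division rounds).
#' @return An object of class `embryo_geometry`: a list with `n_cells`,
#'   `positions` (an `n_cells` x 3 matrix of unit vectors), `neighbor_order`
#'   (an `n_cells` x `n_cells - 1` integer matrix; row i holds every other
#'   cell id ordered by distance from cell i) and `default_index_cell`
#'   (cell 1, the biopsy anchor used unless another index cell is requested).
#' @examples
#' geom <- make_geometry(64)
#' range(sqrt(rowSums(geom$positions^2)))  # all 1
#' @export
make_geometry <- function(n_cells = 256L) {
  n_cells <- as.integer(n_cells)
  if (length(n_cells) != 1L || is.na(n_cells) || n_cells < 1L) {
    stop("`n_cells` must be a single positive integer.", call. = FALSE)
  }
  i <- seq_len(n_cells) - 1L
  z <- 1 - (2 * i + 1) / n_cells
  golden <- pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  positions <- cbind(x = r * cos(i * golden), y = r * sin(i * golden), z = z)
  # renormalise to guard against rounding at the poles
  positions <- positions / sqrt(rowSums(positions^2))

  neighbor_order <- matrix(0L, nrow = n_cells, ncol = max(n_cells - 1L, 0L))
  if (n_cells > 1L) {
    d2 <- as.matrix(stats::dist(positions))^2
    for (cell in seq_len(n_cells)) {
      others <- setdiff(seq_len(n_cells), cell)
      ord <- order(d2[cell, others], others)
      neighbor_order[cell, ] <- others[ord]
    }
  }

  structure(
    list(
      n_cells = n_cells,
      positions = positions,
      neighbor_order = neighbor_order,
      default_index_cell = 1L
    ),
    class = "embryo_geometry"
  )
}

#' @export
print.embryo_geometry <- function(x, ...) {
  cat("<embryo_geometry> ", x$n_cells,
      " cells on a unit-sphere Fibonacci lattice\n", sep = "")
  invisible(x)
}

# 0-based neighbour matrix for the C++ kernels
nbr0 <- function(geometry) geometry$neighbor_order - 1L

#' Cells of a spatially contiguous biopsy
#'
#' The biopsy consists of an index cell plus its `biopsy_size - 1` nearest
#' cells under the geometry's chordal-distance ordering.
#'
#' @param geometry An [make_geometry()] object.
#' @param index_cell Cell id anchoring the biopsy; defaults to the geometry's
#'   default index cell.
#' @param biopsy_size Number of cells sampled (default 5).
#' @return Integer vector of `biopsy_size` cell ids (index cell first).
#' @export
biopsy_cells <- function(geometry, index_cell = NULL, biopsy_size = 5L) {
  if (is.null(index_cell)) index_cell <- geometry$default_index_cell
  index_cell <- as.integer(index_cell)
  if (is.na(index_cell) || index_cell < 1L || index_cell > geometry$n_cells) {
    stop("`index_cell` must be a cell id in 1..", geometry$n_cells, ".",
         call. = FALSE)
  }
  biopsy_size <- as.integer(biopsy_size)
  if (biopsy_size < 1L || biopsy_size > geometry$n_cells) {
    stop("`biopsy_size` must be in 1..", geometry$n_cells, ".", call. = FALSE)
  }
  c(index_cell, geometry$neighbor_order[index_cell, seq_len(biopsy_size - 1L)])
}

# per-session cache: geometry construction is deterministic, so caching does
# not interact with the RNG stream
the <- new.env(parent = emptyenv())

default_geometry <- function(n_cells) {
  key <- paste0("geom_", n_cells)
  if (is.null(the[[key]])) the[[key]] <- make_geometry(n_cells)
  the[[key]]
}
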