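#' Build a regular-grid spatial partition
#'
#' Cell lists over a set of atom positions, the acceleration structure behind
#' the force kernel, collision detection and hydrogen-bond search. The grid
#' bounding box covers all positions padded by one cell; every atom index
#' lands in exactly one cell.
#'
#' @param pos N x 3 position matrix (Angstrom).
#' @param cell_size cell edge length in Angstrom. The default equals the
#'   nonbonded cutoff (8 Angstrom) so a cutoff query scans 27 cells.
#' @return object of class `regular_grid`.
#' @export
build_grid <- function(pos, cell_size = 8) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3)
  stopifnot(nrow(pos) >= 1, cell_size > 0)
  if (!all(is.finite(pos))) stop("build_grid: non-finite coordinates")
  origin <- apply(pos, 2, min) - cell_size
  dims <- pmax(floor((apply(pos, 2, max) - origin) / cell_size) + 2L, 1L)
  ijk <- floor(sweep(pos, 2, origin, "-") / cell_size)
  lin <- 1L + ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3])
  cells <- split(seq_len(nrow(pos)), lin)
  structure(list(origin = origin, cell_size = cell_size, dims = dims,
                 cells = cells, positions = pos),
            class = "regular_grid")
}

#' Query atoms within a cutoff radius of a point
#'
#' Returns exactly the indices whose Euclidean distance to `point` is
#' strictly less than `cutoff` (the same strict-< convention as the force
#' kernel's pair inclusion), ascending. The attribute `cells_touched` counts
#' the cells scanned, for cost instrumentation.
#'
#' @param grid a `regular_grid` from [build_grid()].
#' @param point length-3 query point (Angstrom).
#' @param cutoff radius (Angstrom), strict upper bound on distance.
#' @return integer vector of atom indices (possibly empty), with attribute
#'   `cells_touched`.
#' @export
query_within <- function(grid, point, cutoff) {
  stopifnot(cutoff > 0)
  cand <- grid_candidates(grid, point, cutoff)
  touched <- attr(cand, "cells_touched")
  if (length(cand) == 0L) {
    out <- integer(0)
  } else {
    d2 <- colSums((t(grid$positions[cand, , drop = FALSE]) - point)^2)
    out <- sort(cand[d2 < cutoff^2])
  }
  attr(out, "cells_touched") <- touched
  out
}

# All atom indices in cells intersecting the cube [point - cutoff,
# point + cutoff]; distances are not yet filtered.
grid_candidates <- function(grid, point, cutoff) {
  lo <- pmax(floor((point - cutoff - grid$origin) / grid$cell_size), 0)
  hi <- pmin(floor((point + cutoff - grid$origin) / grid$cell_size),
             grid$dims - 1)
  if (any(hi < lo)) {
    out <- integer(0)
    attr(out, "cells_touched") <- 0L
    return(out)
  }
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  g <- expand.grid(i = ii, j = jj, k = kk)
  lin <- 1L + g$i + grid$dims[1] * (g$j + grid$dims[2] * g$k)
  out <- unlist(grid$cells[as.character(lin)], use.names = FALSE)
  if (is.null(out)) out <- integer(0)
  attr(out, "cells_touched") <- nrow(g)
  out
}
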