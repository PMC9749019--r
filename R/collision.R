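#' Force-magnitude collision detection
#'
#' The flexible-docking scheme: a collision is reported when the magnitude of
#' the total interaction force on the receptor exceeds a threshold (strict
#' `>`). Used with flexible receptors, where vdW-overlap geometry is not
#' meaningful against a deforming structure.
#'
#' @param report a `force_report` from [interaction_forces()].
#' @param threshold force threshold, kJ mol^-1 A^-1. No canonical value
#'   exists; the default 1000 sits an order of magnitude above thermal-scale
#'   forces and below hard-clash forces for small ligands, and is always
#'   recorded in session logs.
#' @return object of class `collision_report` with `colliding`, `mode =
#'   "force"`, `force_magnitude`, `threshold_used`.
#' @export
detect_force_collision <- function(report, threshold = 1000) {
  stopifnot(threshold > 0)
  mag <- sqrt(sum(report$total_force^2))
  structure(list(colliding = mag > threshold, mode = "force",
                 force_magnitude = mag, threshold_used = threshold),
            class = "collision_report")
}

#' Maximum-penetration collision detection
#'
#' The rigid-docking scheme: over all receptor-ligand pairs strictly within
#' the cutoff, computes the maximum interatomic penetration
#' `r_vdw_i + r_vdw_j - d_ij` (floored at zero) using the same grid machinery
#' as the force kernel. Colliding when the maximum exceeds the tolerance.
#' Ties on the maximum break to the lowest (receptor, ligand) index pair.
#'
#' @param receptor,ligand parameterized [molecule()] objects (vdW radii
#'   assigned; ghost atoms are excluded).
#' @param ligand_transform ligand pose.
#' @param cutoff pair cutoff in Angstrom (strict `<`), default 8.
#' @param tolerance allowed penetration in Angstrom; the default 0 makes any
#'   vdW overlap a collision.
#' @param grid optional ligand-local `regular_grid`.
#' @param receptor_positions optional world-frame receptor coordinates.
#' @return `collision_report` with `colliding`, `mode = "overlap"`,
#'   `max_penetration`, `worst_pair` (receptor, ligand indices or `NA`),
#'   `threshold_used`, `pair_count`.
#' @export
detect_overlap_collision <- function(receptor, ligand,
                                     ligand_transform = identity_transform(),
                                     cutoff = 8, tolerance = 0,
                                     grid = NULL, receptor_positions = NULL) {
  stop_if_unparameterized(receptor, "detect_overlap_collision (receptor)")
  stop_if_unparameterized(ligand, "detect_overlap_collision (ligand)")
  rp <- if (is.null(receptor_positions)) positions(receptor)
        else receptor_positions
  lig_local <- positions(ligand)
  if (is.null(grid)) grid <- build_grid(lig_local, cell_size = cutoff)
  rp_local <- apply_transform(invert_transform(ligand_transform), rp)
  la <- ligand$atoms; ra <- receptor$atoms
  lig_active <- !la$is_ghost
  best <- 0
  worst <- c(NA_integer_, NA_integer_)
  pair_count <- 0L
  for (i in seq_len(nrow(rp))) {
    if (ra$is_ghost[i]) next
    js <- query_within(grid, rp_local[i, ], cutoff)
    js <- js[lig_active[js]]
    if (length(js) == 0L) next
    pair_count <- pair_count + length(js)
    d <- sqrt(colSums((t(lig_local[js, , drop = FALSE]) - rp_local[i, ])^2))
    pen <- pmax(ra$vdw_radius[i] + la$vdw_radius[js] - d, 0)
    k <- which.max(pen)  # first max -> lowest ligand index (js ascending)
    if (pen[k] > best) {
      best <- pen[k]
      worst <- c(i, js[k])
    }
  }
  structure(list(colliding = best > tolerance, mode = "overlap",
                 max_penetration = best, worst_pair = worst,
                 threshold_used = tolerance, pair_count = pair_count),
            class = "collision_report")
}

#' @export
print.collision_report <- function(x, ...) {
  metric <- if (x$mode == "force") sprintf("|F| = %.4g kJ/mol/A", x$force_magnitude)
            else sprintf("max penetration = %.4g A", x$max_penetration)
  cat(sprintf("collision_report [%s]: %s (threshold %.4g) -> %s\n", x$mode,
              metric, x$threshold_used,
              if (x$colliding) "COLLIDING" else "clear"))
  invisible(x)
}
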