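#' Nonbonded force-field settings
#'
#' Pairwise receptor-ligand interactions are a 12-6 Lennard-Jones potential
#' plus Coulomb's law screened by a distance-dependent relative permittivity
#' (default `eps_r(r) = D*r` with D = 4 per Angstrom, the common docking
#' choice) or a constant dielectric, truncated sharply at the cutoff. The
#' three force components (vdW repulsive, vdW attractive, electrostatic) can
#' be toggled individually.
#'
#' @param cutoff pair-inclusion cutoff in Angstrom (strict `<`); default 8.
#' @param dielectric `"distance_dependent"` or `"constant"`.
#' @param D slope of the distance-dependent permittivity (per Angstrom).
#' @param eps_r constant relative permittivity (used when
#'   `dielectric = "constant"`).
#' @param combination_rule `"geometric"` (GROMOS-style, on C6 and C12) or
#'   `"lorentz_berthelot"` (arithmetic sigma, geometric epsilon).
#' @param vdw_repulsive,vdw_attractive,electrostatic logical component
#'   toggles; all off is legal and yields zero forces.
#' @return object of class `force_field`.
#' @export
force_field <- function(cutoff = 8,
                        dielectric = c("distance_dependent", "constant"),
                        D = 4, eps_r = 1,
                        combination_rule = c("geometric", "lorentz_berthelot"),
                        vdw_repulsive = TRUE, vdw_attractive = TRUE,
                        electrostatic = TRUE) {
  dielectric <- match.arg(dielectric)
  combination_rule <- match.arg(combination_rule)
  stopifnot(cutoff > 0, D > 0, eps_r >= 1)
  structure(list(
    cutoff = cutoff,
    dielectric = list(type = dielectric, D = D, eps_r = eps_r),
    combination_rule = combination_rule,
    coulomb_constant = 1389.35458,  # kJ mol^-1 A e^-2
    components = c(vdw_repulsive = isTRUE(vdw_repulsive),
                   vdw_attractive = isTRUE(vdw_attractive),
                   electrostatic = isTRUE(electrostatic)),
    min_distance = 1e-6  # clamp, A; degenerate pairs must not overflow
  ), class = "force_field")
}

#' Pairwise 12-6 Lennard-Jones energy and force
#'
#' Energies in the GROMOS C6/C12 form: repulsive `c12/r^12`, attractive
#' `-c6/r^6`. The force magnitude `12 c12/r^13 - 6 c6/r^7` is the exact
#' derivative `-dE/dr`; positive means repulsive, directed along the
#' interatomic axis.
#'
#' @param r interatomic distance(s), Angstrom; must be positive.
#' @param c6 attractive coefficient, kJ mol^-1 A^6.
#' @param c12 repulsive coefficient, kJ mol^-1 A^12.
#' @return list with `energy_rep`, `energy_att`, `force_magnitude`
#'   (vectorized over `r`).
#' @export
pair_lj <- function(r, c6, c12) {
  if (any(r <= 0)) stop("pair_lj: r must be positive")
  inv6 <- 1 / r^6
  list(energy_rep = c12 * inv6^2,
       energy_att = -c6 * inv6,
       force_magnitude = (12 * c12 * inv6 - 6 * c6) * inv6 / r)
}

#' Pairwise screened Coulomb energy and force
#'
#' With the distance-dependent permittivity `eps_r(r) = D*r` the energy is
#' `k_e qi qj / (D r^2)` and the force `2 k_e qi qj / (D r^3)`; with a
#' constant dielectric the familiar `k_e qi qj / (eps_r r)` and
#' `k_e qi qj / (eps_r r^2)`. The force is the exact analytic `-dE/dr`.
#'
#' @param r distance(s), Angstrom; positive.
#' @param qi,qj charges in elementary charge units.
#' @param model the `dielectric` element of a [force_field()] (a list with
#'   `type` and `D` or `eps_r`).
#' @param k_e Coulomb constant, kJ mol^-1 A e^-2.
#' @return list with `energy`, `force_magnitude` (vectorized over `r`).
#' @export
pair_coulomb <- function(r, qi, qj, model = list(type = "distance_dependent", D = 4),
                         k_e = 1389.35458) {
  if (any(r <= 0)) stop("pair_coulomb: r must be positive")
  if (model$type == "distance_dependent") {
    e <- k_e * qi * qj / (model$D * r^2)
    list(energy = e, force_magnitude = 2 * e / r)
  } else {
    e <- k_e * qi * qj / (model$eps_r * r)
    list(energy = e, force_magnitude = e / r)
  }
}

# Combined C6/C12 for one receptor atom against a vector of ligand atoms.
combine_lj <- function(rule, c6i, c12i, c6j, c12j) {
  if (rule == "geometric")
    return(list(c6 = sqrt(c6i * c6j), c12 = sqrt(c12i * c12j)))
  # Lorentz-Berthelot: arithmetic sigma, geometric epsilon; atoms with a
  # vanishing C6 or C12 contribute no LJ term at all.
  ok <- c6i > 0 & c12i > 0 & c6j > 0 & c12j > 0
  c6 <- numeric(length(c6j)); c12 <- numeric(length(c12j))
  if (any(ok)) {
    si <- (c12i / c6i)^(1 / 6); ei <- c6i^2 / (4 * c12i)
    sj <- (c12j[ok] / c6j[ok])^(1 / 6); ej <- c6j[ok]^2 / (4 * c12j[ok])
    s <- (si + sj) / 2; eps <- sqrt(ei * ej)
    c6[ok] <- 4 * eps * s^6; c12[ok] <- 4 * eps * s^12
  }
  list(c6 = c6, c12 = c12)
}

#' Receptor-ligand interaction forces and energies
#'
#' For every non-ghost receptor atom, sums pairwise Lennard-Jones and
#' screened-Coulomb forces and energies over the non-ghost ligand atoms
#' strictly within the cutoff, using the ligand's regular grid for the
#' neighbor search. Receptor atoms are mapped into the ligand's local frame
#' with the inverse ligand transform, so the grid built once on the rigid
#' ligand stays valid for every pose. Per-atom forces are returned in the
#' world frame. Summation order is deterministic (ascending pair index).
#'
#' @param receptor,ligand parameterized [molecule()] objects.
#' @param ff a [force_field()].
#' @param ligand_transform rigid transform placing the ligand in the world
#'   frame.
#' @param grid optional `regular_grid` built on the ligand's local
#'   coordinates (built on the fly when `NULL`).
#' @param receptor_positions optional N x 3 world-frame coordinate override
#'   for the receptor (used by the session layer for deformed/transformed
#'   receptors); defaults to the receptor's stored coordinates.
#' @return object of class `force_report`: `per_atom_force` (N x 3, kJ
#'   mol^-1 A^-1, world frame), `total_force` (length 3),
#'   `energy_vdw_repulsive`, `energy_vdw_attractive`, `energy_electrostatic`,
#'   `energy_total` (kJ mol^-1), `pair_count`, `n_clamped`.
#' @export
interaction_forces <- function(receptor, ligand, ff = force_field(),
                               ligand_transform = identity_transform(),
                               grid = NULL, receptor_positions = NULL) {
  stop_if_unparameterized(receptor, "interaction_forces (receptor)")
  stop_if_unparameterized(ligand, "interaction_forces (ligand)")
  rp <- if (is.null(receptor_positions)) positions(receptor)
        else receptor_positions
  lig_local <- positions(ligand)
  if (is.null(grid)) grid <- build_grid(lig_local, cell_size = ff$cutoff)
  inv <- invert_transform(ligand_transform)
  rp_local <- apply_transform(inv, rp)

  n <- nrow(rp)
  F_local <- matrix(0, n, 3)
  e_rep <- e_att <- e_el <- 0
  pair_count <- 0L
  n_clamped <- 0L
  mask <- ff$components
  ra <- receptor$atoms; la <- ligand$atoms
  lig_active <- !la$is_ghost
  for (i in seq_len(n)) {
    if (ra$is_ghost[i]) next
    js <- query_within(grid, rp_local[i, ], ff$cutoff)
    js <- js[lig_active[js]]
    if (length(js) == 0L) next
    dv <- sweep(lig_local[js, , drop = FALSE], 2, rp_local[i, ], "-")
    d <- sqrt(rowSums(dv^2))
    clamped <- d < ff$min_distance
    n_clamped <- n_clamped + sum(clamped)
    d[clamped] <- ff$min_distance
    pair_count <- pair_count + length(js)

    fmag <- numeric(length(js))
    if (mask["vdw_repulsive"] || mask["vdw_attractive"]) {
      cc <- combine_lj(ff$combination_rule, ra$c6[i], ra$c12[i],
                       la$c6[js], la$c12[js])
      inv6 <- 1 / d^6
      if (mask["vdw_repulsive"]) {
        e_rep <- e_rep + sum(cc$c12 * inv6^2)
        fmag <- fmag + 12 * cc$c12 * inv6^2 / d
      }
      if (mask["vdw_attractive"]) {
        e_att <- e_att - sum(cc$c6 * inv6)
        fmag <- fmag - 6 * cc$c6 * inv6 / d
      }
    }
    if (mask["electrostatic"]) {
      pc <- pair_coulomb(d, ra$charge[i], la$charge[js], ff$dielectric,
                         ff$coulomb_constant)
      e_el <- e_el + sum(pc$energy)
      fmag <- fmag + pc$force_magnitude
    }
    # positive fmag = repulsive: push the receptor atom away from the ligand
    F_local[i, ] <- -colSums(dv * (fmag / d))
  }
  F_world <- F_local %*% t(ligand_transform$rotation)
  structure(list(
    per_atom_force = F_world,
    total_force = colSums(F_world),
    energy_vdw_repulsive = e_rep,
    energy_vdw_attractive = e_att,
    energy_electrostatic = e_el,
    energy_total = e_rep + e_att + e_el,
    pair_count = pair_count,
    n_clamped = n_clamped
  ), class = "force_report")
}

#' An all-zero force report
#' @param n receptor atom count.
#' @return a zero `force_report` for `n` atoms.
#' @export
zero_force_report <- function(n) {
  structure(list(per_atom_force = matrix(0, n, 3), total_force = c(0, 0, 0),
                 energy_vdw_repulsive = 0, energy_vdw_attractive = 0,
                 energy_electrostatic = 0, energy_total = 0,
                 pair_count = 0L, n_clamped = 0L),
            class = "force_report")
}

#' @export
print.force_report <- function(x, ...) {
  cat(sprintf("force_report: %d pairs, E = %.4f kJ/mol (rep %.4f, att %.4f, el %.4f), |F_total| = %.4f kJ/mol/A\n",
              x$pair_count, x$energy_total, x$energy_vdw_repulsive,
              x$energy_vdw_attractive, x$energy_electrostatic,
              sqrt(sum(x$total_force^2))))
  invisible(x)
}
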