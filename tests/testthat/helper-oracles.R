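# Independent brute-force oracles used against the grid-accelerated paths.
# These deliberately avoid the package's neighbor-search machinery.

brute_force_report <- function(rec, lig, ff = force_field(),
                               ligand_transform = identity_transform(),
                               receptor_positions = NULL) {
  rp <- if (is.null(receptor_positions)) positions(rec) else receptor_positions
  lp <- apply_transform(ligand_transform, positions(lig))
  F <- matrix(0, nrow(rp), 3)
  e <- c(rep = 0, att = 0, el = 0)
  pairs <- 0L
  for (i in seq_len(nrow(rp))) {
    if (rec$atoms$is_ghost[i]) next
    for (j in seq_len(nrow(lp))) {
      if (lig$atoms$is_ghost[j]) next
      dv <- lp[j, ] - rp[i, ]
      r <- sqrt(sum(dv^2))
      if (r >= ff$cutoff) next
      pairs <- pairs + 1L
      r <- max(r, ff$min_distance)
      fmag <- 0
      if (ff$combination_rule == "geometric") {
        c6 <- sqrt(rec$atoms$c6[i] * lig$atoms$c6[j])
        c12 <- sqrt(rec$atoms$c12[i] * lig$atoms$c12[j])
      } else {
        ok <- rec$atoms$c6[i] > 0 && rec$atoms$c12[i] > 0 &&
          lig$atoms$c6[j] > 0 && lig$atoms$c12[j] > 0
        if (ok) {
          si <- (rec$atoms$c12[i] / rec$atoms$c6[i])^(1 / 6)
          sj <- (lig$atoms$c12[j] / lig$atoms$c6[j])^(1 / 6)
          ei <- rec$atoms$c6[i]^2 / (4 * rec$atoms$c12[i])
          ej <- lig$atoms$c6[j]^2 / (4 * lig$atoms$c12[j])
          s <- (si + sj) / 2; eps <- sqrt(ei * ej)
          c6 <- 4 * eps * s^6; c12 <- 4 * eps * s^12
        } else c6 <- c12 <- 0
      }
      if (ff$components["vdw_repulsive"]) {
        e["rep"] <- e["rep"] + c12 / r^12
        fmag <- fmag + 12 * c12 / r^13
      }
      if (ff$components["vdw_attractive"]) {
        e["att"] <- e["att"] - c6 / r^6
        fmag <- fmag - 6 * c6 / r^7
      }
      if (ff$components["electrostatic"]) {
        pc <- pair_coulomb(r, rec$atoms$charge[i], lig$atoms$charge[j],
                           ff$dielectric, ff$coulomb_constant)
        e["el"] <- e["el"] + pc$energy
        fmag <- fmag + pc$force_magnitude
      }
      F[i, ] <- F[i, ] - dv * (fmag / r)
    }
  }
  list(per_atom_force = F, total_force = colSums(F),
       energy = unname(e), energy_total = sum(e), pair_count = pairs)
}

brute_max_penetration <- function(rec, lig,
                                  ligand_transform = identity_transform(),
                                  cutoff = 8) {
  rp <- positions(rec)
  lp <- apply_transform(ligand_transform, positions(lig))
  best <- 0
  for (i in seq_len(nrow(rp))) {
    if (rec$atoms$is_ghost[i]) next
    for (j in seq_len(nrow(lp))) {
      if (lig$atoms$is_ghost[j]) next
      d <- sqrt(sum((lp[j, ] - rp[i, ])^2))
      if (d >= cutoff) next
      best <- max(best, rec$atoms$vdw_radius[i] + lig$atoms$vdw_radius[j] - d)
    }
  }
  best
}

# exhaustive triple loop over (donor, hydrogen, acceptor)
brute_hbonds <- function(donor_mol, acceptor_mol,
                         donor_transform = identity_transform(),
                         acceptor_transform = identity_transform(),
                         criteria = hbond_criteria(), intra = FALSE) {
  dp <- apply_transform(donor_transform, positions(donor_mol))
  ap <- apply_transform(acceptor_transform, positions(acceptor_mol))
  da <- donor_mol$atoms; aa <- acceptor_mol$atoms
  out <- NULL
  for (d in which(da$is_donor & !da$is_ghost)) {
    for (h in donor_mol$bonded_hydrogens[[d]]) {
      if (da$is_ghost[h]) next
      for (a in which(aa$is_acceptor & !aa$is_ghost)) {
        if (intra && (a == d || a == h)) next
        dist <- sqrt(sum((ap[a, ] - dp[h, ])^2))
        if (dist >= criteria$distance_cutoff) next
        u <- dp[d, ] - dp[h, ]; v <- ap[a, ] - dp[h, ]
        ang <- acos(min(max(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1)) *
          180 / pi
        if (ang > criteria$angle_cutoff)
          out <- rbind(out, c(d, h, a))
      }
    }
  }
  out
}

hbond_key <- function(tab) {
  if (is.null(tab) || nrow(tab) == 0L) return(character(0))
  if (is.matrix(tab)) sort(paste(tab[, 1], tab[, 2], tab[, 3]))
  else sort(paste(tab$donor_index, tab$hydrogen_index, tab$acceptor_index))
}

random_rigid_transform <- function() {
  axis_angle_transform(stats::rnorm(3), stats::runif(1, -pi, pi),
                       stats::runif(3, -5, 5))
}

analytic_sphere_field <- function(R = 5, spacing = 0.375, pad = 1.5) {
  ax <- seq(-(R + pad), R + pad, by = spacing)
  vals <- array(0, rep(length(ax), 3))
  for (k in seq_along(ax))
    vals[, , k] <- R - sqrt(outer(ax^2, ax^2, "+") + ax[k]^2)
  structure(list(origin = rep(-(R + pad), 3), spacing = spacing,
                 dims = rep(length(ax), 3L), values = vals),
            class = "scalar_field")
}

# two-molecule fixture helpers used across files
two_atom_receptor <- function(separation = 4) {
  p <- make_toy_pair(separation = separation)
  rec <- p$receptor
  rec$atoms <- rbind(rec$atoms, p$ligand$atoms)
  rec$atoms$serial <- 1:2
  rec$bonded_hydrogens <- rep(list(integer(0)), 2)
  rec
}
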