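test_that("pair_lj has its analytic minimum, zero crossing and sign conventions", {
  c6 <- 150; c12 <- 4000
  r_min <- (2 * c12 / c6)^(1 / 6)
  expect_lt(abs(pair_lj(r_min, c6, c12)$force_magnitude), 1e-10)
  r_zero <- (c12 / c6)^(1 / 6)
  at_zero <- pair_lj(r_zero, c6, c12)
  expect_lt(abs(at_zero$energy_rep + at_zero$energy_att), 1e-10)
  expect_gt(pair_lj(0.8 * r_min, c6, c12)$force_magnitude, 0)  # repulsive inside
  expect_lt(pair_lj(1.5 * r_min, c6, c12)$force_magnitude, 0)  # attractive outside
  expect_error(pair_lj(0, c6, c12), "positive")
})

test_that("pair_lj force equals the numerical energy gradient", {
  set.seed(4)
  for (k in 1:25) {
    r <- runif(1, 1.5, 7); c6 <- runif(1, 10, 5000); c12 <- runif(1, 1e3, 5e6)
    h <- 1e-5 * r
    e <- function(x) { l <- pair_lj(x, c6, c12); l$energy_rep + l$energy_att }
    fd <- -(e(r + h) - e(r - h)) / (2 * h)
    f <- pair_lj(r, c6, c12)$force_magnitude
    expect_lt(abs(fd - f) / max(abs(f), 1e-12), 1e-6)
  }
})

test_that("pair_coulomb is symmetric, vanishes for zero charge and matches -dE/dr", {
  dd <- list(type = "distance_dependent", D = 4)
  cc <- list(type = "constant", eps_r = 2)
  expect_equal(pair_coulomb(3, 0, 0.7, dd), list(energy = 0, force_magnitude = 0))
  expect_identical(pair_coulomb(3, 0.4, -0.2, dd), pair_coulomb(3, -0.2, 0.4, dd))
  set.seed(5)
  for (model in list(dd, cc)) {
    for (k in 1:25) {
      r <- runif(1, 1, 7); qi <- runif(1, -1, 1); qj <- runif(1, -1, 1)
      h <- 1e-5 * r
      fd <- -(pair_coulomb(r + h, qi, qj, model)$energy -
                pair_coulomb(r - h, qi, qj, model)$energy) / (2 * h)
      f <- pair_coulomb(r, qi, qj, model)$force_magnitude
      expect_lt(abs(fd - f) / max(abs(f), 1e-9), 1e-6)
    }
  }
  expect_error(pair_coulomb(-1, 1, 1, dd), "positive")
})

test_that("a pair beyond the cutoff yields an identically zero report", {
  p <- make_toy_pair(separation = 9)
  rep <- interaction_forces(p$receptor, p$ligand)
  expect_equal(rep$pair_count, 0L)
  expect_equal(rep$energy_total, 0)
  expect_equal(unname(rep$total_force), c(0, 0, 0))
})

test_that("a single in-cutoff pair reproduces the composed pair kernels", {
  p <- make_toy_pair(separation = 3.5, charges = c(0.3, -0.25))
  rep <- interaction_forces(p$receptor, p$ligand)
  a <- p$receptor$atoms; b <- p$ligand$atoms
  lj <- pair_lj(3.5, sqrt(a$c6 * b$c6), sqrt(a$c12 * b$c12))
  pc <- pair_coulomb(3.5, a$charge, b$charge)
  expect_equal(rep$pair_count, 1L)
  expect_equal(rep$energy_vdw_repulsive, lj$energy_rep)
  expect_equal(rep$energy_vdw_attractive, lj$energy_att)
  expect_equal(rep$energy_electrostatic, pc$energy)
  # force on the receptor atom points along -x for net repulsion
  fmag <- lj$force_magnitude + pc$force_magnitude
  expect_equal(unname(rep$per_atom_force[1, ]), c(-fmag, 0, 0))
})

test_that("grid-accelerated forces equal the brute-force double loop", {
  for (seed in 1:5) {
    fix <- make_docking_pair(50, 20, box = 22, seed = seed)
    got <- interaction_forces(fix$receptor, fix$ligand)
    want <- brute_force_report(fix$receptor, fix$ligand)
    expect_lt(max(abs(got$per_atom_force - want$per_atom_force)), 1e-9)
    expect_equal(got$pair_count, want$pair_count)
    expect_lt(abs(got$energy_total - want$energy_total) /
                max(abs(want$energy_total), 1), 1e-12)
  }
})

test_that("forces agree with the oracle under arbitrary ligand transforms", {
  # the oracle works in the world frame, the kernel in the ligand-local
  # frame; the rotation round trip costs ulps that steep r^-13 contacts
  # amplify, so the comparison is relative to the force scale
  set.seed(33)
  fix <- make_docking_pair(40, 15, box = 20, seed = 1)
  for (k in 1:5) {
    tr <- random_rigid_transform()
    got <- interaction_forces(fix$receptor, fix$ligand, ligand_transform = tr)
    lig_moved <- set_positions(fix$ligand,
                               apply_transform(tr, positions(fix$ligand)))
    want <- brute_force_report(fix$receptor, lig_moved)
    scale <- max(abs(want$per_atom_force), 1)
    expect_lt(max(abs(got$per_atom_force - want$per_atom_force)) / scale, 1e-9)
    expect_equal(got$pair_count, want$pair_count)
  }
})

test_that("Newton's third law holds between receptor and ligand", {
  rec <- make_random_cloud(40, 18, seed = 21)
  lig <- make_random_cloud(18, 18, seed = 22)
  on_rec <- interaction_forces(rec, lig)
  on_lig <- interaction_forces(lig, rec)  # roles swapped, same pair set
  denom <- max(sqrt(sum(on_rec$total_force^2)), 1e-12)
  expect_lt(sqrt(sum((on_rec$total_force + on_lig$total_force)^2)) / denom, 1e-9)
  # and the column-sum invariant of the report itself
  expect_lt(max(abs(colSums(on_rec$per_atom_force) - on_rec$total_force)), 1e-12)
})

test_that("component reports add to the full report", {
  rec <- make_random_cloud(35, 16, seed = 31)
  lig <- make_random_cloud(12, 16, seed = 32)
  full <- interaction_forces(rec, lig, force_field())
  parts <- list(
    force_field(vdw_repulsive = TRUE, vdw_attractive = FALSE, electrostatic = FALSE),
    force_field(vdw_repulsive = FALSE, vdw_attractive = TRUE, electrostatic = FALSE),
    force_field(vdw_repulsive = FALSE, vdw_attractive = FALSE, electrostatic = TRUE))
  F_sum <- matrix(0, n_atoms(rec), 3)
  e_sum <- 0
  for (ffp in parts) {
    r <- interaction_forces(rec, lig, ffp)
    F_sum <- F_sum + r$per_atom_force
    e_sum <- e_sum + r$energy_total
  }
  scale <- max(abs(full$per_atom_force), 1e-12)
  expect_lt(max(abs(F_sum - full$per_atom_force)) / scale, 1e-12)
  expect_lt(abs(e_sum - full$energy_total) / max(abs(full$energy_total), 1e-12), 1e-12)
  # all components off is legal and zero
  off <- interaction_forces(rec, lig, force_field(vdw_repulsive = FALSE,
                                                  vdw_attractive = FALSE,
                                                  electrostatic = FALSE))
  expect_equal(off$energy_total, 0)
  expect_equal(max(abs(off$per_atom_force)), 0)
  expect_gt(off$pair_count, 0L)  # pairs are counted regardless of the mask
})

test_that("energy changes match -F.delta under small ligand displacements", {
  rec <- make_random_cloud(30, 15, seed = 41)
  lig <- make_random_cloud(10, 15, seed = 42)
  base <- interaction_forces(rec, lig)
  h <- 1e-6
  for (axis in 1:3) {
    d <- numeric(3); d[axis] <- h
    ep <- interaction_forces(rec, lig,
                             ligand_transform = rigid_transform(translation = d))$energy_total
    em <- interaction_forces(rec, lig,
                             ligand_transform = rigid_transform(translation = -d))$energy_total
    # moving the ligand by d changes E by -F_ligand . d = +F_receptor . d
    fd <- (ep - em) / (2 * h)
    expect_lt(abs(fd - base$total_force[axis]) /
                max(abs(base$total_force[axis]), 1e-6), 1e-5)
  }
})

test_that("enlarging the cutoff never decreases the pair count", {
  rec <- make_random_cloud(30, 18, seed = 51)
  lig <- make_random_cloud(12, 18, seed = 52)
  counts <- vapply(c(4, 6, 8, 10, 14), function(co)
    interaction_forces(rec, lig, force_field(cutoff = co))$pair_count,
    integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("Lorentz-Berthelot and geometric rules agree for identical atoms", {
  p <- make_toy_pair(separation = 3.7, elements = c("C", "C"))
  g <- interaction_forces(p$receptor, p$ligand,
                          force_field(combination_rule = "geometric"))
  lb <- interaction_forces(p$receptor, p$ligand,
                           force_field(combination_rule = "lorentz_berthelot"))
  expect_equal(g$energy_total, lb$energy_total, tolerance = 1e-12)
  # and the LB path matches its own oracle on mixed atoms
  fix <- make_docking_pair(20, 10, box = 14, seed = 61)
  ff <- force_field(combination_rule = "lorentz_berthelot")
  got <- interaction_forces(fix$receptor, fix$ligand, ff)
  want <- brute_force_report(fix$receptor, fix$ligand, ff)
  expect_lt(max(abs(got$per_atom_force - want$per_atom_force)), 1e-9)
})

test_that("unparameterized molecules are rejected by name", {
  bad <- molecule(data.frame(
    serial = 1, name = "C1", element = "C", resname = "UNK", resseq = 1,
    chain = "A", x = 0, y = 0, z = 0, stringsAsFactors = FALSE))
  ok <- make_toy_pair()$ligand
  expect_error(interaction_forces(bad, ok), "assign_parameters")
})
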