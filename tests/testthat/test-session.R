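far_session <- function(mode = "overlap", seed = 1) {
  rec <- make_random_cloud(20, 12, seed = seed)
  lig0 <- make_random_cloud(8, 10, seed = seed + 10)
  # place the ligand well outside the receptor box
  lig <- set_positions(lig0, sweep(positions(lig0), 2, c(-100, 0, 0)))
  docking_session(rec, lig, collision_mode = mode)
}

test_that("small moves far from contact are accepted; clashes are rejected untouched", {
  s <- far_session()
  r <- propose_move(s, "ligand", rigid_transform(translation = c(0.5, 0, 0)))
  expect_true(r$accepted)
  expect_equal(r$state$ligand_transform$translation, c(0.5, 0, 0))

  # aim a ligand atom exactly at a receptor atom: deep overlap, rejected
  before <- r$state
  aim <- positions(before$receptor)[1, ] -
    apply_transform(before$ligand_transform, positions(before$ligand))[1, ]
  crash <- propose_move(before, "ligand", rigid_transform(translation = aim))
  expect_false(crash$accepted)
  expect_identical(crash$state$ligand_transform$translation,
                   before$ligand_transform$translation)
  expect_identical(crash$state$receptor_transform$rotation,
                   before$receptor_transform$rotation)
  expect_identical(crash$state$deformation, before$deformation)
  # the rejection is recorded in the trace
  expect_equal(length(crash$state$trace), length(before$trace) + 1L)
  last <- crash$state$trace[[length(crash$state$trace)]]
  expect_false(last$accepted)
})

test_that("random move sequences never mutate state through rejections", {
  s <- far_session(seed = 5)
  set.seed(55)
  for (k in 1:25) {
    big <- runif(1) < 0.4
    delta <- axis_angle_transform(
      rnorm(3), runif(1, -0.3, 0.3),
      if (big) c(runif(1, 95, 105), runif(2, -2, 2)) else runif(3, -1, 1))
    before <- s
    r <- propose_move(s, sample(c("ligand", "receptor"), 1), delta)
    if (!r$accepted) {
      expect_identical(r$state$ligand_transform, before$ligand_transform)
      expect_identical(r$state$receptor_transform, before$receptor_transform)
    }
    s <- r$state
  }
  expect_gt(length(s$trace), 25L)
})

test_that("a recorded session replays to identical transforms and energies", {
  s <- far_session(seed = 7)
  set.seed(77)
  for (k in 1:30) {
    delta <- axis_angle_transform(rnorm(3), runif(1, -0.2, 0.2),
                                  runif(3, -1.5, 1.5))
    s <- propose_move(s, sample(c("ligand", "receptor"), 1), delta)$state
  }
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_session_trace(s, path)
  s2 <- replay_session(far_session(seed = 7), path)
  expect_identical(s2$ligand_transform$rotation, s$ligand_transform$rotation)
  expect_identical(s2$ligand_transform$translation, s$ligand_transform$translation)
  expect_identical(s2$receptor_transform$rotation, s$receptor_transform$rotation)
  e1 <- energy_trace(s); e2 <- energy_trace(s2)
  expect_identical(e1$accepted, e2$accepted)
  expect_lt(max(abs(e1$energy_total - e2$energy_total)), 1e-9)
})

test_that("trace energies equal energies recomputed at each recorded pose", {
  s <- far_session(seed = 9)
  set.seed(99)
  poses <- list()
  for (k in 1:10) {
    delta <- rigid_transform(translation = runif(3, -1, 1))
    s <- propose_move(s, "ligand", delta)$state
    poses[[k]] <- s$ligand_transform
  }
  et <- energy_trace(s)
  expect_equal(nrow(et), 11L)  # init + 10 moves
  for (k in c(3, 7, 10)) {
    rep <- interaction_forces(s$receptor, s$ligand,
                              ligand_transform = poses[[k]])
    expect_equal(et$energy_total[k + 1], rep$energy_total, tolerance = 1e-9)
  }
})

test_that("component toggles gate the reported energies and forces", {
  rec <- make_random_cloud(15, 10, seed = 11)
  lig0 <- make_random_cloud(6, 8, seed = 12)
  lig <- set_positions(lig0, sweep(positions(lig0), 2, c(-15, 0, 0)))
  s <- docking_session(rec, lig, collision_mode = "overlap",
                       collision_threshold = 100)
  s <- set_components(s, vdw_repulsive = FALSE, vdw_attractive = FALSE,
                      electrostatic = FALSE)
  rep <- session_forces(s)
  expect_equal(rep$energy_total, 0)
  expect_equal(max(abs(rep$per_atom_force)), 0)
  s <- set_components(s, vdw_repulsive = TRUE, vdw_attractive = TRUE,
                      electrostatic = TRUE)
  full <- session_forces(s)
  expect_gt(abs(full$energy_total), 0)
})

test_that("ghost regions drop out of forces and collisions but stay in output", {
  p <- make_toy_pair(separation = 2.0)  # deep vdW overlap
  s0 <- docking_session(p$receptor, p$ligand, collision_mode = "overlap")
  blocked <- propose_move(s0, "ligand", rigid_transform(translation = c(-0.1, 0, 0)))
  expect_false(blocked$accepted)
  s1 <- set_ghost(s0, 1L, which = "receptor")
  expect_equal(session_forces(s1)$pair_count, 0L)
  passed <- propose_move(s1, "ligand", rigid_transform(translation = c(-0.1, 0, 0)))
  expect_true(passed$accepted)
  # ghosts remain in the merged structure and in written files
  merged <- merge_complex(s1)
  expect_equal(n_atoms(merged), 2L)
  # empty ghost set leaves reports unchanged
  s2 <- set_ghost(s0, integer(0), which = "receptor")
  expect_equal(session_forces(s2)$energy_total,
               session_forces(s0)$energy_total)
})

test_that("distance monitors track the current world-frame distance", {
  s <- far_session(seed = 13)
  s <- add_monitor(s, list(molecule = "receptor", index = 1L),
                   list(molecule = "ligand", index = 1L), target = 3.0)
  d0 <- monitor_distances(s)$current
  rp <- positions(s$receptor)[1, ]
  lp <- positions(s$ligand)[1, ]
  expect_equal(d0, sqrt(sum((rp - lp)^2)))
  s <- propose_move(s, "ligand", rigid_transform(translation = c(5, 0, 0)))$state
  d1 <- monitor_distances(s)$current
  expect_equal(d1, sqrt(sum((rp - lp - c(5, 0, 0))^2)), tolerance = 1e-9)
  expect_equal(monitor_distances(s)$target, 3.0)
})

test_that("merged complexes preserve order, counts and intramolecular hydrogen bonds", {
  rec <- make_random_cloud(10, 12, seed = 15)
  lig0 <- make_random_cloud(3, 6, seed = 16, chain = "A")
  lig <- set_positions(lig0, sweep(positions(lig0), 2, c(-30, 0, 0)))
  s <- docking_session(rec, lig, collision_mode = "overlap")
  merged <- merge_complex(s)
  expect_equal(n_atoms(merged), 13L)
  expect_identical(merged$atoms$serial, 1:13)
  expect_equal(unique(merged$atoms$chain), c("A", "B"))  # ligand re-lettered
  expect_equal(positions(merged)[1:10, ], positions(rec),
               ignore_attr = TRUE)  # identity transforms copy verbatim

  # a merged complex keeps its hydrogen-bond structure through save/load
  fix <- make_hbond_cloud(10, 10, box = 10, seed = 17)
  s2 <- docking_session(fix$donor, fix$acceptor, collision_mode = "force",
                        collision_threshold = 1e9)
  m2 <- merge_complex(s2)
  hb_merged <- detect_hbonds(m2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m2, path)
  back <- read_structure(path)
  back$atoms[c("charge", "c6", "c12", "vdw_radius", "is_donor",
               "is_acceptor", "is_hydrogen")] <-
    m2$atoms[c("charge", "c6", "c12", "vdw_radius", "is_donor",
               "is_acceptor", "is_hydrogen")]
  back$bonded_hydrogens <- m2$bonded_hydrogens
  back$parameterized <- TRUE
  hb_back <- detect_hbonds(back)
  expect_identical(hbond_key(hb_back), hbond_key(hb_merged))
})

test_that("the world<->model frame round trip is exact", {
  set.seed(19)
  tr <- random_rigid_transform()
  xyz <- matrix(rnorm(30), 10, 3)
  back <- apply_transform(invert_transform(tr), apply_transform(tr, xyz))
  expect_lt(max(abs(back - xyz)), 1e-12)
})

test_that("the salt-bridge scene walks its on/off/on state machine", {
  s <- make_salt_bridge_scene()
  # before any relaxation the probe donates to the internal site only
  expect_equal(detect_hbonds(s$receptor)$acceptor_index, 1L)
  expect_equal(session_hbond_count(s), 0L)

  # trigger relaxation at the current pose (null move), electrostatics on
  s <- propose_move(s, "ligand", identity_transform())$state
  rec_now <- set_positions(s$receptor,
                           dockflex:::receptor_world_positions(s))
  nz <- positions(rec_now)[2, ]
  d_lig <- abs(3.8 - nz[1]); d_int <- abs(-3.3 - nz[1])
  expect_lt(d_lig, d_int)  # probe sits closer to the ligand site
  expect_equal(nrow(detect_hbonds(rec_now)), 0L)  # internal bridge broken
  expect_equal(session_hbond_count(s), 1L)        # new bridge to the ligand

  # electrostatics off: the deformation collapses back toward r_o
  s_off <- set_components(s, electrostatic = FALSE)
  expect_lt(max(abs(s_off$deformation)), 0.1)
  rec_off <- set_positions(s_off$receptor,
                           dockflex:::receptor_world_positions(s_off))
  expect_equal(nrow(detect_hbonds(rec_off)), 1L)  # internal bridge restored
  expect_equal(session_hbond_count(s_off), 0L)

  # electrostatics on again: the converged deformation is recovered
  s_on <- set_components(s_off, electrostatic = TRUE)
  expect_equal(s_on$deformation, s$deformation, tolerance = 1e-6)
  expect_equal(session_hbond_count(s_on), 1L)
})

test_that("flexible relaxation inside a session is deterministic", {
  s1 <- make_salt_bridge_scene()
  s1 <- propose_move(s1, "ligand", identity_transform())$state
  s2 <- make_salt_bridge_scene()
  s2 <- propose_move(s2, "ligand", identity_transform())$state
  expect_identical(s1$deformation, s2$deformation)
})
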