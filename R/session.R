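#' Start a headless docking session
#'
#' Holds both molecules and their rigid transforms, the force field, the
#' collision configuration, an optional linear-response model for receptor
#' flexibility, distance monitors and a time-ordered trace of every event.
#' Moves are proposed with [propose_move()] and are rejected (state
#' unchanged) when they collide, the headless analogue of freezing the
#' transform on contact. With a response model present, force-based collision
#' detection is mandatory: vdW-overlap geometry is not meaningful against a
#' deforming receptor.
#'
#' @param receptor,ligand parameterized [molecule()] objects. The ligand is
#'   rigid; the receptor deforms when a response model is supplied.
#' @param ff a [force_field()].
#' @param response_model optional [response_model()] whose `r_o` matches the
#'   receptor (3N check enforced).
#' @param collision_mode `"force"` (default, required for flexible
#'   receptors) or `"overlap"`.
#' @param collision_threshold force threshold (kJ mol^-1 A^-1, default 1000)
#'   or overlap tolerance (Angstrom, default 0) depending on the mode.
#' @param relax a [relaxation_settings()] used after every accepted move
#'   when a response model is present.
#' @return object of class `docking_session`.
#' @export
docking_session <- function(receptor, ligand, ff = force_field(),
                            response_model = NULL,
                            collision_mode = c("force", "overlap"),
                            collision_threshold = NULL,
                            relax = relaxation_settings()) {
  collision_mode <- match.arg(collision_mode)
  stop_if_unparameterized(receptor, "docking_session (receptor)")
  stop_if_unparameterized(ligand, "docking_session (ligand)")
  if (!is.null(response_model)) {
    if (collision_mode != "force")
      stop("docking_session: a flexible receptor (response model) requires ",
           "force-based collision detection")
    if (response_model$N != n_atoms(receptor))
      stop("docking_session: response model is for ", response_model$N,
           " atoms but the receptor has ", n_atoms(receptor))
  }
  if (is.null(collision_threshold))
    collision_threshold <- if (collision_mode == "force") 1000 else 0
  state <- structure(list(
    receptor = receptor, ligand = ligand,
    receptor_transform = identity_transform(),
    ligand_transform = identity_transform(),
    response_model = response_model,
    deformation = numeric(3L * n_atoms(receptor)),
    ff = ff, collision_mode = collision_mode,
    collision_threshold = collision_threshold,
    relax = relax,
    lig_grid = build_grid(positions(ligand), cell_size = ff$cutoff),
    monitors = list(), trace = list(), step = 0L
  ), class = "docking_session")
  append_trace(state, "init", which = NA_character_,
               delta = identity_transform(), accepted = TRUE)
}

# receptor coordinates in its model frame (relaxed + deformation)
receptor_model_coords <- function(state) {
  if (is.null(state$response_model)) {
    flatten_xyz(positions(state$receptor)) + state$deformation
  } else {
    state$response_model$r_o + state$deformation
  }
}

receptor_world_positions <- function(state,
                                     receptor_transform = state$receptor_transform,
                                     deformation = state$deformation) {
  coords <- if (is.null(state$response_model))
    flatten_xyz(positions(state$receptor)) + deformation
  else state$response_model$r_o + deformation
  apply_transform(receptor_transform, unflatten_xyz(coords))
}

#' Current receptor-ligand force report of a session
#'
#' @param state a `docking_session`.
#' @param receptor_transform,ligand_transform,deformation optional overrides
#'   (used internally to evaluate candidate poses).
#' @return a `force_report` in the world frame.
#' @export
session_forces <- function(state,
                           receptor_transform = state$receptor_transform,
                           ligand_transform = state$ligand_transform,
                           deformation = state$deformation) {
  interaction_forces(state$receptor, state$ligand, state$ff,
                     ligand_transform = ligand_transform,
                     grid = state$lig_grid,
                     receptor_positions = receptor_world_positions(
                       state, receptor_transform, deformation))
}

# forces on receptor atoms mapped into the receptor model frame, as the
# length-3N vector Eq-style relaxation consumes
receptor_model_forces <- function(state, coords_model,
                                  receptor_transform = state$receptor_transform,
                                  ligand_transform = state$ligand_transform) {
  world <- apply_transform(receptor_transform, unflatten_xyz(coords_model))
  rep <- interaction_forces(state$receptor, state$ligand, state$ff,
                            ligand_transform = ligand_transform,
                            grid = state$lig_grid,
                            receptor_positions = world)
  # world -> model frame by the inverse receptor rotation
  flatten_xyz(rep$per_atom_force %*% state$receptor_transform$rotation)
}

session_collision <- function(state, receptor_transform, ligand_transform,
                              deformation) {
  if (state$collision_mode == "force") {
    rep <- session_forces(state, receptor_transform, ligand_transform,
                          deformation)
    detect_force_collision(rep, state$collision_threshold)
  } else {
    detect_overlap_collision(state$receptor, state$ligand,
                             ligand_transform = ligand_transform,
                             cutoff = state$ff$cutoff,
                             tolerance = state$collision_threshold,
                             grid = state$lig_grid,
                             receptor_positions = receptor_world_positions(
                               state, receptor_transform, deformation))
  }
}

#' Count receptor-ligand hydrogen bonds in the current pose
#'
#' Sums both directions (receptor donors to ligand acceptors and vice
#' versa); returns `NA` when either direction cannot be evaluated (e.g. a
#' structure without hydrogens).
#' @param state a `docking_session`.
#' @param criteria an [hbond_criteria()].
#' @return integer bond count or `NA`.
#' @export
session_hbond_count <- function(state, criteria = hbond_criteria()) {
  rec <- state$receptor
  rec_pos <- receptor_world_positions(state)
  rec <- set_positions(rec, rec_pos)
  n <- 0L; any_ok <- FALSE
  for (dir in 1:2) {
    res <- tryCatch({
      if (dir == 1)
        detect_hbonds(rec, state$ligand,
                      acceptor_transform = state$ligand_transform,
                      criteria = criteria,
                      donor_tag = "receptor", acceptor_tag = "ligand")
      else
        detect_hbonds(state$ligand, rec,
                      donor_transform = state$ligand_transform,
                      criteria = criteria,
                      donor_tag = "ligand", acceptor_tag = "receptor")
    }, error = function(e) NULL)
    if (!is.null(res)) { n <- n + nrow(res); any_ok <- TRUE }
  }
  if (any_ok) n else NA_integer_
}

append_trace <- function(state, event, which, delta, accepted,
                         extra = list()) {
  rep <- session_forces(state)
  col <- session_collision(state, state$receptor_transform,
                           state$ligand_transform, state$deformation)
  metric <- if (state$collision_mode == "force") col$force_magnitude
            else col$max_penetration
  rec <- c(list(
    event = event, step = state$step, which = which,
    rotation = as.numeric(t(delta$rotation)),
    translation = delta$translation, accepted = accepted,
    energy_vdw_repulsive = rep$energy_vdw_repulsive,
    energy_vdw_attractive = rep$energy_vdw_attractive,
    energy_electrostatic = rep$energy_electrostatic,
    energy_total = rep$energy_total,
    collision_mode = state$collision_mode,
    collision_metric = metric,
    collision_threshold = state$collision_threshold,
    hbond_count = session_hbond_count(state)
  ), extra)
  state$trace[[length(state$trace) + 1L]] <- rec
  state <- update_monitors(state)
  state
}

#' Propose a rigid-body move
#'
#' Applies `delta` (a world-frame increment) to the chosen molecule's
#' transform, evaluates collision at the candidate pose and either commits
#' the move (relaxing the receptor to equilibrium when a response model is
#' present) or rejects it, returning the prior state untouched apart from
#' the appended trace record.
#'
#' @param state a `docking_session`.
#' @param which `"receptor"` or `"ligand"`.
#' @param delta a [rigid_transform()] increment.
#' @return list with `accepted` (logical) and `state` (the new session
#'   state).
#' @export
propose_move <- function(state, which = c("ligand", "receptor"), delta) {
  which <- match.arg(which)
  cand_rec <- state$receptor_transform
  cand_lig <- state$ligand_transform
  if (which == "receptor") cand_rec <- compose_transform(delta, cand_rec)
  else cand_lig <- compose_transform(delta, cand_lig)
  col <- session_collision(state, cand_rec, cand_lig, state$deformation)
  state$step <- state$step + 1L
  if (col$colliding) {
    state <- append_trace(state, "move", which, delta, accepted = FALSE)
    return(list(accepted = FALSE, state = state))
  }
  state$receptor_transform <- cand_rec
  state$ligand_transform <- cand_lig
  if (!is.null(state$response_model)) {
    res <- relax_to_equilibrium(
      state$response_model,
      function(coords) receptor_model_forces(state, coords),
      state$relax)
    state$deformation <- res$deformation
    state$last_relaxation <- res[c("converged", "iterations")]
  }
  state <- append_trace(state, "move", which, delta, accepted = TRUE)
  list(accepted = TRUE, state = state)
}

#' Toggle force components
#'
#' Subsequent force, energy and relaxation calls use the new mask. With a
#' response model present the receptor is re-relaxed immediately, so e.g.
#' switching electrostatics off lets a deformation that was held by
#' electrostatic attraction fall back toward the relaxed structure.
#'
#' @param state a `docking_session`.
#' @param vdw_repulsive,vdw_attractive,electrostatic logical toggles;
#'   `NULL` leaves a component unchanged.
#' @return the updated session state.
#' @export
set_components <- function(state, vdw_repulsive = NULL, vdw_attractive = NULL,
                           electrostatic = NULL) {
  comp <- state$ff$components
  if (!is.null(vdw_repulsive)) comp["vdw_repulsive"] <- isTRUE(vdw_repulsive)
  if (!is.null(vdw_attractive)) comp["vdw_attractive"] <- isTRUE(vdw_attractive)
  if (!is.null(electrostatic)) comp["electrostatic"] <- isTRUE(electrostatic)
  state$ff$components <- comp
  if (!is.null(state$response_model)) {
    res <- relax_to_equilibrium(
      state$response_model,
      function(coords) receptor_model_forces(state, coords),
      state$relax)
    state$deformation <- res$deformation
  }
  state$step <- state$step + 1L
  append_trace(state, "components", NA_character_, identity_transform(),
               accepted = TRUE, extra = list(components = as.list(comp)))
}

#' Mark atoms as ghosts
#'
#' Ghost atoms are kept in the structure, the surface and all output files
#' but excluded from force, collision and hydrogen-bond computation, letting
#' the ligand pass otherwise blocking regions.
#'
#' @param state a `docking_session`.
#' @param selection integer atom indices, a logical vector, or a predicate
#'   `function(atom_table) -> logical`.
#' @param which `"receptor"` or `"ligand"`.
#' @param ghost set (`TRUE`) or clear (`FALSE`) the flag on the selection.
#' @return the updated session state.
#' @export
set_ghost <- function(state, selection, which = c("receptor", "ligand"),
                      ghost = TRUE) {
  which <- match.arg(which)
  mol <- state[[which]]
  sel <- if (is.function(selection)) which(selection(mol$atoms))
         else if (is.logical(selection)) which(selection)
         else as.integer(selection)
  mol$atoms$is_ghost[sel] <- ghost
  state[[which]] <- mol
  if (!is.null(state$response_model)) {
    res <- relax_to_equilibrium(
      state$response_model,
      function(coords) receptor_model_forces(state, coords),
      state$relax)
    state$deformation <- res$deformation
  }
  state$step <- state$step + 1L
  append_trace(state, "ghost", which, identity_transform(), accepted = TRUE,
               extra = list(selection = as.list(sel), ghost = ghost))
}

#' Add a distance monitor
#'
#' Monitors the world-frame distance between one atom of each molecule (or
#' two atoms of the same molecule); the current value is recomputed after
#' every state change and stored with each trace record.
#'
#' @param state a `docking_session`.
#' @param a,b atom references: `list(molecule = "receptor"|"ligand",
#'   index = i)`.
#' @param target optional target distance (Angstrom), stored for reporting.
#' @return the updated session state.
#' @export
add_monitor <- function(state, a, b, target = NULL) {
  state$monitors[[length(state$monitors) + 1L]] <-
    list(a = a, b = b, target = target, current = NA_real_)
  update_monitors(state)
}

monitor_atom_position <- function(state, ref) {
  if (ref$molecule == "receptor")
    receptor_world_positions(state)[ref$index, ]
  else
    apply_transform(state$ligand_transform,
                    positions(state$ligand))[ref$index, ]
}

update_monitors <- function(state) {
  for (m in seq_along(state$monitors)) {
    mon <- state$monitors[[m]]
    d <- sqrt(sum((monitor_atom_position(state, mon$a) -
                   monitor_atom_position(state, mon$b))^2))
    state$monitors[[m]]$current <- d
  }
  state
}

#' Monitored distances as a data frame
#' @param state a `docking_session`.
#' @return data frame with one row per monitor.
#' @export
monitor_distances <- function(state) {
  if (length(state$monitors) == 0L)
    return(data.frame(a = character(0), b = character(0),
                      target = numeric(0), current = numeric(0)))
  do.call(rbind, lapply(state$monitors, function(m) data.frame(
    a = paste0(m$a$molecule, ":", m$a$index),
    b = paste0(m$b$molecule, ":", m$b$index),
    target = if (is.null(m$target)) NA_real_ else m$target,
    current = m$current)))
}

#' Component-energy time series of a session
#' @param state a `docking_session`.
#' @return data frame with one row per trace record: step, event, accepted
#'   flag, the component and total energies, collision metric and hydrogen
#'   bond count.
#' @export
energy_trace <- function(state) {
  do.call(rbind, lapply(state$trace, function(r) data.frame(
    step = r$step, event = r$event,
    accepted = r$accepted,
    energy_vdw_repulsive = r$energy_vdw_repulsive,
    energy_vdw_attractive = r$energy_vdw_attractive,
    energy_electrostatic = r$energy_electrostatic,
    energy_total = r$energy_total,
    collision_metric = r$collision_metric,
    hbond_count = r$hbond_count)))
}

#' Merge the docked complex into a single molecule
#'
#' Receptor atoms (deformed coordinates, receptor transform applied)
#' followed by ligand atoms (ligand transform applied); chains are
#' re-lettered to avoid clashes, serials renumbered. The result is writable
#' with [write_pdb()] and loadable as the receptor of a new session.
#'
#' @param state a `docking_session`.
#' @return a parameterized [molecule()].
#' @export
merge_complex <- function(state) {
  rec <- state$receptor
  rec <- set_positions(rec, receptor_world_positions(state))
  lig <- state$ligand
  lig <- set_positions(lig, apply_transform(state$ligand_transform,
                                            positions(lig)))
  used <- unique(rec$atoms$chain)
  pool <- setdiff(c(LETTERS, letters), used)
  lig_chains <- unique(lig$atoms$chain)
  remap <- stats::setNames(pool[seq_along(lig_chains)], lig_chains)
  lig$atoms$chain <- unname(remap[lig$atoms$chain])
  atoms <- rbind(rec$atoms, lig$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  out <- molecule(atoms, title = "merged complex",
                  source_format = "synthetic")
  out$parameterized <- rec$parameterized && lig$parameterized
  off <- n_atoms(rec)
  out$bonded_hydrogens <- c(rec$bonded_hydrogens,
                            lapply(lig$bonded_hydrogens,
                                   function(v) v + off))
  out
}

#' @export
print.docking_session <- function(x, ...) {
  cat(sprintf("docking_session: receptor %d atoms%s, ligand %d atoms, %s collision (threshold %g), %d trace record(s)\n",
              n_atoms(x$receptor),
              if (!is.null(x$response_model))
                sprintf(" (flexible, M = %d)", x$response_model$M) else "",
              n_atoms(x$ligand), x$collision_mode, x$collision_threshold,
              length(x$trace)))
  invisible(x)
}

#' Write the session trace as JSON-lines
#'
#' One JSON object per line: a header with the full configuration followed
#' by one record per event (step, molecule moved, the 3x3 delta rotation
#' row-major, delta translation, accepted flag, component energies,
#' collision metric, hydrogen-bond count). Streamable, diffable and
#' replayable with [replay_session()].
#'
#' @param state a `docking_session`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_session_trace <- function(state, path) {
  header <- list(
    type = "header",
    cutoff = state$ff$cutoff,
    dielectric = state$ff$dielectric,
    combination_rule = state$ff$combination_rule,
    components = as.list(state$ff$components),
    collision_mode = state$collision_mode,
    collision_threshold = state$collision_threshold,
    flexible = !is.null(state$response_model),
    relax = unclass(state$relax))
  lines <- c(jsonlite::toJSON(header, auto_unbox = TRUE, digits = I(17)),
             vapply(state$trace, function(r)
               as.character(jsonlite::toJSON(r, auto_unbox = TRUE,
                                             digits = I(17))),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a session trace written by [write_session_trace()]
#' @param path JSON-lines trace path.
#' @return list with `header` and `records`.
#' @export
read_session_trace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  objs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  list(header = objs[[1]], records = objs[-1])
}

#' Replay a recorded session
#'
#' Re-applies every recorded event (moves, component toggles, ghost
#' selections) to a freshly constructed session over the same molecules.
#' Replay is deterministic: the transform history is reproduced
#' bit-identically and energies to numerical tolerance.
#'
#' @param state a fresh `docking_session` built with the same molecules and
#'   configuration as the recorded one.
#' @param trace a path to a JSON-lines trace or the result of
#'   [read_session_trace()].
#' @return the replayed session state.
#' @export
replay_session <- function(state, trace) {
  if (is.character(trace)) trace <- read_session_trace(trace)
  for (r in trace$records) {
    if (r$event == "init") next
    if (r$event == "move") {
      delta <- rigid_transform(matrix(r$rotation, 3, 3, byrow = TRUE),
                               r$translation)
      state <- propose_move(state, r$which, delta)$state
    } else if (r$event == "components") {
      state <- set_components(state,
                              vdw_repulsive = r$components$vdw_repulsive,
                              vdw_attractive = r$components$vdw_attractive,
                              electrostatic = r$components$electrostatic)
    } else if (r$event == "ghost") {
      state <- set_ghost(state, unlist(r$selection), which = r$which,
                         ghost = isTRUE(r$ghost))
    }
  }
  state
}
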