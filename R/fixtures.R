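# Synthetic-data generators. Every generator is a pure function of its
# arguments plus the seed: the global RNG stream is saved and restored, so
# fixtures never leak RNG state into the caller.

with_fixture_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# element-cycled nonbonded parameters for synthetic atoms; LJ from the
# bundled element defaults, small mixed-sign charges so the electrostatic
# component is exercised
fixture_elements <- function() {
  tab <- read_parameter_table()
  els <- c("C", "N", "O", "S", "P")
  chg <- c(0.10, -0.30, -0.40, 0.20, 0.40)
  list(elements = els, charges = chg, defaults = tab$element_defaults)
}

#' Random atom cloud fixture
#'
#' `n` atoms uniform in a cubic box with element-cycled parameters (C, N, O,
#' S, P with the bundled element-default Lennard-Jones terms and small
#' mixed-sign charges). Deterministic under `seed`.
#'
#' @param n atom count (>= 1).
#' @param box cube edge, Angstrom.
#' @param seed RNG seed.
#' @param chain chain identifier.
#' @return a parameterized [molecule()].
#' @export
make_random_cloud <- function(n, box = 40, seed = 1, chain = "A") {
  if (n < 1) stop("make_random_cloud: n must be >= 1")
  fe <- fixture_elements()
  with_fixture_seed(seed, {
    xyz <- matrix(stats::runif(3 * n, 0, box), ncol = 3)
    k <- ((seq_len(n) - 1L) %% length(fe$elements)) + 1L
    el <- fe$elements[k]
    atoms <- data.frame(
      serial = seq_len(n), name = paste0(el, seq_len(n)), element = el,
      resname = "UNK", resseq = seq_len(n), chain = chain,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      charge = fe$charges[k],
      c6 = vapply(el, function(e) fe$defaults[[e]]$c6, numeric(1)),
      c12 = vapply(el, function(e) fe$defaults[[e]]$c12, numeric(1)),
      vdw_radius = vapply(el, function(e) fe$defaults[[e]]$vdw_radius,
                          numeric(1)),
      stringsAsFactors = FALSE)
    mol <- molecule(atoms, title = sprintf("random cloud n=%d seed=%d", n, seed))
    mol$parameterized <- TRUE
    mol
  })
}

#' Gaussian ensemble with planted covariance modes
#'
#' Frames are `base + sum_m sqrt(lambda_m) z_m v_m + noise`, `z` standard
#' normal, so the sample covariance converges to
#' `sum_m lambda_m v_m v_m^t + noise_sd^2 I`. The generator feeds the
#' response-model recovery tests with a known ground truth.
#'
#' @param n_atoms atom count (3N coordinates per frame).
#' @param modes list of `list(direction = <3N vector>, lambda = <A^2>)`;
#'   directions are orthonormalized (Gram-Schmidt) before use.
#' @param noise_sd isotropic noise standard deviation, Angstrom.
#' @param n_frames frame count.
#' @param seed RNG seed.
#' @param base optional length-3N base coordinates (default: a compact
#'   random cloud derived from the seed).
#' @return list with `ensemble` (F x 3N matrix), `modes` (orthonormalized
#'   3N x M matrix), `lambda`, `base`.
#' @export
make_harmonic_ensemble <- function(n_atoms, modes = list(), noise_sd = 0,
                                   n_frames = 100, seed = 1, base = NULL) {
  n3 <- 3L * n_atoms
  with_fixture_seed(seed, {
    if (is.null(base))
      base <- as.numeric(matrix(stats::runif(n3, 0, 15), ncol = 3))
    stopifnot(length(base) == n3)
    M <- length(modes)
    V <- NULL; lambda <- numeric(0)
    if (M > 0) {
      V <- matrix(0, n3, M)
      for (m in seq_len(M)) {
        v <- as.numeric(modes[[m]]$direction)
        stopifnot(length(v) == n3)
        if (m > 1) v <- v - V[, 1:(m - 1), drop = FALSE] %*%
            crossprod(V[, 1:(m - 1), drop = FALSE], v)
        V[, m] <- v / sqrt(sum(v^2))
        lambda[m] <- modes[[m]]$lambda
      }
    }
    E <- matrix(rep(base, each = n_frames), n_frames, n3)
    if (M > 0) {
      Z <- matrix(stats::rnorm(n_frames * M), n_frames, M)
      E <- E + Z %*% (t(V) * sqrt(lambda))
    }
    if (noise_sd > 0)
      E <- E + matrix(stats::rnorm(n_frames * n3, sd = noise_sd),
                      n_frames, n3)
    list(ensemble = E, modes = V, lambda = lambda, base = base)
  })
}

#' Exact hydrogen-bond geometry fixture
#'
#' A two-atom donor molecule (donor at the origin, hydrogen at 1.0 Angstrom
#' along +x) and a one-atom acceptor placed so that the hydrogen-acceptor
#' distance and the donor-hydrogen-acceptor angle equal the arguments
#' exactly (angle 180 = linear).
#'
#' @param d_HA hydrogen-acceptor distance, Angstrom.
#' @param angle D-H-A angle, degrees.
#' @return list with `donor` and `acceptor` molecules, parameterized and
#'   role-flagged.
#' @export
make_hbond_geometry <- function(d_HA, angle) {
  phi <- angle * pi / 180
  A <- c(1, 0, 0) + d_HA * c(-cos(phi), sin(phi), 0)
  donor <- molecule(data.frame(
    serial = 1:2, name = c("D", "HD"), element = c("N", "H"),
    resname = "FIX", resseq = 1, chain = "A",
    x = c(0, 1), y = 0, z = 0,
    charge = c(-0.3, 0.3), c6 = 0, c12 = 0, vdw_radius = c(1.55, 1.20),
    is_donor = c(TRUE, FALSE), is_acceptor = FALSE,
    is_hydrogen = c(FALSE, TRUE), stringsAsFactors = FALSE))
  donor$bonded_hydrogens[[1]] <- 2L
  donor$parameterized <- TRUE
  acceptor <- molecule(data.frame(
    serial = 1, name = "A", element = "O", resname = "FIX", resseq = 1,
    chain = "B", x = A[1], y = A[2], z = A[3],
    charge = -0.4, c6 = 0, c12 = 0, vdw_radius = 1.52,
    is_donor = FALSE, is_acceptor = TRUE, is_hydrogen = FALSE,
    stringsAsFactors = FALSE))
  acceptor$parameterized <- TRUE
  list(donor = donor, acceptor = acceptor)
}

#' Random donor/acceptor cloud fixture
#'
#' Donor heavy atoms with one hydrogen each (random orientation, 1.0
#' Angstrom bond) and a separate acceptor molecule, all uniform in a box
#' small enough that hydrogen bonds occur. Feeds the grid-vs-exhaustive
#' oracle tests.
#'
#' @param n_donors,n_acceptors atom counts.
#' @param box cube edge, Angstrom.
#' @param seed RNG seed.
#' @return list with `donor` and `acceptor` molecules.
#' @export
make_hbond_cloud <- function(n_donors = 40, n_acceptors = 40, box = 15,
                             seed = 1) {
  with_fixture_seed(seed, {
    dp <- matrix(stats::runif(3 * n_donors, 0, box), ncol = 3)
    u <- matrix(stats::rnorm(3 * n_donors), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    hp <- dp + u
    atoms <- data.frame(
      serial = seq_len(2 * n_donors),
      name = c(paste0("D", seq_len(n_donors)), paste0("H", seq_len(n_donors))),
      element = rep(c("N", "H"), each = n_donors),
      resname = "FIX", resseq = rep(seq_len(n_donors), 2), chain = "A",
      x = c(dp[, 1], hp[, 1]), y = c(dp[, 2], hp[, 2]),
      z = c(dp[, 3], hp[, 3]),
      charge = rep(c(-0.3, 0.3), each = n_donors), c6 = 0, c12 = 0,
      vdw_radius = rep(c(1.55, 1.20), each = n_donors),
      is_donor = rep(c(TRUE, FALSE), each = n_donors),
      is_acceptor = FALSE,
      is_hydrogen = rep(c(FALSE, TRUE), each = n_donors),
      stringsAsFactors = FALSE)
    donor <- molecule(atoms, title = "hbond donor cloud")
    donor$bonded_hydrogens[seq_len(n_donors)] <-
      as.list(n_donors + seq_len(n_donors))
    donor$parameterized <- TRUE
    ap <- matrix(stats::runif(3 * n_acceptors, 0, box), ncol = 3)
    acc <- molecule(data.frame(
      serial = seq_len(n_acceptors), name = paste0("A", seq_len(n_acceptors)),
      element = "O", resname = "FIX", resseq = seq_len(n_acceptors),
      chain = "B", x = ap[, 1], y = ap[, 2], z = ap[, 3],
      charge = -0.4, c6 = 0, c12 = 0, vdw_radius = 1.52,
      is_donor = FALSE, is_acceptor = TRUE, is_hydrogen = FALSE,
      stringsAsFactors = FALSE), title = "hbond acceptor cloud")
    acc$parameterized <- TRUE
    list(donor = donor, acceptor = acc)
  })
}

#' Salt-bridge docking scene
#'
#' A minimal flexible-receptor session for the electrostatics on/off/on
#' story: the receptor holds a negatively charged internal acceptor site and
#' a mobile positively charged amine-like probe (donor N with two polar
#' hydrogens, one pointing at each site); the one-atom ligand is a
#' negatively charged acceptor. A single response mode translates the probe
#' group along the line between the sites. With electrostatics on, the probe
#' relaxes toward the ligand site, breaking the internal hydrogen bond and
#' forming one to the ligand; switching electrostatics off lets it fall back
#' to the relaxed structure.
#'
#' @param seed kept for API uniformity; the scene is fully deterministic.
#' @return a `docking_session` (force-mode collision, flexible receptor).
#' @export
make_salt_bridge_scene <- function(seed = 1) {
  tab <- read_parameter_table()
  rec <- molecule(data.frame(
    serial = 1:4, name = c("OE1", "NZ", "HZ1", "HZ2"),
    element = c("O", "N", "H", "H"),
    resname = c("SIT", "PRB", "PRB", "PRB"), resseq = c(1, 2, 2, 2),
    chain = "A",
    x = c(-3.3, 0, -1, 1), y = 0, z = 0, stringsAsFactors = FALSE),
    title = "salt-bridge receptor")
  rec <- assign_parameters(rec, tab)
  lig <- molecule(data.frame(
    serial = 1, name = "OC1", element = "O", resname = "LIG", resseq = 1,
    chain = "B", x = 3.8, y = 0, z = 0, stringsAsFactors = FALSE),
    title = "salt-bridge ligand")
  lig <- assign_parameters(lig, tab)
  v <- numeric(12)
  v[c(4, 7, 10)] <- 1 / sqrt(3)  # +x on NZ, HZ1, HZ2
  model <- response_model(r_o = flatten_xyz(positions(rec)),
                          V = matrix(v, ncol = 1), lambda = 0.2,
                          temperature = 300)
  docking_session(rec, lig, ff = force_field(), response_model = model,
                  collision_mode = "force")
}

#' Random receptor-ligand pair without vdW-core interpenetration
#'
#' Two random clouds in overlapping boxes, with ligand atoms rejection
#' resampled until no receptor-ligand (or ligand-ligand) pair sits closer
#' than `min_contact`. Real structures never interpenetrate their vdW cores;
#' keeping fixture contacts above ~1.7 Angstrom also keeps the r^-13
#' repulsion term out of the regime where last-digit rounding is amplified
#' into meaningful force differences.
#'
#' @param n_rec,n_lig atom counts.
#' @param box cube edge for the receptor cloud, Angstrom; the ligand box is
#'   80\% of it, sharing the origin, so the clouds interleave.
#' @param seed RNG seed.
#' @param min_contact smallest allowed interatomic distance involving a
#'   ligand atom, Angstrom.
#' @return list with `receptor` and `ligand` molecules.
#' @export
make_docking_pair <- function(n_rec, n_lig, box = 25, seed = 1,
                              min_contact = 1.7) {
  rec <- make_random_cloud(n_rec, box, seed = seed)
  fe <- fixture_elements()
  with_fixture_seed(seed + 500000L, {
    rp <- positions(rec)
    lp <- matrix(NA_real_, n_lig, 3)
    placed <- 0L
    while (placed < n_lig) {
      cand <- stats::runif(3, 0, 0.8 * box)
      ok <- all(sqrt(colSums((t(rp) - cand)^2)) >= min_contact) &&
        (placed == 0L ||
           all(sqrt(colSums((t(lp[seq_len(placed), , drop = FALSE]) -
                               cand)^2)) >= min_contact))
      if (ok) {
        placed <- placed + 1L
        lp[placed, ] <- cand
      }
    }
    k <- ((seq_len(n_lig) - 1L) %% length(fe$elements)) + 1L
    el <- fe$elements[k]
    atoms <- data.frame(
      serial = seq_len(n_lig), name = paste0(el, seq_len(n_lig)),
      element = el, resname = "UNK", resseq = seq_len(n_lig), chain = "B",
      x = lp[, 1], y = lp[, 2], z = lp[, 3],
      charge = fe$charges[k],
      c6 = vapply(el, function(e) fe$defaults[[e]]$c6, numeric(1)),
      c12 = vapply(el, function(e) fe$defaults[[e]]$c12, numeric(1)),
      vdw_radius = vapply(el, function(e) fe$defaults[[e]]$vdw_radius,
                          numeric(1)),
      stringsAsFactors = FALSE)
    lig <- molecule(atoms, title = sprintf("docking ligand n=%d seed=%d",
                                           n_lig, seed))
    lig$parameterized <- TRUE
    list(receptor = rec, ligand = lig)
  })
}

#' Two isolated single-atom molecules at a given separation
#'
#' The simplest force/collision fixture: one receptor atom at the origin and
#' one ligand atom at `separation` along +x, with element-default
#' parameters and the given charges.
#'
#' @param separation interatomic distance, Angstrom.
#' @param elements length-2 element symbols.
#' @param charges length-2 charges, e.
#' @return list with `receptor` and `ligand` molecules.
#' @export
make_toy_pair <- function(separation = 4, elements = c("C", "C"),
                          charges = c(0.2, -0.2)) {
  fe <- fixture_elements()
  mk <- function(el, q, x, chain) {
    d <- fe$defaults[[el]]
    m <- molecule(data.frame(
      serial = 1, name = paste0(el, 1), element = el, resname = "UNK",
      resseq = 1, chain = chain, x = x, y = 0, z = 0, charge = q,
      c6 = d$c6, c12 = d$c12, vdw_radius = d$vdw_radius,
      stringsAsFactors = FALSE))
    m$parameterized <- TRUE
    m
  }
  list(receptor = mk(elements[1], charges[1], 0, "A"),
       ligand = mk(elements[2], charges[2], separation, "B"))
}
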