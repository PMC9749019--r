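#' Boltzmann constant in kJ mol^-1 K^-1
#' @export
KB_KJ_MOL_K <- 0.0083144621

#' Linear-response model of receptor flexibility
#'
#' Linear response approximates the mean deformation of a receptor under
#' small external forces from its equilibrium fluctuations: with `V` the
#' first M eigenvectors of the 3N x 3N variance-covariance matrix of atomic
#' fluctuations and `lambda` the matching eigenvalues, the displacement from
#' the relaxed structure `r_o` under forces `f` is
#' `dr = beta V diag(lambda) V^t f`, `beta = 1/(k_b T)`. Truncating to the
#' "important subspace" (small M) keeps memory and evaluation time bounded.
#'
#' @param r_o relaxed coordinates, length-3N vector (Angstrom), ordered
#'   (x1, y1, z1, ...).
#' @param V 3N x M eigenvector matrix, columns orthonormal.
#' @param lambda M eigenvalues (Angstrom^2), descending, non-negative.
#' @param temperature absolute temperature, Kelvin.
#' @return object of class `response_model` with fields `r_o`, `V`,
#'   `lambda`, `beta` (mol kJ^-1), `M`, `N`, `temperature`.
#' @export
response_model <- function(r_o, V, lambda, temperature = 300) {
  r_o <- as.numeric(r_o)
  V <- as.matrix(V)
  lambda <- as.numeric(lambda)
  if (length(r_o) %% 3 != 0) stop("response_model: r_o length must be 3N")
  if (nrow(V) != length(r_o))
    stop("response_model: V must have 3N = ", length(r_o), " rows")
  if (ncol(V) != length(lambda))
    stop("response_model: ", ncol(V), " eigenvectors but ",
         length(lambda), " eigenvalues")
  if (any(lambda < 0)) stop("response_model: negative eigenvalue")
  if (is.unsorted(rev(lambda))) stop("response_model: eigenvalues must be descending")
  if (ncol(V) > nrow(V)) stop("response_model: M must be <= 3N")
  orth <- max(abs(crossprod(V) - diag(ncol(V))))
  if (orth > 1e-8)
    stop("response_model: eigenvector columns not orthonormal (max deviation ",
         format(orth), ")")
  structure(list(r_o = r_o, V = V, lambda = lambda,
                 beta = 1 / (KB_KJ_MOL_K * temperature),
                 temperature = temperature,
                 M = length(lambda), N = length(r_o) %/% 3L),
            class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat(sprintf("response_model: N = %d atoms, M = %d modes, T = %g K, lambda[1] = %g A^2\n",
              x$N, x$M, x$temperature,
              if (x$M > 0) x$lambda[1] else NA_real_))
  invisible(x)
}

#' Atomic displacements under external forces
#'
#' Evaluates `dr = beta V diag(lambda) V^t f` as three matrix-vector
#' products; the 3N x 3N response matrix is never materialized.
#'
#' @param model a [response_model()].
#' @param forces length-3N force vector, kJ mol^-1 A^-1, in the model frame.
#' @return length-3N displacement vector, Angstrom.
#' @export
displacement <- function(model, forces) {
  forces <- as.numeric(forces)
  if (length(forces) != 3L * model$N)
    stop("displacement: forces must have length 3N = ", 3L * model$N)
  as.numeric(model$beta * (model$V %*% (model$lambda * crossprod(model$V, forces))))
}

#' Relaxation settings for the iterative equilibrium search
#' @param alpha mixing fraction in (0, 1]; each iteration moves this far
#'   toward the fresh linear-response prediction. Default 0.2 damps the
#'   force-displacement feedback enough for smooth convergence.
#' @param tolerance convergence threshold on the max-norm coordinate change
#'   per iteration, Angstrom.
#' @param max_iterations iteration cap; exceeding it flags non-convergence
#'   rather than raising an error.
#' @return object of class `relaxation_settings`.
#' @export
relaxation_settings <- function(alpha = 0.2, tolerance = 1e-4,
                                max_iterations = 500) {
  stopifnot(alpha > 0, alpha <= 1, tolerance > 0, max_iterations >= 1)
  structure(list(alpha = alpha, tolerance = tolerance,
                 max_iterations = max_iterations),
            class = "relaxation_settings")
}

#' Iterate smoothly to static equilibrium
#'
#' Damped fixed-point iteration
#' `dr_{k+1} = (1 - alpha) dr_k + alpha * displacement(model, f(r_o + dr_k))`
#' from `dr_0 = 0`, stopping when the max-norm change falls below the
#' tolerance. At the fixed point the external ligand forces are balanced by
#' the receptor's restoring forces. The iteration is deterministic: repeated
#' calls for the same pose give identical results.
#'
#' @param model a [response_model()].
#' @param force_function function mapping length-3N coordinates to
#'   length-3N forces (model frame).
#' @param settings a [relaxation_settings()].
#' @return list with `coordinates` (length-3N, `r_o + dr`), `deformation`
#'   (`dr`), `converged`, `iterations`, `trace` (per-iteration max change,
#'   Angstrom).
#' @export
relax_to_equilibrium <- function(model, force_function,
                                 settings = relaxation_settings()) {
  dr <- numeric(3L * model$N)
  trace <- numeric(0)
  converged <- FALSE
  for (k in seq_len(settings$max_iterations)) {
    f <- as.numeric(force_function(model$r_o + dr))
    if (length(f) != 3L * model$N || !all(is.finite(f)))
      stop("relax_to_equilibrium: force function returned non-finite or mis-sized forces")
    dr_new <- (1 - settings$alpha) * dr +
      settings$alpha * displacement(model, f)
    step <- max(abs(dr_new - dr))
    trace <- c(trace, step)
    dr <- dr_new
    if (step < settings$tolerance) { converged <- TRUE; break }
  }
  list(coordinates = model$r_o + dr, deformation = dr,
       converged = converged, iterations = length(trace), trace = trace)
}

#' Kabsch superposition of one coordinate set onto another
#'
#' Least-squares optimal rotation + translation (SVD-based, with the
#' determinant correction for proper rotations).
#'
#' @param mobile,ref N x 3 coordinate matrices.
#' @return list with `xyz` (superposed mobile), `rotation`, `translation`
#'   such that `xyz = mobile %*% t(rotation) + translation` row-wise.
#' @export
kabsch <- function(mobile, ref) {
  cm <- colMeans(mobile); cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm); B <- sweep(ref, 2, cr)
  s <- svd(crossprod(A, B))  # 3x3
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  xyz <- sweep(A %*% t(R), 2, cr, "+")
  list(xyz = xyz, rotation = R, translation = as.numeric(cr - R %*% cm))
}

superpose_ensemble <- function(ensemble) {
  ref <- unflatten_xyz(ensemble[1, ])
  t(apply(ensemble, 1, function(fr)
    flatten_xyz(kabsch(unflatten_xyz(fr), ref)$xyz)))
}

#' Index of the frame closest to the ensemble average
#'
#' After the same optional superposition used by [build_response_model()],
#' returns the (1-based) index of the frame with minimum RMSD to the mean
#' coordinates; ties go to the lowest index.
#'
#' @param ensemble F x 3N coordinate matrix, one frame per row.
#' @param superpose Kabsch-superpose frames onto the first before averaging.
#' @return integer frame index.
#' @export
closest_to_average <- function(ensemble, superpose = TRUE) {
  ensemble <- as.matrix(ensemble)
  stopifnot(nrow(ensemble) >= 1)
  if (nrow(ensemble) == 1L) return(1L)
  if (superpose) ensemble <- superpose_ensemble(ensemble)
  mu <- colMeans(ensemble)
  rmsd <- sqrt(rowMeans(sweep(ensemble, 2, mu)^2) * 3)
  unname(which.min(rmsd))  # which.min takes the first (lowest-index) minimum
}

#' Build a truncated response model from a coordinate ensemble
#'
#' Optionally Kabsch-superposes all frames onto the first (removing
#' rigid-body motion that would otherwise dominate the spectrum), computes
#' the 3N x 3N Cartesian variance-covariance matrix of atomic fluctuations
#' (1/F normalization, no mass weighting) and takes its top-M eigenpairs.
#' For F < 3N the eigenproblem is solved through the F x F Gram matrix, so
#' the dense 3N x 3N covariance is never formed. The relaxed structure `r_o`
#' is the closest-to-average frame.
#'
#' @param ensemble F x 3N coordinate matrix (F >= 2 frames).
#' @param M number of modes to retain, `M <= min(3N, F - 1)`.
#' @param temperature Kelvin.
#' @param superpose superpose frames before the covariance (default TRUE).
#' @return a [response_model()] with extra fields `captured_fraction`
#'   (retained share of total fluctuation, 0 for a zero-variance ensemble),
#'   `r_o_frame` (index of the closest-to-average frame).
#' @export
build_response_model <- function(ensemble, M, temperature = 300,
                                 superpose = TRUE) {
  ensemble <- as.matrix(ensemble)
  F_ <- nrow(ensemble); n3 <- ncol(ensemble)
  if (F_ < 2) stop("build_response_model: need at least 2 frames")
  if (M > min(n3, F_ - 1))
    stop("build_response_model: M = ", M, " exceeds min(3N, F-1) = ",
         min(n3, F_ - 1))
  if (superpose) ensemble <- superpose_ensemble(ensemble)
  mu <- colMeans(ensemble)
  X <- sweep(ensemble, 2, mu)         # F x 3N deviations
  total_var <- sum(X^2) / F_          # trace of the covariance
  if (total_var == 0) {
    warning("build_response_model: zero-variance ensemble; all eigenvalues 0")
    V <- diag(n3)[, seq_len(M), drop = FALSE]
    lambda <- rep(0, M)
    captured <- 0
  } else if (F_ < n3) {
    # Gram trick: eigenvectors of (1/F) X X^t (F x F) lift to covariance
    # eigenvectors X^t u / sqrt(F lambda)
    G <- tcrossprod(X) / F_
    eg <- eigen(G, symmetric = TRUE)
    lambda <- pmax(eg$values[seq_len(M)], 0)
    V <- crossprod(X, eg$vectors[, seq_len(M), drop = FALSE])
    nz <- lambda > 1e-12
    V[, nz] <- sweep(V[, nz, drop = FALSE], 2, sqrt(F_ * lambda[nz]), "/")
    if (any(!nz)) V[, !nz] <- orthonormal_complement(V[, nz, drop = FALSE],
                                                     sum(!nz))
    captured <- sum(lambda) / total_var
  } else {
    C <- crossprod(X) / F_
    eg <- eigen(C, symmetric = TRUE)
    lambda <- pmax(eg$values[seq_len(M)], 0)
    V <- eg$vectors[, seq_len(M), drop = FALSE]
    captured <- sum(lambda) / total_var
  }
  idx <- closest_to_average(ensemble, superpose = FALSE)  # already superposed
  model <- response_model(r_o = ensemble[idx, ], V = V, lambda = lambda,
                          temperature = temperature)
  model$captured_fraction <- captured
  model$r_o_frame <- idx
  model
}

# Fill k extra orthonormal columns orthogonal to the columns of V (used only
# when requested modes exceed the ensemble rank).
orthonormal_complement <- function(V, k) {
  n <- nrow(V)
  out <- matrix(0, n, k)
  got <- 0L
  basis <- V
  for (j in seq_len(n)) {
    v <- numeric(n); v[j] <- 1
    if (ncol(basis) > 0) v <- v - basis %*% crossprod(basis, v)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) {
      v <- v / nv
      got <- got + 1L
      out[, got] <- v
      basis <- cbind(basis, v)
      if (got == k) break
    }
  }
  out
}
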