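#' Construct a molecule
#'
#' A `molecule` is the package's central container: an ordered atom table plus
#' per-donor hydrogen bookkeeping. Coordinates are in Angstrom, charges in
#' elementary charge units, Lennard-Jones parameters in the GROMOS C6/C12 form
#' (kJ mol^-1 A^6 and kJ mol^-1 A^12).
#'
#' @param atoms data frame with (at least) columns `serial`, `name`,
#'   `element`, `resname`, `resseq`, `chain`, `x`, `y`, `z`. Chemistry columns
#'   (`charge`, `c6`, `c12`, `vdw_radius`) and role flags (`is_donor`,
#'   `is_acceptor`, `is_hydrogen`, `is_ghost`) are added as zero/FALSE when
#'   absent; [assign_parameters()] fills them.
#' @param title free-text title.
#' @param source_format one of `"pdb"`, `"mmcif"`, `"synthetic"`.
#' @return object of class `molecule`.
#' @export
molecule <- function(atoms, title = "", source_format = "synthetic") {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "element", "resname", "resseq", "chain",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0L)
    stop("molecule: missing atom columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L)
    stop("molecule: empty structure (no atoms)")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("molecule: non-finite coordinates")
  defaults <- list(insert = "", charge = 0, c6 = 0, c12 = 0, vdw_radius = 0,
                   is_donor = FALSE, is_acceptor = FALSE,
                   is_hydrogen = FALSE, is_ghost = FALSE)
  for (nm in names(defaults))
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  rownames(atoms) <- NULL
  structure(list(
    atoms = atoms,
    bonded_hydrogens = rep(list(integer(0)), nrow(atoms)),
    title = title,
    source_format = source_format,
    parameterized = FALSE
  ), class = "molecule")
}

#' Number of atoms in a molecule
#' @param mol a `molecule`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Atom coordinates as an N x 3 matrix
#' @param mol a `molecule`.
#' @return numeric N x 3 matrix (Angstrom).
#' @export
positions <- function(mol) {
  cbind(x = mol$atoms$x, y = mol$atoms$y, z = mol$atoms$z)
}

#' Replace atom coordinates
#' @param mol a `molecule`.
#' @param xyz N x 3 matrix or length-3N vector ordered (x1,y1,z1,...).
#' @return the molecule with updated coordinates.
#' @export
set_positions <- function(mol, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  stopifnot(nrow(xyz) == n_atoms(mol), ncol(xyz) == 3)
  if (!all(is.finite(xyz))) stop("set_positions: non-finite coordinates")
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

#' Flatten an N x 3 coordinate matrix to the 3N vector convention
#'
#' The package orders flattened coordinates (x1, y1, z1, x2, ...), the same
#' layout as eigenvector file rows.
#' @param xyz N x 3 matrix.
#' @return length-3N numeric vector.
#' @export
flatten_xyz <- function(xyz) as.numeric(t(xyz))

#' Reshape a 3N coordinate vector to N x 3
#' @param v length-3N vector ordered (x1, y1, z1, x2, ...).
#' @return N x 3 matrix.
#' @export
unflatten_xyz <- function(v) matrix(v, ncol = 3, byrow = TRUE)

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule: %d atoms, %d chain(s), source %s%s\n",
              n_atoms(x), length(unique(x$atoms$chain)), x$source_format,
              if (x$parameterized) ", parameterized" else ""))
  if (nzchar(x$title)) cat("  title: ", x$title, "\n", sep = "")
  invisible(x)
}

# Indices of atoms that take part in force/collision/H-bond work.
active_atoms <- function(mol) which(!mol$atoms$is_ghost)

stop_if_unparameterized <- function(mol, what) {
  if (!isTRUE(mol$parameterized))
    stop(what, ": molecule has no nonbonded parameters; run assign_parameters() first")
  bad <- which(mol$atoms$vdw_radius <= 0)
  if (length(bad) > 0L)
    stop(what, ": atoms without vdW radius: ",
         paste(utils::head(mol$atoms$name[bad], 10), collapse = ", "))
  invisible(TRUE)
}
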