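#' Read a molecular structure from PDB or mmCIF
#'
#' Parses ATOM/HETATM records into a [molecule()]. Only the first model of a
#' multi-model file is kept (single-conformer docking semantics). For atoms
#' with alternate locations, the highest-occupancy altloc is kept, ties going
#' to the record that appears first in the file. Chemistry fields (charge,
#' C6/C12, vdW radius, donor/acceptor flags) are left unassigned until
#' [assign_parameters()].
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by file extension).
#' @return a [molecule()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_structure: cannot read '", path, "'")
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb")
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    else  # read.cif warns about its beta status and absent helix/sheet data
      suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE)),
    error = function(e) stop("read_structure: failed to parse '", path,
                             "' as ", format, ": ", conditionMessage(e)))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("read_structure: no atoms parsed from '", path, "'")
  # altloc policy: within an (chain, resno, insert, resname, name) group keep
  # the highest-occupancy record; ties -> first in file
  alt <- at$alt; alt[is.na(alt)] <- ""
  occ <- at$o; occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               at$resid, at$elety, sep = "|")
  keep <- rep(TRUE, nrow(at))
  for (g in split(seq_len(nrow(at)), key)) {
    if (length(g) > 1L && any(nzchar(alt[g]))) {
      best <- g[which.max(occ[g])]
      keep[setdiff(g, best)] <- FALSE
    }
  }
  at <- at[keep, , drop = FALSE]
  elem <- at$elesy
  elem[is.na(elem) | !nzchar(elem)] <-
    guess_element(at$elety[is.na(elem) | !nzchar(elem)])
  atoms <- data.frame(
    serial = at$eleno, name = at$elety, element = toupper(elem),
    resname = at$resid, resseq = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    record = ifelse(at$type == "HETATM", "HETATM", "ATOM"),
    stringsAsFactors = FALSE)
  mol <- molecule(atoms, title = basename(path), source_format = format)
  if (format == "pdb") mol$conect <- read_conect(path, atoms$serial)
  mol
}

guess_element <- function(name) {
  two <- c("CL", "BR", "FE", "ZN", "MG", "NA", "MN", "CA", "SE")
  vapply(name, function(nm) {
    s <- toupper(gsub("[0-9']", "", nm))
    if (nchar(s) >= 2 && substr(s, 1, 2) %in% two) substr(s, 1, 2)
    else substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

# CONECT records as a list serial -> connected serials (used to override the
# distance-based donor-hydrogen association).
read_conect <- function(path, serials) {
  lines <- grep("^CONECT", readLines(path, warn = FALSE), value = TRUE)
  if (length(lines) == 0L) return(NULL)
  out <- list()
  add <- function(a, b) {
    k <- as.character(a)
    out[[k]] <<- unique(c(out[[k]], b))
  }
  for (ln in lines) {
    f <- suppressWarnings(as.integer(strsplit(trimws(substring(ln, 7)),
                                              "\\s+")[[1]]))
    f <- f[!is.na(f)]
    if (length(f) >= 2) {
      for (b in f[-1]) {  # bonds are symmetric even if listed one-way
        add(f[1], b)
        add(b, f[1])
      }
    }
  }
  out
}

#' Write a molecule as a PDB file
#'
#' Fixed-column ATOM/HETATM records, a TER record between chains and a
#' terminating END. Round-trips through [read_structure()] preserving serial,
#' name, residue, chain and coordinates (to the 0.001 Angstrom precision of
#' the format).
#'
#' @param mol a [molecule()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_pdb <- function(mol, path) {
  stopifnot(inherits(mol, "molecule"))
  if (n_atoms(mol) == 0L) stop("write_pdb: empty molecule")
  a <- mol$atoms
  record <- if (is.null(a$record)) rep("ATOM", nrow(a)) else a$record
  # atom-name column: names shorter than 4 characters start in column 14
  nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  lines <- sprintf("%-6s%5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   record, a$serial %% 100000L, nm, substr(a$resname, 1, 3),
                   substr(a$chain, 1, 1), a$resseq %% 10000L,
                   ifelse(nzchar(a$insert), a$insert, " "),
                   a$x, a$y, a$z, 1, 0, a$element)
  # TER after the last atom of every chain but the final one
  chain_end <- which(diff(as.integer(factor(a$chain,
                                            levels = unique(a$chain)))) != 0)
  out <- character(0)
  prev <- 1L
  for (ce in c(chain_end, nrow(a))) {
    out <- c(out, lines[prev:ce], "TER")
    prev <- ce + 1L
  }
  out[length(out)] <- "TER"
  out <- c(out, "END")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("write_pdb: cannot write '", path, "'"))
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Bundled nonbonded parameter table
#'
#' A small synthetic force-field table covering the package's fixture
#' chemistry (generic C/N/O/S/H/P atoms, water, and the charged probe/site
#' atoms of the salt-bridge scene). It is not a redistribution of any
#' published force field; real docking work should supply a user table with
#' `read_parameter_table()`.
#'
#' @param path JSON table path; `NULL` loads the bundled table.
#' @return object of class `parameter_table`: a lookup keyed by
#'   (residue name, atom name) plus element-based defaults, a combination
#'   rule and a provenance tag.
#' @export
read_parameter_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "parameter_table.json", package = "dockflex")
  tab <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- list()
  for (e in tab$entries) {
    lj <- entry_lj(e)
    entries[[paste(e$residue, e$atom, sep = "|")]] <-
      list(charge = as.numeric(e$charge), c6 = lj$c6, c12 = lj$c12,
           vdw_radius = as.numeric(e$vdw_radius),
           donor = isTRUE(e$donor), acceptor = isTRUE(e$acceptor))
  }
  element_defaults <- lapply(tab$element_defaults, function(e) {
    lj <- entry_lj(e)
    list(charge = as.numeric(e$charge %||% 0), c6 = lj$c6, c12 = lj$c12,
         vdw_radius = as.numeric(e$vdw_radius))
  })
  structure(list(entries = entries, element_defaults = element_defaults,
                 combination_rule = tab$combination_rule %||% "geometric",
                 provenance = tab$provenance %||% "unknown"),
            class = "parameter_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sigma (A) / epsilon (kJ/mol) tables are converted to the GROMOS-native
# C6/C12 form: C6 = 4 eps sigma^6, C12 = 4 eps sigma^12.
entry_lj <- function(e) {
  if (!is.null(e$c6) || !is.null(e$c12))
    return(list(c6 = as.numeric(e$c6 %||% 0), c12 = as.numeric(e$c12 %||% 0)))
  if (!is.null(e$sigma)) {
    s <- as.numeric(e$sigma); eps <- as.numeric(e$epsilon %||% 0)
    return(list(c6 = 4 * eps * s^6, c12 = 4 * eps * s^12))
  }
  list(c6 = 0, c12 = 0)
}

#' Bundled donor/acceptor atom-name map
#'
#' Residue-keyed donor and acceptor atom names (standard amino acids,
#' nucleotides, water, common sugar/hetero atoms) used to flag hydrogen-bond
#' roles during parameter assignment. Editable JSON resource.
#'
#' @param path JSON map path; `NULL` loads the bundled map.
#' @return list with `donors` and `acceptors`, each keyed by residue name
#'   (`"*"` = any residue) mapping to atom-name vectors.
#' @export
read_donor_acceptor_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "donor_acceptor_map.json",
                        package = "dockflex")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

map_role <- function(map_side, resname, atname) {
  (resname %in% names(map_side) && atname %in% map_side[[resname]]) ||
    ("*" %in% names(map_side) && atname %in% map_side[["*"]])
}

#' Assign nonbonded parameters and hydrogen-bond roles
#'
#' Looks every atom up by (residue name, atom name) in the parameter table
#' and fills charge, C6, C12 and vdW radius; flags donors and acceptors from
#' the table roles plus the donor/acceptor map; associates each hydrogen with
#' its covalently bonded heavy atom (nearest heavy atom within 1.25 Angstrom;
#' CONECT records, when present, override the distance rule). Hydrogens
#' farther than the threshold from every heavy atom are reported in a
#' warning, never silently dropped.
#'
#' @param mol a [molecule()].
#' @param table a `parameter_table` from [read_parameter_table()].
#' @param policy `"strict"` errors on unknown (residue, atom) pairs;
#'   `"lenient"` falls back to element-based defaults (C 1.70, N 1.55,
#'   O 1.52, S 1.80, H 1.20, P 1.80 Angstrom vdW radius, zero charge) with a
#'   warning.
#' @param da_map donor/acceptor map, default the bundled one.
#' @return the parameterized molecule.
#' @export
assign_parameters <- function(mol, table = read_parameter_table(),
                              policy = c("strict", "lenient"),
                              da_map = read_donor_acceptor_map()) {
  policy <- match.arg(policy)
  stopifnot(inherits(mol, "molecule"))
  a <- mol$atoms
  n <- nrow(a)
  unknown <- character(0)
  for (i in seq_len(n)) {
    key <- paste(a$resname[i], a$name[i], sep = "|")
    e <- table$entries[[key]]
    if (is.null(e)) {
      el <- a$element[i]
      d <- table$element_defaults[[el]]
      if (policy == "strict" || is.null(d)) {
        unknown <- c(unknown, sprintf("%s/%s (atom %d)", a$resname[i],
                                      a$name[i], a$serial[i]))
        next
      }
      e <- list(charge = d$charge, c6 = d$c6, c12 = d$c12,
                vdw_radius = d$vdw_radius,
                donor = map_role(da_map$donors, a$resname[i], a$name[i]),
                acceptor = map_role(da_map$acceptors, a$resname[i], a$name[i]))
    }
    a$charge[i] <- e$charge; a$c6[i] <- e$c6; a$c12[i] <- e$c12
    a$vdw_radius[i] <- e$vdw_radius
    a$is_donor[i] <- isTRUE(e$donor) ||
      map_role(da_map$donors, a$resname[i], a$name[i])
    a$is_acceptor[i] <- isTRUE(e$acceptor) ||
      map_role(da_map$acceptors, a$resname[i], a$name[i])
  }
  if (length(unknown) > 0L)
    stop("assign_parameters: unknown parameters for: ",
         paste(unknown, collapse = "; "))
  a$is_hydrogen <- a$element == "H"
  a$is_donor[a$is_hydrogen] <- FALSE
  a$is_acceptor[a$is_hydrogen] <- FALSE
  mol$atoms <- a
  mol$parameterized <- TRUE
  attach_hydrogens(mol)
}

# Associate each hydrogen to its donor heavy atom: nearest heavy atom within
# 1.25 A (covalent X-H bonds are 0.95-1.1 A); CONECT overrides. Table-flagged
# donors that end up with no bonded hydrogen are demoted with a warning so
# the donor invariant (>= 1 bonded hydrogen) always holds.
attach_hydrogens <- function(mol, threshold = 1.25) {
  a <- mol$atoms
  xyz <- positions(mol)
  hyd <- which(a$is_hydrogen)
  heavy <- which(!a$is_hydrogen)
  bonded <- rep(list(integer(0)), nrow(a))
  orphans <- integer(0)
  for (h in hyd) {
    owner <- NA_integer_
    cn <- mol$conect[[as.character(a$serial[h])]]
    if (!is.null(cn)) {
      cand <- which(a$serial %in% cn & !a$is_hydrogen)
      if (length(cand) > 0L) owner <- cand[1]
    }
    if (is.na(owner) && length(heavy) > 0L) {
      d2 <- colSums((t(xyz[heavy, , drop = FALSE]) - xyz[h, ])^2)
      j <- which.min(d2)
      if (d2[j] <= threshold^2) owner <- heavy[j]
    }
    if (is.na(owner)) orphans <- c(orphans, h)
    else bonded[[owner]] <- c(bonded[[owner]], h)
  }
  if (length(orphans) > 0L)
    warning("assign_parameters: ", length(orphans),
            " hydrogen(s) not within ", threshold,
            " A of any heavy atom (serials ",
            paste(a$serial[orphans], collapse = ", "), ")")
  demote <- which(a$is_donor & lengths(bonded) == 0L)
  if (length(demote) > 0L) {
    warning("assign_parameters: ", length(demote),
            " donor(s) without bonded hydrogens demoted (no hydrogens in structure?)")
    a$is_donor[demote] <- FALSE
  }
  mol$atoms <- a
  mol$bonded_hydrogens <- bonded
  mol
}

#' Read a linear-response model from eigenvalue/eigenvector files
#'
#' File format: the eigenvalue file holds one value per line (Angstrom^2,
#' descending); the eigenvector file holds M whitespace-separated rows of
#' length 3N, row m being mode m in (x1, y1, z1, x2, ...) order.
#'
#' @param eigenvalues_path,eigenvectors_path plain-text file paths.
#' @param relaxed_structure the relaxed receptor [molecule()] (its
#'   coordinates become `r_o`).
#' @param temperature absolute temperature in Kelvin (sets
#'   `beta = 1/(k_b T)`).
#' @return a [response_model()].
#' @export
read_response_model <- function(eigenvalues_path, eigenvectors_path,
                                relaxed_structure, temperature = 300) {
  lambda <- scan(eigenvalues_path, quiet = TRUE)
  if (any(lambda < 0))
    stop("read_response_model: negative eigenvalue in '", eigenvalues_path, "'")
  rows <- lapply(strsplit(trimws(readLines(eigenvectors_path)), "\\s+"),
                 as.numeric)
  rows <- rows[lengths(rows) > 0]
  n3 <- 3L * n_atoms(relaxed_structure)
  bad <- which(lengths(rows) != n3)
  if (length(bad) > 0L)
    stop("read_response_model: eigenvector row(s) ",
         paste(bad, collapse = ", "), " have length != 3N = ", n3)
  if (length(rows) != length(lambda))
    stop("read_response_model: ", length(lambda), " eigenvalues but ",
         length(rows), " eigenvector rows")
  V <- do.call(cbind, rows)  # 3N x M, column m = mode m
  response_model(r_o = flatten_xyz(positions(relaxed_structure)),
                 V = V, lambda = lambda, temperature = temperature)
}

#' Write a linear-response model to eigenvalue/eigenvector files
#' @param model a [response_model()].
#' @param eigenvalues_path,eigenvectors_path output paths.
#' @return invisibly, `NULL`.
#' @export
write_response_model <- function(model, eigenvalues_path, eigenvectors_path) {
  writeLines(format(model$lambda, digits = 17), eigenvalues_path)
  writeLines(apply(t(model$V), 1, function(r)
    paste(format(r, digits = 17), collapse = " ")), eigenvectors_path)
  invisible(NULL)
}
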