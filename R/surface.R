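#' Solvent-excluded-surface scalar field
#'
#' Discrete signed field whose zero level set approximates the SES: nodes
#' inside the solvent-accessible region (within `R_i + probe` of any atom)
#' are found, the Euclidean distance from the complementary exterior node set
#' is computed by a separable distance transform, and the field value is that
#' distance minus the probe radius. The field is therefore positive inside
#' the SES, negative outside, and its zero crossing sits one probe radius
#' inside the solvent-accessible boundary, which is the SES up to grid
#' resolution. Recompute per conformation for a flexible receptor.
#'
#' @param mol parameterized [molecule()] (vdW radii assigned).
#' @param spacing grid spacing in Angstrom; 0.375 and 0.75 are the standard
#'   fine/coarse choices, the coarse one for large structures.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, water).
#' @param max_nodes refuse grids larger than this many nodes, with advice to
#'   coarsen the spacing.
#' @return object of class `scalar_field`: `origin`, `spacing`, `dims`,
#'   `values` (3-D array indexed x, y, z; Angstrom, signed-distance
#'   semantics).
#' @export
ses_field <- function(mol, spacing = 0.375, probe_radius = 1.4,
                      max_nodes = 2.5e7) {
  stop_if_unparameterized(mol, "ses_field")
  stopifnot(probe_radius > 0, spacing > 0)
  xyz <- positions(mol)
  radii <- mol$atoms$vdw_radius
  pad <- max(radii) + probe_radius + 2 * spacing
  origin <- apply(xyz, 2, min) - pad
  span <- apply(xyz, 2, max) + pad - origin
  dims <- pmax(ceiling(span / spacing) + 1L, 2L)
  if (prod(dims) > max_nodes)
    stop("ses_field: grid of ", paste(dims, collapse = "x"),
         " nodes exceeds the limit; use a coarser spacing (e.g. 0.75 A)")
  axes <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spacing)
  # sd = analytic signed distance to the solvent-accessible surface (min over
  # atoms of |x - c_i| - (R_i + probe)); negative inside the SAS region.
  # Only a slab of 2*(R + probe) around each atom can go below the pad value.
  sd <- array(pad, dims)
  for (i in seq_len(nrow(xyz))) {
    R <- radii[i] + probe_radius
    rng <- lapply(1:3, function(a) {
      w <- which(abs(axes[[a]] - xyz[i, a]) <= R + probe_radius + spacing)
      if (length(w) == 0L) integer(0) else w
    })
    if (any(lengths(rng) == 0L)) next
    d2 <- outer(outer((axes[[1]][rng[[1]]] - xyz[i, 1])^2,
                      (axes[[2]][rng[[2]]] - xyz[i, 2])^2, "+"),
                (axes[[3]][rng[[3]]] - xyz[i, 3])^2, "+")
    sd[rng[[1]], rng[[2]], rng[[3]]] <-
      pmin(sd[rng[[1]], rng[[2]], rng[[3]]], sqrt(d2) - R)
  }
  inside <- sd < 0
  dist <- sqrt(edt3_squared(!inside)) * spacing
  vals <- ifelse(inside, dist, -sd) - probe_radius
  # Sub-grid refinement near the zero level set: for an interior node whose
  # radial foot point on its nearest inflated sphere is itself solvent
  # exposed (not inside any other inflated sphere), the analytic -sd IS the
  # distance to the exterior region (contact patch), so it replaces the
  # node-quantized EDT there. Re-entrant (probe-bridged) nodes keep the EDT.
  band <- which(inside & (abs(dist - probe_radius) <= 1.5 * spacing |
                            abs(-sd - probe_radius) <= 1.5 * spacing))
  if (length(band) > 0L) {
    nb <- arrayInd(band, dims)
    ypos <- cbind(axes[[1]][nb[, 1]], axes[[2]][nb[, 2]], axes[[3]][nb[, 3]])
    Ri <- radii + probe_radius
    qr <- max(Ri) + probe_radius + 3 * spacing
    agrid <- build_grid(xyz, cell_size = qr)
    for (k in seq_along(band)) {
      y <- ypos[k, ]
      cand <- query_within(agrid, y, qr)
      if (length(cand) == 0L) next
      dy <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - y)^2))
      i <- which.min(dy - Ri[cand])
      if (dy[i] < 1e-9) next  # node at an atom center: radial direction undefined
      p <- xyz[cand[i], ] + Ri[cand[i]] * (y - xyz[cand[i], ]) / dy[i]
      dp <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - p)^2))
      if (all(dp - Ri[cand] >= -1e-9))
        vals[band[k]] <- -sd[band[k]] - probe_radius
    }
  }
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 values = vals),
            class = "scalar_field")
}

# Squared Euclidean distance transform (in node units) to the TRUE set of a
# logical 3-D array, by the separable lower-envelope algorithm applied along
# each axis in turn.
edt3_squared <- function(seed) {
  BIG <- 1e20
  f <- array(ifelse(seed, 0, BIG), dim(seed))
  for (axis in 1:3) {
    f <- aperm(apply(f, setdiff(1:3, axis), edt1_squared),
               order(c(axis, setdiff(1:3, axis))))
  }
  f
}

edt1_squared <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1] <- 1L; z[1] <- -1e30; z[2] <- 1e30
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- 1e30
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Triangulate an isosurface with Marching Cubes
#'
#' Standard 256-case Marching Cubes with linear interpolation along cube
#' edges. Vertices on shared edges are deduplicated, zero-area triangles are
#' dropped, and the mesh is oriented so normals point toward decreasing
#' field values (out of the molecule for [ses_field()] output).
#'
#' @param field a `scalar_field`.
#' @param iso isolevel (default 0).
#' @return object of class `surface_mesh`: `vertices` (V x 3, Angstrom),
#'   `triangles` (T x 3, 1-based vertex indices), `normals` (V x 3 unit
#'   vectors, area-weighted). Empty mesh (with a warning) when the field
#'   does not straddle the isolevel.
#' @export
marching_cubes <- function(field, iso = 0) {
  vals <- field$values
  dims <- dim(vals)
  if (all(vals >= iso) || all(vals < iso)) {
    warning("marching_cubes: field does not straddle the isolevel; empty mesh")
    return(empty_mesh())
  }
  below <- vals < iso
  nx <- dims[1] - 1L; ny <- dims[2] - 1L; nz <- dims[3] - 1L
  # case index per cube, vectorized over the cube lattice
  caseidx <- array(0L, c(nx, ny, nz))
  for (v in 1:8) {
    o <- mc_vertex_offset[v, ]
    caseidx <- caseidx + bitwShiftL(1L, v - 1L) *
      below[o[1] + 1:nx, o[2] + 1:ny, o[3] + 1:nz]
  }
  active <- which(caseidx > 0L & caseidx < 255L)
  if (length(active) == 0L) return(empty_mesh())
  ai <- arrayInd(active, c(nx, ny, nz))
  axes <- lapply(1:3, function(a)
    field$origin[a] + (seq_len(dims[a]) - 1) * field$spacing)

  vkey <- character(0); vpos <- list(); tri <- list()
  keymap <- new.env(hash = TRUE, parent = emptyenv())
  nverts <- 0L
  for (c_ in seq_along(active)) {
    base <- ai[c_, ]
    case <- caseidx[active[c_]] + 1L
    row <- mc_tri_table[case, ]
    t_ <- 1L
    while (row[t_] >= 0L) {
      ids <- integer(3)
      for (e in 1:3) {
        edge <- row[t_ + e - 1L]
        ends <- mc_edge_ends[edge + 1L, ]
        n1 <- base + mc_vertex_offset[ends[1] + 1L, ]
        n2 <- base + mc_vertex_offset[ends[2] + 1L, ]
        l1 <- n1[1] + dims[1] * (n1[2] - 1L + dims[2] * (n1[3] - 1L))
        l2 <- n2[1] + dims[1] * (n2[2] - 1L + dims[2] * (n2[3] - 1L))
        key <- if (l1 < l2) paste0(l1, "_", l2) else paste0(l2, "_", l1)
        id <- keymap[[key]]
        if (is.null(id)) {
          v1 <- vals[n1[1], n1[2], n1[3]]; v2 <- vals[n2[1], n2[2], n2[3]]
          tt <- (iso - v1) / (v2 - v1)
          p1 <- c(axes[[1]][n1[1]], axes[[2]][n1[2]], axes[[3]][n1[3]])
          p2 <- c(axes[[1]][n2[1]], axes[[2]][n2[2]], axes[[3]][n2[3]])
          nverts <- nverts + 1L
          id <- nverts
          keymap[[key]] <- id
          vpos[[id]] <- p1 + tt * (p2 - p1)
        }
        ids[e] <- id
      }
      if (length(unique(ids)) == 3L) tri[[length(tri) + 1L]] <- ids
      t_ <- t_ + 3L
    }
  }
  if (length(tri) == 0L) return(empty_mesh())
  V <- do.call(rbind, vpos)
  T_ <- do.call(rbind, tri)
  # drop geometrically degenerate triangles left after welding
  e1 <- V[T_[, 2], ] - V[T_[, 1], ]
  e2 <- V[T_[, 3], ] - V[T_[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(cr^2))
  T_ <- T_[area2 > 1e-12, , drop = FALSE]
  mesh <- orient_mesh(list(vertices = V, triangles = T_), field, iso)
  mesh$normals <- vertex_normals(mesh$vertices, mesh$triangles)
  class(mesh) <- "surface_mesh"
  mesh
}

empty_mesh <- function() {
  structure(list(vertices = matrix(0, 0, 3), triangles = matrix(0L, 0, 3),
                 normals = matrix(0, 0, 3)), class = "surface_mesh")
}

# Flip all triangles if the table winding points into the field gradient
# (normals must point toward decreasing field). Majority vote over a sample
# of triangles using a central-difference gradient at triangle centroids.
orient_mesh <- function(mesh, field, iso) {
  T_ <- mesh$triangles; V <- mesh$vertices
  take <- seq_len(nrow(T_))
  if (length(take) > 200L) take <- round(seq(1, nrow(T_), length.out = 200L))
  agree <- 0; total <- 0
  for (t_ in take) {
    p <- (V[T_[t_, 1], ] + V[T_[t_, 2], ] + V[T_[t_, 3], ]) / 3
    g <- field_gradient(field, p)
    nrm <- pracma_cross(V[T_[t_, 2], ] - V[T_[t_, 1], ],
                        V[T_[t_, 3], ] - V[T_[t_, 1], ])
    if (sum(g^2) > 0 && sum(nrm^2) > 0) {
      total <- total + 1
      if (sum(g * nrm) < 0) agree <- agree + 1
    }
  }
  if (total > 0 && agree < total / 2)
    mesh$triangles <- T_[, c(1, 3, 2), drop = FALSE]
  mesh
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# trilinear central-difference gradient of the field at a world point
field_gradient <- function(field, p) {
  ijk <- (p - field$origin) / field$spacing + 1
  ijk <- pmin(pmax(round(ijk), 2), field$dims - 1)
  v <- field$values
  g <- numeric(3)
  for (a in 1:3) {
    lo <- ijk; hi <- ijk
    lo[a] <- lo[a] - 1; hi[a] <- hi[a] + 1
    g[a] <- (v[hi[1], hi[2], hi[3]] - v[lo[1], lo[2], lo[3]]) /
      (2 * field$spacing)
  }
  g
}

vertex_normals <- function(V, T_) {
  N <- matrix(0, nrow(V), 3)
  if (nrow(T_) == 0L) return(N)
  e1 <- V[T_[, 2], , drop = FALSE] - V[T_[, 1], , drop = FALSE]
  e2 <- V[T_[, 3], , drop = FALSE] - V[T_[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # length = 2x area
  for (k in 1:3) {  # accumulate each triangle's (area-weighted) normal
    s <- rowsum(fn, T_[, k])
    idx <- as.integer(rownames(s))
    N[idx, ] <- N[idx, , drop = FALSE] + s
  }
  len <- sqrt(rowSums(N^2))
  N[len > 0, ] <- N[len > 0, , drop = FALSE] / len[len > 0]
  N
}

#' Solvent-excluded-surface mesh of a molecule
#'
#' Composition of [ses_field()] and [marching_cubes()] at isolevel zero.
#' Deterministic: re-running on the same coordinates reproduces the mesh
#' bit-identically; re-running after a deformation yields the surface of the
#' new conformation.
#'
#' @inheritParams ses_field
#' @return a `surface_mesh`.
#' @export
ses_mesh <- function(mol, spacing = 0.375, probe_radius = 1.4,
                     max_nodes = 2.5e7) {
  marching_cubes(ses_field(mol, spacing, probe_radius, max_nodes), iso = 0)
}

#' Total mesh surface area
#' @param mesh a `surface_mesh`.
#' @return area in Angstrom^2.
#' @export
mesh_area <- function(mesh) {
  T_ <- mesh$triangles
  if (nrow(T_) == 0L) return(0)
  V <- mesh$vertices
  e1 <- V[T_[, 2], , drop = FALSE] - V[T_[, 1], , drop = FALSE]
  e2 <- V[T_[, 3], , drop = FALSE] - V[T_[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Enclosed mesh volume (divergence theorem)
#' @param mesh a closed, outward-oriented `surface_mesh`.
#' @return volume in Angstrom^3 (signed; positive for outward orientation).
#' @export
mesh_volume <- function(mesh) {
  T_ <- mesh$triangles
  if (nrow(T_) == 0L) return(0)
  V <- mesh$vertices
  a <- V[T_[, 1], , drop = FALSE]; b <- V[T_[, 2], , drop = FALSE]
  c_ <- V[T_[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Is every mesh edge shared by exactly two triangles?
#' @param mesh a `surface_mesh`.
#' @return logical; `TRUE` for a closed edge-manifold mesh.
#' @export
is_closed_mesh <- function(mesh) {
  T_ <- mesh$triangles
  if (nrow(T_) == 0L) return(FALSE)
  e <- rbind(T_[, 1:2], T_[, 2:3], T_[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Euler characteristic V - E + F of a mesh
#' @param mesh a `surface_mesh`.
#' @return integer Euler characteristic (2 for a topological sphere).
#' @export
euler_characteristic <- function(mesh) {
  T_ <- mesh$triangles
  e <- rbind(T_[, 1:2], T_[, 2:3], T_[, c(3, 1)])
  key <- unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nrow(mesh$vertices) - length(key) + nrow(T_)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles, area %.2f A^2\n",
              nrow(x$vertices), nrow(x$triangles), mesh_area(x)))
  invisible(x)
}

#' Write a mesh as Wavefront OBJ
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (nrow(mesh$normals) > 0)
    writeLines(sprintf("vn %.6f %.6f %.6f", mesh$normals[, 1],
                       mesh$normals[, 2], mesh$normals[, 3]), con)
  writeLines(sprintf("f %d//%d %d//%d %d//%d",
                     mesh$triangles[, 1], mesh$triangles[, 1],
                     mesh$triangles[, 2], mesh$triangles[, 2],
                     mesh$triangles[, 3], mesh$triangles[, 3]), con)
  invisible(path)
}

#' Write a mesh as ASCII PLY
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               "property float nx", "property float ny", "property float nz",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f %.6f %.6f %.6f",
                     mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3], mesh$normals[, 1],
                     mesh$normals[, 2], mesh$normals[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  invisible(path)
}

#' Export the space-filling sphere list as JSON
#'
#' Atom centers and vdW radii for external viewers (the space-filling
#' depiction is just this list).
#' @param mol parameterized [molecule()].
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
write_sphere_list <- function(mol, path) {
  a <- mol$atoms
  jsonlite::write_json(
    list(spheres = data.frame(x = a$x, y = a$y, z = a$z,
                              radius = a$vdw_radius, element = a$element)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
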