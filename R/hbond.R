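#' Geometric hydrogen-bond criteria
#'
#' McDonald-Thornton style: a primary hydrogen bond requires the
#' hydrogen-acceptor distance strictly below the distance cutoff and the
#' donor-hydrogen-acceptor angle strictly above the angle cutoff, where the
#' angle is measured at the hydrogen between the H->D and H->A directions so
#' that 180 degrees is a perfectly linear D-H...A arrangement.
#'
#' @param distance_cutoff Angstrom, default 2.5.
#' @param angle_cutoff degrees, default 90.
#' @return object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(distance_cutoff = 2.5, angle_cutoff = 90) {
  stopifnot(distance_cutoff > 0, angle_cutoff > 0)
  structure(list(distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff),
            class = "hbond_criteria")
}

#' Detect hydrogen bonds between (or within) molecules
#'
#' Enumerates all (donor, hydrogen, acceptor) triples meeting the geometric
#' criteria, with donors taken from `donor_molecule` and acceptors from
#' `acceptor_molecule`. Acceptor positions are indexed in a regular grid and
#' queried around each donor hydrogen with the distance cutoff, the same
#' machinery as the force kernel. Pass the same molecule twice (or omit
#' `acceptor_molecule`) for intramolecular bonds, which exclude
#' acceptor = donor. Ghost atoms never participate.
#'
#' @param donor_molecule parameterized [molecule()] providing donors and
#'   their bonded hydrogens.
#' @param acceptor_molecule parameterized [molecule()] providing acceptors;
#'   default the donor molecule (intramolecular mode).
#' @param donor_transform,acceptor_transform world-frame poses.
#' @param criteria an [hbond_criteria()].
#' @return data frame of class `hbond_list`: `donor_index`,
#'   `hydrogen_index`, `acceptor_index`, `distance` (H...A, Angstrom),
#'   `angle` (D-H-A, degrees), sorted by (donor, acceptor). Attributes
#'   `donor_molecule`/`acceptor_molecule` carry the `"receptor"`/`"ligand"`
#'   style tags when given.
#' @export
detect_hbonds <- function(donor_molecule, acceptor_molecule = donor_molecule,
                          donor_transform = identity_transform(),
                          acceptor_transform = identity_transform(),
                          criteria = hbond_criteria(),
                          donor_tag = "donor", acceptor_tag = "acceptor") {
  intra <- identical(donor_molecule, acceptor_molecule) &&
    identical(donor_transform, acceptor_transform)
  da <- donor_molecule$atoms
  if (!any(da$is_hydrogen))
    stop("detect_hbonds: no hydrogens present in the donor molecule; ",
         "hydrogen-bond detection needs explicit hydrogens in the input structure")
  donors <- which(da$is_donor & !da$is_ghost)
  empty <- donors[lengths(donor_molecule$bonded_hydrogens[donors]) == 0L]
  if (length(empty) > 0L)
    stop("detect_hbonds: donor atom(s) without bonded hydrogens: ",
         paste(da$serial[empty], collapse = ", "))
  aa <- acceptor_molecule$atoms
  acceptors <- which(aa$is_acceptor & !aa$is_ghost)
  out <- data.frame(donor_index = integer(0), hydrogen_index = integer(0),
                    acceptor_index = integer(0), distance = numeric(0),
                    angle = numeric(0))
  if (length(donors) > 0L && length(acceptors) > 0L) {
    dpos <- apply_transform(donor_transform, positions(donor_molecule))
    apos <- apply_transform(acceptor_transform, positions(acceptor_molecule))
    agrid <- build_grid(apos[acceptors, , drop = FALSE],
                        cell_size = criteria$distance_cutoff)
    rows <- list()
    for (d in donors) {
      for (h in donor_molecule$bonded_hydrogens[[d]]) {
        if (da$is_ghost[h]) next
        hp <- dpos[h, ]
        hits <- acceptors[query_within(agrid, hp, criteria$distance_cutoff)]
        if (intra) hits <- hits[hits != d & hits != h]
        if (length(hits) == 0L) next
        av <- sweep(apos[hits, , drop = FALSE], 2, hp, "-")
        dist <- sqrt(rowSums(av^2))
        dv <- dpos[d, ] - hp
        cosang <- (av %*% dv) / (dist * sqrt(sum(dv^2)))
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        keep <- ang > criteria$angle_cutoff
        if (any(keep))
          rows[[length(rows) + 1L]] <- data.frame(
            donor_index = d, hydrogen_index = h,
            acceptor_index = hits[keep],
            distance = dist[keep], angle = ang[keep])
      }
    }
    if (length(rows) > 0L) {
      out <- do.call(rbind, rows)
      out <- out[order(out$donor_index, out$acceptor_index), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  attr(out, "donor_molecule") <- donor_tag
  attr(out, "acceptor_molecule") <- acceptor_tag
  class(out) <- c("hbond_list", class(out))
  out
}
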