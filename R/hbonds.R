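# Geometric hydrogen-bond detection and interaction-particle placement.
#
# Detection is heavy-atom only: donors and acceptors are perceived from
# element, formal charge and bonding pattern, never from explicit protons.
# A bond between protein atom P and ligand atom L becomes two pseudoparticles
# ("interaction particles") at the trisection points of the P->L vector,
# labelled with the ligand atom's role (donor or acceptor). The particles
# are what the diffusion model is conditioned on.

#' Hydrogen-bond geometric criteria
#'
#' @param max_da_distance maximum donor-acceptor heavy-atom distance in
#'   Angstrom. 3.5 A is the conventional upper bound for an N/O...N/O bond.
#' @param min_donor_angle minimum neighbor-donor-acceptor angle in degrees;
#'   the acceptor must lie on the far side of at least one of the donor's
#'   heavy substituents (proxy for a reachable proton direction). Skipped
#'   when the donor has no heavy neighbor.
#' @return list of class HBondCriteria
#' @export
hbond_criteria <- function(max_da_distance = 3.5, min_donor_angle = 120) {
  stopifnot(max_da_distance > 0, min_donor_angle >= 0, min_donor_angle <= 180)
  structure(list(max_da_distance = max_da_distance,
                 min_donor_angle = min_donor_angle),
            class = "HBondCriteria")
}

# Side-chain polar-atom chemistry of the standard residues.
# Backbone: N is a donor (except proline), O / OXT are acceptors.
PROTEIN_SIDECHAIN_POLAR <- list(
  SER = list(donor = "OG",  acceptor = "OG"),
  THR = list(donor = "OG1", acceptor = "OG1"),
  TYR = list(donor = "OH",  acceptor = "OH"),
  ASN = list(donor = "ND2", acceptor = "OD1"),
  GLN = list(donor = "NE2", acceptor = "OE1"),
  ASP = list(donor = character(0), acceptor = c("OD1", "OD2")),
  GLU = list(donor = character(0), acceptor = c("OE1", "OE2")),
  LYS = list(donor = "NZ",  acceptor = character(0)),
  ARG = list(donor = c("NE", "NH1", "NH2"), acceptor = character(0)),
  HIS = list(donor = c("ND1", "NE2"), acceptor = c("ND1", "NE2")),
  TRP = list(donor = "NE1", acceptor = character(0))
)

#' Perceive protein donor/acceptor atoms (table-driven)
#' @param protein full-atom protein data.frame
#' @return data.frame(donor, acceptor) logical, one row per atom
#' @export
protein_donor_acceptor <- function(protein) {
  n <- nrow(protein)
  donor <- logical(n); acceptor <- logical(n)
  donor[protein$name == "N" & protein$resname != "PRO"] <- TRUE
  acceptor[protein$name %in% c("O", "OXT")] <- TRUE
  for (res in names(PROTEIN_SIDECHAIN_POLAR)) {
    rows <- protein$resname == res
    tab <- PROTEIN_SIDECHAIN_POLAR[[res]]
    donor[rows & protein$name %in% tab$donor] <- TRUE
    acceptor[rows & protein$name %in% tab$acceptor] <- TRUE
  }
  # anything not N/O can never participate regardless of the tables
  polar <- protein$element %in% c("N", "O")
  data.frame(donor = donor & polar, acceptor = acceptor & polar)
}

bond_order_sum <- function(ligand) {
  n <- length(ligand$elements)
  bsum <- numeric(n)
  b <- ligand$bonds
  if (nrow(b)) {
    ord <- ifelse(b$order == 4, 1.5, b$order) # 4 = aromatic in SDF
    for (r in seq_len(nrow(b))) {
      bsum[b$i[r]] <- bsum[b$i[r]] + ord[r]
      bsum[b$j[r]] <- bsum[b$j[r]] + ord[r]
    }
  }
  bsum
}

#' Perceive ligand donor/acceptor atoms from element + valence
#'
#' Heavy-atom rules (no explicit hydrogens needed):
#' * O, neutral: acceptor always; donor iff it has a spare valence for a
#'   proton (bond-order sum < 2) or carried an explicit H before stripping.
#' * N: donor iff spare valence (bond-order sum < 3, < 4 if cationic) or
#'   carried an explicit H; acceptor iff neutral, bond-order sum <= 3 and
#'   not an amide nitrogen (single-bonded to a carbonyl carbon).
#' * Charged: anionic O is acceptor-only; cationic N is donor-only.
#'
#' @param ligand a LigandMolecule
#' @return data.frame(donor, acceptor) logical, one row per heavy atom
#' @export
ligand_donor_acceptor <- function(ligand) {
  n <- length(ligand$elements)
  el <- ligand$elements
  chg <- ligand$charges
  bsum <- bond_order_sum(ligand)
  donor <- logical(n); acceptor <- logical(n)

  # amide nitrogens: N single-bonded to a C that is double-bonded to an O
  amide <- logical(n)
  b <- ligand$bonds
  if (nrow(b)) {
    carbonyl_c <- unique(c(b$i[b$order == 2 & el[b$j] == "O"],
                           b$j[b$order == 2 & el[b$i] == "O"]))
    carbonyl_c <- carbonyl_c[el[carbonyl_c] == "C"]
    for (r in seq_len(nrow(b))) {
      if (b$order[r] == 1) {
        if (el[b$i[r]] == "N" && b$j[r] %in% carbonyl_c) amide[b$i[r]] <- TRUE
        if (el[b$j[r]] == "N" && b$i[r] %in% carbonyl_c) amide[b$j[r]] <- TRUE
      }
    }
  }

  isO <- el == "O"; isN <- el == "N"
  implicit_h <- numeric(n)
  implicit_h[isO] <- pmax(0, 2 - bsum[isO] + pmin(chg[isO], 0))
  implicit_h[isN] <- pmax(0, 3 + (chg[isN] > 0) - bsum[isN])
  donor[isO] <- chg[isO] >= 0 &
    (implicit_h[isO] >= 1 | ligand$had_hydrogen[isO])
  acceptor[isO] <- chg[isO] <= 0
  donor[isN] <- implicit_h[isN] >= 1 | ligand$had_hydrogen[isN]
  acceptor[isN] <- chg[isN] <= 0 & bsum[isN] <= 3 & !amide[isN]
  data.frame(donor = donor, acceptor = acceptor)
}

protein_neighbors <- function(protein) {
  # heavy covalent neighbors from a distance window (covers peptide bonds)
  pos <- as.matrix(protein[, c("x", "y", "z")])
  d <- pairwise_dist(pos, pos)
  ri <- COVALENT_RADII[protein$element]
  ri[is.na(ri)] <- 0.77
  lim <- outer(ri, ri, "+") + 0.45
  adj <- d <= lim & d > 0.1
  lapply(seq_len(nrow(protein)), function(i) which(adj[i, ]))
}

ligand_neighbors <- function(ligand) {
  n <- length(ligand$elements)
  nb <- vector("list", n)
  b <- ligand$bonds
  for (r in seq_len(nrow(b))) {
    nb[[b$i[r]]] <- c(nb[[b$i[r]]], b$j[r])
    nb[[b$j[r]]] <- c(nb[[b$j[r]]], b$i[r])
  }
  nb
}

donor_angle_ok <- function(donor_pos, neighbor_pos_list, acceptor_pos,
                           min_angle) {
  if (!length(neighbor_pos_list)) return(TRUE) # no geometry available
  angs <- vapply(neighbor_pos_list, function(np) {
    angle_deg(np, donor_pos, acceptor_pos)
  }, numeric(1))
  max(angs) >= min_angle
}

#' Detect protein-ligand hydrogen bonds geometrically
#'
#' A pair (protein atom P, ligand atom L) is a hydrogen bond iff one side
#' is a perceived donor and the other a perceived acceptor, the
#' donor-acceptor distance is at most `criteria$max_da_distance`, and —
#' when the donor has heavy neighbors — the neighbor-donor-acceptor angle
#' test passes. If both directions pass for the same pair, one bond is
#' recorded with ligand_role "donor" (deterministic tie-break).
#'
#' @param protein full-atom protein data.frame (indices in the result refer
#'   to its rows)
#' @param ligand a LigandMolecule
#' @param criteria see [hbond_criteria()]
#' @return data.frame(protein_atom, ligand_atom, ligand_role, distance),
#'   ordered by (ligand_atom, protein_atom); possibly empty
#' @export
detect_hydrogen_bonds <- function(protein, ligand,
                                  criteria = hbond_criteria()) {
  stopifnot(nrow(protein) > 0, length(ligand$elements) > 0)
  pda <- protein_donor_acceptor(protein)
  lda <- ligand_donor_acceptor(ligand)
  ppolar <- which(pda$donor | pda$acceptor)
  lpolar <- which(lda$donor | lda$acceptor)
  out <- data.frame(protein_atom = integer(0), ligand_atom = integer(0),
                    ligand_role = character(0), distance = numeric(0))
  if (!length(ppolar) || !length(lpolar)) return(out)
  ppos <- as.matrix(protein[, c("x", "y", "z")])
  d <- pairwise_dist(ppos[ppolar, , drop = FALSE],
                     ligand$coords[lpolar, , drop = FALSE])
  hits <- which(d <= criteria$max_da_distance, arr.ind = TRUE)
  if (!nrow(hits)) return(out)
  pnb <- protein_neighbors(protein)
  lnb <- ligand_neighbors(ligand)
  rows <- list()
  for (k in seq_len(nrow(hits))) {
    pi <- ppolar[hits[k, 1]]; li <- lpolar[hits[k, 2]]
    dist_k <- d[hits[k, 1], hits[k, 2]]
    ppos_i <- ppos[pi, ]; lpos_i <- ligand$coords[li, ]
    # ligand as donor, protein as acceptor
    lig_donor_ok <- lda$donor[li] && pda$acceptor[pi] &&
      donor_angle_ok(lpos_i,
                     lapply(lnb[[li]], function(q) ligand$coords[q, ]),
                     ppos_i, criteria$min_donor_angle)
    # protein as donor, ligand as acceptor
    prot_donor_ok <- pda$donor[pi] && lda$acceptor[li] &&
      donor_angle_ok(ppos_i,
                     lapply(pnb[[pi]], function(q) ppos[q, ]),
                     lpos_i, criteria$min_donor_angle)
    if (lig_donor_ok || prot_donor_ok) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_atom = pi, ligand_atom = li,
        ligand_role = if (lig_donor_ok) "donor" else "acceptor",
        distance = dist_k)
    }
  }
  if (!length(rows)) return(out)
  out <- do.call(rbind, rows)
  out <- out[order(out$ligand_atom, out$protein_atom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Place the two interaction particles of one hydrogen bond
#'
#' Particle j (j = 1, 2) sits at x^P + (j/3) (x^L - x^P): the trisection
#' points of the protein-atom -> ligand-atom vector, particle 1 nearer the
#' protein. Both particles carry the ligand atom's donor/acceptor role.
#'
#' @param hbond one row of the hydrogen-bond table
#' @param protein full-atom protein data.frame the bond indexes into
#' @param ligand a LigandMolecule
#' @param bond_id identifier stored with the particles
#' @return data.frame with two rows: bond_id, j, x, y, z, role
#' @export
place_interaction_particles <- function(hbond, protein, ligand,
                                        bond_id = 1L) {
  xp <- as.numeric(protein[hbond$protein_atom, c("x", "y", "z")])
  xl <- as.numeric(ligand$coords[hbond$ligand_atom, ])
  if (vec_norm(xl - xp) < 1e-9) {
    stop("degenerate hydrogen bond: coincident endpoints")
  }
  pos <- rbind(xp + (1 / 3) * (xl - xp), xp + (2 / 3) * (xl - xp))
  data.frame(bond_id = bond_id, j = c(1L, 2L),
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             role = hbond$ligand_role)
}

#' Place interaction particles for every bond in a table
#' @inheritParams place_interaction_particles
#' @param hbonds hydrogen-bond table from [detect_hydrogen_bonds()]
#' @return data.frame, two rows per bond
#' @export
place_all_particles <- function(hbonds, protein, ligand) {
  if (!nrow(hbonds)) {
    return(data.frame(bond_id = integer(0), j = integer(0), x = numeric(0),
                      y = numeric(0), z = numeric(0), role = character(0)))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(hbonds)), function(k) {
    place_interaction_particles(hbonds[k, ], protein, ligand, bond_id = k)
  }))
  rownames(out) <- NULL
  out
}
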