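# Deterministic synthetic protein-ligand complexes with planted hydrogen
# bonds. The geometry is deliberately simple (a bonded ligand blob inside
# a shell of backbone-like residues) but uses real residue and element
# labels so every chemistry-facing code path runs unmodified. Planted
# bonds are constructed to satisfy the default detection criteria exactly:
# donor-acceptor distance inside the requested window and a 180 degree
# neighbor-donor-acceptor angle.

# idealized backbone template in a local frame (CA at origin); distances:
# CA-N 1.47, CA-C 1.53, C-O 1.23, CA-CB 1.53
BACKBONE_TEMPLATE <- rbind(
  N  = c(-1.20,  0.85,  0.00),
  CA = c( 0.00,  0.00,  0.00),
  C  = c( 1.25,  0.88,  0.00),
  O  = c( 1.65,  2.04,  0.00),
  CB = c( 0.00, -1.05, -1.11)
)

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotation_aligning <- function(a, b) {
  # minimal rotation taking unit vector a onto unit vector b (Rodrigues)
  a <- a / vec_norm(a); b <- b / vec_norm(b)
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {
    # pick any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- c(a[2] * ax[3] - a[3] * ax[2], a[3] * ax[1] - a[1] * ax[3],
           a[1] * ax[2] - a[2] * ax[1])
    v <- v / vec_norm(v)
    K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + cth)
}

#' Specification of one synthetic toy complex
#'
#' @param n_pocket_residues number of shell residues
#' @param n_ligand_atoms ligand heavy-atom count
#' @param n_planted_hbonds hydrogen bonds constructed into the geometry
#' @param da_range donor-acceptor distance window the planted bonds are
#'   drawn from (Angstrom); the default 2.7-3.3 is the canonical strong
#'   N/O hydrogen-bond range
#' @param palette element palette the non-planted ligand atoms draw from
#' @param seed integer seed fixing the whole complex
#' @return FixtureSpec list
#' @export
fixture_spec <- function(n_pocket_residues = 8, n_ligand_atoms = 12,
                         n_planted_hbonds = 2, da_range = c(2.7, 3.3),
                         palette = c("C", "C", "C", "N", "O"), seed = 1) {
  stopifnot(n_pocket_residues >= 1, n_ligand_atoms >= 1,
            n_planted_hbonds >= 0, length(da_range) == 2,
            da_range[1] > 0, da_range[1] <= da_range[2])
  if (n_planted_hbonds > n_pocket_residues) {
    stop("infeasible spec: more planted bonds than pocket residues")
  }
  structure(list(n_pocket_residues = n_pocket_residues,
                 n_ligand_atoms = n_ligand_atoms,
                 n_planted_hbonds = n_planted_hbonds,
                 da_range = da_range, palette = palette, seed = seed),
            class = "FixtureSpec")
}

grow_ligand <- function(n, palette, n_pendant = 0) {
  # random bonded tree (1.5 A bonds, 1.9 A clash floor); the last
  # n_pendant atoms attach to core atoms and stay terminal, so they can
  # carry planted hydrogen bonds
  coords <- matrix(0, n, 3)
  parent <- integer(n)
  n_core <- n - n_pendant
  for (k in seq_len(n)[-1]) {
    ok <- FALSE
    for (try in 1:200) {
      p <- if (k <= n_core) sample.int(k - 1, 1) else
        sample.int(n_core, 1)
      dir <- rnorm(3); dir <- dir / vec_norm(dir)
      cand <- coords[p, ] + 1.5 * dir
      dmin <- min(sqrt(rowSums(sweep(coords[seq_len(k - 1), , drop = FALSE],
                                     2, cand, "-")^2))[-p], Inf)
      if (dmin >= 1.9) { coords[k, ] <- cand; parent[k] <- p; ok <- TRUE; break }
    }
    if (!ok) stop("infeasible spec: could not grow a clash-free ligand")
  }
  elements <- sample(palette, n, replace = TRUE)
  bonds <- if (n > 1) data.frame(i = parent[-1], j = seq_len(n)[-1],
                                 order = 1L) else
    data.frame(i = integer(0), j = integer(0), order = integer(0))
  list(coords = coords, elements = elements, bonds = bonds)
}

place_residue <- function(resname, resid, center, rotation) {
  pos <- BACKBONE_TEMPLATE %*% t(rotation)
  pos <- sweep(pos, 2, center, "+")
  names_ <- rownames(BACKBONE_TEMPLATE)
  if (resname == "GLY") { pos <- pos[1:4, , drop = FALSE]; names_ <- names_[1:4] }
  data.frame(element = substr(names_, 1, 1), name = names_,
             resname = resname, resid = resid, chain = "A",
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             stringsAsFactors = FALSE)
}

#' Generate one synthetic toy complex
#'
#' Pocket residues sit on a shell around the ligand with every atom at
#' least 4 A from every ligand atom, so a spec with zero planted bonds
#' yields zero detected bonds. Each planted bond repositions one residue
#' so that its backbone O (ligand-donor bonds) or backbone N
#' (ligand-acceptor bonds) sits at a drawn donor-acceptor distance along
#' the ligand atom's free direction; the matching ligand leaf atom is
#' retyped to O (or N). Under the default criteria, detection provably
#' recovers every planted bond.
#'
#' @param spec a [fixture_spec()]
#' @return unprepared ComplexRecord with a `planted` attribute
#'   (data.frame: ligand_atom, resid, protein_atom_name, ligand_role,
#'   distance)
#' @export
make_toy_complex <- function(spec) {
  with_seed(spec$seed, {
    n_pendant <- if (spec$n_ligand_atoms > spec$n_planted_hbonds) {
      spec$n_planted_hbonds
    } else 0
    if (spec$n_planted_hbonds > max(spec$n_ligand_atoms - 1, 1)) {
      stop("infeasible spec: ", spec$n_planted_hbonds,
           " bonds cannot be carried by ", spec$n_ligand_atoms,
           " ligand atoms")
    }
    lig <- grow_ligand(spec$n_ligand_atoms, spec$palette, n_pendant)
    centroid <- colMeans(lig$coords)
    maxrad <- if (spec$n_ligand_atoms > 1) {
      max(sqrt(rowSums(sweep(lig$coords, 2, centroid, "-")^2)))
    } else 0

    # the pendant atoms grown last are the hydrogen-bond carriers
    planted_atoms <- if (spec$n_planted_hbonds > 0) {
      if (n_pendant > 0) {
        spec$n_ligand_atoms - n_pendant + seq_len(n_pendant)
      } else 1L # single-atom ligand carries the bond itself
    } else integer(0)
    roles <- rep(c("donor", "acceptor"),
                 length.out = spec$n_planted_hbonds)
    lig$elements[planted_atoms] <- "O"
    lig$elements[planted_atoms[roles == "acceptor"]] <-
      rep(c("O", "N"), length.out = sum(roles == "acceptor"))

    # shell residues
    resnames <- sample(setdiff(AA3, "PRO"), spec$n_pocket_residues,
                       replace = TRUE)
    protein <- list()
    planted <- list()
    for (r in seq_len(spec$n_pocket_residues)) {
      k <- match(r, seq_len(spec$n_planted_hbonds))
      if (!is.na(k) && r <= spec$n_planted_hbonds) {
        # planted residue r pairs with ligand atom planted_atoms[r]
        a <- planted_atoms[r]
        xl <- lig$coords[a, ]
        nb <- c(lig$bonds$i[lig$bonds$j == a], lig$bonds$j[lig$bonds$i == a])
        dir <- if (length(nb)) {
          d0 <- xl - lig$coords[nb[1], ]; d0 / vec_norm(d0)
        } else { d0 <- rnorm(3); d0 / vec_norm(d0) }
        dda <- runif(1, spec$da_range[1], spec$da_range[2])
        xp <- xl + dda * dir
        rot <- random_rotation()
        anchor_name <- if (roles[r] == "donor") "O" else "N"
        if (anchor_name == "N") {
          # acceptor lies along -dir from N; put CA anti to it (+dir) so
          # the neighbor-donor-acceptor angle is 180 degrees
          ca_n <- (BACKBONE_TEMPLATE["CA", ] - BACKBONE_TEMPLATE["N", ])
          rot <- rotation_aligning(rot %*% ca_n, dir) %*% rot
        } else {
          # put the carbonyl C on the far side of O, away from the ligand
          c_o <- (BACKBONE_TEMPLATE["O", ] - BACKBONE_TEMPLATE["C", ])
          rot <- rotation_aligning(rot %*% c_o, -dir) %*% rot
        }
        anchor_local <- BACKBONE_TEMPLATE[anchor_name, ]
        center <- xp - as.numeric(rot %*% anchor_local)
        res <- place_residue(resnames[r], r, center, rot)
        planted[[r]] <- data.frame(ligand_atom = a, resid = r,
                                   protein_atom_name = anchor_name,
                                   ligand_role = roles[r], distance = dda)
      } else {
        res <- NULL
        for (try in 1:300) {
          u <- rnorm(3); u <- u / vec_norm(u)
          center <- centroid + (maxrad + runif(1, 5.0, 7.5)) * u
          cand <- place_residue(resnames[r], r, center, random_rotation())
          dmin <- min(pairwise_dist(as.matrix(cand[, c("x", "y", "z")]),
                                    lig$coords))
          # keep clear of the ligand and of previously placed residues
          dres <- if (length(protein)) {
            min(pairwise_dist(as.matrix(cand[, c("x", "y", "z")]),
                              as.matrix(do.call(rbind, protein)[, c("x", "y", "z")])))
          } else Inf
          if (dmin >= 4.0 && dres >= 2.5) { res <- cand; break }
        }
        if (is.null(res)) stop("infeasible spec: could not place residue ", r)
      }
      protein[[length(protein) + 1L]] <- res
    }
    protein <- do.call(rbind, protein)
    rownames(protein) <- NULL
    ligand <- make_ligand(lig$elements, lig$coords, lig$bonds)
    rec <- new_complex_record(
      id = sprintf("toy_s%d_p%d_l%d_h%d", spec$seed, spec$n_pocket_residues,
                   spec$n_ligand_atoms, spec$n_planted_hbonds),
      protein = protein, ligand = ligand)
    attr(rec, "planted") <- if (length(planted)) {
      do.call(rbind, planted)
    } else {
      data.frame(ligand_atom = integer(0), resid = integer(0),
                 protein_atom_name = character(0),
                 ligand_role = character(0), distance = numeric(0))
    }
    attr(rec, "spec") <- spec
    rec
  })
}

#' Generate the standard fixture suite
#'
#' A small train/test split of toy complexes with hydrogen-bond counts
#' spanning 0..6 (drug-like complexes rarely carry more) and varied
#' pocket/ligand sizes.
#'
#' @param seed master seed
#' @param n_train,n_test suite sizes
#' @param dir optional directory; when given, each complex is written as
#'   PDB + SDF + hydrogen-bond sidecar JSON
#' @return list(train = list of ComplexRecord, test = ...)
#' @export
make_fixture_suite <- function(seed = 1, n_train = 8, n_test = 2,
                               dir = NULL) {
  hb <- rep(c(0:6, 2), length.out = n_train + n_test)
  np <- rep(c(6, 8, 10, 12, 14), length.out = n_train + n_test)
  nl <- rep(c(8, 10, 12, 14, 16, 18), length.out = n_train + n_test)
  recs <- lapply(seq_len(n_train + n_test), function(k) {
    make_toy_complex(fixture_spec(
      n_pocket_residues = max(np[k], hb[k]),
      n_ligand_atoms = max(nl[k], 2 * hb[k]),
      n_planted_hbonds = hb[k],
      seed = seed * 1000 + k))
  })
  out <- list(train = recs[seq_len(n_train)],
              test = recs[n_train + seq_len(n_test)])
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (split in names(out)) {
      for (rec in out[[split]]) {
        stem <- file.path(dir, paste0(split, "_", rec$id))
        write_pdb(rec$protein, paste0(stem, ".pdb"))
        write_sdf(list(elements = rec$ligand$elements,
                       coords = rec$ligand$coords,
                       bonds = rec$ligand$bonds,
                       name = rec$id), paste0(stem, ".sdf"))
        prep <- prepare_complex(rec)
        write_hbond_sidecar(prep, paste0(stem, ".hbonds.json"))
      }
    }
  }
  out
}

#' Apply a rigid transform to a whole complex record
#' @param record ComplexRecord
#' @param tf list(R, b) as from [random_rigid_transform()]
#' @return transformed ComplexRecord (pocket/hbonds/particles cleared;
#'   re-run [prepare_complex()])
#' @export
transform_complex <- function(record, tf) {
  p <- as.matrix(record$protein[, c("x", "y", "z")])
  record$protein[, c("x", "y", "z")] <- apply_rigid(p, tf)
  record$ligand$coords <- apply_rigid(record$ligand$coords, tf)
  record$pocket <- NULL
  record$hbonds <- NULL
  record$particles <- NULL
  new_complex_record(record$id, record$protein, record$ligand)
}
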