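# Hydrogen-bond perception, detection and interaction-particle placement.

test_that("ligand hydroxyl donates to a backbone carbonyl at valid geometry", {
  prot <- tiny_protein()
  o_row <- which(prot$name == "O")
  xo <- as.numeric(prot[o_row, c("x", "y", "z")])
  # ligand C-O with the O 2.9 A from the carbonyl O, C anti to it
  dir <- c(1, 0.2, 0.1); dir <- dir / sqrt(sum(dir^2))
  opos <- xo + 2.9 * dir
  cpos <- opos + 1.43 * dir # neighbor-donor-acceptor angle = 180
  lig <- list(elements = c("C", "O"), coords = rbind(cpos, opos),
              bonds = data.frame(i = 1L, j = 2L, order = 1L),
              charges = integer(2), had_hydrogen = c(FALSE, FALSE))
  hb <- detect_hydrogen_bonds(prot, lig)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$protein_atom, o_row)
  expect_equal(hb$ligand_atom, 2L)
  expect_equal(hb$ligand_role, "donor")
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
})

test_that("distance cutoff and element rules exclude non-bonds", {
  one_atom_protein <- function(name, element) {
    data.frame(element = element, name = name, resname = "ALA", resid = 1L,
               chain = "A", x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  }
  # ligand O at 5.0 A from a lone backbone N: beyond the 3.5 A cutoff
  far <- list(elements = "O", coords = matrix(c(5, 0, 0), 1, 3),
              bonds = data.frame(i = integer(0), j = integer(0),
                                 order = integer(0)),
              charges = 0L, had_hydrogen = FALSE)
  expect_equal(nrow(detect_hydrogen_bonds(one_atom_protein("N", "N"), far)), 0)
  # protein carbon vs ligand carbon at 2.9 A: neither donor nor acceptor
  cc <- list(elements = "C", coords = matrix(c(2.9, 0, 0), 1, 3),
             bonds = data.frame(i = integer(0), j = integer(0),
                                order = integer(0)),
             charges = 0L, had_hydrogen = FALSE)
  expect_equal(nrow(detect_hydrogen_bonds(one_atom_protein("CA", "C"), cc)), 0)
})

test_that("donor angle criterion rejects blocked donors", {
  # lone backbone carbonyl O acceptor at the origin
  prot <- data.frame(element = "O", name = "O", resname = "ALA", resid = 1L,
                     chain = "A", x = 0, y = 0, z = 0,
                     stringsAsFactors = FALSE)
  opos <- c(2.9, 0, 0)
  # ligand hydroxyl whose C neighbor sits between donor and acceptor:
  # neighbor-donor-acceptor angle ~ 0 -> rejected
  lig <- list(elements = c("C", "O"),
              coords = rbind(opos - c(1.43, 0, 0), opos),
              bonds = data.frame(i = 1L, j = 2L, order = 1L),
              charges = integer(2), had_hydrogen = c(FALSE, FALSE))
  expect_equal(nrow(detect_hydrogen_bonds(prot, lig)), 0)
  # flipping the neighbor to the far side (angle 180) accepts the bond
  lig$coords[1, ] <- opos + c(1.43, 0, 0)
  expect_equal(nrow(detect_hydrogen_bonds(prot, lig)), 1)
})

test_that("ligand-side perception follows element/valence rules", {
  da <- ligand_donor_acceptor(ethanol())
  expect_equal(da$donor, c(FALSE, FALSE, TRUE))
  expect_equal(da$acceptor, c(FALSE, FALSE, TRUE))
  # ether oxygen: acceptor only
  ether <- list(elements = c("C", "O", "C"),
                coords = rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.1, 1.2, 0)),
                bonds = data.frame(i = c(1, 2), j = c(2, 3), order = c(1L, 1L)),
                charges = integer(3), had_hydrogen = logical(3))
  da2 <- ligand_donor_acceptor(ether)
  expect_false(da2$donor[2]); expect_true(da2$acceptor[2])
  # amide nitrogen: donor but not acceptor
  amide <- list(elements = c("C", "O", "N"),
                coords = rbind(c(0, 0, 0), c(1.23, 0, 0), c(-0.7, 1.2, 0)),
                bonds = data.frame(i = c(1, 1), j = c(2, 3), order = c(2L, 1L)),
                charges = integer(3), had_hydrogen = logical(3))
  da3 <- ligand_donor_acceptor(amide)
  expect_true(da3$donor[3]); expect_false(da3$acceptor[3])
  expect_false(da3$donor[2]); expect_true(da3$acceptor[2]) # carbonyl O
})

test_that("interaction particles trisect the donor-acceptor vector", {
  prot <- tiny_protein()
  prot[1, c("x", "y", "z")] <- c(0, 0, 0)
  lig <- list(elements = "O", coords = matrix(c(3, 0, 0), 1, 3),
              bonds = data.frame(i = integer(0), j = integer(0),
                                 order = integer(0)),
              charges = 0L, had_hydrogen = TRUE)
  hb <- data.frame(protein_atom = 1L, ligand_atom = 1L,
                   ligand_role = "donor", distance = 3)
  pp <- place_interaction_particles(hb, prot, lig)
  expect_equal(as.matrix(pp[, c("x", "y", "z")]),
               rbind(c(1, 0, 0), c(2, 0, 0)), ignore_attr = TRUE)
  expect_equal(pp$role, c("donor", "donor"))
  expect_equal(pp$j, c(1L, 2L))

  prot[1, c("x", "y", "z")] <- c(1, 2, 3)
  lig$coords <- matrix(c(4, 5, 9), 1, 3)
  pp2 <- place_interaction_particles(hb, prot, lig)
  expect_equal(as.matrix(pp2[, c("x", "y", "z")]),
               rbind(c(2, 3, 5), c(3, 4, 7)), ignore_attr = TRUE)

  lig$coords <- matrix(c(1, 2, 3), 1, 3) # coincident endpoints
  expect_error(place_interaction_particles(hb, prot, lig), "degenerate")
})

test_that("trisection is exact to 1e-9 relative on random fixtures", {
  set.seed(42)
  for (k in 1:20) {
    prep <- prepared_toy(seed = 100 + k, n_hb = 1 + k %% 4)
    pa <- prep$pocket_atoms
    for (b in unique(prep$particles$bond_id)) {
      hb <- prep$hbonds[b, ]
      xp <- as.numeric(pa[hb$protein_atom, c("x", "y", "z")])
      xl <- as.numeric(prep$ligand$coords[hb$ligand_atom, ])
      ps <- prep$particles[prep$particles$bond_id == b, ]
      p1 <- as.numeric(ps[ps$j == 1, c("x", "y", "z")])
      p2 <- as.numeric(ps[ps$j == 2, c("x", "y", "z")])
      d1 <- sqrt(sum((p1 - xp)^2)); d2 <- sqrt(sum((p2 - p1)^2))
      d3 <- sqrt(sum((xl - p2)^2))
      expect_lt(abs(d1 - d2) / d1, 1e-9)
      expect_lt(abs(d2 - d3) / d2, 1e-9)
      expect_equal(ps$role, rep(hb$ligand_role, 2))
    }
  }
})

test_that("detection and particles are rigid-transform covariant", {
  set.seed(7)
  rec <- make_toy_complex(fixture_spec(n_planted_hbonds = 3, seed = 9))
  prep <- prepare_complex(rec)
  for (k in 1:5) {
    tf <- random_rigid_transform()
    prep_t <- prepare_complex(transform_complex(rec, tf))
    expect_equal(prep_t$hbonds[, c("protein_atom", "ligand_atom",
                                   "ligand_role")],
                 prep$hbonds[, c("protein_atom", "ligand_atom",
                                 "ligand_role")])
    expect_lt(max(abs(as.matrix(prep_t$particles[, c("x", "y", "z")]) -
                      apply_rigid(as.matrix(prep$particles[, c("x", "y", "z")]),
                                  tf))), 1e-6)
  }
})

test_that("detection is symmetric in pair evaluation order", {
  prep <- prepared_toy(seed = 31, n_hb = 3, n_lig = 10, n_pocket = 8)
  pa <- prep$pocket_atoms
  # reverse the atom order on both sides; the detected set must map back
  perm_p <- rev(seq_len(nrow(pa)))
  pa2 <- pa[perm_p, ]; rownames(pa2) <- NULL
  lig <- prep$ligand
  perm_l <- rev(seq_along(lig$elements))
  lig2 <- lig
  lig2$elements <- lig$elements[perm_l]
  lig2$coords <- lig$coords[perm_l, , drop = FALSE]
  lig2$charges <- lig$charges[perm_l]
  lig2$had_hydrogen <- lig$had_hydrogen[perm_l]
  remap <- match(seq_along(perm_l), perm_l)
  lig2$bonds <- data.frame(i = remap[lig$bonds$i], j = remap[lig$bonds$j],
                           order = lig$bonds$order)
  hb1 <- detect_hydrogen_bonds(pa, lig)
  hb2 <- detect_hydrogen_bonds(pa2, lig2)
  key1 <- paste(pa$name[hb1$protein_atom], pa$resid[hb1$protein_atom],
                hb1$ligand_role, round(hb1$distance, 9))
  key2 <- paste(pa2$name[hb2$protein_atom], pa2$resid[hb2$protein_atom],
                hb2$ligand_role, round(hb2$distance, 9))
  expect_setequal(key2, key1)
})
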