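# Evaluation metrics.

test_that("hbond reconstruction scores the stated cases", {
  prep <- prepared_toy(seed = 13, n_hb = 2)
  prot <- prep$pocket_atoms
  # reference ligand as "generated": every reference bond re-forms -> 1.0
  expect_equal(hbond_reconstruction(prep$ligand, prep$hbonds, prot), 1.0)
  # a far-away molecule forms nothing -> 0.0
  off <- prep$ligand
  off$coords <- off$coords + 100
  expect_equal(hbond_reconstruction(off, prep$hbonds, prot), 0.0)
  # no reference bonds -> excluded-pocket signal (NA), not 0
  expect_warning(
    res <- hbond_reconstruction(prep$ligand, prep$hbonds[0, ], prot),
    "excluded")
  expect_true(is.na(res))
})

test_that("reconstruction can exceed 1 when one protein atom gains two bonds", {
  # lone backbone carbonyl O acceptor; reference has a single bond to it
  prot <- data.frame(element = "O", name = "O", resname = "ALA", resid = 1L,
                     chain = "A", x = 0, y = 0, z = 0,
                     stringsAsFactors = FALSE)
  ref <- data.frame(protein_atom = 1L, ligand_atom = 1L,
                    ligand_role = "donor", distance = 2.9)
  # generated molecule with TWO hydroxyls donating to the same O, each
  # with its own carbon neighbor anti to the acceptor (angle 180)
  gen <- list(elements = c("O", "C", "O", "C"),
              coords = rbind(c(2.9, 0, 0), c(4.33, 0, 0),
                             c(0, 2.9, 0), c(0, 4.33, 0)),
              bonds = data.frame(i = c(1, 3), j = c(2, 4), order = c(1L, 1L)),
              charges = integer(4), had_hydrogen = logical(4))
  score <- hbond_reconstruction(gen, ref, prot)
  expect_equal(score, 2.0)
})

test_that("diversity hits its endpoints and matches hand-set arithmetic", {
  expect_equal(diversity(list(ethanol(), ethanol(), ethanol())), 0)
  # disjoint fingerprints: a carbon chain vs a nitrogen chain
  c2 <- list(elements = c("C", "C"), coords = rbind(c(0, 0, 0), c(1.5, 0, 0)),
             bonds = data.frame(i = 1L, j = 2L, order = 1L))
  n2 <- list(elements = c("N", "N"), coords = rbind(c(0, 0, 0), c(1.4, 0, 0)),
             bonds = data.frame(i = 1L, j = 2L, order = 1L))
  expect_equal(diversity(list(c2, n2)), 1)
  expect_warning(d1 <- diversity(list(c2)), "fewer than 2")
  expect_true(is.na(d1))
  # 3-molecule fixture vs explicit bit-set arithmetic
  mols <- list(c2, n2, ethanol())
  fps <- lapply(mols, path_fingerprint)
  tani <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  oracle <- mean(c(1 - tani(fps[[1]], fps[[2]]),
                   1 - tani(fps[[1]], fps[[3]]),
                   1 - tani(fps[[2]], fps[[3]])))
  expect_equal(diversity(mols), oracle)
})

test_that("path fingerprints encode elements, bonds and path direction", {
  # ethanol paths include C, O, C1C, C1O, C1C1O (canonicalized)
  ps <- pocketdiff:::path_strings(pocketdiff:::as_ligand_graph(ethanol()))
  expect_setequal(ps, c("C", "O", "C1C", "C1O", "C1C1O"))
  # reversal canonicalization: O-C-C enumerated from either end is one path
  expect_equal(sum(ps == "C1C1O"), 1)
  bz <- pocketdiff:::path_strings(pocketdiff:::as_ligand_graph(benzene()))
  expect_true("C4C" %in% bz)
})

test_that("drug properties panel matches the reference descriptors", {
  p_eth <- drug_properties("CCO")
  expect_true(p_eth$valid)
  # frozen from the reference implementation (Crippen logP of ethanol)
  expect_equal(p_eth$logP, -0.0014, tolerance = 1e-6)
  expect_true(p_eth$QED > 0 && p_eth$QED < 1)
  expect_true(p_eth$SA > 0 && p_eth$SA <= 1)
  p_met <- drug_properties("C")
  expect_equal(p_met$lipinski_count, 5)
  # SA monotonicity: unbranched alkane easier than a stereo-dense polycycle
  p_alk <- drug_properties("CCCCCCCC")
  p_poly <- drug_properties("CC12CC3(O)CC(CN3C1)C2(N)C(=O)O")
  expect_gte(p_alk$SA, p_poly$SA)
  # an unsanitizable molecule is flagged, not an error
  bad <- list(elements = c("O", "O", "O", "O", "O"),
              coords = rbind(c(0, 0, 0), c(1.4, 0, 0), c(-1.4, 0, 0),
                             c(0, 1.4, 0), c(0, -1.4, 0)),
              bonds = data.frame(i = c(1, 1, 1, 1), j = 2:5,
                                 order = rep(1L, 4)))
  expect_false(drug_properties(bad)$valid)
})

test_that("donor/acceptor fractions follow the perception rules", {
  expect_equal(unname(donor_acceptor_fractions(list(benzene()))), c(0, 0))
  expect_equal(unname(donor_acceptor_fractions(list(ethanol()))),
               c(1 / 3, 1 / 3))
  # pooled value = atom-weighted mean of per-molecule values
  pooled <- donor_acceptor_fractions(list(ethanol(), benzene()))
  expect_equal(unname(pooled), c(1 / 9, 1 / 9))
})

test_that("substructure angles compute from coordinates", {
  lin <- list(elements = c("C", "C", "C"),
              coords = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
              bonds = data.frame(i = c(1, 2), j = c(2, 3), order = c(1L, 1L)))
  a <- substructure_angles(list(lin), "CCC")
  expect_equal(a$CCC, 180)
  ra <- list(elements = c("C", "C", "C"),
             coords = rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)),
             bonds = data.frame(i = c(1, 2), j = c(2, 3), order = c(1L, 1L)))
  expect_equal(substructure_angles(list(ra), "CCC")$CCC, 90)
  # no matches -> empty, not an error
  expect_length(substructure_angles(list(lin), "OPO")$OPO, 0)
  # gauche butane: dihedral by an independent acos construction
  phi <- 60 * pi / 180
  butane <- list(
    elements = rep("C", 4),
    coords = rbind(c(0, 1, 0), c(0, 0, 0), c(1.5, 0, 0),
                   c(1.5 + cos(phi) * 0, 1 * cos(phi), 1 * sin(phi))),
    bonds = data.frame(i = 1:3, j = 2:4, order = rep(1L, 3)))
  d <- substructure_angles(list(butane), "CCCC")$CCCC
  # oracle: angle between plane normals via acos
  b1 <- butane$coords[1, ] - butane$coords[2, ]
  b2 <- butane$coords[3, ] - butane$coords[2, ]
  b3 <- butane$coords[4, ] - butane$coords[3, ]
  n1 <- pracma_cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                                         u[3] * v[1] - u[1] * v[3],
                                         u[1] * v[2] - u[2] * v[1])
  v1 <- pracma_cross(b1, b2); v2 <- pracma_cross(-b2, b3)
  oracle <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(d, oracle, tolerance = 1e-9)
  # aromatic pattern matches the SDF aromatic ring
  expect_gt(length(substructure_angles(list(benzene()), "cccc")$cccc), 0)
})

test_that("metrics report aggregates per pocket and counts invalids", {
  prep1 <- prepared_toy(seed = 13, n_hb = 2)
  prep2 <- prepared_toy(seed = 14, n_hb = 1)
  per_pocket <- list(
    p1 = list(molecules = list(prep1$ligand, prep1$ligand),
              reference = prep1),
    p2 = list(molecules = list(prep2$ligand, prep2$ligand),
              reference = prep2))
  rep_ <- metrics_report(per_pocket, with_drug_panel = FALSE)
  expect_equal(nrow(rep_$per_pocket), 2)
  expect_equal(rep_$per_pocket$hbond_reconstruction, c(1, 1))
  expect_equal(rep_$per_pocket$diversity, c(0, 0))
  expect_equal(rep_$aggregate$n_pockets, 2)
  expect_equal(rep_$aggregate$mean$hbond_reconstruction, 1)
  csvp <- tempfile(fileext = ".csv"); jsonp <- tempfile(fileext = ".json")
  write_metrics_report(rep_, csvp, jsonp)
  expect_equal(nrow(utils::read.csv(csvp)), 2)
})
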