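# Shared in-code fixtures for the test suite.

# minimal hand-built protein table
tiny_protein <- function() {
  data.frame(
    element = c("N", "C", "C", "O", "O"),
    name = c("N", "CA", "C", "O", "OG"),
    resname = "SER", resid = 1L, chain = "A",
    x = c(-1.20, 0.00, 1.25, 1.65, 0.45),
    y = c(0.85, 0.00, 0.88, 2.04, -1.35),
    z = c(0.00, 0.00, 0.00, 0.00, 0.55),
    stringsAsFactors = FALSE)
}

# ethanol heavy atoms: C-C-O with realistic geometry
ethanol <- function() {
  list(elements = c("C", "C", "O"),
       coords = rbind(c(0, 0, 0), c(1.51, 0, 0), c(2.02, 1.33, 0)),
       bonds = data.frame(i = c(1, 2), j = c(2, 3), order = c(1L, 1L)),
       charges = integer(3), had_hydrogen = c(FALSE, FALSE, TRUE))
}

methane <- function() {
  list(elements = "C", coords = matrix(0, 1, 3),
       bonds = data.frame(i = integer(0), j = integer(0), order = integer(0)),
       charges = 0L, had_hydrogen = TRUE)
}

benzene <- function() {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  list(elements = rep("C", 6),
       coords = cbind(1.39 * cos(ang), 1.39 * sin(ang), 0),
       bonds = data.frame(i = 1:6, j = c(2:6, 1), order = 4L),
       charges = integer(6), had_hydrogen = rep(TRUE, 6))
}

# a prepared toy complex reused across test files
prepared_toy <- function(seed = 3, n_hb = 2, n_lig = 8, n_pocket = 6) {
  prepare_complex(make_toy_complex(fixture_spec(
    n_pocket_residues = n_pocket, n_ligand_atoms = n_lig,
    n_planted_hbonds = n_hb, seed = seed)))
}

expect_rigid_equal <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(a - b)), tol)
}
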