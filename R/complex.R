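# Protein-ligand complex container and pocket reduction.

#' Assemble a ligand object from parsed SDF fields
#' @keywords internal
make_ligand <- function(elements, coords, bonds = NULL, had_hydrogen = NULL,
                        charges = NULL, vocab = default_element_vocab()) {
  n <- length(elements)
  if (n < 1) stop("ligand must contain at least one heavy atom")
  if (is.null(bonds)) bonds <- data.frame(i = integer(0), j = integer(0),
                                          order = integer(0))
  if (is.null(had_hydrogen)) had_hydrogen <- logical(n)
  if (is.null(charges)) charges <- integer(n)
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == n, ncol(coords) == 3)
  if (!all(is.finite(coords))) stop("ligand coordinates must be finite")
  if (nrow(bonds) && any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n)) {
    stop("ligand bond index out of range")
  }
  structure(list(elements = norm_element(elements), coords = coords,
                 onehot = element_one_hot(elements, vocab), bonds = bonds,
                 had_hydrogen = had_hydrogen, charges = charges,
                 vocab = vocab),
            class = "LigandMolecule")
}

#' Load a protein-ligand complex from disk
#'
#' Reads a PDB protein and an SDF/MOL ligand into a `ComplexRecord`.
#' Ligand hydrogens are stripped on ingest; the heavy atoms that carried
#' them are recorded (`had_hydrogen`) because donor perception later needs
#' to know which atoms bore an explicit proton. Hydrogen bonds and
#' interaction particles start empty — see [detect_hydrogen_bonds()] and
#' [place_interaction_particles()].
#'
#' @param protein_path PDB file
#' @param ligand_path SDF/MOL file
#' @param id record id (defaults to the protein file stem)
#' @param vocab ligand element vocabulary
#' @return a ComplexRecord: list(id, protein, pocket = NULL, ligand,
#'   hbonds = empty, particles = empty)
#' @export
load_complex <- function(protein_path, ligand_path, id = NULL,
                         vocab = default_element_vocab()) {
  protein <- read_pdb(protein_path)
  lig <- read_sdf(ligand_path, strip_hydrogens = TRUE)
  ligand <- make_ligand(lig$elements, lig$coords, lig$bonds,
                        lig$had_hydrogen, lig$charges, vocab)
  if (is.null(id)) id <- sub("\\.[^.]+$", "", basename(protein_path))
  new_complex_record(id, protein, ligand)
}

new_complex_record <- function(id, protein, ligand, pocket = NULL,
                               hbonds = NULL, particles = NULL) {
  if (is.null(hbonds)) {
    hbonds <- data.frame(protein_atom = integer(0), ligand_atom = integer(0),
                         ligand_role = character(0), distance = numeric(0))
  }
  if (is.null(particles)) {
    particles <- data.frame(bond_id = integer(0), j = integer(0),
                            x = numeric(0), y = numeric(0), z = numeric(0),
                            role = character(0))
  }
  structure(list(id = id, protein = protein, pocket = pocket,
                 ligand = ligand, hbonds = hbonds, particles = particles),
            class = "ComplexRecord")
}

#' @export
print.ComplexRecord <- function(x, ...) {
  cat("<ComplexRecord>", x$id, "\n")
  cat("  protein atoms:", nrow(x$protein),
      " residues:", length(unique(paste(x$protein$chain, x$protein$resid))), "\n")
  cat("  ligand heavy atoms:", length(x$ligand$elements), "\n")
  cat("  hydrogen bonds:", nrow(x$hbonds),
      " interaction particles:", nrow(x$particles), "\n")
  if (!is.null(x$pocket)) cat("  pocket C-alpha nodes:", nrow(x$pocket$pos), "\n")
  invisible(x)
}

#' Restrict a protein to the residues lining the ligand
#'
#' A residue is retained iff any of its atoms lies within `radius` of any
#' ligand heavy atom; residues are kept or dropped whole so the downstream
#' C-alpha reduction stays meaningful.
#'
#' @param protein full-atom protein data.frame
#' @param ligand a LigandMolecule
#' @param radius inclusion radius in Angstrom (default 10)
#' @return the retained subset of `protein`
#' @export
extract_pocket <- function(protein, ligand, radius = 10.0) {
  stopifnot(radius > 0)
  d <- pairwise_dist(as.matrix(protein[, c("x", "y", "z")]), ligand$coords)
  atom_near <- apply(d, 1, min) <= radius
  key <- paste(protein$chain, protein$resid)
  keep_res <- unique(key[atom_near])
  out <- protein[key %in% keep_res, , drop = FALSE]
  if (!nrow(out)) stop("no residue within ", radius, " A of the ligand")
  rownames(out) <- NULL
  out
}

#' Reduce a pocket to its C-alpha graph
#'
#' One node per residue at the C-alpha position, with a 21-class residue
#' one-hot (20 standard amino acids + unknown).
#'
#' @param pocket full-atom protein data.frame (typically from
#'   [extract_pocket()])
#' @return a CalphaPocket: list(pos n x 3, onehot n x 21, resnames, resids)
#' @export
to_calpha <- function(pocket) {
  key <- paste(pocket$chain, pocket$resid)
  ukey <- unique(key)
  ca <- pocket[pocket$name == "CA", , drop = FALSE]
  ca_key <- paste(ca$chain, ca$resid)
  missing <- setdiff(ukey, ca_key)
  if (length(missing)) {
    stop("residue(s) lacking a CA atom: ", paste(missing, collapse = ", "))
  }
  ca <- ca[match(ukey, ca_key), , drop = FALSE]
  structure(list(pos = as.matrix(ca[, c("x", "y", "z")]),
                 onehot = residue_one_hot(ca$resname),
                 resnames = ca$resname,
                 resids = ca$resid, chains = ca$chain),
            class = "CalphaPocket")
}

#' Run the full preparation pipeline on one complex
#'
#' load -> pocket extraction -> C-alpha reduction -> hydrogen-bond
#' detection -> interaction-particle placement.
#'
#' @param record a ComplexRecord (fresh from [load_complex()] or the
#'   fixture generator)
#' @param radius pocket inclusion radius (Angstrom)
#' @param criteria hydrogen-bond criteria, see [hbond_criteria()]
#' @return the ComplexRecord with pocket, hbonds and particles filled in
#' @export
prepare_complex <- function(record, radius = 10.0,
                            criteria = hbond_criteria()) {
  pocket_atoms <- extract_pocket(record$protein, record$ligand, radius)
  record$pocket <- to_calpha(pocket_atoms)
  # detection runs against the full-atom pocket region, not the C-alpha graph
  record$hbonds <- detect_hydrogen_bonds(pocket_atoms, record$ligand, criteria)
  record$pocket_atoms <- pocket_atoms
  record$particles <- place_all_particles(record$hbonds, pocket_atoms,
                                          record$ligand)
  record
}

#' Write the hydrogen-bond / particle sidecar JSON for a complex
#' @param record prepared ComplexRecord
#' @param path output JSON path
#' @export
write_hbond_sidecar <- function(record, path) {
  hb <- record$hbonds
  prot <- if (!is.null(record$pocket_atoms)) record$pocket_atoms else record$protein
  bonds <- lapply(seq_len(nrow(hb)), function(k) {
    pa <- hb$protein_atom[k]
    list(bond_id = k,
         protein_atom = list(index = pa, name = prot$name[pa],
                             resname = prot$resname[pa],
                             resid = prot$resid[pa]),
         ligand_atom = hb$ligand_atom[k],
         role = hb$ligand_role[k],
         distance = hb$distance[k],
         particles = lapply(which(record$particles$bond_id == k), function(r) {
           list(j = record$particles$j[r],
                position = as.numeric(record$particles[r, c("x", "y", "z")]),
                label = record$particles$role[r])
         }))
  })
  jsonlite::write_json(list(id = record$id, hbonds = bonds), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export the training tensor bundle for a prepared complex
#'
#' Positions, one-hot blocks and node-kind flags for ligand, pocket
#' C-alpha nodes and interaction particles, serialized as JSON arrays
#' (the R analogue of an NPZ bundle).
#' @param record prepared ComplexRecord
#' @param path output JSON path
#' @export
write_tensor_bundle <- function(record, path) {
  p <- record$particles
  jsonlite::write_json(list(
    id = record$id,
    ligand = list(coords = record$ligand$coords,
                  onehot = record$ligand$onehot,
                  elements = record$ligand$elements),
    pocket = list(coords = record$pocket$pos, onehot = record$pocket$onehot),
    particles = list(coords = as.matrix(p[, c("x", "y", "z")]),
                     onehot = particle_one_hot(p$role),
                     bond_id = p$bond_id, j = p$j)
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

particle_one_hot <- function(roles) {
  if (!length(roles)) return(matrix(0, 0, 2))
  m <- matrix(0, length(roles), 2,
              dimnames = list(NULL, c("acceptor", "donor")))
  m[cbind(seq_along(roles), match(roles, c("acceptor", "donor")))] <- 1
  m
}
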