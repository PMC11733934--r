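# Minimal fixed-column PDB and SDF V2000 I/O.
#
# No cheminformatics I/O package ships with the target environment, and the
# subset of both formats this package needs (ATOM/HETATM records; V2000
# counts, atom and bond blocks) is small and rigidly columnar, so the
# readers/writers live here. They are deliberately strict: a malformed
# record is an error naming the offending line, never a silent skip.

#' Read a protein from a PDB file
#'
#' Parses ATOM and HETATM records into a full-atom protein table. Hydrogens
#' are dropped (the whole pipeline is heavy-atom only). Alternate locations
#' other than ' ' or 'A' are skipped.
#'
#' @param path PDB file path
#' @return data.frame with columns element, name, resname, resid, chain,
#'   x, y, z (coordinates in Angstrom)
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (!length(lines)) stop("no ATOM/HETATM records in ", path)
  bad <- nchar(lines) < 54
  if (any(bad)) {
    stop("malformed PDB record (too short): '", lines[which(bad)[1]], "'")
  }
  altloc <- substr(lines, 17, 17)
  lines <- lines[altloc %in% c(" ", "A")]
  name <- trimws(substr(lines, 13, 16))
  resname <- trimws(substr(lines, 18, 20))
  chain <- substr(lines, 22, 22)
  resid <- suppressWarnings(as.integer(substr(lines, 23, 26)))
  x <- suppressWarnings(as.numeric(substr(lines, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(lines, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(lines, 47, 54)))
  element <- trimws(substr(lines, 77, 78))
  # fall back on the atom name when the element column is blank
  blank <- element == ""
  element[blank] <- substr(gsub("[0-9]", "", name[blank]), 1, 1)
  element <- norm_element(element)
  bad <- is.na(x) | is.na(y) | is.na(z) | is.na(resid)
  if (any(bad)) {
    stop("unparseable coordinate/resid in PDB record: '",
         lines[which(bad)[1]], "'")
  }
  df <- data.frame(element = element, name = name, resname = resname,
                   resid = resid, chain = chain, x = x, y = y, z = z,
                   stringsAsFactors = FALSE)
  df[df$element != "H" & df$element != "D", , drop = FALSE]
}

#' Write a full-atom protein table to PDB
#' @param protein data.frame as returned by [read_pdb()]
#' @param path output file
#' @export
write_pdb <- function(protein, path) {
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(protein)),
    ifelse(nchar(protein$name) < 4, paste0(" ", protein$name), protein$name),
    protein$resname, protein$chain, protein$resid,
    protein$x, protein$y, protein$z, toupper(protein$element))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read the first molecule from an SDF/MOL (V2000) file
#'
#' @param path SDF or MOL file
#' @param strip_hydrogens drop explicit hydrogens, recording which heavy
#'   atoms carried them (needed later for donor perception)
#' @return list with elements: elements (character), coords (n x 3 matrix),
#'   bonds (data.frame i, j, order; 1-based into the returned atoms),
#'   had_hydrogen (logical per heavy atom), charges (integer formal charges)
#' @export
read_sdf <- function(path, strip_hydrogens = TRUE) {
  if (!file.exists(path)) stop("SDF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) stop("SDF too short: ", path)
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds)) {
    stop("malformed SDF counts line: '", counts, "'")
  }
  if (natoms < 1) stop("SDF declares zero atoms: ", path)
  atom_lines <- lines[5:(4 + natoms)]
  bad <- nchar(atom_lines) < 34
  if (any(bad)) stop("malformed SDF atom line: '", atom_lines[which(bad)[1]], "'")
  x <- as.numeric(substr(atom_lines, 1, 10))
  y <- as.numeric(substr(atom_lines, 11, 20))
  z <- as.numeric(substr(atom_lines, 21, 30))
  el <- norm_element(substr(atom_lines, 32, 34))
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("unparseable SDF atom coordinates in ", path)
  }
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  if (nbonds > 0) {
    bond_lines <- lines[(5 + natoms):(4 + natoms + nbonds)]
    bonds <- data.frame(
      i = as.integer(substr(bond_lines, 1, 3)),
      j = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9)))
    if (anyNA(bonds)) stop("malformed SDF bond block in ", path)
    if (any(bonds$i < 1 | bonds$i > natoms | bonds$j < 1 | bonds$j > natoms)) {
      stop("SDF bond index out of range in ", path)
    }
  }
  charges <- integer(natoms)
  chg <- grep("^M  CHG", lines, value = TRUE)
  for (ln in chg) {
    toks <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    n <- toks[1]
    for (k in seq_len(n)) charges[toks[2 * k]] <- toks[2 * k + 1]
  }
  coords <- cbind(x, y, z)
  had_h <- logical(natoms)
  if (nrow(bonds)) {
    hmask <- el == "H"
    for (r in seq_len(nrow(bonds))) {
      if (hmask[bonds$i[r]]) had_h[bonds$j[r]] <- TRUE
      if (hmask[bonds$j[r]]) had_h[bonds$i[r]] <- TRUE
    }
  }
  if (strip_hydrogens) {
    keep <- el != "H"
    if (!any(keep)) stop("ligand has no heavy atoms: ", path)
    remap <- cumsum(keep)
    bonds <- bonds[keep[bonds$i] & keep[bonds$j], , drop = FALSE]
    bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
    coords <- coords[keep, , drop = FALSE]
    charges <- charges[keep]
    had_h <- had_h[keep]
    el <- el[keep]
  }
  rownames(bonds) <- NULL
  list(elements = el, coords = coords, bonds = bonds,
       had_hydrogen = had_h, charges = charges)
}

#' Write one or more molecules to an SDF (V2000) file
#'
#' @param mols a single molecule list (elements/coords/bonds) or a list of
#'   them; each may carry a `props` named list written as SDF data fields
#' @param path output file
#' @export
write_sdf <- function(mols, path) {
  if (!is.null(mols$elements)) mols <- list(mols)
  out <- character(0)
  for (m in mols) {
    n <- length(m$elements)
    nb <- if (is.null(m$bonds)) 0L else nrow(m$bonds)
    name <- if (is.null(m$name)) "pocketdiff" else m$name
    block <- c(name, "  pocketdiff", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
    block <- c(block, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              m$coords[, 1], m$coords[, 2], m$coords[, 3],
                              m$elements))
    if (nb > 0) {
      block <- c(block, sprintf("%3d%3d%3d  0", m$bonds$i, m$bonds$j,
                                m$bonds$order))
    }
    block <- c(block, "M  END")
    if (!is.null(m$props)) {
      for (nm in names(m$props)) {
        block <- c(block, sprintf(">  <%s>", nm),
                   as.character(m$props[[nm]]), "")
      }
    }
    out <- c(out, block, "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read every molecule record from a multi-record SDF file
#' @param path SDF file
#' @param strip_hydrogens passed through to the single-record parser
#' @return list of molecules as in [read_sdf()]
#' @export
read_sdf_multi <- function(path, strip_hydrogens = TRUE) {
  lines <- readLines(path, warn = FALSE)
  breaks <- grep("^\\$\\$\\$\\$", lines)
  if (!length(breaks)) breaks <- length(lines) + 1L
  start <- 1L
  mols <- list()
  for (b in breaks) {
    chunk <- lines[start:(b - 1L)]
    start <- b + 1L
    if (!any(nzchar(chunk))) next
    tmp <- tempfile(fileext = ".sdf")
    writeLines(chunk, tmp)
    mols[[length(mols) + 1L]] <- read_sdf(tmp, strip_hydrogens)
    unlink(tmp)
  }
  mols
}
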