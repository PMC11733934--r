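# Evaluation metrics: hydrogen-bond reconstruction, fingerprint diversity,
# drug-likeness panel, donor/acceptor fractions, substructure angles.

as_ligand_graph <- function(mol) {
  # normalize a GeneratedLigand / parsed SDF / LigandMolecule to the
  # fields the perception and fingerprint code needs
  list(elements = mol$elements,
       coords = mol$coords,
       bonds = if (is.null(mol$bonds)) data.frame(i = integer(0),
                                                  j = integer(0),
                                                  order = integer(0)) else mol$bonds,
       charges = mol$charges %||% integer(length(mol$elements)),
       had_hydrogen = mol$had_hydrogen %||% logical(length(mol$elements)))
}

#' Hydrogen-bond reconstruction score of one generated molecule
#'
#' Hydrogen bonds between the generated pose (as-is, no minimization) and
#' the full-atom protein are detected with the same geometric criteria
#' that defined the reference bonds; the score is the number of detected
#' bonds whose protein atom matches some reference bond's protein atom,
#' divided by the number of reference bonds. One protein atom gaining
#' several bonds counts several times, so the score may exceed 1.
#'
#' @param generated a GeneratedLigand (or any ligand-like object)
#' @param reference_hbonds reference bond table (protein_atom indices into
#'   `protein`)
#' @param protein full-atom protein data.frame
#' @param criteria [hbond_criteria()]
#' @return score >= 0, or NA (with a warning) when the pocket has no
#'   reference bonds and is excluded from assessment
#' @export
hbond_reconstruction <- function(generated, reference_hbonds, protein,
                                 criteria = hbond_criteria()) {
  if (!nrow(reference_hbonds)) {
    warning("pocket has no reference hydrogen bonds; excluded from assessment")
    return(NA_real_)
  }
  lig <- as_ligand_graph(generated)
  det <- detect_hydrogen_bonds(protein, lig, criteria)
  sum(det$protein_atom %in% reference_hbonds$protein_atom) /
    nrow(reference_hbonds)
}

# ---- topological path fingerprint -----------------------------------------

path_strings <- function(mol, max_len = 7) {
  # all simple bond paths of 0..max_len bonds, canonicalized by taking the
  # lexicographic min of the forward and reversed label string
  el <- mol$elements
  n <- length(el)
  nb <- vector("list", n)
  ord <- list()
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    nb[[b$i[r]]] <- c(nb[[b$i[r]]], b$j[r])
    nb[[b$j[r]]] <- c(nb[[b$j[r]]], b$i[r])
    ord[[paste(min(b$i[r], b$j[r]), max(b$i[r], b$j[r]))]] <- b$order[r]
  }
  out <- character(0)
  path_label <- function(path) {
    labs <- el[path]
    if (length(path) == 1) return(labs)
    bl <- vapply(seq_len(length(path) - 1), function(k) {
      as.character(ord[[paste(min(path[k], path[k + 1]),
                              max(path[k], path[k + 1]))]])
    }, character(1))
    fwd <- paste(labs, c(bl, ""), sep = "", collapse = "")
    rev_ <- paste(rev(labs), c(rev(bl), ""), sep = "", collapse = "")
    min(fwd, rev_)
  }
  dfs <- function(path) {
    out[[length(out) + 1]] <<- path_label(path)
    if (length(path) > max_len) return()
    for (q in nb[[path[length(path)]]]) {
      if (!(q %in% path)) dfs(c(path, q))
    }
  }
  for (a in seq_len(n)) dfs(a)
  unique(out)
}

str_hash <- function(s, nbits) {
  # deterministic polynomial rolling hash -> [1, nbits]
  vapply(s, function(x) {
    h <- 7
    for (cc in utf8ToInt(x)) h <- (h * 31 + cc) %% 2147483647
    as.integer(h %% nbits) + 1L
  }, integer(1), USE.NAMES = FALSE)
}

#' Topological path fingerprint (bit set)
#'
#' Enumerates all simple bond paths up to `max_len` bonds, labels them by
#' element and bond order, and hashes each canonical path string into a
#' fixed-size bit set — a minimal analogue of the path-based daylight-style
#' fingerprint used for Tanimoto similarity.
#' @param mol ligand-like object (elements + bonds)
#' @param nbits fingerprint size (default 2048)
#' @param max_len maximum path length in bonds
#' @return sorted integer vector of set bit positions
#' @export
path_fingerprint <- function(mol, nbits = 2048, max_len = 7) {
  sort(unique(str_hash(path_strings(as_ligand_graph(mol), max_len), nbits)))
}

#' Tanimoto similarity of two bit sets
#' @param fp1,fp2 integer vectors of set bits
#' @return intersection over union; 1 when both sets are empty
#' @export
tanimoto <- function(fp1, fp2) {
  u <- length(union(fp1, fp2))
  if (u == 0) return(1)
  length(intersect(fp1, fp2)) / u
}

#' Average pairwise dissimilarity of a molecule set
#'
#' Mean of (1 - Tanimoto similarity) over all unordered pairs of
#' fingerprints.
#' @param molecules list of ligand-like objects
#' @param nbits fingerprint size
#' @return value in \[0, 1\], or NA (with a warning) for fewer than 2
#'   molecules
#' @export
diversity <- function(molecules, nbits = 2048) {
  if (length(molecules) < 2) {
    warning("diversity undefined for fewer than 2 molecules")
    return(NA_real_)
  }
  fps <- lapply(molecules, path_fingerprint, nbits = nbits)
  n <- length(fps)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      tot <- tot + (1 - tanimoto(fps[[i]], fps[[j]]))
      np <- np + 1
    }
  }
  tot / np
}

# ---- drug-likeness panel (delegated to the bundled rdkit script) ----------

pd_python <- function() {
  py <- Sys.getenv("POCKETDIFF_PYTHON", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) stop("no python interpreter found; set POCKETDIFF_PYTHON")
  py
}

run_drug_props_script <- function(args) {
  script <- system.file("python", "drug_props.py", package = "pocketdiff")
  if (!nzchar(script)) stop("bundled drug_props.py not found")
  out <- suppressWarnings(system2(pd_python(), shQuote(c(script, args)),
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("descriptor script failed (exit ", status, ")")
  }
  jsonlite::fromJSON(paste(out, collapse = "\n"), simplifyVector = TRUE)
}

#' Drug-likeness descriptor panel for one molecule
#'
#' QED, synthetic accessibility (rescaled so higher = easier, range 0-1),
#' Crippen logP and the Lipinski rule count (satisfied rules out of 5:
#' MW <= 500, logP <= 5, H-donors <= 5, H-acceptors <= 10, rotatable
#' bonds <= 10). Descriptors are computed by rdkit through a bundled
#' helper script; a molecule rdkit cannot sanitize is returned flagged
#' (`valid = FALSE`) with NA descriptors.
#'
#' @param molecule ligand-like object, or a SMILES string
#' @return list(valid, QED, SA, logP, lipinski_count, MW, HBD, HBA, ROTB)
#' @export
drug_properties <- function(molecule) {
  if (is.character(molecule)) {
    res <- run_drug_props_script(c("--smiles", molecule))
  } else {
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp))
    mol <- as_ligand_graph(molecule)
    write_sdf(list(elements = mol$elements, coords = mol$coords,
                   bonds = mol$bonds), tmp)
    res <- run_drug_props_script(c("--sdf", tmp))
  }
  if (!isTRUE(res$valid)) {
    return(list(valid = FALSE, QED = NA_real_, SA = NA_real_,
                logP = NA_real_, lipinski_count = NA_integer_,
                MW = NA_real_, HBD = NA_integer_, HBA = NA_integer_,
                ROTB = NA_integer_))
  }
  lip <- sum(res$mw <= 500, res$logp <= 5, res$hbd <= 5, res$hba <= 10,
             res$rotb <= 10)
  list(valid = TRUE, QED = res$qed, SA = (10 - res$sa) / 9,
       logP = res$logp, lipinski_count = lip, MW = res$mw,
       HBD = res$hbd, HBA = res$hba, ROTB = res$rotb)
}

#' Pooled donor / acceptor atom fractions of a molecule set
#'
#' Uses the same ligand-side perception rules as the hydrogen-bond
#' detector; fractions are pooled (total donors / total heavy atoms).
#' @param molecules list of ligand-like objects
#' @return named numeric c(donor = ..., acceptor = ...)
#' @export
donor_acceptor_fractions <- function(molecules) {
  stopifnot(length(molecules) >= 1)
  nd <- na <- nh <- 0
  for (m in molecules) {
    lig <- as_ligand_graph(m)
    da <- ligand_donor_acceptor(lig)
    nd <- nd + sum(da$donor); na <- na + sum(da$acceptor)
    nh <- nh + length(lig$elements)
  }
  c(donor = nd / nh, acceptor = na / nh)
}

# ---- substructure geometry ------------------------------------------------

parse_pattern <- function(pattern) {
  toks <- regmatches(pattern, gregexpr("=?[A-Za-z]", pattern))[[1]]
  atoms <- gsub("=", "", toks)
  list(elements = toupper(atoms),
       aromatic = atoms %in% letters,
       double_bond = c(grepl("=", toks)[-1]))
}

match_paths <- function(mol, pat) {
  el <- toupper(mol$elements)
  n <- length(el)
  b <- mol$bonds
  adj <- vector("list", n); bord <- list()
  for (r in seq_len(nrow(b))) {
    adj[[b$i[r]]] <- c(adj[[b$i[r]]], b$j[r])
    adj[[b$j[r]]] <- c(adj[[b$j[r]]], b$i[r])
    bord[[paste(min(b$i[r], b$j[r]), max(b$i[r], b$j[r]))]] <- b$order[r]
  }
  arom_atom <- logical(n)
  if (nrow(b)) {
    for (r in which(b$order == 4)) {
      arom_atom[b$i[r]] <- TRUE; arom_atom[b$j[r]] <- TRUE
    }
  }
  k <- length(pat$elements)
  res <- list()
  ok_atom <- function(a, pos) {
    el[a] == pat$elements[pos] && (!pat$aromatic[pos] || arom_atom[a])
  }
  ok_bond <- function(a, b_, pos) {
    o <- bord[[paste(min(a, b_), max(a, b_))]]
    both_arom <- pat$aromatic[pos] && pat$aromatic[pos + 1]
    if (both_arom) return(o == 4)
    if (pat$double_bond[pos]) return(o == 2)
    TRUE
  }
  extend <- function(path) {
    pos <- length(path)
    if (pos == k) {
      if (path[1] < path[k]) res[[length(res) + 1]] <<- path
      return()
    }
    for (q in adj[[path[pos]]]) {
      if (!(q %in% path) && ok_atom(q, pos + 1) && ok_bond(path[pos], q, pos)) {
        extend(c(path, q))
      }
    }
  }
  for (a in seq_len(n)) if (ok_atom(a, 1)) extend(a)
  res
}

#' Bond-angle / dihedral-angle distributions of matched substructures
#'
#' Patterns are element chains ("CCC", "CC=O", "CCCC", ...): uppercase =
#' element, lowercase = aromatic carbon, '=' = double bond between the
#' flanking atoms. Three-atom patterns yield the geometric angle at the
#' central atom; four-atom patterns the (absolute) dihedral. A pattern
#' with no matches yields an empty numeric vector, never an error.
#'
#' @param molecules list of ligand-like objects with coordinates
#' @param patterns character vector of patterns
#' @return named list of numeric vectors (degrees)
#' @export
substructure_angles <- function(molecules,
                                patterns = c("CCC", "CCO", "CNC", "OPO",
                                             "NCC", "CC=O", "COC", "CCCC",
                                             "cccc", "CCCO", "OCCO", "Cccc",
                                             "CC=CC")) {
  out <- setNames(vector("list", length(patterns)), patterns)
  for (p in patterns) {
    pat <- parse_pattern(p)
    vals <- numeric(0)
    for (m in molecules) {
      lig <- as_ligand_graph(m)
      lig$coords <- m$coords
      for (path in match_paths(lig, pat)) {
        co <- lig$coords
        vals <- c(vals, if (length(path) == 3) {
          angle_deg(co[path[1], ], co[path[2], ], co[path[3], ])
        } else if (length(path) == 4) {
          abs(dihedral_deg(co[path[1], ], co[path[2], ], co[path[3], ],
                           co[path[4], ]))
        })
      }
    }
    out[[p]] <- vals
  }
  out
}

#' Metrics report for generated molecules over a set of pockets
#'
#' Per pocket: mean hydrogen-bond reconstruction over its molecules,
#' set diversity, mean drug-likeness descriptors and pooled donor/acceptor
#' fractions; invalid (unsanitizable) molecules are excluded from the
#' chemistry panel but counted. The aggregate row reports mean and sd
#' across pockets.
#'
#' @param per_pocket named list; each element is
#'   list(molecules = list of GeneratedLigand, reference = prepared
#'   ComplexRecord)
#' @param criteria hydrogen-bond criteria
#' @param with_drug_panel run the rdkit descriptor panel (needs python)
#' @return list(per_pocket = data.frame, aggregate = list)
#' @export
metrics_report <- function(per_pocket, criteria = hbond_criteria(),
                           with_drug_panel = TRUE) {
  rows <- list()
  for (id in names(per_pocket)) {
    entry <- per_pocket[[id]]
    ref <- entry$reference
    prot <- ref$pocket_atoms %||% ref$protein
    recon <- vapply(entry$molecules, function(m) {
      if (nrow(ref$hbonds)) {
        hbond_reconstruction(m, ref$hbonds, prot, criteria)
      } else NA_real_
    }, numeric(1))
    dafrac <- donor_acceptor_fractions(entry$molecules)
    props <- NULL
    n_invalid <- 0
    if (with_drug_panel) {
      props <- lapply(entry$molecules, drug_properties)
      valid <- vapply(props, function(p) isTRUE(p$valid), logical(1))
      n_invalid <- sum(!valid)
      props <- props[valid]
    }
    pm <- function(field) {
      if (!length(props)) return(NA_real_)
      mean(vapply(props, function(p) as.numeric(p[[field]]), numeric(1)))
    }
    rows[[id]] <- data.frame(
      pocket = id, n_molecules = length(entry$molecules),
      n_invalid = n_invalid,
      hbond_reconstruction = mean(recon, na.rm = TRUE),
      diversity = suppressWarnings(diversity(entry$molecules)),
      QED = pm("QED"), SA = pm("SA"), logP = pm("logP"),
      lipinski = pm("lipinski_count"),
      donor_fraction = dafrac["donor"],
      acceptor_fraction = dafrac["acceptor"])
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  num <- per[, !(names(per) %in% c("pocket", "n_molecules", "n_invalid")),
             drop = FALSE]
  aggregate <- list(
    n_pockets = nrow(per),
    mean = lapply(num, function(v) mean(v, na.rm = TRUE)),
    sd = lapply(num, function(v) sd(v, na.rm = TRUE)))
  list(per_pocket = per, aggregate = aggregate)
}

#' Write a metrics report as CSV (per pocket) + JSON (aggregate)
#' @param report result of [metrics_report()]
#' @param csv_path,json_path output files
#' @export
write_metrics_report <- function(report, csv_path, json_path) {
  utils::write.csv(report$per_pocket, csv_path, row.names = FALSE)
  jsonlite::write_json(report$aggregate, json_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(report)
}
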