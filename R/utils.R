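#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd ks.test setNames
#' @importFrom utils head tail
NULL

# Standard amino-acid vocabulary; index 21 is the unknown class.
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Default ligand element vocabulary
#'
#' Heavy-atom element symbols the generative model can emit, in the order
#' used for one-hot encodings and argmax decoding (ties break to the lowest
#' index).
#' @return Character vector of element symbols.
#' @export
default_element_vocab <- function() {
  c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "B")
}

# Covalent radii (Angstrom, single-bond, Cordero-style values) for the
# distance-window bond inference used when decoding generated point clouds.
COVALENT_RADII <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39
)

# Typical max valence per element (heavy-bond counting) used to flag
# overflows in decoded molecules.
MAX_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 5, S = 6,
                 Cl = 1, Br = 1, I = 1, H = 1)

norm_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}

one_hot <- function(idx, n) {
  m <- matrix(0, length(idx), n)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Encode residue names as one-hot rows
#'
#' The 20 standard amino acids each get their own class; anything else
#' (e.g. MSE, ligands mis-filed as residues) maps to a 21st unknown class.
#' @param resnames character vector of 3-letter residue codes
#' @return numeric matrix, one row per residue, 21 columns
#' @export
residue_one_hot <- function(resnames) {
  idx <- match(toupper(resnames), AA3)
  idx[is.na(idx)] <- length(AA3) + 1L
  one_hot(idx, length(AA3) + 1L)
}

element_one_hot <- function(elements, vocab = default_element_vocab()) {
  idx <- match(norm_element(elements), vocab)
  if (anyNA(idx)) {
    stop("element(s) outside vocabulary: ",
         paste(unique(elements[is.na(idx)]), collapse = ", "))
  }
  one_hot(idx, length(vocab))
}

vec_norm <- function(v) sqrt(sum(v^2))

pairwise_dist <- function(a, b) {
  # rows of a vs rows of b -> |a| x |b| distance matrix
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Random rigid (proper) transform
#'
#' Draws a uniform random rotation matrix (QR of a Gaussian matrix with
#' sign-fixed diagonal, det +1) and a translation. Used by the equivariance
#' property tests.
#' @param translation_scale scale of the uniform translation components
#' @return list with elements `R` (3x3) and `b` (length-3)
#' @export
random_rigid_transform <- function(translation_scale = 10) {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, b = runif(3, -translation_scale, translation_scale))
}

apply_rigid <- function(coords, tf) {
  sweep(coords %*% t(tf$R), 2, tf$b, "+")
}

angle_deg <- function(a, b, c) {
  # angle at b, degrees
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

dihedral_deg <- function(p1, p2, p3, p4) {
  # signed dihedral via the atan2 formulation (numerically stable near 0/180)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vec_norm(b2)
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
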