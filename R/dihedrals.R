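# Side-chain chi torsions.
#
# Chi angles follow the standard IUPAC atom quadruples (chi1 =
# N-CA-CB-*G, etc.; Arg limited to chi1..chi4). The last chi of Phe,
# Tyr, Asp and Glu is folded into [0, 180) because their terminal
# aromatic/carboxylate groups are two-fold symmetric.

# atom chain along the chi path per residue; quadruple k = chain[k..k+3]
CHI_CHAIN <- list(
  SER = c("N","CA","CB","OG"),
  THR = c("N","CA","CB","OG1"),
  CYS = c("N","CA","CB","SG"),
  VAL = c("N","CA","CB","CG1"),
  PRO = c("N","CA","CB","CG","CD"),
  ILE = c("N","CA","CB","CG1","CD1"),
  LEU = c("N","CA","CB","CG","CD1"),
  ASN = c("N","CA","CB","CG","OD1"),
  ASP = c("N","CA","CB","CG","OD1"),
  HIS = c("N","CA","CB","CG","ND1"),
  PHE = c("N","CA","CB","CG","CD1"),
  TYR = c("N","CA","CB","CG","CD1"),
  TRP = c("N","CA","CB","CG","CD1"),
  MET = c("N","CA","CB","CG","SD","CE"),
  GLU = c("N","CA","CB","CG","CD","OE1"),
  GLN = c("N","CA","CB","CG","CD","OE1"),
  LYS = c("N","CA","CB","CG","CD","CE","NZ"),
  ARG = c("N","CA","CB","CG","CD","NE","CZ")
)

# residues whose last chi is folded into [0, 180)
FOLD_LAST <- c("PHE", "TYR", "ASP", "GLU")

#' Number of chi angles of a residue type
#'
#' 1 for Ser/Thr/Cys/Val; 2 for Pro/Ile/Leu/Asn/Asp/His/Phe/Tyr/Trp;
#' 3 for Met/Glu/Gln; 4 for Lys/Arg; 0 for Ala/Gly and unknown types.
#'
#' @param res_type 3-letter code(s).
#' @return integer vector of chi counts.
#' @export
chi_count <- function(res_type) {
  vapply(res_type, function(r) {
    ch <- CHI_CHAIN[[r]]
    if (is.null(ch)) 0L else length(ch) - 3L
  }, 0L, USE.NAMES = FALSE)
}

#' IUPAC chi-angle atom quadruples for a residue type
#'
#' @param res_type 3-letter code.
#' @return list of character(4) atom-name quadruples (chi1 first); empty
#'   for Ala/Gly and unknown types.
#' @export
chi_definitions <- function(res_type) {
  ch <- CHI_CHAIN[[res_type]]
  if (is.null(ch)) return(list())
  lapply(seq_len(length(ch) - 3L), function(k) ch[k:(k + 3L)])
}

#' Signed dihedral angle of four points
#'
#' atan2 formulation; positive angles follow the right-hand rule about
#' the central bond, and the representative of +/-180 is -180 so the
#' value always lies in `[-180, 180)`.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees in `[-180, 180)`.
#' @export
torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12)
    stopf("torsion undefined: collinear points")
  b2h <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross3(n1, n2) * b2h), sum(n1 * n2)) * 180 / pi
  wrap180(ang)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Fold symmetric terminal-group angles
#'
#' The last chi of Phe/Tyr/Asp/Glu is mapped into `[0, 180)` (chi and
#' chi + 180 are physically identical); every other angle is returned
#' unchanged.
#'
#' @param angle angle(s) in degrees, in `[-180, 180)`.
#' @param res_type 3-letter code.
#' @param chi_index which chi this angle is (1-based).
#' @return folded angle(s) in degrees.
#' @export
fold_symmetric <- function(angle, res_type, chi_index) {
  if (res_type %in% FOLD_LAST && chi_index == chi_count(res_type))
    wrap_fold(angle)
  else
    angle
}

#' Chi-angle vector of one residue
#'
#' All chi angles of the residue in order, with symmetric terminal
#' angles folded. If any required heavy atom is missing the residue has
#' no complete dihedral vector and `NULL` is returned (a data condition,
#' not an error: such residues are excluded from DADF pools).
#'
#' @param s a `protein_structure`.
#' @param key residue key (`chain:resno:insert`), see [residue_keys()].
#' @return numeric vector of chi angles in degrees, or `NULL` when an
#'   atom is missing or the type has no chi angles.
#' @export
residue_chi_vector <- function(s, key) {
  at <- residue_atoms(s, key)
  if (nrow(at) == 0L) stopf("no residue with key '%s'", key)
  chain_atoms <- CHI_CHAIN[[at$resid[1]]]
  if (is.null(chain_atoms)) return(NULL)
  idx <- match(chain_atoms, at$elety)
  if (anyNA(idx)) return(NULL)
  xyz <- as.matrix(at[idx, c("x", "y", "z")])
  nchi <- length(chain_atoms) - 3L
  ang <- vapply(seq_len(nchi), function(k)
    torsion(xyz[k, ], xyz[k + 1L, ], xyz[k + 2L, ], xyz[k + 3L, ]), 0)
  ang[nchi] <- fold_symmetric(ang[nchi], at$resid[1], nchi)
  ang
}

#' Chi-angle table for all residues of a structure
#'
#' @param s a `protein_structure`.
#' @return data.frame with `res_key`, `res_type`, `chi1`..`chi4`
#'   (NA-padded), `n_chi` and `complete` (FALSE when atoms were missing
#'   or the type bears no chi angle).
#' @export
chi_angles <- function(s) {
  keys <- residue_keys(s)
  first <- !duplicated(res_key(s$atoms$chain, s$atoms$resno, s$atoms$insert))
  types <- s$atoms$resid[first]
  chim <- matrix(NA_real_, length(keys), 4,
                 dimnames = list(NULL, paste0("chi", 1:4)))
  complete <- logical(length(keys))
  for (i in seq_along(keys)) {
    v <- residue_chi_vector(s, keys[i])
    if (!is.null(v)) {
      chim[i, seq_along(v)] <- v
      complete[i] <- TRUE
    }
  }
  data.frame(res_key = keys, res_type = types, chim,
             n_chi = chi_count(types), complete = complete,
             stringsAsFactors = FALSE)
}
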