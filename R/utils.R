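# Shared angle helpers and residue tables.

# Three-letter codes of the 20 standard amino acids.
AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
         "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

AA321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Wrap angles into the half-open interval [-180, 180)
#'
#' @param a numeric vector of angles in degrees.
#' @return angles reduced modulo 360 into `[-180, 180)`.
#' @export
wrap180 <- function(a) ((a + 180) %% 360) - 180

#' Fold angles into [0, 180)
#'
#' Used for the last chi angle of Phe, Tyr, Asp and Glu, whose terminal
#' groups are two-fold symmetric so that chi and chi + 180 describe the
#' same conformation.
#'
#' @param a numeric vector of angles in degrees.
#' @return angles reduced modulo 180 into `[0, 180)`.
#' @export
wrap_fold <- function(a) a %% 180

# residue key: unambiguous residue identifier within a structure
res_key <- function(chain, resno, insert) {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste(chain, resno, insert, sep = ":")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
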