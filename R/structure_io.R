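# Minimal structure model on top of bio3d's PDB reader.
#
# A `protein_structure` is a list with an `id` and a flat `atoms`
# data.frame (one row per heavy atom) carrying chain, resno, insert,
# resid (3-letter), elety (atom name), elesy (element), x/y/z, o
# (occupancy) and a `standard` flag for the 20 canonical amino acids.

#' Read a PDB file into a minimal structure model
#'
#' Parses fixed-column ATOM records (first model only; HETATM, waters and
#' hydrogens are dropped). For alternate locations the highest-occupancy
#' conformer is kept, ties resolved by file order. Non-standard amino
#' acids are retained in the model but flagged, so that downstream
#' dihedral pooling and surface classification can exclude them.
#'
#' @param file path to a PDB-format file.
#' @param chains optional character vector of chain identifiers to keep.
#'   Requesting a chain absent from the file is an error.
#' @param id structure label; defaults to the file name.
#' @return an object of class `protein_structure`.
#' @export
read_structure <- function(file, chains = NULL, id = NULL) {
  if (!file.exists(file)) stopf("PDB file not found: %s", file)
  pdb <- bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stopf("no ATOM records in %s", file)

  # element symbol: prefer the element column, fall back to the atom name
  elesy <- trimws(as.character(at$elesy))
  guess <- sub("^[0-9]*", "", trimws(at$elety))
  elesy[is.na(elesy) | elesy == ""] <- substr(guess[is.na(elesy) | elesy == ""], 1, 1)
  at$elesy <- toupper(elesy)
  at <- at[!(at$elesy %in% c("H", "D")), , drop = FALSE]

  at$chain <- as.character(at$chain)
  at$chain[is.na(at$chain)] <- " "
  if (!is.null(chains)) {
    missing <- setdiff(chains, unique(at$chain))
    if (length(missing) > 0L)
      stopf("chain(s) not found in %s: %s", file, paste(missing, collapse = ", "))
    at <- at[at$chain %in% chains, , drop = FALSE]
  }
  if (nrow(at) == 0L) stopf("empty atom selection from %s", file)

  at$insert <- ifelse(is.na(at$insert), "", as.character(at$insert))
  at$o <- ifelse(is.na(at$o), 1, at$o)
  at$elety <- trimws(at$elety)

  # altloc: keep the highest-occupancy conformer per atom, ties by file order
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(factor(key, levels = unique(key)), -at$o,
               seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")),
           , drop = FALSE]
  # restore file order
  at <- at[order(as.numeric(rownames(at))), , drop = FALSE]

  atoms <- data.frame(
    chain = at$chain, resno = at$resno, insert = at$insert,
    resid = at$resid, elety = at$elety, elesy = at$elesy,
    x = at$x, y = at$y, z = at$z, o = at$o,
    stringsAsFactors = FALSE
  )
  atoms$standard <- atoms$resid %in% AA3
  new_structure(atoms, id = id %||% basename(file))
}

new_structure <- function(atoms, id = "structure") {
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  rk <- residue_keys(x)
  cat(sprintf("<protein_structure '%s': %d chains, %d residues, %d atoms>\n",
              x$id, length(unique(x$atoms$chain)), length(rk),
              nrow(x$atoms)))
  invisible(x)
}

#' Residue keys of a structure
#'
#' @param s a `protein_structure`.
#' @return character vector `chain:resno:insert`, in file order.
#' @export
residue_keys <- function(s) {
  unique(res_key(s$atoms$chain, s$atoms$resno, s$atoms$insert))
}

#' Extract a monomer (chain subset) from a complex
#'
#' Returns a new structure containing exactly the requested chains with
#' coordinates unchanged — the isolated-monomer geometry needed to measure
#' SASA loss upon binding.
#'
#' @param s a `protein_structure`.
#' @param chains non-empty character vector of chain ids, all present in `s`.
#' @return a `protein_structure` restricted to `chains`.
#' @export
extract_monomer <- function(s, chains) {
  if (length(chains) == 0L) stopf("empty chain set")
  missing <- setdiff(chains, unique(s$atoms$chain))
  if (length(missing) > 0L)
    stopf("chain(s) not in structure '%s': %s", s$id,
          paste(missing, collapse = ", "))
  new_structure(s$atoms[s$atoms$chain %in% chains, , drop = FALSE],
                id = paste0(s$id, ":", paste(chains, collapse = "")))
}

#' One-letter sequence of a chain with a positional index map
#'
#' Non-standard residue types are emitted as `"X"`.
#'
#' @param s a `protein_structure`.
#' @param chain a single chain id present in `s`.
#' @return list with `seq` (one-letter string) and `map`, a data.frame
#'   linking string position to chain, resno, insert, resid and res_key.
#' @export
residue_sequence <- function(s, chain) {
  if (!chain %in% unique(s$atoms$chain))
    stopf("chain '%s' not in structure '%s'", chain, s$id)
  at <- s$atoms[s$atoms$chain == chain, , drop = FALSE]
  keys <- res_key(at$chain, at$resno, at$insert)
  first <- !duplicated(keys)
  map <- data.frame(
    pos = seq_len(sum(first)),
    chain = at$chain[first], resno = at$resno[first],
    insert = at$insert[first], resid = at$resid[first],
    res_key = keys[first], stringsAsFactors = FALSE
  )
  letters1 <- unname(AA321[map$resid])
  letters1[is.na(letters1)] <- "X"
  list(seq = paste(letters1, collapse = ""), map = map)
}

# atoms of one residue, by key
residue_atoms <- function(s, key) {
  keys <- res_key(s$atoms$chain, s$atoms$resno, s$atoms$insert)
  s$atoms[keys == key, , drop = FALSE]
}

#' Write a structure to a PDB-format file
#'
#' Thin wrapper around [bio3d::write.pdb()] used for toy fixtures and
#' intermediate outputs.
#'
#' @param s a `protein_structure`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(s, file) {
  at <- s$atoms
  bio3d::write.pdb(
    file = file,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$resno, chain = at$chain, resid = at$resid,
    elety = at$elety, insert = ifelse(at$insert == "", NA, at$insert),
    o = at$o, b = rep(0, nrow(at)), elesy = at$elesy,
    eleno = seq_len(nrow(at))
  )
  invisible(file)
}
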