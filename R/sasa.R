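# Solvent-accessible surface area (Shrake-Rupley) and surface/interface
# classification.
#
# Per-atom SASA is estimated by counting accessible test points on each
# atom's probe-expanded sphere, using a deterministic golden-spiral point
# set. Radii follow the Chothia-style heavy-atom table shipped in
# extdata/atom_radii.tsv (N 1.65, O 1.40, S 1.85, sp3 C 1.87, sp2 C 1.76).
# Relative SASA divides residue SASA by a per-type reference maximum
# (extdata/max_sasa.tsv, theoretical maximum accessible areas).

.chigrid_cache <- new.env(parent = emptyenv())

load_table <- function(name) {
  if (is.null(.chigrid_cache[[name]])) {
    path <- system.file("extdata", name, package = "chigrid")
    if (path == "") path <- file.path("inst", "extdata", name)
    .chigrid_cache[[name]] <- utils::read.table(path, header = TRUE,
                                                sep = "\t",
                                                stringsAsFactors = FALSE)
  }
  .chigrid_cache[[name]]
}

# element fallbacks for atoms outside the table
ELEMENT_RADII <- c(C = 1.80, N = 1.65, O = 1.40, S = 1.85, P = 1.90)
DEFAULT_RADIUS <- 1.80

#' Van der Waals radius of a heavy atom
#'
#' Looks up the shipped per-residue radius table; atoms absent from the
#' table fall back to an element default with a warning.
#'
#' @param elety atom name (e.g. `"CA"`, `"OG"`).
#' @param res_type 3-letter residue code.
#' @param elesy element symbol, used for the fallback.
#' @return radius in Angstrom.
#' @export
atom_radius <- function(elety, res_type, elesy = substr(elety, 1, 1)) {
  tab <- load_table("atom_radii.tsv")
  hit <- tab$radius[tab$res_type == res_type & tab$atom == elety]
  if (length(hit) == 1L) return(hit)
  r <- ELEMENT_RADII[toupper(elesy)]
  if (is.na(r)) r <- DEFAULT_RADIUS
  warnf("no tabulated radius for %s/%s; using element default %.2f",
        res_type, elety, r)
  unname(r)
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom, `n_points` test points are placed on the sphere of
#' radius `r_vdw + probe`; a point is buried if it lies inside any other
#' atom's expanded sphere. SASA is the accessible fraction times
#' `4*pi*(r+probe)^2`.
#'
#' @param s a `protein_structure`.
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param n_points number of test points per atom (default 960).
#' @param radii optional numeric vector of per-atom radii; defaults to
#'   [atom_radius()] lookups.
#' @return numeric vector of per-atom SASA (Angstrom^2), in atom order.
#' @export
sasa_atoms <- function(s, probe = 1.4, n_points = 960, radii = NULL) {
  at <- s$atoms
  n <- nrow(at)
  if (n < 1L) stopf("structure has no atoms")
  if (n_points < 1L) stopf("n_points must be >= 1")
  if (is.null(radii)) {
    radii <- vapply(seq_len(n), function(i)
      atom_radius(at$elety[i], at$resid[i], at$elesy[i]), 0)
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rexp <- radii + probe
  pts <- sphere_points(n_points)
  out <- numeric(n)
  # neighbor cutoff: two expanded spheres can interact only within r_i + r_j
  maxr <- max(rexp)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rexp[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (rexp[i] + rexp[nb])^2]
    if (length(nb) == 0L) {
      out[i] <- 4 * pi * rexp[i]^2
      next
    }
    p <- pts * rexp[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    cn <- xyz[nb, , drop = FALSE]
    # squared distances point x neighbor
    d2pn <- outer(rowSums(p^2), rep(1, length(nb))) +
      outer(rep(1, n_points), rowSums(cn^2)) - 2 * tcrossprod(p, cn)
    buried <- rowSums(sweep(d2pn, 2, rexp[nb]^2, "<")) > 0
    out[i] <- mean(!buried) * 4 * pi * rexp[i]^2
  }
  out
}

#' Aggregate per-atom SASA to residues
#'
#' @param s a `protein_structure`.
#' @param atom_sasa per-atom SASA from [sasa_atoms()].
#' @return data.frame with `res_key`, `res_type`, `abs_sasa`.
#' @export
sasa_residues <- function(s, atom_sasa) {
  keys <- res_key(s$atoms$chain, s$atoms$resno, s$atoms$insert)
  agg <- rowsum(atom_sasa, factor(keys, levels = unique(keys)))
  first <- !duplicated(keys)
  data.frame(res_key = keys[first], res_type = s$atoms$resid[first],
             abs_sasa = as.numeric(agg), stringsAsFactors = FALSE)
}

#' Relative solvent accessibility
#'
#' Absolute residue SASA divided by the per-type reference maximum. The
#' value can exceed 1 for extended conformations.
#'
#' @param abs_sasa numeric vector of absolute SASA (Angstrom^2).
#' @param res_type 3-letter codes, recycled against `abs_sasa`.
#' @return numeric vector of fractions.
#' @export
relative_sasa <- function(abs_sasa, res_type) {
  tab <- load_table("max_sasa.tsv")
  ref <- tab$max_sasa[match(res_type, tab$res_type)]
  if (anyNA(ref))
    stopf("no reference max SASA for residue type(s): %s",
          paste(unique(res_type[is.na(ref)]), collapse = ", "))
  abs_sasa / ref
}

#' SASA lost upon binding
#'
#' `monomer - complex` per residue; tiny negative differences (quadrature
#' noise, tolerance 1e-6) are clamped to zero since occlusion can only
#' reduce SASA when coordinates are shared.
#'
#' @param monomer_abs,complex_abs absolute SASA of the same residues in
#'   the isolated monomer and within the complex.
#' @return numeric vector of SASA differences (Angstrom^2).
#' @export
delta_sasa <- function(monomer_abs, complex_abs) {
  d <- monomer_abs - complex_abs
  d[d < 0 & d > -1e-6] <- 0
  d
}

#' Classify a surface residue as interface or non-interface
#'
#' A residue is on the surface if its relative SASA is at least `rel_min`
#' in the bound state and, when an unbound counterpart exists, in the
#' unbound state as well; otherwise it is excluded. Among surface
#' residues, those losing more than `dsasa_min` Angstrom^2 of SASA upon
#' binding are interface, the rest non-interface surface.
#'
#' @param rel_bound relative SASA in the bound (isolated-monomer) state.
#' @param rel_unbound relative SASA in the unbound structure, or `NA`
#'   when no unbound counterpart exists.
#' @param dsasa SASA loss upon binding (Angstrom^2).
#' @param rel_min surface threshold on relative SASA (default 0.25).
#' @param dsasa_min interface threshold on SASA loss (default 1.0).
#' @return character vector over `{"interface", "non_interface_surface",
#'   "excluded"}`.
#' @export
classify_surface <- function(rel_bound, rel_unbound = NA, dsasa,
                             rel_min = 0.25, dsasa_min = 1.0) {
  n <- max(length(rel_bound), length(rel_unbound), length(dsasa))
  rel_bound <- rep_len(rel_bound, n)
  rel_unbound <- rep_len(rel_unbound, n)
  dsasa <- rep_len(dsasa, n)
  surface <- rel_bound >= rel_min &
    (is.na(rel_unbound) | rel_unbound >= rel_min)
  ifelse(!surface, "excluded",
         ifelse(dsasa > dsasa_min, "interface", "non_interface_surface"))
}
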