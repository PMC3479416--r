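# Shared fixtures and independent oracles, all built in code.

# ---- PDB text fixture ----------------------------------------------------

pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, alt = " ", elesy = substr(name, 1, 1),
                          record = "ATOM") {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resid, chain, resno, x, y, z,
          occ, 0, elesy)
}

write_pdb_fixture <- function(lines, file = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), file)
  file
}

# a 5-atom ALA residue as PDB text lines
ala_lines <- function(chain = "A", resno = 1, serial0 = 0, dx = 0) {
  nm <- c("N", "CA", "C", "O", "CB")
  xyz <- rbind(c(0, 0, 0), c(1.46, 0, 0), c(2.0, 1.4, 0),
               c(3.2, 1.5, 0), c(2.0, -0.8, 1.2))
  vapply(seq_along(nm), function(i)
    pdb_atom_line(serial0 + i, nm[i], "ALA", chain, resno,
                  xyz[i, 1] + dx, xyz[i, 2], xyz[i, 3]), "")
}

# ---- independent oracles -------------------------------------------------

# exhaustive global-alignment optimum by enumerating all alignments
# (recursion over (i, j); feasible for sequences of length <= 6)
brute_force_align_score <- function(a, b, match = 1, mismatch = -1,
                                    gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(av)) return(gap * (length(bv) - j + 1))
    if (j > length(bv)) return(gap * (length(av) - i + 1))
    max(rec(i + 1, j + 1) + (if (av[i] == bv[j]) match else mismatch),
        rec(i + 1, j) + gap,
        rec(i, j + 1) + gap)
  }
  rec(1, 1)
}

# nested-loop binning oracle: walks samples one by one and scans the
# per-dimension cell boundaries explicitly (no arithmetic shared with
# cell_index)
oracle_bin_counts <- function(samples, spacing, res_type, offsets) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  dims <- ncol(samples)
  folded <- res_type %in% c("PHE", "TYR", "ASP", "GLU")
  counts_dim <- integer(dims)
  bounds <- list()
  for (d in seq_len(dims)) {
    lo <- if (folded && d == dims) 0 else -180
    wd <- if (folded && d == dims) 180 else 360
    nb <- ceiling(wd / spacing)
    counts_dim[d] <- nb
    # cell k (0-based) covers [lo + off + k*sp, lo + off + (k+1)*sp) on
    # the circle of width wd
    bounds[[d]] <- lapply(seq_len(nb) - 1, function(k) {
      c(lo + offsets[d] + k * spacing,
        min(lo + offsets[d] + (k + 1) * spacing, lo + wd + offsets[d]))
    })
  }
  m <- prod(counts_dim)
  counts <- integer(m)
  for (s in seq_len(nrow(samples))) {
    flat <- 0
    for (d in seq_len(dims)) {
      lo <- if (folded && d == dims) 0 else -180
      wd <- if (folded && d == dims) 180 else 360
      a <- samples[s, d]
      hit <- NA
      for (k in seq_len(counts_dim[d]) - 1) {
        b <- bounds[[d]][[k + 1]]
        # membership on the circle: unwrap the sample into the window
        for (shift in c(-wd, 0, wd)) {
          if (a + shift >= b[1] && a + shift < b[2]) { hit <- k; break }
        }
        if (!is.na(hit)) break
      }
      stopifnot(!is.na(hit))
      flat <- flat * counts_dim[d] + hit
    }
    counts[flat + 1] <- counts[flat + 1] + 1
  }
  counts
}

# vector-algebra torsion oracle: angle between the two bond-plane
# normals, signed by the central bond direction
oracle_torsion <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(p2 - p1, p3 - p2)
  n2 <- cr(p3 - p2, p4 - p3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (sum(cr(n1, n2) * (p3 - p2)) < 0) ang <- -ang
  ((ang + 180) %% 360) - 180
}

# random 3-D rigid rotation matrix
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

transform_structure <- function(s, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s$atoms$x <- xyz[, 1] + t[1]
  s$atoms$y <- xyz[, 2] + t[2]
  s$atoms$z <- xyz[, 3] + t[3]
  s
}

# all chi-bearing residue types
CHI_TYPES <- c("SER", "THR", "CYS", "VAL", "PRO", "ILE", "LEU", "ASN",
               "ASP", "HIS", "PHE", "TYR", "TRP", "MET", "GLU", "GLN",
               "LYS", "ARG")
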