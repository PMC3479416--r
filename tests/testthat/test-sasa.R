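test_that("atom radii come from the shipped table with element fallback", {
  expect_equal(atom_radius("N", "ALA"), 1.65)
  expect_equal(atom_radius("CA", "ALA"), 1.87)   # tetrahedral carbon
  expect_equal(atom_radius("C", "ALA"), 1.76)    # carbonyl carbon
  expect_equal(atom_radius("O", "SER"), 1.40)
  expect_equal(atom_radius("SG", "CYS"), 1.85)
  expect_equal(atom_radius("CZ", "PHE"), 1.76)   # aromatic carbon
  expect_warning(r <- atom_radius("XX", "ALA", elesy = "C"), "default")
  expect_equal(r, 1.80)
})

one_atom <- function(x = 0, y = 0, z = 0, elety = "CA", resid = "GLY",
                     chain = "A", resno = 1) {
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             elety = elety, elesy = substr(elety, 1, 1), x = x, y = y,
             z = z, o = 1, standard = TRUE, stringsAsFactors = FALSE)
}

test_that("an isolated atom matches the closed-form sphere area", {
  s <- chigrid:::new_structure(one_atom())
  expect_equal(sasa_atoms(s), 4 * pi * (1.87 + 1.4)^2, tolerance = 0.01)
  # two atoms far apart: no occlusion, areas add
  s2 <- chigrid:::new_structure(rbind(one_atom(), one_atom(x = 100, resno = 2)))
  expect_equal(sum(sasa_atoms(s2)), 2 * 4 * pi * (1.87 + 1.4)^2,
               tolerance = 1e-6)
  expect_error(sasa_atoms(s, n_points = 0), "n_points")
})

test_that("an atom enclosed by 12 close-packed neighbors is nearly buried", {
  # FCC coordination shell: 12 touching spheres at distance 2r
  r <- 1.87
  h <- sqrt(2) * r
  shell <- rbind(
    expand.grid(x = c(-h, h), y = c(-h, h), z = 0),
    expand.grid(x = c(-h, h), y = 0, z = c(-h, h)),
    expand.grid(x = 0, y = c(-h, h), z = c(-h, h))
  )
  atoms <- rbind(one_atom(),
                 do.call(rbind, lapply(seq_len(12), function(i)
                   one_atom(shell$x[i], shell$y[i], shell$z[i],
                            resno = i + 1))))
  s <- chigrid:::new_structure(atoms)
  impl <- sasa_atoms(s)[1]
  iso <- 4 * pi * (r + 1.4)^2
  expect_lt(impl, 0.05 * iso)
  # independent dense-point oracle for the central atom
  set.seed(1)
  u <- matrix(rnorm(3 * 20000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  p <- u * (r + 1.4)
  xyz <- as.matrix(atoms[-1, c("x", "y", "z")])
  buried <- rowSums(sapply(seq_len(12), function(j)
    rowSums(sweep(p, 2, xyz[j, ])^2) < (r + 1.4)^2)) > 0
  oracle <- mean(!buried) * iso
  expect_lt(abs(impl - oracle), 0.02 * iso)
})

test_that("total SASA is invariant under rigid motion", {
  # many packed residues in varied orientations: per-atom quadrature
  # errors decorrelate, so the total's noise shrinks with atom count
  set.seed(3)
  types <- rep(CHI_TYPES, 2)
  parts <- lapply(seq_along(types), function(i) {
    r <- build_toy_residue(types[i], runif(chi_count(types[i]), -170, 170),
                           resno = i)
    r <- transform_structure(r, random_rotation(),
                             c(5 * (i %% 6), 5 * (i %/% 6), 0) + rnorm(3))
    r$atoms
  })
  s <- chigrid:::new_structure(do.call(rbind, parts))
  tot <- sum(sasa_atoms(s))
  for (k in 1:3) {
    s2 <- transform_structure(s, random_rotation(), rnorm(3, 0, 10))
    expect_equal(sum(sasa_atoms(s2)), tot, tolerance = 0.005)
  }
})

test_that("residue SASA aggregates atoms and conserves the total", {
  s <- build_toy_complex("SER", "VAL")
  atom_sasa <- sasa_atoms(s)
  res <- sasa_residues(s, atom_sasa)
  expect_equal(nrow(res), 2L)
  expect_equal(sum(res$abs_sasa), sum(atom_sasa))
  # hand aggregation
  keys <- with(s$atoms, chigrid:::res_key(chain, resno, insert))
  expect_equal(res$abs_sasa[1], sum(atom_sasa[keys == res$res_key[1]]))
})

test_that("relative SASA divides by the per-type reference maximum", {
  expect_equal(relative_sasa(155.0, "SER"), 1.0)
  expect_equal(relative_sasa(0, "TRP"), 0)
  expect_equal(relative_sasa(274.0 / 2, "ARG"), 0.5)
  expect_error(relative_sasa(10, "XYZ"), "reference")
})

test_that("delta SASA subtracts and clamps quadrature noise", {
  expect_equal(delta_sasa(50, 30), 20)
  expect_equal(delta_sasa(50, 50), 0)
  expect_equal(delta_sasa(50, 50.0000001), 0)
})

test_that("every residue of a toy complex loses non-negative SASA", {
  cplx <- build_toy_complex("LYS", "ARG")
  for (ch in c("A", "B")) {
    mono <- extract_monomer(cplx, ch)
    sm <- sasa_residues(mono, sasa_atoms(mono))
    sc <- sasa_residues(cplx, sasa_atoms(cplx))
    sc <- sc[match(sm$res_key, sc$res_key), ]
    d <- delta_sasa(sm$abs_sasa, sc$abs_sasa)
    expect_true(all(d >= 0))
  }
  # and the chains actually touch: some SASA is lost
  monoA <- extract_monomer(cplx, "A")
  expect_gt(sum(sasa_residues(monoA, sasa_atoms(monoA))$abs_sasa),
            sum(sasa_residues(cplx, sasa_atoms(cplx))$abs_sasa[1]))
})

test_that("surface classification partitions residues by the two thresholds", {
  expect_equal(classify_surface(0.30, 0.30, 5.0), "interface")
  expect_equal(classify_surface(0.30, 0.30, 0.5), "non_interface_surface")
  expect_equal(classify_surface(0.20, 0.30, 5.0), "excluded")
  # no unbound counterpart: bound-only criteria
  expect_equal(classify_surface(0.30, NA, 5.0), "interface")
  expect_equal(classify_surface(0.30, 0.10, 5.0), "excluded")
  # exactly one label each
  set.seed(5)
  cls <- classify_surface(runif(200), runif(200), runif(200, 0, 3))
  expect_true(all(cls %in% c("interface", "non_interface_surface",
                             "excluded")))
})
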