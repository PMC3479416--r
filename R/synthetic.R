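# Synthetic chi-angle pools and toy coordinate fixtures.
#
# Real side-chain angles cluster in rotamers roughly 120 degrees apart,
# with tight intra-rotamer jitter and rare rotamer-to-rotamer flips
# between the bound and unbound states. The generator reproduces exactly
# that structure — a three-component wrapped-normal mixture per chi —
# so pipeline behavior can be studied without any structure download.

#' Rotamer mixture specification
#'
#' Three rotamer centers per chi dimension, 120 degrees apart (default
#' -60/60/180 on full dimensions; 30/90/150 on the folded terminal
#' dimension of Phe/Tyr/Asp/Glu, which lives on a 180-degree circle),
#' unequal mixture weights on the simplex (real rotamer populations are
#' skewed, default 0.5/0.3/0.2), and a wrapped-normal intra-rotamer
#' jitter `sigma` in degrees.
#'
#' @param res_type 3-letter code of a chi-bearing type.
#' @param weights length-3 mixture weights (normalized internally).
#' @param sigma intra-rotamer standard deviation in degrees.
#' @param centers optional dims x 3 matrix of rotamer centers.
#' @return object of class `rotamer_mixture`.
#' @export
rotamer_mixture <- function(res_type, weights = c(0.5, 0.3, 0.2),
                            sigma = 10, centers = NULL) {
  dims <- chi_count(res_type)
  if (dims < 1L) stopf("residue type '%s' has no chi angles", res_type)
  if (length(weights) != 3L || any(weights < 0) || sum(weights) <= 0)
    stopf("weights must be 3 non-negative numbers")
  weights <- weights / sum(weights)
  if (is.null(centers)) {
    centers <- matrix(rep(c(-60, 60, 180), each = dims), dims, 3)
    if (res_type %in% FOLD_LAST) centers[dims, ] <- c(30, 90, 150)
  }
  folded <- logical(dims)
  if (res_type %in% FOLD_LAST) folded[dims] <- TRUE
  structure(list(res_type = res_type, dims = dims, centers = centers,
                 weights = weights, sigma = sigma, folded = folded),
            class = "rotamer_mixture")
}

wrap_dim <- function(a, folded) if (folded) wrap_fold(a) else wrap180(a)

#' Sample a chi-angle pool from a rotamer mixture
#'
#' Per sample and per chi: draw a rotamer by the mixture weights, then
#' an angle from a wrapped normal around its center, reduced into the
#' dimension's range.
#'
#' @param spec a `rotamer_mixture`.
#' @param n number of samples.
#' @param seed optional integer seed.
#' @return numeric matrix (n x dims) of class `chi_pool`, with the
#'   drawn rotamer indices in attribute `rotamers` and the generating
#'   `spec` attached.
#' @export
sample_pool <- function(spec, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 1L) stopf("n must be positive")
  ang <- matrix(NA_real_, n, spec$dims)
  rot <- matrix(NA_integer_, n, spec$dims)
  for (d in seq_len(spec$dims)) {
    rot[, d] <- sample.int(3L, n, replace = TRUE, prob = spec$weights)
    raw <- spec$centers[d, rot[, d]] + stats::rnorm(n, 0, spec$sigma)
    ang[, d] <- wrap_dim(raw, spec$folded[d])
  }
  structure(ang, rotamers = rot, spec = spec, class = c("chi_pool", "matrix"))
}

#' Perturb a pool into its paired ("bound" vs "unbound") counterpart
#'
#' Per sample and per chi: with probability `flip_prob` the rotamer is
#' re-drawn uniformly among the other two and the angle resampled around
#' the new center; wrapped-normal jitter of `jitter_sd` degrees is then
#' always added. This emulates the rare inter-rotamer transitions and
#' the ubiquitous local readjustments seen between bound and unbound
#' side chains.
#'
#' @param pool a `chi_pool` from [sample_pool()].
#' @param flip_prob probability of a rotamer flip, in `[0, 1]`.
#' @param jitter_sd wrapped-normal jitter in degrees.
#' @param seed optional integer seed.
#' @return a `chi_pool` of the same dimensions.
#' @export
perturb_paired <- function(pool, flip_prob, jitter_sd, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (flip_prob < 0 || flip_prob > 1) stopf("flip_prob must be in [0, 1]")
  spec <- attr(pool, "spec")
  rot <- attr(pool, "rotamers")
  n <- nrow(pool)
  ang <- unclass(pool)
  attr(ang, "rotamers") <- NULL; attr(ang, "spec") <- NULL
  for (d in seq_len(spec$dims)) {
    flip <- stats::runif(n) < flip_prob
    if (any(flip)) {
      new_rot <- vapply(rot[flip, d], function(k)
        sample(setdiff(1:3, k), 1L), 0L)
      rot[flip, d] <- new_rot
      ang[flip, d] <- spec$centers[d, new_rot] +
        stats::rnorm(sum(flip), 0, spec$sigma)
    }
    if (jitter_sd > 0)
      ang[, d] <- ang[, d] + stats::rnorm(n, 0, jitter_sd)
    ang[, d] <- wrap_dim(ang[, d], spec$folded[d])
  }
  structure(ang, rotamers = rot, spec = spec, class = c("chi_pool", "matrix"))
}

# internal-coordinate (NeRF) placement: atom d from a-b-c with bond
# length r, bond angle theta at c, and torsion phi about b-c
place_atom <- function(a, b, c, r, theta, phi) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  th <- theta * pi / 180; ph <- phi * pi / 180
  d <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# generic ideal-geometry values for toy construction (Angstrom, degrees)
TOY_GEOM <- list(n_ca = 1.458, ca_cb = 1.530, side = 1.520,
                 ca_c = 1.525, c_o = 1.231,
                 angle_backbone = 111.0, angle_side = 111.0,
                 angle_o = 120.5)

#' Build a single toy residue with prescribed chi angles
#'
#' Places N, CA, C, O and the chi-chain side-chain atoms by sequential
#' internal-coordinate construction with generic ideal bond lengths and
#' angles, setting each chi torsion to the requested target. The
#' resulting structure round-trips through [residue_chi_vector()] to the
#' prescribed values (folded where applicable).
#'
#' @param res_type 3-letter code of a chi-bearing type.
#' @param chi_targets numeric vector of target chi angles (degrees),
#'   length equal to the chi count of `res_type`.
#' @param chain chain id (default "A").
#' @param resno residue number (default 1).
#' @return a single-residue `protein_structure`.
#' @export
build_toy_residue <- function(res_type, chi_targets, chain = "A",
                              resno = 1) {
  chain_atoms <- CHI_CHAIN[[res_type]]
  if (is.null(chain_atoms))
    stopf("unsupported residue type '%s' (no chi angles)", res_type)
  nchi <- length(chain_atoms) - 3L
  if (length(chi_targets) != nchi)
    stopf("%s requires %d chi targets, got %d", res_type, nchi,
          length(chi_targets))
  g <- TOY_GEOM
  pos <- matrix(NA_real_, length(chain_atoms), 3)
  pos[1, ] <- c(0, 0, 0)                       # N
  pos[2, ] <- c(g$n_ca, 0, 0)                  # CA
  th <- 110.5 * pi / 180
  pos[3, ] <- pos[2, ] + g$ca_cb * c(-cos(th), sin(th), 0)  # CB
  for (k in seq_len(nchi)) {
    pos[k + 3L, ] <- place_atom(pos[k, ], pos[k + 1L, ], pos[k + 2L, ],
                                g$side, g$angle_side, chi_targets[k])
  }
  bb_c <- place_atom(pos[3, ], pos[1, ], pos[2, ], g$ca_c,
                     g$angle_backbone, -120)
  bb_o <- place_atom(pos[1, ], pos[2, ], bb_c, g$c_o, g$angle_o, 0)
  names_all <- c(chain_atoms[1:2], "C", "O", chain_atoms[-(1:2)])
  xyz <- rbind(pos[1:2, ], bb_c, bb_o, pos[-(1:2), , drop = FALSE])
  atoms <- data.frame(
    chain = chain, resno = resno, insert = "",
    resid = res_type, elety = names_all,
    elesy = substr(names_all, 1, 1),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1,
    standard = TRUE, stringsAsFactors = FALSE
  )
  new_structure(atoms, id = paste0("toy-", res_type))
}

#' Build a toy two-chain complex
#'
#' Two toy residues on chains A and B, with chain B translated along x
#' so the side chains pack against each other — a minimal complex whose
#' residues lose SASA upon binding.
#'
#' @param res_a,res_b residue types of the two chains.
#' @param chi_a,chi_b chi targets for each (defaults: all -60).
#' @param gap closest-approach distance between the chains in Angstrom.
#' @return a two-chain `protein_structure`.
#' @export
build_toy_complex <- function(res_a = "LYS", res_b = "ARG",
                              chi_a = NULL, chi_b = NULL, gap = 3.5) {
  chi_a <- chi_a %||% rep(-60, chi_count(res_a))
  chi_b <- chi_b %||% rep(-60, chi_count(res_b))
  a <- build_toy_residue(res_a, chi_a, chain = "A", resno = 1)
  b <- build_toy_residue(res_b, chi_b, chain = "B", resno = 1)
  xa <- as.matrix(a$atoms[, c("x", "y", "z")])
  xb <- as.matrix(b$atoms[, c("x", "y", "z")])
  mindist <- function(shift) {
    xb2 <- sweep(xb, 2, c(shift, 0, 0), "+")
    d2 <- outer(rowSums(xa^2), rep(1, nrow(xb2))) +
      outer(rep(1, nrow(xa)), rowSums(xb2^2)) - 2 * tcrossprod(xa, xb2)
    sqrt(max(min(d2), 0))
  }
  # distance grows monotonically once B sits entirely beyond A along x
  lo <- max(a$atoms$x) - min(b$atoms$x)
  shift <- stats::uniroot(function(s) mindist(s) - gap,
                          c(lo, lo + gap + 50), tol = 1e-9)$root
  b$atoms$x <- b$atoms$x + shift
  new_structure(rbind(a$atoms, b$atoms),
                id = paste0("toy-", res_a, "-", res_b))
}

#' Default configuration for the synthetic benchmark
#'
#' Interface pools get a substantially larger flip probability and
#' jitter than non-interface pools, mirroring the larger bound/unbound
#' conformational changes at real interfaces.
#'
#' @param res_types residue types to simulate.
#' @param n samples per pool.
#' @param sigma intra-rotamer jitter of the base mixtures (degrees).
#' @param weights rotamer mixture weights.
#' @param interface_flip,interface_jitter bound-to-unbound perturbation
#'   of interface pools.
#' @param non_interface_flip,non_interface_jitter same for non-interface
#'   pools.
#' @return a named list.
#' @export
synthetic_config <- function(res_types = c("SER", "ASP", "LYS"),
                             n = 2000, sigma = 10,
                             weights = c(0.5, 0.3, 0.2),
                             interface_flip = 0.2, interface_jitter = 20,
                             non_interface_flip = 0.02,
                             non_interface_jitter = 10) {
  list(res_types = res_types, n = n, sigma = sigma, weights = weights,
       interface_flip = interface_flip,
       interface_jitter = interface_jitter,
       non_interface_flip = non_interface_flip,
       non_interface_jitter = non_interface_jitter)
}

#' Generate a fully synthetic four-category benchmark
#'
#' For each residue type, draws an interface and a non-interface
#' "bound" pool from the rotamer mixture and perturbs each into its
#' "unbound" counterpart, yielding the four category pools the analysis
#' compares. Optionally writes the angle tables and a manifest to `dir`
#' in the pipeline's intermediate TSV format.
#'
#' @param config list from [synthetic_config()].
#' @param seed optional integer seed (fixes the whole benchmark).
#' @param dir optional output directory.
#' @return records data.frame (`res_key`, `res_type`, `class`, `state`,
#'   `chi1..chi4`, `n_chi`, `complete`) suitable for [run_analysis()].
#' @export
synthetic_benchmark <- function(config = synthetic_config(), seed = NULL,
                                dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config$n < 1L) stopf("config n must be positive")
  out <- list()
  for (rt in config$res_types) {
    spec <- rotamer_mixture(rt, weights = config$weights,
                            sigma = config$sigma)
    for (cls in c("interface", "non_interface_surface")) {
      flip <- if (cls == "interface") config$interface_flip
              else config$non_interface_flip
      jit <- if (cls == "interface") config$interface_jitter
             else config$non_interface_jitter
      bound <- sample_pool(spec, config$n)
      unbound <- perturb_paired(bound, flip, jit)
      for (st in c("bound", "unbound")) {
        pool <- if (st == "bound") bound else unbound
        chim <- matrix(NA_real_, config$n, 4,
                       dimnames = list(NULL, paste0("chi", 1:4)))
        chim[, seq_len(spec$dims)] <- unclass(pool)[, , drop = FALSE]
        out[[length(out) + 1L]] <- data.frame(
          res_key = sprintf("%s:%s:%s:%d", rt, cls, st,
                            seq_len(config$n)),
          res_type = rt, class = cls, state = st, chim,
          n_chi = spec$dims, complete = TRUE, stringsAsFactors = FALSE
        )
      }
    }
  }
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_angle_table(records[records$state == "bound", ],
                      file.path(dir, "angles_bound.tsv"))
    write_angle_table(records[records$state == "unbound", ],
                      file.path(dir, "angles_unbound.tsv"))
    manifest <- data.frame(
      res_type = config$res_types, n = config$n, sigma = config$sigma,
      interface_flip = config$interface_flip,
      interface_jitter = config$interface_jitter,
      non_interface_flip = config$non_interface_flip,
      non_interface_jitter = config$non_interface_jitter
    )
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  records
}
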