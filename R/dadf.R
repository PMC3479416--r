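# n-dimensional dihedral-angle distribution functions (DADFs) on cubic
# grids with arbitrary split origins.
#
# Each chi dimension is a circle: full dimensions span [-180, 180)
# (period 360) and folded terminal dimensions span [0, 180) (period 180,
# genuine two-fold symmetry). An offset grid therefore wraps at the
# range boundary rather than truncating, so every sample falls in
# exactly one cell for any origin. When the spacing does not divide the
# range width the final (wrap) cell is narrower, per the ceiling rule.

#' Grid specification for a residue type
#'
#' @param spacing cell side length in degrees, in (0, 360].
#' @param res_type 3-letter code of a chi-bearing residue type; the
#'   number of dimensions and the per-dimension ranges (full vs folded
#'   last dimension) follow from the type.
#' @param offsets per-dimension split origin in `[0, spacing)`; recycled
#'   if length 1. Default 0.
#' @return object of class `grid_spec`: list with `spacing`, `dims`,
#'   `start`, `width`, `counts`, `offsets`, `m` (total cell count) and
#'   `res_type`.
#' @export
make_grid <- function(spacing, res_type, offsets = 0) {
  if (!is.finite(spacing) || spacing <= 0 || spacing > 360)
    stopf("spacing must be in (0, 360], got %s", format(spacing))
  dims <- chi_count(res_type)
  if (dims < 1L) stopf("residue type '%s' has no chi angles", res_type)
  folded <- res_type %in% FOLD_LAST
  width <- rep(360, dims)
  start <- rep(-180, dims)
  if (folded) {
    width[dims] <- 180
    start[dims] <- 0
  }
  offsets <- rep_len(offsets, dims)
  if (any(offsets < 0 | offsets >= spacing))
    stopf("offsets must lie in [0, spacing)")
  counts <- as.integer(ceiling(width / spacing))
  structure(list(spacing = spacing, dims = dims, start = start,
                 width = width, counts = counts, offsets = offsets,
                 m = prod(counts), res_type = res_type),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec %s: %d-D, spacing %g deg, counts (%s), m = %d>\n",
              x$res_type, x$dims, x$spacing,
              paste(x$counts, collapse = ", "), x$m))
  invisible(x)
}

#' Random split origins
#'
#' One uniform draw on `[0, spacing)` per dimension, from R's current
#' RNG stream (seed with [set.seed()] for reproducibility).
#'
#' @param spacing grid spacing in degrees.
#' @param dims number of dimensions.
#' @return numeric vector of offsets.
#' @export
random_offsets <- function(spacing, dims) {
  stats::runif(dims, 0, spacing)
}

#' Cell index of chi-angle vectors on a grid
#'
#' Per-dimension index `floor(((angle - start - offset) mod width) /
#' spacing)`, capped at `count - 1` (the cap only engages in the
#' narrower wrap cell of non-divisor spacings); row-major flattening
#' with chi1 as the slowest axis.
#'
#' @param angles numeric matrix (samples x dims) or vector (1-D grids or
#'   a single sample).
#' @param g a `grid_spec`.
#' @return integer vector of 0-based flat cell indices in `[0, m)`.
#' @export
cell_index <- function(angles, g) {
  if (is.null(dim(angles))) {
    angles <- if (g$dims == 1L) matrix(angles, ncol = 1L)
              else matrix(angles, nrow = 1L)
  }
  if (ncol(angles) != g$dims)
    stopf("angle dimensionality %d does not match grid dims %d",
          ncol(angles), g$dims)
  flat <- integer(nrow(angles))
  for (d in seq_len(g$dims)) {
    a <- (angles[, d] - g$start[d] - g$offsets[d]) %% g$width[d]
    idx <- pmin(floor(a / g$spacing), g$counts[d] - 1L)
    flat <- flat * g$counts[d] + as.integer(idx)
  }
  flat
}

#' Build a DADF from a sample pool
#'
#' Cell probabilities are occupancies `count / n`; empty cells are
#' retained with probability 0 (the comparison sums run over all m
#' cells).
#'
#' @param samples chi-angle matrix (samples x dims) or vector for 1-D
#'   types; all rows must be complete.
#' @param g a `grid_spec`.
#' @return object of class `dadf`: list with `grid`, `probs` (length m)
#'   and `n_samples`.
#' @export
build_dadf <- function(samples, g) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = g$dims)
  if (nrow(samples) == 0L) stopf("cannot build a DADF from 0 samples")
  if (anyNA(samples)) stopf("samples contain NA angles")
  idx <- cell_index(samples, g)
  counts <- tabulate(idx + 1L, nbins = g$m)
  structure(list(grid = g, probs = counts / nrow(samples),
                 n_samples = nrow(samples)),
            class = "dadf")
}

#' @export
print.dadf <- function(x, ...) {
  cat(sprintf("<dadf %s: m = %d cells, n = %d samples, %d occupied>\n",
              x$grid$res_type, x$grid$m, x$n_samples, sum(x$probs > 0)))
  invisible(x)
}

#' Export a DADF as a long table
#'
#' One row per cell with the per-dimension index, lower cell boundary
#' and probability, for inspection or plotting.
#'
#' @param x a `dadf`.
#' @return data.frame with index columns `i1..`, boundary columns
#'   `lo1..` and `prob`.
#' @export
dadf_table <- function(x) {
  g <- x$grid
  idx <- arrayInd(seq_len(g$m), rev(g$counts))[, rev(seq_len(g$dims)),
                                               drop = FALSE] - 1L
  out <- as.data.frame(idx)
  names(out) <- paste0("i", seq_len(g$dims))
  for (d in seq_len(g$dims)) {
    lo <- (g$start[d] + g$offsets[d] + idx[, d] * g$spacing)
    lo <- g$start[d] + (lo - g$start[d]) %% g$width[d]
    out[[paste0("lo", d)]] <- lo
  }
  out$prob <- x$probs
  out
}

same_grid <- function(a, b, tol = 1e-9) {
  a$dims == b$dims && a$m == b$m &&
    abs(a$spacing - b$spacing) < tol &&
    all(a$counts == b$counts) &&
    all(abs(a$offsets - b$offsets) < tol) &&
    all(a$start == b$start) && all(a$width == b$width)
}
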