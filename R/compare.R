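# DADF similarity: Pearson correlation over grid cells, Manhattan
# distance, the randomized-origin averaging protocol, significance and
# critical-spacing detection.

#' Pearson correlation between two DADFs
#'
#' `r = sum((X - mean(X)) * (Y - mean(Y))) / (sd_X * sd_Y)` over all m
#' cells, where `sd_X = sqrt(sum((X - mean(X))^2))` (empty cells
#' included; the cell means equal 1/m exactly since probabilities sum to
#' 1). Undefined when either DADF is uniform over the cells.
#'
#' @param x,y `dadf` objects on the same grid (identical m and offsets).
#' @param components if `TRUE`, return a list with the numerator
#'   (`covariance`), the per-DADF standard deviations `sd_x`/`sd_y`,
#'   their product (`denominator`) and `r`, instead of the bare value.
#' @return correlation in `[-1, 1]`, or `NA` when either variance is 0;
#'   with `components = TRUE`, a list.
#' @export
dadf_pearson <- function(x, y, components = FALSE) {
  if (!same_grid(x$grid, y$grid))
    stopf("DADFs are on different grids")
  dx <- x$probs - mean(x$probs)
  dy <- y$probs - mean(y$probs)
  num <- sum(dx * dy)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  r <- if (sx == 0 || sy == 0) NA_real_
       else if (identical(x$probs, y$probs)) 1  # self-correlation is exact
       else num / (sx * sy)
  if (components)
    list(covariance = num, sd_x = sx, sd_y = sy,
         denominator = sx * sy, r = r)
  else r
}

#' Correlation from its covariance/standard-deviation decomposition
#'
#' The correlation between two DADFs is the cell covariance
#' `sum((X - mean(X)) * (Y - mean(Y)))` divided by the product of the
#' cell standard deviations `sqrt(sum((X - mean(X))^2))` etc.; this
#' helper recombines a reported decomposition, e.g. to audit published
#' per-type numerator/denominator tables against their correlations.
#'
#' @param covariance the numerator.
#' @param sd_x,sd_y the two standard deviations.
#' @return `covariance / (sd_x * sd_y)`.
#' @export
correlation_from_components <- function(covariance, sd_x, sd_y) {
  covariance / (sd_x * sd_y)
}

#' Manhattan distance between two DADFs
#'
#' Half the L1 distance between the probability vectors: 0 for identical
#' distributions, 1 for disjoint supports.
#'
#' @param x,y `dadf` objects on the same grid.
#' @return distance in `[0, 1]`.
#' @export
dadf_manhattan <- function(x, y) {
  if (!same_grid(x$grid, y$grid))
    stopf("DADFs are on different grids")
  0.5 * sum(abs(x$probs - y$probs))
}

#' Two-tailed significance of a DADF correlation
#'
#' Treats the m grid cells as the observations of the correlation:
#' `t = r * sqrt((m - 2) / (1 - r^2))` on `m - 2` degrees of freedom.
#' `|r| >= 1` returns 0 (the limit); `m <= 2` is undefined.
#'
#' @param r correlation coefficient.
#' @param m number of grid cells.
#' @return two-tailed p-value, or `NA` when undefined.
#' @export
correlation_significance <- function(r, m) {
  if (is.na(r) || m <= 2) return(NA_real_)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((m - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = m - 2)
}

#' Offset-averaged comparison of two chi-angle pools
#'
#' Repeats `n_repeats` times: draw uniform random split origins, build
#' both DADFs on the shared grid, and evaluate the correlation and the
#' Manhattan distance. Reports the arithmetic means and standard
#' deviations over repeats; repeats with an undefined correlation
#' (a uniform DADF) are skipped for `r` and counted in `n_undefined`.
#' The p-value applies [correlation_significance()] to the mean
#' correlation.
#'
#' @param samples_x,samples_y chi-angle matrices (samples x dims) of the
#'   same residue type; vectors allowed for 1-D types.
#' @param res_type 3-letter code.
#' @param spacing grid spacing in degrees.
#' @param n_repeats number of random split origins (default 100).
#' @param seed optional integer seed applied before the repeat loop.
#' @return one-row data.frame with `res_type`, `spacing`, `mean_r`,
#'   `sd_r`, `mean_d`, `sd_d`, `p_value`, `m`, `n_x`, `n_y`,
#'   `n_repeats`, `n_undefined`.
#' @export
averaged_comparison <- function(samples_x, samples_y, res_type, spacing,
                                n_repeats = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- chi_count(res_type)
  if (dims < 1L) stopf("residue type '%s' has no chi angles", res_type)
  as_mat <- function(s) {
    if (is.null(dim(s))) s <- matrix(s, ncol = dims)
    if (nrow(s) == 0L) stopf("empty sample pool")
    s
  }
  samples_x <- as_mat(samples_x); samples_y <- as_mat(samples_y)
  rs <- numeric(n_repeats); ds <- numeric(n_repeats)
  m <- NA_integer_
  for (k in seq_len(n_repeats)) {
    g <- make_grid(spacing, res_type, random_offsets(spacing, dims))
    dx <- build_dadf(samples_x, g)
    dy <- build_dadf(samples_y, g)
    rs[k] <- dadf_pearson(dx, dy)
    ds[k] <- dadf_manhattan(dx, dy)
    m <- g$m
  }
  n_undef <- sum(is.na(rs))
  if (n_undef == n_repeats)
    stopf("correlation undefined in all %d repeats (uniform DADFs)",
          n_repeats)
  mean_r <- mean(rs, na.rm = TRUE)
  data.frame(
    res_type = res_type, spacing = spacing,
    mean_r = mean_r,
    sd_r = if (n_repeats - n_undef > 1L) stats::sd(rs[!is.na(rs)]) else NA_real_,
    mean_d = mean(ds), sd_d = if (n_repeats > 1L) stats::sd(ds) else NA_real_,
    p_value = correlation_significance(mean_r, m),
    m = m, n_x = nrow(samples_x), n_y = nrow(samples_y),
    n_repeats = n_repeats, n_undefined = n_undef,
    stringsAsFactors = FALSE
  )
}

#' Critical grid spacing
#'
#' The smallest scanned spacing at which the offset-averaged correlation
#' reaches `threshold` (default 0.7), or `NA` if it never does.
#'
#' @param spacings scanned spacings in degrees.
#' @param mean_r offset-averaged correlations, parallel to `spacings`.
#' @param threshold correlation level defining "high" similarity.
#' @return a single spacing, or `NA_real_`.
#' @export
critical_spacing <- function(spacings, mean_r, threshold = 0.7) {
  if (length(spacings) == 0L) stopf("empty spacing series")
  ord <- order(spacings)
  spacings <- spacings[ord]; mean_r <- mean_r[ord]
  hit <- which(!is.na(mean_r) & mean_r >= threshold)
  if (length(hit) == 0L) NA_real_ else spacings[hit[1L]]
}
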