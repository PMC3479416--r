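mkdadf <- function(probs, g) {
  structure(list(grid = g, probs = probs, n_samples = 100L),
            class = "dadf")
}

test_that("correlation is 1 for identical, -1 for anticorrelated,
           undefined for uniform DADFs", {
  g <- make_grid(90, "SER")
  x <- mkdadf(c(0.5, 0.3, 0.2, 0), g)
  expect_equal(dadf_pearson(x, x), 1)
  a <- mkdadf(c(0.5, 0.5, 0, 0), g)
  b <- mkdadf(c(0, 0, 0.5, 0.5), g)
  expect_equal(dadf_pearson(a, b), -1)
  u <- mkdadf(rep(0.25, 4), g)
  expect_true(is.na(dadf_pearson(a, u)))
  expect_error(dadf_pearson(a, mkdadf(rep(1 / 8, 8), make_grid(90, "ASP"))),
               "grids")
})

test_that("correlation matches cor() over the cells on random DADFs", {
  set.seed(31)
  g <- make_grid(20, "SER")
  for (k in 1:20) {
    p <- runif(g$m); p <- p / sum(p)
    q <- runif(g$m); q <- q / sum(q)
    x <- mkdadf(p, g); y <- mkdadf(q, g)
    expect_equal(dadf_pearson(x, y), cor(p, q), tolerance = 1e-12)
    # invariance under a common permutation of the cells
    perm <- sample(g$m)
    expect_equal(dadf_pearson(mkdadf(p[perm], g), mkdadf(q[perm], g)),
                 dadf_pearson(x, y), tolerance = 1e-12)
  }
})

test_that("pearson components expose the covariance/sd decomposition", {
  set.seed(32)
  g <- make_grid(30, "SER")
  p <- runif(g$m); p <- p / sum(p)
  q <- runif(g$m); q <- q / sum(q)
  cmp <- dadf_pearson(mkdadf(p, g), mkdadf(q, g), components = TRUE)
  expect_equal(cmp$covariance, sum((p - mean(p)) * (q - mean(q))))
  expect_equal(cmp$sd_x, sqrt(sum((p - mean(p))^2)))
  expect_equal(cmp$denominator, cmp$sd_x * cmp$sd_y)
  expect_equal(cmp$r, cmp$covariance / cmp$denominator)
})

test_that("Manhattan distance is 0 at identity, 1 at disjoint support,
           and a metric on random triples", {
  g <- make_grid(90, "SER")
  x <- mkdadf(c(0.5, 0.3, 0.2, 0), g)
  expect_identical(dadf_manhattan(x, x), 0)
  a <- mkdadf(c(0.5, 0.5, 0, 0), g)
  b <- mkdadf(c(0, 0, 0.5, 0.5), g)
  expect_equal(dadf_manhattan(a, b), 1)
  expect_equal(dadf_manhattan(mkdadf(c(0.5, 0.5, 0, 0), g),
                              mkdadf(c(0.5, 0, 0.5, 0), g)), 0.5)
  set.seed(33)
  for (k in 1:20) {
    ps <- replicate(3, { v <- runif(4); v / sum(v) }, simplify = FALSE)
    d <- function(i, j) dadf_manhattan(mkdadf(ps[[i]], g), mkdadf(ps[[j]], g))
    expect_equal(d(1, 2), d(2, 1))
    expect_lte(d(1, 3), d(1, 2) + d(2, 3) + 1e-12)
    expect_gte(d(1, 2), 0)
  }
})

test_that("correlation significance follows the t-distribution on m-2 df", {
  expect_equal(correlation_significance(0, 100), 1)
  # independent tail oracle: t = r*sqrt((m-2)/(1-r^2))
  r <- 0.5; m <- 100
  t <- r * sqrt((m - 2) / (1 - r^2))
  expect_equal(t, 5.715476, tolerance = 1e-6)
  p <- correlation_significance(r, m)
  expect_lt(p, 1e-6)
  expect_equal(p, 2 * pt(-t, m - 2))
  # p decreases monotonically as r -> 1
  ps <- sapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 0.99), correlation_significance,
               m = 20)
  expect_true(all(diff(ps) < 0))
  expect_true(is.na(correlation_significance(0.5, 2)))
})

test_that("identical pools give mean_r 1 and mean_d 0 at any spacing", {
  set.seed(34)
  pool <- sample_pool(rotamer_mixture("ASP"), 300)
  for (sp in c(10, 50, 90)) {
    res <- averaged_comparison(pool, pool, "ASP", sp, n_repeats = 10)
    expect_equal(res$mean_r, 1)
    expect_equal(res$mean_d, 0)
    expect_equal(res$sd_d, 0)
  }
})

test_that("averaged comparison is bit-reproducible under a fixed seed", {
  spec <- rotamer_mixture("SER")
  p <- sample_pool(spec, 400, seed = 35)
  q <- perturb_paired(p, 0.05, 10, seed = 36)
  r1 <- averaged_comparison(p, q, "SER", 30, n_repeats = 20, seed = 99)
  r2 <- averaged_comparison(p, q, "SER", 30, n_repeats = 20, seed = 99)
  expect_identical(r1, r2)
  expect_equal(r1$n_repeats, 20)
  expect_true(r1$mean_r > -1 && r1$mean_r <= 1)
  expect_true(r1$mean_d >= 0 && r1$mean_d <= 1)
})

test_that("undefined repeats are skipped and all-undefined errors", {
  # single sample: its DADF is a point mass, the partner's is too,
  # but on a 1-cell grid both are uniform -> undefined correlation
  expect_error(averaged_comparison(10, 20, "SER", 360, n_repeats = 3),
               "undefined")
})

test_that("critical spacing picks the first threshold crossing", {
  expect_equal(critical_spacing(c(10, 20, 30, 50), c(0.60, 0.68, 0.72, 0.80)),
               30)
  expect_equal(critical_spacing(10, 0.9), 10)
  expect_true(is.na(critical_spacing(c(10, 30), c(0.2, 0.5))))
  # order-insensitive input
  expect_equal(critical_spacing(c(50, 10, 30), c(0.8, 0.6, 0.75)), 30)
  expect_error(critical_spacing(numeric(0), numeric(0)), "empty")
})

test_that("mean correlation is non-decreasing in spacing on average", {
  # coarser grids smooth the distributions, raising the correlation;
  # assessed as a positive Spearman trend averaged over 20 generator seeds
  spacings <- c(10, 30, 50, 70, 90)
  trend <- sapply(1:20, function(sd_) {
    set.seed(sd_)
    p <- sample_pool(rotamer_mixture("SER"), 1000)
    q <- perturb_paired(p, 0.02, 10)
    mr <- sapply(spacings, function(s)
      averaged_comparison(p, q, "SER", s, n_repeats = 10)$mean_r)
    cor(spacings, mr, method = "spearman")
  })
  expect_gt(mean(trend), 0)
})

test_that("more rotamer flips increase the Manhattan distance", {
  # with skewed rotamer weights, flips push the paired distribution
  # toward uniformity, so mean_d at 30-degree spacing grows with
  # flip probability (averaged over seeds)
  d_at <- function(flip) {
    mean(sapply(1:6, function(sd_) {
      set.seed(sd_ * 3)
      p <- sample_pool(rotamer_mixture("SER"), 2000)
      q <- perturb_paired(p, flip, 10)
      averaged_comparison(p, q, "SER", 30, n_repeats = 15)$mean_d
    }))
  }
  d0 <- d_at(0); d1 <- d_at(0.1); d3 <- d_at(0.3)
  expect_lt(d0, d1)
  expect_lt(d1, d3)
})
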