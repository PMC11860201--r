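test_that("specs validate their parameter invariants and name the field", {
  expect_error(dist_spec("gamma", shape = 1), "unknown distribution family")
  expect_error(dist_spec("uniform", low = 2, high = 1), "low/high")
  expect_error(dist_spec("triangular", min = 0, mode = 5, max = 3), "mode")
  expect_error(dist_spec("truncated_normal", mean = 0, sd = -1), "sd")
  expect_error(dist_spec("minimum_extreme", mode = 1, scale = 0), "scale")
  expect_error(dist_spec("power_law", alpha = 1, x_min = 1, x_max = 10),
               "alpha")
  expect_error(dist_spec("power_law", alpha = 2, x_min = 10, x_max = 1),
               "x_max")
  expect_error(dist_spec("triangular", min = 0, max = 1), "missing parameter")
})

test_that("sampling is reproducible under a fixed seed", {
  specs <- list(
    dist_spec("uniform", low = 0, high = 2),
    dist_spec("triangular", min = 0, mode = 0, max = 79.23),
    dist_spec("truncated_normal", mean = 70, sd = 14, lower_bound = 0),
    dist_spec("minimum_extreme", mode = 0.29, scale = 0.08,
              lower_bound = 0, upper_bound = 1),
    dist_spec("power_law", alpha = 1.74, x_min = 20, x_max = 5000))
  for (s in specs) {
    expect_identical(dist_sample(s, 100, seed = 42),
                     dist_sample(s, 100, seed = 42))
    expect_false(identical(dist_sample(s, 100, seed = 1),
                           dist_sample(s, 100, seed = 2)))
  }
})

test_that("analytic moments of the scenario families are recovered", {
  n <- 2e5
  # triangular mean (a + c + b) / 3
  x <- dist_sample(dist_spec("triangular", min = 0, mode = 0, max = 79.23),
                   n, seed = 7)
  expect_equal(mean(x), 79.23 / 3, tolerance = 0.01)
  # degenerate support
  expect_equal(dist_sample(dist_spec("triangular", min = 1, mode = 1, max = 1),
                           10, seed = 1), rep(1, 10))
  # Gumbel-minimum mean = mode - gamma * scale
  euler_gamma <- 0.5772156649
  g <- dist_sample(dist_spec("minimum_extreme", mode = 0.29, scale = 0.08),
                   n, seed = 7)
  expect_equal(mean(g), 0.29 - euler_gamma * 0.08, tolerance = 0.005)
  # truncation five sd below the mean is negligible
  tn <- dist_sample(dist_spec("truncated_normal", mean = 70, sd = 14,
                              lower_bound = 0), n, seed = 7)
  expect_true(all(tn >= 0))
  expect_equal(mean(tn), 70, tolerance = 70 * 0.001)
})

test_that("empirical CDFs match analytic CDFs (KS < 0.01 at n = 1e5)", {
  n <- 1e5
  specs <- list(
    uniform = dist_spec("uniform", low = 1, high = 3),
    triangular = dist_spec("triangular", min = 0, mode = 0, max = 79.23),
    truncated_normal = dist_spec("truncated_normal", mean = 16.67, sd = 5.987,
                                 lower_bound = 0),
    minimum_extreme = dist_spec("minimum_extreme", mode = 0.29, scale = 0.08,
                                lower_bound = 0, upper_bound = 1),
    power_law = dist_spec("power_law", alpha = 1.74, x_min = 20,
                          x_max = 5000))
  for (nm in names(specs)) {
    s <- specs[[nm]]
    x <- dist_sample(s, n, seed = 11)
    ks <- suppressWarnings(
      stats::ks.test(x, function(q) dist_cdf(s, q)))
    expect_lt(ks$statistic, 0.01)
  }
})

test_that("truncated families never emit draws outside their bounds", {
  r <- dist_sample(dist_spec("minimum_extreme", mode = 0.29, scale = 0.08,
                             lower_bound = 0, upper_bound = 1),
                   5e4, seed = 3)
  expect_true(all(r > 0 & r <= 1))
  bw <- dist_sample(dist_spec("truncated_normal", mean = 16.67, sd = 5.987,
                              lower_bound = 0), 5e4, seed = 3)
  expect_true(all(bw >= 0))
  pl <- dist_sample(dist_spec("power_law", alpha = 1.74, x_min = 20,
                              x_max = 5000), 5e4, seed = 3)
  expect_true(all(pl >= 20 & pl <= 5000))
})

test_that("power-law quantile inverts the CDF and hits its bounds", {
  expect_equal(power_law_quantile(0, 1.74, 20, 5000), 20)
  expect_equal(power_law_quantile(1, 1.74, 20, 5000), 5000)
  expect_equal(power_law_quantile(0.5, 1.74, 20, 5000), 49.89359,
               tolerance = 1e-6)
  expect_error(power_law_quantile(1.2, 1.74, 20, 5000), "\\[0, 1\\]")
  u <- seq(0, 1, length.out = 201)
  x <- power_law_quantile(u, 1.74, 20, 5000)
  expect_true(all(diff(x) > 0))
  expect_equal(power_law_cdf(x, 1.74, 20, 5000), u, tolerance = 1e-9)
  # the median also agrees with numerical inversion of the integral of
  # b * x^-alpha (independent quadrature oracle)
  dens <- function(x) x^-1.74
  z <- stats::integrate(dens, 20, 5000)$value
  half <- stats::uniroot(function(m) {
    stats::integrate(dens, 20, m)$value / z - 0.5
  }, c(20, 5000), tol = 1e-10)$root
  expect_equal(power_law_quantile(0.5, 1.74, 20, 5000), half,
               tolerance = 1e-6)
})

test_that("power-law normalizer matches its closed form and unit integral", {
  expect_equal(power_law_normalizer(2, 1), 1)
  expect_equal(power_law_normalizer(2, 20), 20)
  expect_equal(power_law_normalizer(1.74, 20), 0.74 * 20^0.74)
  for (p in list(c(2, 20), c(1.74, 20))) {
    b <- power_law_normalizer(p[1], p[2])
    total <- stats::integrate(function(x) b * x^-p[1], p[2], Inf)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  expect_error(power_law_normalizer(1, 20), "alpha")
  expect_error(power_law_normalizer(0.99, 20), "alpha")
})

test_that("inverse-CDF power-law sampler agrees with a rejection oracle", {
  # oracle: rejection sampling under the density envelope at x_min
  rejection_powerlaw <- function(n, alpha, x_min, x_max, seed) {
    set.seed(seed)
    out <- numeric(0)
    dmax <- x_min^-alpha
    while (length(out) < n) {
      x <- stats::runif(n, x_min, x_max)
      keep <- stats::runif(n) < (x^-alpha) / dmax
      out <- c(out, x[keep])
    }
    out[seq_len(n)]
  }
  a <- rejection_powerlaw(1e4, 1.74, 20, 5000, seed = 5)
  b <- dist_sample(dist_spec("power_law", alpha = 1.74, x_min = 20,
                             x_max = 5000), 1e4, seed = 6)
  ks <- suppressWarnings(stats::ks.test(a, b))
  expect_gt(ks$p.value, 0.01)
})
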