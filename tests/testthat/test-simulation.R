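test_that("point-valued scenarios are deterministic and hand-checkable", {
  res <- run_simulation(point_scenario(), seed = 1)
  ecr_adult <- res$receptor_draws$ECR[res$receptor_draws$receptor == "adult"]
  # every iteration identical (up to the fixture's near-degenerate volume
  # support), so any percentile equals the value itself
  expect_lt(diff(range(ecr_adult)) / mean(ecr_adult), 1e-11)
  expect_equal(risk_percentile(res, "ECR", "adult", 0.95), ecr_adult[1])
  # composition of the two hand computations: C_w2 = 1.035e-5 mg/L and the
  # adult intake factor 0.026331...
  want <- 0.014 * 1.035e-5 * (1.95 * 345 * 25 / (70 * 9125))
  expect_equal(ecr_adult[1], want, tolerance = 1e-10)
})

test_that("percentiles use linear interpolation between order statistics", {
  r <- fake_result(as.numeric(1:100))
  expect_equal(risk_percentile(r, "ECR", "adult", 0.95), 95.05)
  expect_equal(risk_percentile(r, "ECR", "adult", 1), 100)
  const <- fake_result(rep(4.2, 10))
  for (q in c(0, 0.3, 0.95, 1)) {
    expect_equal(risk_percentile(const, "ECR", "adult", q), 4.2)
  }
  expect_error(risk_percentile(r, "XYZ", "adult"), "metric")
  expect_error(risk_percentile(r, "ECR", "nobody"), "receptor")
  expect_error(risk_percentile(r, "ECR", "adult", 1.5), "\\[0, 1\\]")
})

test_that("exceedance probability is the strict exceedance fraction", {
  r <- fake_result(c(1, 2, 3, 4))
  expect_equal(exceedance_probability(r, "ECR", "adult", 2.5), 0.5)
  expect_equal(exceedance_probability(r, "ECR", "adult", 0), 1)
  expect_equal(exceedance_probability(r, "ECR", "adult", 10), 0)
})

test_that("fixed seeds give bit-identical runs, different seeds differ", {
  cfg <- default_scenario(n_iterations = 400)
  a <- run_simulation(cfg, seed = 99)
  b <- run_simulation(cfg, seed = 99)
  expect_identical(a$inputs, b$inputs)
  expect_identical(a$receptor_draws, b$receptor_draws)
  c <- run_simulation(cfg, seed = 100)
  expect_false(identical(a$receptor_draws$ECR, c$receptor_draws$ECR))
})

test_that("the ECR/HQ identity holds elementwise in every run", {
  res <- run_simulation(default_scenario(n_iterations = 1000), seed = 3)
  rd <- res$receptor_draws
  expect_equal(rd$ECR, 0.014 * 0.02 * rd$HQ, tolerance = 1e-12)
  expect_true(all(rd$ECR >= 0 & rd$HQ >= 0 & rd$ADD >= 0))
  expect_equal(nrow(rd), 2 * 1000)
})

test_that("headline percentiles are seed-stable at full iteration count", {
  cfg <- default_scenario()
  p1 <- risk_percentile(run_simulation(cfg, seed = 1), "ECR", "adult", 0.95)
  p2 <- risk_percentile(run_simulation(cfg, seed = 2), "ECR", "adult", 0.95)
  expect_lt(abs(p1 - p2) / p1, 0.05)
})

test_that("sensitivity contributions are normalised, signed and rank-based", {
  res <- run_simulation(default_scenario(n_iterations = 2000), seed = 5)
  for (rec in c("adult", "child")) {
    sens <- sensitivity_analysis(res, rec)
    expect_equal(sum(abs(sens$contribution_pct)), 100, tolerance = 0.1)
    # point-valued leach fractions cannot contribute
    expect_equal(sens$contribution_pct[sens$input %in% c("L1", "L2")],
                 c(0, 0))
    # body weight enters the denominator: negative association
    expect_lt(sens$contribution_pct[sens$input == "BW"], 0)
  }
})

test_that("a single varying input owns the entire output variance", {
  set.seed(7)
  x <- stats::runif(500)
  r <- fake_result(ecr = 2 * x,
                   inputs = tibble::tibble(
                     iteration = 1:500, C_mp = x, rho = 1, V = 1, R = 1,
                     L1 = 0, L2 = 0))
  sens <- sensitivity_analysis(r, "adult")
  expect_equal(sens$contribution_pct[sens$input == "C_mp"], 100,
               tolerance = 1e-9)
  expect_equal(sum(abs(sens$contribution_pct)), 100, tolerance = 1e-9)
})

test_that("iid factors split the contribution evenly and ranks are invariant", {
  set.seed(11)
  n <- 20000
  x <- stats::rlnorm(n); y <- stats::rlnorm(n)
  base <- tibble::tibble(iteration = seq_len(n), C_mp = x, rho = 1, V = y,
                         R = 1, L1 = 0, L2 = 0)
  r <- fake_result(ecr = x * y, inputs = base)
  sens <- sensitivity_analysis(r, "adult")
  cx <- sens$contribution_pct[sens$input == "C_mp"]
  cv <- sens$contribution_pct[sens$input == "V"]
  expect_equal(cx, 50, tolerance = 2)
  expect_equal(cv, 50, tolerance = 2)
  # a strictly increasing transform of an input leaves its rank correlation
  # (hence its contribution) unchanged
  r2 <- fake_result(ecr = x * y,
                    inputs = dplyr::mutate(base, C_mp = exp(C_mp)))
  sens2 <- sensitivity_analysis(r2, "adult")
  expect_equal(sens2$contribution_pct[sens2$input == "C_mp"], cx,
               tolerance = 1e-9)
})

test_that("sensitivity requires at least one varying input", {
  r <- fake_result(rep(1, 50))
  expect_error(sensitivity_analysis(r, "adult"), "varying")
})

test_that("scaling up the content distribution never lowers a percentile", {
  make_cfg <- function(k) {
    cfg <- default_scenario(n_iterations = 4000)
    cfg$inputs$R <- dist_spec("minimum_extreme", mode = k * 0.29,
                              scale = 0.08, lower_bound = 0, upper_bound = 1,
                              label = "R")
    cfg
  }
  r1 <- run_simulation(make_cfg(1), seed = 21)
  r2 <- run_simulation(make_cfg(1.5), seed = 21)
  for (q in c(0.05, 0.5, 0.95)) {
    expect_gte(risk_percentile(r2, "ECR", "adult", q),
               risk_percentile(r1, "ECR", "adult", q))
  }
})

test_that("reports round-trip and are byte-identical across repeat runs", {
  cfg <- default_scenario(n_iterations = 300)
  res <- run_simulation(cfg, seed = 12)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_report(res, d1)
  p2 <- write_report(run_simulation(cfg, seed = 12), d2)
  for (i in seq_along(p1)) {
    expect_identical(readLines(p1[i]), readLines(p2[i]))
  }
  perc <- readr::read_csv(file.path(d1, "percentiles.csv"),
                          show_col_types = FALSE)
  want <- risk_percentile(res, "ECR", "child", 0.95)
  got <- perc$value[perc$receptor == "child" & perc$metric == "ECR" &
                    perc$quantile == 0.95]
  expect_equal(got, want, tolerance = 1e-10)
  meta <- yaml::read_yaml(file.path(d1, "run_metadata.yml"))
  expect_equal(meta$seed, 12)
  expect_equal(meta$n_iterations, 300)
})

test_that("scenario files round-trip through the key-value schema", {
  cfg <- default_scenario(volume = "fiber", n_iterations = 500)
  path <- withr::local_tempfile(fileext = ".yml")
  write_scenario(cfg, path)
  cfg2 <- read_scenario(path)
  r1 <- run_simulation(cfg, seed = 8)
  r2 <- run_simulation(cfg2, seed = 8)
  expect_equal(r1$receptor_draws$ECR, r2$receptor_draws$ECR)
})

test_that("scenario validation names the missing symbol", {
  cfg <- default_scenario(n_iterations = 10)
  broken <- cfg
  broken$inputs$rho <- NULL
  expect_error(validate_scenario(broken), "rho")
  broken2 <- cfg
  broken2$receptors$adult$BW <- NULL
  expect_error(validate_scenario(broken2), "BW")
  broken3 <- cfg
  broken3$toxicity$SF0 <- NULL
  expect_error(validate_scenario(broken3), "SF0")
})

test_that("autoplot methods return ggplot objects", {
  res <- run_simulation(default_scenario(n_iterations = 200), seed = 2)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(sensitivity_analysis(res, "adult")), "ggplot")
  f <- fit_power_law(generate_abundance_table(1.74, seed = 1))
  expect_s3_class(autoplot(f), "ggplot")
})
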