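# shared fixtures built in code

# the five per-site power-law indices of the regional groundwater survey
site_alphas <- c(1.97, 1.81, 0.99, 2.28, 1.62)

# minimal risk_result with hand-chosen vectors, for summary-stage unit tests
fake_result <- function(ecr, receptor = "adult", inputs = NULL,
                        hq = ecr / (0.014 * 0.02)) {
  n <- length(ecr)
  structure(list(
    inputs = inputs %||% tibble::tibble(
      iteration = seq_len(n), C_mp = rep(1, n), rho = rep(1, n),
      V = rep(1, n), R = rep(1, n), L1 = rep(0, n), L2 = rep(0, n)),
    receptor_draws = tibble::tibble(
      receptor = receptor, iteration = seq_len(n),
      CR_w = rep(1, n), EF = rep(365, n), BW = rep(70, n),
      ADD = ecr / 0.014, HQ = hq, ECR = ecr),
    config = NULL, seed = NA_integer_, n_iterations = n),
    class = "risk_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# scenario with every input collapsed to a point, for deterministic checks
point_scenario <- function(c_mp = 10, rho = 1.38, v = 1e6, r = 0.3,
                           l1 = 0, l2 = 0.0025, density_unit = "g_cm3") {
  # pin the sampled volume at v via a sphere on (near-)degenerate support
  size_for_v <- (6 * v / pi)^(1 / 3)
  sd2 <- size_distribution(2, size_for_v * (1 - 1e-13), size_for_v)
  vd <- volume_distribution("per_shape", sd2, shape = "sphere")
  scenario(
    inputs = list(C_mp = c_mp, rho = rho, R = r, L1 = l1, L2 = l2),
    volume = vd,
    receptors = list(
      adult = list(CR_w = 1.95, EF = 345, ED = 25, BW = 70, AT = 9125),
      child = list(CR_w = 1.25, EF = 345, ED = 6, BW = 16.67, AT = 2190)),
    toxicity = list(RfD0 = 0.02, SF0 = 0.014),
    density_unit = density_unit,
    n_iterations = 50)
}
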