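#' Specify an input distribution
#'
#' Builds a validated distribution specification for one model input. The
#' supported families are those commonly used to encode survey-derived
#' uncertainty in probabilistic exposure assessment: a degenerate point value,
#' uniform, triangular, normal truncated below, the minimum extreme value
#' (Gumbel) distribution for minima, and a truncated power law for particle
#' size spectra.
#'
#' Family parameters:
#' \describe{
#'   \item{point}{`value`}
#'   \item{uniform}{`low`, `high` with `low < high`}
#'   \item{triangular}{`min`, `mode`, `max` with `min <= mode <= max`,
#'     `min < max` (a fully degenerate `min = mode = max` is accepted and
#'     behaves as a point value)}
#'   \item{truncated_normal}{`mean`, `sd >= 0`, optional `lower_bound`
#'     (default `-Inf`); draws below the bound are resampled}
#'   \item{minimum_extreme}{`mode` (location), `scale > 0`, optional
#'     `lower_bound`/`upper_bound`; the Gumbel distribution for minima with
#'     CDF `1 - exp(-exp((x - mode)/scale))`, out-of-bound draws resampled}
#'   \item{power_law}{`alpha`, `x_min`, `x_max` with
#'     `0 < x_min < x_max`, `alpha > 0`, `alpha != 1`; density proportional
#'     to `x^-alpha` on `[x_min, x_max]`}
#' }
#'
#' @param family Distribution family name (see Details).
#' @param ... Named family-specific parameters.
#' @param label Optional symbol name the specification instantiates
#'   (e.g. `"C_mp"`, `"R"`, `"BW"`).
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("triangular", min = 0, mode = 0, max = 79.23, label = "C_mp")
#' dist_spec("minimum_extreme", mode = 0.29, scale = 0.08,
#'           lower_bound = 0, upper_bound = 1, label = "R")
#' @export
dist_spec <- function(family, ..., label = NULL) {
  families <- c("point", "uniform", "triangular", "truncated_normal",
                "minimum_extreme", "power_law")
  if (!is.character(family) || length(family) != 1L || !family %in% families) {
    stop("unknown distribution family: ", paste(family, collapse = ", "),
         " (must be one of ", paste(families, collapse = ", "), ")",
         call. = FALSE)
  }
  p <- list(...)
  validate_dist_params(family, p)
  structure(list(family = family, params = p, label = label),
            class = "dist_spec")
}

required_dist_params <- function(family) {
  switch(family,
    point            = "value",
    uniform          = c("low", "high"),
    triangular       = c("min", "mode", "max"),
    truncated_normal = c("mean", "sd"),
    minimum_extreme  = c("mode", "scale"),
    power_law        = c("alpha", "x_min", "x_max"))
}

validate_dist_params <- function(family, p) {
  req <- required_dist_params(family)
  missing <- setdiff(req, names(p))
  if (length(missing)) {
    stop("family '", family, "' is missing parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) {
      stop("invalid '", field, "' for family '", family, "': ", why,
           call. = FALSE)
    }
  }
  switch(family,
    uniform = chk(p$low < p$high, "low/high", "requires low < high"),
    triangular = {
      chk(p$min <= p$mode && p$mode <= p$max, "mode",
          "requires min <= mode <= max")
    },
    truncated_normal = chk(p$sd >= 0, "sd", "must be non-negative"),
    minimum_extreme = {
      chk(p$scale > 0, "scale", "must be positive")
      lb <- p$lower_bound %||% -Inf
      ub <- p$upper_bound %||% Inf
      chk(lb < ub, "lower_bound/upper_bound", "requires lower < upper")
    },
    power_law = {
      chk(p$x_min > 0, "x_min", "must be positive")
      chk(p$x_min < p$x_max, "x_max", "requires x_min < x_max")
      chk(p$alpha > 0, "alpha", "must be positive")
      chk(p$alpha != 1, "alpha", "the value 1 makes the CDF singular")
    },
    NULL)
  invisible(TRUE)
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- paste(names(x$params), vapply(x$params, format, ""),
                sep = " = ", collapse = ", ")
  cat("<dist_spec> ", x$family, "(", pars, ")",
      if (!is.null(x$label)) paste0("  [", x$label, "]"), "\n", sep = "")
  invisible(x)
}

#' Draw from a distribution specification
#'
#' Families with truncation bounds (`truncated_normal`, `minimum_extreme`)
#' resample out-of-bound draws, so every returned value respects its bounds.
#' With the same `seed` the draws are identical across calls.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws (`n >= 1`).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (as inside the Monte Carlo engine).
#' @return Numeric vector of length `n`.
#' @examples
#' dist_sample(dist_spec("triangular", min = 0, mode = 0, max = 79.23),
#'             5, seed = 1)
#' @export
dist_sample <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "dist_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  p <- spec$params
  switch(spec$family,
    point = rep(p$value, n),
    uniform = stats::runif(n, p$low, p$high),
    triangular = rtriangular(n, p$min, p$mode, p$max),
    truncated_normal =
      resample_within(function(m) stats::rnorm(m, p$mean, p$sd),
                      n, p$lower_bound %||% -Inf, Inf),
    minimum_extreme =
      resample_within(function(m) qgumbel_min(stats::runif(m), p$mode, p$scale),
                      n, p$lower_bound %||% -Inf, p$upper_bound %||% Inf),
    power_law = power_law_quantile(stats::runif(n), p$alpha, p$x_min, p$x_max))
}

#' Analytic quantile of a distribution specification
#'
#' For truncated families this is the quantile of the truncated distribution
#' (probability mass renormalised to the bounds), which is the distribution
#' [dist_sample()] realises by resampling.
#'
#' @inheritParams dist_sample
#' @param u Probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles, same length as `u`.
#' @export
dist_quantile <- function(spec, u) {
  stopifnot(inherits(spec, "dist_spec"))
  if (any(u < 0 | u > 1, na.rm = TRUE)) {
    stop("u must lie in [0, 1]", call. = FALSE)
  }
  p <- spec$params
  switch(spec$family,
    point = rep(p$value, length(u)),
    uniform = stats::qunif(u, p$low, p$high),
    triangular = qtriangular(u, p$min, p$mode, p$max),
    truncated_normal = {
      lb <- p$lower_bound %||% -Inf
      pl <- stats::pnorm(lb, p$mean, p$sd)
      stats::qnorm(pl + u * (1 - pl), p$mean, p$sd)
    },
    minimum_extreme = {
      lb <- p$lower_bound %||% -Inf
      ub <- p$upper_bound %||% Inf
      pl <- pgumbel_min(lb, p$mode, p$scale)
      pu <- pgumbel_min(ub, p$mode, p$scale)
      qgumbel_min(pl + u * (pu - pl), p$mode, p$scale)
    },
    power_law = power_law_quantile(u, p$alpha, p$x_min, p$x_max))
}

#' Analytic CDF of a distribution specification
#'
#' @inheritParams dist_sample
#' @param x Evaluation points.
#' @return Numeric vector of cumulative probabilities.
#' @export
dist_cdf <- function(spec, x) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  switch(spec$family,
    point = as.numeric(x >= p$value),
    uniform = stats::punif(x, p$low, p$high),
    triangular = ptriangular(x, p$min, p$mode, p$max),
    truncated_normal = {
      lb <- p$lower_bound %||% -Inf
      pl <- stats::pnorm(lb, p$mean, p$sd)
      pmax(0, (stats::pnorm(x, p$mean, p$sd) - pl) / (1 - pl))
    },
    minimum_extreme = {
      lb <- p$lower_bound %||% -Inf
      ub <- p$upper_bound %||% Inf
      pl <- pgumbel_min(lb, p$mode, p$scale)
      pu <- pgumbel_min(ub, p$mode, p$scale)
      pmin(1, pmax(0, (pgumbel_min(x, p$mode, p$scale) - pl) / (pu - pl)))
    },
    power_law = power_law_cdf(x, p$alpha, p$x_min, p$x_max))
}

# rejection step for bounded families; truncation mass is small for every
# scenario default, so a round cap of 1000 is never approached in practice
resample_within <- function(draw, n, lower, upper) {
  x <- draw(n)
  for (round in seq_len(1000L)) {
    bad <- x < lower | x > upper
    if (!any(bad)) return(x)
    x[bad] <- draw(sum(bad))
  }
  stop("truncation bounds leave too little probability mass to sample",
       call. = FALSE)
}

rtriangular <- function(n, a, c, b) {
  qtriangular(stats::runif(n), a, c, b)
}

qtriangular <- function(u, a, c, b) {
  if (a == b) return(rep(a, length(u)))
  fc <- (c - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

ptriangular <- function(x, a, c, b) {
  if (a == b) return(as.numeric(x >= a))
  out <- numeric(length(x))
  lo <- x > a & x <= c
  hi <- x > c & x < b
  out[lo] <- (x[lo] - a)^2 / ((b - a) * (c - a))
  out[hi] <- 1 - (b - x[hi])^2 / ((b - a) * (b - c))
  out[x >= b] <- 1
  out
}

# Gumbel distribution for minima: location = mode, scale = beta
pgumbel_min <- function(x, mode, scale) {
  1 - exp(-exp((x - mode) / scale))
}

qgumbel_min <- function(u, mode, scale) {
  mode + scale * log(-log1p(-u))
}

#' Truncated power-law quantile function
#'
#' Inverts the CDF of the size spectrum with density proportional to
#' `x^-alpha` on `[x_min, x_max]`:
#' `F(x) = (x_min^(1-alpha) - x^(1-alpha)) / (x_min^(1-alpha) - x_max^(1-alpha))`.
#'
#' @param u Probabilities in `[0, 1]`.
#' @param alpha Power-law index (`alpha != 1`).
#' @param x_min,x_max Support bounds, `0 < x_min < x_max` (micrometres for
#'   particle sizes).
#' @return Sizes in `[x_min, x_max]`, strictly increasing in `u`.
#' @examples
#' power_law_quantile(0.5, alpha = 1.74, x_min = 20, x_max = 5000)
#' @export
power_law_quantile <- function(u, alpha, x_min, x_max) {
  if (any(u < 0 | u > 1, na.rm = TRUE)) {
    stop("u must lie in [0, 1]", call. = FALSE)
  }
  validate_dist_params("power_law",
                       list(alpha = alpha, x_min = x_min, x_max = x_max))
  k <- 1 - alpha
  (x_min^k - u * (x_min^k - x_max^k))^(1 / k)
}

#' Truncated power-law CDF
#'
#' @inheritParams power_law_quantile
#' @param x Evaluation points (clamped to the support).
#' @return Cumulative probabilities in `[0, 1]`.
#' @export
power_law_cdf <- function(x, alpha, x_min, x_max) {
  validate_dist_params("power_law",
                       list(alpha = alpha, x_min = x_min, x_max = x_max))
  k <- 1 - alpha
  x <- pmin(pmax(x, x_min), x_max)
  (x_min^k - x^k) / (x_min^k - x_max^k)
}

#' Power-law normalising prefactor on unbounded support
#'
#' Returns `b = (alpha - 1) * x_min^(alpha - 1)`, the prefactor that makes
#' `b * x^-alpha` integrate to one on `[x_min, Inf)`. Defined only for
#' `alpha > 1`; a shallower spectrum has no normaliser on unbounded support.
#'
#' @param alpha Power-law index, `> 1`.
#' @param x_min Lower support bound, `> 0`.
#' @return The prefactor `b`.
#' @examples
#' power_law_normalizer(2, 1)    # 1
#' power_law_normalizer(1.74, 20)
#' @export
power_law_normalizer <- function(alpha, x_min) {
  if (!(x_min > 0)) stop("x_min must be positive", call. = FALSE)
  if (!(alpha > 1)) {
    stop("alpha must exceed 1: the normalizer is undefined on unbounded ",
         "support for alpha <= 1", call. = FALSE)
  }
  (alpha - 1) * x_min^(alpha - 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
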