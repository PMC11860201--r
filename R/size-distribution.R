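#' Continuous particle-size distribution on bounded support
#'
#' Constructs the truncated power-law size spectrum used throughout the risk
#' model: density proportional to `x^-alpha` on `[x_min, x_max]` micrometres.
#' The unbounded-support prefactor `b = (alpha - 1) * x_min^(alpha - 1)` is
#' attached when `alpha > 1`; for shallower spectra (`alpha <= 1`) it does not
#' exist and is stored as `NA`, while the bounded-support CDF and quantile
#' remain valid.
#'
#' @param alpha Power-law index (`alpha > 0`, `alpha != 1`).
#' @param x_min,x_max Support bounds in micrometres, `0 < x_min < x_max`.
#' @return An object of classes `power_law_dist` and `dist_spec`, usable with
#'   [dist_sample()], [dist_quantile()] and [dist_cdf()].
#' @examples
#' sd <- size_distribution(1.74, 20, 5000)
#' dist_quantile(sd, 0.5)   # median size, ~49.9 um
#' @export
size_distribution <- function(alpha, x_min, x_max) {
  spec <- dist_spec("power_law", alpha = alpha, x_min = x_min, x_max = x_max,
                    label = "size")
  spec$b <- if (alpha > 1) power_law_normalizer(alpha, x_min) else NA_real_
  class(spec) <- c("power_law_dist", class(spec))
  spec
}

#' @export
print.power_law_dist <- function(x, ...) {
  cat("<power_law_dist> alpha = ", format(x$params$alpha),
      ", support [", format(x$params$x_min), ", ", format(x$params$x_max),
      "] um, b = ", format(x$b), "\n", sep = "")
  invisible(x)
}

#' Fit a power-law abundance model to one site's size table
#'
#' Regresses log abundance on log size by ordinary least squares, the
#' standard log-log "power trendline" fit: `y = b * x^-alpha` becomes
#' `ln y = ln b - alpha * ln x`, so the index `alpha` is the negated slope and
#' goodness of fit is the coefficient of determination of the log-log
#' regression. Zero-abundance bins are dropped (their log is undefined) and
#' at least three positive bins are required. A constant-abundance table is
#' reported as `alpha = 0`, `r_squared = 0`.
#'
#' @param data Data frame with one row per size bin.
#' @param size,abundance Tidy-select columns holding the bin size (upper edge
#'   of the class, micrometres) and the relative abundance in percent.
#'   Defaults `size_um`, `abundance_pct`.
#' @param site_label Optional site name carried into the result; defaults to
#'   the unique value of a `site` column when present.
#' @param method `"loglog_ols"` (default) or `"nls"` for nonlinear least
#'   squares of `y = b * x^-alpha` in linear space (initialised at the OLS
#'   estimate).
#' @return An object of class `power_law_fit` with fields `alpha`, `b`,
#'   `r_squared`, `site_label`, `n_points`, plus the fitted log-log model.
#'   [generics::tidy()] and [generics::glance()] methods are provided.
#' @examples
#' tbl <- tibble::tibble(size_um = c(20, 50, 100, 500),
#'                       abundance_pct = 5 * c(20, 50, 100, 500)^-2)
#' fit_power_law(tbl)
#' @export
fit_power_law <- function(data, size = "size_um", abundance = "abundance_pct",
                          site_label = NULL,
                          method = c("loglog_ols", "nls")) {
  method <- match.arg(method)
  x <- data[[size]]
  y <- data[[abundance]]
  if (is.null(x) || is.null(y)) {
    stop("data must contain columns '", size, "' and '", abundance, "'",
         call. = FALSE)
  }
  if (is.null(site_label) && "site" %in% names(data)) {
    site_label <- as.character(unique(data$site))
    if (length(site_label) != 1L) {
      stop("data contains several sites; fit one site at a time or use ",
           "fit_power_laws()", call. = FALSE)
    }
  }
  keep <- !is.na(x) & !is.na(y) & y > 0
  x <- x[keep]; y <- y[keep]
  if (any(x <= 0)) stop("sizes must be strictly positive", call. = FALSE)
  if (length(x) < 3L) {
    stop("insufficient data: need at least 3 bins with positive abundance, ",
         "got ", length(x), call. = FALSE)
  }
  lx <- log(x); ly <- log(y)
  if (stats::var(ly) == 0) {
    # flat spectrum: slope 0 by construction, no variance to explain
    return(new_power_law_fit(alpha = 0, b = mean(y), r_squared = 0,
                             site_label = site_label, n_points = length(x),
                             model = NULL, data = tibble::tibble(size = x,
                                                                 abundance = y)))
  }
  fit <- stats::lm(ly ~ lx)
  alpha <- -unname(stats::coef(fit)[2])
  b <- exp(unname(stats::coef(fit)[1]))
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((ly - mean(ly))^2)
  if (method == "nls") {
    nfit <- stats::nls(y ~ bb * x^(-aa), start = list(bb = b, aa = alpha))
    alpha <- unname(stats::coef(nfit)["aa"])
    b <- unname(stats::coef(nfit)["bb"])
    r2 <- 1 - sum(stats::resid(nfit)^2) / sum((y - mean(y))^2)
    fit <- nfit
  }
  new_power_law_fit(alpha = alpha, b = b, r_squared = r2,
                    site_label = site_label, n_points = length(x),
                    model = fit,
                    data = tibble::tibble(size = x, abundance = y))
}

new_power_law_fit <- function(alpha, b, r_squared, site_label, n_points,
                              model, data) {
  structure(list(alpha = alpha, b = b, r_squared = r_squared,
                 site_label = site_label, n_points = n_points,
                 model = model, data = data),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("<power_law_fit>",
      if (!is.null(x$site_label)) paste0(" site = ", x$site_label),
      " alpha = ", format(round(x$alpha, 4)),
      ", b = ", format(signif(x$b, 5)),
      ", R^2 = ", format(round(x$r_squared, 4)),
      " (", x$n_points, " bins)\n", sep = "")
  invisible(x)
}

#' Fit power laws to every site in a stacked abundance table
#'
#' @param data Data frame with columns `site`, `size_um`, `abundance_pct`
#'   (the CSV dialect written by [generate_survey()] and read by
#'   [read_abundance_table()]).
#' @inheritParams fit_power_law
#' @return A tibble with one row per site: `site`, `alpha`, `b`, `r_squared`,
#'   `n_points`.
#' @export
fit_power_laws <- function(data, method = c("loglog_ols", "nls")) {
  method <- match.arg(method)
  validate_abundance_table(data)
  data |>
    dplyr::group_by(.data$site) |>
    dplyr::group_map(function(d, key) {
      f <- fit_power_law(d, site_label = as.character(key$site),
                         method = method)
      tibble::tibble(site = f$site_label, alpha = f$alpha, b = f$b,
                     r_squared = f$r_squared, n_points = f$n_points)
    }) |>
    dplyr::bind_rows()
}

#' Aggregate power-law indices across sites
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' per-site indices, the convention used when a single regional spectrum is
#' distilled from several survey locations. A single fit yields `sd = 0`
#' with a warning.
#'
#' @param fits A tibble with an `alpha` column (as from [fit_power_laws()]),
#'   a list of `power_law_fit` objects, or a bare numeric vector of indices.
#' @return A one-row tibble: `mean_alpha`, `sd_alpha`, `n_sites`.
#' @examples
#' aggregate_alpha(c(1.97, 1.81, 0.99, 2.28, 1.62))
#' @export
aggregate_alpha <- function(fits) {
  alphas <-
    if (is.numeric(fits)) {
      fits
    } else if (is.data.frame(fits)) {
      fits$alpha
    } else if (is.list(fits)) {
      vapply(fits, function(f) f$alpha, numeric(1))
    } else {
      NULL
    }
  if (is.null(alphas) || length(alphas) == 0L) {
    stop("no fits supplied: need at least one alpha value", call. = FALSE)
  }
  s <- if (length(alphas) == 1L) {
    warning("single fit: standard deviation undefined, reported as 0",
            call. = FALSE)
    0
  } else {
    stats::sd(alphas)
  }
  tibble::tibble(mean_alpha = mean(alphas), sd_alpha = s,
                 n_sites = length(alphas))
}

#' Read / validate the site abundance CSV dialect
#'
#' Columns: `site` (character), `size_um` (bin upper edge, micrometres),
#' `abundance_pct` (relative abundance, percent). Per site, sizes must be
#' strictly positive and increasing, abundances non-negative and summing to
#' 100 within +/- 1, with at least three positive bins.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_abundance_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  validate_abundance_table(tbl)
  tbl
}

#' @rdname read_abundance_table
#' @param data A data frame to validate in place.
#' @export
validate_abundance_table <- function(data) {
  need <- c("site", "size_um", "abundance_pct")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("abundance table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  by_site <- split(data, data$site)
  for (nm in names(by_site)) {
    d <- by_site[[nm]]
    x <- d$size_um; y <- d$abundance_pct
    if (any(x <= 0)) stop("site ", nm, ": sizes must be positive", call. = FALSE)
    if (is.unsorted(x, strictly = TRUE)) {
      stop("site ", nm, ": sizes must be strictly increasing", call. = FALSE)
    }
    if (any(y < 0)) stop("site ", nm, ": abundances must be >= 0", call. = FALSE)
    if (abs(sum(y) - 100) > 1) {
      stop("site ", nm, ": abundances sum to ", format(sum(y)),
           ", expected 100 +/- 1", call. = FALSE)
    }
    if (sum(y > 0) < 3L) {
      stop("site ", nm, ": need at least 3 bins with positive abundance",
           call. = FALSE)
    }
  }
  invisible(data)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "b"),
                 estimate = c(x$alpha, x$b))
}

#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, b = x$b, r.squared = x$r_squared,
                 nobs = x$n_points,
                 site = x$site_label %||% NA_character_)
}
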