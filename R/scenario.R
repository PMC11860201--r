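#' Default groundwater PVC/DEHP exposure scenario
#'
#' Bundles every Monte Carlo input for the DEHP-in-PVC groundwater ingestion
#' assessment into a validated scenario object:
#'
#' * `C_mp` particles/L: triangular(0, 0, 79.23);
#' * `rho` density: triangular over 1.10-1.58 with mode at the midpoint 1.34
#'   (a symmetric triangle is the minimal assumption for a bare range);
#' * `R` additive mass fraction: minimum extreme (Gumbel-minimum) with mode
#'   0.29 and scale 0.08, truncated to (0, 1] by resampling (content outside
#'   0-100 % is physically impossible);
#' * `L1 = leach_fraction(4.37, 0.341)` (about 1.28e-5, i.e. 0.0013 %) and
#'   `L2 = 0.0025`, both point values;
#' * particle volume: by default the uniform envelope between the smallest
#'   fiber and largest fragment volume over a power-law size spectrum with
#'   index 1.74 on 20-5000 um, or a per-shape distribution via `volume`;
#' * receptors: adult CR_w ~ normal(1.95, 0.64) L/day, child
#'   normal(1.25, 0.57), both truncated at 0; EF ~ triangular(180, 345, 365)
#'   days/year; adult ED 25 y / AT 9125 d / BW ~ normal(70, 14) kg; child
#'   ED 6 y / AT 2190 d / BW ~ normal(16.67, 5.987) kg (truncated at 0);
#' * toxicity: oral reference dose `RfD0 = 0.02` mg/kg-day and slope factor
#'   `SF0 = 0.014` (mg/kg-day)^-1;
#' * 50,000 Monte Carlo iterations.
#'
#' `density_unit` defaults to `"mg_cm3"`: the 1.10-1.58 density values are
#' used literally on a mg/cm^3 scale, the convention under which this
#' scenario reproduces published groundwater-MP risk figures; set
#' `"g_cm3"` to treat them as the physical PVC density in g/cm^3 (all risk
#' outputs scale up by exactly 1000). See the vignette.
#'
#' @param volume `"uniform_envelope"` (default) or one of `"fragment"`,
#'   `"fiber"`, `"film"`, `"sphere"` for a per-shape volume model.
#' @param alpha,x_min,x_max Power-law size spectrum parameters.
#' @param density_unit `"mg_cm3"` or `"g_cm3"`.
#' @param ratio_table Aspect-ratio bounds, default [shape_ratio_table()].
#' @param envelope `"global"` or `"size_conditional"` envelope
#'   interpretation (envelope mode only).
#' @param n_iterations Monte Carlo iterations, default 50000.
#' @return An object of class `mprisk_scenario`.
#' @examples
#' default_scenario()
#' default_scenario(volume = "fragment", n_iterations = 1000)
#' @export
default_scenario <- function(volume = c("uniform_envelope", "fragment",
                                        "fiber", "film", "sphere"),
                             alpha = 1.74, x_min = 20, x_max = 5000,
                             density_unit = c("mg_cm3", "g_cm3"),
                             ratio_table = shape_ratio_table(),
                             envelope = c("global", "size_conditional"),
                             n_iterations = 50000) {
  volume <- match.arg(volume)
  density_unit <- match.arg(density_unit)
  envelope <- match.arg(envelope)
  sdist <- size_distribution(alpha, x_min, x_max)
  vd <- if (volume == "uniform_envelope") {
    volume_distribution("uniform_envelope", sdist, ratio_table = ratio_table,
                        envelope = envelope)
  } else {
    volume_distribution("per_shape", sdist, shape = volume,
                        ratio_table = ratio_table, ratio_sampling = "max")
  }
  scenario(
    inputs = list(
      C_mp = dist_spec("triangular", min = 0, mode = 0, max = 79.23,
                       label = "C_mp"),
      rho  = dist_spec("triangular", min = 1.10, mode = 1.34, max = 1.58,
                       label = "rho"),
      R    = dist_spec("minimum_extreme", mode = 0.29, scale = 0.08,
                       lower_bound = 0, upper_bound = 1, label = "R"),
      L1   = dist_spec("point", value = leach_fraction(4.37, 0.341),
                       label = "L1"),
      L2   = dist_spec("point", value = 0.25 / 100, label = "L2")
    ),
    volume = vd,
    receptors = list(
      adult = list(
        CR_w = dist_spec("truncated_normal", mean = 1.95, sd = 0.64,
                         lower_bound = 0, label = "CR_w"),
        EF = dist_spec("triangular", min = 180, mode = 345, max = 365,
                       label = "EF"),
        ED = 25, BW = dist_spec("truncated_normal", mean = 70, sd = 14,
                                lower_bound = 0, label = "BW"),
        AT = 9125),
      child = list(
        CR_w = dist_spec("truncated_normal", mean = 1.25, sd = 0.57,
                         lower_bound = 0, label = "CR_w"),
        EF = dist_spec("triangular", min = 180, mode = 345, max = 365,
                       label = "EF"),
        ED = 6, BW = dist_spec("truncated_normal", mean = 16.67, sd = 5.987,
                               lower_bound = 0, label = "BW"),
        AT = 2190)
    ),
    toxicity = list(RfD0 = 0.02, SF0 = 0.014),
    density_unit = density_unit,
    n_iterations = n_iterations
  )
}

#' Assemble and validate a scenario
#'
#' Lower-level constructor behind [default_scenario()]; every symbol the
#' simulation engine needs must be bound exactly once.
#'
#' @param inputs Named list of [dist_spec()]s for `C_mp`, `rho`, `R`, `L1`,
#'   `L2` (point values may be given as bare numbers).
#' @param volume A [volume_distribution()].
#' @param receptors Named list of receptor parameter sets, each with
#'   `CR_w`, `EF` ([dist_spec()] or number), and numeric `ED`, `BW`
#'   (spec or number), `AT`.
#' @param toxicity List with positive `RfD0` and `SF0`.
#' @param density_unit `"mg_cm3"` or `"g_cm3"`.
#' @param n_iterations Default iteration count, `>= 1`.
#' @return An object of class `mprisk_scenario`.
#' @export
scenario <- function(inputs, volume, receptors, toxicity,
                     density_unit = "mg_cm3", n_iterations = 50000) {
  cfg <- structure(list(inputs = lapply(inputs, as_dist_spec),
                        volume = volume,
                        receptors = lapply(receptors, function(r) {
                          r$CR_w <- as_dist_spec(r$CR_w)
                          r$EF <- as_dist_spec(r$EF)
                          r$BW <- as_dist_spec(r$BW)
                          r
                        }),
                        toxicity = toxicity,
                        density_unit = density_unit,
                        n_iterations = as.integer(n_iterations)),
                   class = "mprisk_scenario")
  validate_scenario(cfg)
}

as_dist_spec <- function(x) {
  if (inherits(x, "dist_spec")) return(x)
  if (is.numeric(x) && length(x) == 1L) {
    return(dist_spec("point", value = x))
  }
  stop("expected a dist_spec or a single number", call. = FALSE)
}

#' @rdname scenario
#' @param config An `mprisk_scenario` to validate.
#' @export
validate_scenario <- function(config) {
  stopifnot(inherits(config, "mprisk_scenario"))
  need <- c("C_mp", "rho", "R", "L1", "L2")
  miss <- setdiff(need, names(config$inputs))
  if (length(miss)) {
    stop("scenario is missing input symbol(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(config$inputs))) {
    stop("scenario binds an input symbol more than once: ",
         paste(unique(names(config$inputs)[duplicated(names(config$inputs))]),
               collapse = ", "), call. = FALSE)
  }
  if (!inherits(config$volume, "volume_dist")) {
    stop("scenario is missing a volume_dist for symbol V", call. = FALSE)
  }
  if (length(config$receptors) < 1L) {
    stop("scenario needs at least one receptor", call. = FALSE)
  }
  for (nm in names(config$receptors)) {
    r <- config$receptors[[nm]]
    rmiss <- setdiff(c("CR_w", "EF", "ED", "BW", "AT"), names(r))
    if (length(rmiss)) {
      stop("receptor ", nm, " is missing symbol(s): ",
           paste(rmiss, collapse = ", "), call. = FALSE)
    }
    if (!(r$ED > 0) || !(r$AT > 0)) {
      stop("receptor ", nm, ": ED and AT must be positive", call. = FALSE)
    }
  }
  tox <- config$toxicity
  if (is.null(tox$RfD0) || is.null(tox$SF0) || tox$RfD0 <= 0 || tox$SF0 <= 0) {
    stop("toxicity values RfD0 and SF0 must both be positive", call. = FALSE)
  }
  if (!config$density_unit %in% c("mg_cm3", "g_cm3")) {
    stop("density_unit must be 'mg_cm3' or 'g_cm3'", call. = FALSE)
  }
  if (config$n_iterations < 1L) {
    stop("n_iterations must be >= 1", call. = FALSE)
  }
  invisible(config)
}

#' @export
print.mprisk_scenario <- function(x, ...) {
  cat("<mprisk_scenario> ", length(x$inputs), " inputs, ",
      length(x$receptors), " receptors (",
      paste(names(x$receptors), collapse = ", "), "), volume mode = ",
      x$volume$mode,
      if (identical(x$volume$mode, "per_shape")) paste0(" [", x$volume$shape, "]"),
      ", density unit = ", x$density_unit,
      ", n_iterations = ", x$n_iterations, "\n", sep = "")
  invisible(x)
}

# ---- scenario file round-trip (YAML key-value schema) -----------------------

spec_to_list <- function(s) {
  c(list(family = s$family), s$params,
    if (!is.null(s$label)) list(label = s$label))
}

spec_from_list <- function(l) {
  do.call(dist_spec, c(list(family = l$family),
                       l[setdiff(names(l), c("family", "label"))],
                       list(label = l$label)))
}

#' Write / read a scenario configuration file
#'
#' Serialises a scenario to a YAML document with one key per model symbol
#' (`inputs.C_mp`, `inputs.rho`, ..., `receptors.adult.CR_w`, `toxicity.RfD0`,
#' `volume.*`, `density_unit`, `n_iterations`), each distribution written as
#' its family name plus named parameters. `read_scenario()` reconstructs and
#' re-validates the scenario, so a round-trip yields an equivalent object.
#'
#' @param config An `mprisk_scenario`.
#' @param path File path.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns the scenario.
#' @export
write_scenario <- function(config, path) {
  validate_scenario(config)
  vd <- config$volume
  doc <- list(
    inputs = lapply(config$inputs, spec_to_list),
    volume = list(mode = vd$mode, shape = vd$shape,
                  ratio_sampling = vd$ratio_sampling,
                  envelope = vd$envelope,
                  size = list(alpha = vd$size_dist$params$alpha,
                              x_min = vd$size_dist$params$x_min,
                              x_max = vd$size_dist$params$x_max),
                  ratio_table = lapply(seq_len(nrow(vd$ratio_table)),
                                       function(i) as.list(vd$ratio_table[i, ]))),
    receptors = lapply(config$receptors, function(r) {
      list(CR_w = spec_to_list(r$CR_w), EF = spec_to_list(r$EF),
           ED = r$ED, BW = spec_to_list(r$BW), AT = r$AT)
    }),
    toxicity = config$toxicity,
    density_unit = config$density_unit,
    n_iterations = config$n_iterations
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  doc <- yaml::read_yaml(path)
  sdist <- size_distribution(doc$volume$size$alpha, doc$volume$size$x_min,
                             doc$volume$size$x_max)
  rt <- dplyr::bind_rows(lapply(doc$volume$ratio_table, tibble::as_tibble))
  vd <- volume_distribution(doc$volume$mode, sdist, shape = doc$volume$shape,
                            ratio_table = rt,
                            ratio_sampling = doc$volume$ratio_sampling,
                            envelope = doc$volume$envelope)
  scenario(
    inputs = lapply(doc$inputs, spec_from_list),
    volume = vd,
    receptors = lapply(doc$receptors, function(r) {
      list(CR_w = spec_from_list(r$CR_w), EF = spec_from_list(r$EF),
           ED = r$ED, BW = spec_from_list(r$BW), AT = r$AT)
    }),
    toxicity = doc$toxicity,
    density_unit = doc$density_unit,
    n_iterations = doc$n_iterations
  )
}
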