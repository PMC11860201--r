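#' Aspect-ratio bounds for the common microplastic morphologies
#'
#' Returns the packaged length:width:height (L:W:H) ratio table: for each
#' shape, lower and upper bounds on the width-to-length (`wl_*`) and
#' height-to-length (`hl_*`) ratios, with length the longest dimension so
#' every ratio lies in (0, 1]. The shipped table
#' (`extdata/synthetic_shape_ratios.csv`) is a synthetic stand-in chosen on
#' morphology grounds — fragments and spheres share the 1:1:1 upper corner,
#' fibers are slender cylinders (W/L up to 0.35), films are thin sheets (H/L
#' at most 0.01) — and reproduces the qualitative volume ordering
#' fragment > fiber > film at the upper ratio bounds and the fiber minimum
#' at the lower bounds. Supply your own table with the same columns to
#' override it.
#'
#' @param path CSV with columns `shape`, `wl_low`, `wl_high`, `hl_low`,
#'   `hl_high`; defaults to the packaged synthetic table.
#' @return A tibble, one row per shape.
#' @examples
#' shape_ratio_table()
#' @export
shape_ratio_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "synthetic_shape_ratios.csv",
                        package = "mprisk", mustWork = TRUE)
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("shape", "wl_low", "wl_high", "hl_low", "hl_high")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    stop("ratio table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in need[-1]) {
    v <- tbl[[col]]
    if (any(v <= 0 | v > 1)) {
      stop("ratio table column ", col, " must lie in (0, 1]", call. = FALSE)
    }
  }
  if (any(tbl$wl_low > tbl$wl_high) || any(tbl$hl_low > tbl$hl_high)) {
    stop("ratio table bounds must satisfy low <= high", call. = FALSE)
  }
  tbl
}

shape_kinds <- c("fragment", "fiber", "film", "sphere")

#' Particle volume from size, shape and aspect ratios
#'
#' Maps the longest dimension L (the reported particle "size") to a volume
#' using the idealised geometry of each morphology: fragments are ellipsoids
#' `4/3 * pi * (L/2)(W/2)(H/2)`, fibers are cylinders of length L and
#' diameter W (`pi * (W/2)^2 * L`), films are rectangular boxes `L * W * H`,
#' and spheres are `4/3 * pi * (L/2)^3`. Width and height enter through the
#' dimensionless ratios `W = width_ratio * L`, `H = height_ratio * L`, so the
#' volume scales as `L^3` for fixed ratios.
#'
#' @param kind One of `"fragment"`, `"fiber"`, `"film"`, `"sphere"`
#'   (vectorised, recycled against `size`).
#' @param size Longest dimension L in micrometres, `> 0`.
#' @param width_ratio,height_ratio Ratios in (0, 1]. `height_ratio` is
#'   ignored for fibers (circular section) and spheres.
#' @return Volumes in cubic micrometres.
#' @examples
#' particle_volume("sphere", 2)                      # 4*pi/3
#' particle_volume("film", 10, 0.5, 0.1)             # 50
#' particle_volume("fiber", 1, width_ratio = 1)      # pi/4
#' @export
particle_volume <- function(kind, size, width_ratio = 1, height_ratio = 1) {
  if (!all(kind %in% shape_kinds)) {
    stop("unknown shape kind: ",
         paste(setdiff(unique(kind), shape_kinds), collapse = ", "),
         call. = FALSE)
  }
  if (any(size <= 0)) stop("size must be positive", call. = FALSE)
  if (any(width_ratio <= 0 | width_ratio > 1) ||
      any(height_ratio <= 0 | height_ratio > 1)) {
    stop("aspect ratios must lie in (0, 1]", call. = FALSE)
  }
  d <- tibble::tibble(kind = kind, L = size,
                      W = width_ratio * size, H = height_ratio * size)
  dplyr::case_when(
    d$kind == "fragment" ~ 4 / 3 * pi * (d$L / 2) * (d$W / 2) * (d$H / 2),
    d$kind == "fiber"    ~ pi * (d$W / 2)^2 * d$L,
    d$kind == "film"     ~ d$L * d$W * d$H,
    d$kind == "sphere"   ~ 4 / 3 * pi * (d$L / 2)^3
  )
}

#' Specify a particle-volume distribution
#'
#' Two modes are supported. `per_shape` draws a size from the power-law size
#' spectrum and applies the shape's size-to-volume map; by default the
#' aspect ratios are held at their upper bounds (`ratio_sampling = "max"`,
#' the convention under which the sphere coincides with the fragment), or
#' drawn uniformly within their bounds (`"uniform"`). `uniform_envelope`
#' draws volumes uniformly between the smallest attainable fiber volume and
#' the largest attainable fragment volume; `envelope = "global"` fixes those
#' bounds over the whole size support, while `"size_conditional"` recomputes
#' them at each sampled size.
#'
#' @param mode `"per_shape"` or `"uniform_envelope"`.
#' @param size_dist A [size_distribution()].
#' @param shape Shape kind, required in `per_shape` mode.
#' @param ratio_table Aspect-ratio bounds, default [shape_ratio_table()].
#' @param ratio_sampling `"max"` or `"uniform"` (per_shape mode).
#' @param envelope `"global"` or `"size_conditional"` (envelope mode).
#' @return An object of class `volume_dist`.
#' @examples
#' sd <- size_distribution(1.74, 20, 5000)
#' volume_distribution("per_shape", sd, shape = "fragment")
#' volume_distribution("uniform_envelope", sd)
#' @export
volume_distribution <- function(mode = c("per_shape", "uniform_envelope"),
                                size_dist,
                                shape = NULL,
                                ratio_table = shape_ratio_table(),
                                ratio_sampling = c("max", "uniform"),
                                envelope = c("global", "size_conditional")) {
  mode <- match.arg(mode)
  ratio_sampling <- match.arg(ratio_sampling)
  envelope <- match.arg(envelope)
  stopifnot(inherits(size_dist, "power_law_dist"))
  if (mode == "per_shape") {
    if (is.null(shape) || !shape %in% ratio_table$shape) {
      stop("per_shape mode needs a shape present in the ratio table",
           call. = FALSE)
    }
  } else {
    # envelope bounds are fixed at construction so they are part of the spec
    eb <- envelope_bounds(ratio_table, size_dist)
    if (envelope == "global" && !(eb[["v_min"]] < eb[["v_max"]])) {
      stop("degenerate envelope: v_min must be < v_max", call. = FALSE)
    }
  }
  structure(list(mode = mode, shape = shape, size_dist = size_dist,
                 ratio_table = ratio_table, ratio_sampling = ratio_sampling,
                 envelope = envelope,
                 envelope_bounds = if (mode == "uniform_envelope") {
                   envelope_bounds(ratio_table, size_dist)
                 }),
            class = "volume_dist")
}

#' @export
print.volume_dist <- function(x, ...) {
  cat("<volume_dist> mode = ", x$mode,
      if (x$mode == "per_shape") paste0(", shape = ", x$shape,
                                        ", ratios = ", x$ratio_sampling),
      if (x$mode == "uniform_envelope")
        paste0(" (", x$envelope, "), [",
               format(signif(x$envelope_bounds[["v_min"]], 4)), ", ",
               format(signif(x$envelope_bounds[["v_max"]], 4)), "] um^3"),
      "\n", sep = "")
  invisible(x)
}

#' Volume envelope bounds over a size spectrum
#'
#' The envelope minimum is the smallest attainable fiber volume (thinnest
#' ratio bounds at the smallest size) and the maximum the largest attainable
#' fragment volume (widest ratio bounds at the largest size), the
#' convention for bounding all morphologies by the slimmest and bulkiest
#' ones.
#'
#' @param ratio_table Aspect-ratio bounds containing at least `fiber` and
#'   `fragment` rows.
#' @param size_dist A [size_distribution()] providing `x_min`, `x_max`.
#' @return Named numeric vector `c(v_min, v_max)` in cubic micrometres.
#' @export
envelope_bounds <- function(ratio_table, size_dist) {
  for (s in c("fiber", "fragment")) {
    if (!s %in% ratio_table$shape) {
      stop("ratio table must contain a '", s, "' row for envelope bounds",
           call. = FALSE)
    }
  }
  fib <- ratio_table[ratio_table$shape == "fiber", ][1, ]
  frg <- ratio_table[ratio_table$shape == "fragment", ][1, ]
  v_min <- particle_volume("fiber", size_dist$params$x_min,
                           fib$wl_low, fib$hl_low)
  v_max <- particle_volume("fragment", size_dist$params$x_max,
                           frg$wl_high, frg$hl_high)
  c(v_min = v_min, v_max = v_max)
}

#' Sample particle volumes
#'
#' @param vd A [volume_distribution()].
#' @param n Number of draws.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Numeric vector of volumes in cubic micrometres, all positive.
#' @examples
#' sd <- size_distribution(1.74, 20, 5000)
#' vd <- volume_distribution("per_shape", sd, shape = "film")
#' summary(sample_volumes(vd, 1000, seed = 1))
#' @export
sample_volumes <- function(vd, n, seed = NULL) {
  stopifnot(inherits(vd, "volume_dist"))
  if (!is.null(seed)) set.seed(seed)
  if (vd$mode == "per_shape") {
    sizes <- dist_sample(vd$size_dist, n)
    r <- vd$ratio_table[vd$ratio_table$shape == vd$shape, ][1, ]
    if (vd$ratio_sampling == "max") {
      wl <- r$wl_high
      hl <- r$hl_high
    } else {
      wl <- stats::runif(n, r$wl_low, r$wl_high)
      hl <- stats::runif(n, r$hl_low, r$hl_high)
    }
    particle_volume(vd$shape, sizes, wl, hl)
  } else if (vd$envelope == "global") {
    eb <- vd$envelope_bounds
    stats::runif(n, eb[["v_min"]], eb[["v_max"]])
  } else {
    sizes <- dist_sample(vd$size_dist, n)
    fib <- vd$ratio_table[vd$ratio_table$shape == "fiber", ][1, ]
    frg <- vd$ratio_table[vd$ratio_table$shape == "fragment", ][1, ]
    lo <- particle_volume("fiber", sizes, fib$wl_low, fib$hl_low)
    hi <- particle_volume("fragment", sizes, frg$wl_high, frg$hl_high)
    stats::runif(n, lo, hi)
  }
}
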