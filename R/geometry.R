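# Mechanical description of a two-tether DNA braid and the maps between
# catenation number, extension and crossover angle.

#' Braid geometry
#'
#' Describes the mechanics of a braid formed by two DNA tethers held by one
#' magnetic bead: the relaxed extension, the sharp extension drop when the
#' first crossing is introduced, and the near-linear shortening per
#' additional turn. The crossover angle `beta` and the peak height `h` are
#' tied together by `(l - h) / l = cos(beta / 2)`, so exactly one of `h` and
#' `beta` must be supplied.
#'
#' @param l Relaxed braid extension at `Ca = 0`, in micrometres.
#' @param h Extension drop between `Ca = 0` and `Ca = +/-1` (micrometres).
#' @param beta Crossover angle in degrees; alternative to `h`.
#' @param delta Extension lost per turn for `|Ca| >= 1` (micrometres/turn).
#'   Defaults to `0.01 * l`, matching the shallow, visually linear flanks of
#'   measured extension-rotation curves.
#' @param ca_max Largest catenation number for which the linear model is
#'   taken to hold (turns).
#'
#' @return An object of class `braid_geometry`: a list with fields `l`, `h`,
#'   `beta`, `delta` and `ca_max`.
#' @examples
#' geom <- braid_geometry(l = 2.3, beta = 47)
#' braid_extension(geom, ca = 0:5)
#' @export
braid_geometry <- function(l, h = NULL, beta = NULL, delta = 0.01 * l,
                           ca_max = 50) {
  if (!is.numeric(l) || length(l) != 1L || !is.finite(l) || l <= 0) {
    stop("`l` must be a single positive extension in micrometres.", call. = FALSE)
  }
  if (is.null(h) == is.null(beta)) {
    stop("Supply exactly one of `h` or `beta`.", call. = FALSE)
  }
  if (is.null(h)) {
    h <- peak_height(l, beta)
  } else {
    beta <- crossover_angle(l, h)
  }
  if (delta < 0) stop("`delta` must be non-negative.", call. = FALSE)
  if (ca_max < 1) stop("`ca_max` must be at least 1.", call. = FALSE)
  structure(
    list(l = l, h = h, beta = beta, delta = delta, ca_max = ca_max),
    class = "braid_geometry"
  )
}

#' @export
print.braid_geometry <- function(x, ...) {
  cat(sprintf(
    "<braid_geometry> l = %.3f um, h = %.4f um (beta = %.1f deg), delta = %.4f um/turn, ca_max = %d\n",
    x$l, x$h, x$beta, x$delta, as.integer(x$ca_max)
  ))
  invisible(x)
}

#' Crossover angle from the extension-rotation peak
#'
#' The angle between the two DNA strands at a braid crossing, from the
#' relaxed extension `l` and the height `h` of the peak at `Ca = 0`:
#' `beta = 2 * acos((l - h) / l)`. Bead curvature and the finite diameter of
#' the duplexes are deliberately ignored; the formula is intended for
#' classifying braids into broad angle groups, not for precision geometry.
#'
#' @param l Relaxed extension (micrometres), positive.
#' @param h Peak height (micrometres), `0 <= h <= l`.
#' @return Crossover angle in degrees, in `[0, 180]`.
#' @examples
#' crossover_angle(l = 2.0, h = 0.166) # about 47 degrees
#' @seealso [peak_height()] for the inverse map.
#' @export
crossover_angle <- function(l, h) {
  if (any(!is.finite(l)) || any(l <= 0)) {
    stop("`l` must be positive and finite.", call. = FALSE)
  }
  if (any(!is.finite(h)) || any(h < 0)) {
    stop("`h` must be non-negative and finite.", call. = FALSE)
  }
  if (any(h > l)) {
    stop("`h` must not exceed `l`: the peak cannot be taller than the tether.",
         call. = FALSE)
  }
  2 * acos((l - h) / l) * 180 / pi
}

#' Peak height from the crossover angle
#'
#' Algebraic inverse of [crossover_angle()]: `h = l * (1 - cos(beta / 2))`.
#'
#' @param l Relaxed extension (micrometres), positive.
#' @param beta Crossover angle in degrees, in `[0, 180]`.
#' @return Peak height in micrometres.
#' @export
peak_height <- function(l, beta) {
  if (any(!is.finite(l)) || any(l <= 0)) {
    stop("`l` must be positive and finite.", call. = FALSE)
  }
  if (any(!is.finite(beta)) || any(beta < 0) || any(beta > 180)) {
    stop("`beta` must lie in [0, 180] degrees.", call. = FALSE)
  }
  l * (1 - cos(beta / 2 * pi / 180))
}

#' Braid extension at a given catenation number
#'
#' Piecewise-linear extension model: `z(0) = l`; the first crossing costs
#' `h`, so `z(+/-1) = l - h`; each further turn costs `delta`. The curve is
#' symmetric in `Ca` and clamped at zero. `ca` may be fractional (the first
#' segment interpolates linearly through the peak), which is what makes the
#' displacement-to-turns map invertible.
#'
#' @param geom A [braid_geometry()].
#' @param ca Catenation number(s), possibly fractional; `|ca| <= ca_max`.
#' @return Extension(s) in micrometres.
#' @export
braid_extension <- function(geom, ca) {
  stopifnot(inherits(geom, "braid_geometry"))
  if (any(!is.finite(ca))) stop("`ca` must be finite.", call. = FALSE)
  if (any(abs(ca) > geom$ca_max)) {
    stop(sprintf("|ca| exceeds ca_max = %g: outside the linear regime.",
                 geom$ca_max), call. = FALSE)
  }
  a <- abs(ca)
  z <- ifelse(a <= 1, geom$l - a * geom$h,
              geom$l - geom$h - (a - 1) * geom$delta)
  pmax(z, 0)
}

# Continuous inverse of braid_extension on ca >= 0 (clamped to [0, ca_max]).
ca_of_extension <- function(geom, z) {
  ca <- ifelse(z >= geom$l - geom$h,
               (geom$l - z) / ifelse(geom$h > 0, geom$h, Inf),
               1 + (geom$l - geom$h - z) / ifelse(geom$delta > 0, geom$delta, Inf))
  pmin(pmax(ca, 0), geom$ca_max)
}

#' Catenation change producing a given elongation
#'
#' Inverts the extension curve piecewise: starting from catenation number
#' `ca_start`, how many turns (possibly fractional) must be removed for the
#' braid to lengthen by `dz`? This is the map used to convert measured bead
#' displacements into released catenanes.
#'
#' @param geom A [braid_geometry()].
#' @param ca_start Catenation number before the elongation (`>= 0`).
#' @param dz Elongation in micrometres (`>= 0` for decatenation).
#' @return Decrease in catenation number (turns, real-valued).
#' @export
delta_ca_from_displacement <- function(geom, ca_start, dz) {
  stopifnot(inherits(geom, "braid_geometry"))
  if (any(ca_start < 0) || any(ca_start > geom$ca_max)) {
    stop("`ca_start` must lie in [0, ca_max].", call. = FALSE)
  }
  if (any(dz < 0)) stop("`dz` must be non-negative for decatenation.", call. = FALSE)
  z0 <- braid_extension(geom, ca_start)
  z1 <- z0 + dz
  if (any(z1 > geom$l + 1e-9)) {
    stop("`dz` exceeds the elongation of full decatenation.", call. = FALSE)
  }
  ca_start - ca_of_extension(geom, pmin(z1, geom$l))
}

#' Tabulate an extension-versus-catenation curve
#'
#' Convenience wrapper returning a tidy table of the model curve over a
#' symmetric grid, e.g. for plotting or for braid quality control.
#'
#' @param geom A [braid_geometry()].
#' @param ca_range Maximum |Ca| of the grid (defaults to `ca_max`).
#' @param step Grid step in turns.
#' @return A tibble with columns `ca` and `extension_um`.
#' @export
braid_curve <- function(geom, ca_range = geom$ca_max, step = 1) {
  ca <- seq(-ca_range, ca_range, by = step)
  tibble::tibble(ca = ca, extension_um = braid_extension(geom, ca))
}

# Boltzmann constant in pN um / K.
KB_PN_UM <- 1.3806e-5

#' Force from transverse bead fluctuations
#'
#' Equipartition (inverted-pendulum) estimate of the stretching force: for a
#' tethered bead at mean extension `<z>`, the transverse fluctuations obey
#' `F = kB T <z> / var(x)`. Uses `kB = 1.3806e-23 J/K`, i.e. `kT` of about
#' `4.28e-3 pN um` at 310 K.
#'
#' @param transverse_positions Numeric vector of transverse bead positions
#'   (micrometres); at least 100 samples.
#' @param mean_extension Mean tether extension (micrometres), positive.
#' @param temperature Absolute temperature in kelvin.
#' @return A one-row tibble with columns `force_pn`, `kt_pn_um`,
#'   `temperature_k`, `mean_extension_um`, `transverse_variance_um2` and `n`.
#' @examples
#' x <- rnorm(5000, sd = sqrt(4.28e-3 * 2.0 / 2.0))
#' estimate_force(x, mean_extension = 2.0)
#' @export
estimate_force <- function(transverse_positions, mean_extension,
                           temperature = 310) {
  x <- transverse_positions[is.finite(transverse_positions)]
  if (length(x) < 100) {
    stop("Need at least 100 transverse samples for a variance estimate.",
         call. = FALSE)
  }
  if (!is.finite(mean_extension) || mean_extension <= 0) {
    stop("`mean_extension` must be positive.", call. = FALSE)
  }
  v <- stats::var(x)
  if (v <= 0) {
    stop("Transverse variance is zero; cannot calibrate force.", call. = FALSE)
  }
  kt <- KB_PN_UM * temperature
  tibble::tibble(
    force_pn = kt * mean_extension / v,
    kt_pn_um = kt,
    temperature_k = temperature,
    mean_extension_um = mean_extension,
    transverse_variance_um2 = v,
    n = length(x)
  )
}
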