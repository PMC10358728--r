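#' Wavelength sampling grid
#'
#' Defines the regular wavelength grid on which every spectral quantity in the
#' package (stimuli, color matching functions, valence curves) is sampled.
#' The default, 400--700 nm in 5 nm steps, is the grid on which the packaged
#' standard-observer table is tabulated exactly, so no interpolation is needed.
#'
#' @param start_nm First wavelength (nm).
#' @param stop_nm Last wavelength (nm); must exceed `start_nm`.
#' @param step_nm Sample spacing (nm); `(stop_nm - start_nm) / step_nm` must be
#'   a whole number so the grid closes on `stop_nm`.
#' @return An object of class `wl_grid` with fields `start_nm`, `stop_nm`,
#'   `step_nm` and the sample vector `wl`.
#' @examples
#' g <- wl_grid()
#' length(g$wl) # 61
#' @export
wl_grid <- function(start_nm = 400, stop_nm = 700, step_nm = 5) {
  if (!(start_nm < stop_nm)) stop("wl_grid: start_nm must be < stop_nm")
  if (step_nm <= 0) stop("wl_grid: step_nm must be > 0")
  n_span <- (stop_nm - start_nm) / step_nm
  if (abs(n_span - round(n_span)) > 1e-9)
    stop("wl_grid: (stop_nm - start_nm) must be an integer multiple of step_nm")
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
         wl = seq(start_nm, stop_nm, by = step_nm)),
    class = "wl_grid"
  )
}

#' @export
print.wl_grid <- function(x, ...) {
  cat(sprintf("<wl_grid> %g-%g nm, step %g nm (%d samples)\n",
              x$start_nm, x$stop_nm, x$step_nm, length(x$wl)))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$wl, b$wl, tolerance = 1e-9))
}

#' Spectral radiance distribution
#'
#' Container for a non-negative spectral radiance sampled on a [wl_grid()].
#' Radiance is in arbitrary energy units; only ratios matter downstream.
#'
#' @param grid A [wl_grid()].
#' @param radiance Numeric vector of per-sample radiance, same length as the
#'   grid; all values must be finite and `>= 0` (physical light).
#' @return An object of class `spd`.
#' @export
spd <- function(grid, radiance) {
  stopifnot(inherits(grid, "wl_grid"))
  radiance <- as.numeric(radiance)
  if (length(radiance) != length(grid$wl))
    stop("spd: radiance length must match the grid")
  if (any(!is.finite(radiance)))
    stop("spd: radiance must be finite")
  if (any(radiance < 0))
    stop("spd: radiance must be non-negative (physical light)")
  structure(list(grid = grid, radiance = radiance), class = "spd")
}

#' @export
print.spd <- function(x, ...) {
  cat(sprintf("<spd> %g-%g nm step %g; radiance in [%.4g, %.4g], integral %.4g\n",
              x$grid$start_nm, x$grid$stop_nm, x$grid$step_nm,
              min(x$radiance), max(x$radiance), spd_integral(x)))
  invisible(x)
}

#' Integral of a spectrum over its grid
#'
#' Rectangle-rule quadrature (`sum(radiance) * step`), the convention used for
#' every spectral integral in the package, matching standard colorimetric
#' practice for tabulated functions.
#'
#' @param x An [spd()].
#' @return A scalar.
#' @export
spd_integral <- function(x) {
  stopifnot(inherits(x, "spd"))
  sum(x$radiance) * x$grid$step_nm
}

#' Equienergetic (flat) spectrum
#'
#' The grey reference of the matching task is an equienergetic stimulus; this
#' constructor builds any flat spectrum, including the all-zero dark stimulus.
#'
#' @param grid A [wl_grid()].
#' @param radiance Constant radiance, `>= 0`.
#' @return An [spd()] with every sample equal to `radiance`.
#' @export
flat_spectrum <- function(grid, radiance) {
  if (length(radiance) != 1 || !is.finite(radiance))
    stop("flat_spectrum: radiance must be a finite scalar")
  if (radiance < 0) stop("flat_spectrum: radiance must be non-negative")
  spd(grid, rep(radiance, length(grid$wl)))
}

#' Quasi-monochromatic stimulus
#'
#' A narrow Gaussian spectral radiance added on top of a low-radiance
#' equienergetic background. This is the stimulus class used for both test
#' lights and cancellation lights: a truly monochromatic delta function cannot
#' be represented on a sampled grid (nor shown on a display), while a narrow
#' Gaussian can, without changing the chromaticity appreciably.
#'
#' The Gaussian is evaluated at the true grid sample positions; `peak_nm` need
#' not coincide with a sample, but it must lie inside the grid range.
#'
#' @param grid A [wl_grid()].
#' @param peak_nm Center wavelength of the Gaussian (nm), inside the grid.
#' @param height Gaussian amplitude at its mode (radiance units), `>= 0`.
#' @param sigma_nm Gaussian standard deviation (nm), `> 0`. Default 5 nm:
#'   narrow relative to the ~100 nm scale of the color matching functions.
#' @param pedestal Background radiance, `>= 0`.
#' @return An [spd()] with `radiance(l) = pedestal + height * exp(-(l-peak)^2/(2 sigma^2))`.
#' @export
quasi_mono <- function(grid, peak_nm, height = 1, sigma_nm = 5, pedestal = 0) {
  stopifnot(inherits(grid, "wl_grid"))
  if (peak_nm < grid$start_nm || peak_nm > grid$stop_nm)
    stop(sprintf("quasi_mono: peak %g nm outside the %g-%g nm grid",
                 peak_nm, grid$start_nm, grid$stop_nm))
  if (height < 0) stop("quasi_mono: height must be non-negative")
  if (sigma_nm <= 0) stop("quasi_mono: sigma_nm must be positive")
  if (pedestal < 0) stop("quasi_mono: pedestal must be non-negative")
  r <- pedestal + height * exp(-(grid$wl - peak_nm)^2 / (2 * sigma_nm^2))
  out <- spd(grid, r)
  attr(out, "peak_nm") <- peak_nm
  out
}

#' Signed superposition of cancellation lights
#'
#' Physical light superposition is always additive, so a negative weight on a
#' cancellation light cannot subtract radiance from the test stimulus; by the
#' standard color-matching convention it instead means adding the same amount
#' of that light to the reference side. This function applies a signed weight
#' vector accordingly and returns both sides of the match, each a physical
#' (non-negative) spectrum.
#'
#' @param test Test stimulus, an [spd()].
#' @param lights List of cancellation-light [spd()]s, all on the test's grid.
#' @param weights Numeric vector of signed energies, one per light.
#' @param reference Reference (grey) stimulus on the same grid.
#' @return A list with elements `test_side` and `reference_side`, both [spd()].
#' @export
signed_superposition <- function(test, lights, weights, reference) {
  stopifnot(inherits(test, "spd"), inherits(reference, "spd"))
  if (length(lights) != length(weights))
    stop("signed_superposition: one weight per light required")
  if (!same_grid(test$grid, reference$grid))
    stop("signed_superposition: test and reference grids differ")
  t_side <- test$radiance
  r_side <- reference$radiance
  for (i in seq_along(lights)) {
    li <- lights[[i]]
    stopifnot(inherits(li, "spd"))
    if (!same_grid(li$grid, test$grid))
      stop("signed_superposition: light grid mismatch")
    w <- weights[i]
    if (w >= 0) t_side <- t_side + w * li$radiance
    else        r_side <- r_side + (-w) * li$radiance
  }
  list(test_side = spd(test$grid, t_side),
       reference_side = spd(test$grid, r_side))
}

#' Write / read a spectrum as delimited text
#'
#' Two-column CSV (`wavelength_nm`, `radiance`) with one header line.
#'
#' @param x An [spd()].
#' @param path File path.
#' @return `write_spd_csv` returns `path` invisibly; `read_spd_csv` returns an
#'   [spd()].
#' @export
write_spd_csv <- function(x, path) {
  stopifnot(inherits(x, "spd"))
  utils::write.csv(
    data.frame(wavelength_nm = x$grid$wl, radiance = x$radiance),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spd_csv
#' @export
read_spd_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "radiance") %in% names(d)))
    stop("read_spd_csv: expected columns wavelength_nm, radiance")
  wl <- d$wavelength_nm
  step <- unique(round(diff(wl), 9))
  if (length(step) != 1) stop("read_spd_csv: wavelengths not on a regular grid")
  spd(wl_grid(wl[1], wl[length(wl)], step), d$radiance)
}
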