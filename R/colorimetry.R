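#' Standard-observer color matching functions
#'
#' Loads one of the packaged observers, resampled to a working grid by linear
#' interpolation (exact at the 5 nm tabulation knots):
#'
#' * `"cie1931_2deg"` — the CIE 1931 2-degree standard observer, tabulated at
#'   5 nm on 400--700 nm from the standard published values.
#' * `"hpe_lms"` — cone-fundamental-style LMS sensitivities obtained from the
#'   CIE 1931 observer by the fixed Hunt--Pointer--Estevez cone transform
#'   (equal-energy normalization). Any externally tabulated cone fundamentals
#'   can be used instead via [read_observer_csv()].
#'
#' @param name One of `"cie1931_2deg"`, `"hpe_lms"`.
#' @param grid Working [wl_grid()]; must lie inside 400--700 nm.
#' @return An object of class `observer_cmfs`: list with `grid`, `M` (n x 3
#'   sensitivity matrix) and `name`.
#' @export
load_observer <- function(name = c("cie1931_2deg", "hpe_lms"), grid = wl_grid()) {
  name <- match.arg(name)
  path <- system.file("extdata", "cie1931_2deg_5nm.csv", package = "huecancel",
                      mustWork = TRUE)
  tab <- utils::read.csv(path)
  if (grid$start_nm < min(tab$wavelength_nm) || grid$stop_nm > max(tab$wavelength_nm))
    stop("load_observer: working grid extends beyond the packaged 400-700 nm table")
  M <- vapply(c("xbar", "ybar", "zbar"), function(col) {
    stats::approx(tab$wavelength_nm, tab[[col]], xout = grid$wl)$y
  }, numeric(length(grid$wl)))
  colnames(M) <- c("xbar", "ybar", "zbar")
  if (name == "hpe_lms") {
    M <- M %*% t(hpe_matrix())
    colnames(M) <- c("lbar", "mbar", "sbar")
  }
  structure(list(grid = grid, M = M, name = name), class = "observer_cmfs")
}

# Hunt-Pointer-Estevez cone matrix, equal-energy normalization (LMS = H %*% XYZ)
hpe_matrix <- function() {
  matrix(c(0.38971,  0.68898, -0.07868,
           -0.22981, 1.18340,  0.04641,
           0.00000,  0.00000,  1.00000),
         nrow = 3, byrow = TRUE)
}

#' Read an observer table from CSV
#'
#' Expects columns `wavelength_nm` plus exactly three sensitivity columns, the
#' dialect used by the packaged tables.
#'
#' @param path CSV file path.
#' @param grid Working [wl_grid()] to resample onto (linear interpolation).
#' @param name Label to attach.
#' @return An `observer_cmfs` object.
#' @export
read_observer_csv <- function(path, grid = wl_grid(), name = basename(path)) {
  tab <- utils::read.csv(path)
  if (!("wavelength_nm" %in% names(tab)) || ncol(tab) != 4)
    stop("read_observer_csv: expected wavelength_nm + 3 sensitivity columns")
  cols <- setdiff(names(tab), "wavelength_nm")
  if (grid$start_nm < min(tab$wavelength_nm) || grid$stop_nm > max(tab$wavelength_nm))
    stop("read_observer_csv: working grid extends beyond the table")
  M <- vapply(cols, function(col) {
    stats::approx(tab$wavelength_nm, tab[[col]], xout = grid$wl)$y
  }, numeric(length(grid$wl)))
  colnames(M) <- cols
  structure(list(grid = grid, M = M, name = name), class = "observer_cmfs")
}

#' @export
print.observer_cmfs <- function(x, ...) {
  cat(sprintf("<observer_cmfs> %s on %g-%g nm step %g\n", x$name,
              x$grid$start_nm, x$grid$stop_nm, x$grid$step_nm))
  invisible(x)
}

#' Tristimulus vector
#'
#' A 3-vector of coordinates in a named color space. The space label travels
#' with the vector and is checked by every binary operation, so values from
#' different representations cannot be mixed silently.
#'
#' @param v Numeric length-3, finite.
#' @param space Space label (e.g. `"xyz"`, `"lms"`, `"atd"`, `"rgb_linear"`,
#'   `"rgb_digital"`).
#' @return Class `tristim` numeric vector with a `space` attribute.
#' @export
tristim <- function(v, space = "xyz") {
  v <- as.numeric(v)
  if (length(v) != 3 || any(!is.finite(v))) stop("tristim: need 3 finite values")
  structure(v, space = space, class = "tristim")
}

#' @export
print.tristim <- function(x, ...) {
  cat(sprintf("<tristim %s> [%.6g, %.6g, %.6g]\n", attr(x, "space"),
              x[1], x[2], x[3]))
  invisible(x)
}

tristim_space <- function(t) attr(t, "space")

#' Spectrum to tristimulus
#'
#' The retinal front end: integrates a spectral radiance against the three
#' observer sensitivities (rectangle rule, `sum * step`).
#'
#' @param x An [spd()].
#' @param cmfs An `observer_cmfs` on the same grid.
#' @return A [tristim()] in space `"xyz"` for the CIE observer, `"lms"` for a
#'   cone observer.
#' @export
spectrum_to_tristimulus <- function(x, cmfs) {
  stopifnot(inherits(x, "spd"), inherits(cmfs, "observer_cmfs"))
  if (!same_grid(x$grid, cmfs$grid))
    stop("spectrum_to_tristimulus: spectrum and observer grids differ")
  v <- drop(crossprod(cmfs$M, x$radiance)) * x$grid$step_nm
  tristim(v, space = if (cmfs$name == "hpe_lms") "lms" else "xyz")
}

#' Chromaticity coordinates
#'
#' Projective coordinates of a tristimulus vector: the first two components of
#' `v / sum(v)`. Defined only for vectors with strictly positive coordinate
#' sum.
#'
#' @param t A [tristim()] or numeric length-3.
#' @return Numeric length-2 `(c1, c2)`.
#' @export
chromaticity_of <- function(t) {
  v <- as.numeric(t)
  s <- sum(v)
  if (!is.finite(s) || s <= 0)
    stop("chromaticity_of: coordinate sum must be strictly positive")
  v[1:2] / s
}

# Lift a chromaticity (c1, c2) to the unit-coordinate-sum 3-vector.
lift_chromaticity <- function(c2) {
  c(c2[1], c2[2], 1 - c2[1] - c2[2])
}

#' Spectral locus chromaticities
#'
#' Chromaticity of the monochromatic light at every grid sample, i.e. of each
#' column-normalized row of the CMF table.
#'
#' @param cmfs An `observer_cmfs`.
#' @return A matrix with columns `wavelength_nm`, `c1`, `c2`.
#' @export
spectral_locus <- function(cmfs) {
  cc <- t(apply(cmfs$M, 1, function(r) r[1:2] / sum(r)))
  cbind(wavelength_nm = cmfs$grid$wl, c1 = cc[, 1], c2 = cc[, 2])
}

#' Complementary light of a monochromatic stimulus
#'
#' Extends the ray from the query light's chromaticity through the white point
#' until it meets the far boundary of the chromaticity diagram. If the ray
#' meets the spectral locus (treated as a polyline between grid samples) the
#' complement is a monochromatic light and the crossing wavelength is returned
#' by linear interpolation; if it meets the purple line joining the locus
#' extremes, the complement is a non-spectral purple (the "auxiliary magenta")
#' and only its boundary chromaticity is returned. For mid-green queries the
#' complement is always purple. Ties between adjacent locus segments are
#' broken toward the longer-wavelength segment.
#'
#' @param lambda_nm Query wavelength, inside the observer grid.
#' @param white Chromaticity (length-2) of the white point.
#' @param cmfs An `observer_cmfs`.
#' @return A list of class `complement_result` with fields `kind`
#'   (`"spectral"` or `"purple"`), `wavelength_nm` (`NA` for purple),
#'   `chromaticity`, and `mixing_ratio`: the proportion `a` such that
#'   `a * query + (1 - a) * complement` (in lifted unit-sum coordinates)
#'   reproduces the white chromaticity.
#' @export
complementary_wavelength <- function(lambda_nm, white, cmfs) {
  stopifnot(inherits(cmfs, "observer_cmfs"))
  wl <- cmfs$grid$wl
  if (lambda_nm < wl[1] || lambda_nm > wl[length(wl)])
    stop("complementary_wavelength: query wavelength outside the grid")
  locus <- spectral_locus(cmfs)
  cq <- locus_chromaticity(lambda_nm, locus)
  d <- cq - white
  if (sqrt(sum(d^2)) < 1e-12)
    stop("complementary_wavelength: query chromaticity equals the white; direction undefined")
  dir <- -d / sqrt(sum(d^2))  # away from the query, through the white

  n <- nrow(locus)
  best <- NULL
  # spectral-locus segments; walk from long to short wavelength so the first
  # accepted hit at a tie is the longer-wavelength segment
  for (i in seq(n - 1, 1)) {
    hit <- ray_segment_intersect(white, dir, locus[i, 2:3], locus[i + 1, 2:3])
    if (!is.null(hit) && (is.null(best) || hit$t < best$t - 1e-12)) {
      lam <- unname(locus[i, 1] + hit$s * (locus[i + 1, 1] - locus[i, 1]))
      best <- c(hit, list(kind = "spectral", wavelength_nm = lam))
    }
  }
  hitp <- ray_segment_intersect(white, dir, locus[n, 2:3], locus[1, 2:3])
  if (!is.null(hitp) && (is.null(best) || hitp$t < best$t - 1e-12))
    best <- c(hitp, list(kind = "purple", wavelength_nm = NA_real_))
  if (is.null(best))
    stop("complementary_wavelength: no boundary intersection found")
  cc <- unname(white + best$t * dir)
  # mixing ratio a: a*cq + (1-a)*cc = white  (affine in lifted coordinates)
  a <- sum((white - cc) * (cq - cc)) / sum((cq - cc)^2)
  structure(list(kind = best$kind, wavelength_nm = best$wavelength_nm,
                 chromaticity = cc, mixing_ratio = a),
            class = "complement_result")
}

# chromaticity of a (possibly off-sample) wavelength by locus interpolation
locus_chromaticity <- function(lambda_nm, locus) {
  c(stats::approx(locus[, 1], locus[, 2], xout = lambda_nm)$y,
    stats::approx(locus[, 1], locus[, 3], xout = lambda_nm)$y)
}

# Intersection of ray p + t*dir (t > eps) with segment a--b; returns t and the
# segment parameter s in [0,1], or NULL.
ray_segment_intersect <- function(p, dir, a, b, eps = 1e-9) {
  e <- b - a
  den <- dir[1] * (-e[2]) - dir[2] * (-e[1])
  if (abs(den) < 1e-15) return(NULL)
  rhs <- a - p
  t <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / den
  s <- (dir[1] * rhs[2] - dir[2] * rhs[1]) / den
  if (t > eps && s >= -1e-9 && s <= 1 + 1e-9)
    list(t = t, s = min(max(s, 0), 1))
  else NULL
}

#' Reference opponent valence curves
#'
#' The package's stand-in for measured human valence data: the classical
#' linear valence model built from the CIE color matching functions,
#' `RG = xbar - ybar` and `YB = 0.4 * (ybar - zbar)`. Coefficients are
#' exposed, and an externally digitized data file (CSV with columns
#' `wavelength_nm`, `rg`, `yb`) can be supplied instead; it is resampled to
#' the working grid by linear interpolation.
#'
#' @param grid Working [wl_grid()].
#' @param rg_coef,yb_coef Length-3 coefficient vectors applied to the CIE
#'   `(xbar, ybar, zbar)` rows.
#' @param file Optional path to a user-supplied valence CSV.
#' @return A `valence_curves` object (see [run_cancellation_curves()]).
#' @export
jh_reference_valences <- function(grid = wl_grid(),
                                  rg_coef = c(1, -1, 0),
                                  yb_coef = c(0, 0.4, -0.4),
                                  file = NULL) {
  if (!is.null(file)) {
    d <- utils::read.csv(file)
    if (!all(c("wavelength_nm", "rg", "yb") %in% names(d)))
      stop("jh_reference_valences: file must have columns wavelength_nm, rg, yb")
    rg <- stats::approx(d$wavelength_nm, d$rg, xout = grid$wl, rule = 2)$y
    yb <- stats::approx(d$wavelength_nm, d$yb, xout = grid$wl, rule = 2)$y
    return(new_valence_curves(grid, rg, yb, source = file))
  }
  cmfs <- load_observer("cie1931_2deg", grid)
  rg <- drop(cmfs$M %*% rg_coef)
  yb <- drop(cmfs$M %*% yb_coef)
  new_valence_curves(grid, rg, yb, source = "linear valence model")
}
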