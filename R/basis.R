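#' Build a cancellation-light primary basis
#'
#' Constructs the three new primaries of the change-of-basis view of hue
#' cancellation for a configuration `(lambda1, lambda2 = lambda1 + delta)`.
#' The two chromatic axes run from each cancellation wavelength through the
#' white point to its complement (spectral, or purple for mid-green lights);
#' the third primary points along the white.
#'
#' * Option 1: the chromatic primaries are the cancellation lights' own
#'   chromaticities lifted to unit-coordinate-sum 3-vectors, i.e. vectors
#'   whose chromaticities sit on the two axes.
#' * Option 2: the same two vectors orthogonalized (Euclidean inner product in
#'   the tristimulus space) against the white primary, so they carry no
#'   brightness component.
#'
#' All scales `gamma_i` start at 1; they are free parameters fitted later
#' ([fit_gammas()]) and do not affect curve shapes.
#'
#' @param lambda1_nm Short cancellation wavelength (nm).
#' @param delta_nm Offset to the second wavelength; `lambda2 = lambda1 + delta`,
#'   inside the grid, `delta != 0`.
#' @param option 1 or 2 (see above).
#' @param white Grey reference [spd()].
#' @param cmfs `observer_cmfs` defining the tristimulus space.
#' @return Object of class `primaries_basis`: `primaries` (3x3 matrix, columns
#'   `R(P_i)`), `chromaticities`, `gammas`, `option`, `lambda1_nm`,
#'   `lambda2_nm`, `complements` (two [complementary_wavelength()] results),
#'   `white_chromaticity`.
#' @export
build_primaries <- function(lambda1_nm, delta_nm, option = 2, white, cmfs) {
  stopifnot(inherits(white, "spd"), inherits(cmfs, "observer_cmfs"))
  if (delta_nm == 0) stop("build_primaries: delta_nm must be nonzero")
  lambda2_nm <- lambda1_nm + delta_nm
  wl <- cmfs$grid$wl
  if (lambda1_nm < wl[1] || lambda2_nm > wl[length(wl)] || lambda2_nm < wl[1])
    stop("build_primaries: cancellation wavelengths outside the grid")

  w_chrom <- chromaticity_of(spectrum_to_tristimulus(white, cmfs))
  locus <- spectral_locus(cmfs)
  c1 <- locus_chromaticity(lambda1_nm, locus)
  c2 <- locus_chromaticity(lambda2_nm, locus)
  comp1 <- complementary_wavelength(lambda1_nm, w_chrom, cmfs)
  comp2 <- complementary_wavelength(lambda2_nm, w_chrom, cmfs)

  P3 <- lift_chromaticity(w_chrom)
  P1 <- lift_chromaticity(c1)
  P2 <- lift_chromaticity(c2)
  if (option == 2) {
    P1 <- P1 - sum(P1 * P3) / sum(P3 * P3) * P3
    P2 <- P2 - sum(P2 * P3) / sum(P3 * P3) * P3
  } else if (option != 1) stop("build_primaries: option must be 1 or 2")

  P <- cbind(P1, P2, P3)
  if (abs(det(P)) < 1e-12)
    stop("build_primaries: degenerate configuration (collinear axes)")
  chrom <- apply(P, 2, function(v) {
    s <- sum(v)
    if (s > 1e-9) v[1:2] / s else c(NA_real_, NA_real_)
  })
  structure(list(primaries = P, chromaticities = chrom,
                 gammas = c(1, 1, 1), option = option,
                 lambda1_nm = lambda1_nm, lambda2_nm = lambda2_nm,
                 delta_nm = delta_nm,
                 complements = list(comp1, comp2),
                 white_chromaticity = w_chrom),
            class = "primaries_basis")
}

#' @export
print.primaries_basis <- function(x, ...) {
  ckind <- vapply(x$complements, function(ci) ci$kind, character(1))
  cat(sprintf("<primaries_basis> option %d, lambda1 %g nm, lambda2 %g nm (complements: %s)\n",
              x$option, x$lambda1_nm, x$lambda2_nm, paste(ckind, collapse = ", ")))
  invisible(x)
}

#' Change-of-basis matrix
#'
#' Inverse of the column matrix of the primaries, including the gamma scales:
#' `M = (diag(gamma) applied) [R(P1) R(P2) R(P3)]^-1`, so
#' `M %*% R(P_i) = e_i` and the rows of `M` are the dual sensitivities of the
#' new primaries.
#'
#' @param basis A [build_primaries()] result.
#' @return A 3x3 matrix of class `basis_matrix` (attribute `basis` keeps the
#'   source configuration).
#' @export
change_of_basis_matrix <- function(basis) {
  stopifnot(inherits(basis, "primaries_basis"))
  P <- sweep(basis$primaries, 2, basis$gammas, "*")
  if (kappa(P, exact = TRUE) > 1e12)
    stop("change_of_basis_matrix: primaries are ill-conditioned")
  m <- unname(solve(P))
  structure(m, basis = basis, class = c("basis_matrix", "matrix"))
}

#' Analytic valence curves from a change of basis
#'
#' The tristimulus values of the monochromatic lights re-expressed in the
#' cancellation-light basis: row `i` of `m` applied to the color matching
#' functions gives the weight of primary `i` needed at each wavelength. The
#' two chromatic channels are the predicted valence curves; the channel of
#' the axis with the longer cancellation wavelength is labeled red-green.
#' Channel orientations are fixed so that red-green is positive at the
#' long-wavelength end and yellow-blue positive in the mid-wavelength
#' (yellow) region.
#'
#' @param cmfs `observer_cmfs`.
#' @param m A [change_of_basis_matrix()].
#' @param grid Output [wl_grid()] (defaults to the observer grid).
#' @return A `valence_curves` object (`source = "analytic"`).
#' @export
predicted_valences <- function(cmfs, m, grid = cmfs$grid) {
  stopifnot(inherits(m, "basis_matrix"))
  M <- cmfs$M
  if (!same_grid(grid, cmfs$grid)) {
    M <- vapply(seq_len(ncol(M)), function(j)
      stats::approx(cmfs$grid$wl, M[, j], xout = grid$wl)$y,
      numeric(length(grid$wl)))
  }
  ch <- M %*% t(unclass(m))                 # n x 3: weights of P1, P2, P3
  basis <- attr(m, "basis")
  if (!is.null(basis)) {
    purple <- vapply(basis$complements, function(ci) ci$kind == "purple",
                     logical(1))
    rg_ax <- rg_axis_of(purple, basis$lambda1_nm, basis$lambda2_nm)
  } else rg_ax <- 2L
  if (rg_ax == 2L) { rg <- ch[, 2]; yb <- ch[, 1] } else { rg <- ch[, 1]; yb <- ch[, 2] }
  if (rg[which.min(abs(grid$wl - 650))] < 0) rg <- -rg
  if (yb[which.min(abs(grid$wl - 550))] < 0) yb <- -yb
  out <- new_valence_curves(grid, rg, yb, source = "analytic")
  out$achromatic <- ch[, 3]
  out$basis <- basis
  out
}

#' Fit the primary length scales to a reference
#'
#' The free lengths `gamma_i` of the chromatic primaries rescale each
#' predicted channel without changing its shape. This computes the
#' closed-form per-channel least-squares gains against a reference and
#' returns both the fitted curves and the equivalent updated gammas
#' (`gamma_i / gain_i`, since the channel output scales as `1 / gamma_i`).
#'
#' @param pred Predicted `valence_curves` (from [predicted_valences()]).
#' @param ref Reference `valence_curves` on the same grid.
#' @return List with `gammas` (length 2: rg, yb channels), `gains`, and
#'   `fitted` (the rescaled curves).
#' @export
fit_gammas <- function(pred, ref) {
  fitted <- scale_to_reference(pred, ref)
  gains <- fitted$gains
  list(gammas = 1 / gains, gains = gains, fitted = fitted)
}

#' Reassign instrumental complement weights to the cancelling lights
#'
#' When a complement is non-spectral (the auxiliary magenta), the physical
#' instrumental light used on that axis is not itself a cancellation light of
#' interest; its signed contribution can always be bookkept as the
#' opposite-signed contribution of its partner cancelling light on the same
#' axis. Curve values are unchanged (the axis curve is the difference of the
#' pair); only the per-light weight columns move.
#'
#' @param curves A `valence_curves` carrying per-light weights and a light
#'   set with purple flags (see [complementary_light_set()]).
#' @return The `valence_curves` with reassigned weight columns.
#' @export
assign_instrumental_to_cancelling <- function(curves) {
  stopifnot(inherits(curves, "valence_curves"))
  lights <- curves$lights
  W <- curves$per_light_weights
  if (is.null(lights) || is.null(W)) return(curves)
  purple <- lights$purple
  if (is.null(purple) || !any(purple)) return(curves)
  axes <- lights$axes
  for (k in which(purple)) {
    prim <- axes[[k]][1]; part <- axes[[k]][2]
    W[, prim] <- W[, prim] - W[, part]
    W[, part] <- 0
  }
  curves$per_light_weights <- W
  curves
}

#' Complementary cancellation light set
#'
#' Builds the four lights of a change-of-basis style configuration: the two
#' primaries at `lambda1` and `lambda2 = lambda1 + delta`, plus their
#' complements. A spectral complement becomes a quasi-monochromatic light at
#' the complementary wavelength; a purple complement becomes an auxiliary
#' magenta — the physical mixture of narrow lights at the two spectral
#' extremes whose chromaticity is closest to the required purple-line point.
#'
#' Lights are ordered (primary1, primary2, partner1, partner2) with axes
#' (1,3) and (2,4), so the downstream valence combination matches the
#' classical blue/green/yellow/red roles.
#'
#' @param lambda1_nm,delta_nm Configuration; `lambda2 = lambda1 + delta`.
#' @param grid Working [wl_grid()].
#' @param cmfs `observer_cmfs` used for complement geometry.
#' @param white Grey reference [spd()].
#' @param height,sigma_nm Gaussian height and width of the lights.
#' @return A `cancellation_lights` object with extra fields `purple`
#'   (per-axis flags) and `complements`.
#' @export
complementary_light_set <- function(lambda1_nm, delta_nm, grid = wl_grid(),
                                    cmfs, white, height = 5, sigma_nm = 5) {
  lambda2_nm <- lambda1_nm + delta_nm
  w_chrom <- chromaticity_of(spectrum_to_tristimulus(white, cmfs))
  comp1 <- complementary_wavelength(lambda1_nm, w_chrom, cmfs)
  comp2 <- complementary_wavelength(lambda2_nm, w_chrom, cmfs)
  mk <- function(ci) {
    if (ci$kind == "spectral")
      quasi_mono(grid, ci$wavelength_nm, height, sigma_nm, pedestal = 0)
    else
      magenta_light(ci$chromaticity, grid, cmfs, height, sigma_nm)
  }
  lights <- list(quasi_mono(grid, lambda1_nm, height, sigma_nm, 0),
                 quasi_mono(grid, lambda2_nm, height, sigma_nm, 0),
                 mk(comp1), mk(comp2))
  peaks <- c(lambda1_nm, lambda2_nm,
             if (comp1$kind == "spectral") comp1$wavelength_nm else NA_real_,
             if (comp2$kind == "spectral") comp2$wavelength_nm else NA_real_)
  structure(list(lights = lights, peaks = peaks,
                 axes = list(axis1 = c(1, 3), axis2 = c(2, 4)),
                 purple = c(comp1$kind == "purple", comp2$kind == "purple"),
                 complements = list(comp1, comp2),
                 height = height, sigma_nm = sigma_nm,
                 labels = c("blue", "green", "yellow", "red")),
            class = "cancellation_lights")
}

# physical stand-in for a purple-line chromaticity: mixture of narrow lights
# at the spectral extremes, mixed to the closest point on their chromaticity
# segment, scaled to the energy of a single cancellation light
magenta_light <- function(target_chrom, grid, cmfs, height, sigma_nm) {
  gS <- quasi_mono(grid, grid$start_nm, height, sigma_nm, 0)
  gL <- quasi_mono(grid, grid$stop_nm, height, sigma_nm, 0)
  tS <- as.numeric(spectrum_to_tristimulus(gS, cmfs))
  tL <- as.numeric(spectrum_to_tristimulus(gL, cmfs))
  cS <- chromaticity_of(tS); cL <- chromaticity_of(tL)
  seg <- cL - cS
  s <- sum((target_chrom - cS) * seg) / sum(seg * seg)
  s <- min(max(s, 0), 1)
  # tristimulus-sum weights reproduce chromaticities affinely
  a <- (1 - s) / sum(tS); b <- s / sum(tL)
  mix <- a * gS$radiance + b * gL$radiance
  e1 <- sum(quasi_mono(grid, 550, height, sigma_nm, 0)$radiance)
  out <- spd(grid, mix * e1 / sum(mix))
  attr(out, "peak_nm") <- NA_real_
  out
}
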