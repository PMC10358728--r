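#' Resolved configuration for a simulation run
#'
#' Collects every tunable of the pipeline with its default, so a run is fully
#' described by one object (and one seed). Defaults are the study
#' conditions: 400--700 nm grid at 5 nm, equienergetic grey reference of unit
#' radiance that doubles as the stimulus background, quasi-monochromatic
#' lights of Gaussian height 5 and width 5 nm with equal initial energies,
#' classical cancellation wavelengths 475/500/580/700 nm, a dense analytic
#' scan (lambda1 420--520 nm step 5, delta 5--60 nm step 5) and a coarse
#' network scan (step 15 nm both ways, on a 10 nm curve sweep).
#'
#' @param grid Working [wl_grid()].
#' @param white_radiance Radiance of the equienergetic grey reference (and of
#'   the stimulus background).
#' @param height,sigma_nm Gaussian height and width of all quasi-monochromatic
#'   lights.
#' @param classical_peaks The classical cancellation wavelengths (nm).
#' @param gamma_display,headroom Display parameters for the digital RGB space.
#' @param opt An [optimizer_config()].
#' @param analytic_lambda1,analytic_delta Analytic scan grids (nm).
#' @param network_lambda1,network_delta Network scan grids (nm).
#' @param network_curve_step Wavelength step (nm) of the cancellation sweep
#'   used inside network-scan cells.
#' @param seed Seed for the run's stochastic elements (permutation tests).
#' @return A list of class `hc_config` with resolved fields, including the
#'   observer (`cmfs`), the white [spd()], [space_params()] and the packaged
#'   reference valence curves.
#' @export
hc_config <- function(grid = wl_grid(),
                      white_radiance = 1,
                      height = 5, sigma_nm = 5,
                      classical_peaks = c(475, 500, 580, 700),
                      gamma_display = 2.2, headroom = 4,
                      opt = optimizer_config(),
                      analytic_lambda1 = seq(420, 520, by = 5),
                      analytic_delta = seq(5, 60, by = 5),
                      network_lambda1 = seq(420, 495, by = 15),
                      network_delta = seq(15, 60, by = 15),
                      network_curve_step = 10,
                      seed = 0) {
  cmfs <- load_observer("cie1931_2deg", grid)
  white <- flat_spectrum(grid, white_radiance)
  params <- space_params(as.numeric(spectrum_to_tristimulus(white, cmfs)),
                         gamma_display = gamma_display, headroom = headroom)
  structure(list(grid = grid, cmfs = cmfs, white = white, params = params,
                 ref = jh_reference_valences(grid),
                 white_radiance = white_radiance,
                 height = height, sigma_nm = sigma_nm,
                 classical_peaks = classical_peaks,
                 gamma_display = gamma_display, headroom = headroom,
                 opt = opt,
                 analytic_lambda1 = analytic_lambda1,
                 analytic_delta = analytic_delta,
                 network_lambda1 = network_lambda1,
                 network_delta = network_delta,
                 network_curve_step = network_curve_step,
                 seed = seed),
            class = "hc_config")
}

identity_net_for <- function(cfg, space) {
  identity_network(cfg$cmfs, space, cfg$params)
}

#' Classical-setting experiments in three color representations
#'
#' Runs the full cancellation sweep with the classical lights for identity
#' networks whose input representations are, by default, device digital RGB,
#' cone LMS and opponent ATD. Each curve set is gain-fitted to the packaged
#' reference; pairwise Pearson correlations between the experiments (on the
#' concatenated rg and yb curves) and residual summaries are reported.
#'
#' @param cfg An [hc_config()].
#' @param spaces Character vector of front-end space labels.
#' @return List with `curves` (named list of `valence_curves`),
#'   `correlations` (matrix), `max_residual`, `lights`.
#' @export
run_classical_experiments <- function(cfg,
                                      spaces = c("rgb_digital", "lms", "atd")) {
  stopifnot(inherits(cfg, "hc_config"))
  lights <- cancellation_lights(cfg$grid, cfg$classical_peaks,
                                cfg$height, cfg$sigma_nm)
  curves <- list()
  for (sp in spaces) {
    res <- try(run_cancellation_curves(cfg$grid, lights,
                                       identity_net_for(cfg, sp),
                                       cfg$white, cfg$opt), silent = TRUE)
    if (inherits(res, "try-error")) {
      warning(sprintf("experiment in space '%s' failed: %s", sp, res))
      next
    }
    curves[[sp]] <- scale_to_reference(res, cfg$ref)
  }
  n <- length(curves)
  corr <- matrix(NA_real_, n, n, dimnames = list(names(curves), names(curves)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    corr[i, j] <- stats::cor(c(curves[[i]]$rg, curves[[i]]$yb),
                             c(curves[[j]]$rg, curves[[j]]$yb))
  }
  # residuals relative to the response norm of the grey reference, per space
  rel_resid <- vapply(names(curves), function(sp) {
    w_norm <- match_distance(response(identity_net_for(cfg, sp), cfg$white),
                             tristim(c(0, 0, 0), sp))
    max(curves[[sp]]$residual) / w_norm
  }, numeric(1))
  list(curves = curves, correlations = corr,
       max_residual = max(vapply(curves, function(cv) max(cv$residual),
                                 numeric(1))),
       max_rel_residual = max(rel_resid),
       lights = lights)
}

# Relative MSE of gain-fitted curves against the reference: normalized by the
# reference power so it is invariant to joint rescaling of the reference.
# Wavelengths whose match did not converge are excluded from both the gain
# fit and the error; a curve with no converged samples yields NA.
valence_mse <- function(curves, ref) {
  keep <- if (is.null(curves$converged)) rep(TRUE, length(curves$rg))
          else curves$converged
  if (!any(keep)) return(NA_real_)
  gain <- function(cv, rf) sum(cv[keep] * rf[keep]) / sum(cv[keep]^2)
  g_rg <- gain(curves$rg, ref$rg)
  g_yb <- gain(curves$yb, ref$yb)
  num <- mean(c((g_rg * curves$rg[keep] - ref$rg[keep])^2,
                (g_yb * curves$yb[keep] - ref$yb[keep])^2))
  den <- mean(c(ref$rg[keep]^2, ref$yb[keep]^2))
  num / den
}

#' Error of one cancellation-light configuration
#'
#' Builds the four lights of the configuration `(lambda1, lambda2 =
#' lambda1 + delta, complements)`, obtains valence curves by the requested
#' route, gain-fits them to the packaged reference and returns the mean
#' squared error over both curves, normalized by the reference power.
#'
#' @param lambda1_nm,delta_nm Configuration (nm).
#' @param cfg An [hc_config()].
#' @param method `"analytic"` (change-of-basis prediction) or `"network"`
#'   (identity-network simulation).
#' @param option Basis option (1 or 2), analytic route.
#' @param space Front-end space, network route.
#' @return A non-negative scalar, or `NA` for a degenerate configuration.
#' @export
error_of_config <- function(lambda1_nm, delta_nm, cfg, method = "analytic",
                            option = 2, space = "lms") {
  res <- try({
    if (method == "analytic") {
      basis <- build_primaries(lambda1_nm, delta_nm, option, cfg$white, cfg$cmfs)
      pred <- predicted_valences(cfg$cmfs, change_of_basis_matrix(basis))
      valence_mse(pred, cfg$ref)
    } else if (method == "network") {
      sweep_grid <- wl_grid(cfg$grid$start_nm, cfg$grid$stop_nm,
                            cfg$network_curve_step)
      lights <- complementary_light_set(lambda1_nm, delta_nm, cfg$grid,
                                        cfg$cmfs, cfg$white,
                                        cfg$height, cfg$sigma_nm)
      net <- identity_net_for(cfg, space)
      curves <- suppressWarnings(
        run_cancellation_curves(sweep_grid, lights, net, cfg$white, cfg$opt))
      valence_mse(curves, jh_reference_valences(sweep_grid))
    } else stop("error_of_config: unknown method")
  }, silent = TRUE)
  if (inherits(res, "try-error")) NA_real_ else res
}

#' Scan an error surface over cancellation-light configurations
#'
#' Evaluates [error_of_config()] on a `(lambda1, delta)` grid. The analytic
#' route is cheap and defaults to a dense grid; the network route simulates
#' full cancellation sweeps per cell and defaults to a coarse grid.
#' Degenerate cells are `NA` and excluded from the minima search.
#'
#' @param cfg An [hc_config()].
#' @param method `"analytic"` or `"network"`.
#' @param option Basis option (analytic route).
#' @param space Front-end space (network route).
#' @param lambda1,delta Scan grids (nm); defaults taken from `cfg` by method.
#' @return Object of class `error_surface`: `lambda1`, `delta`, `mse` matrix
#'   (rows = lambda1), `method`, `option`, `space`, `minima`.
#' @export
scan_surface <- function(cfg, method = "analytic", option = 2, space = "lms",
                         lambda1 = NULL, delta = NULL) {
  stopifnot(inherits(cfg, "hc_config"))
  if (is.null(lambda1))
    lambda1 <- if (method == "analytic") cfg$analytic_lambda1 else cfg$network_lambda1
  if (is.null(delta))
    delta <- if (method == "analytic") cfg$analytic_delta else cfg$network_delta
  mse <- matrix(NA_real_, length(lambda1), length(delta),
                dimnames = list(lambda1, delta))
  for (i in seq_along(lambda1)) for (j in seq_along(delta)) {
    mse[i, j] <- error_of_config(lambda1[i], delta[j], cfg, method, option, space)
  }
  surf <- structure(list(lambda1 = lambda1, delta = delta, mse = mse,
                         method = method, option = option, space = space),
                    class = "error_surface")
  surf$minima <- find_minima(surf)
  surf
}

#' @export
print.error_surface <- function(x, ...) {
  gm <- x$minima[[1]]
  cat(sprintf("<error_surface> %s (option %s, space %s): %dx%d cells; global min at lambda1=%g, lambda2=%g (mse %.4g)\n",
              x$method, x$option, x$space, length(x$lambda1), length(x$delta),
              gm$lambda1_nm, gm$lambda1_nm + gm$delta_nm, gm$mse))
  invisible(x)
}

#' Local minima of an error surface
#'
#' Cells whose error is less than or equal to that of all valid 8-neighbors,
#' sorted by ascending error (global minimum first). On a plateau every
#' interior cell qualifies.
#'
#' @param surface An `error_surface`.
#' @return List of `list(lambda1_nm, delta_nm, mse)`.
#' @export
find_minima <- function(surface) {
  m <- surface$mse
  if (all(!is.finite(m))) stop("find_minima: no valid cells")
  out <- list()
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    v <- m[i, j]
    if (!is.finite(v)) next
    nb <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m))
        nb <- c(nb, m[ii, jj])
    }
    nb <- nb[is.finite(nb)]
    if (length(nb) == 0 || all(v <= nb))
      out[[length(out) + 1]] <- list(lambda1_nm = surface$lambda1[i],
                                     delta_nm = surface$delta[j], mse = v)
  }
  out[order(vapply(out, function(u) u$mse, numeric(1)))]
}

#' Monotone-trend test of error vs distance from the classical setting
#'
#' Spearman rank correlation between cell errors and the chromaticity-plane
#' distance of each configuration from the classical one (sum of the
#' distances between the two cancellation lights' chromaticities and the
#' classical 475/500 nm pair), with a permutation p-value.
#'
#' @param surface An `error_surface`.
#' @param cfg An [hc_config()].
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation draw (defaults to the config seed).
#' @return List with `rho`, `p_value`, `n` (valid cells).
#' @export
surface_trend_test <- function(surface, cfg, n_perm = 1000, seed = cfg$seed) {
  locus <- spectral_locus(cfg$cmfs)
  cl1 <- locus_chromaticity(475, locus)
  cl2 <- locus_chromaticity(500, locus)
  cells <- expand.grid(i = seq_along(surface$lambda1),
                       j = seq_along(surface$delta))
  mse <- mapply(function(i, j) surface$mse[i, j], cells$i, cells$j)
  dist <- mapply(function(i, j) {
    l1 <- surface$lambda1[i]; l2 <- l1 + surface$delta[j]
    c1 <- locus_chromaticity(l1, locus); c2 <- locus_chromaticity(l2, locus)
    sqrt(sum((c1 - cl1)^2)) + sqrt(sum((c2 - cl2)^2))
  }, cells$i, cells$j)
  ok <- is.finite(mse)
  mse <- mse[ok]; dist <- dist[ok]
  rho <- stats::cor(mse, dist, method = "spearman")
  set.seed(seed)
  perm <- replicate(n_perm, stats::cor(sample(mse), dist, method = "spearman"))
  list(rho = rho, p_value = (1 + sum(perm >= rho)) / (n_perm + 1),
       n = sum(ok))
}

#' @export
as.data.frame.error_surface <- function(x, ...) {
  d <- expand.grid(lambda1_nm = x$lambda1, delta_nm = x$delta)
  d$lambda2_nm <- d$lambda1_nm + d$delta_nm
  d$mse <- as.vector(x$mse)
  d
}

#' Run the full study and write its artifacts
#'
#' Reproduces the main pipeline in one call: classical-setting experiments in
#' three representations, the dense analytic option-2 error surface, and its
#' minima. Writes `config.json`, `curves.csv` (classical LMS curves),
#' `surface.csv`, `minima.json` into `outdir`. Outputs contain no timestamps,
#' so a rerun with the same configuration and seed is byte-identical.
#'
#' @param outdir Output directory (created if needed).
#' @param cfg An [hc_config()].
#' @return Invisibly, a list with the experiments, surface and minima.
#' @export
run_full_study <- function(outdir, cfg = hc_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  resolved <- list(grid = c(cfg$grid$start_nm, cfg$grid$stop_nm, cfg$grid$step_nm),
                   white_radiance = cfg$white_radiance,
                   height = cfg$height, sigma_nm = cfg$sigma_nm,
                   classical_peaks = cfg$classical_peaks,
                   gamma_display = cfg$gamma_display, headroom = cfg$headroom,
                   analytic_lambda1 = cfg$analytic_lambda1,
                   analytic_delta = cfg$analytic_delta,
                   network_lambda1 = cfg$network_lambda1,
                   network_delta = cfg$network_delta,
                   network_curve_step = cfg$network_curve_step,
                   seed = cfg$seed)
  jsonlite::write_json(resolved, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  classical <- run_classical_experiments(cfg, spaces = "lms")
  write_curves_csv(classical$curves$lms, file.path(outdir, "curves.csv"))
  surf <- scan_surface(cfg, method = "analytic", option = 2)
  utils::write.csv(as.data.frame(surf), file.path(outdir, "surface.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(surf$minima, file.path(outdir, "minima.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(classical = classical, surface = surf, minima = surf$minima))
}
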