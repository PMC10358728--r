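#' Cancellation light set
#'
#' The four quasi-monochromatic cancellation lights of the matching task,
#' with equal initial energies (equal Gaussian heights). Lights are pure
#' narrow Gaussians (no pedestal): the weights scale the Gaussian heights, as
#' in the simulated experiment, while the background is carried by the test
#' stimulus and the grey reference.
#'
#' The four lights are organized into two opponent axes. Sorting the peaks in
#' increasing wavelength, axis 1 pairs the 1st and 3rd lights and axis 2 the
#' 2nd and 4th; for the classical set (475, 500, 580, 700 nm) this gives the
#' blue/yellow and green/red pairs. Each axis is oriented (primary = shorter
#' member, partner = longer member) and its valence curve is
#' `w_partner - w_primary`.
#'
#' @param grid Working [wl_grid()].
#' @param peaks Four distinct peak wavelengths (nm) inside the grid. Default:
#'   the classical cancellation wavelengths 475, 500, 580, 700 nm.
#' @param height Common Gaussian height (equal initial energy).
#' @param sigma_nm Gaussian width.
#' @return An object of class `cancellation_lights`: list with `lights` (four
#'   [spd()]s), `peaks`, `axes` (two index pairs `c(primary, partner)`),
#'   `height`, `sigma_nm`, `labels`.
#' @export
cancellation_lights <- function(grid = wl_grid(),
                                peaks = c(475, 500, 580, 700),
                                height = 5, sigma_nm = 5) {
  if (length(peaks) != 4 || anyDuplicated(peaks))
    stop("cancellation_lights: need four distinct peak wavelengths")
  ord <- order(peaks)
  peaks <- peaks[ord]
  lights <- lapply(peaks, function(p) quasi_mono(grid, p, height, sigma_nm, pedestal = 0))
  structure(list(lights = lights, peaks = peaks,
                 axes = list(axis1 = c(1, 3), axis2 = c(2, 4)),
                 purple = c(FALSE, FALSE),
                 height = height, sigma_nm = sigma_nm,
                 labels = c("blue", "green", "yellow", "red")),
            class = "cancellation_lights")
}

#' @export
print.cancellation_lights <- function(x, ...) {
  cat(sprintf("<cancellation_lights> peaks %s nm, height %g, sigma %g nm\n",
              paste(round(x$peaks, 1), collapse = "/"), x$height, x$sigma_nm))
  invisible(x)
}

#' Optimizer configuration for the matching task
#'
#' First-order descent on the squared match distance, started from zero
#' weight deviations (equal initial light energies). Observers that are
#' linear end to end use conjugate-gradient descent with exact steps; other
#' observers use nonlinear conjugate gradient (Polak-Ribiere) with
#' finite-difference gradients and Armijo backtracking, which degrades
#' gracefully to plain gradient descent. Conjugate directions matter:
#' configurations whose cancellation lights are nearly parallel in
#' tristimulus space (e.g. two close complements) make the quadratic so
#' ill-conditioned that steepest descent cannot converge in any reasonable
#' iteration budget, while conjugate gradient solves the 4-weight problem in
#' a handful of steps. Descent runs in a variable scaled by the tristimulus
#' norms of the lights (diagonal preconditioning); the scaling cannot change
#' the solution set, and the canonical (minimum-norm) representative
#' reported after null-space projection is scaling-independent.
#'
#' @param max_iter Iteration cap; non-convergence is flagged, never an error.
#' @param tol Relative decrease of the squared distance below which descent
#'   stops.
#' @param fd_step Relative finite-difference step for nonlinear observers
#'   (analytic gradients are used whenever front end and transform are
#'   jointly linear).
#' @param armijo Sufficient-decrease constant for backtracking.
#' @return A list of class `optimizer_config`.
#' @export
optimizer_config <- function(max_iter = 10000, tol = 1e-18,
                             fd_step = 1e-6, armijo = 1e-4) {
  structure(list(max_iter = max_iter, tol = tol, fd_step = fd_step,
                 armijo = armijo), class = "optimizer_config")
}

# front-end tristimulus (xyz for the CIE observer) of a list of spds -> 3 x n
front_matrix <- function(spds, cmfs) {
  vapply(spds, function(s) as.numeric(spectrum_to_tristimulus(s, cmfs)),
         numeric(3))
}

# test stimulus: the grey background plus a narrow Gaussian at lambda
make_test_stimulus <- function(lambda_nm, white, height, sigma_nm) {
  g <- quasi_mono(white$grid, lambda_nm, height, sigma_nm, pedestal = 0)
  spd(white$grid, white$radiance + g$radiance)
}

#' Solve the hue-cancellation match at a single wavelength
#'
#' Finds the signed cancellation-light energies that make the test stimulus
#' (grey background plus a narrow Gaussian at `lambda_nm`, same height and
#' width as the cancellation lights) match the grey reference in the
#' network's output representation, by gradient descent on the squared match
#' distance. Positive weights add light to the test side, negative weights to
#' the reference side (physical superposition is always positive).
#'
#' @param lambda_nm Test wavelength (nm), inside the grid.
#' @param lights A [cancellation_lights()] set.
#' @param net An [observer_network()].
#' @param white Grey reference [spd()] (also the stimulus background).
#' @param opt An [optimizer_config()].
#' @param test_height Gaussian height of the test stimulus; defaults to the
#'   cancellation lights' height. `0` makes the test stimulus the grey
#'   reference itself.
#' @return A list of class `cancellation_result`: `wavelength_nm`, `weights`
#'   (signed energies, one per light), `residual` (match distance at the
#'   returned weights), `iterations`, `converged`.
#' @export
cancel_single <- function(lambda_nm, lights, net, white,
                          opt = optimizer_config(),
                          test_height = lights$height) {
  stopifnot(inherits(lights, "cancellation_lights"),
            inherits(net, "observer_network"), inherits(white, "spd"))
  test <- make_test_stimulus(lambda_nm, white, test_height, lights$sigma_nm)
  A_front <- front_matrix(lights$lights, net$cmfs)       # 3 x 4, front space
  t_test  <- as.numeric(spectrum_to_tristimulus(test, net$cmfs))
  t_white <- as.numeric(spectrum_to_tristimulus(white, net$cmfs))
  front_space <- tristim_space(spectrum_to_tristimulus(white, net$cmfs))
  if (front_space != "xyz") {  # express the front end in xyz; all space maps start there
    to_xyz <- function(v) as.numeric(to_space(tristim(v, front_space), "xyz", net$params))
    A_front <- vapply(seq_len(ncol(A_front)), function(i) to_xyz(A_front[, i]),
                      numeric(3))
    t_test <- to_xyz(t_test); t_white <- to_xyz(t_white)
    front_space <- "xyz"
  }

  scale <- apply(A_front, 2, function(v) sqrt(sum(v^2)))
  scale[scale < 1e-300] <- 1

  linear <- !is.null(net$linear) && is_linear_space(net$space)
  if (linear) {
    B <- net$linear %*% space_matrix(net$space, net$params)
    M <- B %*% sweep(A_front, 2, scale, "/")
    cvec <- drop(B %*% (t_test - t_white))
    fobj <- function(u) { r <- drop(M %*% u) + cvec; sum(r * r) }
    gobj <- function(u) drop(2 * crossprod(M, drop(M %*% u) + cvec))
  } else {
    fobj <- function(u) {
      w <- u / scale
      pos <- pmax(w, 0); neg <- pmax(-w, 0)
      rt <- response_from_front(net, tristim(t_test + drop(A_front %*% pos),
                                             space = front_space))
      rr <- response_from_front(net, tristim(t_white + drop(A_front %*% neg),
                                             space = front_space))
      match_distance(rt, rr)^2
    }
    gobj <- function(u) {
      f0 <- fobj(u)
      g <- numeric(4)
      for (i in 1:4) {
        du <- opt$fd_step * max(1, abs(u[i]))
        up <- u; up[i] <- up[i] + du
        g[i] <- (fobj(up) - f0) / du
      }
      g
    }
  }

  if (linear) {
    # conjugate-gradient descent on the preconditioned quadratic; starting
    # from zero it stays in the row space, hence converges to the
    # minimum-norm solution of the underdetermined match
    u <- numeric(4)
    r <- -drop(crossprod(M, cvec))          # -(1/2) gradient at u = 0
    d <- r
    rr <- sum(r * r)
    r0 <- max(rr, .Machine$double.eps)
    iter <- 0
    while (iter < opt$max_iter && rr > 1e-28 * r0) {
      iter <- iter + 1
      Md <- drop(M %*% d)
      dHd <- sum(Md * Md)
      if (dHd <= 0) break
      a <- rr / dHd
      u <- u + a * d
      r <- r - a * drop(crossprod(M, Md))
      rr_new <- sum(r * r)
      d <- r + (rr_new / rr) * d
      rr <- rr_new
      if (iter %% 8 == 0) {  # periodic restart clears accumulated roundoff
        r <- -drop(crossprod(M, drop(M %*% u) + cvec))
        d <- r
        rr <- sum(r * r)
      }
    }
    f <- fobj(u)
    converged <- rr <= 1e-20 * r0 || f <= 1e-16 * max(sum(cvec^2), .Machine$double.eps)
  } else {
    # nonlinear conjugate gradient (Polak-Ribiere, non-negative beta) with
    # Armijo backtracking; reduces to plain gradient descent when beta = 0
    u <- numeric(4)
    f <- fobj(u)
    f_scale <- max(f, .Machine$double.eps)
    g <- gobj(u)
    d <- -g
    alpha <- 1
    iter <- 0
    converged <- FALSE
    while (iter < opt$max_iter) {
      iter <- iter + 1
      slope <- sum(g * d)
      if (slope >= 0) { d <- -g; slope <- -sum(g * g) }
      if (-slope <= 1e-30 * f_scale) { converged <- TRUE; break }
      alpha <- min(alpha * 2, 1e6)
      ok <- FALSE
      for (bt in 1:80) {
        u_new <- u + alpha * d
        f_new <- fobj(u_new)
        if (f_new <= f + opt$armijo * alpha * slope) { ok <- TRUE; break }
        alpha <- alpha / 2
      }
      if (!ok) break
      improved <- f - f_new
      g_new <- gobj(u_new)
      beta <- max(0, sum(g_new * (g_new - g)) / max(sum(g * g), 1e-300))
      if (iter %% 10 == 0) beta <- 0
      d <- -g_new + beta * d
      u <- u_new; f <- f_new; g <- g_new
      if (improved <= opt$tol * f_scale) { converged <- TRUE; break }
    }
    if (!converged && f <= 1e-14 * f_scale) converged <- TRUE
  }

  w <- u / scale
  test_ref <- signed_superposition(test, lights$lights, w, white)
  resid <- match_distance(response(net, test_ref$test_side),
                          response(net, test_ref$reference_side))
  structure(list(wavelength_nm = lambda_nm, weights = w, residual = resid,
                 iterations = iter, converged = converged),
            class = "cancellation_result")
}

#' Closed-form cancellation weights for linear observers
#'
#' Independent oracle for the matching task: when front end and transform are
#' jointly linear the match condition is the 3-equation, 4-unknown linear
#' system `sum_i w_i R'(E_ci) = R'(W) - R'(E_lambda)`, solved here by the
#' minimum-norm solution (Moore-Penrose pseudo-inverse).
#'
#' @inheritParams cancel_single
#' @return A length-4 weight vector.
#' @export
closed_form_weights <- function(lambda_nm, lights, net, white,
                                test_height = lights$height) {
  stopifnot(inherits(net, "observer_network"))
  if (is.null(net$linear) || !is_linear_space(net$space))
    stop("closed_form_weights: network must be linear (front end and transform)")
  test <- make_test_stimulus(lambda_nm, white, test_height, lights$sigma_nm)
  B <- net$linear %*% space_matrix(net$space, net$params)
  t_w <- spectrum_to_tristimulus(white, net$cmfs)
  front_space <- tristim_space(t_w)
  A_front <- front_matrix(lights$lights, net$cmfs)
  if (front_space != "xyz") {
    to_xyz <- function(v) as.numeric(to_space(tristim(v, front_space), "xyz", net$params))
    A_front <- vapply(seq_len(ncol(A_front)), function(i) to_xyz(A_front[, i]),
                      numeric(3))
  }
  A <- B %*% A_front
  if (qr(A)$rank < 3)
    stop("closed_form_weights: cancellation-light tristimulus matrix has rank < 3")
  d_front <- as.numeric(t_w) - as.numeric(spectrum_to_tristimulus(test, net$cmfs))
  if (front_space != "xyz")
    d_front <- as.numeric(to_space(tristim(d_front, front_space), "xyz", net$params))
  b <- drop(B %*% d_front)
  drop(MASS::ginv(A) %*% b)
}

#' Canonical (minimum-norm) weight representative
#'
#' With four cancellation lights and a rank-3 tristimulus matrix the match
#' condition leaves one free direction: jointly increasing the energies of
#' opposing lights in the null combination changes nothing. This projects a
#' weight vector onto the orthogonal complement of that null direction,
#' yielding the unique minimum-norm representative of its solution class, so
#' weights found by different observers (or optimizers) become comparable.
#'
#' @param w Length-4 weight vector.
#' @param lights A [cancellation_lights()] set.
#' @param cmfs The front-end `observer_cmfs` in which the light tristimulus
#'   matrix (and hence the null direction) is computed.
#' @return A length-4 weight vector orthogonal to the null direction.
#' @export
canonicalize_weights <- function(w, lights, cmfs) {
  A <- front_matrix(lights$lights, cmfs)
  sv <- svd(A, nu = 0, nv = 4)
  d <- sv$d
  if (d[3] <= 1e-10 * d[1])
    stop("canonicalize_weights: null space dimension != 1 (rank-deficient lights)")
  n <- sv$v[, 4]
  w - sum(w * n) * n
}

new_valence_curves <- function(grid, rg, yb, weights = NULL, residual = NULL,
                               converged = NULL, lights = NULL,
                               gains = c(rg = 1, yb = 1), source = NULL) {
  structure(list(grid = grid, rg = rg, yb = yb, per_light_weights = weights,
                 residual = residual, converged = converged, lights = lights,
                 gains = gains, source = source),
            class = "valence_curves")
}

#' @export
print.valence_curves <- function(x, ...) {
  cat(sprintf("<valence_curves> %d samples on %g-%g nm%s\n",
              length(x$rg), x$grid$start_nm, x$grid$stop_nm,
              if (!is.null(x$source)) paste0(" [", x$source, "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.valence_curves <- function(x, ...) {
  d <- data.frame(wavelength_nm = x$grid$wl, rg = x$rg, yb = x$yb)
  if (!is.null(x$per_light_weights)) {
    w <- x$per_light_weights
    colnames(w) <- paste0("w_", if (!is.null(x$lights)) x$lights$labels
                          else seq_len(ncol(w)))
    d <- cbind(d[1], as.data.frame(w), d[-1])
  }
  if (!is.null(x$residual)) d$residual <- x$residual
  if (!is.null(x$converged)) d$converged <- x$converged
  d
}

#' Run a full cancellation sweep and assemble valence curves
#'
#' Solves the matching task at every wavelength of the sweep, canonicalizes
#' the weights, and combines the four per-light weight functions into the two
#' opponent valence curves: each axis contributes `w_partner - w_primary`
#' (see [cancellation_lights()]), the red-green curve is the axis whose
#' primary has the longer wavelength, and one overall sign is fixed so that
#' the red-green valence is positive at the long-wavelength end (red
#' positive, matching the orientation of the human curves).
#'
#' Non-converged wavelengths never abort the sweep; they are flagged in the
#' result and summarized in a warning.
#'
#' @param grid Sweep [wl_grid()] (test wavelengths; the working grid of the
#'   stimuli is taken from the lights).
#' @inheritParams cancel_single
#' @param canonical Project each solution onto its minimum-norm
#'   representative (default TRUE).
#' @return A `valence_curves` object carrying the weight matrix, residuals
#'   and convergence flags.
#' @export
run_cancellation_curves <- function(grid, lights, net, white,
                                    opt = optimizer_config(),
                                    canonical = TRUE) {
  wl <- grid$wl
  W <- matrix(NA_real_, length(wl), 4)
  resid <- numeric(length(wl))
  conv <- logical(length(wl))
  for (k in seq_along(wl)) {
    res <- cancel_single(wl[k], lights, net, white, opt)
    w <- res$weights
    if (canonical) w <- canonicalize_weights(w, lights, net$cmfs)
    W[k, ] <- w
    resid[k] <- res$residual
    conv[k] <- res$converged
  }
  if (any(!conv))
    warning(sprintf("run_cancellation_curves: %d of %d wavelengths did not converge",
                    sum(!conv), length(wl)))
  crv <- combine_weights(wl, W, lights)
  new_valence_curves(grid, crv$rg, crv$yb, weights = W, residual = resid,
                     converged = conv, lights = lights,
                     source = net$name)
}

# Which of the two axes plays the red-green role. A purple (magenta)
# complement marks the green-magenta axis, i.e. red-green; when neither or
# both complements are purple, the axis whose primary light has the longer
# wavelength takes the role (ties broken by axis order).
rg_axis_of <- function(purple, peak1, peak2) {
  if (xor(purple[1], purple[2])) return(if (purple[1]) 1L else 2L)
  if (peak2 >= peak1) 2L else 1L
}

# combine the four weight functions into oriented rg / yb curves
combine_weights <- function(wl, W, lights) {
  ax <- lights$axes
  curve1 <- W[, ax$axis1[2]] - W[, ax$axis1[1]]
  curve2 <- W[, ax$axis2[2]] - W[, ax$axis2[1]]
  purple <- if (is.null(lights$purple)) c(FALSE, FALSE) else lights$purple
  rg_ax <- rg_axis_of(purple, lights$peaks[ax$axis1[1]], lights$peaks[ax$axis2[1]])
  if (rg_ax == 2L) { rg <- curve2; yb <- curve1 } else { rg <- curve1; yb <- curve2 }
  k650 <- which.min(abs(wl - 650))
  if (rg[k650] < 0) { rg <- -rg; yb <- -yb }
  list(rg = rg, yb = yb)
}

#' Least-squares gain fit of valence curves to a reference
#'
#' Applies the closed-form per-curve gain `<curve, ref> / <curve, curve>` that
#' minimizes the squared error to the reference; the free per-curve scale of
#' the valence functions carries no shape information. Gains are recorded in
#' the result.
#'
#' @param curves,ref `valence_curves` on the same grid.
#' @return The rescaled `valence_curves` with updated `gains`.
#' @export
scale_to_reference <- function(curves, ref) {
  stopifnot(inherits(curves, "valence_curves"), inherits(ref, "valence_curves"))
  if (!same_grid(curves$grid, ref$grid))
    stop("scale_to_reference: grids differ")
  g <- c(rg = ls_gain(curves$rg, ref$rg), yb = ls_gain(curves$yb, ref$yb))
  out <- curves
  out$rg <- g["rg"] * curves$rg
  out$yb <- g["yb"] * curves$yb
  out$gains <- g
  out
}

ls_gain <- function(curve, ref) {
  den <- sum(curve^2)
  if (den <= 0) stop("gain fit undefined for an identically-zero curve")
  sum(curve * ref) / den
}

#' Write valence curves as CSV
#'
#' Columns: `wavelength_nm`, per-light weights (when present), `rg`, `yb`,
#' `residual`, `converged`.
#'
#' @param x A `valence_curves` object.
#' @param path Output path.
#' @export
write_curves_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
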