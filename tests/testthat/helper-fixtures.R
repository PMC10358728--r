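# Shared fixtures, computed once per test run and cached. The heavier objects
# (full cancellation sweeps, the coarse network error surface) are reused by
# both the acceptance tests and the module tests.

.fx <- new.env(parent = emptyenv())

fx_get <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

fx_cfg <- function() fx_get("cfg", function() hc_config())

fx_lights <- function() fx_get("lights", function() {
  cancellation_lights(fx_cfg()$grid)
})

# full 5 nm cancellation sweep for an identity network in `space`
fx_classical <- function(space) {
  fx_get(paste0("classical_", space), function() {
    cfg <- fx_cfg()
    run_cancellation_curves(cfg$grid, fx_lights(),
                            identity_network(cfg$cmfs, space, cfg$params),
                            cfg$white)
  })
}

# coarse network error surface (identity net, lms) on the default 6x4 grid
fx_network_surface <- function() {
  fx_get("network_surface", function() {
    scan_surface(fx_cfg(), method = "network", space = "lms")
  })
}

# dense analytic option-2 surface on the default scan grids
fx_analytic_surface <- function() {
  fx_get("analytic_surface", function() {
    scan_surface(fx_cfg(), method = "analytic", option = 2)
  })
}

# sign changes of a curve restricted to [lo, hi] nm
zero_crossings <- function(wl, v, lo, hi) {
  keep <- wl >= lo & wl <= hi
  s <- sign(v[keep])
  s <- s[s != 0]
  sum(diff(s) != 0)
}

# Brute-force complement oracle, independent of the package's ray/segment
# solver: walks the spectral locus on a fine wavelength grid (plus the purple
# line on a fine parameter grid) and returns the boundary point most nearly
# collinear with (and opposite to) the query direction through the white.
brute_force_complement <- function(lambda_nm, white, cmfs, step = 0.1) {
  locus <- spectral_locus(cmfs)
  wl_f <- seq(cmfs$grid$start_nm, cmfs$grid$stop_nm, by = step)
  cf <- cbind(stats::approx(locus[, 1], locus[, 2], xout = wl_f)$y,
              stats::approx(locus[, 1], locus[, 3], xout = wl_f)$y)
  cq <- c(stats::approx(locus[, 1], locus[, 2], xout = lambda_nm)$y,
          stats::approx(locus[, 1], locus[, 3], xout = lambda_nm)$y)
  d <- (cq - white); d <- d / sqrt(sum(d^2))
  score <- function(pt) {
    v <- pt - white
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) return(Inf)
    v <- v / nv
    sum(abs(v + d))  # 0 when exactly opposite the query direction
  }
  sc_spec <- apply(cf, 1, score)
  k <- which.min(sc_spec)
  s_pur <- seq(0, 1, by = 0.001)
  pur <- outer(1 - s_pur, cf[nrow(cf), ]) + outer(s_pur, cf[1, ])
  sc_pur <- apply(pur, 1, score)
  kp <- which.min(sc_pur)
  if (sc_spec[k] <= sc_pur[kp])
    list(kind = "spectral", wavelength_nm = wl_f[k], chromaticity = cf[k, ])
  else
    list(kind = "purple", wavelength_nm = NA_real_, chromaticity = pur[kp, ])
}

# ray-casting point-in-polygon test (polygon as n x 2 matrix)
point_in_polygon <- function(p, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if (((yi > p[2]) != (yj > p[2])) &&
        (p[1] < (xj - xi) * (p[2] - yi) / (yj - yi) + xi)) inside <- !inside
    j <- i
  }
  inside
}
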