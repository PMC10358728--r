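test_that("primary bases are non-degenerate and option 2 is white-orthogonal", {
  cfg <- fx_cfg()
  for (opt in 1:2) {
    b <- build_primaries(475, 25, opt, cfg$white, cfg$cmfs)
    expect_gt(abs(det(b$primaries)), 1e-6)
    # classical-like config: one spectral and one purple complement
    expect_equal(b$complements[[1]]$kind, "spectral")
    expect_equal(b$complements[[2]]$kind, "purple")
  }
  b2 <- build_primaries(475, 25, 2, cfg$white, cfg$cmfs)
  P <- b2$primaries
  expect_lt(abs(sum(P[, 1] * P[, 3])), 1e-10)
  expect_lt(abs(sum(P[, 2] * P[, 3])), 1e-10)
  # the white primary points along the white tristimulus
  w <- as.numeric(spectrum_to_tristimulus(cfg$white, cfg$cmfs))
  expect_lt(max(abs(P[, 3] / sum(P[, 3]) - w / sum(w))), 1e-12)
  expect_error(build_primaries(475, 0, 2, cfg$white, cfg$cmfs), "nonzero")
})

test_that("the change-of-basis matrix inverts the primaries and factorizes by gamma", {
  cfg <- fx_cfg()
  b <- build_primaries(470, 30, 1, cfg$white, cfg$cmfs)
  m <- change_of_basis_matrix(b)
  expect_equal(unclass(m) %*% b$primaries, diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(drop(unclass(m) %*% b$primaries[, 2]), c(0, 1, 0),
               tolerance = 1e-10)
  # doubling gamma_1 halves row 1
  b2 <- b; b2$gammas <- c(2, 1, 1)
  m2 <- change_of_basis_matrix(b2)
  expect_equal(unclass(m2)[1, ], unclass(m)[1, ] / 2, tolerance = 1e-12)
  expect_equal(unclass(m2)[2:3, ], unclass(m)[2:3, ], tolerance = 1e-12)
  # Eq.-style self-consistency: direct inverse vs diag(1/gamma) x
  # (chromaticity matrix inverse), using the unit-sum chromaticity lift
  gam <- colSums(b$primaries)
  R <- sweep(b$primaries, 2, gam, "/")
  b3 <- b; b3$gammas <- c(1.3, 0.6, 2.2)
  m3 <- change_of_basis_matrix(b3)
  alt <- diag(1 / (b3$gammas * gam)) %*% solve(R)
  expect_equal(unclass(m3), alt, tolerance = 1e-10, ignore_attr = TRUE)
  # identity primaries give the identity matrix
  bi <- b
  bi$primaries <- diag(3)
  expect_equal(unclass(change_of_basis_matrix(bi)), diag(3), ignore_attr = TRUE)
})

test_that("predicted valences vanish at the white and reduce to CMFs for m = I", {
  cfg <- fx_cfg()
  b <- build_primaries(475, 25, 2, cfg$white, cfg$cmfs)
  m <- change_of_basis_matrix(b)
  w <- as.numeric(spectrum_to_tristimulus(cfg$white, cfg$cmfs))
  chan <- drop(unclass(m) %*% w)
  expect_lt(max(abs(chan[1:2])), 1e-10 * abs(chan[3]))
  # identity matrix: curves are the raw CMFs (up to orientation flips)
  bi <- b; bi$primaries <- diag(3)
  mi <- change_of_basis_matrix(bi)
  pv <- predicted_valences(cfg$cmfs, mi)
  expect_equal(abs(pv$rg), cfg$cmfs$M[, 2], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(abs(pv$yb), cfg$cmfs$M[, 1], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("predicted curves cross zero at the cancellation wavelengths", {
  cfg <- fx_cfg()
  b <- build_primaries(475, 25, 2, cfg$white, cfg$cmfs)
  pv <- predicted_valences(cfg$cmfs, change_of_basis_matrix(b))
  wl <- cfg$grid$wl
  # rg vanishes on the lambda1 axis (475 nm and its ~577 nm complement)
  expect_lt(abs(pv$rg[wl == 475]), 1e-10)
  expect_equal(zero_crossings(wl, pv$rg, 560, 600), 1)
  # yb vanishes at lambda2 = 500 nm
  expect_lt(abs(pv$yb[wl == 500]), 1e-10)
})

test_that("curve shapes are invariant to the free gamma scales", {
  cfg <- fx_cfg()
  b <- build_primaries(460, 40, 2, cfg$white, cfg$cmfs)
  base <- predicted_valences(cfg$cmfs, change_of_basis_matrix(b))
  set.seed(21)
  for (k in 1:5) {
    bg <- b; bg$gammas <- stats::runif(3, 0.2, 5)
    pg <- predicted_valences(cfg$cmfs, change_of_basis_matrix(bg))
    expect_equal(pg$rg / sqrt(sum(pg$rg^2)), base$rg / sqrt(sum(base$rg^2)),
                 tolerance = 1e-10)
    expect_equal(pg$yb / sqrt(sum(pg$yb^2)), base$yb / sqrt(sum(base$yb^2)),
                 tolerance = 1e-10)
  }
})

test_that("gamma fitting equals per-channel least squares", {
  cfg <- fx_cfg()
  b <- build_primaries(475, 25, 2, cfg$white, cfg$cmfs)
  pred <- predicted_valences(cfg$cmfs, change_of_basis_matrix(b))
  self_fit <- fit_gammas(pred, pred)
  expect_equal(unname(self_fit$gains), c(1, 1))
  fit <- fit_gammas(pred, cfg$ref)
  # joint rescaling of both curves leaves the gains unchanged
  pred2 <- pred; pred2$rg <- 3 * pred$rg; pred2$yb <- 3 * pred$yb
  ref2 <- cfg$ref; ref2$rg <- 3 * ref2$rg; ref2$yb <- 3 * ref2$yb
  fit2 <- fit_gammas(pred2, ref2)
  expect_equal(fit2$gains, fit$gains, tolerance = 1e-12)
  # fitted error never exceeds the unfitted error
  mse <- function(cv) mean((cv$rg - cfg$ref$rg)^2 + (cv$yb - cfg$ref$yb)^2)
  expect_lte(mse(fit$fitted), mse(pred))
})

test_that("instrumental magenta weights can be reassigned without changing curves", {
  cfg <- fx_cfg()
  sg <- wl_grid(400, 700, 30)
  lights <- complementary_light_set(480, 20, cfg$grid, cfg$cmfs, cfg$white,
                                    cfg$height, cfg$sigma_nm)
  expect_true(any(lights$purple))
  net <- identity_network(cfg$cmfs, "lms", cfg$params)
  cv <- run_cancellation_curves(sg, lights, net, cfg$white)
  re <- assign_instrumental_to_cancelling(cv)
  expect_equal(re$rg, cv$rg)
  expect_equal(re$yb, cv$yb)
  for (k in which(lights$purple)) {
    part <- lights$axes[[k]][2]
    expect_true(all(re$per_light_weights[, part] == 0))
  }
  # all-spectral complements: the operation is the identity
  lights_sp <- complementary_light_set(440, 20, cfg$grid, cfg$cmfs, cfg$white,
                                       cfg$height, cfg$sigma_nm)
  expect_false(any(lights_sp$purple))
  cv_sp <- run_cancellation_curves(sg, lights_sp, net, cfg$white)
  expect_identical(assign_instrumental_to_cancelling(cv_sp)$per_light_weights,
                   cv_sp$per_light_weights)
})

test_that("auxiliary magenta lights land on their target purple chromaticity", {
  cfg <- fx_cfg()
  lights <- complementary_light_set(500, 20, cfg$grid, cfg$cmfs, cfg$white,
                                    cfg$height, cfg$sigma_nm)
  for (k in which(lights$purple)) {
    idx <- lights$axes[[k]][2]
    cm <- chromaticity_of(spectrum_to_tristimulus(lights$lights[[idx]], cfg$cmfs))
    expect_equal(cm, lights$complements[[k]]$chromaticity, tolerance = 2e-3,
                 ignore_attr = TRUE)
  }
})
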