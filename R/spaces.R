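#' Color-space conversion parameters
#'
#' Bundles the fixed matrices and display parameters that define the package's
#' color representations, all reached from CIE XYZ:
#'
#' * `lms` — Hunt--Pointer--Estevez cone transform (equal-energy variant).
#' * `atd` — an achromatic/opponent model with rows normalized at the working
#'   white `(Xw, Yw, Zw)`: `A = Y/Yw`, `T = X/Xw - Y/Yw`,
#'   `D = 0.4 * (Y/Yw - Z/Zw)`. By construction A has an all-positive spectral
#'   sensitivity, T and D are opponent, and the chromatic channels are exactly
#'   zero for the working equienergetic white (including any grid-truncation
#'   effects).
#' * `rgb_linear` — the standard sRGB primaries matrix applied to XYZ.
#' * `rgb_digital` — `rgb_linear` rescaled into `[0, 1]` (the working white
#'   maps to `1 / headroom` on its largest channel), clipped, then compressed
#'   by a power law with exponent `1 / gamma_display`: an idealized
#'   device-dependent digital RGB with a mild pointwise nonlinearity.
#'
#' @param white_xyz Tristimulus of the working white in XYZ (used by the atd
#'   normalization and the digital scaling).
#' @param gamma_display Display exponent for `rgb_digital`; `1` makes the
#'   digital space identical to `rgb_linear` scaling aside.
#' @param headroom Factor by which the digital scale exceeds the white's
#'   largest linear-RGB channel, leaving room for superposed cancellation
#'   lights before clipping.
#' @return A list of class `space_params`.
#' @export
space_params <- function(white_xyz, gamma_display = 2.2, headroom = 4) {
  w <- as.numeric(white_xyz)
  if (length(w) != 3 || any(w <= 0))
    stop("space_params: white_xyz must be a positive 3-vector")
  atd <- rbind(A = c(0, 1 / w[2], 0),
               T = c(1 / w[1], -1 / w[2], 0),
               D = c(0, 0.4 / w[2], -0.4 / w[3]))
  rgb <- srgb_matrix()
  structure(list(white_xyz = w,
                 lms = hpe_matrix(),
                 atd = atd,
                 rgb = rgb,
                 digital_scale = 1 / (headroom * max(rgb %*% w)),
                 gamma_display = gamma_display),
            class = "space_params")
}

# sRGB linear primaries matrix (RGB = S %*% XYZ)
srgb_matrix <- function() {
  matrix(c( 3.2406, -1.5372, -0.4986,
           -0.9689,  1.8758,  0.0415,
            0.0557, -0.2040,  1.0570),
         nrow = 3, byrow = TRUE)
}

#' Convert a tristimulus vector between color spaces
#'
#' Conversions are defined from and to `"xyz"`; any pair of known spaces is
#' reached through it. `"lms"`, `"atd"` and `"rgb_linear"` are invertible 3x3
#' maps; `"rgb_digital"` additionally applies the display scaling, `[0, 1]`
#' clipping and the power-law compression, and is only invertible for in-range
#' values. Out-of-range digital inputs are clipped with a warning.
#'
#' @param t A [tristim()].
#' @param space Target space label: one of `"xyz"`, `"lms"`, `"atd"`,
#'   `"rgb_linear"`, `"rgb_digital"`.
#' @param params A [space_params()].
#' @return A [tristim()] in the target space.
#' @export
to_space <- function(t, space, params) {
  stopifnot(inherits(t, "tristim"), inherits(params, "space_params"))
  from <- tristim_space(t)
  if (from == space) return(t)
  xyz <- switch(from,
    xyz = as.numeric(t),
    lms = drop(solve(params$lms, as.numeric(t))),
    atd = drop(solve(params$atd, as.numeric(t))),
    rgb_linear = drop(solve(params$rgb, as.numeric(t))),
    rgb_digital = {
      v <- pmax(as.numeric(t), 0)^params$gamma_display / params$digital_scale
      drop(solve(params$rgb, v))
    },
    stop(sprintf("to_space: no conversion path from '%s'", from))
  )
  out <- switch(space,
    xyz = xyz,
    lms = drop(params$lms %*% xyz),
    atd = drop(params$atd %*% xyz),
    rgb_linear = drop(params$rgb %*% xyz),
    rgb_digital = {
      v <- drop(params$rgb %*% xyz) * params$digital_scale
      if (any(v < -1e-9) || any(v > 1 + 1e-9))
        warning("to_space: rgb_digital value outside [0,1]; clipped")
      pmin(pmax(v, 0), 1)^(1 / params$gamma_display)
    },
    stop(sprintf("to_space: unknown target space '%s'", space))
  )
  tristim(out, space = space)
}

#' Is a space an invertible linear map of XYZ?
#'
#' @param space Space label.
#' @return Logical.
#' @export
is_linear_space <- function(space) {
  space %in% c("xyz", "lms", "atd", "rgb_linear")
}

# 3x3 matrix taking xyz to a linear space
space_matrix <- function(space, params) {
  switch(space,
         xyz = diag(3),
         lms = params$lms,
         atd = params$atd,
         rgb_linear = params$rgb,
         stop(sprintf("space_matrix: '%s' is not a linear space", space)))
}
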