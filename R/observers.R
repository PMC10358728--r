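#' Observer networks
#'
#' An observer network is the model organism of the simulated psychophysics:
#' a fixed front end mapping radiance to the network's input representation
#' (observer CMFs + color space), followed by an arbitrary post-retinal
#' transform on 3-vectors. The matching task never looks inside the
#' transform; the point of the study design is that a trivial identity
#' transform already reproduces opponent valence curves.
#'
#' @param cmfs An `observer_cmfs` (the retinal sensitivities).
#' @param space Input-space label for the network (see [to_space()]).
#' @param params A [space_params()].
#' @param transform A function from 3-vector to 3-vector. Default: identity.
#' @param name Label for reports.
#' @return An object of class `observer_network`.
#' @export
observer_network <- function(cmfs, space = "xyz", params,
                             transform = identity, name = space,
                             linear = NULL) {
  stopifnot(inherits(cmfs, "observer_cmfs"), is.function(transform))
  structure(list(cmfs = cmfs, space = space, params = params,
                 transform = transform, name = name, linear = linear),
            class = "observer_network")
}

#' Identity network
#'
#' The trivial observer: its output equals its input representation,
#' `R'(R(C)) = R(C)`. Instantiated over different front-end spaces it yields
#' the study's counter-example observers (digital RGB, cone LMS, opponent
#' ATD).
#'
#' @inheritParams observer_network
#' @return An `observer_network` whose transform is the identity.
#' @export
identity_network <- function(cmfs, space = "xyz", params, name = paste0("identity-", space)) {
  observer_network(cmfs, space, params, transform = identity, name = name,
                   linear = diag(3))
}

#' Linear-map network
#'
#' Post-retinal transform given by a fixed 3x3 matrix. With an invertible
#' matrix the zero set of the match distance is the same as the identity
#' network's, which is exactly why the cancellation curves cannot identify
#' the post-retinal architecture.
#'
#' @inheritParams observer_network
#' @param M A 3x3 matrix.
#' @export
linear_network <- function(cmfs, space = "xyz", params, M,
                           name = paste0("linear-", space)) {
  M <- as.matrix(M)
  stopifnot(all(dim(M) == c(3, 3)))
  observer_network(cmfs, space, params,
                   transform = function(v) drop(M %*% v), name = name,
                   linear = M)
}

#' Network response to a spectral stimulus
#'
#' `R' = transform(to_space(spectrum_to_tristimulus(spd), space))`.
#'
#' @param net An `observer_network`.
#' @param x An [spd()] on the network's grid.
#' @return A [tristim()] labeled with the network's space.
#' @export
response <- function(net, x) {
  stopifnot(inherits(net, "observer_network"))
  r <- spectrum_to_tristimulus(x, net$cmfs)
  r <- to_space(r, net$space, net$params)
  tristim(net$transform(as.numeric(r)), space = net$space)
}

# response from a precomputed front-end (xyz or lms) tristimulus vector;
# avoids re-integrating spectra inside optimization loops
response_from_front <- function(net, v_front) {
  r <- to_space(v_front, net$space, net$params)
  tristim(net$transform(as.numeric(r)), space = net$space)
}

#' Match distance between two responses
#'
#' Euclidean norm of the difference, the metric minimized by the matching
#' task. Both vectors must carry the same space label.
#'
#' @param a,b [tristim()] vectors in the same space.
#' @return Non-negative scalar.
#' @export
match_distance <- function(a, b) {
  stopifnot(inherits(a, "tristim"), inherits(b, "tristim"))
  if (!identical(tristim_space(a), tristim_space(b)))
    stop(sprintf("match_distance: space mismatch ('%s' vs '%s')",
                 tristim_space(a), tristim_space(b)))
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}
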