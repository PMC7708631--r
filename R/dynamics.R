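#' Gaussian-weighted local saliency input to the attention stream
#'
#' The attention map relaxes toward the saliency map seen through a
#' Gaussian aperture around fixation: the elementwise product `S * G_A`,
#' normalized to unit sum over the grid.
#'
#' @param S Nonnegative saliency matrix.
#' @param G Aperture matrix from [gaussian_map()] (same shape as `S`).
#' @return Normalized input map (sums to 1).
#' @export
attention_input <- function(S, G) {
  stopifnot(identical(dim(S), dim(G)))
  if (any(S < 0)) stop("saliency must be nonnegative", call. = FALSE)
  M <- S * G
  s <- sum(M)
  if (!is.finite(s) || s <= 0) {
    stop("saliency is degenerate under the attention aperture (zero sum)",
         call. = FALSE)
  }
  M / s
}

#' Closed-form relaxation of an activation map
#'
#' Both streams evolve as linear relaxations `dM/dt = omega * (target - M)`
#' toward their (normalized) input map. The exact solution over a step of
#' length `dt` is `target + exp(-omega * dt) * (M0 - target)`, used here in
#' place of any numerical ODE stepping.
#'
#' @param M0 Map at the start of the step.
#' @param target Normalized input map (unit sum): the Gaussian-weighted
#'   local saliency for attention, the normalized fixation Gaussian for
#'   inhibition.
#' @param omega Decay rate (1/s), > 0.
#' @param dt Step duration (s), >= 0.
#' @return Map after `dt` seconds.
#' @export
evolve_map <- function(M0, target, omega, dt) {
  stopifnot(identical(dim(M0), dim(target)))
  if (!is.finite(dt) || dt < 0) stop("`dt` must be nonnegative", call. = FALSE)
  if (!is.finite(omega) || omega <= 0) stop("`omega` must be positive", call. = FALSE)
  target + exp(-omega * dt) * (M0 - target)
}

#' Combine attention and inhibition into the signed priority map
#'
#' Each stream is shaped by the exponent `gamma` and sum-normalized before
#' the weighted subtraction
#' `u = A^gamma / sum(A^gamma) - C_F * F^gamma / sum(F^gamma)`.
#' Maps are clipped at zero before exponentiation to absorb round-off.
#'
#' @param A,F Nonnegative activation and inhibition maps, each with a
#'   positive sum.
#' @param gamma Shaping exponent (> 0).
#' @param C_F Inhibition weight (>= 0).
#' @return Signed priority map (may contain negative values).
#' @export
combine_priority <- function(A, F, gamma, C_F) {
  stopifnot(identical(dim(A), dim(F)), gamma > 0)
  A <- pmax(A, 0)
  F <- pmax(F, 0)
  ag <- A^gamma
  fg <- F^gamma
  sa <- sum(ag)
  sf <- sum(fg)
  if (sa <= 0) stop("activation map is identically zero", call. = FALSE)
  if (sf <= 0) stop("inhibition map is identically zero", call. = FALSE)
  ag / sa - C_F * (fg / sf)
}

#' Rectify a signed priority map
#'
#' Subtraction of the inhibition stream can produce negative values; only
#' the positive component is retained for target selection.
#'
#' @param u Signed priority map.
#' @return `pmax(u, 0)` elementwise.
#' @export
rectify_map <- function(u) {
  pmax(u, 0)
}

#' Target-selection probability map
#'
#' Mixes the normalized rectified priority map with a uniform floor:
#' `pi = (1 - zeta) * u_star / sum(u_star) + zeta / (n_x * n_y)`.
#' With `zeta = 1` the map is exactly uniform; if `u_star` sums to zero
#' and `zeta > 0`, the uniform component is all there is.
#'
#' @param u_star Rectified (nonnegative) priority map.
#' @param zeta Selection noise in (0, 1], or 0 if `u_star` has positive
#'   sum.
#' @return Probability map over grid cells (nonnegative, sums to 1).
#' @export
selection_probability <- function(u_star, zeta) {
  stopifnot(zeta >= 0, zeta <= 1)
  n <- length(u_star)
  su <- sum(u_star)
  if (su <= 0) {
    if (zeta <= 0) {
      stop("all-zero priority map with `zeta` = 0: selection undefined",
           call. = FALSE)
    }
    return(array(1 / n, dim = dim(u_star)))
  }
  (1 - zeta) * (u_star / su) + zeta / n
}

#' Full priority-to-probability computation for one map state
#'
#' Convenience wrapper chaining [combine_priority()], the optional
#' oculomotor potential, [rectify_map()] and [selection_probability()].
#' This is the map from which the next saccade target is drawn.
#'
#' @param A,F Activation and inhibition maps.
#' @param params An [sw_params()] object.
#' @param grid An [sw_grid()]; required when the oculomotor potential is
#'   active.
#' @param fix Current fixation position `c(x, y)` in degrees (center of
#'   the oculomotor potential); `NULL` disables the potential (e.g. for
#'   the first fixation, where no current fixation exists yet).
#' @return Probability map over grid cells.
#' @export
priority_probability <- function(A, F, params, grid = NULL, fix = NULL) {
  stopifnot(is_sw_params(params))
  psi <- exp(params$log_psi)
  if (sum(pmax(F, 0)^params$gamma) > 0) {
    u <- combine_priority(A, F, params$gamma, params$C_F)
  } else {
    # F can be identically zero only at t = 0 under center-bias
    # initialization; the inhibition term is then absent.
    A2 <- pmax(A, 0)
    u <- A2^params$gamma / sum(A2^params$gamma)
  }
  if (psi > 0 && !is.null(fix)) {
    stopifnot(is_sw_grid(grid))
    omp <- oculomotor_map(fix, params$chi, grid)
    u <- apply_oculomotor(u, omp, psi, sign = params$omp_sign)
  }
  selection_probability(rectify_map(u), exp(params$log_zeta))
}
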