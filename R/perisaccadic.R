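#' Phase schedule of one fixation
#'
#' Each fixation of duration `t_fix` splits into up to three contiguous
#' phases. During the post-saccadic shift (`[0, tau_post]`) attention is
#' centered at the remap location along the previous saccade vector; the
#' main phase (`[tau_post, t_fix - tau_pre]`) realigns attention with the
#' fixation position; during the pre-saccadic shift
#' (`[t_fix - tau_pre, t_fix]`) attention already points at the upcoming
#' target. The inhibition stream is centered at the fixation position
#' throughout. For short fixations (`t_fix < tau_pre + tau_post`) the
#' pre-saccadic phase keeps priority (target selection must occur at
#' `t_fix - tau_pre`), the post-saccadic phase is truncated to the
#' remainder, and the main phase may be empty. The first fixation of a
#' trial has no preceding saccade and hence no post-saccadic phase.
#'
#' @param t_fix Fixation duration in seconds (> 0).
#' @param tau_pre,tau_post Phase durations in seconds (>= 0).
#' @param has_prev_saccade Does a preceding saccade exist?
#' @param fix_n Current fixation `c(x, y)` (degrees).
#' @param fix_next Upcoming fixation `c(x, y)`, or `NULL` if not yet
#'   selected (the pre-shift attention center is then unknown).
#' @param remap Post-saccadic remap location `c(x, y)` from
#'   [remap_location()], or `NULL`.
#' @return A tibble with one row per non-empty phase: `phase`
#'   (`"post_shift"`, `"main"`, `"pre_shift"`), `start`, `end` (s),
#'   `a_center_x/y`, `f_center_x/y` (degrees; `NA` when unknown).
#' @examples
#' schedule_phases(0.3, 0.1, 0.05, TRUE, c(8, 6), c(10, 6), c(9, 6))
#' @export
schedule_phases <- function(t_fix, tau_pre, tau_post, has_prev_saccade,
                            fix_n, fix_next = NULL, remap = NULL) {
  if (!is.finite(t_fix) || t_fix <= 0) {
    stop("`t_fix` must be positive", call. = FALSE)
  }
  stopifnot(tau_pre >= 0, tau_post >= 0)
  pre <- min(tau_pre, t_fix)
  post <- if (has_prev_saccade) min(tau_post, t_fix - pre) else 0
  main <- t_fix - pre - post
  na2 <- c(NA_real_, NA_real_)
  if (is.null(fix_next)) fix_next <- na2
  if (is.null(remap)) remap <- na2
  ph <- tibble(
    phase = c("post_shift", "main", "pre_shift"),
    start = c(0, post, post + main),
    end = c(post, post + main, t_fix),
    a_center_x = c(remap[1], fix_n[1], fix_next[1]),
    a_center_y = c(remap[2], fix_n[2], fix_next[2]),
    f_center_x = fix_n[1],
    f_center_y = fix_n[2]
  )
  ph[ph$end > ph$start, ]
}

#' Pre-saccadic attention Gaussian
#'
#' Once the next target is selected, the attention aperture re-centers on
#' the upcoming fixation location for the final `tau_pre` seconds of the
#' current fixation, while inhibition stays put. The map is the ordinary
#' attention Gaussian evaluated at the upcoming location.
#'
#' @param next_fix Upcoming fixation `c(x, y)` in degrees.
#' @param sigma_A Attention width in degrees.
#' @param grid An [sw_grid()].
#' @return Matrix over grid cells.
#' @export
presaccadic_gaussian <- function(next_fix, sigma_A, grid) {
  gaussian_map(next_fix, sigma_A, grid)
}

#' Post-saccadic remap location
#'
#' After a saccade, attention briefly sits beyond the landing point: the
#' previous saccade vector is extended by the shift amplitude `eta`, so
#' `(x_s, y_s) = fix_curr + eta * (fix_curr - fix_prev) / |fix_curr - fix_prev|`.
#' The result may fall outside the image; maps are evaluated with
#' border-truncated Gaussians, so the center is never clamped.
#'
#' @param fix_prev,fix_curr Previous and current fixation `c(x, y)` in
#'   degrees; must differ.
#' @param eta Shift amplitude in degrees (>= 0).
#' @return A list with `location` (`c(x_s, y_s)`) and `saccade` (the
#'   vector `fix_curr - fix_prev`).
#' @examples
#' remap_location(c(0, 0), c(3, 0), eta = 0.415)$location  # (3.415, 0)
#' @export
remap_location <- function(fix_prev, fix_curr, eta) {
  stopifnot(length(fix_prev) == 2, length(fix_curr) == 2, eta >= 0)
  delta <- fix_curr - fix_prev
  len <- sqrt(sum(delta^2))
  if (len == 0) {
    stop("zero-length saccade: remap direction undefined", call. = FALSE)
  }
  list(location = fix_curr + delta / len * eta, saccade = delta)
}

#' Post-saccadic attention Gaussian
#'
#' The attention aperture during the first `tau_post` seconds of a
#' fixation, centered at the remap location with width `sigma_post`.
#'
#' @param shift Result of [remap_location()] (or a list with `location`).
#' @param sigma_post Width in degrees.
#' @param grid An [sw_grid()].
#' @return Matrix over grid cells.
#' @export
postsaccadic_gaussian <- function(shift, sigma_post, grid) {
  loc <- if (is.list(shift)) shift$location else shift
  gaussian_map(loc, sigma_post, grid)
}

#' Attention relaxation with a facilitation-of-return window
#'
#' Identical to [evolve_map()] except that cells inside the square window
#' `|x - x_prev| < nu & |y - y_prev| < nu` around the previous fixation
#' decay with the slower rate `omega_FoR` instead of `omega_A`. The window
#' changes only the approach rate, never the fixed point.
#'
#' @param A0 Attention map at the start of the step.
#' @param target Normalized input map.
#' @param omega_A Decay rate outside the window (1/s).
#' @param omega_FoR Decay rate inside the window (1/s), `<= omega_A`.
#' @param prev_fix Previous fixation `c(x, y)` in degrees, or `NULL` for
#'   no window.
#' @param nu Window half-width in degrees.
#' @param dt Step duration (s).
#' @param grid An [sw_grid()].
#' @return Map after `dt` seconds.
#' @export
evolve_attention_for <- function(A0, target, omega_A, omega_FoR,
                                 prev_fix, nu, dt, grid) {
  stopifnot(is_sw_grid(grid))
  if (!is.finite(dt) || dt < 0) stop("`dt` must be nonnegative", call. = FALSE)
  if (omega_FoR > omega_A) stop("`omega_FoR` must not exceed `omega_A`", call. = FALSE)
  decay <- matrix(exp(-omega_A * dt), grid$n_x, grid$n_y)
  if (!is.null(prev_fix) && omega_FoR != omega_A) {
    ix <- abs(grid$xs - prev_fix[1]) < nu
    jy <- abs(grid$ys - prev_fix[2]) < nu
    decay[ix, jy] <- exp(-omega_FoR * dt)
  }
  target + decay * (A0 - target)
}

#' Initial map state with center-bias activation
#'
#' The extended model starts a trial with a central activation blob:
#' `A(0)` is the sum-normalized Gaussian of widths `sigma_CB` at the image
#' center, and the inhibition map is zero. During the first fixation the
#' activation relaxes toward the ordinary local-saliency input at the
#' first fixation's location with the slower decay `omega_CB`.
#'
#' @param S Saliency matrix (used only for shape validation here; the
#'   first fixation's input map is built during evolution).
#' @param params An [sw_params()] object.
#' @param grid An [sw_grid()].
#' @return A list (map state) with `A`, `F` and `t = 0`.
#' @export
initial_state_center_bias <- function(S, params, grid) {
  stopifnot(is_sw_params(params), is_sw_grid(grid))
  stopifnot(nrow(S) == grid$n_x, ncol(S) == grid$n_y)
  center <- c(grid$extent_x / 2, grid$extent_y / 2)
  A0 <- normalize_map(gaussian_map(center, params$sigma_CB, grid))
  list(A = A0, F = matrix(0, grid$n_x, grid$n_y), t = 0)
}

#' Plus-shaped oculomotor potential
#'
#' `OMP(x, y) = ((x - x_f)^2 * (y - y_f)^2)^chi` evaluated at cell
#' centers: exactly zero on the cardinal cross through the fixation and
#' growing with distance from both axes, with steepness set by `chi`.
#' The value at zero base is defined as 0 for every `chi >= 0` so the
#' plus-shaped support is preserved continuously in `chi`.
#'
#' @param fix Current fixation `c(x, y)` in degrees.
#' @param chi Steepness exponent (>= 0).
#' @param grid An [sw_grid()].
#' @return Nonnegative matrix over grid cells.
#' @export
oculomotor_map <- function(fix, chi, grid) {
  stopifnot(is_sw_grid(grid), length(fix) == 2, chi >= 0)
  # separable: ((x-xf)^2 (y-yf)^2)^chi = ((x-xf)^2)^chi * ((y-yf)^2)^chi,
  # with 0^chi := 0 so the cardinal cross stays zero for every chi >= 0
  dx2 <- (grid$xs - fix[1])^2
  dy2 <- (grid$ys - fix[2])^2
  px <- dx2^chi
  px[dx2 == 0] <- 0
  py <- dy2^chi
  py[dy2 == 0] <- 0
  outer(px, py)
}

#' Add the oculomotor potential to the priority map
#'
#' Under the default `"suppress"` convention the sum-normalized potential
#' is subtracted, `u - psi * OMP / sum(OMP)`, which lowers priority away
#' from the cardinal axes and produces the cardinal-direction saccade
#' preference. The `"literal"` convention applies the additive form
#' `u + psi * |OMP / sum(OMP)|` instead (kept behind a flag: it rewards
#' off-cardinal cells, the opposite of the intended effect).
#'
#' @param u Signed priority map.
#' @param omp Oculomotor map from [oculomotor_map()].
#' @param psi Weight (>= 0).
#' @param sign `"suppress"` (default) or `"literal"`.
#' @return Signed priority map.
#' @export
apply_oculomotor <- function(u, omp, psi, sign = c("suppress", "literal")) {
  sign <- match.arg(sign)
  stopifnot(identical(dim(u), dim(omp)), psi >= 0)
  if (psi == 0) return(u)
  so <- sum(omp)
  if (so <= 0) stop("oculomotor map has zero sum with `psi` > 0", call. = FALSE)
  if (sign == "suppress") u - psi * (omp / so) else u + psi * abs(omp / so)
}
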