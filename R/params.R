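#' Model parameters for the baseline and extended scan-path models
#'
#' Bundles the estimated and fixed parameters of the SceneWalk model
#' family. Defaults for the estimated parameters are the across-subject
#' point estimates reported for the Potsdam scene-viewing corpus; fixed
#' parameters follow the published couplings: the inhibition stream and
#' the facilitation-of-return window decay one order of magnitude slower
#' than attention (`omega_F = omega_FoR = omega_A / 10`), the inhibition
#' weight is `C_F = 0.3`, the center bias has width 4.3 degrees and decay
#' 1.5/s, the facilitation window half-width is `nu = 2` degrees
#' (approximately the fovea), and the perisaccadic phases last
#' `tau_pre = 0.1` s and `tau_post = 0.05` s.
#'
#' @param variant `"extended"` (perisaccadic shifts, facilitation of
#'   return, center bias, oculomotor potential) or `"baseline"` (pure
#'   activation/inhibition dynamics, uniform initialization, no phases).
#' @param omega_A Attention decay rate (1/s).
#' @param sigma_A Attention Gaussian width (degrees).
#' @param sigma_F Inhibition Gaussian width (degrees).
#' @param gamma Priority-map shaping exponent (dimensionless, > 0).
#' @param log_zeta Natural log of the selection noise `zeta`; `zeta =
#'   exp(log_zeta)` must lie in (0, 1]. Estimated on the log scale.
#' @param chi Steepness of the oculomotor potential (>= 0; extended only).
#' @param eta Post-saccadic shift amplitude in degrees (extended only).
#' @param log_psi Natural log of the oculomotor weight `psi` (extended
#'   only; estimated on the log scale). Use `-Inf` for `psi = 0`.
#' @param omega_F Inhibition decay rate (1/s); fixed at `omega_A / 10`.
#' @param omega_FoR Attention decay inside the facilitation-of-return
#'   window (1/s); fixed at `omega_A / 10`. Must not exceed `omega_A`.
#' @param C_F Weight of the inhibition stream in the priority map.
#' @param sigma_CB Center-bias widths, scalar or `c(sx, sy)` degrees.
#' @param omega_CB Center-bias decay rate during the first fixation (1/s).
#' @param nu Half-width of the square facilitation window (degrees).
#' @param tau_pre,tau_post Durations (s) of the pre-/post-saccadic
#'   attention-shift phases.
#' @param sigma_post Width (degrees) of the post-saccadic attention
#'   Gaussian. Default 1 degree (foveal scale): the retinotopic trace is
#'   a compact blob at the remap location. A trace as wide as the
#'   attention span would make the shift unobservable, since its
#'   displacement `eta` is small relative to `sigma_A`.
#' @param center_bias Initialize the first fixation's activation from a
#'   central Gaussian evolving with `omega_CB`? Default `TRUE` for the
#'   extended variant, `FALSE` for baseline.
#' @param omp_sign `"suppress"` (default) subtracts the normalized
#'   oculomotor map from the priority map, which suppresses off-cardinal
#'   cells and yields the cardinal-direction preference; `"literal"`
#'   applies the verbatim additive form instead.
#' @return An object of class `sw_params` (a named list).
#' @examples
#' sw_params("extended")
#' sw_params("baseline", sigma_A = 5)
#' @export
sw_params <- function(variant = c("extended", "baseline"),
                      omega_A = NULL, sigma_A = NULL, sigma_F = NULL,
                      gamma = NULL, log_zeta = NULL,
                      chi = 0.059, eta = 0.415, log_psi = -0.613,
                      omega_F = omega_A / 10,
                      omega_FoR = if (variant == "extended") omega_A / 10 else omega_A,
                      C_F = 0.3,
                      sigma_CB = c(4.3, 4.3), omega_CB = 1.5, nu = 2,
                      tau_pre = if (variant == "extended") 0.1 else 0,
                      tau_post = if (variant == "extended") 0.05 else 0,
                      sigma_post = 1,
                      center_bias = variant == "extended",
                      omp_sign = c("suppress", "literal")) {
  variant <- match.arg(variant)
  omp_sign <- match.arg(omp_sign)
  defaults <- if (variant == "extended") {
    list(omega_A = 9.996, sigma_A = 7.320, sigma_F = 6.834,
         gamma = 0.956, log_zeta = -1.727)
  } else {
    list(omega_A = 14.802, sigma_A = 7.482, sigma_F = 4.629,
         gamma = 0.935, log_zeta = -1.132)
  }
  if (is.null(omega_A)) omega_A <- defaults$omega_A
  if (is.null(sigma_A)) sigma_A <- defaults$sigma_A
  if (is.null(sigma_F)) sigma_F <- defaults$sigma_F
  if (is.null(gamma)) gamma <- defaults$gamma
  if (is.null(log_zeta)) log_zeta <- defaults$log_zeta
  # re-evaluate couplings that default on omega_A / sigma_A
  omega_F <- eval(omega_F)
  omega_FoR <- eval(omega_FoR)
  sigma_post <- eval(sigma_post)
  if (variant == "baseline") {
    chi <- 0
    log_psi <- -Inf
    eta <- 0
  }
  p <- list(
    variant = variant,
    omega_A = omega_A, sigma_A = sigma_A, sigma_F = sigma_F,
    gamma = gamma, log_zeta = log_zeta,
    chi = chi, eta = eta, log_psi = log_psi,
    omega_F = omega_F, omega_FoR = omega_FoR, C_F = C_F,
    sigma_CB = rep_len(as.numeric(sigma_CB), 2),
    omega_CB = omega_CB, nu = nu,
    tau_pre = tau_pre, tau_post = tau_post, sigma_post = sigma_post,
    center_bias = isTRUE(center_bias), omp_sign = omp_sign
  )
  class(p) <- "sw_params"
  validate_sw_params(p)
  p
}

validate_sw_params <- function(p) {
  pos <- c("omega_A", "sigma_A", "sigma_F", "gamma", "omega_F",
           "omega_FoR", "omega_CB", "nu", "sigma_post")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("`%s` must be strictly positive and finite", nm),
           call. = FALSE)
    }
  }
  if (any(p$sigma_CB <= 0)) stop("`sigma_CB` must be positive", call. = FALSE)
  if (p$tau_pre < 0 || p$tau_post < 0) {
    stop("phase durations must be nonnegative", call. = FALSE)
  }
  zeta <- exp(p$log_zeta)
  if (!is.finite(zeta) || zeta <= 0 || zeta > 1) {
    stop("`exp(log_zeta)` must lie in (0, 1]", call. = FALSE)
  }
  if (p$chi < 0) stop("`chi` must be nonnegative", call. = FALSE)
  if (p$eta < 0) stop("`eta` must be nonnegative", call. = FALSE)
  if (exp(p$log_psi) < 0) stop("`psi` must be nonnegative", call. = FALSE)
  if (p$omega_FoR > p$omega_A + 1e-12) {
    stop("`omega_FoR` must not exceed `omega_A`", call. = FALSE)
  }
  if (p$C_F < 0) stop("`C_F` must be nonnegative", call. = FALSE)
  invisible(p)
}

is_sw_params <- function(x) inherits(x, "sw_params")

#' @export
print.sw_params <- function(x, ...) {
  cat(sprintf("<sw_params> %s model\n", x$variant))
  cat(sprintf(
    "  estimated: omega_A=%.4g/s sigma_A=%.4g deg sigma_F=%.4g deg gamma=%.4g zeta=%.4g\n",
    x$omega_A, x$sigma_A, x$sigma_F, x$gamma, exp(x$log_zeta)
  ))
  if (x$variant == "extended") {
    cat(sprintf("             chi=%.4g eta=%.4g deg psi=%.4g\n",
                x$chi, x$eta, exp(x$log_psi)))
  }
  cat(sprintf(
    "  fixed:     omega_F=%.4g omega_FoR=%.4g C_F=%.2g tau_pre=%.3g tau_post=%.3g nu=%.3g\n",
    x$omega_F, x$omega_FoR, x$C_F, x$tau_pre, x$tau_post, x$nu
  ))
  cat(sprintf("             center_bias=%s (sigma_CB=%.3g/%.3g, omega_CB=%.3g), omp_sign=%s\n",
              x$center_bias, x$sigma_CB[1], x$sigma_CB[2], x$omega_CB, x$omp_sign))
  invisible(x)
}

#' Names of the estimated parameters of a model variant
#'
#' The remaining parameters are fixed or derived couplings and are never
#' sampled during inference.
#'
#' @param variant `"baseline"` or `"extended"`.
#' @return Character vector of parameter names.
#' @export
estimated_param_names <- function(variant = c("extended", "baseline")) {
  variant <- match.arg(variant)
  base <- c("omega_A", "sigma_A", "sigma_F", "gamma", "log_zeta")
  if (variant == "extended") c(base, "chi", "eta", "log_psi") else base
}

#' Rebuild a parameter object from an estimated-parameter vector
#'
#' Applies the fixed-parameter couplings (`omega_F`, `omega_FoR` derived
#' from `omega_A`; `sigma_post` from `sigma_A`) so that samplers only ever
#' see the estimated subset.
#'
#' @param theta Named numeric vector over [estimated_param_names()].
#' @param template An `sw_params` object providing variant and fixed
#'   values.
#' @return An `sw_params` object.
#' @export
params_from_vector <- function(theta, template) {
  stopifnot(is_sw_params(template))
  nms <- estimated_param_names(template$variant)
  stopifnot(all(nms %in% names(theta)))
  sw_params(
    variant = template$variant,
    omega_A = unname(theta[["omega_A"]]),
    sigma_A = unname(theta[["sigma_A"]]),
    sigma_F = unname(theta[["sigma_F"]]),
    gamma = unname(theta[["gamma"]]),
    log_zeta = unname(theta[["log_zeta"]]),
    chi = if (template$variant == "extended") unname(theta[["chi"]]) else 0,
    eta = if (template$variant == "extended") unname(theta[["eta"]]) else 0,
    log_psi = if (template$variant == "extended") unname(theta[["log_psi"]]) else -Inf,
    C_F = template$C_F,
    sigma_CB = template$sigma_CB, omega_CB = template$omega_CB,
    nu = template$nu,
    tau_pre = template$tau_pre, tau_post = template$tau_post,
    center_bias = template$center_bias, omp_sign = template$omp_sign
  )
}

#' Extract the estimated-parameter vector from a parameter object
#'
#' @param params An `sw_params` object.
#' @return Named numeric vector over [estimated_param_names()].
#' @export
params_to_vector <- function(params) {
  stopifnot(is_sw_params(params))
  unlist(params[estimated_param_names(params$variant)])
}

#' Read and write model parameters as YAML
#'
#' The full parameter set (estimated, fixed, and flags) round-trips
#' through a plain YAML mapping, so that every simulation or fit can log
#' its configuration verbatim.
#'
#' @param params An `sw_params` object.
#' @param path File path.
#' @return `write_params_yaml()` returns `path` invisibly;
#'   `read_params_yaml()` returns an `sw_params` object.
#' @export
write_params_yaml <- function(params, path) {
  stopifnot(is_sw_params(params))
  x <- unclass(params)
  x$sigma_CB <- as.list(x$sigma_CB)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  sw_params(
    variant = x$variant,
    omega_A = x$omega_A, sigma_A = x$sigma_A, sigma_F = x$sigma_F,
    gamma = x$gamma, log_zeta = x$log_zeta,
    chi = x$chi, eta = x$eta,
    log_psi = if (is.null(x$log_psi)) -Inf else x$log_psi,
    omega_F = x$omega_F, omega_FoR = x$omega_FoR, C_F = x$C_F,
    sigma_CB = unlist(x$sigma_CB), omega_CB = x$omega_CB, nu = x$nu,
    tau_pre = x$tau_pre, tau_post = x$tau_post, sigma_post = x$sigma_post,
    center_bias = x$center_bias, omp_sign = x$omp_sign
  )
}
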