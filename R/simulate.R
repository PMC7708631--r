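#' Sample fixation durations
#'
#' Fixation durations are modelled as independent gamma draws. The default
#' shape 9 and scale 0.0305 s give a mean of about 275 ms with a
#' coefficient of variation near 1/3, typical for scene viewing.
#'
#' @param n Number of durations.
#' @param shape,scale Gamma parameters (> 0); scale in seconds.
#' @return Numeric vector of positive durations (s).
#' @export
sample_duration <- function(n, shape = 9, scale = 0.0305) {
  if (!is.finite(shape) || shape <= 0 || !is.finite(scale) || scale <= 0) {
    stop("gamma `shape` and `scale` must be positive", call. = FALSE)
  }
  rgamma(n, shape = shape, scale = scale)
}

#' Draw a saccade target from a probability map
#'
#' One multinomial draw over grid cells, returned as the selected cell's
#' center in degrees.
#'
#' @param pi_map Probability map (nonnegative, sums to 1).
#' @param grid An [sw_grid()].
#' @return Numeric `c(x, y)` in degrees.
#' @export
sample_target <- function(pi_map, grid) {
  stopifnot(is_sw_grid(grid))
  if (any(pi_map < 0) || abs(sum(pi_map) - 1) > 1e-6) {
    stop("`pi_map` is not a probability map", call. = FALSE)
  }
  sample_cell_deg(pi_map, grid)
}

#' Simulate one scan path
#'
#' Generates a fixation sequence from the model: starting from the
#' center-bias initial state (extended variant) or the image center
#' (baseline), each fixation's duration is drawn from the gamma
#' distribution, the maps evolve through the fixation's phase schedule,
#' the next target is drawn from the priority-derived probability map at
#' the selection instant `t_fix - tau_pre`, and the pre-saccadic shift
#' runs before the saccade executes.
#'
#' @param S Saliency matrix over `grid`.
#' @param params An [sw_params()] object.
#' @param grid An [sw_grid()].
#' @param n_fix Number of fixations to generate.
#' @param duration_shape,duration_scale Gamma duration parameters, see
#'   [sample_duration()].
#' @param first_duration Duration (s) assigned to the baseline variant's
#'   first (center-placed) fixation.
#' @param durations Optional explicit duration vector (overrides the
#'   gamma draws); length `n_fix`.
#' @param engine `"cpp"` (default, compiled) or `"r"` (reference
#'   implementation); both consume the RNG stream identically, so results
#'   agree for a given seed.
#' @return A tibble with columns `fix_index`, `x_deg`, `y_deg`, `dur_s`.
#' @examples
#' g <- sw_grid(32, 24, 32, 24)
#' S <- make_saliency(g, n_blobs = 3, seed = 1)
#' set.seed(1)
#' simulate_scanpath(S, sw_params("extended"), g, n_fix = 5)
#' @export
simulate_scanpath <- function(S, params, grid, n_fix,
                              duration_shape = 9, duration_scale = 0.0305,
                              first_duration = 0.275, durations = NULL,
                              engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(is_sw_params(params), is_sw_grid(grid), n_fix >= 1)
  validate_saliency(S)
  if (is.null(durations)) {
    durations <- sample_duration(n_fix, duration_shape, duration_scale)
    if (!params$center_bias) durations[1] <- first_duration
  }
  stopifnot(length(durations) == n_fix, all(durations > 0))
  m <- if (engine == "cpp") {
    cpp_simulate(durations, S, params_for_cpp(params, grid))
  } else {
    simulate_r(S, params, grid, durations)
  }
  tibble(fix_index = seq_len(n_fix), x_deg = m[, 1], y_deg = m[, 2],
         dur_s = m[, 3])
}

#' Simulate scan paths for several subjects and images
#'
#' Convenience wrapper producing a standard fixation table. Every
#' `(subject, image)` pair gets one or more paths; paths of the same pair
#' are concatenated rows (a new path restarts the model state).
#'
#' @inheritParams simulate_scanpath
#' @param saliency A single saliency matrix or a named list of matrices
#'   (one per image).
#' @param n_subjects Number of simulated subjects.
#' @param n_paths Paths per subject and image.
#' @param n_fix Fixations per path.
#' @param subject_params Optional list of `sw_params`, one per subject
#'   (e.g. jittered around a common value); defaults to `params` for all.
#' @return A fixation tibble (`subject`, `image`, `path`, `x_deg`,
#'   `y_deg`, `dur_s`).
#' @export
simulate_dataset <- function(saliency, params, grid, n_subjects = 1,
                             n_paths = 1, n_fix = 30,
                             duration_shape = 9, duration_scale = 0.0305,
                             subject_params = NULL,
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (is.matrix(saliency)) saliency <- list(image_1 = saliency)
  if (is.null(names(saliency))) {
    names(saliency) <- paste0("image_", seq_along(saliency))
  }
  if (is.null(subject_params)) {
    subject_params <- rep(list(params), n_subjects)
  }
  stopifnot(length(subject_params) == n_subjects)
  out <- vector("list", n_subjects * length(saliency) * n_paths)
  k <- 0
  for (s in seq_len(n_subjects)) {
    for (im in names(saliency)) {
      for (p in seq_len(n_paths)) {
        sp <- simulate_scanpath(
          saliency[[im]], subject_params[[s]], grid, n_fix,
          duration_shape = duration_shape, duration_scale = duration_scale,
          engine = engine
        )
        k <- k + 1
        out[[k]] <- tibble(
          subject = sprintf("s%02d", s), image = im, path = p,
          x_deg = sp$x_deg, y_deg = sp$y_deg, dur_s = sp$dur_s
        )
      }
    }
  }
  dplyr::bind_rows(out)
}
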