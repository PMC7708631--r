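#' Exact per-fixation likelihood of observed scan paths
#'
#' Replays each observed scan path through the model ("teacher-forced":
#' the observed fixation positions and durations drive the map evolution;
#' the model's own samples are never substituted). The probability of the
#' first fixation is read off the initial map at `t = 0`; each later
#' fixation's probability is the value of the selection probability map,
#' evaluated at the instant `t_fix - tau_pre` of the preceding fixation,
#' at the cell of the next observed fixation. Probabilities are reported
#' as log2, so the per-fixation unit is the bit: a uniform selection map
#' on a 128 x 128 grid scores `log2(1/128^2) = -14` bits per fixation and
#' a perfect predictor scores 0.
#'
#' A zero probability at an observed cell (possible only when `zeta = 0`)
#' yields `-Inf` with a warning, never a silently dropped fixation. With
#' `zeta > 0` every per-fixation value is bounded below by
#' `log2(zeta / (n_x * n_y))`.
#'
#' @param fixations Fixation tibble (`subject`, `image`, `x_deg`, `y_deg`,
#'   `dur_s`, optional `path`); rows in fixation order within each path.
#' @param saliency A saliency matrix, or a named list of matrices keyed by
#'   the `image` column.
#' @param params An [sw_params()] object.
#' @param grid An [sw_grid()].
#' @param engine `"cpp"` (default) or `"r"` (reference implementation).
#' @return A tibble with one row per fixation: the id columns,
#'   `fix_index`, and `log2_p`.
#' @export
scanpath_loglik <- function(fixations, saliency, params, grid,
                            engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(is_sw_params(params), is_sw_grid(grid))
  if (is.matrix(saliency)) {
    imgs <- unique(fixations$image)
    saliency <- setNames(rep(list(saliency), length(imgs)), imgs)
  }
  paths <- split_paths(fixations)
  # per-path terms are independent given the parameters, so evaluation
  # order cannot affect the result
  rows <- lapply(paths, function(p) {
    S <- saliency[[as.character(p$image)]]
    if (is.null(S)) {
      stop("no saliency map for image '", p$image, "'", call. = FALSE)
    }
    ll <- if (engine == "cpp") {
      cpp_replay(p$mat, S, params_for_cpp(params, grid))
    } else {
      replay_r(p$mat, S, params, grid)
    }
    tibble(subject = p$subject, image = p$image,
           fix_index = seq_along(ll), log2_p = ll)
  })
  out <- dplyr::bind_rows(rows)
  if (any(is.infinite(out$log2_p))) {
    warning("zero selection probability at ",
            sum(is.infinite(out$log2_p)),
            " observed fixation(s): log2_p = -Inf (zeta = 0?)",
            call. = FALSE)
  }
  out
}

#' Mean log2-likelihood per fixation over a dataset
#'
#' The model-comparison currency: per-fixation log2 probabilities pooled
#' over all scan paths, then averaged. (Parameter estimation instead uses
#' the non-normalized sum, see [log_posterior()].)
#'
#' @inheritParams scanpath_loglik
#' @return A single number (bits per fixation).
#' @export
dataset_mean_bits <- function(fixations, saliency, params, grid,
                              engine = c("cpp", "r")) {
  if (nrow(fixations) == 0) stop("empty fixation table", call. = FALSE)
  ll <- scanpath_loglik(fixations, saliency, params, grid, engine = engine)
  mean(ll$log2_p)
}

#' Sum log2-likelihood of a dataset
#'
#' @inheritParams scanpath_loglik
#' @return A single number (bits).
#' @export
dataset_sum_bits <- function(fixations, saliency, params, grid,
                             engine = c("cpp", "r")) {
  ll <- scanpath_loglik(fixations, saliency, params, grid, engine = engine)
  sum(ll$log2_p)
}

#' Static reference comparators for the likelihood ladder
#'
#' Two dynamics-free baselines bracket the dynamical models in
#' likelihood comparisons. `comparator_density()` scores every fixation
#' against one fixed probability map (the long-run fixation density,
#' e.g. a smoothed histogram of training fixations via
#' [empirical_density()]). `comparator_local_saliency()` scores each
#' fixation against the saliency map seen through the attention aperture
#' at the previous fixation (no evolving state); its first fixation is
#' scored against the normalized saliency map.
#'
#' Both mix in the uniform floor `zeta` exactly like the dynamical models
#' so the comparison is on equal footing.
#'
#' @inheritParams scanpath_loglik
#' @param density_map Probability map over the grid (sums to 1).
#' @param sigma_A Aperture width (degrees) for the local-saliency
#'   comparator.
#' @param zeta Uniform mixing weight in (0, 1].
#' @return A tibble like [scanpath_loglik()]'s.
#' @export
comparator_density <- function(fixations, density_map, grid, zeta = 0.01) {
  stopifnot(is_sw_grid(grid), abs(sum(density_map) - 1) < 1e-6)
  pi_map <- selection_probability(density_map, zeta)
  cells <- deg_to_cell(cbind(fixations$x_deg, fixations$y_deg), grid)
  tibble(subject = fixations$subject, image = fixations$image,
         log2_p = log2(pi_map[cbind(cells[, 1], cells[, 2])]))
}

#' @rdname comparator_density
#' @export
comparator_local_saliency <- function(fixations, saliency, grid,
                                      sigma_A = 7.3, zeta = 0.01) {
  stopifnot(is_sw_grid(grid))
  if (is.matrix(saliency)) {
    imgs <- unique(fixations$image)
    saliency <- setNames(rep(list(saliency), length(imgs)), imgs)
  }
  paths <- split_paths(fixations)
  rows <- lapply(paths, function(p) {
    S <- saliency[[as.character(p$image)]]
    n <- nrow(p$mat)
    ll <- numeric(n)
    cells <- deg_to_cell(p$mat[, 1:2, drop = FALSE], grid)
    pi1 <- selection_probability(normalize_map(S), zeta)
    ll[1] <- log2(pi1[cells[1, 1], cells[1, 2]])
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        w <- attention_input(S, gaussian_map(p$mat[i, 1:2], sigma_A, grid))
        pim <- selection_probability(w, zeta)
        ll[i + 1] <- log2(pim[cells[i + 1, 1], cells[i + 1, 2]])
      }
    }
    tibble(subject = p$subject, image = p$image,
           fix_index = seq_len(n), log2_p = ll)
  })
  dplyr::bind_rows(rows)
}

#' Smoothed empirical fixation density on a grid
#'
#' A 2D histogram of fixation positions smoothed with an isotropic
#' Gaussian kernel and normalized to unit sum; the static density used by
#' [comparator_density()].
#'
#' @param fixations Fixation tibble.
#' @param grid An [sw_grid()].
#' @param bandwidth Kernel standard deviation in degrees.
#' @return Probability matrix over grid cells.
#' @export
empirical_density <- function(fixations, grid, bandwidth = 1) {
  stopifnot(is_sw_grid(grid), nrow(fixations) > 0, bandwidth > 0)
  cells <- deg_to_cell(cbind(fixations$x_deg, fixations$y_deg), grid)
  H <- matrix(0, grid$n_x, grid$n_y)
  for (r in seq_len(nrow(cells))) {
    H[cells[r, 1], cells[r, 2]] <- H[cells[r, 1], cells[r, 2]] + 1
  }
  # smooth by separable Gaussian filtering along both axes
  gauss_filter <- function(v, centers, sd) {
    W <- exp(-outer(centers, centers, "-")^2 / (2 * sd^2))
    W %*% v
  }
  H <- gauss_filter(H, grid$xs, bandwidth)
  H <- t(gauss_filter(t(H), grid$ys, bandwidth))
  normalize_map(H)
}
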