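#' Synthetic saliency map
#'
#' A mixture of Gaussian blobs over a uniform floor, sum-normalized:
#' a stand-in for the empirical saliency of natural scenes, with blob
#' count, placement, size and weight drawn reproducibly from the given
#' seed.
#'
#' @param grid An [sw_grid()].
#' @param n_blobs Number of Gaussian blobs (0 gives a uniform map).
#' @param sigma_range Blob width range in degrees.
#' @param weight_range Blob weight range (relative).
#' @param background Uniform floor as a fraction of total mass (in
#'   (0, 1]; must be positive when `n_blobs = 0`).
#' @param margin Blob centers are kept this fraction of the extent away
#'   from the borders.
#' @param seed Optional integer seed; identical seeds give identical maps.
#' @param centers Optional n-by-2 matrix of blob centers (degrees),
#'   overriding random placement.
#' @return A probability matrix over grid cells (positive, sums to 1).
#' @export
make_saliency <- function(grid, n_blobs = 4, sigma_range = c(1.5, 4),
                          weight_range = c(0.5, 1), background = 0.1,
                          margin = 0.1, seed = NULL, centers = NULL) {
  stopifnot(is_sw_grid(grid), n_blobs >= 0, background > 0, background <= 1)
  if (!is.null(seed)) {
    old <- .Random.seed_store()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  S <- matrix(0, grid$n_x, grid$n_y)
  if (n_blobs > 0) {
    if (is.null(centers)) {
      centers <- cbind(
        runif(n_blobs, margin * grid$extent_x, (1 - margin) * grid$extent_x),
        runif(n_blobs, margin * grid$extent_y, (1 - margin) * grid$extent_y)
      )
    }
    stopifnot(nrow(centers) == n_blobs)
    sig <- runif(n_blobs, sigma_range[1], sigma_range[2])
    w <- runif(n_blobs, weight_range[1], weight_range[2])
    for (b in seq_len(n_blobs)) {
      S <- S + w[b] * normalize_map(gaussian_map(centers[b, ], sig[b], grid))
    }
    S <- (1 - background) * S / sum(S)
  }
  S <- S + background / (grid$n_x * grid$n_y)
  normalize_map(S)
}

#' Benchmark dataset with known ground truth
#'
#' Simulates a multi-subject, multi-image fixation dataset from the model
#' at known parameters, with optional per-subject jitter of the
#' attention-span and decay parameters (mimicking inter-individual
#' differences). Everything needed to score parameter recovery is
#' returned: the fixation table, the saliency maps, and the per-subject
#' true parameter values.
#'
#' @param params An [sw_params()] object (the population-level truth).
#' @param grid An [sw_grid()].
#' @param n_subjects,n_images,n_paths,n_fix Dataset dimensions.
#' @param jitter_sd Standard deviation of multiplicative lognormal jitter
#'   applied per subject to `sigma_A` and `omega_A` (0 = identical
#'   subjects).
#' @param seed Integer seed; the dataset is a pure function of the
#'   arguments and this seed.
#' @param dir Optional directory: when given, the standard CSV/matrix
#'   files (`fixations.csv`, `saliency_<image>.txt`, `truth.csv`,
#'   `params.yaml`) are written there.
#' @return A list with `fixations` (tibble), `saliency` (named list of
#'   matrices), `truth` (tibble of per-subject parameters), `params`,
#'   `grid`, `seed`.
#' @export
make_benchmark_dataset <- function(params, grid, n_subjects = 5,
                                   n_images = 3, n_paths = 2, n_fix = 30,
                                   jitter_sd = 0.15, seed = 1, dir = NULL) {
  stopifnot(is_sw_params(params), is_sw_grid(grid))
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  saliency <- lapply(seq_len(n_images), function(i) {
    make_saliency(grid, n_blobs = sample(2:5, 1))
  })
  names(saliency) <- sprintf("image_%02d", seq_len(n_images))
  subject_params <- vector("list", n_subjects)
  truth <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    th <- params_to_vector(params)
    th[["sigma_A"]] <- th[["sigma_A"]] * exp(rnorm(1, 0, jitter_sd))
    th[["omega_A"]] <- th[["omega_A"]] * exp(rnorm(1, 0, jitter_sd))
    subject_params[[s]] <- params_from_vector(th, params)
    truth[[s]] <- tibble(subject = sprintf("s%02d", s),
                         as_tibble(as.list(th)))
  }
  fixations <- simulate_dataset(
    saliency, params, grid, n_subjects = n_subjects, n_paths = n_paths,
    n_fix = n_fix, subject_params = subject_params
  )
  truth <- dplyr::bind_rows(truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fixations(fixations, file.path(dir, "fixations.csv"))
    readr::write_csv(truth, file.path(dir, "truth.csv"), progress = FALSE)
    for (im in names(saliency)) {
      write_saliency(saliency[[im]], file.path(dir, paste0("saliency_", im, ".txt")))
    }
    write_params_yaml(params, file.path(dir, "params.yaml"))
  }
  list(fixations = fixations, saliency = saliency, truth = truth,
       params = params, grid = grid, seed = seed)
}

#' Synthesize a raw gaze trace from a scan path
#'
#' Renders a fixation sequence as uniformly sampled gaze coordinates:
#' stationary fixation epochs with isotropic Gaussian jitter, joined by
#' smooth (raised-cosine velocity profile) saccadic flights of fixed
#' duration. The inverse operation is [detect_saccades()].
#'
#' @param path Tibble or matrix with fixation `x_deg`, `y_deg`, `dur_s`
#'   (columns 1:3 if a matrix).
#' @param rate Sampling rate in Hz (default 500).
#' @param noise_sd Fixational jitter standard deviation in degrees.
#' @param saccade_dur Saccade flight time in seconds (default 0.04).
#' @return A tibble with `t` (s), `x`, `y` (degrees).
#' @export
simulate_gaze_trace <- function(path, rate = 500, noise_sd = 0.05,
                                saccade_dur = 0.04) {
  m <- if (is.matrix(path)) path else cbind(path$x_deg, path$y_deg, path$dur_s)
  n <- nrow(m)
  dt <- 1 / rate
  xs <- list()
  k <- 0
  for (i in seq_len(n)) {
    nf <- max(1, round(m[i, 3] * rate))
    k <- k + 1
    xs[[k]] <- cbind(
      x = m[i, 1] + rnorm(nf, 0, noise_sd),
      y = m[i, 2] + rnorm(nf, 0, noise_sd)
    )
    if (i < n) {
      ns <- max(2, round(saccade_dur * rate))
      # raised-cosine position profile: smooth velocity, zero at endpoints
      s <- (1 - cos(pi * seq_len(ns) / (ns + 1))) / 2
      k <- k + 1
      xs[[k]] <- cbind(
        x = m[i, 1] + s * (m[i + 1, 1] - m[i, 1]),
        y = m[i, 2] + s * (m[i + 1, 2] - m[i, 2])
      )
    }
  }
  out <- do.call(rbind, xs)
  tibble(t = (seq_len(nrow(out)) - 1) * dt, x = out[, "x"], y = out[, "y"])
}

#' Velocity-based saccade detection
#'
#' The detector used on raw gaze recordings: velocities are estimated
#' with a 5-point smoothed differentiator; a sample is saccadic when its
#' velocity exceeds `lambda` median-based standard deviations (an
#' elliptic threshold combining the horizontal and vertical components,
#' each scaled by 1.4826 x the median absolute deviation); runs of at
#' least `min_samples` consecutive saccadic samples whose displacement is
#' at least `min_amplitude` degrees count as saccades. The epochs between
#' saccades are returned as fixations with their mean position and
#' duration.
#'
#' @param trace Tibble with `t`, `x`, `y` from a uniformly sampled
#'   recording (e.g. [simulate_gaze_trace()]).
#' @param lambda Velocity threshold multiplier (default 6).
#' @param min_samples Minimum consecutive samples above threshold
#'   (default 6; 12 ms at 500 Hz).
#' @param min_amplitude Minimum saccade amplitude in degrees (default
#'   0.5).
#' @return A list with `fixations` (tibble `x_deg`, `y_deg`, `dur_s`) and
#'   `saccades` (tibble `t_start`, `t_end`, `amplitude`).
#' @export
detect_saccades <- function(trace, lambda = 6, min_samples = 6,
                            min_amplitude = 0.5) {
  n <- nrow(trace)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  dt <- median(diff(trace$t))
  if (n < max(5, min_samples)) {
    return(list(
      fixations = tibble(x_deg = mean(trace$x), y_deg = mean(trace$y),
                         dur_s = n * dt),
      saccades = tibble(t_start = numeric(), t_end = numeric(),
                        amplitude = numeric())
    ))
  }
  # 5-point smoothed differentiation
  vel <- function(z) {
    v <- rep(0, n)
    v[3:(n - 2)] <- (z[5:n] + z[4:(n - 1)] - z[2:(n - 3)] - z[1:(n - 4)]) /
      (6 * dt)
    v
  }
  vx <- vel(trace$x)
  vy <- vel(trace$y)
  sx <- mad(vx)
  sy <- mad(vy)
  if (sx == 0) sx <- .Machine$double.eps
  if (sy == 0) sy <- .Machine$double.eps
  hot <- (vx / (lambda * sx))^2 + (vy / (lambda * sy))^2 > 1
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- which(runs$values & runs$lengths >= min_samples)
  sacc <- list()
  for (ci in cand) {
    i0 <- starts[ci]
    i1 <- ends[ci]
    amp <- sqrt((trace$x[i1] - trace$x[i0])^2 + (trace$y[i1] - trace$y[i0])^2)
    if (amp >= min_amplitude) {
      sacc[[length(sacc) + 1]] <- c(i0, i1, amp)
    }
  }
  if (length(sacc) == 0) {
    return(list(
      fixations = tibble(x_deg = mean(trace$x), y_deg = mean(trace$y),
                         dur_s = n * dt),
      saccades = tibble(t_start = numeric(), t_end = numeric(),
                        amplitude = numeric())
    ))
  }
  sm <- do.call(rbind, sacc)
  # fixations are the epochs between consecutive saccades
  bounds <- rbind(c(1, sm[1, 1] - 1),
                  cbind(sm[-nrow(sm), 2] + 1, sm[-1, 1] - 1),
                  c(sm[nrow(sm), 2] + 1, n))
  bounds <- bounds[bounds[, 2] >= bounds[, 1] & bounds[, 1] >= 1, , drop = FALSE]
  fx <- apply(bounds, 1, function(b) {
    idx <- b[1]:b[2]
    c(mean(trace$x[idx]), mean(trace$y[idx]), length(idx) * dt)
  })
  list(
    fixations = tibble(x_deg = fx[1, ], y_deg = fx[2, ], dur_s = fx[3, ]),
    saccades = tibble(t_start = trace$t[sm[, 1]], t_end = trace$t[sm[, 2]],
                      amplitude = sm[, 3])
  )
}
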