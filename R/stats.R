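#' Saccade records from fixation sequences
#'
#' Converts each scan path of n fixations into n - 1 saccade records:
#' launch and landing positions, amplitude (Euclidean distance in
#' degrees), absolute direction (degrees counterclockwise from rightward,
#' in `[0, 360)`), the signed turning angle relative to the previous
#' saccade (degrees in (-180, 180]; `NA` for each path's first saccade),
#' and the duration of the fixation preceding the saccade.
#'
#' @param fixations Fixation tibble (`subject`, `image`, optional `path`,
#'   `x_deg`, `y_deg`, `dur_s`).
#' @return A tibble of saccade records; paths with fewer than two
#'   fixations contribute no rows.
#' @export
saccades <- function(fixations) {
  paths <- split_paths(fixations)
  rows <- lapply(paths, function(p) {
    m <- p$mat
    n <- nrow(m)
    if (n < 2) return(NULL)
    dx <- diff(m[, 1])
    dy <- diff(m[, 2])
    amp <- sqrt(dx^2 + dy^2)
    dir <- (atan2(dy, dx) * 180 / pi) %% 360
    # turning angle is undefined for the first saccade of a path and
    # whenever either saccade of the pair has zero amplitude
    turn <- rep(NA_real_, n - 1)
    if (n >= 3) {
      pv <- cbind(dx, dy)[-(n - 1), , drop = FALSE]
      nv <- cbind(dx, dy)[-1, , drop = FALSE]
      defined <- rowSums(pv^2) > 0 & rowSums(nv^2) > 0
      if (any(defined)) {
        turn[-1][defined] <- turning_angle(pv[defined, , drop = FALSE],
                                           nv[defined, , drop = FALSE])
      }
    }
    tibble(
      subject = p$subject, image = p$image,
      sacc_index = seq_len(n - 1),
      x0 = m[-n, 1], y0 = m[-n, 2], x1 = m[-1, 1], y1 = m[-1, 2],
      amplitude = amp, direction = dir, turning = turn,
      prev_dur = m[-n, 3]
    )
  })
  dplyr::bind_rows(rows)
}

#' Signed turning angle between consecutive saccade vectors
#'
#' The divergence of a saccade from the previous saccade's direction:
#' 0 means the direction is maintained (a forward saccade), 180 a full
#' reversal (a return saccade); the sign follows the counterclockwise
#' convention. Result in (-180, 180].
#'
#' @param prev_vec,next_vec Numeric `c(dx, dy)` vectors, or n-by-2
#'   matrices of vectors; all must be non-zero.
#' @return Angle(s) in degrees.
#' @examples
#' turning_angle(c(1, 0), c(0, 1))   # 90
#' turning_angle(c(1, 0), c(-1, 0))  # 180
#' @export
turning_angle <- function(prev_vec, next_vec) {
  p <- if (is.matrix(prev_vec)) prev_vec else matrix(prev_vec, ncol = 2)
  q <- if (is.matrix(next_vec)) next_vec else matrix(next_vec, ncol = 2)
  stopifnot(nrow(p) == nrow(q))
  if (any(rowSums(p^2) == 0) || any(rowSums(q^2) == 0)) {
    stop("zero-length saccade vector: turning angle undefined", call. = FALSE)
  }
  cross <- p[, 1] * q[, 2] - p[, 2] * q[, 1]
  dot <- p[, 1] * q[, 1] + p[, 2] * q[, 2]
  a <- atan2(cross, dot) * 180 / pi
  a[a <= -180] <- 180
  if (is.matrix(prev_vec) || is.matrix(next_vec)) a else a[1]
}

#' Saccade-relative landing density
#'
#' For every pair of consecutive saccades, the landing point of the
#' second is expressed in coordinates normalized to the first: the
#' current fixation is the origin, the previous saccade direction is the
#' +x axis, and the previous amplitude is 1. The previous saccade thus
#' ran from (-1, 0) to (0, 0); a perfect return saccade lands at (-1, 0)
#' and an equal-amplitude forward saccade at (1, 0). Returns a binned 2D
#' histogram of these normalized landing points.
#'
#' @param sacc Saccade tibble from [saccades()].
#' @param window Half-width of the square histogram window (default 2, in
#'   units of the previous amplitude).
#' @param binwidth Bin side length (default 0.1).
#' @return A list with `density` (tibble `x`, `y`, `count`, `density` per
#'   bin), `points` (the normalized landing points), and `n_skipped`
#'   (records dropped for zero-amplitude previous saccades).
#' @export
relative_saccade_density <- function(sacc, window = 2, binwidth = 0.1) {
  ok <- !is.na(sacc$turning)
  cur <- sacc[ok, ]
  prev <- sacc[which(ok) - 1, ]
  keep <- prev$amplitude > 0
  n_skipped <- sum(!keep)
  cur <- cur[keep, ]
  prev <- prev[keep, ]
  # rotate the landing vector into the previous saccade's frame and scale
  theta <- atan2(prev$y1 - prev$y0, prev$x1 - prev$x0)
  vx <- cur$x1 - cur$x0
  vy <- cur$y1 - cur$y0
  xn <- (cos(-theta) * vx - sin(-theta) * vy) / prev$amplitude
  yn <- (sin(-theta) * vx + cos(-theta) * vy) / prev$amplitude
  breaks <- seq(-window, window, by = binwidth)
  inside <- xn >= -window & xn <= window & yn >= -window & yn <= window
  xb <- cut(xn[inside], breaks, include.lowest = TRUE)
  yb <- cut(yn[inside], breaks, include.lowest = TRUE)
  tab <- table(xb, yb)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  dens <- tibble(
    x = rep(mids, times = length(mids)),
    y = rep(mids, each = length(mids)),
    count = as.vector(tab)
  )
  total <- sum(dens$count)
  dens$density <- if (total > 0) dens$count / (total * binwidth^2) else 0
  list(density = dens, points = tibble(x = xn, y = yn),
       n_skipped = n_skipped)
}

#' Per-turning-angle-bin means of a saccade property
#'
#' Folds turning angles to `[0, 180]` (forward/return symmetry), bins them,
#' and reports the across-subject mean of the per-subject means of either
#' the preceding fixation duration or the saccade amplitude, with a
#' percentile-bootstrap confidence band over subjects. Empty bins are
#' reported as missing, not zero.
#'
#' @param sacc Saccade tibble from [saccades()].
#' @param value `"prev_dur"` or `"amplitude"`.
#' @param bin_width Bin width in degrees (default 30).
#' @param n_boot Bootstrap resamples of subjects (default 1000).
#' @param conf_level Confidence level for the band.
#' @return A tibble with `angle_bin` (midpoint, degrees), `mean`,
#'   `ci_lower`, `ci_upper`, `n_subjects`.
#' @export
binned_by_turning_angle <- function(sacc, value = c("prev_dur", "amplitude"),
                                    bin_width = 30, n_boot = 1000,
                                    conf_level = 0.95) {
  value <- match.arg(value)
  s <- sacc[!is.na(sacc$turning), ]
  if (nrow(s) == 0) stop("no saccades with a defined turning angle", call. = FALSE)
  folded <- abs(s$turning)
  breaks <- seq(0, 180, by = bin_width)
  bin <- cut(folded, breaks, include.lowest = TRUE)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  per_subj <- dplyr::summarise(
    dplyr::group_by(
      tibble(subject = s$subject, bin = bin, v = s[[value]]),
      .data$subject, .data$bin, .drop = FALSE
    ),
    m = mean(.data$v), n = dplyr::n(), .groups = "drop"
  )
  per_subj <- per_subj[per_subj$n > 0, ]
  subjects <- unique(per_subj$subject)
  boot_mean <- function(b) {
    dat <- per_subj[per_subj$bin == b, ]
    if (nrow(dat) == 0) return(c(NA_real_, NA_real_, NA_real_, 0))
    est <- mean(dat$m)
    if (length(unique(dat$subject)) < 2) {
      return(c(est, NA_real_, NA_real_, length(unique(dat$subject))))
    }
    bs <- vapply(seq_len(n_boot), function(i) {
      pick <- sample(dat$subject, length(unique(dat$subject)), replace = TRUE)
      mean(dat$m[match(pick, dat$subject)], na.rm = TRUE)
    }, numeric(1))
    qs <- quantile(bs, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                   na.rm = TRUE)
    c(est, qs[1], qs[2], length(unique(dat$subject)))
  }
  res <- t(vapply(levels(bin), boot_mean, numeric(4)))
  tibble(angle_bin = mids, mean = res[, 1], ci_lower = res[, 2],
         ci_upper = res[, 3], n_subjects = as.integer(res[, 4]))
}

#' Distribution summaries of saccade amplitude and angles
#'
#' Per-subject normalized histograms of saccade amplitude, absolute
#' direction, and signed turning angle, plus the across-subject mean and
#' a percentile band for each. With a single subject the band is omitted
#' (`NA`).
#'
#' @param sacc Saccade tibble from [saccades()].
#' @param amplitude_binwidth Bin width in degrees (default 1).
#' @param angle_binwidth Bin width in degrees for both angle histograms
#'   (default 10).
#' @param conf_level Width of the between-subject percentile band.
#' @return A named list of tibbles (`amplitude`, `direction`, `turning`),
#'   each with `bin` (midpoint), `mean_density`, `band_lower`,
#'   `band_upper` (densities integrate to 1 per subject over the binned
#'   range).
#' @export
distribution_summaries <- function(sacc, amplitude_binwidth = 1,
                                   angle_binwidth = 10, conf_level = 0.95) {
  hist_band <- function(x, subject, breaks) {
    keep <- !is.na(x)
    x <- x[keep]
    subject <- subject[keep]
    mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
    bw <- diff(breaks)[1]
    per <- lapply(split(x, subject), function(v) {
      v <- v[v >= breaks[1] & v <= breaks[length(breaks)]]
      h <- hist(v, breaks = breaks, plot = FALSE)
      h$counts / (length(v) * bw)
    })
    M <- do.call(rbind, per)
    lo <- (1 - conf_level) / 2
    band <- if (nrow(M) >= 2) {
      apply(M, 2, quantile, probs = c(lo, 1 - lo))
    } else {
      matrix(NA_real_, 2, ncol(M))
    }
    tibble(bin = mids, mean_density = colMeans(M),
           band_lower = band[1, ], band_upper = band[2, ])
  }
  amax <- max(sacc$amplitude)
  amp_breaks <- seq(0, ceiling(amax / amplitude_binwidth) * amplitude_binwidth,
                    by = amplitude_binwidth)
  list(
    amplitude = hist_band(sacc$amplitude, sacc$subject, amp_breaks),
    direction = hist_band(sacc$direction, sacc$subject,
                          seq(0, 360, by = angle_binwidth)),
    turning = hist_band(sacc$turning, sacc$subject,
                        seq(-180, 180, by = angle_binwidth))
  )
}
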