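#' Default prior specification
#'
#' Broad, relatively uninformative bounded-uniform priors over the
#' estimated parameters, wide enough to bracket the published per-subject
#' estimates by several credibility widths: `omega_A` in (0.1, 60) 1/s,
#' `sigma_A` and `sigma_F` in (0.5, 15) degrees, `gamma` in (0.1, 3),
#' `log_zeta` in (-6, 0), and for the extended model `chi` in (0, 0.5),
#' `eta` in (0, 3) degrees, `log_psi` in (-4, 1).
#'
#' @param variant `"baseline"` or `"extended"`.
#' @return A tibble with columns `param`, `lower`, `upper`.
#' @export
sw_priors <- function(variant = c("extended", "baseline")) {
  variant <- match.arg(variant)
  pr <- tibble(
    param = c("omega_A", "sigma_A", "sigma_F", "gamma", "log_zeta",
              "chi", "eta", "log_psi"),
    lower = c(0.1, 0.5, 0.5, 0.1, -6, 0, 0, -4),
    upper = c(60, 15, 15, 3, 0, 0.5, 3, 1)
  )
  pr[pr$param %in% estimated_param_names(variant), ]
}

prior_logdensity <- function(theta, priors) {
  lo <- priors$lower[match(names(theta), priors$param)]
  hi <- priors$upper[match(names(theta), priors$param)]
  if (any(theta <= lo) || any(theta >= hi)) return(-Inf)
  -sum(log(hi - lo))
}

prior_sample <- function(priors) {
  setNames(runif(nrow(priors), priors$lower, priors$upper), priors$param)
}

#' Log posterior density of model parameters
#'
#' `log P(theta) + log L(theta | data)` up to the evidence constant, where
#' the log likelihood is the non-normalized sum over all of the subject's
#' scan paths (in nats). Parameters outside the prior support return
#' `-Inf` without evaluating the likelihood; the fixed-parameter couplings
#' (`omega_F = omega_FoR = omega_A / 10`, `C_F`, center-bias constants,
#' phase durations) are enforced inside via [params_from_vector()] and are
#' never sampled.
#'
#' @param theta Named numeric vector over [estimated_param_names()].
#' @param fixations Fixation tibble (one subject's training paths).
#' @param saliency Saliency matrix or named list keyed by image.
#' @param template An [sw_params()] object fixing variant and couplings.
#' @param grid An [sw_grid()].
#' @param priors Prior tibble from [sw_priors()].
#' @param engine `"cpp"` or `"r"`.
#' @return A single number (may be `-Inf`).
#' @export
log_posterior <- function(theta, fixations, saliency, template, grid,
                          priors = sw_priors(template$variant),
                          engine = "cpp") {
  lp <- prior_logdensity(theta, priors)
  if (!is.finite(lp)) return(-Inf)
  params <- params_from_vector(theta, template)
  bits <- suppressWarnings(
    dataset_sum_bits(fixations, saliency, params, grid, engine = engine)
  )
  lp + bits * log(2)
}

#' Differential-evolution MCMC with snooker updates
#'
#' A DREAM-class sampler: multiple chains propose jumps along difference
#' vectors of states sampled from the chains' joint past (the "z" archive
#' variant), with occasional snooker updates and occasional unit jump
#' scale for mode hopping. This family works with as few as three chains
#' even in moderate dimension because proposal directions come from the
#' archive rather than only from the other current chains.
#'
#' @param log_post Function `function(theta) -> log density` (named
#'   vector in, scalar out, `-Inf` allowed).
#' @param priors Prior tibble from [sw_priors()]; also used to initialize
#'   chains and the archive.
#' @param n_chains Number of chains (>= 3 recommended).
#' @param n_iter Iterations per chain.
#' @param seed Optional integer seed.
#' @param gamma_scale Base jump scale for full-space jumps; default
#'   `2.38 / sqrt(2 d)` (subspace jumps rescale by the number of updated
#'   coordinates).
#' @param p_snooker Probability of a snooker update.
#' @param p_gamma1 Probability of proposing with unit jump scale.
#' @param archive_stride Append current states to the archive every this
#'   many iterations.
#' @param init Optional matrix of starting points (`n_chains` rows).
#' @return A list with `draws` (tibble: `chain`, `iter`, parameters,
#'   `log_posterior`), `acceptance` (per chain), and `n_evals`.
#' @export
run_mcmc <- function(log_post, priors, n_chains = 3, n_iter = 2000,
                     seed = NULL, gamma_scale = NULL, p_snooker = 0.1,
                     p_gamma1 = 0.1, archive_stride = 10, init = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- nrow(priors)
  nms <- priors$param
  if (is.null(gamma_scale)) gamma_scale <- 2.38 / sqrt(2 * d)
  # current states and their log posteriors
  X <- matrix(NA_real_, n_chains, d, dimnames = list(NULL, nms))
  lp <- numeric(n_chains)
  for (c in seq_len(n_chains)) {
    ok <- FALSE
    for (tries in 1:100) {
      x0 <- if (!is.null(init)) init[c, ] else prior_sample(priors)
      names(x0) <- nms
      v <- log_post(x0)
      if (is.finite(v)) {
        X[c, ] <- x0
        lp[c] <- v
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not find a finite starting point for chain ", c,
                  call. = FALSE)
  }
  # archive of past states; seeded from the prior so early proposals span
  # the support
  Z <- matrix(NA_real_, max(10 * d, 2 * n_chains), d)
  for (r in seq_len(nrow(Z))) Z[r, ] <- prior_sample(priors)
  n_z <- nrow(Z)
  grow <- function(M, add) rbind(M, matrix(NA_real_, add, ncol(M)))
  draws <- array(NA_real_, c(n_iter, n_chains, d))
  lpost <- matrix(NA_real_, n_iter, n_chains)
  accepts <- integer(n_chains)
  n_evals <- 0L
  eps <- 1e-6
  for (it in seq_len(n_iter)) {
    for (c in seq_len(n_chains)) {
      x <- X[c, ]
      snooker <- runif(1) < p_snooker
      if (snooker) {
        zi <- sample.int(n_z, 3)
        z <- Z[zi[1], ]
        dvec <- x - z
        dd <- sum(dvec^2)
        if (dd == 0) next
        proj <- function(v) sum(v * dvec) / dd * dvec
        gs <- runif(1, 1.2, 2.2)
        xp <- x + gs * (proj(Z[zi[2], ]) - proj(Z[zi[3], ]))
        # snooker Metropolis correction for the move's non-symmetry
        corr <- (d - 1) / 2 *
          (log(sum((xp - z)^2)) - log(dd))
      } else {
        # parallel-direction jump restricted to a random coordinate
        # subspace (crossover), the standard DREAM mixing device
        zi <- sample.int(n_z, 2)
        cr <- sample(c(1 / 3, 2 / 3, 1), 1)
        sel <- runif(d) < cr
        if (!any(sel)) sel[sample.int(d, 1)] <- TRUE
        g <- if (runif(1) < p_gamma1) 1 else 2.38 / sqrt(2 * sum(sel))
        jump <- g * (Z[zi[1], ] - Z[zi[2], ]) + runif(d, -eps, eps)
        jump[!sel] <- 0
        xp <- x + jump
        corr <- 0
      }
      names(xp) <- nms
      lpp <- log_post(xp)
      n_evals <- n_evals + 1L
      if (is.finite(lpp) &&
          log(runif(1)) < (lpp - lp[c] + corr)) {
        X[c, ] <- xp
        lp[c] <- lpp
        accepts[c] <- accepts[c] + 1L
      }
    }
    draws[it, , ] <- X
    lpost[it, ] <- lp
    if (it %% archive_stride == 0) {
      if (n_z + n_chains > nrow(Z)) Z <- grow(Z, max(1000, n_chains))
      Z[n_z + seq_len(n_chains), ] <- X
      n_z <- n_z + n_chains
    }
  }
  tbl <- dplyr::bind_rows(lapply(seq_len(n_chains), function(c) {
    out <- as_tibble(as.data.frame(draws[, c, ]))
    names(out) <- nms
    out$chain <- c
    out$iter <- seq_len(n_iter)
    out$log_posterior <- lpost[, c]
    out
  }))
  list(
    draws = tbl[, c("chain", "iter", nms, "log_posterior")],
    acceptance = accepts / n_iter,
    n_evals = n_evals
  )
}

#' Fit a scan-path model to one subject's data
#'
#' Runs [run_mcmc()] on [log_posterior()] for the given variant,
#' estimating only the free parameters (fixed couplings enforced inside
#' the likelihood). Subjects are fitted independently: pass one subject's
#' fixations at a time.
#'
#' @inheritParams log_posterior
#' @param variant `"baseline"` or `"extended"`.
#' @param n_chains,n_iter,seed Passed to [run_mcmc()].
#' @param burn_in Fraction of initial iterations discarded from the
#'   posterior summaries (default 0.5); the full chains are kept in
#'   `$draws`.
#' @param template Optional [sw_params()] overriding the default fixed
#'   values.
#' @return An object of class `sw_fit` with elements `draws`,
#'   `posterior` (post burn-in draws), `rhat`, `acceptance`, `priors`,
#'   `template`, `grid` and the call settings. Convergence is summarised
#'   by the Gelman-Rubin statistic; values above 1.1 are reported with a
#'   warning, never hidden.
#' @export
fit_scanpath_model <- function(fixations, saliency, grid,
                               variant = c("extended", "baseline"),
                               n_chains = 3, n_iter = 2000, seed = NULL,
                               burn_in = 0.5, template = NULL,
                               priors = NULL, engine = "cpp") {
  variant <- match.arg(variant)
  if (is.null(template)) template <- sw_params(variant)
  if (is.null(priors)) priors <- sw_priors(variant)
  lpfun <- make_logpost_closure(fixations, saliency, template, grid,
                                priors, engine)
  res <- run_mcmc(lpfun, priors, n_chains = n_chains, n_iter = n_iter,
                  seed = seed)
  keep <- res$draws$iter > burn_in * n_iter
  posterior <- res$draws[keep, ]
  rh <- vapply(priors$param, function(nm) {
    gelman_rubin(posterior[[nm]], posterior$chain)
  }, numeric(1))
  if (any(rh > 1.1, na.rm = TRUE)) {
    warning("Gelman-Rubin R-hat > 1.1 for: ",
            paste(names(rh)[rh > 1.1], collapse = ", "),
            " - chains may not have converged", call. = FALSE)
  }
  structure(
    list(draws = res$draws, posterior = posterior, rhat = rh,
         acceptance = res$acceptance, n_evals = res$n_evals,
         priors = priors, template = template, grid = grid,
         variant = variant, n_chains = n_chains, n_iter = n_iter,
         burn_in = burn_in, seed = seed),
    class = "sw_fit"
  )
}

# pre-splits the data once so each posterior evaluation is just the
# compiled replays plus the prior check; equals log_posterior() exactly
make_logpost_closure <- function(fixations, saliency, template, grid,
                                 priors, engine = "cpp") {
  if (is.matrix(saliency)) {
    imgs <- unique(fixations$image)
    saliency <- setNames(rep(list(saliency), length(imgs)), imgs)
  }
  paths <- split_paths(fixations)
  smaps <- lapply(paths, function(p) saliency[[as.character(p$image)]])
  if (any(vapply(smaps, is.null, logical(1)))) {
    stop("missing saliency map for some image", call. = FALSE)
  }
  ln2 <- log(2)
  function(theta) {
    lp <- prior_logdensity(theta, priors)
    if (!is.finite(lp)) return(-Inf)
    params <- params_from_vector(theta, template)
    pc <- params_for_cpp(params, grid)
    bits <- 0
    for (k in seq_along(paths)) {
      bits <- bits + sum(if (engine == "cpp") {
        cpp_replay(paths[[k]]$mat, smaps[[k]], pc)
      } else {
        replay_r(paths[[k]]$mat, smaps[[k]], params, grid)
      })
    }
    if (!is.finite(bits)) return(-Inf)
    lp + bits * ln2
  }
}

#' Gelman-Rubin potential scale reduction factor
#'
#' @param x Numeric draws.
#' @param chain Chain labels aligned with `x`.
#' @return R-hat (>= 1; `NA` for a single chain or constant draws).
#' @export
gelman_rubin <- function(x, chain) {
  groups <- split(x, chain)
  m <- length(groups)
  if (m < 2) return(NA_real_)
  n <- min(lengths(groups))
  groups <- lapply(groups, function(g) g[seq_len(n)])
  means <- vapply(groups, mean, numeric(1))
  vars <- vapply(groups, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Highest-posterior-density interval and point estimate
#'
#' The shortest interval containing a fraction `alpha` of the draws
#' (unimodality assumed); the point estimate is the interval midpoint.
#' With `alpha = 0.5` this is the reported point estimator; with
#' `alpha = 0.95` it is the usual credible interval.
#'
#' @param x Numeric draws (>= 100 unless `n_min` is lowered).
#' @param alpha Fraction of draws the interval must contain.
#' @param n_min Minimum number of draws required.
#' @return Named vector `c(estimate, lower, upper)`.
#' @export
hpd_interval <- function(x, alpha = 0.5, n_min = 100) {
  x <- x[is.finite(x)]
  if (length(x) < n_min) {
    stop("need at least ", n_min, " draws for an HPD interval", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha <= 1)
  xs <- sort(x)
  n <- length(xs)
  m <- max(1, ceiling(alpha * n))
  if (m >= n) {
    lo <- xs[1]
    hi <- xs[n]
  } else {
    width <- xs[seq(m, n)] - xs[seq(1, n - m + 1)]
    k <- which.min(width)
    lo <- xs[k]
    hi <- xs[k + m - 1]
  }
  c(estimate = (lo + hi) / 2, lower = lo, upper = hi)
}

#' @export
print.sw_fit <- function(x, ...) {
  cat(sprintf("<sw_fit> %s model: %d chains x %d iterations (burn-in %g%%)\n",
              x$variant, x$n_chains, x$n_iter, 100 * x$burn_in))
  cat(sprintf("  acceptance: %s; max R-hat: %.3f\n",
              paste(sprintf("%.2f", x$acceptance), collapse = " "),
              max(x$rhat, na.rm = TRUE)))
  print(tidy(x))
  invisible(x)
}

#' Tidy posterior summaries of a fitted model
#'
#' One row per estimated parameter: the point estimate (midpoint of the
#' 50% highest-density interval), its bounds, a wider credible interval,
#' and the Gelman-Rubin statistic.
#'
#' @param x An `sw_fit` object.
#' @param conf_level Width of the reported credible interval.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `hpd50_lower`,
#'   `hpd50_upper`, `conf.low`, `conf.high`, `rhat`.
#' @export
tidy.sw_fit <- function(x, conf_level = 0.95, ...) {
  dplyr::bind_rows(lapply(x$priors$param, function(nm) {
    v <- x$posterior[[nm]]
    h50 <- hpd_interval(v, 0.5)
    hci <- hpd_interval(v, conf_level)
    tibble(term = nm, estimate = h50[["estimate"]],
           hpd50_lower = h50[["lower"]], hpd50_upper = h50[["upper"]],
           conf.low = hci[["lower"]], conf.high = hci[["upper"]],
           rhat = unname(x$rhat[nm]))
  }))
}

#' One-row summary of a fitted model
#'
#' @param x An `sw_fit` object.
#' @param ... Unused.
#' @return A tibble with sampler settings, mean acceptance, max R-hat and
#'   the best log posterior seen.
#' @export
glance.sw_fit <- function(x, ...) {
  tibble(
    variant = x$variant, n_chains = x$n_chains, n_iter = x$n_iter,
    n_evals = x$n_evals, mean_acceptance = mean(x$acceptance),
    max_rhat = max(x$rhat, na.rm = TRUE),
    max_log_posterior = max(x$posterior$log_posterior)
  )
}

#' Parameter object at the posterior point estimate
#'
#' @param fit An `sw_fit` object.
#' @return An [sw_params()] built from the HPD point estimates.
#' @export
fitted_params <- function(fit) {
  stopifnot(inherits(fit, "sw_fit"))
  td <- tidy(fit)
  params_from_vector(setNames(td$estimate, td$term), fit$template)
}
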