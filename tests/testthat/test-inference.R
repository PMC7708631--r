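test_that("log posterior is prior plus sum log likelihood in nats", {
  g <- tiny_grid(16, 12)
  S <- tiny_saliency(g, seed = 34)
  tmpl <- sw_params("baseline")
  pr <- sw_priors("baseline")
  set.seed(35)
  sp <- simulate_scanpath(S, tmpl, g, n_fix = 8)
  fx <- path_tbl(cbind(sp$x_deg, sp$y_deg, sp$dur_s))
  th <- params_to_vector(tmpl)
  lp <- log_posterior(th, fx, S, tmpl, g, priors = pr)
  bits <- dataset_sum_bits(fx, S, params_from_vector(th, tmpl), g)
  expect_equal(lp, -sum(log(pr$upper - pr$lower)) + bits * log(2),
               tolerance = 1e-6)
  # outside the prior support the posterior is -Inf without evaluation
  th_bad <- th
  th_bad[["sigma_A"]] <- 1e4
  expect_identical(log_posterior(th_bad, fx, S, tmpl, g, priors = pr), -Inf)
  # flat prior: posterior differences equal log-likelihood differences
  th2 <- th
  th2[["sigma_A"]] <- th[["sigma_A"]] + 1
  d_post <- log_posterior(th2, fx, S, tmpl, g, priors = pr) - lp
  d_lik <- (dataset_sum_bits(fx, S, params_from_vector(th2, tmpl), g) -
              bits) * log(2)
  expect_equal(d_post, d_lik, tolerance = 1e-9)
})

test_that("a single fixation under full noise scores the uniform density", {
  g <- tiny_grid(16, 12)
  S <- tiny_saliency(g, seed = 36)
  tmpl <- sw_params("baseline", log_zeta = log(1 - 1e-12))
  pr <- sw_priors("baseline")
  fx <- path_tbl(matrix(c(10, 10, 0.3), 1, 3))
  th <- params_to_vector(tmpl)
  lp <- log_posterior(th, fx, S, tmpl, g, priors = pr)
  expect_equal(lp, -sum(log(pr$upper - pr$lower)) + log(1 / (16 * 12)),
               tolerance = 1e-6)
})

test_that("the sampler recovers a two-parameter Gaussian toy posterior", {
  mu <- c(1.5, -0.5)
  Sig <- matrix(c(1, 0.6, 0.6, 0.8), 2)
  Sinv <- solve(Sig)
  lp <- function(theta) {
    d <- theta - mu
    -0.5 * drop(t(d) %*% Sinv %*% d)
  }
  pr <- tibble::tibble(param = c("a", "b"), lower = c(-10, -10),
                       upper = c(10, 10))
  res <- run_mcmc(lp, pr, n_chains = 3, n_iter = 5000, seed = 37)
  draws <- res$draws[res$draws$iter > 2500, ]
  est_mu <- c(mean(draws$a), mean(draws$b))
  est_cov <- stats::cov(cbind(draws$a, draws$b))
  expect_lt(max(abs(est_mu - mu)), 0.05 * max(abs(mu)) + 0.05)
  expect_lt(max(abs(est_cov - Sig)), 0.05 * max(Sig) + 0.05)
  # fixed seed reproduces the chains exactly
  res2 <- run_mcmc(lp, pr, n_chains = 3, n_iter = 200, seed = 38)
  res3 <- run_mcmc(lp, pr, n_chains = 3, n_iter = 200, seed = 38)
  expect_identical(res2$draws, res3$draws)
})

test_that("a constant likelihood returns the prior", {
  pr <- tibble::tibble(param = c("a", "b"), lower = c(-2, 1),
                       upper = c(3, 4))
  # posterior = prior x constant likelihood (the target always carries
  # the prior; a flat likelihood contributes nothing)
  lp <- function(theta) {
    if (any(theta <= pr$lower) || any(theta >= pr$upper)) -Inf else 0
  }
  res <- run_mcmc(lp, pr, n_chains = 3, n_iter = 5000, seed = 39)
  draws <- res$draws[res$draws$iter > 1000 & res$draws$iter %% 50 == 0, ]
  # thinned draws against the uniform prior, per parameter
  expect_gt(stats::ks.test(draws$a, "punif", -2, 3)$p.value, 0.01)
  expect_gt(stats::ks.test(draws$b, "punif", 1, 4)$p.value, 0.01)
})

test_that("HPD intervals are the shortest alpha-mass intervals", {
  expect_equal(hpd_interval(rep(2.5, 200), 0.5),
               c(estimate = 2.5, lower = 2.5, upper = 2.5))
  x <- seq(0, 1, length.out = 1001)
  expect_equal(hpd_interval(x, 1),
               c(estimate = 0.5, lower = 0, upper = 1))
  set.seed(41)
  z <- rnorm(20000)
  h <- hpd_interval(z, 0.5)
  expect_lt(abs(h[["estimate"]] - median(z)), 0.03)
  expect_lt(abs((h[["upper"]] - h[["lower"]]) - 2 * qnorm(0.75)), 0.05)
  expect_error(hpd_interval(rnorm(10), 0.5), "at least")
})

test_that("recorded log posteriors match recomputation on a real fit", {
  g <- tiny_grid(16, 12)
  S <- tiny_saliency(g, seed = 42)
  set.seed(43)
  fx <- simulate_dataset(S, sw_params("baseline"), g, n_subjects = 1,
                         n_paths = 3, n_fix = 10)
  fit <- suppressWarnings(
    fit_scanpath_model(fx, S, g, "baseline", n_chains = 3, n_iter = 100,
                       seed = 44)
  )
  pr <- fit$priors
  pick <- fit$draws[c(10, 150, 290), ]
  for (r in seq_len(nrow(pick))) {
    th <- unlist(pick[r, pr$param])
    expect_equal(pick$log_posterior[r],
                 log_posterior(th, fx, S, fit$template, g, priors = pr),
                 tolerance = 1e-6)
  }
  # tidy/glance summaries expose estimates, intervals and diagnostics
  td <- tidy(fit)
  expect_setequal(td$term, pr$param)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$variant, "baseline")
  expect_true(is.finite(gl$max_rhat))
  expect_s3_class(fitted_params(fit), "sw_params")
})

test_that("split chains on a stationary target pass the R-hat gate", {
  lp <- function(theta) -0.5 * sum(theta^2)
  pr <- tibble::tibble(param = c("a", "b"), lower = c(-8, -8),
                       upper = c(8, 8))
  res <- run_mcmc(lp, pr, n_chains = 4, n_iter = 3000, seed = 45)
  keep <- res$draws[res$draws$iter > 1500, ]
  expect_lt(gelman_rubin(keep$a, keep$chain), 1.1)
  expect_lt(gelman_rubin(keep$b, keep$chain), 1.1)
  expect_true(is.na(gelman_rubin(keep$a[keep$chain == 1],
                                 keep$chain[keep$chain == 1])))
})
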