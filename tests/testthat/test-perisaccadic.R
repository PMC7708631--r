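test_that("phase schedules partition the fixation", {
  fixn <- c(8, 6)
  nxt <- c(10, 6)
  rm <- c(9, 6)
  ph <- schedule_phases(0.30, 0.1, 0.05, TRUE, fixn, nxt, rm)
  expect_equal(ph$phase, c("post_shift", "main", "pre_shift"))
  expect_equal(ph$start, c(0, 0.05, 0.20))
  expect_equal(ph$end, c(0.05, 0.20, 0.30))
  expect_equal(ph$f_center_x, rep(8, 3))
  expect_equal(ph$a_center_x, c(9, 8, 10))
  # no phase boundaries with both taus zero: a single main phase
  ph0 <- schedule_phases(0.4, 0, 0, TRUE, fixn, nxt, rm)
  expect_equal(ph0$phase, "main")
  expect_equal(c(ph0$start, ph0$end), c(0, 0.4))
  # short fixation: pre-saccadic phase keeps priority, post truncated
  phs <- schedule_phases(0.12, 0.1, 0.05, TRUE, fixn, nxt, rm)
  expect_equal(phs$phase, c("post_shift", "pre_shift"))
  expect_equal(phs$end - phs$start, c(0.02, 0.10))
  # first fixation has no post-saccadic phase
  ph1 <- schedule_phases(0.3, 0.1, 0.05, FALSE, fixn, nxt, NULL)
  expect_false("post_shift" %in% ph1$phase)
  # schedules always span [0, t_fix] contiguously
  set.seed(7)
  for (k in 1:30) {
    tf <- runif(1, 0.05, 0.6)
    ph <- schedule_phases(tf, 0.1, 0.05, TRUE, fixn, nxt, rm)
    expect_equal(ph$start[1], 0)
    expect_equal(ph$end[nrow(ph)], tf)
    if (nrow(ph) > 1) expect_equal(ph$start[-1], ph$end[-nrow(ph)])
  }
  expect_error(schedule_phases(0, 0.1, 0.05, TRUE, fixn), "positive")
})

test_that("remap extends the saccade vector by eta", {
  r <- remap_location(c(0, 0), c(3, 0), eta = 0.415)
  expect_equal(r$location, c(3.415, 0))
  expect_equal(remap_location(c(1, 1), c(1, 4), 1)$location, c(1, 5))
  set.seed(8)
  for (k in 1:20) {
    a <- runif(2, 0, 30)
    b <- runif(2, 0, 30)
    eta <- runif(1, 0.1, 2)
    r <- remap_location(a, b, eta)
    expect_equal(sqrt(sum((r$location - b)^2)), eta)
  }
  expect_error(remap_location(c(1, 1), c(1, 1), 0.4), "zero-length")
})

test_that("peri-saccadic Gaussians are ordinary apertures at shifted centers", {
  g <- tiny_grid(33, 25)
  p <- sw_params("extended")
  fix <- c(12, 9)
  expect_identical(presaccadic_gaussian(fix, p$sigma_A, g),
                   gaussian_map(fix, p$sigma_A, g))
  sh <- remap_location(c(6, 9), fix, 2)
  Gp <- postsaccadic_gaussian(sh, 1, g)
  expect_equal(unname(which(Gp == max(Gp), arr.ind = TRUE)[1, ]),
               deg_to_cell(sh$location, g))
  expect_identical(postsaccadic_gaussian(list(location = fix), p$sigma_A, g),
                   gaussian_map(fix, p$sigma_A, g))
})

test_that("pre-saccadic evolution moves attention mass to the next target", {
  g <- sw_grid(48, 36, 32, 24)
  S <- tiny_saliency(g, seed = 9)
  p <- sw_params("extended")
  A0 <- normalize_map(attention_input(S, gaussian_map(c(8, 12), p$sigma_A, g)))
  nxt <- c(26, 16)
  target <- attention_input(S, presaccadic_gaussian(nxt, p$sigma_A, g))
  A1 <- evolve_map(A0, target, p$omega_A, 0.1)
  disc <- outer((g$xs - nxt[1])^2, rep(1, g$n_y)) +
    outer(rep(1, g$n_x), (g$ys - nxt[2])^2) < (2 * p$sigma_A)^2
  expect_gt(sum(A1[disc]), sum(A0[disc]))
})

test_that("facilitation window slows decay without moving the fixed point", {
  g <- tiny_grid(32, 24)
  set.seed(10)
  A0 <- random_map(g$n_x, g$n_y)
  tgt <- normalize_map(random_map(g$n_x, g$n_y))
  prev <- c(10, 10)
  # omega_FoR = omega_A is plain relaxation
  expect_equal(evolve_attention_for(A0, tgt, 5, 5, prev, 2, 0.2, g),
               evolve_map(A0, tgt, 5, 0.2))
  # closed form with the published coupling omega_FoR = omega_A / 10
  one <- matrix(1, g$n_x, g$n_y)
  zero <- matrix(0, g$n_x, g$n_y)
  Af <- evolve_attention_for(one, zero, 1, 0.1, prev, 2, 1, g)
  cc <- deg_to_cell(prev, g)
  far <- deg_to_cell(c(30, 2), g)
  expect_equal(Af[cc[1], cc[2]], exp(-0.1))
  expect_equal(Af[far[1], far[2]], exp(-1))
  # window cells retain strictly more of (A0 - target)
  A2 <- evolve_attention_for(A0, tgt, 8, 0.8, prev, 2, 0.3, g)
  plain <- evolve_map(A0, tgt, 8, 0.3)
  ix <- abs(g$xs - prev[1]) < 2
  jy <- abs(g$ys - prev[2]) < 2
  win <- outer(ix, jy)
  pos <- win & (A0 > tgt)
  expect_true(all(A2[pos] > plain[pos]))
  expect_equal(A2[!win], plain[!win])
  # the fixed point is unchanged by the window
  expect_lt(max(abs(evolve_attention_for(A0, tgt, 5, 0.5, prev, 2, 80, g) -
                      tgt)), 1e-10)
  expect_error(evolve_attention_for(A0, tgt, 1, 2, prev, 2, 0.1, g),
               "omega_A")
})

test_that("center-bias initialization starts central and fades", {
  g <- sw_grid(43, 43, 30, 30)
  p <- sw_params("extended")
  S <- matrix(1, g$n_x, g$n_y)  # uniform saliency isolates the bias
  st <- initial_state_center_bias(S, p, g)
  expect_equal(unname(which(st$A == max(st$A), arr.ind = TRUE)[1, ]),
               deg_to_cell(c(15, 15), g))
  expect_true(all(st$F == 0))
  expect_equal(sum(st$A), 1, tolerance = 1e-12)
  # long evolution recovers the ordinary local-saliency target
  first_fix <- c(20, 18)
  tgt <- attention_input(S, gaussian_map(first_fix, p$sigma_A, g))
  A_inf <- evolve_map(st$A, tgt, p$omega_CB, 40)
  expect_lt(max(abs(A_inf - tgt)), 1e-10)
  # central mass decreases monotonically in t with the published
  # sigma_CB = 4.3, omega_CB = 1.5
  disc <- outer((g$xs - 15)^2, rep(1, g$n_y)) +
    outer(rep(1, g$n_x), (g$ys - 15)^2) < 4.3^2
  mass <- vapply(c(0, 0.2, 0.5, 1, 2), function(t) {
    sum(evolve_map(st$A, tgt, p$omega_CB, t)[disc])
  }, numeric(1))
  expect_true(all(diff(mass) < 0))
})

test_that("oculomotor potential is plus-shaped and suppressive by default", {
  g <- sw_grid(21, 21, 21, 21)
  fix <- cell_to_deg(c(11, 11), g)
  # chi = 0.5 is |dx| * |dy|
  omp <- oculomotor_map(fix, 0.5, g)
  expect_equal(omp, outer(abs(g$xs - fix[1]), abs(g$ys - fix[2])),
               tolerance = 1e-12)
  # zero on the cardinal cross through the fixation cell
  omp2 <- oculomotor_map(fix, 0.059, g)
  expect_true(all(omp2[11, ] == 0))
  expect_true(all(omp2[, 11] == 0))
  # one cell diagonal offset: (1 * 1)^chi = 1 (unit cell size here)
  expect_equal(omp2[12, 12], 1)
  # chi = 0 keeps the plus-shaped support (0^0 := 0 on the cross)
  omp0 <- oculomotor_map(fix, 0, g)
  expect_true(all(omp0[11, ] == 0))
  expect_equal(omp0[12, 12], 1)
  # psi = 0 is the identity
  u <- matrix(rnorm(21 * 21), 21, 21)
  expect_identical(apply_oculomotor(u, omp2, 0), u)
  # default convention: cross unchanged, everything else decreases
  u2 <- apply_oculomotor(u, omp2, psi = exp(-0.613))
  expect_equal(u2[11, ], u[11, ])
  expect_true(all(u2[-11, -11] < u[-11, -11]))
  # literal convention adds mass off the cross instead
  u3 <- apply_oculomotor(u, omp2, psi = 0.5, sign = "literal")
  expect_true(all(u3[-11, -11] > u[-11, -11]))
  expect_error(apply_oculomotor(u, matrix(0, 21, 21), 0.5), "zero sum")
})

test_that("cardinal-direction peaks appear with the oculomotor potential", {
  g <- sw_grid(48, 36, 32, 24)
  S <- make_saliency(g, 0)  # uniform saliency isolates the potential
  p_on <- sw_params("extended", log_psi = -0.613)
  p_off <- sw_params("extended", log_psi = -Inf)
  set.seed(11)
  fx_on <- simulate_dataset(S, p_on, g, n_subjects = 4, n_paths = 15,
                            n_fix = 30)
  set.seed(11)
  fx_off <- simulate_dataset(S, p_off, g, n_subjects = 4, n_paths = 15,
                             n_fix = 30)
  card_mass <- function(fx) {
    d <- saccades(fx)$direction
    near <- function(a) mean(pmin(abs(d - a), 360 - abs(d - a)) < 15)
    near(0) + near(90) + near(180) + near(270)
  }
  expect_gt(card_mass(fx_on), card_mass(fx_off))
  expect_gt(card_mass(fx_on), 1 / 3)
})
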