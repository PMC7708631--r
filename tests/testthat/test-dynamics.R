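test_that("attention input is the normalized saliency-aperture product", {
  # 2-cell toy: S = (1, 3), G = (2, 1) -> (2/5, 3/5)
  S <- matrix(c(1, 3), 1, 2)
  G <- matrix(c(2, 1), 1, 2)
  expect_equal(attention_input(S, G), matrix(c(0.4, 0.6), 1, 2))
  # constant saliency cancels: output equals normalized aperture
  g <- tiny_grid()
  GA <- gaussian_map(c(10, 10), 4, g)
  expect_equal(attention_input(matrix(2, g$n_x, g$n_y), GA),
               GA / sum(GA), tolerance = 1e-14)
  expect_equal(sum(attention_input(tiny_saliency(g), GA)), 1,
               tolerance = 1e-12)
  expect_error(attention_input(matrix(0, g$n_x, g$n_y), GA), "degenerate")
})

test_that("closed-form relaxation matches its limits and the ODE oracle", {
  one <- matrix(1, 1, 1)
  zero <- matrix(0, 1, 1)
  expect_equal(evolve_map(zero, one, omega = 1, dt = 1),
               matrix(1 - exp(-1), 1, 1))
  set.seed(3)
  M0 <- random_map(6, 5)
  tgt <- normalize_map(random_map(6, 5))
  expect_identical(evolve_map(M0, tgt, 2, 0), M0)
  # fixed point: omega * dt >= 30 lands on the target
  expect_lt(max(abs(evolve_map(M0, tgt, 3, 10) - tgt)), 1e-10)
  # semigroup property: dt1 then dt2 equals dt1 + dt2
  for (k in 1:20) {
    M <- random_map(4, 4)
    tg <- normalize_map(random_map(4, 4))
    om <- runif(1, 0.5, 20)
    d1 <- runif(1, 0, 0.3)
    d2 <- runif(1, 0, 0.3)
    two <- evolve_map(evolve_map(M, tg, om, d1), tg, om, d2)
    expect_lt(max(abs(two - evolve_map(M, tg, om, d1 + d2))), 1e-12)
  }
  # independent Runge-Kutta oracle on random instances
  for (k in 1:25) {
    M <- random_map(8, 8)
    tg <- normalize_map(random_map(8, 8))
    om <- runif(1, 0.5, 15)
    dt <- runif(1, 0.02, 0.5)
    expect_lt(max(abs(evolve_map(M, tg, om, dt) -
                        rk4_evolve(M, tg, om, dt))), 1e-6)
  }
  expect_error(evolve_map(M0, tgt, 1, -0.1), "nonnegative")
})

test_that("priority combination follows the shaped subtraction", {
  # 2-cell toy: A_norm = (.2, .8), F_norm = (.5, .5), C_F = .3
  A <- matrix(c(0.2, 0.8), 1, 2)
  F <- matrix(c(0.5, 0.5), 1, 2)
  expect_equal(combine_priority(A, F, gamma = 1, C_F = 0.3),
               matrix(c(0.05, 0.65), 1, 2))
  # C_F = 0 reduces to Luce's choice rule over A
  set.seed(4)
  A2 <- random_map(5, 5)
  expect_equal(combine_priority(A2, A2, 1, 0), A2 / sum(A2))
  # A = F with unit weight cancels exactly
  expect_equal(max(abs(combine_priority(A2, A2, 1, 1))), 0)
  expect_error(combine_priority(matrix(0, 2, 2), F = matrix(1, 2, 2), 1, 0.3),
               "zero")
})

test_that("rectification keeps only the positive part", {
  u <- matrix(c(-0.1, 0.65), 1, 2)
  expect_equal(rectify_map(u), matrix(c(0, 0.65), 1, 2))
  up <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_identical(rectify_map(up), up)
  expect_equal(rectify_map(-up), matrix(0, 2, 2))
})

test_that("selection probability mixes in the uniform floor", {
  us <- matrix(c(0.05, 0.65), 1, 2)
  pi2 <- selection_probability(us, zeta = 0.1)
  expect_equal(pi2, matrix(c(0.9 * 0.05 / 0.7 + 0.05,
                             0.9 * 0.65 / 0.7 + 0.05), 1, 2),
               tolerance = 1e-12)
  expect_equal(round(pi2[1], 5), 0.11429)
  # zeta = 1 is exactly uniform
  expect_equal(selection_probability(us, 1), matrix(0.5, 1, 2))
  # convex combination of unit-sum maps sums to one
  set.seed(5)
  for (k in 1:20) {
    u <- rectify_map(random_map(6, 6) - 0.5)
    expect_equal(sum(selection_probability(u, runif(1, 0.01, 1))), 1,
                 tolerance = 1e-12)
  }
  expect_equal(selection_probability(matrix(0, 3, 3), 0.2),
               matrix(1 / 9, 3, 3))
  expect_error(selection_probability(matrix(0, 3, 3), 0), "undefined")
})

test_that("gamma sharpens the argmax and saliency scale cancels", {
  g <- tiny_grid()
  set.seed(6)
  for (k in 1:10) {
    A <- random_map(g$n_x, g$n_y)
    F <- random_map(g$n_x, g$n_y)
    p <- sw_params("baseline", gamma = 1, log_zeta = log(0.05))
    p_hi <- sw_params("baseline", gamma = 1.8, log_zeta = log(0.05))
    pi1 <- priority_probability(A, F, p)
    pi2 <- priority_probability(A, F, p_hi)
    i_max <- which.max(A)
    expect_gt(pi2[i_max], pi1[i_max])
  }
  # pi is invariant to positive rescaling of the saliency map
  S <- tiny_saliency(g)
  p <- sw_params("baseline")
  path <- matrix(c(10, 10, 0.3, 14, 12, 0.25, 8, 9, 0.3), 3, 3, byrow = TRUE)
  ll1 <- scanpath_loglik(path_tbl(path), S, p, g)
  ll2 <- scanpath_loglik(path_tbl(path), 37.5 * S, p, g)
  expect_equal(ll1$log2_p, ll2$log2_p, tolerance = 1e-12)
})
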