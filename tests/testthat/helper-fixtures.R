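# shared fixtures: everything is generated in code, no files

tiny_grid <- function(n_x = 16, n_y = 12, ex = 32, ey = 24) {
  sw_grid(n_x, n_y, ex, ey)
}

tiny_saliency <- function(grid, seed = 101) {
  make_saliency(grid, n_blobs = 3, seed = seed)
}

# a fixation tibble for one path from a raw matrix
path_tbl <- function(m, subject = "s01", image = "img") {
  tibble::tibble(subject = subject, image = image,
                 x_deg = m[, 1], y_deg = m[, 2], dur_s = m[, 3])
}

# classic 4th-order Runge-Kutta for dM/dt = omega * (target - M),
# the independent oracle for the closed-form map relaxation
rk4_evolve <- function(M0, target, omega, dt, n_steps = 200) {
  h <- dt / n_steps
  M <- M0
  f <- function(M) omega * (target - M)
  for (s in seq_len(n_steps)) {
    k1 <- f(M)
    k2 <- f(M + h / 2 * k1)
    k3 <- f(M + h / 2 * k2)
    k4 <- f(M + h * k3)
    M <- M + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  M
}

# random nonnegative map with positive sum
random_map <- function(n_x, n_y) {
  matrix(rexp(n_x * n_y), n_x, n_y)
}
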