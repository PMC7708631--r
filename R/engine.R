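# R reference engine: drives one trial's map dynamics fixation by
# fixation, either teacher-forced on observed fixations (likelihood
# replay) or generatively (simulation). A compiled twin of this code
# (src/engine.cpp) is the default at run time; tests assert the two agree
# elementwise to <= 1e-12. Any change here must be mirrored there.

engine_init_state <- function(S, params, grid) {
  if (params$center_bias) {
    initial_state_center_bias(S, params, grid)
  } else {
    # the original model starts both streams uniform
    list(A = uniform_map(grid), F = uniform_map(grid), t = 0)
  }
}

# probability map for the very first fixation: read off the initial state
# at t = 0; no oculomotor potential (no current fixation exists yet)
engine_initial_pi <- function(state, params, grid) {
  priority_probability(state$A, state$F, params, grid, fix = NULL)
}

# evolve through the post-saccadic and main phases of the fixation at
# `pos` (duration `dur`), up to the selection instant t_fix - tau_pre;
# returns the selection probability map and everything needed to finish
# the fixation once the next target is known
engine_advance <- function(state, S, params, grid, pos, dur, prev, first) {
  pre <- min(params$tau_pre, dur)
  post <- 0
  remap <- NULL
  if (!is.null(prev) && any(prev != pos)) {
    post <- min(params$tau_post, dur - pre)
    if (post > 0) remap <- remap_location(prev, pos, params$eta)$location
  }
  main <- dur - pre - post
  om_A <- if (first && params$center_bias) params$omega_CB else params$omega_A
  om_FoR <- if (is.null(prev)) om_A else min(params$omega_FoR, om_A)
  A <- state$A
  F <- state$F
  if (post > 0) {
    At <- attention_input(S, postsaccadic_gaussian(remap, params$sigma_post, grid))
    A <- evolve_attention_for(A, At, om_A, om_FoR, prev, params$nu, post, grid)
  }
  if (main > 0) {
    At <- attention_input(S, gaussian_map(pos, params$sigma_A, grid))
    A <- evolve_attention_for(A, At, om_A, om_FoR, prev, params$nu, main, grid)
  }
  Ftarget <- normalize_map(gaussian_map(pos, params$sigma_F, grid))
  F <- evolve_map(F, Ftarget, params$omega_F, post + main)
  pi_map <- priority_probability(A, F, params, grid, fix = pos)
  list(A = A, F = F, Ftarget = Ftarget, pi = pi_map,
       pre = pre, om_A = om_A, om_FoR = om_FoR, prev = prev)
}

# pre-saccadic phase: attention re-centers on the chosen next target for
# the remaining `pre` seconds; inhibition keeps relaxing in place
engine_finish <- function(adv, nxt, S, params, grid) {
  A <- adv$A
  F <- adv$F
  if (adv$pre > 0) {
    At <- attention_input(S, presaccadic_gaussian(nxt, params$sigma_A, grid))
    A <- evolve_attention_for(A, At, adv$om_A, adv$om_FoR, adv$prev,
                              params$nu, adv$pre, grid)
    F <- evolve_map(F, adv$Ftarget, params$omega_F, adv$pre)
  }
  list(A = A, F = F)
}

# teacher-forced replay: per-fixation log2 probabilities for one path
replay_r <- function(path_mat, S, params, grid) {
  n <- nrow(path_mat)
  stopifnot(n >= 1)
  state <- engine_init_state(S, params, grid)
  ll <- numeric(n)
  cell1 <- deg_to_cell(path_mat[1, 1:2], grid)
  pi0 <- engine_initial_pi(state, params, grid)
  ll[1] <- log2(pi0[cell1[1], cell1[2]])
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      pos <- path_mat[i, 1:2]
      prev <- if (i > 1) path_mat[i - 1, 1:2] else NULL
      adv <- engine_advance(state, S, params, grid, pos, path_mat[i, 3],
                            prev, first = i == 1)
      nxt <- path_mat[i + 1, 1:2]
      cc <- deg_to_cell(nxt, grid)
      ll[i + 1] <- log2(adv$pi[cc[1], cc[2]])
      state <- engine_finish(adv, nxt, S, params, grid)
    }
  }
  ll
}

# generative twin of replay_r; consumes one runif(1) per sampled fixation
# (first fixation included for the center-bias start), so that the R and
# compiled engines consume the RNG stream identically
simulate_r <- function(S, params, grid, durations) {
  n <- length(durations)
  stopifnot(n >= 1)
  state <- engine_init_state(S, params, grid)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "dur")))
  out[, 3] <- durations
  if (params$center_bias) {
    pi0 <- engine_initial_pi(state, params, grid)
    out[1, 1:2] <- sample_cell_deg(pi0, grid)
  } else {
    out[1, 1:2] <- c(grid$extent_x / 2, grid$extent_y / 2)
  }
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      pos <- out[i, 1:2]
      prev <- if (i > 1) out[i - 1, 1:2] else NULL
      adv <- engine_advance(state, S, params, grid, pos, durations[i],
                            prev, first = i == 1)
      nxt <- sample_cell_deg(adv$pi, grid)
      out[i + 1, 1:2] <- nxt
      state <- engine_finish(adv, nxt, S, params, grid)
    }
  }
  out
}

# one multinomial draw over grid cells by cumulative-sum inversion;
# returns the selected cell center in degrees
sample_cell_deg <- function(pi_map, grid) {
  u <- runif(1)
  k <- match(TRUE, u < cumsum(pi_map))
  if (is.na(k)) k <- length(pi_map)
  i <- ((k - 1) %% grid$n_x) + 1
  j <- ((k - 1) %/% grid$n_x) + 1
  c(grid$xs[i], grid$ys[j])
}

# pack an sw_params object into the flat list the compiled engine expects
params_for_cpp <- function(params, grid) {
  list(
    omega_A = params$omega_A, omega_F = params$omega_F,
    omega_FoR = params$omega_FoR, omega_CB = params$omega_CB,
    sigma_A = params$sigma_A, sigma_F = params$sigma_F,
    sigma_post = params$sigma_post,
    sigma_CB_x = params$sigma_CB[1], sigma_CB_y = params$sigma_CB[2],
    gamma = params$gamma, C_F = params$C_F,
    zeta = exp(params$log_zeta), psi = exp(params$log_psi),
    chi = params$chi, eta = params$eta, nu = params$nu,
    tau_pre = params$tau_pre, tau_post = params$tau_post,
    center_bias = params$center_bias,
    omp_literal = identical(params$omp_sign, "literal"),
    xs = grid$xs, ys = grid$ys,
    extent_x = grid$extent_x, extent_y = grid$extent_y
  )
}
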