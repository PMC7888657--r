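# Reduced steady-state solver.
#
# The cascade is feed-forward except for FnrN auto-regulation: L and R are
# constitutive, K depends only on (L, R, c), and F depends only on (K, N, c).
# Steady states therefore reduce to a one-dimensional fixed-point problem in
# N, which is solved by bracketing sign changes of phi(N) = rate_N(N)/delta - N
# on a dense grid and polishing with uniroot. This is fast enough to sit in
# the calibration inner loop; the general multi-start Newton solver
# (find_steady_states) is the reference implementation and the two are
# cross-checked in the test suite.

slaved_levels <- function(c_o2, p, g) {
  L <- if (g$hfixl_functional) p$beta_L / p$delta else 0
  R <- if (g$fxkr_functional) p$beta_R / p$delta else 0
  aL <- p$K_L^p$n_L / (p$K_L^p$n_L + c_o2^p$n_L)
  Ra <- (L * p$delta / p$beta_L) * R * aL
  K <- if (g$fixk_functional) {
    (p$alpha_K + p$beta_K * Ra / (p$K_RK + Ra)) / p$delta
  } else 0
  list(L = L, R = R, K = K,
       aN = p$K_NO2^p$n_NO2 / (p$K_NO2^p$n_NO2 + c_o2^p$n_NO2))
}

fnrn_rate_given <- function(N, K, aN, p) {
  Na <- N * aN
  th_d <- theta_total_(K, Na, p$A_K_dist, p$A_N_dist, p$n_DNA)
  th_p <- theta_total_(K, Na, p$rho_K * p$A_K_dist, p$rho_N * p$A_N_dist,
                       p$n_DNA)
  p$alpha_N + p$beta_N * th_d * (1 - th_p)
}

# All steady-state N values for a genotype at one oxygen level, with the
# 1-D stability sign (phi'(N) < 0 <=> stable). polish = FALSE estimates the
# crossings by linear interpolation only (enough for counting and for the
# calibration penalty audit).
reduced_n_roots <- function(c_o2, p, g, grid_n = 600, polish = TRUE) {
  sl <- slaved_levels(c_o2, p, g)
  if (!g$fnrn_functional) {
    return(list(sl = sl, roots = 0, stable = TRUE))
  }
  upper <- (p$alpha_N + p$beta_N) / p$delta
  phi <- function(N) fnrn_rate_given(N, sl$K, sl$aN, p) / p$delta - N
  grid <- seq(0, upper * 1.05, length.out = grid_n)
  v <- phi(grid)
  roots <- numeric(0)
  for (i in seq_len(grid_n - 1)) {
    if (v[i] == 0) roots <- c(roots, grid[i])
    else if (v[i] * v[i + 1] < 0) {
      roots <- c(roots, if (polish) {
        uniroot(phi, c(grid[i], grid[i + 1]), tol = 1e-13)$root
      } else {
        grid[i] - v[i] * (grid[i + 1] - grid[i]) / (v[i + 1] - v[i])
      })
    }
  }
  if (v[grid_n] == 0) roots <- c(roots, grid[grid_n])
  if (!length(roots)) roots <- uniroot(phi, c(0, upper * 1.05),
                                       extendInt = "yes", tol = 1e-13)$root
  roots <- sort(unique(roots))
  h <- 1e-7 * max(1, upper)
  stable <- vapply(roots, function(r) phi(r + h) - phi(max(r - h, 0)) < 0,
                   logical(1))
  list(sl = sl, roots = roots, stable = stable)
}

reduced_full_state <- function(N, c_o2, p, g, sl = NULL) {
  sl <- sl %||% slaved_levels(c_o2, p, g)
  Na <- N * sl$aN
  Fv <- (p$alpha_F +
         p$beta_F * theta_total_(sl$K, Na, p$A_K_fix, p$A_N_fix, p$n_DNA)) /
        p$delta
  cascade_state(L = sl$L, R = sl$R, K = sl$K, N = N, F = Fv)
}

# Steady state selected by the history rule: the 1-D flow dN/dt = phi(N)
# started from N0 converges to the adjacent root in the direction of the
# initial derivative. Exact for every genotype because K never depends on N.
reduced_history_state <- function(c_o2, p, g, from_N) {
  rr <- reduced_n_roots(c_o2, p, g)
  roots <- rr$roots
  if (length(roots) == 1) {
    return(reduced_full_state(roots[1], c_o2, p, g, rr$sl))
  }
  phi0 <- fnrn_rate_given(from_N, rr$sl$K, rr$sl$aN, p) / p$delta - from_N
  sel <- if (abs(phi0) < 1e-12) {
    roots[which.min(abs(roots - from_N))]
  } else if (phi0 > 0) {
    cand <- roots[roots >= from_N - 1e-12]
    if (length(cand)) min(cand) else max(roots)
  } else {
    cand <- roots[roots <= from_N + 1e-12]
    if (length(cand)) max(cand) else min(roots)
  }
  reduced_full_state(sel, c_o2, p, g, rr$sl)
}

# Scenario-resolved steady state (reduced path). For history-selected
# scenarios the starting point is the genotype's free-living steady state.
reduced_scenario_state <- function(scen, p, g) {
  c_o2 <- scen$oxygen$dissolved
  if (identical(scen$state_selection, "history")) {
    fl <- reduced_n_roots(headspace_to_dissolved(0.01, p), p, g)
    start_N <- min(fl$roots[fl$stable])
    reduced_history_state(c_o2, p, g, from_N = start_N)
  } else {
    rr <- reduced_n_roots(c_o2, p, g)
    stable <- rr$roots[rr$stable]
    if (length(stable) > 1) {
      warning("scenario '", scen$name, "' is multistable; using the ",
              "lowest stable state", call. = FALSE)
    }
    reduced_full_state(min(stable), c_o2, p, g, rr$sl)
  }
}
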