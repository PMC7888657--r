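# Shared fixtures and independent oracles for the test suite.

# A fixed, deliberately uncalibrated parameter set for unit tests that must
# not depend on the shipped calibration.
test_params <- function() {
  cascade_params(alpha_K = 0.02, beta_K = 1, alpha_N = 0.02, beta_N = 1,
                 alpha_F = 0.02, beta_F = 1, K_RK = 0.1,
                 A_K_dist = 1, A_N_dist = 0.05, rho_K = 4, rho_N = 4)
}

# Independent root-multiplicity oracle: because hFixL, FxkR and FixK do not
# depend on FnrN, their steady levels are unique and can be taken from a
# single long integration; the FnrN fixed-point residual is then scanned on
# a dense grid using only the public rhs. Returns the N values of all roots.
oracle_fnrn_roots <- function(c_o2, params, genotype, n_grid = 4000) {
  base <- integrate_to_steady(cascade_state(), c_o2, params, genotype,
                              t_max = 4000)
  stopifnot(base$converged)
  st <- base$state
  resid <- function(N) {
    s <- st
    s[["N"]] <- N
    cascade_rhs(s, c_o2, params, genotype)[["N"]]
  }
  n_max <- (params$alpha_N + params$beta_N) / params$delta * 1.05
  grid <- seq(0, n_max, length.out = n_grid)
  v <- vapply(grid, resid, numeric(1))
  roots <- numeric(0)
  for (i in seq_len(n_grid - 1)) {
    if (v[i] == 0) roots <- c(roots, grid[i])
    else if (v[i] * v[i + 1] < 0) {
      roots <- c(roots, uniroot(resid, c(grid[i], grid[i + 1]),
                                tol = 1e-12)$root)
    }
  }
  sort(roots)
}

# Perturb-and-integrate stability oracle: a stable state attracts a small
# perturbation back; an unstable one is abandoned.
oracle_is_stable <- function(state, c_o2, params, genotype,
                             eps = 1e-3, t_max = 400) {
  scale <- pmax(abs(state), 0.01)
  for (sgn in c(-1, 1)) {
    pert <- pmax(state + sgn * eps * scale, 0)
    res <- integrate_to_steady(pert, c_o2, params, genotype, t_max = t_max)
    if (max(abs(res$state - state) / pmax(abs(state), 1e-6)) > 1e-3) {
      return(FALSE)
    }
  }
  TRUE
}

# Brute-force regex motif oracle (forward strand only; callers handle the
# reverse strand by scanning the reverse complement).
oracle_motif_starts <- function(sequence, consensus) {
  pat <- gsub("N", "[ACGT]", consensus)
  hits <- gregexpr(paste0("(?=", pat, ")"), sequence, perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

oracle_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}
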