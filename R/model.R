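#' @importFrom rlang %||% .data
#' @importFrom stats rnorm runif setNames uniroot nlminb optimize rlnorm
#' @importFrom utils modifyList
#' @importFrom Rcpp sourceCpp
#' @useDynLib fixcascade, .registration = TRUE
NULL

#' An all-zero cascade state
#'
#' States are named numeric vectors over the five modelled species:
#' `L` (hFixL), `R` (FxkR), `K` (FixK), `N` (FnrN) and `F` (FixNOQP), in
#' arbitrary concentration units.
#'
#' @param L,R,K,N,F Non-negative component values.
#' @return Named numeric vector of length 5.
#' @export
#' @examples
#' cascade_state()
#' cascade_state(L = 1, R = 1)
cascade_state <- function(L = 0, R = 0, K = 0, N = 0, F = 0) {
  s <- c(L = L, R = R, K = K, N = N, F = F)
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("cascade state components must be finite and non-negative",
         call. = FALSE)
  }
  s
}

state_names <- c("L", "R", "K", "N", "F")

check_state <- function(state) {
  if (!is.numeric(state) || length(state) != 5) {
    stop("a cascade state is a numeric vector of length 5 (L, R, K, N, F)",
         call. = FALSE)
  }
  if (any(!is.finite(state)) || any(state < 0)) {
    stop("cascade state components must be finite and non-negative",
         call. = FALSE)
  }
  setNames(as.numeric(state), state_names)
}

check_conc <- function(c_o2) {
  if (!is.numeric(c_o2) || any(!is.finite(c_o2))) {
    stop("dissolved O2 must be finite numeric (uM)", call. = FALSE)
  }
  if (any(c_o2 < 0)) {
    stop("dissolved O2 concentration must be >= 0", call. = FALSE)
  }
  c_o2
}

#' Oxygen-sensing transfer functions
#'
#' Fraction of the sensor pool in the active (signalling) form as a function
#' of dissolved O2. hFixL binds O2 cooperatively (Hill coefficient `n_L`,
#' default 2, half-inactivation `K_L` = 12 uM); FnrN's iron-sulfur cluster is
#' destroyed by O2 with first-order kinetics (`n_NO2` = 1, half-inactivation
#' `K_NO2` = 120 nM). Both are monotone decreasing, equal to 1 under anoxia
#' and 0.5 at their half-inactivation concentration.
#'
#' @param c_o2 Dissolved O2 in uM (vectorised).
#' @param params A `cascade_params` object.
#' @return Active fraction(s) in \[0, 1\].
#' @export
#' @examples
#' hfixl_active_fraction(12)    # 0.5 at K_L
#' fnrn_active_fraction(12)     # ~0.0099: FnrN mostly inactive at 1% O2
hfixl_active_fraction <- function(c_o2, params = cascade_params()) {
  check_conc(c_o2)
  params$K_L^params$n_L / (params$K_L^params$n_L + c_o2^params$n_L)
}

#' @rdname hfixl_active_fraction
#' @export
fnrn_active_fraction <- function(c_o2, params = cascade_params()) {
  check_conc(c_o2)
  params$K_NO2^params$n_NO2 / (params$K_NO2^params$n_NO2 + c_o2^params$n_NO2)
}

#' Competitive anaerobox occupancy
#'
#' FixK and FnrN dimers compete for a single anaerobox operator. With
#' effective bound-dimer propensities `x = (K / A_K)^n` and
#' `y = (N_active / A_N)^n`, the fractional occupancies are
#' `theta_fixk = x / (1 + x + y)` and `theta_fnrn = y / (1 + x + y)`.
#' Their sum is below 1 for finite inputs; both factors have an identical
#' induction effect when bound, so transcription responds to
#' `theta_total = theta_fixk + theta_fnrn`.
#'
#' @param K_conc FixK concentration (arbitrary units, vectorised).
#' @param N_active Active FnrN concentration (arbitrary units, vectorised).
#' @param A_K,A_N Half-saturation constants of FixK and FnrN at this box.
#' @param n_DNA Hill coefficient of DNA binding (default 2, dimers).
#' @return A tibble with columns `theta_fixk`, `theta_fnrn`, `theta_total`.
#' @export
#' @examples
#' anaerobox_occupancy(1, 0, A_K = 1, A_N = 0.05)  # theta_fixk = 0.5
anaerobox_occupancy <- function(K_conc, N_active, A_K, A_N, n_DNA = 2) {
  if (any(K_conc < 0) || any(N_active < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (A_K <= 0 || A_N <= 0) stop("affinities must be positive", call. = FALSE)
  x <- (K_conc / A_K)^n_DNA
  y <- (N_active / A_N)^n_DNA
  d <- 1 + x + y
  tibble::tibble(theta_fixk = x / d, theta_fnrn = y / d,
                 theta_total = (x + y) / d)
}

# Scalar/vector fast path used by the dynamics (no tibble allocation).
theta_total_ <- function(K_conc, N_active, A_K, A_N, n_DNA) {
  x <- (K_conc / A_K)^n_DNA
  y <- (N_active / A_N)^n_DNA
  (x + y) / (1 + x + y)
}

#' Per-promoter transcription rates
#'
#' Instantaneous transcription rates of the three regulated promoters given
#' the current regulator levels and dissolved O2 -- the quantity a
#' transcriptional reporter fusion reads out.
#'
#' * fixK: basal rate plus a saturating first-order response of the K-box to
#'   active FxkR. Active FxkR is treated at phosphotransfer quasi-steady
#'   state, `R_active = (L / L_wt) x R x hfixl_active_fraction(c)` with
#'   `L_wt = beta_L / delta` the wild-type kinase level; the kinase factor
#'   is dimensionless, so `R_active` equals `R x hfixl_active_fraction(c)`
#'   in wild type and vanishes smoothly in the hfixL knockout.
#' * fnrN: basal rate plus the maximal rate times occupancy of the distal
#'   activating anaerobox times the probability that the proximal,
#'   sterically repressing box (affinities penalised by `rho_K`, `rho_N`)
#'   is free. Both FixK and FnrN act at both boxes.
#' * fixNOQP: basal rate plus the maximal rate times occupancy of its single
#'   activating anaerobox (its own affinity pair `A_K_fix`, `A_N_fix`).
#'
#' Knockouts act through the state (absent proteins), so the genotype is
#' accepted for interface symmetry but does not modify the rate laws.
#'
#' @param state Cascade state (named numeric of length 5).
#' @param c_o2 Dissolved O2 (uM).
#' @param params A `cascade_params` object.
#' @param genotype A `cascade_genotype` (or preset name).
#' @return Named numeric vector with components `fixK`, `fnrN`, `fixNOQP`.
#' @export
#' @examples
#' promoter_rates(cascade_state(), 12)  # all-basal at the zero state
promoter_rates <- function(state, c_o2, params = cascade_params(),
                           genotype = "wt") {
  state <- check_state(state)
  check_conc(c_o2)
  genotype <- as_genotype(genotype)
  p <- params
  aL <- hfixl_active_fraction(c_o2, p)
  aN <- fnrn_active_fraction(c_o2, p)
  R_active <- (state[["L"]] * p$delta / p$beta_L) * state[["R"]] * aL
  N_active <- state[["N"]] * aN
  K_conc <- state[["K"]]
  rate_fixK <- p$alpha_K + p$beta_K * R_active / (p$K_RK + R_active)
  th_dist <- theta_total_(K_conc, N_active, p$A_K_dist, p$A_N_dist, p$n_DNA)
  th_prox <- theta_total_(K_conc, N_active,
                          p$rho_K * p$A_K_dist, p$rho_N * p$A_N_dist, p$n_DNA)
  rate_fnrN <- p$alpha_N + p$beta_N * th_dist * (1 - th_prox)
  rate_fixNOQP <- p$alpha_F +
    p$beta_F * theta_total_(K_conc, N_active, p$A_K_fix, p$A_N_fix, p$n_DNA)
  c(fixK = unname(rate_fixK), fnrN = unname(rate_fnrN),
    fixNOQP = unname(rate_fixNOQP))
}

#' Right-hand side of the cascade ODE system
#'
#' Time derivatives of the five species. Each species is produced at its
#' (regulated or constitutive) synthesis rate and removed with the shared
#' first-order rate `delta`; knocked-out genes have their synthesis zeroed.
#'
#' @inheritParams promoter_rates
#' @return Named numeric vector of derivatives (`L`, `R`, `K`, `N`, `F`).
#' @export
#' @examples
#' cascade_rhs(cascade_state(), 12)
cascade_rhs <- function(state, c_o2, params = cascade_params(),
                        genotype = "wt") {
  state <- check_state(state)
  genotype <- as_genotype(genotype)
  r <- promoter_rates(state, c_o2, params, genotype)
  p <- params
  c(L = (if (genotype$hfixl_functional) p$beta_L else 0) - p$delta * state[["L"]],
    R = (if (genotype$fxkr_functional) p$beta_R else 0) - p$delta * state[["R"]],
    K = (if (genotype$fixk_functional) r[["fixK"]] else 0) - p$delta * state[["K"]],
    N = (if (genotype$fnrn_functional) r[["fnrN"]] else 0) - p$delta * state[["N"]],
    F = r[["fixNOQP"]] - p$delta * state[["F"]])
}

# Vectorised rhs over a matrix of states (rows = cells), used by the
# Langevin ensemble simulator. No input validation in the hot loop.
rhs_matrix <- function(S, c_o2, p, g) {
  aL <- p$K_L^p$n_L / (p$K_L^p$n_L + c_o2^p$n_L)
  aN <- p$K_NO2^p$n_NO2 / (p$K_NO2^p$n_NO2 + c_o2^p$n_NO2)
  L <- S[, 1L]; R <- S[, 2L]; K <- S[, 3L]; N <- S[, 4L]; F <- S[, 5L]
  Ra <- (L * p$delta / p$beta_L) * R * aL
  Na <- N * aN
  xK <- (K / p$A_K_dist)^p$n_DNA
  yN <- (Na / p$A_N_dist)^p$n_DNA
  th_d <- (xK + yN) / (1 + xK + yN)
  xKp <- (K / (p$rho_K * p$A_K_dist))^p$n_DNA
  yNp <- (Na / (p$rho_N * p$A_N_dist))^p$n_DNA
  th_p <- (xKp + yNp) / (1 + xKp + yNp)
  xKf <- (K / p$A_K_fix)^p$n_DNA
  yNf <- (Na / p$A_N_fix)^p$n_DNA
  th_f <- (xKf + yNf) / (1 + xKf + yNf)
  cbind((if (g$hfixl_functional) p$beta_L else 0) - p$delta * L,
        (if (g$fxkr_functional) p$beta_R else 0) - p$delta * R,
        (if (g$fixk_functional)
           p$alpha_K + p$beta_K * Ra / (p$K_RK + Ra) else 0) - p$delta * K,
        (if (g$fnrn_functional)
           p$alpha_N + p$beta_N * th_d * (1 - th_p) else 0) - p$delta * N,
        p$alpha_F + p$beta_F * th_f - p$delta * F)
}
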