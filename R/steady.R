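#' Integrate the cascade to steady state
#'
#' Time-marches the ODE system with `deSolve::lsoda` until the right-hand
#' side max-norm drops below `tol`, checking at geometrically spaced
#' checkpoints up to `t_max`.
#'
#' @param start Initial cascade state.
#' @param c_o2 Dissolved O2 (uM).
#' @param params A `cascade_params` object.
#' @param genotype A `cascade_genotype` or preset name.
#' @param t_max Maximum integration time (units of 1/delta).
#' @param tol Convergence tolerance on the rhs max-norm.
#' @return A list with `state` (named numeric), `converged` (logical) and
#'   `rhs_norm`. Non-convergence is reported, never silently returned as a
#'   steady state.
#' @export
#' @examples
#' integrate_to_steady(cascade_state(), 252)$state
integrate_to_steady <- function(start, c_o2, params = cascade_params(),
                                genotype = "wt",
                                t_max = 2000, tol = 1e-9) {
  start <- check_state(start)
  genotype <- as_genotype(genotype)
  if (t_max <= 0) stop("t_max must be positive", call. = FALSE)
  deriv <- function(t, y, parms) {
    list(unname(cascade_rhs(pmax(y, 0), c_o2, params, genotype)))
  }
  state <- start
  t_done <- 0
  span <- 50
  while (t_done < t_max) {
    span <- min(span, t_max - t_done)
    sol <- deSolve::lsoda(y = state, times = c(0, span), func = deriv,
                          rtol = 1e-10, atol = 1e-12)
    state <- pmax(setNames(as.numeric(sol[nrow(sol), -1]), state_names), 0)
    t_done <- t_done + span
    nrm <- max(abs(cascade_rhs(state, c_o2, params, genotype)))
    if (nrm < tol) {
      return(list(state = state, converged = TRUE, rhs_norm = nrm,
                  time = t_done))
    }
    span <- span * 2
  }
  list(state = state, converged = FALSE,
       rhs_norm = max(abs(cascade_rhs(state, c_o2, params, genotype))),
       time = t_done)
}

# Finite-difference (central) Jacobian of the rhs at a state. All ten
# perturbed states are evaluated in one vectorised rhs_matrix call.
rhs_jacobian <- function(state, c_o2, params, genotype, h_rel = 1e-6) {
  genotype <- as_genotype(genotype)
  n <- length(state)
  h <- h_rel * pmax(abs(state), 1)
  P <- matrix(rep(unname(state), each = 2 * n), nrow = 2 * n)
  for (j in seq_len(n)) {
    P[2 * j - 1, j] <- state[j] + h[j]
    P[2 * j, j] <- max(state[j] - h[j], 0)
  }
  V <- rhs_matrix(P, c_o2, params, genotype)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    J[, j] <- (V[2 * j - 1, ] - V[2 * j, ]) / (P[2 * j - 1, j] - P[2 * j, j])
  }
  J
}

# One damped-Newton solve from a single start; returns state or NULL.
# Uses the unvalidated vectorised rhs in the hot loop.
newton_solve <- function(start, c_o2, params, genotype,
                         tol = 1e-9, max_iter = 60) {
  rhs1 <- function(x) rhs_matrix(matrix(x, nrow = 1), c_o2, params,
                                 genotype)[1, ]
  x <- pmax(unname(start), 0)
  for (i in seq_len(max_iter)) {
    fx <- rhs1(x)
    if (max(abs(fx)) < tol) return(setNames(x, state_names))
    J <- rhs_jacobian(x, c_o2, params, genotype)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    f0 <- sum(fx^2)
    repeat {
      xn <- pmax(x + lam * step, 0)
      fn <- rhs1(xn)
      if (sum(fn^2) < f0 || lam < 1e-6) break
      lam <- lam / 2
    }
    if (lam < 1e-6 && sum(fn^2) >= f0) return(NULL)
    x <- xn
  }
  fx <- rhs1(x)
  if (max(abs(fx)) < tol) setNames(x, state_names) else NULL
}

dedup_states <- function(states, rel_tol = 1e-4) {
  kept <- list()
  for (s in states) {
    dup <- FALSE
    for (k in kept) {
      if (max(abs(s - k)) / max(1, max(abs(k))) < rel_tol) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1]] <- s
  }
  kept
}

#' Find all steady states at one oxygen concentration
#'
#' Multi-start damped-Newton root finding on the cascade rhs. Starts are the
#' basal state, the all-on state, any user-supplied seed states (used for
#' branch continuation), and `n_starts` Latin-hypercube samples of the
#' biologically reachable box (each synthesis maximum over `delta`).
#' Solutions are deduplicated by relative distance (1e-4) and sorted by
#' FnrN level. Deterministic for a fixed seed.
#'
#' @inheritParams integrate_to_steady
#' @param n_starts Number of Latin-hypercube starts (>= 1).
#' @param seed Integer seed for the Latin-hypercube draw.
#' @param extra_starts Optional list of additional starting states.
#' @param tol Root tolerance on the rhs max-norm.
#' @return A list of steady states (named numeric vectors), sorted by
#'   increasing `N`. Empty (with a warning) if no root converged.
#' @export
#' @examples
#' find_steady_states(12, default_params(), "wt")
find_steady_states <- function(c_o2, params = cascade_params(),
                               genotype = "wt",
                               n_starts = 50, seed = 0,
                               extra_starts = NULL, tol = 1e-9) {
  if (n_starts < 1) stop("n_starts must be >= 1", call. = FALSE)
  genotype <- as_genotype(genotype)
  p <- params
  cap <- c(p$beta_L, p$beta_R, p$alpha_K + p$beta_K,
           p$alpha_N + p$beta_N, p$alpha_F + p$beta_F) / p$delta
  basal <- cascade_state(
    L = if (genotype$hfixl_functional) p$beta_L / p$delta else 0,
    R = if (genotype$fxkr_functional) p$beta_R / p$delta else 0,
    K = if (genotype$fixk_functional) p$alpha_K / p$delta else 0,
    N = if (genotype$fnrn_functional) p$alpha_N / p$delta else 0,
    F = p$alpha_F / p$delta)
  starts <- c(list(basal, cap), extra_starts %||% list())
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  H <- lhs::randomLHS(n_starts, 5)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  for (i in seq_len(n_starts)) {
    starts[[length(starts) + 1]] <- setNames(H[i, ] * cap, state_names)
  }
  roots <- list()
  for (s in starts) {
    r <- newton_solve(s, c_o2, params, genotype, tol = tol)
    if (!is.null(r)) roots[[length(roots) + 1]] <- r
  }
  roots <- dedup_states(roots)
  if (!length(roots)) {
    warning("no steady state found at c = ", c_o2, " uM", call. = FALSE)
    return(list())
  }
  roots[order(vapply(roots, function(s) s[["N"]], numeric(1)))]
}

#' Classify the stability of a steady state
#'
#' A steady state is stable iff every eigenvalue of the finite-difference
#' (central) Jacobian of the rhs has negative real part. Eigenvalues with
#' `|Re| <` `margin` are treated as borderline: the state is classified
#' unstable and flagged with a warning.
#'
#' @inheritParams integrate_to_steady
#' @param state A steady state (rhs max-norm below `steady_tol`).
#' @param margin Stability margin on real parts (default 1e-7).
#' @param steady_tol Tolerance used to verify the input is a steady state.
#' @return `"stable"` or `"unstable"`.
#' @export
classify_stability <- function(state, c_o2, params = cascade_params(),
                               genotype = "wt",
                               margin = 1e-7, steady_tol = 1e-6) {
  state <- check_state(state)
  genotype <- as_genotype(genotype)
  nrm <- max(abs(cascade_rhs(state, c_o2, params, genotype)))
  if (nrm > steady_tol) {
    stop("state is not a steady state (rhs max-norm ", signif(nrm, 3), ")",
         call. = FALSE)
  }
  ev <- Re(eigen(rhs_jacobian(state, c_o2, params, genotype),
                 only.values = TRUE)$values)
  if (any(abs(ev) < margin)) {
    warning("borderline eigenvalue (|Re| < ", margin,
            "); classifying as unstable", call. = FALSE)
    return("unstable")
  }
  if (all(ev < 0)) "stable" else "unstable"
}

#' Sweep steady states across an oxygen grid
#'
#' Computes all steady states with stability labels at each point of a
#' descending dissolved-O2 grid (high to low, a bacterium's journey into the
#' nodule). Each point's Newton starts are seeded with the previous point's
#' roots so that branches are tracked through folds.
#'
#' @inheritParams find_steady_states
#' @param c_grid Descending vector of dissolved O2 (uM); default
#'   [default_o2_grid()] with 200 points.
#' @return A tibble of class `cascade_sweep` with one row per (grid point,
#'   root): columns `oxygen` (uM), `branch` (root index at that point,
#'   ordered by N), `L`, `R`, `K`, `N`, `F`, promoter activities
#'   `rate_fnrN`, `rate_fixNOQP`, and `stability`. Attributes carry the
#'   parameters and genotype for downstream refinement.
#' @export
#' @examples
#' \donttest{
#' sw <- sweep_bifurcation(default_params(), "wt", default_o2_grid(40))
#' }
sweep_bifurcation <- function(params = cascade_params(),
                              genotype = "wt",
                              c_grid = default_o2_grid(200, params),
                              n_starts = 50, seed = 0) {
  genotype <- as_genotype(genotype)
  if (is.unsorted(rev(c_grid))) {
    stop("c_grid must be descending (high to low O2)", call. = FALSE)
  }
  prev <- NULL
  rows <- vector("list", length(c_grid))
  for (i in seq_along(c_grid)) {
    ci <- c_grid[i]
    roots <- find_steady_states(ci, params, genotype, n_starts = n_starts,
                                seed = seed, extra_starts = prev)
    prev <- roots
    if (!length(roots)) next
    lab <- vapply(roots, classify_stability, character(1),
                  c_o2 = ci, params = params, genotype = genotype)
    rates <- lapply(roots, promoter_rates, c_o2 = ci, params = params,
                    genotype = genotype)
    rows[[i]] <- tibble::tibble(
      oxygen = ci, branch = seq_along(roots),
      L = vapply(roots, `[[`, numeric(1), "L"),
      R = vapply(roots, `[[`, numeric(1), "R"),
      K = vapply(roots, `[[`, numeric(1), "K"),
      N = vapply(roots, `[[`, numeric(1), "N"),
      F = vapply(roots, `[[`, numeric(1), "F"),
      rate_fnrN = vapply(rates, `[[`, numeric(1), "fnrN"),
      rate_fixNOQP = vapply(rates, `[[`, numeric(1), "fixNOQP"),
      stability = lab)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "params") <- params
  attr(out, "genotype") <- genotype
  attr(out, "n_starts") <- n_starts
  attr(out, "seed") <- seed
  class(out) <- c("cascade_sweep", class(out))
  out
}

#' Detect the bistable oxygen window of a sweep
#'
#' Returns the maximal contiguous oxygen interval over which the sweep has
#' at least two stable steady states. The boundary between a bistable grid
#' point and a monostable neighbour is refined by bisection on the stable
#' state count.
#'
#' @param sweep A `cascade_sweep` from [sweep_bifurcation()].
#' @param refine_iter Bisection iterations per boundary.
#' @return A tibble with columns `lower` and `upper` (dissolved O2, uM) and
#'   `n_points` (bistable grid points); zero rows if the window is empty.
#' @export
detect_bistable_window <- function(sweep, refine_iter = 30) {
  stopifnot(inherits(sweep, "cascade_sweep"))
  params <- attr(sweep, "params")
  genotype <- attr(sweep, "genotype")
  counts <- sweep |>
    dplyr::filter(.data$stability == "stable") |>
    dplyr::count(.data$oxygen, name = "n_stable") |>
    dplyr::arrange(dplyr::desc(.data$oxygen))
  bist <- counts$n_stable >= 2
  if (!any(bist)) {
    return(tibble::tibble(lower = numeric(0), upper = numeric(0),
                          n_points = integer(0)))
  }
  # maximal contiguous run of bistable points (longest run if several)
  r <- rle(bist)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  i0 <- starts[best]; i1 <- ends[best]
  ox <- counts$oxygen  # descending
  n_stable_at <- function(c_o2) {
    roots <- find_steady_states(c_o2, params, genotype,
                                n_starts = attr(sweep, "n_starts") %||% 50,
                                seed = attr(sweep, "seed") %||% 0)
    sum(vapply(roots, classify_stability, character(1), c_o2 = c_o2,
               params = params, genotype = genotype) == "stable")
  }
  bisect <- function(c_in, c_out) {
    for (i in seq_len(refine_iter)) {
      mid <- sqrt(c_in * c_out)
      if (n_stable_at(mid) >= 2) c_in <- mid else c_out <- mid
      if (abs(log(c_in / c_out)) < 1e-6) break
    }
    sqrt(c_in * c_out)
  }
  upper <- if (i0 > 1) bisect(ox[i0], ox[i0 - 1]) else ox[i0]
  lower <- if (i1 < length(ox)) bisect(ox[i1], ox[i1 + 1]) else ox[i1]
  tibble::tibble(lower = lower, upper = upper, n_points = i1 - i0 + 1L)
}
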