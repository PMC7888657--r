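test_that("integration reaches a verified steady state and reports failure honestly", {
  p <- test_params()
  res <- integrate_to_steady(cascade_state(), 252, p, t_max = 2000)
  expect_true(res$converged)
  expect_lt(res$rhs_norm, 1e-9)
  # sensors off at 21%: regulated species near their basal levels
  expect_equal(res$state[["K"]], p$alpha_K / p$delta, tolerance = 0.05)
  expect_equal(res$state[["L"]], p$beta_L / p$delta)
  bad <- integrate_to_steady(cascade_state(), 12, p, t_max = 0.01)
  expect_false(bad$converged)
  # fnrN knockout: N decays to zero
  ko <- integrate_to_steady(cascade_state(N = 1), 12, p, "fnrN")
  expect_true(ko$converged)
  expect_lt(ko$state[["N"]], 1e-8)
})

test_that("Newton root finding agrees with the grid-scan oracle on multiplicity", {
  p <- default_params()
  # wild type is monostable at a spread of oxygen levels
  for (c_o2 in c(252, 12, 0.12, 0.03)) {
    roots <- find_steady_states(c_o2, p, "wt")
    expect_length(roots, length(oracle_fnrn_roots(c_o2, p, genotype("wt"))))
  }
  # the hfixL knockout has three states inside its bistable window
  win <- detect_bistable_window(
    sweep_bifurcation(p, "hfixL", default_o2_grid(60, p)))
  expect_equal(nrow(win), 1)
  c_mid <- sqrt(win$lower * win$upper)
  roots <- find_steady_states(c_mid, p, "hfixL")
  o <- oracle_fnrn_roots(c_mid, p, genotype("hfixL"))
  expect_length(roots, 3)
  expect_length(o, 3)
  expect_equal(vapply(roots, `[[`, numeric(1), "N"), o, tolerance = 1e-5)
  # every returned root satisfies the rhs tolerance
  for (r in roots) {
    expect_lt(max(abs(cascade_rhs(r, c_mid, p, "hfixL"))), 1e-9)
  }
})

test_that("duplicate starts do not duplicate roots", {
  p <- test_params()
  r1 <- find_steady_states(12, p, "wt", n_starts = 5, seed = 1)
  r2 <- find_steady_states(12, p, "wt", n_starts = 5, seed = 1,
                           extra_starts = rep(r1, 4))
  expect_length(r2, length(r1))
})

test_that("eigenvalue stability agrees with the perturb-and-integrate oracle", {
  p <- default_params()
  wt <- find_steady_states(252, p, "wt")
  expect_identical(classify_stability(wt[[1]], 252, p, "wt"), "stable")
  expect_true(oracle_is_stable(wt[[1]], 252, p, genotype("wt")))
  win <- detect_bistable_window(
    sweep_bifurcation(p, "hfixL", default_o2_grid(60, p)))
  c_mid <- sqrt(win$lower * win$upper)
  roots <- find_steady_states(c_mid, p, "hfixL")
  labs <- vapply(roots, classify_stability, character(1), c_o2 = c_mid,
                 params = p, genotype = "hfixL")
  expect_identical(labs, c("stable", "unstable", "stable"))
  oracle <- vapply(roots, oracle_is_stable, logical(1), c_o2 = c_mid,
                   params = p, genotype = genotype("hfixL"))
  expect_identical(oracle, c(TRUE, FALSE, TRUE))
  expect_error(classify_stability(cascade_state(L = 5), 12, p),
               "not a steady state")
})

test_that("sweeps track branches and stable roots exist everywhere", {
  p <- default_params()
  sw <- sweep_bifurcation(p, "wt", default_o2_grid(40, p))
  counts <- dplyr::count(dplyr::filter(sw, stability == "stable"), oxygen)
  expect_equal(nrow(counts), 40)
  expect_true(all(counts$n >= 1))
  # branch continuity: consecutive states on the single WT branch move smoothly
  wtb <- dplyr::arrange(dplyr::filter(sw, branch == 1), dplyr::desc(oxygen))
  # steps stay bounded on the coarse grid; a fold jump would be many-fold
  steps <- abs(diff(wtb$N)) / pmax(wtb$N[-1], 1e-6)
  expect_lt(max(steps), 1)
})

test_that("window detection is stable under grid refinement", {
  p <- default_params()
  w1 <- detect_bistable_window(
    sweep_bifurcation(p, "hfixL", default_o2_grid(50, p)))
  w2 <- detect_bistable_window(
    sweep_bifurcation(p, "hfixL", default_o2_grid(100, p)))
  expect_equal(nrow(w1), 1)
  expect_equal(nrow(w2), 1)
  coarse_cell <- exp(abs(diff(log(default_o2_grid(50, p)[1:2]))))
  expect_lt(abs(log(w1$upper / w2$upper)), log(coarse_cell))
  expect_lt(abs(log(w1$lower / w2$lower)), log(coarse_cell))
})

test_that("a monostable branch yields an empty window", {
  p <- default_params()
  sw <- sweep_bifurcation(p, "wt", default_o2_grid(30, p))
  expect_equal(nrow(detect_bistable_window(sw)), 0)
})
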