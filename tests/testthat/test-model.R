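test_that("sensor transfer functions hit their anchor values", {
  p <- cascade_params()
  expect_equal(hfixl_active_fraction(0, p), 1)
  expect_equal(hfixl_active_fraction(p$K_L, p), 0.5)
  expect_equal(hfixl_active_fraction(2 * p$K_L, p), 0.2)  # 1/(1+4), Hill 2
  expect_equal(fnrn_active_fraction(0, p), 1)
  expect_equal(fnrn_active_fraction(p$K_NO2, p), 0.5)
  expect_equal(fnrn_active_fraction(12, p), 0.12 / 12.12, tolerance = 1e-12)
  expect_lt(fnrn_active_fraction(12, p), 0.01)  # FnrN mostly inactive at 1% O2
})

test_that("transfer functions are bounded and monotone non-increasing", {
  p <- cascade_params()
  withr::with_seed(7, {
    for (i in 1:5) {
      grid <- sort(runif(40, 0, 400))
      for (f in list(hfixl_active_fraction, fnrn_active_fraction)) {
        v <- f(grid, p)
        expect_true(all(v >= 0 & v <= 1))
        expect_true(all(diff(v) <= 0))
      }
    }
  })
})

test_that("competitive occupancy follows the two-species binding isotherm", {
  occ0 <- anaerobox_occupancy(0, 0, A_K = 1, A_N = 0.05)
  expect_equal(occ0$theta_total, 0)
  occ1 <- anaerobox_occupancy(1, 0, A_K = 1, A_N = 0.05)
  expect_equal(occ1$theta_fixk, 0.5)
  occ2 <- anaerobox_occupancy(2, 0.1, A_K = 2, A_N = 0.1)
  expect_equal(occ2$theta_fixk, 1 / 3)
  expect_equal(occ2$theta_fnrn, 1 / 3)
  withr::with_seed(11, {
    K <- runif(50, 0, 20); N <- runif(50, 0, 20)
    occ <- anaerobox_occupancy(K, N, A_K = 0.7, A_N = 0.2)
    expect_true(all(occ$theta_fixk >= 0 & occ$theta_fnrn >= 0))
    expect_true(all(occ$theta_total < 1))
    expect_equal(occ$theta_total, occ$theta_fixk + occ$theta_fnrn)
  })
})

test_that("promoter rates reduce to basal rates in limiting regimes", {
  p <- test_params()
  r0 <- promoter_rates(cascade_state(), 12, p)
  expect_equal(unname(r0), c(p$alpha_K, p$alpha_N, p$alpha_F))
  # saturating FnrN occupies the proximal box: steric repression to basal
  hiN <- cascade_state(L = 1, R = 1, K = 0, N = 1e7)
  rN <- promoter_rates(hiN, 0, p)
  expect_equal(rN[["fnrN"]], p$alpha_N, tolerance = 1e-4)
  # at atmospheric O2 both sensors are off: everything near-basal
  wt_atm <- integrate_to_steady(cascade_state(), 252, p)$state
  r_atm <- promoter_rates(wt_atm, 252, p)
  expect_equal(r_atm[["fnrN"]], p$alpha_N, tolerance = 0.05)
  expect_equal(r_atm[["fixNOQP"]], p$alpha_F, tolerance = 0.05)
  expect_lt((r_atm[["fixK"]] - p$alpha_K) / p$beta_K, 0.05)
})

test_that("the rhs implements synthesis-minus-removal with knockout zeroing", {
  p <- test_params()
  d0 <- cascade_rhs(cascade_state(), 12, p)
  expect_equal(unname(d0),
               c(p$beta_L, p$beta_R, p$alpha_K, p$alpha_N, p$alpha_F))
  # fnrN knockout: pure decay of N regardless of state
  withr::with_seed(3, {
    for (i in 1:10) {
      s <- cascade_state(L = runif(1, 0, 2), R = runif(1, 0, 2),
                         K = runif(1, 0, 2), N = runif(1, 0, 2),
                         F = runif(1, 0, 2))
      d <- cascade_rhs(s, runif(1, 0, 252), p, "fnrN")
      expect_equal(d[["N"]], -p$delta * s[["N"]])
    }
  })
})

test_that("the rhs preserves non-negativity at the boundary", {
  p <- test_params()
  withr::with_seed(5, {
    for (i in 1:20) {
      s <- cascade_state(L = runif(1, 0, 2), R = runif(1, 0, 2),
                         K = runif(1, 0, 2), N = runif(1, 0, 2),
                         F = runif(1, 0, 2))
      j <- sample(5, 1)
      s[j] <- 0
      d <- cascade_rhs(s, runif(1, 0, 252), p)
      expect_gte(d[[j]], 0)
    }
  })
})

test_that("states and parameters are validated", {
  expect_error(cascade_state(L = -1), "non-negative")
  expect_error(cascade_rhs(c(1, 2, 3), 12), "length 5")
  expect_error(hfixl_active_fraction(-1), ">= 0")
  expect_error(cascade_params(alpha_K = -1), "positive")
  expect_error(cascade_params(A_N_dist = 2, A_K_dist = 1), "smaller than A_K")
  expect_error(cascade_params(rho_K = 0.5), "exceed 1")
})

test_that("parameter files round-trip and reject unknown keys", {
  p <- test_params()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_params(p, path)
  q <- read_params(path)
  expect_equal(unclass(q), unclass(p))
  writeLines(c("K_L: 12", "bogus_key: 1"), path)
  expect_error(read_params(path), "bogus_key")
  expect_error(update_params(p, nope = 1), "nope")
})
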