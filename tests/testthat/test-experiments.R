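test_that("self-ratio is 100% and identical scenarios give unit fold", {
  p <- test_params()
  expect_equal(expression_ratio("wt", "fnrN", "free_living", p), 100)
  expect_equal(expression_ratio("wt", "fixNOQP", "in_planta", p), 100)
  expect_equal(fold_induction("fnrN", "wt", "free_living", "free_living", p), 1)
})

test_that("reduced and ODE steady-state routes agree", {
  p <- default_params()
  for (gt in c("wt", "hfixL", "fnrN")) {
    for (sc in c("atmospheric", "free_living", "in_planta")) {
      a <- scenario_steady_state(gt, sc, p, method = "reduced")
      b <- scenario_steady_state(gt, sc, p, method = "ode")
      expect_equal(a, b, tolerance = 1e-6)
    }
  }
})

test_that("expression ratios are invariant to the protein concentration unit", {
  p <- default_params()
  q <- rescale_concentration_unit(p, 3.7)
  for (gt in c("hfixL", "fnrN")) {
    for (rep in c("fnrN", "fixNOQP")) {
      expect_equal(expression_ratio(gt, rep, "free_living", p),
                   expression_ratio(gt, rep, "free_living", q),
                   tolerance = 1e-8)
      expect_equal(expression_ratio(gt, rep, "in_planta", p),
                   expression_ratio(gt, rep, "in_planta", q),
                   tolerance = 1e-8)
    }
  }
  expect_equal(fold_induction("fixNOQP", "wt", "atmospheric", "free_living", p),
               fold_induction("fixNOQP", "wt", "atmospheric", "free_living", q),
               tolerance = 1e-8)
})

test_that("the history rule reduces to the unique state when monostable", {
  p <- default_params()
  # wild type is monostable in planta: history and direct selection agree
  hist <- scenario_steady_state("wt", scenario("in_planta"), p)
  direct <- find_steady_states(0.03, p, "wt")
  expect_length(direct, 1)
  expect_equal(hist, direct[[1]], tolerance = 1e-7)
})

test_that("protein-level readout matches rate readout up to removal", {
  p <- default_params()
  r_rate <- expression_ratio("fnrN", "fixNOQP", "free_living", p,
                             readout = "rate")
  r_prot <- expression_ratio("fnrN", "fixNOQP", "free_living", p,
                             readout = "protein")
  expect_equal(r_rate, r_prot, tolerance = 1e-6)
})

test_that("nodule profiles reproduce the spatial contrasts", {
  p <- default_params()
  grad <- nodule_gradient(80)
  expect_true(all(diff(grad$oxygen) < 0))
  prof_wt <- nodule_zone_profile("wt", p, grad)
  prof_hf <- nodule_zone_profile("hfixL", p, grad)
  prof_fn <- nodule_zone_profile("fnrN", p, grad)
  st_wt <- onset_steepness(prof_wt)
  st_hf <- onset_steepness(prof_hf)
  # abrupt interzone onset of fixNOQP requires the hFixL pathway
  expect_gt(st_wt$steepness[st_wt$reporter == "fixNOQP"],
            st_hf$steepness[st_hf$reporter == "fixNOQP"])
  # fnrN is already expressed at the nodule tip in wild type: the hFixL
  # pathway induces it well above the basal (leaky) rate in zone I
  fnrn_wt <- dplyr::filter(prof_wt, reporter == "fnrN")
  expect_gt(fnrn_wt$activity[1], 2 * p$alpha_N)
  # minimal fixNOQP anywhere in the fnrN mutant
  fx_wt <- dplyr::filter(prof_wt, reporter == "fixNOQP")
  fx_fn <- dplyr::filter(prof_fn, reporter == "fixNOQP")
  expect_true(all(fx_fn$activity <= 0.1 * max(fx_wt$activity)))
  # deterministic recomputation
  expect_identical(prof_wt, nodule_zone_profile("wt", p, grad))
})

test_that("gradient and scenario inputs are validated", {
  p <- test_params()
  bad <- tibble::tibble(position = c(0, 1), oxygen = c(1, 2))
  expect_error(nodule_zone_profile("wt", p, bad), "decreasing")
  expect_error(scenario("nowhere"), "arg")
})
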