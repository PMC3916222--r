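test_that("knockout conditions reproduce the measured-panel simulations", {
  mef10 <- preset_condition("mef_10gy")
  expect_equal(pge2_48h(knockout(mef10, "C3")), 525, tolerance = 1e-3)
  # double knockout: no cleavage flux, no PGE2, at steady state or 48 h
  dko <- knockout(mef10, c("C3", "C7"))
  expect_lt(tail_pge2(run_protocol(dko, kp_base, grid = c(0, 2880))), 1e-6)
})

test_that("the NFkB clamp response is biphasic and saturates", {
  sc <- nfkb_clamp_scan(c(1e-5, 1e-2, 0.1, 1))
  expect_s3_class(sc, "scan_result")
  expect_true(all(is.finite(sc$readout_values) & sc$readout_values >= 0))
  expect_lt(sc$readout_values[1], 5)                      # silent below 1e-4 µM
  expect_equal(sc$readout_values[3], 285, tolerance = 2e-3) # 4T1 baseline
  expect_lt(sc$readout_values[4] / sc$readout_values[2], 1.35) # near-flat top
  expect_error(nfkb_clamp_scan(c(0, 0.1)), "positive")
  expect_error(nfkb_clamp_scan(0.1, preset_condition("4t1_10gy")),
               "unirradiated")
})

test_that("PGE2 falls monotonically with the COX2-inhibitor strength", {
  alphas <- c(0, 0.5, 1, 2, 5, 10)
  sc <- cox2_inhibition_scan(alphas)
  expect_equal(sc$readout_values[1], sc$baseline_readout, tolerance = 1e-9)
  expect_equal(sc$readout_values[1], 1801, tolerance = 1e-3)
  expect_true(all(diff(sc$readout_values) < 0))
  # overwhelming inhibition shuts the COX2 flux down almost completely
  floor_val <- cox2_inhibition_scan(1e6)$readout_values
  expect_lt(floor_val, 1)
  expect_error(cox2_inhibition_scan(-1), "non-negative")
})

test_that("iPLA2 silencing reduces PGE2 approximately linearly", {
  ks <- seq(0.018, 0.09, length.out = 5)
  sc <- ipla2_silencing_scan(ks)
  expect_equal(sc$readout_values[5], 1801, tolerance = 1e-3)  # baseline
  expect_true(all(diff(sc$readout_values) > 0))
  fit <- stats::lm(sc$readout_values ~ ks)
  expect_gt(summary(fit)$r.squared, 0.95)
  # total silencing: no iPLA2 synthesis, so no AA source and ~no PGE2
  expect_lt(ipla2_silencing_scan(0)$readout_values, sc$baseline_readout)
  expect_error(ipla2_silencing_scan(0.2), "baseline")
})

test_that("removing both competitive feedbacks barely changes PGE2", {
  base <- pge2_48h(preset_condition("mef_10gy"))
  nofb <- pge2_48h(preset_condition("mef_10gy"), remove_feedback(kp_base))
  rel <- (nofb - base) / base
  expect_gt(rel, 0)        # inhibition removal can only increase output
  expect_lt(rel, 0.02)
  # at the unirradiated steady state the effect is even smaller
  b0 <- pge2_48h(preset_condition("mef_0gy"))
  n0 <- pge2_48h(preset_condition("mef_0gy"), remove_feedback(kp_base))
  expect_lt((n0 - b0) / b0, 0.005)
})

test_that("the activation-rate grid reproduces the four scan scenarios", {
  g_k1 <- activation_rate_grid(c(0.1, 1), "baseline-k3")
  expect_equal(g_k1$readout_values[2], 1801, tolerance = 1e-3)
  expect_lt(g_k1$readout_values[1], g_k1$readout_values[2]) # k1 matters
  g_c3ko <- activation_rate_grid(c(1, 10), "C3KO")
  expect_equal(g_c3ko$readout_values[1], 525, tolerance = 1e-3)
  expect_lt(g_c3ko$readout_values[1], g_c3ko$readout_values[2]) # k3 matters in C3KO
  # with caspase-3 active, the k3 response is flat in comparison:
  # two orders of magnitude in k3 move 4T1 PGE2 by a few percent at most
  g_k3 <- activation_rate_grid(c(1, 100, 1000), "baseline-k1",
                               cp = preset_condition("4t1_10gy"))
  expect_lt(g_k3$readout_values[2] / g_k3$readout_values[1], 1.05)
  expect_lt(g_k3$readout_values[3] / g_k3$readout_values[1], 1.05)
  expect_error(activation_rate_grid(-1, "baseline-k3"), "positive")
})

test_that("only the AA-supply and PGE2-lifetime constants are sensitive", {
  sens <- sensitivity_scan(kp_base, preset_condition("mef_10gy"), factor = 2)
  expect_identical(nrow(sens), 25L)
  expect_identical(sort(sensitive_constants(sens)),
                   sort(c("k_minus5", "k6", "k7", "k17")))
  folds <- sens$fold_up
  names(folds) <- sens$constant
  # proportional to the synthesis constants, inverse in the decay constants
  expect_equal(unname(folds["k_minus5"]), 2, tolerance = 0.05)
  expect_equal(unname(folds["k6"]), 2, tolerance = 0.05)
  expect_equal(unname(folds["k17"]), 0.5, tolerance = 0.05)
  expect_equal(unname(folds["k7"]), 0.5, tolerance = 0.05)
  expect_true(all(is.finite(sens$fold_up)) && all(is.finite(sens$fold_down)))
  expect_error(sensitivity_scan(kp_base, factor = 1), "> 1")
})

test_that("scans leave their input parameter objects untouched", {
  kp <- kinetic_params()
  cp <- preset_condition("mef_10gy")
  invisible(cox2_inhibition_scan(c(0, 1), cp, kp))
  invisible(sensitivity_scan(kp, cp))
  expect_identical(kp, kinetic_params())
  expect_identical(cp, preset_condition("mef_10gy"))
})

test_that("scan results validate their shape", {
  expect_error(scan_result("x", 1:3, 1:2, 0), "equal length")
  expect_error(scan_result("x", 1, NaN, 0), "finite")
})
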