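test_that("the activation gate is 0 before the delay and 1 from it onwards", {
  expect_identical(heaviside_activation(1000, 1440), 0)
  expect_identical(heaviside_activation(1440, 1440), 1)
  expect_identical(heaviside_activation(0, 0), 1)
  expect_identical(heaviside_activation(c(0, 1439.99, 1440, 2880), 1440),
                   c(0, 0, 1, 1))
  expect_error(heaviside_activation(-1, 1440), "non-negative")
})

test_that("individual rate laws match hand-evaluated values", {
  kp <- kp_base
  cp <- preset_condition("mef_0gy")
  s <- stats::setNames(numeric(10), species_names())
  s["c3star"] <- 2e-4
  s["ipla2"] <- 1.5
  v <- reaction_rates(0, s, kp, cp)
  # Michaelis-Menten cleavage: 144 * 2e-4 * 1.5 / (11 + 1.5)
  expect_equal(v[["v2"]], 3.456e-3, tolerance = 1e-12)
  s2 <- stats::setNames(numeric(10), species_names())
  s2["nfkb"] <- 0.1
  v2 <- reaction_rates(0, s2, kp, cp)
  # Hill transcription: 7.68e-4 * 0.01 / (0.01 + 2.704e-5)
  expect_equal(v2[["v10"]], 7.6592893e-4, tolerance = 1e-7)
})

test_that("an all-zero state annihilates every rate except constitutive synthesis", {
  cp <- condition_params("resting", 0)  # k1 = k3 = k9 = 0
  s <- stats::setNames(numeric(10), species_names())
  v <- reaction_rates(0, s, kp_base, cp)
  expect_equal(v[["v5syn"]], kp_base$k_minus5)
  expect_true(all(v[setdiff(names(v), "v5syn")] == 0))
})

test_that("rate laws are first-order in their catalyst", {
  set.seed(42)
  cp <- preset_condition("mef_10gy")
  for (i in 1:5) {
    s <- random_state()
    s2 <- s
    s2["c3star"] <- 2 * s["c3star"]
    v1 <- reaction_rates(0, s, kp_base, cp)
    v2 <- reaction_rates(0, s2, kp_base, cp)
    expect_equal(v2[["v2"]], 2 * v1[["v2"]], tolerance = 1e-12)
    s3 <- s
    s3["cox2"] <- 2 * s["cox2"]
    v3 <- reaction_rates(0, s3, kp_base, cp)
    expect_equal(v3[["v14"]], 2 * v1[["v14"]], tolerance = 1e-12)
  }
})

test_that("removing the competitive feedbacks can only speed the inhibited steps", {
  set.seed(7)
  cp <- preset_condition("mef_10gy")
  kp_nf <- remove_feedback(kp_base)
  expect_identical(kp_nf$Ki14, Inf)
  expect_identical(kp_nf$Ki16, Inf)
  # baseline untouched (scans and perturbations are pure)
  expect_identical(kp_base$Ki14, 30)
  for (i in 1:10) {
    s <- random_state()
    v <- reaction_rates(0, s, kp_base, cp)
    vn <- reaction_rates(0, s, kp_nf, cp)
    expect_gte(vn[["v14"]], v[["v14"]])
    expect_gte(vn[["v16"]], v[["v16"]])
    if (s[["pge2"]] > 0) expect_gt(vn[["v14"]], v[["v14"]])
    if (s[["aa"]] > 0) expect_gt(vn[["v16"]], v[["v16"]])
  }
})

test_that("mass balances wire the rates with the volume correction on v6 and v16", {
  set.seed(11)
  cp <- preset_condition("4t1_10gy")
  for (t in c(100, 2000)) {
    s <- random_state()
    v <- reaction_rates(t, s, kp_base, cp)
    d <- ode_rhs(t, s, kp_base, cp)
    b <- kp_base$beta
    expect_equal(d[["c3star"]], v[["v1"]])
    expect_equal(d[["c7star"]], v[["v3"]])
    expect_equal(d[["nfkb"]], v[["v9"]])
    expect_equal(d[["ipla2"]],
                 v[["v5syn"]] - v[["v5deg"]] - v[["v2"]] - v[["v4"]])
    expect_equal(d[["ipla2star"]], v[["v2"]] + v[["v4"]] - v[["v7"]])
    expect_equal(d[["cox2_mrna"]], v[["v10"]] - v[["v11"]])
    expect_equal(d[["cox2"]], v[["v12"]] - v[["v13"]])
    expect_equal(d[["aa"]], v[["v6"]] / b - v[["v8"]] - v[["v14"]])
    expect_equal(d[["pgh2"]], v[["v14"]] - v[["v15"]] - v[["v16"]])
    expect_equal(d[["pge2"]], v[["v16"]] / b - v[["v17"]])
  }
})

test_that("the compiled rhs integrates to the same states as the R rhs", {
  set.seed(3)
  cp <- preset_condition("mef_10gy")
  r_rhs <- function(t, y, parms) {
    y[y < 0] <- 0  # trial steps may undershoot; match the compiled clip
    list(unname(ode_rhs(t, y, kp_base, cp)))
  }
  for (i in 1:3) {
    s0 <- random_state()
    # start beyond the activation delay so both paths see the gate open
    times <- c(1500, 1530)
    compiled <- phoenixsim:::.integrate(s0, times, kp_base, cp, heaviside = 1,
                                        rtol = 1e-10, atol = 1e-14)
    plain <- deSolve::ode(s0, times, r_rhs, NULL, method = "ode45",
                          rtol = 1e-10, atol = 1e-14)
    expect_equal(unname(compiled[2, -1]), unname(plain[2, -1]),
                 tolerance = 1e-8)
  }
})

test_that("reaction_rates rejects negative concentrations", {
  s <- stats::setNames(numeric(10), species_names())
  s["aa"] <- -0.1
  expect_error(reaction_rates(0, s, kp_base, preset_condition("mef_0gy")),
               "non-negative")
})
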