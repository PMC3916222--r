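test_that("a cell with no caspase input settles at the closed-form iPLA2 level", {
  cp <- condition_params("no caspases", 0, nfkb0 = 0, c3star0 = 0, c7star0 = 0)
  for (solve in list(relax_to_steady_state, algebraic_steady_state)) {
    ss <- solve(cp, kp_base)
    expect_equal(ss[["ipla2"]], kp_base$k_minus5 / kp_base$k5,
                 tolerance = 1e-6)  # 1.5 µM
    expect_equal(unname(ss[c("ipla2star", "aa", "pgh2", "pge2")]),
                 rep(0, 4), tolerance = 1e-9)
  }
})

test_that("double caspase knockout yields zero secreted PGE2 at steady state", {
  cp <- knockout(preset_condition("mef_0gy"), c("C3", "C7"))
  expect_identical(algebraic_steady_state(cp, kp_base)[["pge2"]], 0)
  expect_lt(relax_to_steady_state(cp, kp_base)[["pge2"]], 1e-12)
})

test_that("the algebraic cascade reproduces hand-derived steady-state levels", {
  ss <- algebraic_steady_state(preset_condition("mef_0gy"), kp_base)
  expect_equal(ss[["aa"]], 0.175, tolerance = 0.01)
  expect_equal(ss[["cox2"]], 0.0958, tolerance = 0.005)
  ss_ko <- algebraic_steady_state(preset_condition("c3ko_mef_0gy"), kp_base)
  expect_equal(ss_ko[["ipla2star"]], 0.246, tolerance = 0.01)
})

test_that("ODE relaxation and the algebraic cascade agree on every preset", {
  for (nm in std_presets) {
    cp <- unirradiated(preset_condition(nm))
    relaxed <- relax_to_steady_state(cp, kp_base)
    algebraic <- algebraic_steady_state(cp, kp_base)
    nz <- algebraic > 0
    expect_lt(max(abs(relaxed[nz] - algebraic[nz]) / algebraic[nz]), 0.005)
    if (any(!nz)) expect_lt(max(abs(relaxed[!nz])), 1e-9)
  }
})

test_that("the two steady-state routes agree under random parameter perturbation", {
  set.seed(101)
  perturbable <- c("k2", "K2", "k4", "K4", "k5", "k_minus5", "k6", "k7",
                   "k8", "k10", "K10", "k11", "k12", "k13", "k14", "K14",
                   "Ki14", "k15", "k16", "K16", "Ki16", "k17")
  cp <- preset_condition("mef_0gy")
  for (i in 1:8) {
    kp <- kp_base
    for (nm in sample(perturbable, 5)) {
      kp[[nm]] <- kp[[nm]] * stats::runif(1, 0.5, 2)
    }
    relaxed <- relax_to_steady_state(cp, kp)
    algebraic <- algebraic_steady_state(cp, kp)
    nz <- algebraic > 0
    expect_lt(max(abs(relaxed[nz] - algebraic[nz]) / algebraic[nz]), 0.005)
  }
})

test_that("the model rhs vanishes at the algebraic steady state", {
  for (nm in c("mef_0gy", "4t1_0gy", "c3ko_mef_0gy")) {
    cp <- preset_condition(nm)
    ss <- algebraic_steady_state(cp, kp_base)
    expect_lt(max(abs(ode_rhs(0, ss, kp_base, cp))), 1e-9)
  }
})

test_that("steady-state PGE2 responds monotonically to the main controls", {
  base <- preset_condition("mef_0gy")
  pge2_at <- function(cp, kp = kp_base) algebraic_steady_state(cp, kp)[["pge2"]]
  # non-decreasing in the caspase inputs and the AA supply chain
  for (field in c("c3star0", "c7star0")) {
    vals <- vapply(c(0.5, 1, 2, 4), function(f) {
      cp <- base; cp[[field]] <- cp[[field]] * f; pge2_at(cp)
    }, numeric(1))
    expect_false(is.unsorted(vals), info = field)
  }
  for (const in c("k6", "k_minus5")) {
    vals <- vapply(c(0.5, 1, 2, 4), function(f) {
      kp <- kp_base; kp[[const]] <- kp[[const]] * f; pge2_at(base, kp)
    }, numeric(1))
    expect_false(is.unsorted(vals), info = const)
  }
  # non-increasing in the COX2 inhibitor and the PGE2 decay rate
  for (const in c("alpha", "k17")) {
    vals <- vapply(c(1, 2, 4, 8), function(f) {
      kp <- kp_base
      kp[[const]] <- if (const == "alpha") f - 1 else kp[[const]] * f
      pge2_at(base, kp)
    }, numeric(1))
    expect_false(is.unsorted(rev(vals)), info = const)
  }
})

test_that("steady-state solvers refuse irradiated conditions", {
  cp <- preset_condition("mef_10gy")
  expect_error(relax_to_steady_state(cp, kp_base), "unirradiated")
  expect_error(algebraic_steady_state(cp, kp_base), "unirradiated")
})
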