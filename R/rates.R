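#' Heaviside activation gate
#'
#' Caspase-3 and caspase-7 activation after irradiation is delayed: their
#' zero-order activation rates are multiplied by a unit step that is 0
#' before the delay `tau` and 1 from `tau` onwards (the boundary belongs to
#' the "on" side).
#'
#' @param t Time since irradiation (min), non-negative.
#' @param tau Activation delay (min), non-negative.
#' @return 0 if `t < tau`, 1 if `t >= tau` (vectorized over `t`).
#' @examples
#' heaviside_activation(1000, 1440)  # 0
#' heaviside_activation(1440, 1440)  # 1
#' @export
heaviside_activation <- function(t, tau) {
  if (any(t < 0)) stop("time 't' must be non-negative")
  if (any(tau < 0)) stop("delay 'tau' must be non-negative")
  as.numeric(t >= tau)
}

#' Reaction rates of the seventeen-interaction network
#'
#' Evaluates every reaction rate at one state. Caspase-3/7 activation
#' (`v1`, `v3`) is zero-order and gated by [heaviside_activation()]; NFkB
#' production (`v9`) is zero-order from time zero. iPLA2 cleavage by the
#' caspases (`v2`, `v4`) follows Michaelis-Menten kinetics in iPLA2 with
#' the caspase as catalyst. iPLA2 turnover is a constant synthesis term
#' (`v5syn`) and first-order degradation (`v5deg`). Arachidonic-acid
#' release (`v6`) is proportional to activated iPLA2. COX2 transcription
#' (`v10`) is a Hill function of NFkB; translation (`v12`) is linear in the
#' mRNA. COX2 catalysis (`v14`) is Michaelis-Menten in AA with competitive
#' inhibition by PGE2 and by an exogenous drug of strength `alpha`; PGES
#' catalysis (`v16`) is Michaelis-Menten in PGH2 with competitive
#' inhibition by AA. All remaining rates are first-order degradations
#' (`v7` activated iPLA2, `v8` AA, `v11` COX2 mRNA, `v13` COX2, `v15`
#' PGH2, `v17` PGE2).
#'
#' @param t Time (min).
#' @param state Named numeric vector over [species_names()] (µM),
#'   non-negative.
#' @param kp [kinetic_params()].
#' @param cp [condition_params()].
#' @return Named numeric vector of rates (µM/min): `v1`..`v4`, `v5deg`,
#'   `v5syn`, `v6`..`v17`.
#' @export
reaction_rates <- function(t, state, kp, cp) {
  s <- as.list(state[species_names()])
  if (any(unlist(s) < 0)) stop("state must be non-negative")
  H <- heaviside_activation(t, kp$tau)
  hill <- s$nfkb^kp$n / (kp$K10^kp$n + s$nfkb^kp$n)
  c(v1 = cp$k1 * H,
    v2 = kp$k2 * s$c3star * s$ipla2 / (kp$K2 + s$ipla2),
    v3 = cp$k3 * H,
    v4 = kp$k4 * s$c7star * s$ipla2 / (kp$K4 + s$ipla2),
    v5deg = kp$k5 * s$ipla2,
    v5syn = kp$k_minus5,
    v6 = kp$k6 * s$ipla2star,
    v7 = kp$k7 * s$ipla2star,
    v8 = kp$k8 * s$aa,
    v9 = cp$k9,
    v10 = kp$k10 * hill,
    v11 = kp$k11 * s$cox2_mrna,
    v12 = kp$k12 * s$cox2_mrna,
    v13 = kp$k13 * s$cox2,
    v14 = kp$k14 * s$cox2 * s$aa /
      (kp$K14 * (1 + s$pge2 / kp$Ki14 + kp$alpha) + s$aa),
    v15 = kp$k15 * s$pgh2,
    v16 = kp$k16 * kp$pges * s$pgh2 /
      (kp$K16 * (1 + s$aa / kp$Ki16) + s$pgh2),
    v17 = kp$k17 * s$pge2)
}

#' Mass-balance right-hand side of the model ODEs
#'
#' Time derivatives of the ten species. The caspase and NFkB inputs only
#' accumulate (their inactivation is outside the 48-h scope). Fluxes that
#' deliver material into the shared medium volume — AA release (`v6`) and
#' PGE2 synthesis (`v16`) — are scaled by `1/beta` in the balances of the
#' medium-referenced species AA and PGE2, because those concentrations are
#' defined per total volume while the producing reactions run in the cell
#' volume. The AA consumed by COX2 (`v14`) and all degradation terms act on
#' the species' own reference volume and enter unscaled.
#'
#' @inheritParams reaction_rates
#' @return Named numeric vector of derivatives (µM/min) over
#'   [species_names()].
#' @export
ode_rhs <- function(t, state, kp, cp) {
  v <- reaction_rates(t, state, kp, cp)
  b <- kp$beta
  c(c3star = v[["v1"]],
    c7star = v[["v3"]],
    nfkb = v[["v9"]],
    ipla2 = v[["v5syn"]] - v[["v5deg"]] - v[["v2"]] - v[["v4"]],
    ipla2star = v[["v2"]] + v[["v4"]] - v[["v7"]],
    cox2_mrna = v[["v10"]] - v[["v11"]],
    cox2 = v[["v12"]] - v[["v13"]],
    aa = v[["v6"]] / b - v[["v8"]] - v[["v14"]],
    pgh2 = v[["v14"]] - v[["v15"]] - v[["v16"]],
    pge2 = v[["v16"]] / b - v[["v17"]])
}

# parameter vector for the compiled rhs (order fixed by src/model.c), with
# the Heaviside value frozen per integration segment so the solver never
# steps across the discontinuity
.model_parms <- function(kp, cp, heaviside) {
  c(kp$k2, kp$K2, kp$k4, kp$K4, kp$k5, kp$k_minus5, kp$k6, kp$k7, kp$k8,
    kp$k10, kp$K10, kp$n, kp$k11, kp$k12, kp$k13, kp$k14, kp$K14, kp$Ki14,
    kp$k15, kp$k16, kp$K16, kp$Ki16, kp$k17, kp$pges, kp$alpha, kp$beta,
    cp$k1, cp$k3, cp$k9, heaviside)
}

# initial state for a condition: caspases and NFkB at their resting levels,
# everything downstream at zero
.initial_state <- function(cp) {
  s <- stats::setNames(numeric(10L), species_names())
  s["c3star"] <- cp$c3star0
  s["c7star"] <- cp$c7star0
  s["nfkb"] <- cp$nfkb0
  s
}

# one deSolve integration segment with the Dormand-Prince 4(5) pair and the
# compiled rhs
.integrate <- function(y0, times, kp, cp, heaviside, rtol = 1e-8, atol = 1e-12) {
  out <- deSolve::ode(y = y0, times = times, func = "pr_derivs",
                      parms = .model_parms(kp, cp, heaviside),
                      dllname = "phoenixsim", initfunc = "pr_initmod",
                      method = "ode45", rtol = rtol, atol = atol,
                      maxsteps = 1e6)
  if (attr(out, "istate")[1L] < 0)
    stop("ODE integration failed for condition '", cp$cell_label, "'")
  out
}
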