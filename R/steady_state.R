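#' Unirradiated steady state by ODE relaxation
#'
#' Integrates the model from the resting initial condition — caspases and
#' NFkB clamped at their resting levels, all downstream species zero — until
#' the trajectory has relaxed, and verifies convergence by the relative
#' rate-of-change of every species. This mirrors the original numerical
#' procedure used to initialize the radiation protocol.
#'
#' @param cp [condition_params()] with `k1 = k3 = k9 = 0`.
#' @param kp [kinetic_params()].
#' @param horizon Integration horizon (min); the slowest intrinsic
#'   timescale is 1/0.06 min, so the default 2880 min (48 h) is ~170 time
#'   constants.
#' @param tol Convergence tolerance on `max |ds_i/dt| / max(s_i, 1e-12)`.
#' @return Named numeric steady-state vector over [species_names()] (µM).
#' @examples
#' ss <- relax_to_steady_state(preset_condition("mef_0gy"), kinetic_params())
#' pge2_to_pg_per_ml(ss[["pge2"]])  # ~388 pg/mL
#' @export
relax_to_steady_state <- function(cp, kp = kinetic_params(),
                                  horizon = 2880, tol = 1e-6) {
  stopifnot(inherits(cp, "condition_params"), inherits(kp, "kinetic_params"))
  if (cp$k1 != 0 || cp$k3 != 0 || cp$k9 != 0)
    stop("steady-state relaxation requires an unirradiated condition ",
         "(k1 = k3 = k9 = 0); use unirradiated() first")
  # tight solver tolerances so the residual test measures the model, not
  # integration noise (the PGH2 balance is a small difference of ~0.3
  # µM/min fluxes)
  out <- .integrate(.initial_state(cp), c(0, horizon), kp, cp, heaviside = 0,
                    rtol = 1e-10, atol = 1e-14)
  s <- out[nrow(out), -1L]
  s[s < 0] <- 0
  ds <- ode_rhs(horizon, s, kp, cp)
  rel <- abs(ds) / pmax(s, 1e-12)
  if (max(rel) >= tol)
    stop("not converged: relative rate ", format(max(rel)),
         " at horizon ", horizon, " min exceeds tol ", tol)
  s
}

#' Unirradiated steady state by the algebraic cascade
#'
#' Solves the steady-state balances directly, independently of any ODE
#' integration, exploiting the feed-forward structure of the network:
#' (i) a 1-D root-find for iPLA2 balancing constitutive synthesis against
#' degradation plus caspase cleavage; (ii) activated iPLA2 from the
#' cleavage flux; (iii) COX2 mRNA and protein from the Hill transcription
#' law; (iv) the coupled AA/PGH2/PGE2 balances, solved by two nested 1-D
#' root-finds with the weak PGE2-on-COX2 product feedback iterated to a
#' fixed point (it contracts quickly because PGE2/Ki14 << 1 at all
#' physiological outputs).
#'
#' Serves as an independent cross-check of [relax_to_steady_state()].
#'
#' @inheritParams relax_to_steady_state
#' @param max_iter Maximum fixed-point iterations on the PGE2 feedback.
#' @return Named numeric steady-state vector over [species_names()] (µM).
#' @export
algebraic_steady_state <- function(cp, kp = kinetic_params(), max_iter = 50L) {
  stopifnot(inherits(cp, "condition_params"), inherits(kp, "kinetic_params"))
  if (cp$k1 != 0 || cp$k3 != 0 || cp$k9 != 0)
    stop("algebraic steady state requires an unirradiated condition")
  s <- .initial_state(cp)

  cleave <- function(L) {
    kp$k2 * cp$c3star0 * L / (kp$K2 + L) + kp$k4 * cp$c7star0 * L / (kp$K4 + L)
  }
  L_max <- kp$k_minus5 / kp$k5
  f <- function(L) kp$k_minus5 - kp$k5 * L - cleave(L)
  if (cleave(L_max) == 0) {
    L <- L_max  # no caspase flux: closed form
  } else {
    L <- stats::uniroot(f, c(0, L_max), tol = 1e-14)$root
  }
  s["ipla2"] <- L
  s["ipla2star"] <- cleave(L) / kp$k7

  hill <- cp$nfkb0^kp$n / (kp$K10^kp$n + cp$nfkb0^kp$n)
  s["cox2_mrna"] <- kp$k10 * hill / kp$k11
  s["cox2"] <- kp$k12 * s[["cox2_mrna"]] / kp$k13
  cox2 <- s[["cox2"]]

  src <- kp$k6 * s[["ipla2star"]] / kp$beta  # AA source flux per V_t
  if (src == 0) return(s)                    # nothing downstream

  v14_at <- function(A, P) {
    kp$k14 * cox2 * A / (kp$K14 * (1 + P / kp$Ki14 + kp$alpha) + A)
  }
  P <- 0
  for (i in seq_len(max_iter)) {
    # AA balance: src = k8*A + v14(A, P); monotone in A on [0, src/k8]
    A <- stats::uniroot(function(A) src - kp$k8 * A - v14_at(A, P),
                        c(0, src / kp$k8), tol = 1e-14)$root
    v14 <- v14_at(A, P)
    if (v14 == 0) { H <- 0; P_new <- 0 }
    else {
      # PGH2 balance: v14 = k15*H + v16(H, A); monotone in H on [0, v14/k15]
      v16_at <- function(H) kp$k16 * kp$pges * H / (kp$K16 * (1 + A / kp$Ki16) + H)
      H <- stats::uniroot(function(H) v14 - kp$k15 * H - v16_at(H),
                          c(0, v14 / kp$k15), tol = 1e-14)$root
      P_new <- v16_at(H) / (kp$beta * kp$k17)
    }
    if (abs(P_new - P) <= 1e-12 * max(P_new, 1e-12)) { P <- P_new; break }
    P <- P_new
  }
  s["aa"] <- A
  s["pgh2"] <- H
  s["pge2"] <- P
  s
}
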