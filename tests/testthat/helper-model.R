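# shared fixtures: baseline kinetics and the six standard conditions
kp_base <- kinetic_params()

std_presets <- c("c3ko_mef_0gy", "c3ko_mef_10gy", "mef_0gy", "mef_10gy",
                 "4t1_0gy", "4t1_10gy")

# 48-h secreted PGE2 (pg/mL): steady state for unirradiated conditions,
# radiation protocol otherwise
pge2_48h <- function(cp, kp = kp_base) {
  if (cp$k1 == 0 && cp$k3 == 0 && cp$k9 == 0) {
    pge2_to_pg_per_ml(relax_to_steady_state(cp, kp)[["pge2"]], kp)
  } else {
    tail_pge2(run_protocol(cp, kp, grid = c(0, 2880)))
  }
}

# a strictly positive random state, for rate-law property checks
random_state <- function() {
  s <- stats::setNames(stats::runif(10, 1e-4, 2), species_names())
  s["c3star"] <- stats::runif(1, 0, 1e-3)
  s["c7star"] <- stats::runif(1, 0, 1e-2)
  s
}
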