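#' Western-blot band intensity to concentration
#'
#' Converts a background-subtracted band intensity into an absolute
#' concentration by normalizing against a reference band of known
#' concentration — by default total caspase-3 in unirradiated cells,
#' taken to be 200 nM.
#'
#' @param band_intensity Background-subtracted intensity of the band of
#'   interest (arbitrary units, >= 0).
#' @param reference_intensity Intensity of the reference band (> 0).
#' @param reference_conc Concentration assigned to the reference band (nM).
#' @return Concentration in nM.
#' @examples
#' blot_band_to_concentration(0.2, 1.0)  # 40 nM
#' @export
blot_band_to_concentration <- function(band_intensity, reference_intensity,
                                       reference_conc = 200) {
  if (any(reference_intensity <= 0)) stop("reference intensity must be > 0")
  if (any(band_intensity < 0)) stop("band intensity must be >= 0")
  band_intensity / reference_intensity * reference_conc
}

#' Caspase-3 activation rate from the day-2 measurement
#'
#' Activated caspase-3 is first detectable between 24 and 48 h after
#' irradiation; its zero-order activation rate is the day-2 rise above the
#' resting level (0.2 nM) spread over the 1440 min during which activation
#' is on.
#'
#' @param c3star_day2 Measured activated caspase-3 at day 2 (µM).
#' @param c3star_baseline Resting level (µM), default 2e-4 (0.2 nM).
#' @param window Activation window (min), default 1440.
#' @return `k1` in µM/min.
#' @examples
#' k1_from_day2_c3star(0.04050)  # 2.8e-5, the MEF 10-Gy value
#' @export
k1_from_day2_c3star <- function(c3star_day2, c3star_baseline = 2e-4,
                                window = 1440) {
  if (any(c3star_day2 < c3star_baseline))
    stop("day-2 [C3*] must not be below the resting level")
  if (window <= 0) stop("'window' must be positive")
  (c3star_day2 - c3star_baseline) / window
}

#' NFkB production rate from its fold increase
#'
#' NFkB rises approximately linearly after irradiation; a rise of
#' `fold_increase` times the resting level over `duration` minutes gives a
#' zero-order production rate `nfkb0 * fold_increase / duration`. The
#' standard choice — a one-fold rise of 0.1 µM over 48 h — yields
#' 3.47e-5 µM/min.
#'
#' @param nfkb0 Resting NFkB concentration (µM), > 0.
#' @param fold_increase Fold rise over the window (>= 0).
#' @param duration Window length (min), > 0.
#' @return `k9` in µM/min.
#' @export
k9_from_fold_increase <- function(nfkb0 = 0.1, fold_increase = 1,
                                  duration = 2880) {
  if (duration <= 0) stop("'duration' must be positive")
  if (nfkb0 <= 0) stop("'nfkb0' must be positive")
  if (fold_increase < 0) stop("'fold_increase' must be >= 0")
  nfkb0 * fold_increase / duration
}

#' Fit the resting activated-caspase-7 concentration
#'
#' Finds the `c7star0` for which the unirradiated steady-state secreted
#' PGE2 equals a measured value, by bracketed root-finding on the
#' monotone map `c7star0 -> PGE2`. This is how the resting caspase-7
#' level is calibrated against the unirradiated C3-knockout MEF (335
#' pg/mL, giving 6.0 nM) and wild-type 4T1 (285 pg/mL, giving 3.8 nM)
#' measurements.
#'
#' @param target_pge2 Measured steady-state PGE2 (pg/mL).
#' @param cp Unirradiated [condition_params()]; its `c7star0` is ignored.
#' @param kp [kinetic_params()].
#' @param upper Upper bracket for `c7star0` (µM).
#' @param tol Tolerance on the matched PGE2 (pg/mL).
#' @return Fitted `c7star0` in nM.
#' @export
fit_c7star0 <- function(target_pge2, cp = preset_condition("c3ko_mef_0gy"),
                        kp = kinetic_params(), upper = 0.1, tol = 0.1) {
  if (target_pge2 < 0) stop("'target_pge2' must be >= 0")
  if (cp$k1 != 0 || cp$k3 != 0 || cp$k9 != 0)
    stop("fitting c7star0 uses the unirradiated steady state")
  obj <- function(c7) {
    cpi <- cp; cpi$c7star0 <- c7
    pge2_to_pg_per_ml(relax_to_steady_state(cpi, kp)[["pge2"]], kp) - target_pge2
  }
  f_lo <- obj(0)
  if (abs(f_lo) <= tol) return(0)
  f_hi <- obj(upper)
  if (f_lo > 0 || f_hi < 0)
    stop("target PGE2 of ", target_pge2, " pg/mL is outside the reachable ",
         "range [", format(f_lo + target_pge2), ", ",
         format(f_hi + target_pge2), "]")
  root <- stats::uniroot(obj, c(0, upper), tol = 1e-10)$root
  if (abs(obj(root)) > tol) stop("root-finding did not reach the target PGE2")
  root * 1e3
}

#' Fit the caspase-7 activation rate
#'
#' Finds the `k3` for which the 48-h post-irradiation secreted PGE2 of a
#' caspase-3-knockout condition equals a measured value, by bracketed
#' root-finding on the monotone map `k3 -> PGE2(48 h)`. Calibrating
#' against the irradiated C3-knockout MEF measurement (525 pg/mL) gives
#' 3.24e-6 µM/min.
#'
#' @param target_pge2_48h Measured 48-h PGE2 (pg/mL).
#' @param cp Irradiated [condition_params()]; its `k3` is ignored.
#' @param kp [kinetic_params()].
#' @param upper Upper bracket for `k3` (µM/min).
#' @param tol Tolerance on the matched PGE2 (pg/mL).
#' @return Fitted `k3` in µM/min.
#' @export
fit_k3 <- function(target_pge2_48h, cp = preset_condition("c3ko_mef_10gy"),
                   kp = kinetic_params(), upper = 1e-3, tol = 0.1) {
  if (target_pge2_48h < 0) stop("'target_pge2_48h' must be >= 0")
  obj <- function(k3) {
    cpi <- cp; cpi$k3 <- k3
    tail_pge2(run_protocol(cpi, kp, grid = c(0, 2880))) - target_pge2_48h
  }
  f_lo <- obj(0)
  if (abs(f_lo) <= tol) return(0)
  f_hi <- obj(upper)
  if (f_lo > 0 || f_hi < 0)
    stop("target PGE2 of ", target_pge2_48h, " pg/mL is outside the ",
         "reachable range [", format(f_lo + target_pge2_48h), ", ",
         format(f_hi + target_pge2_48h), "]")
  root <- stats::uniroot(obj, c(0, upper), tol = 1e-14)$root
  if (abs(obj(root)) > tol) stop("root-finding did not reach the target PGE2")
  root
}

# measured 48-h secreted PGE2 (pg/mL) for the six standard conditions
table1_measured <- function() {
  c(c3ko_mef_0gy = 335, c3ko_mef_10gy = 525,
    mef_0gy = 398, mef_10gy = 1730,
    `4t1_0gy` = 285, `4t1_10gy` = 2100)
}

#' Validation report against the measured PGE2 panel
#'
#' Simulates all six standard conditions — steady state for the
#' unirradiated presets, the full radiation protocol for the 10-Gy
#' presets — and compares the secreted PGE2 with the embedded experimental
#' panel (335, 525, 398, 1730, 285, 2100 pg/mL). The relative difference
#' is denominated by the measured value; the model is accepted when the
#' maximum, rounded to the nearest percent (the precision at which such
#' panel comparisons are quoted), does not exceed `max_rel_diff_pct`.
#'
#' @param kp [kinetic_params()].
#' @param max_rel_diff_pct Pass threshold on the maximum relative
#'   difference (percent), default 9.
#' @return A `table1_report`: list with `table` (condition, measured,
#'   simulated, rel_diff_pct), `max_rel_diff_pct` and logical `pass`.
#' @export
validate_against_table1 <- function(kp = kinetic_params(),
                                    max_rel_diff_pct = 9) {
  measured <- table1_measured()
  sim <- vapply(names(measured), function(nm) {
    .pge2_48h(preset_condition(nm), kp)
  }, numeric(1))
  rel <- abs(sim - measured) / measured * 100
  report <- list(
    table = data.frame(condition = names(measured),
                       measured_pg_per_ml = unname(measured),
                       simulated_pg_per_ml = unname(sim),
                       rel_diff_pct = unname(rel),
                       row.names = NULL),
    max_rel_diff_pct = max(rel),
    pass = round(max(rel)) <= max_rel_diff_pct)
  class(report) <- "table1_report"
  report
}

#' @export
print.table1_report <- function(x, ...) {
  df <- x$table
  df$measured_pg_per_ml <- round(df$measured_pg_per_ml)
  df$simulated_pg_per_ml <- round(df$simulated_pg_per_ml)
  df$rel_diff_pct <- round(df$rel_diff_pct, 2)
  print(df)
  cat(sprintf("max relative difference: %.2f%% -> %s\n",
              x$max_rel_diff_pct, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Write the validation report
#'
#' @param x A `table1_report`.
#' @param path Output path (`.json` or `.csv` by extension).
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(x, path) {
  stopifnot(inherits(x, "table1_report"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(table = x$table,
                              max_rel_diff_pct = x$max_rel_diff_pct,
                              pass = x$pass),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(x$table, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
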