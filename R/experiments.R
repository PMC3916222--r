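#' Scan result container
#'
#' Tabular output of a one-parameter scan: the scanned values, the readout
#' per value (secreted PGE2 at 48 h, pg/mL, unless stated otherwise) and
#' the unperturbed baseline readout.
#'
#' @param scanned_name Name of the scanned quantity.
#' @param scanned_values Numeric vector of scanned values.
#' @param readout_values Numeric vector, same length.
#' @param baseline_readout Readout at the unperturbed baseline.
#' @param readout_name Label of the readout.
#' @return An object of class `scan_result`.
#' @export
scan_result <- function(scanned_name, scanned_values, readout_values,
                        baseline_readout,
                        readout_name = "PGE2 at 48 h, pg/mL") {
  if (length(scanned_values) != length(readout_values))
    stop("scanned and readout vectors must have equal length")
  if (!all(is.finite(readout_values)) || any(readout_values < 0))
    stop("readout values must be finite and non-negative")
  structure(list(scanned_name = scanned_name,
                 scanned_values = as.numeric(scanned_values),
                 readout_name = readout_name,
                 readout_values = as.numeric(readout_values),
                 baseline_readout = baseline_readout),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Scan of %s (%d values); readout: %s; baseline = %.4g\n",
              x$scanned_name, length(x$scanned_values), x$readout_name,
              x$baseline_readout))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.scan_result <- function(x, ...) {
  df <- data.frame(scan_param = x$scanned_name,
                   value = x$scanned_values,
                   readout = x$readout_values)
  names(df)[3L] <- if (grepl("pg/mL", x$readout_name, fixed = TRUE))
    "pge2_pg_per_ml" else "readout"
  df
}

#' Write a scan result as tidy CSV or JSON
#'
#' @param x A [scan_result()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(x, path) {
  stopifnot(inherits(x, "scan_result"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scan_csv
#' @export
write_scan_json <- function(x, path) {
  stopifnot(inherits(x, "scan_result"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' In-silico caspase knockout
#'
#' Knocking out caspase-3 and/or caspase-7 zeroes both the resting
#' concentration of the activated form and its post-irradiation activation
#' rate, in a copy of the condition.
#'
#' @param cp [condition_params()].
#' @param genes Character subset of `c("C3", "C7")`; empty means no change.
#' @return A modified [condition_params()].
#' @examples
#' dko <- knockout(preset_condition("mef_10gy"), c("C3", "C7"))
#' @export
knockout <- function(cp, genes = character()) {
  stopifnot(inherits(cp, "condition_params"))
  genes <- toupper(as.character(genes))
  bad <- setdiff(genes, c("C3", "C7"))
  if (length(bad)) stop("unknown gene label(s): ", paste(bad, collapse = ", "),
                        "; knockouts are limited to C3 and C7")
  c3 <- cp$c3star0; c7 <- cp$c7star0; k1 <- cp$k1; k3 <- cp$k3
  lab <- cp$cell_label
  if ("C3" %in% genes) { c3 <- 0; k1 <- 0; lab <- paste(lab, "C3-KO") }
  if ("C7" %in% genes) { c7 <- 0; k3 <- 0; lab <- paste(lab, "C7-KO") }
  condition_params(lab, cp$dose_Gy, nfkb0 = cp$nfkb0,
                   c3star0 = c3, c7star0 = c7, k1 = k1, k3 = k3, k9 = cp$k9)
}

# 48-h PGE2 readout (pg/mL) for a condition: steady state if unirradiated,
# radiation protocol otherwise
.pge2_48h <- function(cp, kp, t_end = 2880) {
  if (cp$k1 == 0 && cp$k3 == 0 && cp$k9 == 0) {
    pge2_to_pg_per_ml(relax_to_steady_state(cp, kp)[["pge2"]], kp)
  } else {
    tail_pge2(run_protocol(cp, kp, t_end = t_end, grid = c(0, t_end)))
  }
}

#' NFkB clamp scan
#'
#' Fixes the (time-independent) NFkB concentration at each requested level
#' in an unirradiated condition and records the steady-state secreted PGE2.
#' The response is biphasic and saturating: it vanishes below ~1e-4 µM and
#' is nearly flat above ~1e-2 µM, because the Hill transcription law is
#' already near saturation at the resting 0.1 µM.
#'
#' @param levels Positive NFkB levels (µM).
#' @param cp Unirradiated [condition_params()] (default wild-type 4T1).
#' @param kp [kinetic_params()].
#' @return A [scan_result()] with the clamp level as scanned value.
#' @export
nfkb_clamp_scan <- function(levels, cp = preset_condition("4t1_0gy"),
                            kp = kinetic_params()) {
  if (any(levels <= 0)) stop("NFkB clamp levels must be positive")
  if (cp$k1 != 0 || cp$k3 != 0 || cp$k9 != 0)
    stop("NFkB clamping uses unirradiated semantics (k1 = k3 = k9 = 0)")
  run_one <- function(lv) {
    cpi <- condition_params(cp$cell_label, cp$dose_Gy, nfkb0 = lv,
                            c3star0 = cp$c3star0, c7star0 = cp$c7star0)
    .pge2_48h(cpi, kp)
  }
  scan_result("nfkb0_uM", levels, vapply(levels, run_one, numeric(1)),
              baseline_readout = .pge2_48h(cp, kp))
}

#' Exogenous COX2-inhibition scan
#'
#' Varies the dimensionless competitive-inhibitor strength `alpha`
#' (drug concentration over its COX2 binding constant) and records the
#' 48-h post-irradiation secreted PGE2. The drug is assumed present
#' throughout, so the pre-irradiation steady state is recomputed at each
#' `alpha`.
#'
#' @param alphas Non-negative inhibitor strengths.
#' @param cp Irradiated [condition_params()] (default wild-type MEF,
#'   10 Gy).
#' @param kp [kinetic_params()].
#' @return A [scan_result()].
#' @export
cox2_inhibition_scan <- function(alphas, cp = preset_condition("mef_10gy"),
                                 kp = kinetic_params()) {
  if (any(alphas < 0)) stop("'alpha' values must be non-negative")
  run_one <- function(a) {
    kpi <- kp; kpi$alpha <- a
    .pge2_48h(cp, kpi)
  }
  scan_result("alpha", alphas, vapply(alphas, run_one, numeric(1)),
              baseline_readout = .pge2_48h(cp, kp))
}

#' iPLA2-silencing scan
#'
#' Models shRNA silencing of iPLA2 expression by reducing the constitutive
#' synthesis rate `k_minus5` below its baseline (0.09 µM/min). Silencing is
#' assumed in place before irradiation, so the pre-irradiation steady state
#' is recomputed at each value. The 48-h PGE2 falls approximately linearly
#' with `k_minus5`.
#'
#' @param k_minus5_values Values in `[0, baseline]` (µM/min).
#' @param cp Irradiated [condition_params()] (default wild-type MEF,
#'   10 Gy).
#' @param kp [kinetic_params()].
#' @return A [scan_result()].
#' @export
ipla2_silencing_scan <- function(k_minus5_values,
                                 cp = preset_condition("mef_10gy"),
                                 kp = kinetic_params()) {
  if (any(k_minus5_values < 0) || any(k_minus5_values > kp$k_minus5))
    stop("silencing values must lie in [0, baseline k_minus5]")
  run_one <- function(v) {
    kpi <- kp; kpi$k_minus5 <- v
    .pge2_48h(cp, kpi)
  }
  scan_result("k_minus5_uM_per_min", k_minus5_values,
              vapply(k_minus5_values, run_one, numeric(1)),
              baseline_readout = .pge2_48h(cp, kp))
}

#' Disable the competitive-inhibition feedbacks
#'
#' Returns a parameter copy with both product-inhibition loops removed —
#' PGE2 on COX2 (`Ki14`) and arachidonic acid on PGES (`Ki16`) — by setting
#' the inhibition constants to infinity (equivalently `1/Ki = 0`).
#'
#' @param kp [kinetic_params()].
#' @return A [kinetic_params()] copy with `Ki14 = Ki16 = Inf`.
#' @export
remove_feedback <- function(kp) {
  stopifnot(inherits(kp, "kinetic_params"))
  kp$Ki14 <- Inf
  kp$Ki16 <- Inf
  kp
}

#' Caspase activation-rate grid
#'
#' Scans the caspase-3 (`k1`) or caspase-7 (`k3`) activation rate over
#' multiplicative factors of its wild-type MEF 10-Gy baseline, for the four
#' standard scenarios: vary `k1` with `k3` at baseline (`"baseline-k3"`),
#' vary `k3` with `k1` at baseline (`"baseline-k1"`), vary `k1` in
#' caspase-7-knockout cells (`"C7KO"`), and vary `k3` in
#' caspase-3-knockout cells (`"C3KO"`). The readout is secreted PGE2 at
#' 48 h post irradiation.
#'
#' @param factors Positive multiplicative factors applied to the varied
#'   rate's baseline (2.8e-5 µM/min for `k1`, 3.24e-6 µM/min for `k3`).
#' @param scenario One of `"baseline-k3"`, `"baseline-k1"`, `"C7KO"`,
#'   `"C3KO"`.
#' @param cp Irradiated wild-type base condition (default MEF, 10 Gy).
#' @param kp [kinetic_params()].
#' @return A [scan_result()] with the factor as scanned value.
#' @export
activation_rate_grid <- function(factors,
                                 scenario = c("baseline-k3", "baseline-k1",
                                              "C7KO", "C3KO"),
                                 cp = preset_condition("mef_10gy"),
                                 kp = kinetic_params()) {
  scenario <- match.arg(scenario)
  if (any(factors <= 0)) stop("factors must be positive")
  base <- switch(scenario,
    "baseline-k3" = cp,
    "baseline-k1" = cp,
    "C7KO" = knockout(cp, "C7"),
    "C3KO" = knockout(cp, "C3"))
  vary_k1 <- scenario %in% c("baseline-k3", "C7KO")
  # factors are relative to the wild-type baseline rate, including in the
  # knockout scenarios (where the condition's own rate has been zeroed)
  ref <- if (vary_k1) cp$k1 else cp$k3
  run_one <- function(f) {
    cpi <- base
    if (vary_k1) cpi$k1 <- f * ref else cpi$k3 <- f * ref
    .pge2_48h(cpi, kp)
  }
  scan_result(if (vary_k1) "k1_factor" else "k3_factor",
              factors, vapply(factors, run_one, numeric(1)),
              baseline_readout = .pge2_48h(cp, kp))
}

# the 25 scanned rate and equilibrium constants: 3 condition-dependent
# activation rates plus the 22 condition-independent constants (n, PGES,
# beta, alpha and the delay are structural and excluded)
sensitivity_constants <- function() {
  c("k1", "k3", "k9",
    "k2", "K2", "k4", "K4", "k5", "k_minus5", "k6", "k7", "k8",
    "k10", "K10", "k11", "k12", "k13", "k14", "K14", "Ki14",
    "k15", "k16", "K16", "Ki16", "k17")
}

#' Local sensitivity analysis of secreted PGE2
#'
#' Perturbs each of the 25 rate and equilibrium constants one at a time by
#' a multiplicative factor (default 2) and its reciprocal, reruns the full
#' radiation protocol (pre-irradiation steady state included), and reports
#' the fold change of 48-h secreted PGE2 relative to baseline. Only
#' `k_minus5`, `k6`, `k7` and `k17` — the constants that set the
#' arachidonic-acid supply (iPLA2 synthesis, AA release per unit activated
#' iPLA2, activated-iPLA2 turnover) and the PGE2 lifetime — move the
#' output appreciably.
#'
#' @param kp [kinetic_params()].
#' @param cp Irradiated [condition_params()] (default wild-type MEF,
#'   10 Gy).
#' @param factor Perturbation factor, > 1.
#' @return An object of class `sensitivity_result`: data frame with
#'   columns `constant`, `fold_up` (x factor) and `fold_down`
#'   (x 1/factor), with the baseline PGE2 (pg/mL) as attribute
#'   `baseline_pge2`.
#' @export
sensitivity_scan <- function(kp = kinetic_params(),
                             cp = preset_condition("mef_10gy"),
                             factor = 2) {
  if (factor <= 1) stop("'factor' must be > 1")
  baseline <- .pge2_48h(cp, kp)
  consts <- sensitivity_constants()
  run_one <- function(nm, f) {
    kpi <- kp; cpi <- cp
    if (nm %in% c("k1", "k3", "k9")) cpi[[nm]] <- cpi[[nm]] * f
    else kpi[[nm]] <- kpi[[nm]] * f
    .pge2_48h(cpi, kpi) / baseline
  }
  res <- data.frame(
    constant = consts,
    fold_up = vapply(consts, run_one, numeric(1), f = factor),
    fold_down = vapply(consts, run_one, numeric(1), f = 1 / factor),
    row.names = NULL)
  attr(res, "baseline_pge2") <- baseline
  attr(res, "factor") <- factor
  class(res) <- c("sensitivity_result", "data.frame")
  res
}

#' Constants flagged as sensitive
#'
#' @param x A `sensitivity_result` from [sensitivity_scan()].
#' @param threshold Flag a constant when `|fold - 1| >` threshold under
#'   either perturbation (default 0.25, i.e. a >25% move in PGE2).
#' @return Character vector of sensitive constant names.
#' @export
sensitive_constants <- function(x, threshold = 0.25) {
  stopifnot(inherits(x, "sensitivity_result"))
  hit <- abs(x$fold_up - 1) > threshold | abs(x$fold_down - 1) > threshold
  x$constant[hit]
}
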