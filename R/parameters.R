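#' Species tracked by the model
#'
#' Canonical order of the ten state variables, in µM. `c3star`, `c7star`,
#' `nfkb`, `ipla2`, `ipla2star`, `cox2_mrna`, `cox2` and `pgh2` are moles per
#' unit cell volume; `aa` and `pge2` are moles per total volume (cells plus
#' medium), reflecting that arachidonic acid and PGE2 partition into the
#' culture medium where they are measured.
#'
#' @return Character vector of the ten species names.
#' @export
species_names <- function() {
  c("c3star", "c7star", "nfkb", "ipla2", "ipla2star",
    "cox2_mrna", "cox2", "aa", "pgh2", "pge2")
}

#' Condition-independent kinetic parameters
#'
#' Constructs the full set of rate and equilibrium constants shared by all
#' simulated conditions. Defaults are the baseline values of the model:
#' caspase-catalyzed iPLA2 cleavage (`k2`/`K2` for caspase-3, `k4`/`K4` for
#' caspase-7, Michaelis-Menten), constitutive iPLA2 turnover (`k_minus5`
#' synthesis, `k5` degradation), arachidonic-acid release proportional to
#' activated iPLA2 (`k6`), Hill-type NFkB-driven COX2 transcription
#' (`k10`, `K10`, `n`), linear translation (`k12`), COX2 catalysis with
#' competitive inhibition by PGE2 and an exogenous drug (`k14`, `K14`,
#' `Ki14`, `alpha`), PGES catalysis with competitive inhibition by
#' arachidonic acid (`k16`, `K16`, `Ki16`), and first-order degradation of
#' every species (`k7`, `k8`, `k11`, `k13`, `k15`, `k17`).
#'
#' @param k2,k4 Catalytic constants for caspase-3/-7 cleavage of iPLA2
#'   (min^-1).
#' @param K2,K4 Michaelis constants of the cleavage reactions (µM).
#' @param k5 First-order iPLA2 degradation rate (min^-1).
#' @param k_minus5 Constitutive (zeroth-order) iPLA2 synthesis rate
#'   (µM/min); the steady-state iPLA2 level in resting cells is
#'   `k_minus5 / k5` = 1.5 µM.
#' @param k6 Arachidonic-acid production rate per unit activated iPLA2
#'   (min^-1).
#' @param k7,k8,k11,k13,k15,k17 First-order degradation rates of activated
#'   iPLA2, AA, COX2 mRNA, COX2, PGH2 and PGE2 (min^-1). mRNA decays at
#'   0.6 min^-1, proteins and metabolites at 0.06 min^-1.
#' @param k10 Maximal COX2 transcription rate (µM/min).
#' @param K10 NFkB concentration at half-maximal transcription (µM).
#' @param n Hill coefficient of the transcription law (dimensionless, >= 1).
#' @param k12 Translation rate per unit COX2 mRNA (min^-1).
#' @param k14 COX2 catalytic constant for AA -> PGH2 (min^-1).
#' @param K14 Michaelis constant of COX2 for AA (µM).
#' @param Ki14 Inhibition constant for competitive product inhibition of
#'   COX2 by PGE2 (µM); use `Inf` to disable the feedback.
#' @param k16 PGES catalytic constant for PGH2 -> PGE2 (min^-1).
#' @param K16 Michaelis constant of PGES for PGH2 (µM).
#' @param Ki16 Inhibition constant for competitive inhibition of PGES by AA
#'   (µM); use `Inf` to disable the feedback.
#' @param pges Constant PGES concentration (µM); PGES expression is treated
#'   as time-independent over the 48-h simulation window.
#' @param alpha Dimensionless strength of an exogenous competitive COX2
#'   inhibitor, \[drug\]/K_binding; 0 means no drug.
#' @param beta Ratio of total volume (cells + medium) to cell volume,
#'   V_t/V_c. Fluxes that cross the membrane into the medium (`v6`, `v16`)
#'   are diluted by `1/beta` in the AA and PGE2 balances.
#' @param tau Activation delay for caspase-3/7 (min): their zero-order
#'   activation switches on at `t >= tau` (24 h after irradiation).
#' @param pge2_conversion Conversion factor from µM to pg/mL for PGE2
#'   (3.525e5 pg mL^-1 per µM).
#'
#' @return An object of class `kinetic_params` (a validated named list).
#' @examples
#' kp <- kinetic_params()
#' kp$k_minus5 / kp$k5   # resting iPLA2 steady state, 1.5 µM
#' @export
kinetic_params <- function(k2 = 144, K2 = 11,
                           k4 = 26, K4 = 12,
                           k5 = 0.06, k_minus5 = 0.09,
                           k6 = 6e3,
                           k7 = 0.06, k8 = 0.06,
                           k10 = 7.68e-4, K10 = 5.2e-3, n = 2,
                           k11 = 0.6, k12 = 4.5, k13 = 0.06,
                           k14 = 1000, K14 = 50, Ki14 = 30,
                           k15 = 0.06,
                           k16 = 3000, K16 = 160, Ki16 = 0.3,
                           k17 = 0.06,
                           pges = 0.5, alpha = 0, beta = 5000,
                           tau = 1440, pge2_conversion = 3.525e5) {
  kp <- list(k2 = k2, K2 = K2, k4 = k4, K4 = K4,
             k5 = k5, k_minus5 = k_minus5, k6 = k6, k7 = k7, k8 = k8,
             k10 = k10, K10 = K10, n = n, k11 = k11, k12 = k12, k13 = k13,
             k14 = k14, K14 = K14, Ki14 = Ki14, k15 = k15,
             k16 = k16, K16 = K16, Ki16 = Ki16, k17 = k17,
             pges = pges, alpha = alpha, beta = beta, tau = tau,
             pge2_conversion = pge2_conversion)
  validate_kinetic_params(kp)
  structure(kp, class = "kinetic_params")
}

validate_kinetic_params <- function(kp) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  for (nm in names(kp)) {
    if (!num1(kp[[nm]])) stop("kinetic parameter '", nm, "' must be a single number")
    if (kp[[nm]] < 0) stop("kinetic parameter '", nm, "' must be >= 0")
  }
  strictly_pos <- c("K2", "K4", "K10", "K14", "K16", "Ki14", "Ki16",
                    "beta", "pges", "pge2_conversion")
  for (nm in strictly_pos) {
    if (kp[[nm]] <= 0) stop("kinetic parameter '", nm, "' must be > 0")
  }
  if (kp$beta <= 1) stop("'beta' is a total-to-cell volume ratio and must be > 1")
  if (kp$n < 1) stop("Hill coefficient 'n' must be >= 1")
  invisible(kp)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Condition-independent kinetic parameters (min, µM)\n")
  vals <- unlist(x)
  print(format(vals, digits = 4), quote = FALSE)
  invisible(x)
}

#' Condition-dependent model constants
#'
#' The inputs that distinguish cell line, genotype and radiation dose: the
#' resting concentrations of activated caspase-3 (`c3star0`), activated
#' caspase-7 (`c7star0`) and NFkB (`nfkb0`), and the zero-order
#' post-irradiation activation rates `k1` (caspase-3), `k3` (caspase-7) and
#' `k9` (NFkB). In unirradiated cells all three rates are zero; after
#' irradiation `k9` acts from time zero while `k1` and `k3` are gated by the
#' 24-h activation delay.
#'
#' @param cell_label Free-text label for the condition.
#' @param dose_Gy Radiation dose in Gray (0 or 10 for the shipped presets).
#' @param nfkb0 Resting NFkB concentration (µM).
#' @param c3star0,c7star0 Resting activated caspase-3/-7 concentrations (µM).
#' @param k1,k3,k9 Activation rates of caspase-3, caspase-7 and NFkB
#'   (µM/min).
#'
#' @return An object of class `condition_params`.
#' @seealso [preset_condition()] for the shipped cell-line presets.
#' @export
condition_params <- function(cell_label = "custom", dose_Gy = 0,
                             nfkb0 = 0.1, c3star0 = 0, c7star0 = 0,
                             k1 = 0, k3 = 0, k9 = 0) {
  cp <- list(cell_label = as.character(cell_label)[1], dose_Gy = dose_Gy,
             nfkb0 = nfkb0, c3star0 = c3star0, c7star0 = c7star0,
             k1 = k1, k3 = k3, k9 = k9)
  for (nm in c("dose_Gy", "nfkb0", "c3star0", "c7star0", "k1", "k3", "k9")) {
    v <- cp[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("condition parameter '", nm, "' must be a single non-negative number")
  }
  structure(cp, class = "condition_params")
}

#' @export
print.condition_params <- function(x, ...) {
  cat(sprintf("Condition: %s (%g Gy)\n", x$cell_label, x$dose_Gy))
  cat(sprintf("  [NFkB]0 = %g uM, [C3*]0 = %g uM, [C7*]0 = %g uM\n",
              x$nfkb0, x$c3star0, x$c7star0))
  cat(sprintf("  k1 = %g, k3 = %g, k9 = %g uM/min\n", x$k1, x$k3, x$k9))
  invisible(x)
}

#' Names of the shipped condition presets
#'
#' @return Character vector of preset names accepted by
#'   [preset_condition()].
#' @export
preset_names <- function() {
  c("c3ko_mef_0gy", "c3ko_mef_10gy", "mef_0gy", "mef_10gy",
    "4t1_0gy", "4t1_10gy", "c7ko_mef_10gy")
}

#' Condition presets for the modeled cell lines
#'
#' Returns the condition constants for C3-knockout MEF, wild-type MEF and
#' wild-type 4T1 cells, unirradiated (`_0gy`) or at 48 h after 10-Gy
#' radiation (`_10gy`). All presets share `nfkb0 = 0.1` µM; wild-type cells
#' carry a basal 0.2 nM of activated caspase-3; resting activated caspase-7
#' is 6.0 nM in MEF and 3.8 nM in 4T1 cells. Irradiated presets share
#' `k3 = 3.24e-6` and `k9 = 3.47e-5` µM/min, while `k1` is cell-line
#' specific (2.8e-5 MEF, 6.8e-5 4T1). The derived `c7ko_mef_10gy` preset is
#' the caspase-7 knockout of `mef_10gy`.
#'
#' @param name One of [preset_names()].
#' @return A [condition_params()] object.
#' @examples
#' preset_condition("mef_10gy")
#' @export
preset_condition <- function(name) {
  if (!is.character(name) || length(name) != 1L || !(name %in% preset_names()))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid presets: ", paste(preset_names(), collapse = ", "))
  k3_irr <- 3.24e-6
  k9_irr <- 3.47e-5
  switch(name,
    c3ko_mef_0gy = condition_params("C3 KO MEF", 0,
      nfkb0 = 0.1, c3star0 = 0, c7star0 = 6.0e-3),
    c3ko_mef_10gy = condition_params("C3 KO MEF", 10,
      nfkb0 = 0.1, c3star0 = 0, c7star0 = 6.0e-3,
      k1 = 0, k3 = k3_irr, k9 = k9_irr),
    mef_0gy = condition_params("wild-type MEF", 0,
      nfkb0 = 0.1, c3star0 = 2e-4, c7star0 = 6.0e-3),
    mef_10gy = condition_params("wild-type MEF", 10,
      nfkb0 = 0.1, c3star0 = 2e-4, c7star0 = 6.0e-3,
      k1 = 2.8e-5, k3 = k3_irr, k9 = k9_irr),
    `4t1_0gy` = condition_params("wild-type 4T1", 0,
      nfkb0 = 0.1, c3star0 = 2e-4, c7star0 = 3.8e-3),
    `4t1_10gy` = condition_params("wild-type 4T1", 10,
      nfkb0 = 0.1, c3star0 = 2e-4, c7star0 = 3.8e-3,
      k1 = 6.8e-5, k3 = k3_irr, k9 = k9_irr),
    c7ko_mef_10gy = knockout(preset_condition("mef_10gy"), "C7")
  )
}

#' Strip irradiation inputs from a condition
#'
#' Returns the matching unirradiated condition: same cell line and resting
#' concentrations, but `k1 = k3 = k9 = 0` and dose 0. Used to compute the
#' pre-irradiation steady state that initializes the radiation protocol.
#'
#' @param cp A [condition_params()] object.
#' @return A [condition_params()] object with all activation rates zero.
#' @export
unirradiated <- function(cp) {
  stopifnot(inherits(cp, "condition_params"))
  condition_params(cp$cell_label, 0,
                   nfkb0 = cp$nfkb0, c3star0 = cp$c3star0,
                   c7star0 = cp$c7star0, k1 = 0, k3 = 0, k9 = 0)
}
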