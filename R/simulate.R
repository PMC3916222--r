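#' Convert PGE2 between µM and pg/mL
#'
#' Secreted PGE2 is reported in pg/mL in the experimental literature while
#' the model works in µM; the conversion factor is 3.525e5 pg mL^-1 per µM.
#'
#' @param c Concentration in µM (or pg/mL for the inverse), non-negative.
#' @param kp [kinetic_params()] carrying the conversion factor.
#' @return Converted concentration.
#' @examples
#' pge2_to_pg_per_ml(1.1007e-3)   # ~388 pg/mL
#' pge2_from_pg_per_ml(2100)      # ~5.957e-3 µM
#' @export
pge2_to_pg_per_ml <- function(c, kp = kinetic_params()) {
  if (any(c < 0)) stop("PGE2 concentration must be non-negative")
  c * kp$pge2_conversion
}

#' @rdname pge2_to_pg_per_ml
#' @export
pge2_from_pg_per_ml <- function(c, kp = kinetic_params()) {
  if (any(c < 0)) stop("PGE2 concentration must be non-negative")
  c / kp$pge2_conversion
}

#' Run the post-irradiation protocol
#'
#' Implements the study protocol: the matching unirradiated condition
#' (same cell line, all activation rates zero) is relaxed to steady state,
#' that state initializes the irradiated system at t = 0, and the model is
#' integrated to `t_end`. NFkB production (`k9`) acts from t = 0; the
#' caspase activation rates `k1` and `k3` switch on at `t = tau` (24 h).
#' The integration is split at `tau` so the solver never steps across the
#' discontinuity.
#'
#' @param cp [condition_params()], typically an irradiated preset.
#' @param kp [kinetic_params()].
#' @param t_end End time (min), default 2880 (48 h).
#' @param grid Output time grid (min); defaults to every 10 min from 0 to
#'   `t_end`.
#' @param rtol,atol Solver tolerances (relative; absolute in µM).
#' @return A `trajectory` object: list with `times` (min), `states`
#'   (matrix, one row per time over [species_names()], µM), `condition`
#'   and `parameters`.
#' @examples
#' tr <- run_protocol(preset_condition("mef_10gy"))
#' tail(pge2_pg_per_ml(tr), 1)  # ~1801 pg/mL at 48 h
#' @export
run_protocol <- function(cp, kp = kinetic_params(), t_end = 2880,
                         grid = NULL, rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(cp, "condition_params"), inherits(kp, "kinetic_params"))
  if (t_end <= 0) stop("'t_end' must be positive")
  if (is.null(grid)) grid <- seq(0, t_end, by = min(10, t_end))
  grid <- sort(unique(c(0, grid, t_end)))
  if (any(grid < 0) || any(grid > t_end)) stop("grid must lie in [0, t_end]")

  s0 <- relax_to_steady_state(unirradiated(cp), kp)

  if (t_end <= kp$tau) {
    seg <- .integrate(s0, grid, kp, cp, heaviside = 0, rtol = rtol, atol = atol)
    states <- seg[, -1L, drop = FALSE]
  } else {
    pre <- sort(unique(c(grid[grid <= kp$tau], kp$tau)))
    post <- sort(unique(c(kp$tau, grid[grid >= kp$tau])))
    seg1 <- .integrate(s0, pre, kp, cp, heaviside = 0, rtol = rtol, atol = atol)
    y_tau <- seg1[nrow(seg1), -1L]
    seg2 <- .integrate(y_tau, post, kp, cp, heaviside = 1, rtol = rtol, atol = atol)
    keep1 <- seg1[, 1L] %in% grid & seg1[, 1L] < kp$tau
    keep2 <- seg2[, 1L] %in% grid
    states <- rbind(seg1[keep1, -1L, drop = FALSE],
                    seg2[keep2, -1L, drop = FALSE])
  }
  states[states < 0 & states > -1e-9] <- 0
  colnames(states) <- species_names()
  structure(list(times = grid, states = states, condition = cp,
                 parameters = kp),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %s (%g Gy), %d time points over [0, %g] min\n",
              x$condition$cell_label, x$condition$dose_Gy,
              length(x$times), max(x$times)))
  cat(sprintf("  final [PGE2] = %.4g uM (%.1f pg/mL)\n",
              x$states[nrow(x$states), "pge2"], tail_pge2(x)))
  invisible(x)
}

#' Trajectory accessors
#'
#' `pge2_pg_per_ml()` returns the secreted-PGE2 time course in pg/mL;
#' `tail_pge2()` its final value; `final_state()` the last state vector.
#'
#' @param traj A `trajectory` from [run_protocol()].
#' @return Numeric vector (or scalar for the `tail_`/`final_` forms).
#' @export
pge2_pg_per_ml <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  pge2_to_pg_per_ml(traj$states[, "pge2"], traj$parameters)
}

#' @rdname pge2_pg_per_ml
#' @export
tail_pge2 <- function(traj) {
  p <- pge2_pg_per_ml(traj)
  p[[length(p)]]
}

#' @rdname pge2_pg_per_ml
#' @export
final_state <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  traj$states[nrow(traj$states), ]
}

#' Coerce a trajectory to a data frame
#'
#' One row per time point: `time_min`, the ten species in µM, and a
#' companion `pge2_pg_per_ml` column (the dual-unit convention used for
#' the secreted output).
#'
#' @param x A `trajectory`.
#' @param ... Unused.
#' @return A `data.frame`.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  df <- data.frame(time_min = x$times, x$states)
  names(df)[-1L] <- paste0(species_names(), "_uM")
  df$pge2_pg_per_ml <- pge2_to_pg_per_ml(x$states[, "pge2"], x$parameters)
  df
}

#' Write / read a trajectory as CSV
#'
#' The CSV holds the [as.data.frame.trajectory()] table at full double
#' precision; `read_trajectory_csv()` restores the numeric content (the
#' condition/parameter provenance lives in the JSON writer).
#'
#' @param traj A `trajectory`.
#' @param path File path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a `data.frame`.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Write a trajectory as JSON with full provenance
#'
#' Emits the time grid, the state matrix, and an echo of the resolved
#' condition and kinetic parameters so a run can be reproduced from the
#' output file alone.
#'
#' @inheritParams write_trajectory_csv
#' @return `path`, invisibly.
#' @export
write_trajectory_json <- function(traj, path) {
  obj <- list(
    condition = unclass(traj$condition),
    parameters = unclass(traj$parameters),
    time_min = traj$times,
    states_uM = as.data.frame(traj$states),
    pge2_pg_per_ml = unname(pge2_to_pg_per_ml(traj$states[, "pge2"],
                                              traj$parameters)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
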