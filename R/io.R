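#' Load a run configuration from JSON or YAML
#'
#' A configuration selects a condition — either a `preset` name or an
#' explicit `condition` block with [condition_params()] fields — and may
#' override kinetic constants (`overrides`), the simulation horizon
#' (`t_end`, min), the output grid spacing (`grid_by`, min), solver
#' tolerances (`rtol`, `atol`), output paths (`out_csv`, `out_json`) and a
#' `seed` (reserved; the model is deterministic). Unknown keys are
#' rejected.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `run_config`: list with validated `condition`
#'   ([condition_params()]), `parameters` ([kinetic_params()]) and the run
#'   settings.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (!is.list(cfg)) stop("config must be a mapping/object")
  known <- c("preset", "condition", "overrides", "t_end", "grid_by",
             "out_csv", "out_json", "rtol", "atol", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(known, collapse = ", "))
  if (!is.null(cfg$preset) && !is.null(cfg$condition))
    stop("specify either 'preset' or 'condition', not both")
  if (is.null(cfg$preset) && is.null(cfg$condition))
    stop("config must specify 'preset' or 'condition'")

  cp <- if (!is.null(cfg$preset)) {
    preset_condition(cfg$preset)
  } else {
    do.call(condition_params, cfg$condition)
  }

  kp_args <- cfg$overrides
  if (!is.null(kp_args)) {
    bad <- setdiff(names(kp_args), names(formals(kinetic_params)))
    if (length(bad))
      stop("unknown kinetic parameter override(s): ",
           paste(bad, collapse = ", "))
  }
  kp <- do.call(kinetic_params, as.list(kp_args))

  structure(list(condition = cp, parameters = kp,
                 t_end = cfg$t_end %||% 2880,
                 grid_by = cfg$grid_by %||% 10,
                 rtol = cfg$rtol %||% 1e-8,
                 atol = cfg$atol %||% 1e-12,
                 out_csv = cfg$out_csv, out_json = cfg$out_json,
                 seed = cfg$seed),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- command-line interface ------------------------------------------------

.cli_usage <- function() {
  paste(
    "usage: phoenixsim <command> [options]",
    "",
    "commands:",
    "  simulate      --preset <name> | --config <file>  [--t-end MIN]",
    "                [--grid-by MIN] [--out-csv F] [--out-json F]",
    "  steady-state  --preset <name> | --config <file>  [--out-csv F]",
    "  scan          --param alpha|k_minus5|nfkb0 (--values a,b,c |",
    "                --log-range lo,hi,n) [--preset <name>] [--out-csv F]",
    "  sensitivity   [--preset <name>] [--factor F] [--out-csv F]",
    "  calibrate     --fit c7star0|k3 --target <pg/mL> [--preset <name>]",
    "  validate      [--out <file.json|.csv>]",
    "",
    "global: --verbose",
    sprintf("presets: %s", paste(preset_names(), collapse = ", ")),
    sep = "\n")
}

.cli_parse_opts <- function(args) {
  opts <- list(flags = character())
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (key %in% c("verbose")) {
      opts$flags <- c(opts$flags, key)
      i <- i + 1L
    } else {
      if (i == length(args)) stop("option --", key, " needs a value")
      opts[[gsub("-", "_", key)]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  opts
}

.cli_condition <- function(opts) {
  if (!is.null(opts$config)) {
    cfg <- load_config(opts$config)
    list(cp = cfg$condition, kp = cfg$parameters, cfg = cfg)
  } else {
    name <- opts$preset %||% "mef_10gy"
    list(cp = preset_condition(name), kp = kinetic_params(), cfg = NULL)
  }
}

.parse_values <- function(opts) {
  if (!is.null(opts$values)) {
    as.numeric(strsplit(opts$values, ",")[[1]])
  } else if (!is.null(opts$log_range)) {
    p <- as.numeric(strsplit(opts$log_range, ",")[[1]])
    if (length(p) != 3L || any(is.na(p)) || p[1] <= 0 || p[3] < 2)
      stop("--log-range expects lo,hi,n with lo > 0 and n >= 2")
    exp(seq(log(p[1]), log(p[2]), length.out = p[3]))
  } else stop("provide --values or --log-range")
}

#' Command-line entry point
#'
#' Thin shell interface over the package: `simulate` (radiation-protocol
#' trajectory), `steady-state`, `scan` (alpha, `k_minus5` or NFkB clamp),
#' `sensitivity`, `calibrate` (`c7star0` or `k3`) and `validate` (the
#' measured-panel report, nonzero exit on failure). Installed as
#' `exec/phoenixsim`; see `phoenixsim --help`.
#'
#' @param argv Character vector of arguments (default: the process
#'   command line).
#' @return Integer exit status, invisibly (0 on success).
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) == 0L || argv[[1]] %in% c("-h", "--help", "help")) {
      cat(.cli_usage(), "\n")
      return(invisible(0L))
    }
    cmd <- argv[[1]]
    opts <- .cli_parse_opts(argv[-1L])
    verbose <- "verbose" %in% opts$flags
    switch(cmd,
      simulate = .cli_simulate(opts, verbose),
      `steady-state` = .cli_steady_state(opts, verbose),
      scan = .cli_scan(opts, verbose),
      sensitivity = .cli_sensitivity(opts, verbose),
      calibrate = .cli_calibrate(opts, verbose),
      validate = .cli_validate(opts, verbose),
      stop("unknown command '", cmd, "'\n", .cli_usage()))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.cli_simulate <- function(opts, verbose) {
  x <- .cli_condition(opts)
  t_end <- as.numeric(opts$t_end %||% (x$cfg$t_end %||% 2880))
  grid_by <- as.numeric(opts$grid_by %||% (x$cfg$grid_by %||% 10))
  tr <- run_protocol(x$cp, x$kp, t_end = t_end,
                     grid = seq(0, t_end, by = grid_by))
  if (verbose)
    message(sprintf("integrated %d output points over [0, %g] min",
                    length(tr$times), t_end))
  out_csv <- opts$out_csv %||% x$cfg$out_csv
  out_json <- opts$out_json %||% x$cfg$out_json
  if (!is.null(out_csv)) write_trajectory_csv(tr, out_csv)
  if (!is.null(out_json)) write_trajectory_json(tr, out_json)
  print(tr)
}

.cli_steady_state <- function(opts, verbose) {
  x <- .cli_condition(opts)
  cp <- unirradiated(x$cp)
  ss <- relax_to_steady_state(cp, x$kp)
  df <- data.frame(species = species_names(), concentration_uM = unname(ss))
  print(df)
  cat(sprintf("PGE2: %.1f pg/mL\n", pge2_to_pg_per_ml(ss[["pge2"]], x$kp)))
  if (!is.null(opts$out_csv))
    utils::write.csv(df, opts$out_csv, row.names = FALSE, quote = FALSE)
}

.cli_scan <- function(opts, verbose) {
  x <- .cli_condition(opts)
  values <- .parse_values(opts)
  param <- opts$param %||% stop("scan needs --param")
  res <- switch(param,
    alpha = cox2_inhibition_scan(values, x$cp, x$kp),
    k_minus5 = ipla2_silencing_scan(values, x$cp, x$kp),
    nfkb0 = nfkb_clamp_scan(values, unirradiated(x$cp), x$kp),
    stop("unknown scan parameter '", param,
         "'; choose alpha, k_minus5 or nfkb0"))
  print(res)
  if (!is.null(opts$out_csv)) write_scan_csv(res, opts$out_csv)
  if (!is.null(opts$out_json)) write_scan_json(res, opts$out_json)
}

.cli_sensitivity <- function(opts, verbose) {
  x <- .cli_condition(opts)
  res <- sensitivity_scan(x$kp, x$cp, factor = as.numeric(opts$factor %||% 2))
  print(as.data.frame(res))
  cat("sensitive constants: ",
      paste(sensitive_constants(res), collapse = ", "), "\n")
  if (!is.null(opts$out_csv))
    utils::write.csv(as.data.frame(res), opts$out_csv,
                     row.names = FALSE, quote = FALSE)
}

.cli_calibrate <- function(opts, verbose) {
  target <- as.numeric(opts$target %||% stop("calibrate needs --target"))
  fit <- opts$fit %||% stop("calibrate needs --fit c7star0|k3")
  if (fit == "c7star0") {
    cp <- preset_condition(opts$preset %||% "c3ko_mef_0gy")
    val <- fit_c7star0(target, cp)
    cat(sprintf("fitted c7star0 = %.4g nM\n", val))
  } else if (fit == "k3") {
    cp <- preset_condition(opts$preset %||% "c3ko_mef_10gy")
    val <- fit_k3(target, cp)
    cat(sprintf("fitted k3 = %.4g uM/min\n", val))
  } else stop("--fit must be c7star0 or k3")
}

.cli_validate <- function(opts, verbose) {
  rep <- validate_against_table1()
  print(rep)
  if (!is.null(opts$out)) write_validation_report(rep, opts$out)
  if (!rep$pass) stop("validation failed: max relative difference ",
                      sprintf("%.2f%%", rep$max_rel_diff_pct))
}
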