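#' Load a run configuration
#'
#' Reads the package's single configuration dialect: a flat YAML mapping of
#' documented keys to values. Recognised keys are the [wnt_params()] fields
#' (e.g. `k1`, `p3`, `t_max`), the [wnt_scenario()] fields
#' (`feedback_multiplier`, `initial_receptor_multiplier`, `ligand_multiplier`,
#' `sfrp1_enabled`, `hs_enabled`, `dnfzd7_condition`), the grid / solver
#' settings `n_cells`, `n_time_samples`, `rtol`, `atol`, and the run keys
#' `experiment` and `output_dir`. Parsing is strict: an unknown key, a
#' non-numeric value for a numeric key, or a parameter-invariant violation is
#' a configuration error naming the offending key. An empty file yields the
#' model's reference parameterisation unchanged.
#'
#' @param path path to the YAML configuration file.
#' @return Object of class `wnt_config`: list with `params`, `scenario`,
#'   `n_cells`, `n_time_samples`, `rtol`, `atol`, `experiment`, `output_dir`
#'   and `resolved` (every effective key-value pair, defaults included, for
#'   provenance).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping of key: value pairs")

  param_keys <- names(formals(wnt_params))
  param_keys <- setdiff(param_keys, c("k5", "k6"))  # values default to k1
  param_keys <- c(param_keys, "k5", "k6")
  scen_keys <- names(formals(wnt_scenario))
  run_keys <- c("n_cells", "n_time_samples", "rtol", "atol",
                "experiment", "output_dir")
  unknown <- setdiff(names(raw), c(param_keys, scen_keys, run_keys))
  if (length(unknown))
    stop("unknown configuration key: ", paste(unknown, collapse = ", "))
  if (is.null(names(raw)) && length(raw))
    stop("config must be a YAML mapping of key: value pairs")

  num_key <- function(key, default) {
    v <- if (key %in% names(raw)) raw[[key]] else default
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("configuration key '", key, "' must be a single finite number")
    v
  }
  pargs <- raw[intersect(names(raw), param_keys)]
  for (k in names(pargs)) {
    if (!is.numeric(pargs[[k]]) || length(pargs[[k]]) != 1)
      stop("configuration key '", k, "' must be a single number")
    pargs[[k]] <- as.numeric(pargs[[k]])
  }
  params <- tryCatch(do.call(wnt_params, pargs),
                     error = function(e)
                       stop("invalid parameter configuration: ",
                            conditionMessage(e)))
  sargs <- raw[intersect(names(raw), scen_keys)]
  sargs <- lapply(sargs, function(v) if (is.numeric(v)) as.numeric(v) else v)
  scenario <- tryCatch(do.call(wnt_scenario, sargs),
                       error = function(e)
                         stop("invalid scenario configuration: ",
                              conditionMessage(e)))
  experiment <- if ("experiment" %in% names(raw)) raw$experiment else "simulate"
  known_exp <- c("simulate", "feedback-sweep", "robustness", "dnfzd7",
                 "sfrp1-hs", "fixtures-check")
  if (!is.character(experiment) || length(experiment) != 1 ||
      !experiment %in% known_exp)
    stop("configuration key 'experiment' must be one of: ",
         paste(known_exp, collapse = ", "))
  cfg <- list(params = params, scenario = scenario,
              n_cells = as.integer(num_key("n_cells", 200)),
              n_time_samples = as.integer(num_key("n_time_samples", 101)),
              rtol = num_key("rtol", 1e-6), atol = num_key("atol", 1e-9),
              experiment = experiment,
              output_dir = if ("output_dir" %in% names(raw))
                raw$output_dir else "wntgrad-output")
  cfg$resolved <- c(unclass(params), unclass(scenario),
                    cfg[c("n_cells", "n_time_samples", "rtol", "atol",
                          "experiment", "output_dir")])
  class(cfg) <- "wnt_config"
  cfg
}

fmt_full <- function(x) sprintf("%.17g", x)

provenance_list <- function(traj_or_cfg, extra = list()) {
  c(extra, list(package = "wntgrad",
                package_version = as.character(utils::packageVersion("wntgrad")),
                r_version = R.version.string))
}

#' Write a trajectory to delimited text files
#'
#' Writes three files into `path`: `profiles.csv`, a long-format table with
#' columns `time_s`, `x_um`, `species`, `concentration_nM` covering all 14
#' state components at every saved time and cell; `kymograph.csv`, the omega
#' space-time matrix (first column `time_s`, remaining columns the cell-centre
#' positions); and `provenance.yml` recording every parameter, scenario
#' switch, grid and solver setting used, so the run can be regenerated
#' exactly. Numeric values are written with 17 significant digits and
#' round-trip losslessly.
#'
#' @param traj a `wnt_trajectory`.
#' @param path output directory (created if missing).
#' @return Invisibly, the paths of the files written.
#' @export
write_profiles <- function(traj, path) {
  stopifnot(inherits(traj, "wnt_trajectory"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path)
  g <- traj$grid
  nt <- length(traj$times); nc <- g$n_cells
  species <- wnt_species()

  prof_path <- file.path(path, "profiles.csv")
  con <- file(prof_path, "w")
  writeLines("time_s,x_um,species,concentration_nM", con)
  for (i in seq_len(nt)) {
    M <- traj$states[i, , , drop = FALSE]
    lines <- paste(fmt_full(traj$times[i]),
                   rep(fmt_full(g$cell_centers), times = N_SPECIES),
                   rep(species, each = nc),
                   fmt_full(as.vector(M)), sep = ",")
    writeLines(lines, con)
  }
  close(con)

  kymo_path <- file.path(path, "kymograph.csv")
  K <- traj$states[, , "omega", drop = TRUE]
  header <- paste(c("time_s", fmt_full(g$cell_centers)), collapse = ",")
  rows <- vapply(seq_len(nt), function(i)
    paste(c(fmt_full(traj$times[i]), fmt_full(K[i, ])), collapse = ","),
    character(1))
  writeLines(c(header, rows), kymo_path)

  prov_path <- file.path(path, "provenance.yml")
  prov <- provenance_list(extra = list(
    params = unclass(traj$params),
    scenario = unclass(traj$scenario),
    grid = list(n_cells = g$n_cells, x_max = g$x_max,
                cell_width = g$cell_width),
    solver = traj$diagnostics))
  yaml::write_yaml(prov, prov_path)
  invisible(c(profiles = prof_path, kymograph = kymo_path,
              provenance = prov_path))
}

write_experiment <- function(exp, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (nm in names(exp$tables)) {
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(exp$tables[[nm]], f, row.names = FALSE)
    written <- c(written, f)
  }
  prov <- provenance_list(extra = list(
    experiment = exp$name,
    params = unclass(exp$provenance$params),
    grid = list(n_cells = exp$provenance$grid$n_cells,
                x_max = exp$provenance$grid$x_max),
    solver = exp$provenance$solver,
    scenarios = lapply(exp$runs, function(r) unclass(r$scenario))))
  pf <- file.path(path, "provenance.yml")
  yaml::write_yaml(prov, pf)
  invisible(c(written, pf))
}

#' Command-line entry point
#'
#' Dispatches the package's experiments from a character vector of arguments
#' (`simulate`, `feedback-sweep`, `robustness`, `dnfzd7`, `sfrp1-hs`,
#' `fixtures-check`), with options `--config <path>` and `--out <dir>`
#' (overriding the config's `output_dir`). A thin Rscript wrapper is
#' installed at `system.file("scripts", "wntgrad", package = "wntgrad")`.
#'
#' @param argv character vector of command-line arguments.
#' @return Exit status, invisibly: 0 on success, non-zero on usage or
#'   invariant errors.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: wntgrad <subcommand> [--config <path>] [--out <dir>]",
    "  subcommands: simulate | feedback-sweep | robustness | dnfzd7 |",
    "               sfrp1-hs | fixtures-check", sep = "\n")
  fail <- function(...) { message(...); invisible(1L) }
  if (length(argv) < 1) return(fail(usage))
  sub <- argv[1]
  known <- c("simulate", "feedback-sweep", "robustness", "dnfzd7",
             "sfrp1-hs", "fixtures-check")
  if (!sub %in% known) return(fail("unknown subcommand: ", sub, "\n", usage))
  opts <- argv[-1]
  get_opt <- function(flag) {
    i <- which(opts == flag)
    if (length(i) == 0) return(NULL)
    if (length(i) > 1 || i[length(i)] == length(opts)) stop("bad usage: ", flag)
    opts[i + 1]
  }
  status <- tryCatch({
    cfgp <- get_opt("--config")
    cfg <- if (is.null(cfgp)) {
      list(params = wnt_params(), scenario = wnt_scenario(), n_cells = 200L,
           n_time_samples = 101L, rtol = 1e-6, atol = 1e-9,
           output_dir = "wntgrad-output")
    } else load_config(cfgp)
    outdir <- get_opt("--out")
    if (is.null(outdir)) outdir <- cfg$output_dir
    grid <- discretize_domain(cfg$params$x_max, cfg$n_cells)

    if (sub == "fixtures-check") {
      ok <- TRUE
      for (f in make_fixture_scenarios()) {
        tr <- simulate_fixture(f)
        mb <- mass_balance_report(tr)
        worst <- max(mb$wnt_resid_rel, mb$fzd_resid_rel, mb$dnfzd7_resid_rel)
        hs <- max(mb$hs_max_dev_rel)
        mono <- all(apply(tr$states[, , "omega", drop = TRUE], 2,
                          function(v) all(diff(v) >= -1e-12)))
        pass <- worst < 1e-4 && hs < 1e-6 && mono
        ok <- ok && pass
        message(sprintf("%-18s balance %.3g  HS %.3g  omega-monotone %s  [%s]",
                        f$name, worst, hs, mono,
                        if (pass) "ok" else "FAIL"))
      }
      return(invisible(if (ok) 0L else 1L))
    }

    if (sub == "simulate") {
      tr <- simulate_trajectory(cfg$scenario, cfg$params, grid,
                                n_time_samples = cfg$n_time_samples,
                                rtol = cfg$rtol, atol = cfg$atol)
      write_profiles(tr, outdir)
      message("trajectory written to ", outdir)
      return(invisible(0L))
    }

    exp <- switch(sub,
      "feedback-sweep" = run_feedback_sweep(
        cfg$params, grid, base_scenario = cfg$scenario,
        n_time_samples = cfg$n_time_samples, rtol = cfg$rtol, atol = cfg$atol),
      "robustness" = run_robustness_experiment(
        cfg$params, grid, base_scenario = cfg$scenario,
        n_time_samples = cfg$n_time_samples, rtol = cfg$rtol, atol = cfg$atol),
      "dnfzd7" = run_dnfzd7_experiment(
        cfg$params, grid, base_scenario = cfg$scenario,
        n_time_samples = cfg$n_time_samples, rtol = cfg$rtol, atol = cfg$atol),
      "sfrp1-hs" = run_sfrp1_hs_experiment(
        cfg$params, grid, base_scenario = cfg$scenario,
        n_time_samples = cfg$n_time_samples, rtol = cfg$rtol, atol = cfg$atol))
    write_experiment(exp, outdir)
    message(exp$name, " results written to ", outdir)
    invisible(0L)
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    invisible(1L)
  })
  status
}
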