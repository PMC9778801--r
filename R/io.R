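#' Read and validate a run configuration
#'
#' A run configuration is a YAML file resolving to exactly one parameter set
#' and one experiment. Recognized top-level keys: \code{label} (catalog
#' variant name), \code{overrides} (map of rate-constant overrides applied
#' to the basal set; combined with \code{label} they apply on top of the
#' catalog variant), \code{environment} (map with any of fum, suc, O2,
#' Hplus, E_out), \code{experiment} (map: \code{type} = simulate | sweep |
#' ros | titrate, plus grid fields), \code{seed}, \code{tol_scale},
#' \code{method}. Unknown keys, unknown override names and non-positive
#' pool totals are rejected with the offending field named.
#'
#' @param path YAML file path.
#' @return A list of class \code{"sdh_config"} with elements \code{ps},
#'   \code{env}, \code{experiment}, \code{seed}, \code{method},
#'   \code{tol_scale}, \code{source}.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_run_config(raw, source = path)
}

#' Build a run configuration from a list
#'
#' @param raw Named list with the same structure as the YAML file accepted
#'   by [read_run_config()].
#' @param source Provenance string stored on the result.
#' @return A validated \code{"sdh_config"} object.
#' @export
as_run_config <- function(raw, source = "<list>") {
  known <- c("label", "overrides", "environment", "experiment", "seed",
             "tol_scale", "method")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown configuration key: '", extra[1L], "'", call. = FALSE)
  base <- build_base_parameters()
  ps <- if (!is.null(raw$label) && raw$label != "basal")
    variant_parameters(raw$label, base) else base
  if (!is.null(raw$overrides) && length(raw$overrides))
    ps <- make_variant(ps, raw$overrides,
                       label = if (!is.null(raw$label)) raw$label else NULL)
  env_known <- c("fum", "suc", "O2", "Hplus", "E_out")
  env_args <- raw$environment
  extra <- setdiff(names(env_args), env_known)
  if (length(extra))
    stop("unknown environment key: 'environment.", extra[1L], "'",
         call. = FALSE)
  env <- do.call(sdh_env, if (is.null(env_args)) list() else env_args)
  ex <- raw$experiment
  if (is.null(ex)) ex <- list(type = "simulate")
  if (is.null(ex$type) ||
      !ex$type %in% c("simulate", "sweep", "ros", "titrate"))
    stop("'experiment.type' must be simulate, sweep, ros or titrate",
         call. = FALSE)
  structure(list(ps = ps, env = env, experiment = ex,
                 seed = if (is.null(raw$seed)) 0L else as.integer(raw$seed),
                 method = if (is.null(raw$method)) "integration"
                          else raw$method,
                 tol_scale = if (is.null(raw$tol_scale)) 1e-9
                             else as.numeric(raw$tol_scale),
                 source = source),
            class = "sdh_config")
}

.config_grid <- function(ex, default_from = 100, default_to = -400,
                         default_by = -2) {
  g <- ex$grid
  if (is.null(g)) return(seq(default_from, default_to, by = default_by))
  if (is.list(g))
    return(seq(g$from, g$to, by = if (is.null(g$by)) default_by else g$by))
  as.numeric(g)
}

#' Run the experiment described by a configuration
#'
#' Dispatches on \code{experiment.type}: \code{simulate} solves a single
#' steady state, \code{sweep} and \code{ros} run an electrode-potential
#' sweep, \code{titrate} a fumarate titration. Randomness (used only for
#' crosscheck initializations, if requested) is seeded from the
#' configuration for full determinism.
#'
#' @param config An \code{"sdh_config"} from [read_run_config()].
#' @return For \code{simulate}, a one-row sweep-format data.frame;
#'   otherwise the experiment's tidy table.
#' @export
run_config <- function(config) {
  stopifnot(inherits(config, "sdh_config"))
  set.seed(config$seed)
  ex <- config$experiment
  switch(ex$type,
    simulate = {
      ss <- steady_state(config$ps, config$env, method = config$method,
                         tol_scale = config$tol_scale)
      .sweep_row(ss, config$ps, c(E_out = config$env$E_out))
    },
    sweep = eout_sweep(config$ps, config$env, .config_grid(ex),
                       method = config$method),
    ros = ros_scan(config$ps, config$env,
                   .config_grid(ex, default_from = 0),
                   method = config$method),
    titrate = fumarate_titration(
      config$ps,
      fum_grid = if (is.null(ex$fum_grid)) 10^seq(0, 4, by = 0.25)
                 else as.numeric(ex$fum_grid),
      E_out_set = if (is.null(ex$E_out_set)) c(0, -50, -100, -150, -200)
                  else as.numeric(ex$E_out_set),
      suc = config$env$suc, env_template = config$env,
      method = config$method))
}

# Order-independent parameter fingerprint for provenance lines.
.param_hash <- function(ps) {
  v <- c(unlist(ps$k), unlist(ps$kr), unlist(ps$Keq), unlist(ps$pools),
         ps$Vmax21, ps$Km21, ps$k22, ps$constants$vT, ps$constants$alpha)
  bytes <- serialize(round(v, 12), NULL)
  sprintf("%08x", sum(as.integer(bytes) * seq_along(bytes)) %% 2^31)
}

#' Run a configuration and write its result table with provenance
#'
#' Writes the experiment table as CSV (full double precision) preceded by
#' comment lines recording the package version, variant label, parameter
#' fingerprint, seed, thermal voltage and the four detailed-balance cycle
#' products, making the run auditable and reproducible.
#'
#' @param config An \code{"sdh_config"}.
#' @param file Output file path.
#' @return Invisibly the result data.frame.
#' @export
cli_simulate <- function(config, file) {
  res <- run_config(config)
  con <- file(file, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("sdhrev"))
  writeLines(c(
    sprintf("# sdhrev %s", ver),
    sprintf("# label: %s", config$ps$label),
    sprintf("# parameter_hash: %s", .param_hash(config$ps)),
    sprintf("# seed: %d", config$seed),
    sprintf("# thermal_voltage_mV: %g", config$ps$constants$vT),
    sprintf("# cycle_products: %s",
            paste(sprintf("%.15g", cycle_products(config$ps)),
                  collapse = " "))), con)
  df <- res
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(res)
}

#' Generate the figure-variant configuration fixtures
#'
#' Writes one YAML run configuration per captioned figure curve (electrode
#' sweeps, ROS scans, fumarate titrations) plus the basal set, and a
#' \code{catalog.csv} manifest mapping figure/panel/curve to variant label
#' and parameter overrides. Every emitted configuration is validated for
#' detailed-balance consistency before writing.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly the catalog data.frame with a \code{file} column.
#' @export
generate_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cat <- variant_catalog()
  base <- build_base_parameters()
  files <- character(nrow(cat))
  for (i in seq_len(nrow(cat))) {
    ov <- .parse_overrides(cat$overrides[i])
    ps <- make_variant(base, ov, label = cat$label[i])
    validate_parameters(ps)
    cfg <- list(label = cat$label[i],
                overrides = if (length(ov)) ov else NULL,
                environment = list(fum = 1000, suc = 50, O2 = 240,
                                   Hplus = 1, E_out = 0),
                experiment = switch(cat$experiment[i],
                  sweep = list(type = "sweep",
                               grid = list(from = 100, to = -400, by = -2)),
                  ros = list(type = "ros",
                             grid = list(from = 0, to = -400, by = -2)),
                  titrate = list(type = "titrate",
                                 E_out_set = c(0, -50, -100, -150, -200))),
                seed = 0L)
    cfg <- Filter(Negate(is.null), cfg)
    f <- file.path(dir, paste0(cat$label[i], ".yaml"))
    yaml::write_yaml(cfg, f)
    files[i] <- f
  }
  cat$file <- files
  utils::write.csv(cat, file.path(dir, "catalog.csv"), row.names = FALSE)
  invisible(cat)
}
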