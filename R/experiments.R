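# Assemble one tidy sweep row from a converged steady state.
.sweep_row <- function(ss, ps, swept = c(E_out = NA_real_)) {
  comp <- complement_species(ss$state, ps)
  spec <- flux_to_specific_rate(ss$rates$VH2O2, ps$constants)
  out <- c(list(label = ps$label), as.list(swept),
           as.list(ss$state), as.list(comp),
           as.list(ss$rates$V),
           list(V_rev_tot = ss$rates$V_rev_tot,
                V_suc_tot = ss$rates$V_suc_tot,
                VH2O2 = ss$rates$VH2O2,
                VH2O2_specific = spec,
                converged = ss$converged,
                residual_norm = ss$residual_norm))
  as.data.frame(out, stringsAsFactors = FALSE)
}

.as_variant_list <- function(ps_variants) {
  if (inherits(ps_variants, "sdh_params")) list(ps_variants) else ps_variants
}

#' Electrode-potential sweep
#'
#' Computes one steady state per (parameter variant, E_out) pair and returns
#' a tidy table: all 13 species, the 4 conserved complements, the 22 reaction
#' rates, the aggregate fluxes (total reverse electron transfer
#' \code{V_rev_tot}, total succinate release \code{V_suc_tot}, total H2O2
#' production \code{VH2O2} in uM/s and pmol/min/mg), and per-row convergence
#' diagnostics. Each grid point is solved independently from the fully
#' oxidized default initial condition (no continuation), so any
#' initial-condition dependence shows up in the crosscheck rather than being
#' imported from neighboring grid points. Rows that fail to converge are
#' flagged, not fatal.
#'
#' @param ps_variants A single \code{sdh_params} object or a list of them.
#' @param env_template An [sdh_env()] giving the clamped concentrations
#'   (default fum = 1000 uM, suc = 50 uM); its \code{E_out} is ignored.
#' @param grid Numeric vector of E_out values, mV (at least 2; default
#'   +100 to -400 mV in 2 mV steps).
#' @param method Steady-state method passed to [steady_state()].
#' @return A data.frame, one row per (variant, E_out).
#' @export
eout_sweep <- function(ps_variants, env_template = sdh_env(),
                       grid = seq(100, -400, by = -2),
                       method = "integration") {
  ps_variants <- .as_variant_list(ps_variants)
  if (length(grid) < 1L) stop("empty E_out grid", call. = FALSE)
  rows <- vector("list", length(ps_variants) * length(grid))
  i <- 0L
  for (ps in ps_variants) {
    validate_parameters(ps)
    for (E in grid) {
      env <- env_template
      env$E_out <- E
      ss <- suppressWarnings(steady_state(ps, env, method = method))
      i <- i + 1L
      rows[[i]] <- .sweep_row(ss, ps, c(E_out = E))
    }
  }
  do.call(rbind, rows)
}

#' Detect the threshold potential of a flux curve
#'
#' The threshold is operationalized as the electrode potential of the
#' interior maximum of a steady-state flux curve, refined by a quadratic fit
#' through the three bracketing grid points. A monotone curve (maximum on
#' the grid boundary) yields no threshold. Grid spacing is reported as the
#' location uncertainty. Unconverged rows inside the bracket mark the result
#' unreliable.
#'
#' @param sweep A sweep table from [eout_sweep()], one or more variants.
#' @param flux_column Column to maximize (default \code{"V_rev_tot"}).
#' @return A data.frame with one row per variant label: \code{E_threshold}
#'   (mV, \code{NA} when none), \code{peak_rate}, \code{grid_spacing},
#'   \code{reliable}.
#' @export
threshold_detect <- function(sweep, flux_column = "V_rev_tot") {
  stopifnot(flux_column %in% names(sweep))
  out <- lapply(split(sweep, sweep$label), function(d) {
    d <- d[order(-d$E_out), ]   # sweep direction: decreasing E_out
    y <- d[[flux_column]]
    E <- d$E_out
    n <- length(y)
    i <- which.max(y)
    spacing <- if (n > 1L) max(abs(diff(E))) else NA_real_
    if (n < 3L || i == 1L || i == n) {
      return(data.frame(label = d$label[1L], E_threshold = NA_real_,
                        peak_rate = y[i], grid_spacing = spacing,
                        reliable = all(d$converged)))
    }
    idx <- (i - 1L):(i + 1L)
    fit <- stats::lm(y[idx] ~ E[idx] + I(E[idx]^2))
    b <- stats::coef(fit)
    E_star <- if (is.finite(b[3L]) && b[3L] < 0) -b[2L] / (2 * b[3L]) else E[i]
    # keep the refinement inside the bracket
    E_star <- min(max(E_star, min(E[idx])), max(E[idx]))
    peak <- sum(b * c(1, E_star, E_star^2))
    data.frame(label = d$label[1L], E_threshold = unname(E_star),
               peak_rate = unname(peak), grid_spacing = spacing,
               reliable = all(d$converged[idx]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Succinate-flux decomposition
#'
#' Extracts the three free-succinate release channels from a sweep: release
#' from the oxidized complex (V8), from the flavin-semiquinone complex
#' (V14), and from the fully reduced complex (V16), together with their sum
#' \code{V_suc_tot}.
#'
#' @param sweep A sweep table from [eout_sweep()] or [fumarate_titration()].
#' @return A data.frame with the identifying columns plus V8, V14, V16,
#'   V_suc_tot.
#' @export
flux_decomposition <- function(sweep) {
  keep <- intersect(c("label", "E_out", "fum"), names(sweep))
  out <- sweep[, c(keep, "V8", "V14", "V16", "V_suc_tot")]
  rownames(out) <- NULL
  out
}

#' ROS production scan over electrode potential
#'
#' An electrode-potential sweep focused on hydrogen-peroxide output: the
#' total H2O2 production rate \code{VH2O2 = V17 + V21} (flavin-mediated plus
#' superoxide dismutation), which at steady state equals the matrix efflux
#' V22, is reported both in uM/s and as a protein-specific rate
#' (pmol/min/mg, factor 220). O2 is clamped at the value in
#' \code{env_template} (default 240 uM).
#'
#' @inheritParams eout_sweep
#' @return A sweep data.frame (same layout as [eout_sweep()]).
#' @export
ros_scan <- function(ps_variants, env_template = sdh_env(),
                     grid = seq(0, -400, by = -2), method = "integration") {
  eout_sweep(ps_variants, env_template, grid, method)
}

#' Fumarate titration of succinate production
#'
#' Steady-state succinate production versus fumarate concentration at fixed
#' succinate and a set of electrode potentials, one curve per (variant,
#' E_out).
#'
#' @param ps_variants A single \code{sdh_params} or a list.
#' @param fum_grid Fumarate concentrations, uM (spanning >= 2 decades for
#'   the saturation behavior to show).
#' @param E_out_set Electrode potentials, mV.
#' @param suc Clamped succinate concentration, uM.
#' @param env_template Base environment (fum and E_out overridden).
#' @param method Steady-state method.
#' @return A data.frame, one row per (variant, E_out, fum).
#' @export
fumarate_titration <- function(ps_variants,
                               fum_grid = 10^seq(0, 4, by = 0.25),
                               E_out_set = c(0, -50, -100, -150, -200),
                               suc = 50, env_template = sdh_env(),
                               method = "integration") {
  ps_variants <- .as_variant_list(ps_variants)
  rows <- list()
  for (ps in ps_variants) {
    validate_parameters(ps)
    for (E in E_out_set) {
      for (fm in fum_grid) {
        env <- env_template
        env$suc <- suc
        env$fum <- fm
        env$E_out <- E
        ss <- suppressWarnings(steady_state(ps, env, method = method))
        rows[[length(rows) + 1L]] <-
          .sweep_row(ss, ps, c(E_out = E, fum = fm))
      }
    }
  }
  do.call(rbind, rows)
}

#' Redox-state profile of the ROS-producing centers
#'
#' Extracts from a sweep the concentrations of the proposed ROS-generating
#' redox centers: flavin semiquinone (FADH), fully reduced flavin (FADH2),
#' and the \[3Fe-4S\] and \[2Fe-2S\] clusters in the reduced state, together
#' with the oxidized cluster complements. All concentrations are bounded by
#' the pool totals.
#'
#' @param sweep A sweep table from [eout_sweep()].
#' @return A data.frame keyed like the sweep.
#' @export
redox_profile <- function(sweep) {
  keep <- intersect(c("label", "E_out", "fum"), names(sweep))
  out <- sweep[, c(keep, "FADH", "FADH2", "Fe3S4red", "Fe2S2red",
                   "Fe3S4ox", "Fe2S2ox")]
  rownames(out) <- NULL
  out
}

#' Write a sweep table to CSV at full double precision
#'
#' @param sweep A sweep data.frame.
#' @param file Output path.
#' @return Invisibly \code{file}.
#' @export
write_sweep <- function(sweep, file) {
  df <- sweep
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
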