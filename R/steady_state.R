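# Residual criterion: max |dy/dt| below tol_scale * max(pool totals, 1) uM/s,
# floored at what double precision can resolve. Each species is represented
# to machine epsilon of its moiety pool (the oxidized complements are
# differences against the pool total), and those representation errors
# propagate through the rate sensitivities: near full reduction the backward
# term of the relay reactions amplifies an eps*pool error by ~1e12/s. A
# species is therefore also accepted as stationary when its residual is
# below a few times |S| |dV/dy| s_eps, the first-order noise bound of the
# residual evaluation itself.
.residual_tol <- function(ps, tol_scale = 1e-9) {
  tol_scale * max(max(ps$pools), 1)
}

.residual_norm <- function(state, env, ps) {
  max(abs(ode_rhs(state, env, ps, check = FALSE)))
}

.noise_floor <- function(y, env, ps) {
  s_eps <- .Machine$double.eps *
    pmax(abs(y), c(ps$pools[c(1L, 2L, 3L)], rep(ps$pools[[4L]], 8L), 0, 0))
  amp <- abs(.rates_jac(y, env, ps)) %*% s_eps
  4 * drop(.stoich_abs %*% amp)
}

.is_stationary <- function(state, env, ps, tol) {
  y <- unname(state[.species])
  dy <- abs(.rhs_from_rates(.rates_raw(y, env, ps)))
  ok <- all(dy < pmax(tol, .noise_floor(y, env, ps)))
  list(residual = max(dy), converged = ok)
}

# Stiff integration to steady state. Integrates from `init` over decade-wise
# extended spans until the residual criterion holds or t_max is exhausted.
.ss_integrate <- function(ps, env, init, tol, t_final = 1e6, t_max = 1e8,
                          rtol = 1e-10, atol = 1e-12) {
  parms <- list(env = env, ps = ps)
  y <- unname(init[.species])
  t_end <- t_final
  t0 <- 0
  repeat {
    sol <- suppressWarnings(
      deSolve::lsoda(y, times = c(t0, t_end), func = .desolve_func,
                     jacfunc = .desolve_jac, jactype = "fullusr",
                     parms = parms, rtol = rtol, atol = atol,
                     maxsteps = 1e5))
    y <- unname(sol[nrow(sol), -1L])
    st <- stats::setNames(pmax(y, 0), .species)
    chk <- if (is.finite(tol)) .is_stationary(st, env, ps, tol)
           else list(residual = .residual_norm(st, env, ps), converged = FALSE)
    if (chk$converged || t_end >= t_max)
      return(list(state = st, residual = chk$residual,
                  converged = chk$converged, t_end = t_end))
    t0 <- t_end
    t_end <- t_end * 10
  }
}

# Damped Newton on the reduced 13-species system, analytic Jacobian.
.newton_once <- function(ps, env, init, tol, maxit = 60L) {
  f <- function(y) {
    .rhs_from_rates(.rates_raw(y, env, ps))
  }
  y <- unname(init[.species])
  fy <- f(y)
  ny <- max(abs(fy))
  for (it in seq_len(maxit)) {
    if (all(abs(fy) < pmax(tol, .noise_floor(y, env, ps))))
      return(list(state = stats::setNames(pmax(y, 0), .species),
                  residual = ny, converged = TRUE, iterations = it - 1L))
    J <- .rhs_jac(y, env, ps)
    delta <- tryCatch(solve(J, -fy), error = function(e) NULL)
    if (is.null(delta)) break
    # damping: backtrack until the residual decreases and the state (with
    # its conserved complements) stays near-feasible
    lambda <- 1
    ok <- FALSE
    while (lambda >= 1e-8) {
      ytry <- y + lambda * delta
      comp_ok <- all(ytry > -1e-6 * max(ps$pools)) &&
        complement_species(stats::setNames(ytry, .species), ps)[["FAD"]] >
          -1e-6 * max(ps$pools)
      if (comp_ok) {
        ftry <- f(ytry)
        ntry <- max(abs(ftry))
        if (is.finite(ntry) && ntry < ny * (1 - 0.25 * lambda) ||
            (is.finite(ntry) && ntry < tol)) {
          y <- ytry; fy <- ftry; ny <- ntry; ok <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!ok) break
  }
  conv <- all(abs(fy) < pmax(tol, .noise_floor(y, env, ps)))
  list(state = stats::setNames(pmax(y, 0), .species), residual = ny,
       converged = conv, iterations = maxit)
}

.ss_rootfind <- function(ps, env, init, tol) {
  # start cascade: the detailed-balance equilibrium construction (ROS
  # species zeroed to avoid the astronomically large equilibrium peroxide
  # level) is the best-conditioned guess and exact at the zero-current
  # potential; then the supplied initial state, then short integration
  # bursts of increasing length
  starts <- list(init)
  eq <- tryCatch(equilibrium_state(ps, env), error = function(e) NULL)
  if (!is.null(eq)) {
    eq[["O2sup"]] <- 0; eq[["H2O2"]] <- 0
    starts <- c(list(eq), starts)
  }
  for (tb in c(1, 100)) {
    burst <- tryCatch(
      .ss_integrate(ps, env, init, tol = Inf, t_final = tb, t_max = tb)$state,
      error = function(e) NULL)
    if (!is.null(burst)) starts <- c(starts, list(burst))
  }
  best <- NULL
  for (s in starts) {
    res <- .newton_once(ps, env, s, tol)
    if (res$converged) return(res)
    if (is.null(best) || res$residual < best$residual) best <- res
  }
  best
}

#' Steady state of the clamped system
#'
#' Solves for the stationary state of the 13-species network with the
#' environment (fumarate, succinate, O2, H+, electrode potential) clamped.
#' Two independent methods are provided: \code{"integration"} (the primary
#' route) integrates the stiff ODE system with \code{deSolve::lsoda} over
#' successively longer spans until the residual criterion
#' \code{max |dy/dt| < 1e-9 * max(pool totals)} uM/s is met, and
#' \code{"rootfind"} runs a damped Newton iteration on the reduced
#' 13-dimensional system (conservation substituted), restarting from a
#' cascade of crude initial guesses if needed. The rate constants span more
#' than ten orders of magnitude, so the integrator runs at tight tolerances.
#'
#' @param ps An \code{sdh_params} object (validated for detailed balance).
#' @param env An [sdh_env()] object.
#' @param init Initial state: \code{"default"} (fully oxidized pools, all
#'   flavin as free FAD) or a named state vector.
#' @param method \code{"integration"} or \code{"rootfind"}.
#' @param tol_scale Residual tolerance as a fraction of the largest pool
#'   total.
#' @return A list of class \code{"sdh_steady"}: \code{state}, \code{rates}
#'   (an \code{sdh_rates} object), \code{residual_norm} (uM/s),
#'   \code{method}, \code{converged}.
#' @export
steady_state <- function(ps, env, init = "default",
                         method = c("integration", "rootfind"),
                         tol_scale = 1e-9) {
  method <- match.arg(method)
  validate_parameters(ps)
  if (identical(init, "default")) init <- default_state(ps)
  if (!all(.species %in% names(init)))
    stop("'init' must name all dynamic species", call. = FALSE)
  tol <- .residual_tol(ps, tol_scale)
  res <- switch(method,
                integration = .ss_integrate(ps, env, init, tol),
                rootfind = .ss_rootfind(ps, env, init, tol))
  if (!res$converged)
    warning(sprintf("steady state not converged (method %s): residual %.3e",
                    method, res$residual), call. = FALSE)
  structure(list(state = res$state,
                 rates = reaction_rates(res$state, env, ps, check = FALSE),
                 residual_norm = res$residual, method = method,
                 converged = res$converged, env = env, label = ps$label),
            class = "sdh_steady")
}

#' @export
print.sdh_steady <- function(x, ...) {
  cat(sprintf("Steady state [%s, %s]: %sconverged, residual %.3e uM/s\n",
              x$label, x$method, if (x$converged) "" else "NOT ",
              x$residual_norm))
  cat(sprintf("  E_out = %g mV, fum = %g uM, suc = %g uM\n",
              x$env$E_out, x$env$fum, x$env$suc))
  cat(sprintf("  V_rev_tot = %.6g, V_suc_tot = %.6g, VH2O2 = %.6g uM/s\n",
              x$rates$V_rev_tot, x$rates$V_suc_tot, x$rates$VH2O2))
  invisible(x)
}

#' Random conserving initial state
#'
#' Draws a positive state that respects all four conservation relations:
#' each cluster pair is split uniformly and the flavin pool is partitioned
#' over its nine states by a normalized uniform draw. Used to probe
#' initial-condition independence of the steady state.
#'
#' @param ps An \code{sdh_params} object.
#' @return Named state vector.
#' @export
random_conserving_state <- function(ps) {
  st <- default_state(ps)
  st[["Fe3S4red"]] <- stats::runif(1) * ps$pools[["Fe3S4"]]
  st[["Fe4S4red"]] <- stats::runif(1) * ps$pools[["Fe4S4"]]
  st[["Fe2S2red"]] <- stats::runif(1) * ps$pools[["Fe2S2"]]
  w <- stats::runif(9)
  w <- w / sum(w) * ps$pools[["FAD"]]
  st[c("FAD.fum", "FADH.fum", "FADH2.fum", "FAD.suc", "FADH.suc",
       "FADH2.suc", "FADH", "FADH2")] <- w[1:8]  # w[9] is free FAD
  st[["O2sup"]] <- 0
  st[["H2O2"]] <- 0
  st
}

#' Cross-validate the two steady-state methods
#'
#' Computes the steady state by stiff integration and by damped Newton and
#' compares every species and aggregate flux. Disagreement beyond \code{tol}
#' relative (on the scale of the pool totals for species, of the larger
#' magnitude for fluxes) is flagged rather than hidden, since it would
#' indicate multistability or a stiffness failure.
#'
#' @param ps An \code{sdh_params} object.
#' @param env An [sdh_env()] object.
#' @param tol Relative agreement tolerance.
#' @return A list of class \code{"sdh_crosscheck"}: \code{agree} (logical),
#'   \code{max_rel_diff}, and the two \code{sdh_steady} results.
#' @export
crosscheck_steady_state <- function(ps, env, tol = 1e-4) {
  a <- steady_state(ps, env, method = "integration")
  b <- steady_state(ps, env, method = "rootfind")
  scale_sp <- max(ps$pools)
  d_sp <- max(abs(a$state - b$state)) / scale_sp
  flux <- function(x) c(x$rates$V_rev_tot, x$rates$V_suc_tot, x$rates$VH2O2)
  fa <- flux(a); fb <- flux(b)
  d_fl <- max(abs(fa - fb) / pmax(abs(fa), abs(fb), 1e-12))
  maxd <- max(d_sp, d_fl)
  structure(list(agree = a$converged && b$converged && maxd < tol,
                 max_rel_diff = maxd, integration = a, rootfind = b,
                 tol = tol),
            class = "sdh_crosscheck")
}

#' @export
print.sdh_crosscheck <- function(x, ...) {
  cat(sprintf("Steady-state crosscheck: %s (max relative difference %.3e)\n",
              if (x$agree) "methods agree" else "DISAGREEMENT",
              x$max_rel_diff))
  invisible(x)
}

#' Closed-form zero-current potential
#'
#' The electrode potential at which the whole fumarate-reduction chain is at
#' equilibrium (no net current), obtained by chaining the electrode Nernst
#' relation through the cluster relay and the flavin cycle:
#' \deqn{E_{eq} = (vT/2) \ln(fum \cdot H^2 (Keq1 Keq2 Keq3)^2 / suc)}
#' For the basal potentials Keq1*Keq2*Keq3 = 1, so with fum = 1000 uM and
#' suc = 50 uM the zero-current point sits at 12.5 ln(20) = +37.4 mV.
#'
#' @param ps An \code{sdh_params} object.
#' @param env An [sdh_env()] object (E_out ignored).
#' @return Potential in mV.
#' @export
zero_current_potential <- function(ps, env) {
  if (env$suc <= 0 || env$fum <= 0)
    stop("fum and suc must be positive for a finite equilibrium potential",
         call. = FALSE)
  K123 <- ps$Keq[["Keq1"]] * ps$Keq[["Keq2"]] * ps$Keq[["Keq3"]]
  (ps$constants$vT / 2) *
    log(env$fum * env$Hplus^2 * K123^2 / env$suc)
}
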