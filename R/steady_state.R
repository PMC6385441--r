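# Expanding-steady-state solving: integrate-and-check with Newton polishing.
#
# The full system couples slow dilution (~0.05 hr^-1) to fast O2 relaxation
# (k_O2 = 25 hr^-1 plus a respiration sink k_res*[FS] that can exceed
# 1e4 hr^-1), so a stiff integrator is mandatory; lsoda switches to BDF
# automatically.

.steady_norm <- function(dy, y) max(abs(dy) / pmax(abs(y), 1))

# Damped finite-difference Newton on rhs(y) = 0, guarded against leaving the
# non-negative orthant. Returns NULL when it fails to improve.
.newton_polish <- function(system, y, max_iter = 25L, tol = 1e-13) {
  n <- length(y)
  f <- function(v) system$rhs(0, v)[[1]]
  fy <- f(y)
  for (it in seq_len(max_iter)) {
    if (.steady_norm(fy, y) < tol) break
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- max(1e-7 * abs(y[j]), 1e-9)
      yh <- y; yh[j] <- yh[j] + h
      J[, j] <- (f(yh) - fy) / h
    }
    step <- tryCatch(solve(J, -fy), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    improved <- FALSE
    for (k in 1:8) {
      cand <- y + lambda * step
      if (all(cand >= 0)) {
        fc <- f(cand)
        if (all(is.finite(fc)) &&
            .steady_norm(fc, cand) < .steady_norm(fy, y)) {
          y <- cand; fy <- fc; improved <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  list(y = y, dy = fy)
}

#' Solve a system to its expanding steady state
#'
#' Integrates from the canonical initial conditions (10 uM per iron
#' component, 0 uM O2) over geometrically growing time horizons until the
#' scaled derivative norm `max |d[X]/dt| / max(|[X]|, 1 uM)` falls below
#' `tol`, then polishes the state with a damped Newton iteration on the
#' steady-state algebra for residual tightening. Non-convergence by `t_max`
#' is reported in the `converged` flag, never raised as an error.
#'
#' @param system An [build_system()] object.
#' @param tol Relative rate tolerance for convergence (hr^-1); default 1e-9.
#' @param t_max Maximum integration horizon (hr); default 1e4.
#' @param state0 Optional initial-state override (named numeric).
#' @param polish Apply Newton polishing after convergence (default `TRUE`).
#' @return A `steady_state_result` with elements `system`, `state` (a
#'   [cell_state()]), `rates` (the full [rate_vector()] for tier C9, or the
#'   tier's applicable subset), `residuals` (per-equation imbalance, uM/hr),
#'   `converged`, and `t_final`.
#' @examples
#' \donttest{
#' sys <- build_system("C1", condition("WT", 1))
#' solve_steady(sys)$state  # ~59 uM whole-cell iron
#' }
#' @export
solve_steady <- function(system, tol = 1e-9, t_max = 1e4, state0 = NULL,
                         polish = TRUE) {
  y <- if (is.null(state0)) system$state0 else {
    stopifnot(setequal(names(state0), system$components))
    as.numeric(state0[system$components])
  }
  names(y) <- system$components
  t_now <- 0
  horizon <- 50
  converged <- FALSE
  while (t_now < t_max) {
    t_next <- min(t_now + horizon, t_max)
    # lsoda may hand back a partial chunk on very stiff excursions; that is
    # fine here because convergence is re-checked on the returned state, so
    # the step-budget warnings are muffled (all other warnings propagate).
    out <- withCallingHandlers(
      deSolve::ode(y = y, times = c(t_now, t_next), func = system$rhs,
                   parms = NULL, method = "lsoda",
                   rtol = 1e-10, atol = 1e-8, maxsteps = 1e5),
      warning = function(w) {
        if (grepl("maxsteps|Returning early|excessive amount",
                  conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    y <- out[nrow(out), -1]
    names(y) <- system$components
    t_reached <- out[nrow(out), 1]
    if (t_reached <= t_now) break  # no progress: give up, flag unconverged
    t_now <- t_reached
    dy <- system$rhs(0, y)[[1]]
    if (.steady_norm(dy, y) < tol) { converged <- TRUE; break }
    horizon <- horizon * 4
  }
  y <- pmax(y, 0)
  if (converged && polish) {
    pol <- .newton_polish(system, y)
    if (!is.null(pol) && all(pol$y >= 0)) y <- pol$y
  }
  dy <- stats::setNames(system$rhs(0, y)[[1]], system$components)
  rates <- if (system$tier == "C9") {
    rate_vector(y, system$parameters, system$N, system$geometry)
  } else {
    .tier_rates(system, y)
  }
  structure(list(system = system,
                 condition = condition(system$parameters$strain, system$N),
                 state = cell_state(system$tier, pmax(y, 0)),
                 rates = rates, residuals = dy,
                 converged = converged, t_final = t_now,
                 tol = tol),
            class = "steady_state_result")
}

# Rates applicable to the coarser tiers, reported on the same naming scheme.
.tier_rates <- function(system, y) {
  p <- system$parameters; N <- system$N
  alpha <- system$alpha
  out <- c(alpha = alpha,
           R_cell = hill_rate(N, p$R_cell_max, p$K_N, p$sens))
  if (system$tier %in% c("C3", "C4")) {
    sub <- y[[1]]
    out <- c(out,
             R_cyt = hill_rate(N, p$R_cyt_max, p$K_N, p$sens),
             R_mit = p$k_mit_c3 * sub,
             R_vac = hill_rate(sub, p$R_vac_max, p$K_vac, p$nvac))
    if (system$tier == "C4") {
      out <- c(out, R_cia = hill_rate(sub, p$R_cia_max, p$K_cia, p$ncia))
    }
  }
  out
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf("Expanding steady state [%s, strain %s, N = %g uM] %s\n",
              x$system$tier, x$condition$strain, x$condition$N,
              if (x$converged) "(converged)" else "(NOT converged)"))
  print(round(unclass(x$state), 4))
  invisible(x)
}

#' Steady-state residuals of the nine-component algebra
#'
#' Evaluates the imbalance of each steady-state balance line of the full
#' model (the eight iron-component lines written in their `R = ...` form plus
#' the O2 balance) at a solved state. All lines are at most `tol` in scaled
#' magnitude when the result converged.
#'
#' @param res A `steady_state_result` holding a tier-C9 state.
#' @return Named numeric vector of residuals (uM/hr): `cyt_influx`, `mit`,
#'   `vac`, `cia`, `isu`, `vp`, `f23`, `mp`, `o2`.
#' @export
steady_residuals <- function(res) {
  stopifnot(inherits(res, "steady_state_result"))
  if (res$system$tier != "C9") {
    stop("steady_residuals() requires a C9 result", call. = FALSE)
  }
  y <- res$state; r <- res$rates; a <- r[["alpha"]]
  g <- res$system$geometry
  v_mit <- g[["f_mit"]] / g[["f_cyt"]]
  v_vac <- g[["f_vac"]] / g[["f_cyt"]]
  c(cyt_influx = r[["R_cyt"]] -
      (r[["R_mit"]] + r[["R_vac"]] + r[["R_cia"]] + a * y[["C"]]),
    mit = r[["R_mit"]] -
      v_mit * (r[["R_isu"]] + r[["R_mp"]] + a * y[["FM"]]),
    vac = r[["R_vac"]] - v_vac * (r[["R_23"]] + a * y[["F2"]]),
    cia = r[["R_cia"]] - a * y[["CIA"]],
    isu = r[["R_isu"]] - a * y[["FS"]],
    vp = r[["R_vp"]] - a * y[["VP"]],
    f23 = r[["R_23"]] - (r[["R_vp"]] + a * y[["F3"]]),
    mp = r[["R_mp"]] - a * y[["MP"]],
    o2 = r[["R_O2"]] - (r[["R_mp"]] + r[["R_res"]] + a * y[["O2"]]))
}

#' Probe the uniqueness of a steady state
#'
#' Re-solves the system from initial conditions scaled by the given factors
#' and reports the maximum relative disagreement between the resulting steady
#' states. The full model is bistable at low nutrient iron (a healthy
#' iron-sulfur-dominated attractor coexists with a nanoparticle-dominated
#' one), and this probe is the detector: disagreement far above the solver
#' tolerance flags a condition inside the switch region.
#'
#' @param system An `ode_system`.
#' @param scales Numeric vector of initial-condition scale factors applied to
#'   the iron components (O2 always starts at 0).
#' @param ... Passed to [solve_steady()].
#' @return List with `states` (matrix, one row per scale) and
#'   `max_rel_disagreement`.
#' @export
steady_uniqueness_probe <- function(system, scales = c(0.1, 1, 10), ...) {
  states <- t(vapply(scales, function(s) {
    y0 <- system$state0 * s
    if ("O2" %in% system$components) y0[["O2"]] <- 0
    as.numeric(solve_steady(system, state0 = y0, ...)$state)
  }, numeric(length(system$components))))
  colnames(states) <- system$components
  ref <- states[which(scales == 1)[1], ]
  rel <- apply(states, 1, function(s) max(abs(s - ref) / pmax(abs(ref), 1)))
  list(states = states, max_rel_disagreement = max(rel))
}

#' Steady-state summary table across conditions
#'
#' Solves one tier at several conditions and assembles a wide table (one row
#' per strain x N) of the steady concentrations and rates -- the layout used
#' by the package's observation fixtures.
#'
#' @param conditions List of [condition()] objects.
#' @param tier Model tier.
#' @param parameters Optional named list of `strain_parameters` keyed by
#'   strain label; defaults to canonical sets.
#' @param ... Passed to [solve_steady()].
#' @return Data frame with the steady components, rates, and a `converged`
#'   flag.
#' @export
steady_table <- function(conditions, tier = "C9", parameters = NULL, ...) {
  rows <- lapply(conditions, function(cond) {
    p <- if (is.null(parameters)) canonical_parameters(cond$strain) else
      parameters[[cond$strain]]
    res <- solve_steady(build_system(tier, cond, p), ...)
    cbind(data.frame(strain = cond$strain, N = cond$N,
                     converged = res$converged),
          as.data.frame(t(unclass(res$state))),
          as.data.frame(t(res$rates)))
  })
  do.call(rbind, rows)
}
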