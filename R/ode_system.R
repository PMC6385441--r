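# Assembly of the C1/C3/C4/C9 ODE systems.
#
# Every state equation carries the growth-dilution term -alpha*[X] (including
# the O2 balance).  Transfer into an organelle is scaled by the volume ratio
# f_cyt/f_organelle so that moles are conserved when iron changes compartment;
# the matching efflux terms from cyt carry no factor because they are written
# on the cyt concentration basis.

#' Build a compartmental ODE system
#'
#' Assembles one of the four model tiers at a fixed nutrient iron
#' concentration. `N` is constant during a run (the medium is treated as
#' boundless, consistent with the expanding-steady-state setting).
#'
#' Tier conventions:
#' * `C1`: `d[Fe_cell]/dt = R_cell(N) - alpha*[Fe_cell]` with the Hill import
#'   law parameterized by `R_cell_max`.
#' * `C3`: cytosolic import `R_cyt(N)` (parameter `R_cyt_max`), mitochondrial
#'   import `k_mit_c3 * [Fe_cyt]` and vacuolar import `Hill([Fe_cyt])`; in
#'   this pure three-compartment system the cytosolic free-iron proxy
#'   coincides with total cytosolic iron.
#' * `C4`: as `C3` but cytosolic iron is split into free iron `C` (the
#'   substrate of all cytosolic efflux reactions) and the cytosolic
#'   iron-sulfur pool `CIA`.
#' * `C9`: full speciation plus the matrix O2 balance; mitochondrial import
#'   uses the `k_mit` value (re-scaled relative to `k_mit_c3` when the full
#'   model was solved).
#'
#' @param tier `"C1"`, `"C3"`, `"C4"`, or `"C9"`.
#' @param condition A [condition()] (strain label and nutrient iron `N`), or
#'   a numeric `N` if `p` is given explicitly.
#' @param p `strain_parameters`; defaults to [canonical_parameters()] for the
#'   condition's strain.
#' @param geometry A [compartment_geometry()].
#' @return An `ode_system` object with elements `tier`, `N`, `alpha`,
#'   `parameters`, `geometry`, `state0` (canonical initial conditions: 10 uM
#'   for every iron component, 0 uM for O2), and `rhs(t, y, ...)` in the form
#'   expected by [deSolve::ode()].
#' @export
build_system <- function(tier, condition, p = NULL,
                         geometry = compartment_geometry()) {
  tier <- match.arg(tier, names(.tier_components))
  if (inherits(condition, "growth_condition")) {
    N <- condition$N
    if (is.null(p)) p <- canonical_parameters(condition$strain)
  } else {
    N <- as.numeric(condition)
    if (is.null(p)) stop("supply strain parameters when `condition` is numeric",
                         call. = FALSE)
  }
  if (!is.finite(N) || N < 0) stop("N must be non-negative", call. = FALSE)
  stopifnot(inherits(p, "strain_parameters"))

  alpha <- growth_rate(N, p$alpha_max, p$K_alpha)
  comp <- tier_components(tier)
  state0 <- stats::setNames(rep(10, length(comp)), comp)
  if ("O2" %in% comp) state0[["O2"]] <- 0

  f_cyt <- geometry[["f_cyt"]]; f_mit <- geometry[["f_mit"]]
  f_vac <- geometry[["f_vac"]]

  rhs <- switch(tier,
    C1 = {
      R_cell <- hill_rate(N, p$R_cell_max, p$K_N, p$sens)
      function(t, y, parms = NULL) {
        y <- pmax(y, 0)
        list(R_cell - alpha * y[[1]])
      }
    },
    C3 = {
      R_cyt <- hill_rate(N, p$R_cyt_max, p$K_N, p$sens)
      function(t, y, parms = NULL) {
        y <- pmax(y, 0)
        R_mit <- p$k_mit_c3 * y[[1]]
        R_vac <- hill_rate(y[[1]], p$R_vac_max, p$K_vac, p$nvac)
        list(c(R_cyt - R_mit - R_vac - alpha * y[[1]],
               (f_cyt / f_mit) * R_mit - alpha * y[[2]],
               (f_cyt / f_vac) * R_vac - alpha * y[[3]]))
      }
    },
    C4 = {
      R_cyt <- hill_rate(N, p$R_cyt_max, p$K_N, p$sens)
      function(t, y, parms = NULL) {
        y <- pmax(y, 0)
        R_mit <- p$k_mit_c3 * y[[1]]
        R_vac <- hill_rate(y[[1]], p$R_vac_max, p$K_vac, p$nvac)
        R_cia <- hill_rate(y[[1]], p$R_cia_max, p$K_cia, p$ncia)
        list(c(R_cyt - R_mit - R_vac - R_cia - alpha * y[[1]],
               R_cia - alpha * y[[2]],
               (f_cyt / f_mit) * R_mit - alpha * y[[3]],
               (f_cyt / f_vac) * R_vac - alpha * y[[4]]))
      }
    },
    C9 = function(t, y, parms = NULL) {
      y <- pmax(y, 0)
      names(y) <- comp
      r <- rate_vector(y, p, N, geometry)
      list(c(r[["R_cyt"]] - r[["R_mit"]] - r[["R_vac"]] - r[["R_cia"]] -
               alpha * y[["C"]],
             r[["R_cia"]] - alpha * y[["CIA"]],
             (f_cyt / f_mit) * r[["R_mit"]] - r[["R_isu"]] - r[["R_mp"]] -
               alpha * y[["FM"]],
             r[["R_isu"]] - alpha * y[["FS"]],
             r[["R_mp"]] - alpha * y[["MP"]],
             (f_cyt / f_vac) * r[["R_vac"]] - r[["R_23"]] - alpha * y[["F2"]],
             r[["R_23"]] - r[["R_vp"]] - alpha * y[["F3"]],
             r[["R_vp"]] - alpha * y[["VP"]],
             r[["R_O2"]] - r[["R_mp"]] - r[["R_res"]] - alpha * y[["O2"]]))
    })

  structure(list(tier = tier, N = N, alpha = alpha, parameters = p,
                 geometry = geometry, components = comp, state0 = state0,
                 rhs = rhs),
            class = "ode_system")
}

#' Evaluate the time-derivative of a system at a state
#'
#' @param system An `ode_system`.
#' @param state Named numeric vector matching the system's components.
#' @return Named numeric vector of time derivatives (uM/hr).
#' @export
system_derivative <- function(system, state) {
  y <- as.numeric(state[system$components])
  d <- system$rhs(0, y)[[1]]
  stats::setNames(d, system$components)
}

#' Integrate a trajectory
#'
#' Stiff integration (lsoda) of the system from its initial conditions,
#' returned in tidy long format.
#'
#' @param system An `ode_system`.
#' @param times Numeric vector of output times (hr).
#' @param state0 Optional initial-state override (named, same components).
#' @param rtol,atol Integrator tolerances.
#' @param tidy If `TRUE` (default) return a long data frame with columns
#'   `time_hr, component, value_uM, tier, strain, N`; otherwise the wide
#'   deSolve matrix.
#' @return A data frame or matrix of the trajectory.
#' @export
run_trajectory <- function(system, times, state0 = NULL,
                           rtol = 1e-10, atol = 1e-8, tidy = TRUE) {
  y0 <- if (is.null(state0)) system$state0 else {
    stopifnot(setequal(names(state0), system$components))
    as.numeric(state0[system$components])
  }
  names(y0) <- system$components
  out <- deSolve::ode(y = y0, times = times, func = system$rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (!tidy) return(out)
  m <- as.data.frame(out)
  long <- do.call(rbind, lapply(system$components, function(cc) {
    data.frame(time_hr = m$time, component = cc, value_uM = m[[cc]],
               tier = system$tier, strain = system$parameters$strain,
               N = system$N, stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}

#' Experimental condition (strain x nutrient iron)
#'
#' @param strain Strain label.
#' @param N Total nutrient iron concentration (uM), including the 1 uM of
#'   endogenous iron present in untreated minimal medium; the canonical data
#'   grid is `{1, 2, 11, 41}`.
#' @return A `condition` object.
#' @export
condition <- function(strain, N) {
  N <- as.numeric(N)
  if (!is.finite(N) || N < 0) stop("N must be non-negative", call. = FALSE)
  structure(list(strain = normalize_strain(strain), N = N),
            class = "growth_condition")
}

#' @export
print.growth_condition <- function(x, ...) {
  cat(sprintf("Condition: strain %s, N = %g uM\n", x$strain, x$N))
  invisible(x)
}

#' Residuals of the three-compartment balance along a fine-tier trajectory
#'
#' Along any nine-component trajectory the compartment sums obey the
#' three-compartment equations with the induced rates, by construction of the
#' model. This helper evaluates both sides at a set of states and returns the
#' per-compartment imbalance, which should vanish to rounding error.
#'
#' @param system A tier-`C9` `ode_system`.
#' @param states Matrix of states (rows = time points, columns = components).
#' @return Matrix with columns `cyt`, `mit`, `vac` of absolute residuals
#'   (uM/hr).
#' @export
collapse_residuals <- function(system, states) {
  stopifnot(system$tier == "C9")
  g <- system$geometry
  p <- system$parameters
  res <- t(apply(states, 1, function(y) {
    names(y) <- system$components
    d <- system_derivative(system, y)
    r <- rate_vector(y, p, system$N, g)
    a <- system$alpha
    c(cyt = (d[["C"]] + d[["CIA"]]) -
        (r[["R_cyt"]] - r[["R_mit"]] - r[["R_vac"]] -
           a * (y[["C"]] + y[["CIA"]])),
      mit = (d[["FM"]] + d[["FS"]] + d[["MP"]]) -
        ((g[["f_cyt"]] / g[["f_mit"]]) * r[["R_mit"]] -
           a * (y[["FM"]] + y[["FS"]] + y[["MP"]])),
      vac = (d[["F2"]] + d[["F3"]] + d[["VP"]]) -
        ((g[["f_cyt"]] / g[["f_vac"]]) * r[["R_vac"]] -
           a * (y[["F2"]] + y[["F3"]] + y[["VP"]])))
  }))
  abs(res)
}
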