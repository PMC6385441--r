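# Normalized-error objective, coordinate-descent optimizer, tiered fitting
# pipeline with parameter transfer, and one-at-a-time sensitivity analysis.

#' Normalized mean relative error between simulations and data
#'
#' Mean over datapoints of `2*|sim - dat| / (sim + dat)`: each point is
#' weighted evenly regardless of magnitude, and every term is bounded by 2.
#' Pairs with `sim + dat == 0` carry no information and are skipped with a
#' warning.
#'
#' @param sim,dat Equal-length numeric vectors of non-negative values.
#' @return Dimensionless error (0 iff `sim == dat` on all used points).
#' @examples
#' err_metric(1, 3)  # 2*2/4 = 1
#' @export
err_metric <- function(sim, dat) {
  stopifnot(length(sim) == length(dat))
  denom <- sim + dat
  keep <- is.finite(denom) & denom > 0
  if (any(!keep)) {
    warning(sum(!keep), " datapoint(s) with sim + dat = 0 skipped")
  }
  if (!any(keep)) return(0)
  mean(2 * abs(sim[keep] - dat[keep]) / denom[keep])
}

#' Multiplicative coordinate descent
#'
#' For each step size in `schedule`, cycles through the parameters in their
#' declared order, testing the candidate values `p*(1+step)` and `p*(1-step)`
#' and accepting a candidate only if it strictly lowers the objective
#' (ties reject; non-finite objective values reject and are logged). Cycling
#' at a given step size repeats until a full cycle accepts nothing (or
#' `max_cycles` is reached), then the next, smaller step is used. Fully
#' deterministic.
#'
#' @param objective Function taking a named numeric parameter vector and
#'   returning a scalar; must be finite at `params`.
#' @param params Named numeric starting vector.
#' @param schedule Numeric vector of fractional step sizes; default
#'   `c(0.10, 0.05, 0.01)`.
#' @param max_cycles Maximum cycles per step size (default 50).
#' @param order Parameter cycling order (default the order of `params`).
#' @return List with `par`, `value`, `n_eval`, and `history` (a data frame
#'   with one row per candidate: step, parameter, candidate value, objective,
#'   accepted flag).
#' @export
coordinate_descent <- function(objective, params,
                               schedule = c(0.10, 0.05, 0.01),
                               max_cycles = 50L, order = names(params)) {
  stopifnot(length(names(params)) == length(params),
            all(order %in% names(params)))
  best <- objective(params)
  if (!is.finite(best)) stop("objective not finite at the starting point",
                             call. = FALSE)
  hist <- list()
  n_eval <- 1L
  for (step in schedule) {
    for (cycle in seq_len(max_cycles)) {
      any_accept <- FALSE
      for (pn in order) {
        for (dir in c(1, -1)) {
          cand <- params
          cand[[pn]] <- cand[[pn]] * (1 + dir * step)
          val <- tryCatch(objective(cand), error = function(e) NaN)
          n_eval <- n_eval + 1L
          accept <- is.finite(val) && val < best
          hist[[length(hist) + 1L]] <-
            data.frame(step = step, parameter = pn,
                       candidate = cand[[pn]], objective = val,
                       accepted = accept)
          if (accept) {
            params <- cand; best <- val; any_accept <- TRUE
          }
        }
      }
      if (!any_accept) break
    }
  }
  list(par = params, value = best, n_eval = n_eval,
       history = do.call(rbind, hist))
}

# ---- parameter packing -----------------------------------------------------

# Flat vector names: shared parameters keep their field name; strain-specific
# ones are suffixed "@WT" / "@DD".
.pack_free <- function(plist, fields) {
  out <- numeric(0)
  for (f in fields) {
    if (f %in% .strain_specific_fields) {
      for (s in names(plist)) out[paste0(f, "@", s)] <- plist[[s]][[f]]
    } else {
      out[f] <- plist[[1]][[f]]
    }
  }
  out
}

.unpack_free <- function(plist, flat) {
  for (nm in names(flat)) {
    parts <- strsplit(nm, "@", fixed = TRUE)[[1]]
    if (length(parts) == 2) {
      args <- stats::setNames(list(flat[[nm]]), parts[1])
      plist[[parts[2]]] <- do.call(update_parameters,
                                   c(list(plist[[parts[2]]]), args))
    } else {
      for (s in names(plist)) {
        args <- stats::setNames(list(flat[[nm]]), nm)
        plist[[s]] <- do.call(update_parameters, c(list(plist[[s]]), args))
      }
    }
  }
  plist
}

# ---- tier objectives -------------------------------------------------------

# Free cytosolic iron at the coarse-tier steady state: solves the free-iron
# balance R_cyt(N) = k*C + R_vac(C) + R_cia(C) + alpha*C.  Using the
# free-iron proxy (rather than total cytosolic iron) as the substrate is what
# makes k_mit and R_vac_max transferable between tiers.
.free_iron_steady <- function(p, N, with_cia = TRUE) {
  R_cyt <- hill_rate(N, p$R_cyt_max, p$K_N, p$sens)
  alpha <- growth_rate(N, p$alpha_max, p$K_alpha)
  bal <- function(C) {
    R_cyt - p$k_mit_c3 * C - hill_rate(C, p$R_vac_max, p$K_vac, p$nvac) -
      (if (with_cia) hill_rate(C, p$R_cia_max, p$K_cia, p$ncia) else 0) -
      alpha * C
  }
  upper <- R_cyt / alpha + 1
  stats::uniroot(bal, c(0, upper), tol = 1e-12)$root
}

# Returns, per observation record, named sim and dat vectors for one tier.
.tier_points <- function(tier, rec, p, geometry) {
  N <- rec$condition$N
  fl <- rec$fluxes_dat
  alpha_sim <- growth_rate(N, p$alpha_max, p$K_alpha)
  if (tier == "C1") {
    sim <- c(alpha = alpha_sim,
             R_cell = hill_rate(N, p$R_cell_max, p$K_N, p$sens))
    dat <- c(alpha = rec$alpha_dat, R_cell = fl[["R_cell"]])
    return(list(sim = sim, dat = dat))
  }
  if (tier %in% c("C3", "C4")) {
    C <- .free_iron_steady(p, N, with_cia = TRUE)
    R_mit <- p$k_mit_c3 * C
    R_vac <- hill_rate(C, p$R_vac_max, p$K_vac, p$nvac)
    R_cyt <- hill_rate(N, p$R_cyt_max, p$K_N, p$sens)
    sim <- c(R_mit = R_mit, R_vac = R_vac,
             R_cyt_only = R_cyt - R_mit - R_vac)
    dat <- c(R_mit = fl[["R_mit"]], R_vac = fl[["R_vac"]],
             R_cyt_only = fl[["R_cyt"]] - fl[["R_mit"]] - fl[["R_vac"]])
    if (tier == "C4") {
      sim <- c(sim, R_cia = hill_rate(C, p$R_cia_max, p$K_cia, p$ncia))
      dat <- c(dat, R_cia = fl[["R_cia"]])
    }
    return(list(sim = sim, dat = dat))
  }
  stop("unknown tier for objective: ", tier, call. = FALSE)
}

# C9 datapoints: steady pools plus all component formation rates.
.c9_points <- function(rec, p, geometry, guess_env = NULL) {
  cond <- rec$condition
  key <- paste0(cond$strain, "@", cond$N)
  sys <- build_system("C9", cond, p, geometry)
  guess <- if (!is.null(guess_env)) guess_env[[key]] else NULL
  res <- NULL
  if (!is.null(guess)) {
    pol <- .newton_polish(sys, guess)
    if (!is.null(pol) && .steady_norm(pol$dy, pol$y) < 1e-9 &&
        all(pol$y >= 0)) {
      y <- stats::setNames(pmax(pol$y, 0), sys$components)
      res <- list(state = y,
                  rates = rate_vector(y, p, cond$N, geometry))
    }
  }
  if (is.null(res)) {
    ss <- solve_steady(sys)
    if (!ss$converged) return(NULL)
    res <- list(state = unclass(ss$state), rates = ss$rates)
  }
  if (!is.null(guess_env)) guess_env[[key]] <- res$state
  pools <- res$state[c("C", "CIA", "FM", "FS", "MP", "F2", "F3", "VP")]
  r <- res$rates
  sim <- c(pools,
           R_mit = r[["R_mit"]], R_vac = r[["R_vac"]],
           R_cia = r[["R_cia"]], R_isu = r[["R_isu"]],
           R_vp = r[["R_vp"]], R_23 = r[["R_23"]], R_mp = r[["R_mp"]])
  fl <- rec$fluxes_dat
  dat <- c(rec$pools_dat,
           R_mit = fl[["R_mit"]], R_vac = fl[["R_vac"]],
           R_cia = fl[["R_cia"]], R_isu = fl[["R_isu"]],
           R_vp = fl[["R_vp"]], R_23 = fl[["R_23"]], R_mp = fl[["R_mp"]])
  list(sim = sim, dat = dat)
}

.tier_objective <- function(tier, observations, plist, free,
                            geometry = compartment_geometry()) {
  guess_env <- new.env(parent = emptyenv())
  function(flat) {
    pl <- tryCatch(.unpack_free(plist, flat), error = function(e) NULL)
    if (is.null(pl)) return(NaN)
    sims <- numeric(0); dats <- numeric(0)
    for (rec in observations) {
      p <- pl[[rec$condition$strain]]
      pts <- if (tier == "C9") {
        .c9_points(rec, p, geometry, guess_env)
      } else {
        tryCatch(.tier_points(tier, rec, p, geometry),
                 error = function(e) NULL)
      }
      if (is.null(pts)) return(NaN)
      sims <- c(sims, pts$sim); dats <- c(dats, pts$dat)
    }
    suppressWarnings(err_metric(sims, dats))
  }
}

# ---- tiered pipeline -------------------------------------------------------

.stage_free <- list(
  C1 = c("alpha_max", "K_alpha", "R_cell_max", "K_N", "sens"),
  C3 = c("k_mit_c3", "R_cyt_max", "R_vac_max", "K_vac", "nvac"),
  C4 = c("R_cia_max", "K_cia", "ncia"),
  C9 = c("k_mit", "R_isu_max", "K_isu", "nisu", "k_vp", "nvp",
         "k_23", "FS_sp", "n23", "k_mp", "k_O2", "k_res")
)

#' Multi-tier fitting with parameter transfer
#'
#' Reproduces the tiered optimization strategy: each tier frees only the
#' parameters its data can constrain, transfers the result to the next tier,
#' and is optimized by the same multiplicative coordinate descent
#' ([coordinate_descent()]).
#'
#' Stages: **C1** fits the growth law and cellular import
#' (`alpha_max, K_alpha, R_cell_max, K_N, sens`) to growth rates and cellular
#' import rates. **C3** transfers those, initializes
#' `R_cyt_max = R_cell_max / f_cyt`, and fits the compartment import laws
#' (`k_mit_c3, R_cyt_max, R_vac_max, K_vac, nvac`) to the compartment fluxes.
#' **C4** fits the cytosolic iron-sulfur assembly law
#' (`R_cia_max, K_cia, ncia`). **C9** first applies the mitochondrial-import
#' rescale (`k_mit = 2*k_mit_c3` for WT, `k_mit_c3 / 1.3` for the deletion
#' strain) and then refines all full-model parameters against the pool
#' concentrations and component formation rates. A final joint pass re-frees
#' every stage's parameters (shared parameters stay shared between strains).
#'
#' @param observations List of [observation_record()]s covering at least two
#'   `N` values per strain.
#' @param start Named list of `strain_parameters` (`WT`, `DD`) to start from;
#'   defaults to the canonical sets.
#' @param tiers Which stages to run, in order (default all four).
#' @param schedule Step-size schedule passed to [coordinate_descent()].
#' @param final_joint Run the final joint pass (default `TRUE` when tier C9
#'   is included).
#' @param transfer_R_cyt Initialize `R_cyt_max` from `R_cell_max / f_cyt` at
#'   the C3 stage (default `TRUE`).
#' @param kmit_rescale Apply the C9 `k_mit` rescale (default `TRUE`).
#' @param geometry A [compartment_geometry()].
#' @param max_cycles Per-step cycle cap for the optimizer.
#' @return A `fit_result`: list with `parameters` (named list of
#'   `strain_parameters`), `err_by_tier`, `history` (with a `stage` column),
#'   `datapoints_used`, and `stage_changes` (audit of which parameters each
#'   stage actually moved).
#' @export
fit_tiered <- function(observations, start = NULL,
                       tiers = c("C1", "C3", "C4", "C9"),
                       schedule = c(0.10, 0.05, 0.01),
                       final_joint = "C9" %in% tiers,
                       transfer_R_cyt = TRUE, kmit_rescale = TRUE,
                       geometry = compartment_geometry(),
                       max_cycles = 50L) {
  strains <- unique(vapply(observations, function(r) r$condition$strain,
                           character(1)))
  for (s in strains) {
    nN <- length(unique(vapply(
      observations[vapply(observations,
                          function(r) r$condition$strain == s, logical(1))],
      function(r) r$condition$N, numeric(1))))
    if (nN < 2) warning("strain ", s, " has fewer than 2 N values; ",
                        "stages may be unidentifiable")
  }
  plist <- if (is.null(start)) {
    stats::setNames(lapply(strains, canonical_parameters), strains)
  } else start[strains]

  err_by_tier <- c()
  history <- list()
  stage_changes <- list()
  datapoints <- list()

  run_stage <- function(stage_label, tier, fields, plist) {
    free0 <- .pack_free(plist, fields)
    npts <- length(observations) *
      switch(tier, C1 = 2, C3 = 3, C4 = 4, C9 = 15)
    if (length(free0) > npts) {
      warning("stage ", stage_label, ": more free parameters (",
              length(free0), ") than datapoints (", npts, ")")
    }
    obj <- .tier_objective(tier, observations, plist, fields, geometry)
    fit <- coordinate_descent(obj, free0, schedule = schedule,
                              max_cycles = max_cycles)
    moved <- names(free0)[abs(fit$par - free0) > 0]
    h <- fit$history
    if (!is.null(h) && nrow(h) > 0) h$stage <- stage_label
    list(plist = .unpack_free(plist, fit$par), value = fit$value,
         history = h, moved = moved)
  }

  for (tier in tiers) {
    if (tier == "C3" && transfer_R_cyt) {
      for (s in strains) {
        plist[[s]] <- update_parameters(
          plist[[s]],
          R_cyt_max = plist[[s]]$R_cell_max / geometry[["f_cyt"]])
      }
    }
    if (tier == "C9" && kmit_rescale) {
      for (s in strains) {
        km <- if (s == "WT") 2 * plist[[s]]$k_mit_c3 else
          plist[[s]]$k_mit_c3 / 1.3
        plist[[s]] <- update_parameters(plist[[s]], k_mit = km)
      }
    }
    st <- run_stage(tier, tier, .stage_free[[tier]], plist)
    plist <- st$plist
    err_by_tier[tier] <- st$value
    history[[tier]] <- st$history
    stage_changes[[tier]] <- st$moved
    datapoints[[tier]] <- switch(tier,
      C1 = c("alpha", "R_cell"),
      C3 = c("R_mit", "R_vac", "R_cyt_only"),
      C4 = c("R_mit", "R_vac", "R_cyt_only", "R_cia"),
      C9 = c("pools C..VP", "R_mit", "R_vac", "R_cia", "R_isu", "R_vp",
             "R_23", "R_mp"))
  }

  if (final_joint) {
    all_fields <- unique(unlist(.stage_free[tiers]))
    st <- run_stage("joint", tiers[length(tiers)], all_fields, plist)
    plist <- st$plist
    err_by_tier["joint"] <- st$value
    history[["joint"]] <- st$history
    stage_changes[["joint"]] <- st$moved
  }

  structure(list(parameters = plist, err_by_tier = err_by_tier,
                 history = do.call(rbind, history),
                 datapoints_used = datapoints,
                 stage_changes = stage_changes),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Tiered fit result\n  ERR by stage:\n")
  for (nm in names(x$err_by_tier)) {
    cat(sprintf("    %-6s %.6g\n", nm, x$err_by_tier[[nm]]))
  }
  invisible(x)
}

#' One-at-a-time sensitivity indices
#'
#' For each parameter, perturbs the operating point by plus and minus
#' `delta` (default 1 percent) and reports
#' `S = (ERR(+delta) + ERR(-delta)) / (2 * ERR(opt))`. A parameter the
#' objective ignores gives exactly 1; at a smooth local minimum every index
#' is at least 1 up to solver noise. Large indices mark the parameters with
#' the greatest leverage on the fit.
#'
#' @param objective Function of a named numeric parameter vector.
#' @param params_opt Named numeric operating point.
#' @param delta Fractional perturbation (default 0.01).
#' @return A `sensitivity_report`: list with `S` (named vector) and
#'   `err_opt`.
#' @export
sensitivity_scan <- function(objective, params_opt, delta = 0.01) {
  err_opt <- objective(params_opt)
  if (!is.finite(err_opt)) stop("objective not finite at the operating point",
                                call. = FALSE)
  if (err_opt == 0) stop("sensitivity index undefined: ERR(opt) = 0",
                         call. = FALSE)
  S <- vapply(names(params_opt), function(pn) {
    up <- params_opt; up[[pn]] <- up[[pn]] * (1 + delta)
    dn <- params_opt; dn[[pn]] <- dn[[pn]] * (1 - delta)
    (objective(up) + objective(dn)) / (2 * err_opt)
  }, numeric(1))
  structure(list(S = S, err_opt = err_opt, delta = delta),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity scan (delta = %g, ERR_opt = %.6g)\n",
              x$delta, x$err_opt))
  s <- sort(x$S, decreasing = TRUE)
  for (nm in names(s)) cat(sprintf("  %-14s %.4f\n", nm, s[[nm]]))
  invisible(x)
}
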