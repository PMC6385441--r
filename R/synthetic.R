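# Synthetic observation tables with the measurement structure the analysis
# assumes: per-condition growth rate, whole-cell iron, and Moessbauer-group
# concentrations generated from known ground-truth parameters, with
# independent multiplicative lognormal noise on every observable.
#
# Lognormal noise (mean 1, coefficient of variation noise_cv) is the natural
# choice here: all observables are positive and span four orders of
# magnitude, and the printed two-significant-figure data carry an implicit
# 5-10 percent relative precision.

#' Configuration for the synthetic-observation generator
#'
#' @param true_parameters Named list of `strain_parameters` keyed by strain
#'   label (default: canonical sets for WT and DD).
#' @param N_values Nutrient iron concentrations to observe (uM).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (0 = noise-free).
#' @param seed Integer seed fixing the full output.
#' @param geometry A [compartment_geometry()].
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(true_parameters = NULL,
                             N_values = c(1, 2, 11, 41),
                             noise_cv = 0.05, seed = 1L,
                             geometry = compartment_geometry()) {
  if (is.null(true_parameters)) {
    true_parameters <- list(WT = canonical_parameters("WT"),
                            DD = canonical_parameters("DD"))
  }
  stopifnot(noise_cv >= 0, length(N_values) >= 1)
  structure(list(true_parameters = true_parameters,
                 N_values = as.numeric(N_values),
                 noise_cv = noise_cv, seed = as.integer(seed),
                 geometry = geometry),
            class = "synthetic_config")
}

# mean-1 lognormal multiplicative noise factors
.lognormal_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Solve the noiseless ground truth for a synthetic configuration
#'
#' Full-model steady states for every strain x N condition of the
#' configuration; reusable across noise replicates so that Monte-Carlo
#' studies do not re-integrate the ODEs.
#'
#' @param cfg A [synthetic_config()].
#' @return List of per-condition lists with `condition`, `state`, `alpha`,
#'   `Fe_cell`, `groups`, `converged`.
#' @export
synthetic_truth <- function(cfg) {
  out <- list()
  for (strain in names(cfg$true_parameters)) {
    p <- cfg$true_parameters[[strain]]
    for (N in cfg$N_values) {
      cond <- condition(strain, N)
      res <- solve_steady(build_system("C9", cond, p, cfg$geometry))
      if (!res$converged) {
        warning("steady state did not converge for ", strain, " N=", N,
                "; condition skipped")
        next
      }
      s <- unclass(res$state)
      pools <- s[c("C", "CIA", "FM", "FS", "MP", "F2", "F3", "VP")]
      out[[paste0(strain, "@", N)]] <- list(
        condition = cond, state = s, alpha = res$rates[["alpha"]],
        Fe_cell = whole_cell_total(res$state, cfg$geometry),
        pools = pools,
        groups = groups_from_pools(pools, cfg$geometry))
    }
  }
  out
}

#' Generate synthetic observation records
#'
#' For each condition, takes the ground-truth steady state, maps the pools
#' forward to Moessbauer-group observables, applies independent lognormal
#' noise (coefficient of variation `noise_cv`) to every observable (the
#' groups, the growth rate, the whole-cell iron, and the assumed cytosolic
#' free-iron concentration), inverts the groups back to pools, and recomputes
#' the data-based fluxes from the noisy values -- exactly the reduction a
#' real measurement undergoes. Noisy group combinations that would imply a
#' (slightly) negative inferred pool are clipped to zero, mirroring how a
#' practitioner treats a below-detection difference.
#'
#' @param cfg A [synthetic_config()].
#' @param truth Optional precomputed [synthetic_truth()] (for replicate
#'   studies).
#' @return List of [observation_record()]s; each carries the ground truth in
#'   its `truth` element. Fully determined by `cfg` (same seed, same output).
#' @export
generate_observations <- function(cfg, truth = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.null(truth)) truth <- synthetic_truth(cfg)
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(cfg$seed)
  g <- cfg$geometry
  lapply(truth, function(tr) {
    fac <- .lognormal_factors(10, cfg$noise_cv)
    alpha_obs <- tr$alpha * fac[1]
    Fe_cell_obs <- tr$Fe_cell * fac[2]
    groups_obs <- unclass(tr$groups) * fac[3:9]
    C_obs <- tr$pools[["C"]] * fac[10]
    f_cyt <- g[["f_cyt"]]; f_mit <- g[["f_mit"]]; f_vac <- g[["f_vac"]]
    gr <- groups_obs
    pools_obs <- c(
      C = C_obs,
      CIA = max((gr[["CD_cell"]] - f_mit * gr[["CD_mit"]]) / f_cyt, 0),
      FM = gr[["FeII_mit"]], FS = gr[["CD_mit"]],
      MP = gr[["NPplusFeIII_mit"]],
      F2 = max((gr[["FeII_cell"]] - f_cyt * C_obs -
                  f_mit * gr[["FeII_mit"]]) / f_vac, 0),
      F3 = gr[["FeIII_cell"]] / f_vac,
      VP = max((gr[["NP_cell"]] - f_mit * gr[["NPplusFeIII_mit"]]) / f_vac, 0))
    rec <- observation_record(tr$condition, alpha_obs, Fe_cell_obs,
                              pools_obs, geometry = g)
    rec$truth <- tr
    rec
  })
}

#' Write synthetic observations in the fixture CSV schema
#'
#' Emits `observations.csv` (same long schema as the bundled fixture, basis
#' `"data"`) and `ground_truth.csv` alongside.
#'
#' @param obs Output of [generate_observations()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_synthetic_csv <- function(obs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list(); trows <- list()
  for (rec in obs) {
    cond <- rec$condition
    g <- rec$geometry
    comp <- rec$compartments_dat
    vals <- c(alpha = rec$alpha_dat, Fe_cell = rec$Fe_cell_dat,
              fFe_cyt = g[["f_cyt"]] * comp[["Fe_cyt"]],
              fFe_mit = g[["f_mit"]] * comp[["Fe_mit"]],
              fFe_vac = g[["f_vac"]] * comp[["Fe_vac"]],
              R_cell = rec$fluxes_dat[["R_cell"]],
              R_mit = rec$fluxes_dat[["R_mit"]],
              R_vac = rec$fluxes_dat[["R_vac"]],
              R_cyt_only = rec$fluxes_dat[["R_cyt"]] -
                rec$fluxes_dat[["R_mit"]] - rec$fluxes_dat[["R_vac"]],
              rec$pools_dat)
    rows[[length(rows) + 1L]] <- data.frame(
      strain = cond$strain, N = cond$N, basis = "data",
      quantity = names(vals), value = unname(vals), flag = "ok",
      note = "synthetic", stringsAsFactors = FALSE)
    if (!is.null(rec$truth)) {
      tv <- c(alpha = rec$truth$alpha, Fe_cell = rec$truth$Fe_cell,
              rec$truth$pools)
      trows[[length(trows) + 1L]] <- data.frame(
        strain = cond$strain, N = cond$N, quantity = names(tv),
        value = unname(tv), stringsAsFactors = FALSE)
    }
  }
  f1 <- file.path(dir, "observations.csv")
  f2 <- file.path(dir, "ground_truth.csv")
  utils::write.csv(do.call(rbind, rows), f1, row.names = FALSE)
  utils::write.csv(do.call(rbind, trows), f2, row.names = FALSE)
  invisible(c(f1, f2))
}
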