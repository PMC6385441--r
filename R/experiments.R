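# In-silico experiments: nutrient sweeps, the oxygen/nanoparticle switch,
# parameter-perturbation traces, and the frataxin-deficiency scan.

#' Default nutrient sweep grid
#'
#' 33 log2-spaced points on `[1, 41]` uM -- dense enough to resolve the
#' abrupt oxygen switch of the deletion strain.
#' @param n Number of points.
#' @param range Nutrient iron range (uM).
#' @return Numeric grid.
#' @export
default_N_grid <- function(n = 33, range = c(1, 41)) {
  2^seq(log2(range[1]), log2(range[2]), length.out = n)
}

#' Steady-state sweep over nutrient iron
#'
#' Solves the chosen tier to its expanding steady state at each grid point.
#' Grid points outside the calibrated range `[1, 41]` uM are allowed with a
#' warning (extrapolation).
#'
#' @param strain Strain label.
#' @param grid Numeric vector of N values (uM), strictly increasing.
#' @param tier Model tier (default `"C9"`).
#' @param p Optional `strain_parameters` override.
#' @param ... Passed to [solve_steady()].
#' @return A `sweep_result`: list with `strain`, `grid`, `results` (one
#'   `steady_state_result` per N), and `curves` (wide data frame of steady
#'   components and rates vs N, with a `converged` column; non-convergence is
#'   flagged, never raised).
#' @export
sweep_N <- function(strain, grid = default_N_grid(), tier = "C9", p = NULL,
                    ...) {
  stopifnot(length(grid) >= 1, !is.unsorted(grid, strictly = TRUE))
  if (min(grid) < 1 || max(grid) > 41) {
    warning("grid extends outside the calibrated range [1, 41] uM")
  }
  if (is.null(p)) p <- canonical_parameters(strain)
  results <- lapply(grid, function(N) {
    solve_steady(build_system(tier, condition(strain, N), p), ...)
  })
  curves <- do.call(rbind, lapply(seq_along(grid), function(i) {
    res <- results[[i]]
    cbind(data.frame(N = grid[i], converged = res$converged),
          as.data.frame(t(unclass(res$state))),
          as.data.frame(t(res$rates)))
  }))
  structure(list(strain = normalize_strain(strain), grid = grid, tier = tier,
                 results = results, curves = curves),
            class = "sweep_result")
}

#' Frataxin-deficiency scan: nanoparticles vs iron-sulfur assembly capacity
#'
#' Sweeps the maximal iron-sulfur cluster assembly rate `R_isu_max` downward
#' from its optimized value and records the steady mitochondrial
#' nanoparticle concentration. Low `R_isu_max` emulates the slow cluster
#' assembly of frataxin-deficient (Yfh1-depleted) cells, whose mitochondria
#' accumulate nanoparticles; `R_isu_max = 0` is handled as the exact
#' assembly-free limit.
#'
#' @param grid Numeric vector of `R_isu_max` values (uM/hr), within
#'   `[0, canonical]`.
#' @param strain Strain whose other parameters are used (default `"WT"`).
#' @param N Fixed nutrient iron concentration (default 11 uM).
#' @param ... Passed to [solve_steady()].
#' @return Data frame with columns `R_isu_max`, `MP`, `FS`, `FM`, `O2`,
#'   `converged`.
#' @export
yfh1_scan <- function(grid = seq(0, 180, by = 20), strain = "WT", N = 11,
                      ...) {
  p0 <- canonical_parameters(strain)
  if (any(grid < 0) || any(grid > p0$R_isu_max)) {
    stop("grid must lie within [0, R_isu_max canonical]", call. = FALSE)
  }
  rows <- lapply(grid, function(r) {
    # R_isu_max = 0 is the assembly-free limit; strain_parameters() requires
    # strictly positive values, so a tiny epsilon stands in for exact zero
    # (the Hill numerator then vanishes to ~1e-12 uM/hr, far below dilution).
    p <- update_parameters(p0, R_isu_max = max(r, 1e-10))
    res <- solve_steady(build_system("C9", condition(strain, N), p), ...)
    s <- res$state
    data.frame(R_isu_max = r, MP = s[["MP"]], FS = s[["FS"]],
               FM = s[["FM"]], O2 = s[["O2"]], converged = res$converged)
  })
  do.call(rbind, rows)
}

#' Parameter-perturbation traces of the matrix oxygen curve
#'
#' Re-computes the steady matrix `[O2]`-vs-N curve with one parameter scaled
#' by each factor while all others stay at their optimized values, and
#' summarizes the displacement from the unperturbed curve.
#'
#' @param parameter Name of a `strain_parameters` field.
#' @param factors Scale factors (default `c(0.9, 1.1)`).
#' @param strain Strain (default `"DD"`, where the switch lives).
#' @param grid Nutrient iron grid.
#' @param component Which steady component to trace (default `"O2"`).
#' @param ... Passed to [solve_steady()].
#' @return List with `curves` (data frame: N, factor, value) and
#'   `displacement` (named vector: per factor, the maximum vertical gap to
#'   the factor-1 curve, relative to the unperturbed curve's range).
#' @export
perturbation_traces <- function(parameter, factors = c(0.9, 1.1),
                                strain = "DD", grid = default_N_grid(9),
                                component = "O2", ...) {
  p0 <- canonical_parameters(strain)
  if (!parameter %in% names(p0)) {
    stop("unknown parameter: ", parameter, call. = FALSE)
  }
  factors <- sort(unique(c(1, factors)))
  curves <- do.call(rbind, lapply(factors, function(fac) {
    args <- stats::setNames(list(p0[[parameter]] * fac), parameter)
    p <- do.call(update_parameters, c(list(p0), args))
    sw <- sweep_N(strain, grid, tier = "C9", p = p, ...)
    data.frame(N = grid, factor = fac, value = sw$curves[[component]])
  }))
  base <- curves$value[curves$factor == 1]
  rng <- max(base) - min(base)
  disp <- vapply(setdiff(factors, 1), function(fac) {
    max(abs(curves$value[curves$factor == fac] - base)) / max(rng, 1e-12)
  }, numeric(1))
  names(disp) <- setdiff(factors, 1)
  list(parameter = parameter, component = component,
       curves = curves, displacement = disp)
}
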