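# Rate-law kernels. Every concentration is in uM, every rate in uM/hr.
#
# Non-integer exponents (nisu = 2.3, nvp = 2.4, n23 = 1.6) are evaluated as
# real powers of non-negative arguments; callers that integrate ODEs clip
# transient negative undershoot to zero before calling these kernels.

#' Growth rate as a function of nutrient iron
#'
#' Michaelis-Menten dependence of the exponential growth rate on the nutrient
#' iron concentration: `alpha_max * N / (K_alpha + N)`.
#'
#' @param N Nutrient iron concentration (uM), `>= 0`.
#' @param alpha_max Maximal growth rate (hr^-1).
#' @param K_alpha Half-saturation concentration (uM).
#' @return Growth rate in hr^-1; vectorized over `N`.
#' @examples
#' growth_rate(2, 0.204, 3.9)  # the deletion strain at N = 2 uM: ~0.069 hr^-1
#' @export
growth_rate <- function(N, alpha_max, K_alpha) {
  if (any(N < 0)) stop("N must be non-negative", call. = FALSE)
  stopifnot(alpha_max > 0, K_alpha > 0)
  alpha_max * N / (K_alpha + N)
}

#' Hill rate law
#'
#' `Vmax * x^n / (K^n + x^n)`. With `n = 1` this reduces to the
#' Michaelis-Menten form used for the growth rate.
#'
#' @param x Substrate concentration (uM), `>= 0`.
#' @param Vmax Maximal rate (uM/hr).
#' @param K Half-saturation concentration (uM).
#' @param n Hill exponent, `>= 1`.
#' @return Rate in uM/hr; vectorized over `x`.
#' @examples
#' hill_rate(41, 180, 4, 2)   # cellular import at high nutrient iron: ~178 uM/hr
#' hill_rate(11, 1140, 11, 3) # half-saturation: Vmax / 2
#' @export
hill_rate <- function(x, Vmax, K, n) {
  if (any(x < 0)) stop("x must be non-negative", call. = FALSE)
  stopifnot(Vmax > 0, K > 0, n >= 1)
  xn <- x^n
  Vmax * xn / (K^n + xn)
}

#' Mass-action rate law
#'
#' `k * x^n`; used for mitochondrial import (`n = 1`) and vacuolar
#' nanoparticle formation (`n = nvp`).
#'
#' @param k Rate constant (units `uM^(1-n) hr^-1`).
#' @param x Substrate concentration (uM), `>= 0`.
#' @param n Exponent, `>= 1`.
#' @return Rate in uM/hr; vectorized over `x`.
#' @export
mass_action_rate <- function(k, x, n = 1) {
  if (any(x < 0)) stop("x must be non-negative", call. = FALSE)
  stopifnot(k >= 0, n >= 1)
  k * x^n
}

#' Iron-sufficiency valve (regulatory factor on vacuolar Fe(II) oxidation)
#'
#' The sigmoidal factor `1 / (1 + (FS_sp / FS)^n23)` gates the conversion of
#' vacuolar Fe(II) to Fe(III) according to the mitochondrial iron-sulfur
#' cluster pool `FS`. It is nearly 0 when `FS` is far below the set-point
#' `FS_sp` (valve closed) and approaches 1 when `FS` far exceeds it. The
#' printed formula is singular at `FS = 0`; the continuous limit value 0 is
#' used there.
#'
#' @param FS Mitochondrial iron-sulfur cluster concentration (uM), `>= 0`.
#' @param FS_sp Set-point concentration (uM).
#' @param n23 Steepness exponent, `>= 1`.
#' @return Dimensionless factor in `[0, 1)`; vectorized over `FS`.
#' @examples
#' reg_fs(370, 370, 1.6)  # at the set-point the valve is half open
#' @export
reg_fs <- function(FS, FS_sp, n23) {
  if (any(FS < 0)) stop("FS must be non-negative", call. = FALSE)
  stopifnot(FS_sp > 0, n23 >= 1)
  out <- ifelse(FS == 0, 0, 1 / (1 + (FS_sp / FS)^n23))
  as.numeric(out)
}

#' Closed-form steady matrix oxygen concentration
#'
#' At an expanding steady state the matrix O2 balance (diffusive influx,
#' nanoparticle formation, respiration, and dilution) solves in closed form:
#' `O2 = O2_cyt * k_O2 / (k_O2 + k_mp*FM + k_res*FS + alpha)`.
#'
#' @param FM Matrix non-heme high-spin Fe(II) concentration (uM), `>= 0`.
#' @param FS Mitochondrial iron-sulfur cluster concentration (uM), `>= 0`.
#' @param alpha Growth rate (hr^-1), `>= 0`.
#' @param p A `strain_parameters` object (fields `O2_cyt`, `k_O2`, `k_mp`,
#'   `k_res`).
#' @return Steady matrix O2 concentration (uM), strictly below `O2_cyt` for
#'   any positive sink.
#' @export
o2_matrix_steady <- function(FM, FS, alpha, p) {
  if (any(FM < 0) || any(FS < 0) || any(alpha < 0)) {
    stop("FM, FS and alpha must be non-negative", call. = FALSE)
  }
  p$O2_cyt * p$k_O2 / (p$k_O2 + p$k_mp * FM + p$k_res * FS + alpha)
}

#' All instantaneous rates of the nine-component model at a state
#'
#' Evaluates every rate-law expression of the full model at the given
#' component concentrations. Used both for assembling the ODE right-hand side
#' and for reporting the rates of a converged steady state.
#'
#' @param state Named numeric vector with components
#'   `C, CIA, FM, FS, MP, F2, F3, VP, O2` (uM); negative entries are clipped
#'   to zero before evaluation.
#' @param p A `strain_parameters` object.
#' @param N Nutrient iron concentration (uM).
#' @param geometry A [compartment_geometry()].
#' @return Named numeric vector with elements `alpha`, `R_cell`, `R_cyt`,
#'   `R_mit`, `R_vac`, `R_cia`, `R_isu`, `R_23`, `R_vp`, `R_mp`, `R_res`,
#'   `R_O2` (rates in uM/hr, `alpha` in hr^-1).
#' @export
rate_vector <- function(state, p, N, geometry = compartment_geometry()) {
  s <- pmax(state, 0)
  alpha <- growth_rate(N, p$alpha_max, p$K_alpha)
  R_cyt <- hill_rate(N, p$R_cyt_max, p$K_N, p$sens)
  c(alpha = alpha,
    R_cell = hill_rate(N, p$R_cell_max, p$K_N, p$sens),
    R_cyt = R_cyt,
    R_mit = mass_action_rate(p$k_mit, s[["C"]]),
    R_vac = hill_rate(s[["C"]], p$R_vac_max, p$K_vac, p$nvac),
    R_cia = hill_rate(s[["C"]], p$R_cia_max, p$K_cia, p$ncia),
    R_isu = hill_rate(s[["FM"]], p$R_isu_max, p$K_isu, p$nisu),
    R_23 = p$k_23 * s[["F2"]] * reg_fs(s[["FS"]], p$FS_sp, p$n23),
    R_vp = mass_action_rate(p$k_vp, s[["F3"]], p$nvp),
    R_mp = p$k_mp * s[["FM"]] * s[["O2"]],
    R_res = p$k_res * s[["FS"]] * s[["O2"]],
    R_O2 = p$k_O2 * (p$O2_cyt - s[["O2"]]))
}
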