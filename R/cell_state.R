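# Tier-tagged state vectors and the maps between model tiers.

.tier_components <- list(
  C1 = "Fe_cell",
  C3 = c("Fe_cyt", "Fe_mit", "Fe_vac"),
  C4 = c("C", "CIA", "Fe_mit", "Fe_vac"),
  C9 = c("C", "CIA", "FM", "FS", "MP", "F2", "F3", "VP", "O2")
)

#' Component names of a model tier
#'
#' @param tier One of `"C1"`, `"C3"`, `"C4"`, `"C9"`.
#' @return Character vector of component names in canonical order.
#' @export
tier_components <- function(tier) {
  tier <- match.arg(tier, names(.tier_components))
  .tier_components[[tier]]
}

#' Construct a tier-tagged cell state
#'
#' @param tier Model tier (`"C1"`, `"C3"`, `"C4"`, `"C9"`).
#' @param values Named numeric vector of component concentrations (uM); names
#'   must match [tier_components()] for the tier. All values must be
#'   non-negative.
#' @return A `cell_state` object (named numeric vector with a `tier`
#'   attribute).
#' @examples
#' cell_state("C3", c(Fe_cyt = 385, Fe_mit = 690, Fe_vac = 5050))
#' @export
cell_state <- function(tier, values) {
  comp <- tier_components(tier)
  if (!setequal(names(values), comp)) {
    stop("state components for tier ", tier, " must be exactly {",
         paste(comp, collapse = ", "), "}", call. = FALSE)
  }
  v <- as.numeric(values[comp])
  names(v) <- comp
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("all concentrations must be finite and non-negative", call. = FALSE)
  }
  structure(v, tier = tier, class = c("cell_state", "numeric"))
}

#' Tier of a cell state
#' @param state A `cell_state`.
#' @return The tier label.
#' @export
state_tier <- function(state) {
  t <- attr(state, "tier")
  if (is.null(t)) stop("not a tier-tagged cell state", call. = FALSE)
  t
}

#' Collapse a fine-tier state to the three-compartment tier
#'
#' Sums the speciated components within each compartment:
#' `Fe_cyt = C + CIA`, `Fe_mit = FM + FS + MP`, `Fe_vac = F2 + F3 + VP`
#' (O2 is dropped). For a four-component state, `Fe_cyt = C + CIA` with the
#' organellar totals passed through.
#'
#' @param fine A `cell_state` of tier `"C4"` or `"C9"`.
#' @return A `cell_state` of tier `"C3"`.
#' @export
collapse_state <- function(fine) {
  tier <- state_tier(fine)
  if (tier == "C9") {
    out <- c(Fe_cyt = fine[["C"]] + fine[["CIA"]],
             Fe_mit = fine[["FM"]] + fine[["FS"]] + fine[["MP"]],
             Fe_vac = fine[["F2"]] + fine[["F3"]] + fine[["VP"]])
  } else if (tier == "C4") {
    out <- c(Fe_cyt = fine[["C"]] + fine[["CIA"]],
             Fe_mit = fine[["Fe_mit"]], Fe_vac = fine[["Fe_vac"]])
  } else {
    stop("collapse_state() requires a C4 or C9 state, got ", tier,
         call. = FALSE)
  }
  cell_state("C3", out)
}

#' Whole-cell iron concentration from compartment totals
#'
#' The volume-fraction-weighted sum
#' `f_cyt*[Fe_cyt] + f_mit*[Fe_mit] + f_vac*[Fe_vac]`. Fine-tier states are
#' collapsed first, so the result is invariant under [collapse_state()].
#'
#' @param state A `cell_state` of tier `"C3"`, `"C4"`, or `"C9"`.
#' @param geometry A [compartment_geometry()].
#' @return Whole-cell iron concentration (uM).
#' @examples
#' s <- cell_state("C3", c(Fe_cyt = 385, Fe_mit = 690, Fe_vac = 5050))
#' whole_cell_total(s)  # ~882 uM
#' @export
whole_cell_total <- function(state, geometry = compartment_geometry()) {
  tier <- state_tier(state)
  if (tier == "C1") stop("whole_cell_total() requires tier C3 or finer",
                         call. = FALSE)
  s3 <- if (tier == "C3") state else collapse_state(state)
  sum(geometry * s3[c("Fe_cyt", "Fe_mit", "Fe_vac")])
}
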