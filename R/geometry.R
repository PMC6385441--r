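#' Compartment geometry (fractional volumes)
#'
#' The cell is partitioned into "cyt" (cytosol plus every organelle other than
#' mitochondria and vacuoles), mitochondria, and vacuoles. Only volume
#' *fractions* enter the model equations -- every transfer term uses ratios
#' such as `f_cyt / f_mit` -- so absolute volumes are never stored.
#'
#' @param f_cyt,f_mit,f_vac Fractional volumes, each strictly in (0, 1) and
#'   summing to 1. Defaults are the canonical respiring-yeast values
#'   0.8 / 0.1 / 0.1.
#' @return An object of class `compartment_geometry`: a named numeric vector
#'   with elements `f_cyt`, `f_mit`, `f_vac`.
#' @examples
#' g <- compartment_geometry()
#' g["f_mit"] / g["f_cyt"]  # mitochondria-to-cyt volume ratio used in transfer terms
#' @export
compartment_geometry <- function(f_cyt = 0.8, f_mit = 0.1, f_vac = 0.1) {
  g <- c(f_cyt = as.numeric(f_cyt), f_mit = as.numeric(f_mit),
         f_vac = as.numeric(f_vac))
  if (any(!is.finite(g)) || any(g <= 0) || any(g >= 1)) {
    stop("all volume fractions must lie strictly in (0, 1)", call. = FALSE)
  }
  if (abs(sum(g) - 1) > 1e-12) {
    stop("volume fractions must sum to 1 (got ", format(sum(g), digits = 15), ")",
         call. = FALSE)
  }
  class(g) <- c("compartment_geometry", "numeric")
  g
}

#' @export
print.compartment_geometry <- function(x, ...) {
  cat("Compartment geometry (volume fractions):\n")
  cat(sprintf("  cyt %.3f | mit %.3f | vac %.3f\n", x[["f_cyt"]], x[["f_mit"]],
              x[["f_vac"]]))
  invisible(x)
}
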