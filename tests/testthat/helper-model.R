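# Shared helpers for the test suite.

# Canonical parameter sets with the tier-linked pairs aligned so the four
# model tiers are exactly nested: the full-model mitochondrial rate constant
# is used at every tier and the whole-cell import capacity is the
# volume-consistent f_cyt * R_cyt_max.  Used wherever a test needs the tiers
# to agree to solver precision rather than to the few-percent level of the
# independently optimized printed values.
aligned_parameters <- function(strain, geometry = compartment_geometry()) {
  p <- canonical_parameters(strain)
  update_parameters(p,
                    k_mit_c3 = p$k_mit,
                    R_cell_max = geometry[["f_cyt"]] * p$R_cyt_max)
}

canonical_conditions <- function() {
  out <- list()
  for (s in c("WT", "DD")) for (N in c(1, 2, 11, 41)) {
    out[[paste0(s, "@", N)]] <- condition(s, N)
  }
  out
}

# Memoised full-model steady states for the canonical conditions, so that
# multiple test files can share the expensive solves within one run.
.steady_cache <- new.env(parent = emptyenv())
cached_steady <- function(strain, N) {
  key <- paste0(strain, "@", N)
  if (is.null(.steady_cache[[key]])) {
    .steady_cache[[key]] <-
      solve_steady(build_system("C9", condition(strain, N)))
  }
  .steady_cache[[key]]
}

# Relative error helper
rel_err <- function(x, ref) abs(x - ref) / abs(ref)
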