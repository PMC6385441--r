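test_that("collapse maps speciated states onto compartment totals", {
  # measured pools for wild type at N = 41
  s9 <- cell_state("C9", c(C = 5, CIA = 380, FM = 210, FS = 480, MP = 0,
                           F2 = 450, F3 = 4600, VP = 0, O2 = 1))
  s3 <- collapse_state(s9)
  expect_equal(unclass(s3),
               c(Fe_cyt = 385, Fe_mit = 690, Fe_vac = 5050),
               ignore_attr = TRUE)
  # zero maps to zero
  z <- cell_state("C9", stats::setNames(rep(0, 9), tier_components("C9")))
  expect_true(all(collapse_state(z) == 0))
  # coarse states cannot be collapsed
  expect_error(collapse_state(s3), "C4 or C9")
})

test_that("whole-cell total is the volume-weighted compartment sum and is
          collapse-invariant", {
  s9 <- cell_state("C9", c(C = 5, CIA = 380, FM = 210, FS = 480, MP = 0,
                           F2 = 450, F3 = 4600, VP = 0, O2 = 1))
  expect_equal(whole_cell_total(s9), 0.8 * 385 + 0.1 * 690 + 0.1 * 5050)
  expect_equal(whole_cell_total(s9), 882)  # printed whole-cell iron: 880
  expect_equal(whole_cell_total(collapse_state(s9)), whole_cell_total(s9))
  z <- cell_state("C3", c(Fe_cyt = 0, Fe_mit = 0, Fe_vac = 0))
  expect_equal(whole_cell_total(z), 0)
})

test_that("one-component system is pure influx at zero iron", {
  sys <- build_system("C1", condition("WT", 11))
  d <- system_derivative(sys, c(Fe_cell = 0))
  expect_gt(d[["Fe_cell"]], 0)
  expect_equal(d[["Fe_cell"]], hill_rate(11, 180, 4, 2))
})

test_that("full-model derivative vanishes at its own converged steady state", {
  res <- cached_steady("WT", 41)
  d <- system_derivative(res$system, res$state)
  expect_true(all(abs(d) <= 1e-6 * pmax(unclass(res$state), 1)))
})

test_that("the nine-component trajectory collapses onto the three-compartment
          balance at every stored point", {
  sys <- build_system("C9", condition("DD", 11))
  traj <- run_trajectory(sys, times = seq(0, 50, by = 2), tidy = FALSE)
  states <- traj[, sys$components, drop = FALSE]
  res <- collapse_residuals(sys, states)
  scale <- pmax(apply(states, 1, max), 1)
  expect_lt(max(res / scale), 1e-8)
})

test_that("mass bookkeeping: whole-cell iron changes only by import and
          dilution", {
  sys <- build_system("C9", condition("WT", 2))
  traj <- run_trajectory(sys, times = seq(0, 80, by = 4), tidy = FALSE)
  g <- sys$geometry
  for (i in seq_len(nrow(traj))) {
    y <- traj[i, sys$components]
    names(y) <- sys$components
    d <- system_derivative(sys, y)
    dtot <- g[["f_cyt"]] * (d[["C"]] + d[["CIA"]]) +
      g[["f_mit"]] * (d[["FM"]] + d[["FS"]] + d[["MP"]]) +
      g[["f_vac"]] * (d[["F2"]] + d[["F3"]] + d[["VP"]])
    tot <- whole_cell_total(cell_state("C9", pmax(y, 0)))
    r <- rate_vector(y, sys$parameters, sys$N, g)
    rhs <- g[["f_cyt"]] * r[["R_cyt"]] - sys$alpha * tot
    # absolute comparison on the flux scale: the balance crosses zero
    expect_lt(abs(dtot - rhs), 1e-9 * max(1, abs(rhs)))
  }
})

test_that("trajectories from non-negative starts stay non-negative", {
  for (cond in list(condition("WT", 1), condition("DD", 41))) {
    sys <- build_system("C9", cond)
    traj <- run_trajectory(sys, times = seq(0, 200, by = 5), tidy = FALSE)
    expect_true(all(traj[, -1] >= -1e-8))
  }
})

test_that("with organelle pathways switched off the free-iron dynamics reduce
          to the one-component model", {
  eps <- 1e-12
  g <- compartment_geometry()
  p <- update_parameters(canonical_parameters("WT"),
                         k_mit = eps, k_mit_c3 = eps, R_vac_max = eps,
                         R_cia_max = eps, R_isu_max = eps, k_mp = 1e-15,
                         k_vp = 1e-20,
                         R_cell_max = 0.8 * 230)  # align the two import tiers
  times <- seq(0, 40, by = 2)
  sys9 <- build_system("C9", condition("WT", 11), p)
  y0 <- sys9$state0
  y0[] <- 0; y0[["C"]] <- 12.5
  tr9 <- run_trajectory(sys9, times, state0 = y0, tidy = FALSE)
  sys1 <- build_system("C1", condition("WT", 11), p)
  tr1 <- run_trajectory(sys1, times, state0 = c(Fe_cell = 10), tidy = FALSE)
  expect_equal(tr9[, "C"], tr1[, "Fe_cell"] / g[["f_cyt"]],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("tidy trajectories carry the condition metadata", {
  sys <- build_system("C3", condition("WT", 2))
  tr <- run_trajectory(sys, times = c(0, 1, 2))
  expect_named(tr, c("time_hr", "component", "value_uM", "tier", "strain", "N"))
  expect_setequal(unique(tr$component), tier_components("C3"))
  expect_true(all(tr$strain == "WT") && all(tr$N == 2))
})

test_that("mismatched states are rejected", {
  expect_error(cell_state("C3", c(Fe_cyt = 1, Fe_mit = 1)), "exactly")
  expect_error(cell_state("C9", stats::setNames(rep(-1, 9),
                                                tier_components("C9"))),
               "non-negative")
  sys <- build_system("C3", condition("WT", 2))
  expect_error(run_trajectory(sys, c(0, 1), state0 = c(Fe_cyt = 1)),
               "setequal")
})
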