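test_that("one-component steady states match the closed-form dilution balance", {
  # at steady state the whole-cell iron is import rate over growth rate
  res <- solve_steady(build_system("C1", condition("WT", 1)))
  expect_true(res$converged)
  closed <- hill_rate(1, 180, 4, 2) / growth_rate(1, 0.204, 0.13)
  expect_equal(res$state[["Fe_cell"]], closed, tolerance = 1e-8)
  expect_equal(signif(res$state[["Fe_cell"]], 2), 59)  # printed as 60

  res2 <- solve_steady(build_system("C1", condition("DD", 11)))
  closed2 <- hill_rate(11, 390, 4, 2) / growth_rate(11, 0.204, 3.9)
  expect_equal(res2$state[["Fe_cell"]], closed2, tolerance = 1e-8)
  expect_equal(signif(res2$state[["Fe_cell"]], 3), 2290)  # printed 2300
})

test_that("non-convergence is flagged honestly, not raised", {
  sys <- build_system("C9", condition("DD", 11))
  res <- solve_steady(sys, tol = 1e-12, t_max = 0.01)
  expect_false(res$converged)
  expect_s3_class(res, "steady_state_result")
})

test_that("steady-state residuals of every balance line vanish at convergence", {
  res <- cached_steady("WT", 41)
  expect_true(res$converged)
  r <- steady_residuals(res)
  scale <- pmax(abs(unclass(res$state)), 1)
  # map each balance line onto a natural scale: use the state-based bound
  expect_lt(max(abs(r)) / max(scale), 1e-6)
  expect_lt(max(abs(res$residuals) / scale), 1e-9)
})

test_that("steady residuals reject coarse tiers and detect perturbed states", {
  res1 <- solve_steady(build_system("C3", condition("WT", 2)))
  expect_error(steady_residuals(res1), "C9")

  res <- cached_steady("WT", 41)
  pert <- res
  st <- unclass(res$state)
  st[["FS"]] <- st[["FS"]] * 1.1
  pert$state <- cell_state("C9", st)
  pert$rates <- rate_vector(st, res$system$parameters, res$system$N,
                            res$system$geometry)
  r <- steady_residuals(pert)
  expect_gt(abs(r[["isu"]]), 1)  # R_isu - alpha*FS is far from zero
})

test_that("stored rates are exactly reproducible from the stored state", {
  res <- cached_steady("DD", 41)
  expect_identical(res$rates,
                   rate_vector(unclass(res$state), res$system$parameters,
                               res$system$N, res$system$geometry))
})

test_that("closed-form matrix oxygen agrees with the integrated steady state", {
  for (key in list(c("WT", 41), c("DD", 41), c("DD", 1))) {
    res <- cached_steady(key[1], as.numeric(key[2]))
    s <- res$state
    closed <- o2_matrix_steady(s[["FM"]], s[["FS"]], res$rates[["alpha"]],
                               res$system$parameters)
    expect_equal(s[["O2"]], closed, tolerance = 1e-6)
  }
})

test_that("growth-rate consistency ties the tiers together at steady state", {
  res <- cached_steady("WT", 41)
  r <- res$rates
  s <- res$state
  a <- r[["alpha"]]
  g <- res$system$geometry
  # cytosolic and cellular import rates are linked by the cyt volume fraction
  expect_equal(r[["R_cyt"]],
               hill_rate(41, 230, 4, 2))
  expect_equal(hill_rate(41, 0.8 * 230, 4, 2) / g[["f_cyt"]], r[["R_cyt"]])
  # every downstream pool balances dilution
  expect_equal(r[["R_cia"]], a * s[["CIA"]], tolerance = 1e-9)
  expect_equal(r[["R_isu"]], a * s[["FS"]], tolerance = 1e-9)
  expect_equal(r[["R_mp"]], a * s[["MP"]], tolerance = 1e-9)
  expect_equal(r[["R_vp"]], a * s[["VP"]], tolerance = 1e-9)
})

test_that("initial-condition probe: unique attractor at iron-replete
          conditions, bistability detected in the low-iron switch region", {
  monostable <- list(c("WT", 11), c("WT", 41), c("DD", 11), c("DD", 41))
  for (key in monostable) {
    sys <- build_system("C9", condition(key[1], as.numeric(key[2])))
    probe <- steady_uniqueness_probe(sys, scales = c(0.1, 1, 10))
    expect_lt(probe$max_rel_disagreement, 1e-4)
  }
  # the healthy and nanoparticle-dominated attractors coexist at low N:
  # scaling the initial iron up tenfold lands on the healthy branch
  sys <- build_system("C9", condition("DD", 1))
  probe <- steady_uniqueness_probe(sys, scales = c(1, 10))
  expect_gt(probe$max_rel_disagreement, 1e-2)
})

test_that("steady_table assembles one row per condition", {
  tab <- steady_table(list(condition("WT", 41), condition("DD", 41)))
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$converged))
  expect_true(all(c("FS", "MP", "R_cyt", "alpha") %in% names(tab)))
})
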