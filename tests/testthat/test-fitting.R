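test_that("normalized error metric: hand values, symmetry, bounds", {
  expect_equal(err_metric(3, 3), 0)
  expect_equal(err_metric(1, 3), 1)
  expect_equal(err_metric(c(1, 2), c(1, 2)), 0)
  expect_equal(err_metric(c(1, 4), c(3, 4)), 0.5)
  set.seed(11)
  a <- stats::runif(50, 0, 100); b <- stats::runif(50, 0, 100)
  expect_equal(err_metric(a, b), err_metric(b, a))
  expect_lte(err_metric(a, b), 2)
  expect_warning(err_metric(c(0, 1), c(0, 1)), "skipped")
})

test_that("coordinate descent walks a quadratic to its minimum and never
          increases the objective", {
  obj <- function(p) (p[["x"]] - 5)^2 + 1
  fit <- coordinate_descent(obj, c(x = 2), max_cycles = 100)
  expect_lt(abs(fit$par[["x"]] - 5) / 5, 0.02)
  acc <- fit$history[fit$history$accepted, "objective"]
  expect_true(all(diff(acc) < 0))
  expect_lte(fit$value, obj(c(x = 2)))
})

test_that("coordinate descent is deterministic and rejects non-finite
          candidates", {
  obj <- function(p) {
    if (p[["x"]] > 2.5) return(NaN)
    (p[["x"]] - 2)^2
  }
  f1 <- coordinate_descent(obj, c(x = 2.4))
  f2 <- coordinate_descent(obj, c(x = 2.4))
  expect_identical(f1$history, f2$history)
  expect_true(all(is.finite(f1$history$objective[f1$history$accepted])))
  expect_lte(f1$par[["x"]], 2.5)
})

test_that("sensitivity indices: ignored parameter gives exactly 1, scaling is
          by definition, zero optimum errors", {
  obj <- function(p) 2 + (p[["a"]] - 1)^2  # ignores b
  rep <- sensitivity_scan(obj, c(a = 1, b = 7))
  expect_equal(rep$S[["b"]], 1)
  expect_equal(rep$S[["a"]], 1 + (0.01)^2 / 2)  # (2+1e-4 + 2+1e-4) / 4
  obj0 <- function(p) 0
  expect_error(sensitivity_scan(obj0, c(a = 1)), "undefined")
})

test_that("sensitivity grows with perturbation size at a smooth minimum", {
  obj <- function(p) 1 + (p[["a"]] - 1)^2 + (p[["b"]] - 2)^2
  s1 <- sensitivity_scan(obj, c(a = 1, b = 2), delta = 0.01)$S
  s2 <- sensitivity_scan(obj, c(a = 1, b = 2), delta = 0.02)$S
  expect_true(all(s2 >= s1))
})

test_that("tier transfer: cytosolic capacity initializes from the whole-cell
          capacity over f_cyt, and the mitochondrial constant is rescaled for
          the full model", {
  # one condition per strain suffices here (no optimizer steps are taken),
  # at the price of the expected identifiability warning
  obs <- load_fixture_tables()[c(2, 6)]
  fit <- suppressWarnings(
    fit_tiered(obs, tiers = "C3", schedule = numeric(0),
               final_joint = FALSE))
  expect_equal(fit$parameters$WT$R_cyt_max, 180 / 0.8)  # 225, printed 230
  expect_lt(abs(fit$parameters$WT$R_cyt_max - 230) / 230, 0.03)
  expect_equal(fit$parameters$DD$R_cyt_max, 390 / 0.8)

  start <- list(WT = canonical_parameters("WT"),
                DD = canonical_parameters("DD"))
  fit9 <- suppressWarnings(
    fit_tiered(obs, start = start, tiers = "C9",
               schedule = numeric(0), final_joint = FALSE))
  expect_equal(fit9$parameters$WT$k_mit, 2 * 2.8)   # 5.6 ~ bundled 5.5
  expect_equal(fit9$parameters$DD$k_mit, 1.6 / 1.3) # 1.23 ~ bundled 1.2
  expect_lt(abs(fit9$parameters$WT$k_mit - 5.5) / 5.5, 0.02)
  expect_lt(abs(fit9$parameters$DD$k_mit - 1.2) / 1.2, 0.03)
})

test_that("an underdetermined stage warns explicitly but still runs", {
  obs <- load_fixture_tables()[2]  # a single wild-type condition
  w <- character(0)
  withCallingHandlers(
    fit <- fit_tiered(obs, tiers = "C1", schedule = numeric(0),
                      final_joint = FALSE),
    warning = function(x) {
      w <<- c(w, conditionMessage(x)); invokeRestart("muffleWarning")
    })
  expect_true(any(grepl("fewer than 2 N values", w)))
  expect_s3_class(fit, "fit_result")
})

test_that("growth-tier fit recovers known parameters from noise-free
          synthetic observations", {
  cfg <- synthetic_config(N_values = 2^seq(0, log2(41), length.out = 8),
                          noise_cv = 0, seed = 1)
  obs <- generate_observations(cfg)
  truth <- list(WT = canonical_parameters("WT"),
                DD = canonical_parameters("DD"))
  start <- list(
    WT = update_parameters(truth$WT, alpha_max = 0.204 * 1.25,
                           K_alpha = 0.13 * 0.8, R_cell_max = 180 * 1.25,
                           K_N = 4 * 1.25, sens = 2 * 1.2),
    DD = update_parameters(truth$DD, K_alpha = 3.9 * 0.8,
                           R_cell_max = 390 * 1.25))
  fit <- fit_tiered(obs, start = start, tiers = "C1", final_joint = FALSE)
  expect_lt(fit$err_by_tier[["C1"]], 0.02)
  got <- fit$parameters
  expect_lt(rel_err(got$WT$alpha_max, 0.204), 0.05)
  expect_lt(rel_err(got$WT$K_alpha, 0.13), 0.05)
  expect_lt(rel_err(got$DD$K_alpha, 3.9), 0.05)
  expect_lt(rel_err(got$WT$K_N, 4), 0.05)
  expect_lt(rel_err(got$WT$sens, 2), 0.05)
  # the cellular capacity converges to the volume-consistent effective value
  expect_lt(rel_err(got$WT$R_cell_max, 0.8 * 230), 0.05)
  expect_lt(rel_err(got$DD$R_cell_max, 0.8 * 480), 0.05)
})

test_that("with aligned tiers and noise-free data every stage is already
          optimal: tiny error, no parameter moves beyond one step", {
  truth <- list(WT = aligned_parameters("WT"), DD = aligned_parameters("DD"))
  cfg <- synthetic_config(true_parameters = truth, N_values = c(2, 41),
                          noise_cv = 0, seed = 1)
  obs <- generate_observations(cfg)
  fit <- fit_tiered(obs, start = truth, tiers = c("C1", "C3", "C4", "C9"),
                    schedule = 0.01, final_joint = FALSE,
                    transfer_R_cyt = FALSE, kmit_rescale = FALSE,
                    max_cycles = 2)
  expect_true(all(fit$err_by_tier < 1e-3))
  # audit: no stage moved any parameter by more than one 1% step
  for (stage in names(fit$stage_changes)) {
    h <- fit$history[fit$history$stage == stage & fit$history$accepted, ]
    expect_lte(nrow(h), length(unique(h$parameter)))
  }
})

test_that("earlier-stage parameters are untouched by later stages except the
          prescribed transfer and rescale", {
  obs <- load_fixture_tables()[c(2, 6)]
  start <- list(WT = canonical_parameters("WT"),
                DD = canonical_parameters("DD"))
  fit <- suppressWarnings(
    fit_tiered(obs, start = start, tiers = c("C1", "C4"),
               schedule = numeric(0), final_joint = FALSE,
               transfer_R_cyt = FALSE))
  # no optimizer steps were allowed, so every parameter is exactly the start
  for (s in c("WT", "DD")) {
    expect_identical(unclass(fit$parameters[[s]]), unclass(start[[s]]))
  }
  expect_true(all(vapply(fit$stage_changes, length, integer(1)) == 0))
})
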