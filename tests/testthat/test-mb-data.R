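test_that("pool/group maps are exact inverses for arbitrary non-negative pools", {
  set.seed(7)
  for (i in 1:20) {
    pools <- stats::setNames(stats::runif(8, 0, 5000),
                             c("C", "CIA", "FM", "FS", "MP", "F2", "F3", "VP"))
    g <- groups_from_pools(pools)
    back <- pools_from_groups(g, C_assumed = pools[["C"]])
    expect_equal(back, pools, tolerance = 1e-12)
  }
})

test_that("wild-type iron-replete groups invert to the printed pools and
          conserve whole-cell iron", {
  pools <- c(C = 5, CIA = 380, FM = 210, FS = 480, MP = 0,
             F2 = 450, F3 = 4600, VP = 0)
  groups <- groups_from_pools(pools)
  back <- pools_from_groups(groups, C_assumed = 5)
  expect_equal(back, pools)
  comp <- c(Fe_cyt = 385, Fe_mit = 690, Fe_vac = 5050)
  total <- sum(compartment_geometry() * comp)
  expect_equal(total, 882)
  expect_lt(abs(total - 880) / 880, 0.10)  # printed whole-cell iron
})

test_that("degenerate and inconsistent group inputs are handled", {
  zero <- mb_groups(0, 0, 0, 0, 0, 0, 0)
  expect_true(all(pools_from_groups(zero, C_assumed = 0) == 0))
  # a cytosolic assumption larger than the whole-cell Fe(II) pool is
  # inconsistent and must name the offending pool
  g <- groups_from_pools(c(C = 1, CIA = 10, FM = 10, FS = 10, MP = 0,
                           F2 = 1, F3 = 0, VP = 0))
  expect_error(pools_from_groups(g, C_assumed = 50), "F2")
  expect_error(mb_groups(-1, 0, 0, 0, 0, 0, 0), "non-negative")
})

test_that("data-based fluxes follow the dilution algebra", {
  rec <- observation_record(
    condition("WT", 1), alpha_dat = 0.18, Fe_cell_dat = 120,
    pools_dat = c(C = 2.5, CIA = 92, FM = 60, FS = 320, MP = 0,
                  F2 = 600, F3 = 0, VP = 0),
    compartments_dat = c(Fe_cyt = 98.75, Fe_mit = 410, Fe_vac = 0))
  fl <- data_based_fluxes(rec)
  expect_equal(fl[["R_cell"]], 21.6)              # printed 22
  expect_equal(fl[["R_mit"]], 0.18 * 410 / 8)     # 9.225, printed 9.2
  expect_equal(fl[["R_cyt"]], 21.6 / 0.8)
  expect_equal(fl[["R_vac"]], 0)
  expect_equal(fl[["R_isu"]], 0.18 * 320)
  # the zero-growth limit carries zero fluxes
  rec0 <- rec; rec0$alpha_dat <- 0
  fl0 <- data_based_fluxes(rec0)
  expect_true(all(fl0 == 0))
  # missing pools are an error
  recNA <- rec; recNA$pools_dat[["F3"]] <- NA
  expect_error(data_based_fluxes(recNA), "missing pools")
})

test_that("bundled observation tables load as eight self-consistent records", {
  recs <- load_fixture_tables()
  expect_length(recs, 8)
  keys <- vapply(recs, function(r) paste0(r$condition$strain, "@",
                                          r$condition$N), character(1))
  expect_setequal(keys, c("WT@1", "WT@2", "WT@11", "WT@41",
                          "DD@1", "DD@2", "DD@11", "DD@41"))
  wt2 <- recs[[which(keys == "WT@2")]]
  expect_equal(wt2$alpha_dat, 0.18)
  expect_equal(wt2$Fe_cell_dat, 200)
  fl <- wt2$fluxes_dat
  expect_equal(fl[["R_cell"]], 36, tolerance = 0.05)   # printed 37
  expect_equal(fl[["R_mit"]], 9.675, tolerance = 1e-9) # printed 9.9
  expect_equal(fl[["R_vac"]], 18.45, tolerance = 1e-9) # printed 19
  # every record conserves mass within the 2-significant-figure rounding
  for (rec in recs) {
    total <- sum(rec$geometry * rec$compartments_dat)
    expect_lt(abs(total - rec$Fe_cell_dat) / rec$Fe_cell_dat, 0.10)
  }
})

test_that("recomputed fluxes reproduce the printed rate cells within the
          rounding tolerance", {
  audit <- validate_fixtures()
  expect_true(attr(audit, "ok"))
  expect_equal(nrow(audit), 8)
})

test_that("the fixture loader validates its schema", {
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(load_fixture_tables(path = bad), "columns")
})
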