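make_plate <- function(doses, viab_by_dose, blank = 0.1, vehicle = 1.1,
                       reps = 2, drug = "drugX") {
  rows <- list(
    data.frame(drug = drug, dose = NA_real_, unit = "nM",
               replicate = seq_len(reps), absorbance = blank,
               role = "blank"),
    data.frame(drug = drug, dose = NA_real_, unit = "nM",
               replicate = seq_len(reps), absorbance = vehicle,
               role = "vehicle"))
  for (i in seq_along(doses)) {
    abs_i <- blank + (vehicle - blank) * viab_by_dose[i]
    rows[[length(rows) + 1]] <- data.frame(
      drug = drug, dose = doses[i], unit = "nM",
      replicate = seq_len(reps), absorbance = abs_i, role = "treated")
  }
  do.call(rbind, rows)
}

test_that("plate normalization computes fraction-of-vehicle viability", {
  raw <- make_plate(c(10, 100), c(0.5, 0.2))
  dr <- normalize_plate(raw)
  # blank 0.1, vehicle 1.1, well 0.6 -> (0.6-0.1)/(1.1-0.1) = 0.5
  expect_equal(dr$viability$viability[dr$viability$dose == 10], c(0.5, 0.5))
  expect_equal(dr$viability$viability[dr$viability$dose == 100],
               c(0.2, 0.2))
  # well equal to vehicle mean -> viability 1
  raw1 <- make_plate(10, 1.0)
  expect_equal(normalize_plate(raw1)$viability$viability, c(1, 1))
  # replicates preserved, not pre-averaged
  expect_equal(nrow(dr$viability), 4)

  # well below blank: negative viability retained with warning
  rawneg <- make_plate(10, 0.5)
  rawneg$absorbance[rawneg$role == "treated"] <- 0.05
  expect_warning(drn <- normalize_plate(rawneg), "negative")
  expect_lt(drn$viability$viability[1], 0)

  # uninterpretable plate: vehicle <= blank
  rawbad <- make_plate(10, 0.5, blank = 1.0, vehicle = 0.9)
  expect_error(normalize_plate(rawbad), "uninterpretable")
})

test_that("default dose grids match the published designs", {
  das <- default_dose_grid("dasatinib")
  expect_equal(das$doses, c(50, 100, 200, 500, 1000, 5000))
  expect_equal(das$unit, "nM")
  tbb <- default_dose_grid("tbb")
  expect_equal(tbb$doses, c(10, 20, 50, 100, 200, 500))
  expect_equal(tbb$unit, "uM")
})

test_that("noiseless 4PL round-trips recover the generating curve", {
  doses <- default_dose_grid("dasatinib")$doses
  truth <- list(lower = 0, upper = 1, ec50 = 300, hill = 1.2)
  dr <- dose_response("x", data.frame(
    dose = rep(doses, each = 2), replicate = 1:2,
    viability = rep(fourpl(doses, truth$lower, truth$upper, truth$ec50,
                           truth$hill), each = 2)))
  fit <- fit_4pl(dr)
  expect_true(fit$converged)
  expect_equal(fit$ec50, truth$ec50, tolerance = 0.01)
  expect_equal(fit$lower, truth$lower, tolerance = 0.02)
  expect_equal(fit$upper, truth$upper, tolerance = 0.02)
})

test_that("analytic IC50 identities hold", {
  # symmetric curve: IC50 equals ec50
  f1 <- list(lower = 0, upper = 1, ec50 = 120, hill = 1,
             dose_range = c(10, 5000))
  expect_equal(ic50_from_fit(f1), 120)
  # lower = 0.25 case: 0.5 = 0.25 + 0.75/(1 + c/100) crosses at c = 200
  f2 <- list(lower = 0.25, upper = 1, ec50 = 100, hill = 1,
             dose_range = c(10, 5000))
  expect_equal(ic50_from_fit(f2), 200)
  # fitted-curve consistency: the fitted curve crosses 0.5 at the ic50
  doses <- c(10, 50, 100, 500, 1000, 5000)
  dr <- dose_response("x", data.frame(
    dose = doses, replicate = 1,
    viability = fourpl(doses, 0.25, 1, 100, 1)))
  fit <- fit_4pl(dr)
  expect_equal(fit$ic50, 200, tolerance = 0.01)
  expect_equal(fourpl(fit$ic50, fit$lower, fit$upper, fit$ec50, fit$hill),
               0.5, tolerance = 1e-6)
})

test_that("IC50 is censored as not reached when the curve misses 0.5", {
  # plateau at 60% viability: the published no-IC50 situation
  f <- list(lower = 0.60, upper = 1, ec50 = 100, hill = 1,
            dose_range = c(10, 5000))
  expect_true(is.na(ic50_from_fit(f)))
  # crossing outside the tested range
  f2 <- list(lower = 0, upper = 1, ec50 = 1e6, hill = 1,
             dose_range = c(10, 5000))
  expect_true(is.na(ic50_from_fit(f2)))
  # property: any fit with lower >= 0.5 is censored
  set.seed(31)
  for (i in 1:50) {
    f3 <- list(lower = runif(1, 0.5, 1), upper = runif(1, 1, 1.5),
               ec50 = 10^runif(1, 1, 3), hill = runif(1, 0.2, 5),
               dose_range = c(1, 1e4))
    expect_true(is.na(ic50_from_fit(f3)))
  }
})

test_that("random noiseless generator round-trips recover ec50 and ic50", {
  set.seed(32)
  doses <- exp(seq(log(10), log(10000), length.out = 8))
  for (i in 1:50) {
    truth <- list(lower = runif(1, 0, 0.35), upper = 1,
                  ec50 = 10^runif(1, 1.7, 3.3), hill = runif(1, 0.8, 2.5))
    dr <- dose_response("x", data.frame(
      dose = doses, replicate = 1,
      viability = fourpl(doses, truth$lower, truth$upper, truth$ec50,
                         truth$hill)))
    fit <- fit_4pl(dr)
    expect_equal(fit$ec50, truth$ec50, tolerance = 0.05)
    ic_true <- truth$ec50 * ((truth$upper - 0.5) /
                               (0.5 - truth$lower))^(1 / truth$hill)
    if (ic_true >= min(doses) && ic_true <= max(doses)) {
      expect_equal(fit$ic50, ic_true, tolerance = 1e-3)
    }
  }
})

test_that("flat plates produce a degenerate but labelled fit", {
  dr <- dose_response("x", data.frame(dose = c(10, 100, 1000, 10000),
                                      replicate = 1, viability = 1))
  fit <- fit_4pl(dr)
  expect_lt(fit$rss, 1e-6)
  expect_true(is.na(fit$ic50))
  expect_error(fit_4pl(dose_response("x", data.frame(
    dose = c(10, 100, 1000), replicate = 1, viability = 1))), ">= 4")
})

test_that("noisy quadruplicate fits recover ec50 on the published grids", {
  recovered <- vapply(1:60, function(s) {
    tr <- preset_viability_truth("tbb", noise_sd = 0.02, seed = 9000 + s)
    raw <- simulate_viability(default_dose_grid("tbb")$doses, tr,
                              n_replicates = 4, drug = "tbb", unit = "uM")
    fit <- fit_4pl(normalize_plate(raw))
    abs(fit$ec50 - tr$ec50) / tr$ec50
  }, numeric(1))
  expect_gte(mean(recovered <= 0.1), 0.9)
})

test_that("the dasatinib-shaped preset yields a censored IC50", {
  tr <- preset_viability_truth("dasatinib", noise_sd = 0.02, seed = 4)
  raw <- simulate_viability(default_dose_grid("dasatinib")$doses, tr,
                            n_replicates = 4, drug = "dasatinib")
  fit <- fit_4pl(normalize_plate(raw))
  expect_true(is.na(fit$ic50))
  expect_false(fit$ic50_reached)
  expect_gt(fit$lower, 0.5)
})

test_that("Bliss combination analysis flags the published enhancement pattern", {
  # worked example: mono-A 0.80, fixed-B 0.50, combo 0.05
  mono <- dose_response("dasatinib", data.frame(
    dose = c(500, 5000), replicate = 1, viability = c(0.85, 0.80)))
  combo <- dose_response("dasatinib+tbb", data.frame(
    dose = c(500, 5000), replicate = 1, viability = c(0.05, 0.05)))
  res <- analyze_combination(mono, 0.50, combo)
  row <- res$table[res$table$dose == 5000, ]
  expect_equal(row$bliss_expected, 0.40)
  expect_equal(row$excess, 0.35)
  expect_true(res$enhancement_flag)
  expect_equal(res$statistic, "enhancement (Bliss excess)")

  # independence null: excess 0, not flagged
  combo_null <- dose_response("c", data.frame(
    dose = c(500, 5000), replicate = 1, viability = c(0.85, 0.80) * 0.5))
  res0 <- analyze_combination(mono, 0.50, combo_null)
  expect_equal(res0$table$excess, c(0, 0))
  expect_false(res0$enhancement_flag)

  # neutral element: both monotherapies at viability 1
  mono1 <- dose_response("a", data.frame(dose = 10, replicate = 1,
                                         viability = 1))
  combo1 <- dose_response("c", data.frame(dose = 10, replicate = 1,
                                          viability = 1))
  res1 <- analyze_combination(mono1, 1.0, combo1, min_doses = 1)
  expect_equal(res1$table$bliss_expected, 1)

  # no shared doses is an error
  combo_off <- dose_response("c", data.frame(dose = 7, replicate = 1,
                                             viability = 0.5))
  expect_error(analyze_combination(mono, 0.5, combo_off), "shared")
})
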