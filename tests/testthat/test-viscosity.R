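noiseless_points <- function(a = 0.41, b = 0.021,
                             cc = c(120, 150, 180, 200), mab = "mabA") {
  tibble::tibble(
    sample_id = paste0("b", seq_along(cc)), mab_id = mab,
    compound_id = NA_character_, concentration_mg_ml = cc,
    viscosity_cp = a * exp(b * cc), ph = 6, excipient_mm = 0
  )
}

test_that("baseline fit recovers exact parameters from noiseless data", {
  fit <- fit_baseline(noiseless_points())
  expect_equal(fit$a, 0.41, tolerance = 1e-9)
  expect_equal(fit$b, 0.021, tolerance = 1e-9)
  expect_lt(fit$rms_log_residual, 1e-12)

  two <- fit_baseline(noiseless_points(cc = c(130, 170)))
  expect_equal(two$rms_log_residual, 0, tolerance = 1e-12)
  expect_equal(two$n_points, 2L)

  expect_error(fit_baseline(noiseless_points(cc = c(150, 150))),
               class = "vra_fit_error")
  expect_error(fit_baseline(noiseless_points()[0, ]), class = "vra_fit_error")
})

test_that("baseline fit recovers the growth rate under multiplicative noise", {
  a <- 0.5; b <- 0.02
  bs <- replicate(200, {
    cc <- seq(120, 200, length.out = 50)
    eta <- a * exp(b * cc) * exp(rnorm(50, 0, sqrt(log(1 + 0.05^2))))
    pts <- tibble::tibble(mab_id = "m", compound_id = NA_character_,
                          concentration_mg_ml = cc, viscosity_cp = eta)
    fit_baseline(pts)$b
  })
  expect_lt(abs(mean(bs) - b) / b, 0.02)
})

test_that("relative viscosity is the measured-over-baseline ratio", {
  fit <- fit_baseline(noiseless_points())
  on_curve <- noiseless_points()[2, ]
  on_curve$compound_id <- "cmpd"
  rel <- relative_viscosity(on_curve, fit)
  expect_equal(rel$rel_visc, 1.0, tolerance = 1e-12)

  m <- on_curve
  m$viscosity_cp <- 0.6 * m$viscosity_cp
  expect_equal(relative_viscosity(m, fit)$rel_visc, 0.6, tolerance = 1e-12)

  m$viscosity_cp <- 12
  m$concentration_mg_ml <- log(20 / fit$a) / fit$b  # baseline predicts 20 cP
  expect_equal(relative_viscosity(m, fit)$rel_visc, 0.6, tolerance = 1e-9)

  up <- on_curve
  up$viscosity_cp <- up$viscosity_cp * 1.4  # viscosity-increasing excipient
  expect_gt(relative_viscosity(up, fit)$rel_visc, 1)

  far <- on_curve
  far$concentration_mg_ml <- 240
  expect_warning(relative_viscosity(far, fit), "extrapolate")

  expect_error(relative_viscosity(dplyr::mutate(on_curve, mab_id = "other"),
                                  fit),
               class = "vra_fit_error")
})

test_that("relative viscosities of the fitted baseline points average one", {
  set.seed(4)
  cc <- seq(120, 200, length.out = 30)
  pts <- tibble::tibble(mab_id = "m", compound_id = NA_character_,
                        concentration_mg_ml = cc,
                        viscosity_cp = 0.3 * exp(0.028 * cc) *
                          exp(rnorm(30, 0, 0.05)))
  fit <- fit_baseline(pts)
  rel <- relative_viscosity(pts, fit)
  expect_equal(mean(log(rel$rel_visc)), 0, tolerance = 1e-10)
})

test_that("VRA classification averages across antibodies with inclusive cutoff", {
  fits <- dplyr::bind_rows(
    fit_baseline(noiseless_points(mab = "mabA")),
    fit_baseline(noiseless_points(a = 0.35, b = 0.025, mab = "mabB"))
  )
  class(fits) <- c("vra_baseline_fit", class(fits))
  mk <- function(id, rA, rB) {
    # build viscosities from the fitted curves so the planted ratios are exact
    dplyr::bind_rows(
      tibble::tibble(sample_id = paste0(id, "A"), mab_id = "mabA",
                     compound_id = id, concentration_mg_ml = 150,
                     viscosity_cp = rA * predict_baseline(fits, "mabA", 150),
                     ph = 6, excipient_mm = 25),
      tibble::tibble(sample_id = paste0(id, "B"), mab_id = "mabB",
                     compound_id = id, concentration_mg_ml = 150,
                     viscosity_cp = rB * predict_baseline(fits, "mabB", 150),
                     ph = 6, excipient_mm = 25)
    )
  }
  m <- dplyr::bind_rows(mk("at_cut", 0.8, 0.8), mk("mixed", 0.6, 0.9),
                        mk("flat", 1.0, 1.0))
  rec <- classify_vra(m, fits)
  expect_true(rec$is_vra[rec$compound_id == "at_cut"])    # 0.8 inclusive
  expect_true(rec$is_vra[rec$compound_id == "mixed"])     # mean 0.75
  expect_equal(rec$avg_rel_visc[rec$compound_id == "mixed"], 0.75,
               tolerance = 1e-9)
  expect_false(rec$is_vra[rec$compound_id == "flat"])

  # invariant to antibody ordering
  rec2 <- classify_vra(m[nrow(m):1, ], fits)
  expect_equal(rec$avg_rel_visc, rec2$avg_rel_visc)

  expect_warning(classify_vra(noiseless_points(), fits), "no excipient")
})

test_that("measurement CSV round-trips through the reader", {
  f <- tempfile(fileext = ".csv")
  m <- noiseless_points()
  m$compound_id[1] <- "arg"
  readr::write_csv(m, f)
  back <- read_measurements(f)
  expect_equal(back$compound_id[1], "arg")
  expect_true(all(is.na(back$compound_id[-1])))
  expect_equal(back$viscosity_cp, m$viscosity_cp)
})

test_that("tested-compound tables classify with the same inclusive threshold", {
  f <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    compound_id = c("T001", "T002", "T003"),
    rel_visc_mabA = c(0.55, 0.85, 1.02),
    rel_visc_mabB = c(0.65, 0.75, 0.98)
  ), f)
  got <- read_tested_compounds(f)
  expect_equal(got$avg_rel_visc, c(0.60, 0.80, 1.00))
  expect_equal(got$is_vra, c(TRUE, TRUE, FALSE))
})
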