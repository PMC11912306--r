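test_that("responses are derived by direct embryo counting per endpoint", {
  set <- make_tiny_set()
  cum <- derive_responses(set, "S1", "cumulative", 0, 96)
  # pooled over both experiments (same substance and exposure design):
  # 1 umol/L: t1 has edema, t2 normal -> 1/2; 5 umol/L: the E2 embryo has
  # only a quantitative record -> 0/1; 10 umol/L: coagulated + two
  # sublethal effects -> 2/2
  expect_equal(cum$concentration_umol_L, c(1, 5, 10))
  expect_equal(cum$n_affected, c(1L, 0L, 2L))
  expect_equal(cum$n_total, c(2L, 1L, 2L))
  let <- derive_responses(set, "S1", "lethal", 0, 96)
  expect_equal(let$n_affected, c(0L, 0L, 1L))  # only coagulation counts
  expect_true(all(cum$n_affected >= let$n_affected))
  expect_error(derive_responses(set, "NOPE", "lethal", 0, 96),
               "no matching treatments")
})

test_that("flat null matches its closed form", {
  d <- tibble::tibble(concentration_umol_L = c(1, 3, 10),
                      n_affected = c(10L, 10L, 10L), n_total = 20L)
  flat <- fit_flat_null(d)
  expect_equal(flat$flat_p, 0.5)
  expect_equal(flat$loglik, loglik_oracle(d$n_affected, d$n_total, 0.5))
  expect_equal(flat$aic, 2 - 2 * flat$loglik)
})

test_that("maximum likelihood agrees with a grid-search oracle on a toy set", {
  d <- tibble::tibble(concentration_umol_L = c(1, 5, 25),
                      n_affected = c(2L, 9L, 17L), n_total = 20L)
  for (fam in c("LL2", "W12", "W22")) {
    fit <- fit_drm(d, fam)
    sgn <- if (fam == "W22") 1 else -1
    grid <- expand.grid(b = sgn * exp(seq(log(0.05), log(20), length.out = 400)),
                        eta = seq(log(0.2), log(150), length.out = 400))
    p <- mapply(function(b, eta) {
      loglik_oracle(d$n_affected, d$n_total,
                    pmin(pmax(curve_oracle(fam, b, exp(eta),
                                           d$concentration_umol_L),
                              1e-12), 1 - 1e-12))
    }, grid$b, grid$eta)
    expect_gte(fit$loglik, max(p) - 1e-3)
    expect_lte(abs(fit$loglik - max(p)), 1e-1)  # grid is coarse
  }
})

test_that("effective concentrations invert the curve in closed form", {
  d <- simulate_counts("LL2", -2, 10,
                       exp(seq(log(0.5), log(200), length.out = 7)), 200)
  # deterministic counts for this check
  d$n_affected <- round(d$n_total * curve_oracle("LL2", -2, 10,
                                                 d$concentration_umol_L))
  fit <- select_drm(d)
  expect_true(fit$valid)
  # LL2 EC50 is the location parameter itself
  if (fit$family == "LL2") {
    expect_equal(effective_concentration(fit, 50)$value, fit$e)
  }
  ec <- effective_concentration(fit, c(5, 50, 99))
  expect_true(all(diff(ec$value) > 0))  # EC5 < EC50 < EC99
  # forward evaluation returns the level for every family
  for (fam in c("LL2", "W12", "W22")) {
    b <- if (fam == "W22") 1.7 else -1.7
    f <- structure(list(family = fam, b = b, e = 12, vcov = NULL,
                        valid = TRUE, invalid_reasons = character()),
                   class = "zfet_fit")
    for (level in c(1, 5, 50, 99)) {
      cc <- effective_concentration(f, level)$value
      expect_equal(curve_oracle(fam, b, 12, cc), level / 100,
                   tolerance = 1e-10)
    }
  }
  # hand-computed W22 EC50 with unit slope: e * ln 2
  f22 <- structure(list(family = "W22", b = 1, e = 10, vcov = NULL,
                        valid = TRUE, invalid_reasons = character()),
                   class = "zfet_fit")
  expect_equal(effective_concentration(f22, 50)$value, 10 * log(2),
               tolerance = 1e-12)
})

test_that("AIC ordering between families ignores the binomial constant", {
  set.seed(11)
  d <- simulate_counts("LL2", -2, 10,
                       exp(seq(log(0.5), log(200), length.out = 7)), 50)
  fits <- lapply(c("LL2", "W12", "W22"), function(f) fit_drm(d, f))
  const <- sum(lchoose(d$n_total, d$n_affected))
  aic_with <- vapply(fits, `[[`, 0, "aic")
  aic_without <- aic_with + 2 * const  # dropping the constant shifts all alike
  expect_equal(order(aic_with), order(aic_without))
})

test_that("validity gates fire on flat, out-of-range and unstable fits", {
  # gate i: no dose signal
  flat_d <- tibble::tibble(concentration_umol_L = c(1, 3, 10, 30),
                           n_affected = 5L, n_total = 20L)
  sel <- select_drm(flat_d)
  expect_false(sel$valid)
  expect_true("AIC not below flat null" %in% sel$invalid_reasons)
  flat <- fit_flat_null(flat_d)
  for (fam in c("LL2", "W12", "W22")) {
    f <- fit_drm(flat_d, fam)
    if (is.finite(f$aic)) expect_gte(f$aic, flat$aic - 2)
  }

  # gate ii: curve location far above the tested range
  set.seed(21)
  concs <- exp(seq(log(0.1), log(10), length.out = 7))
  d2 <- simulate_counts("LL2", -2, 100, concs, 100)
  sel2 <- select_drm(d2)
  expect_false(sel2$valid)
  expect_true(any(grepl("EC50 above maximum tested", sel2$invalid_reasons)) ||
                any(grepl("AIC not below flat null", sel2$invalid_reasons)))

  # gate iii: tiny, noisy data cannot pin the EC50 down
  d3 <- tibble::tibble(concentration_umol_L = c(1, 100),
                       n_affected = c(1L, 2L), n_total = 3L)
  sel3 <- select_drm(d3)
  expect_false(sel3$valid)

  # degenerate data are flagged, not fitted
  all_aff <- tibble::tibble(concentration_umol_L = c(1, 10),
                            n_affected = 10L, n_total = 10L)
  f <- fit_drm(all_aff, "LL2")
  expect_false(f$converged)
  expect_match(f$invalid_reasons, "degenerate")
})

test_that("model selection recovers a planted log-logistic curve", {
  concs <- exp(seq(log(10 / 30), log(10 * 30), length.out = 7))
  set.seed(31)
  hits <- 0; rel_err <- numeric(0)
  for (i in 1:30) {
    d <- simulate_counts("LL2", -2, 10, concs, 200)
    if (sum(d$n_affected) == 0 || sum(d$n_affected) == sum(d$n_total)) next
    sel <- select_drm(d)
    others <- attr(sel, "all_fits")
    # the selected family's loglik is no worse than the other sigmoids'
    for (fam in c("LL2", "W12", "W22")) {
      if (is.finite(others[[fam]]$loglik)) {
        expect_gte(sel$loglik + 1e-6, others[[fam]]$loglik - 1)
      }
    }
    if (sel$valid) {
      ec50 <- effective_concentration(sel, 50)$value
      rel_err <- c(rel_err, abs(ec50 - 10) / 10)
      hits <- hits + 1
    }
  }
  expect_gte(hits, 25)
  expect_lte(median(rel_err), 0.15)
})

test_that("sensitivity ratios divide LC50 by EC50 and propagate absence", {
  ec <- tibble::tibble(level = 50, value = 10, se = 1)
  lc <- tibble::tibble(level = 50, value = 50, se = 5)
  expect_equal(sensitivity_ratio(lc, ec)$sr, 5)
  expect_equal(sensitivity_ratio(ec, ec)$sr, 1)
  # fit table with no valid lethal fits yields an empty SR table, not zeros
  fits <- tibble::tibble(
    substance_id = "S", substance_name = "s", endpoint = "cumulative",
    exposure_start_hpf = 0L, ec50 = 10, ec50_se = 1, valid = TRUE)
  expect_equal(nrow(sensitivity_ratios(fits)), 0)
})

test_that("tidy and glance expose fit parameters", {
  set.seed(41)
  d <- simulate_counts("LL2", -2, 10,
                       exp(seq(log(0.5), log(200), length.out = 7)), 100)
  fit <- fit_drm(d, "LL2")
  td <- tidy(fit)
  expect_equal(td$term, c("b", "log_e"))
  expect_equal(td$estimate[2], log(fit$e))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(fit)
  expect_equal(gl$aic, 4 - 2 * fit$loglik)
})
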