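# Two-parameter dose-response modelling ---------------------------------------
#
# Families, parameterized in (b, eta = ln e), concentration c in umol/L:
#   LL2: p(c) = 1 / (1 + exp(b * (ln c - eta)))          monotone up for b < 0
#   W12: p(c) = exp(-exp(b * (ln c - eta)))              monotone up for b < 0
#   W22: p(c) = 1 - exp(-exp(b * (ln c - eta)))          monotone up for b > 0
# e is the location parameter (the EC50 for LL2); b the (dimensionless) slope.

.drm_families <- c("LL2", "W12", "W22")

.drm_p <- function(family, b, eta, conc) {
  z <- b * (log(conc) - eta)
  switch(family,
         LL2 = 1 / (1 + exp(z)),
         W12 = exp(-exp(z)),
         W22 = 1 - exp(-exp(z)),
         stop("unknown family: ", family, call. = FALSE))
}

# g(p) such that ln ECp = eta + g(p) / b
.drm_g <- function(family, p) {
  switch(family,
         LL2 = log((1 - p) / p),
         W12 = log(-log(p)),
         W22 = log(-log(1 - p)),
         stop("unknown family: ", family, call. = FALSE))
}

# sign restriction making p(c) non-decreasing in c
.drm_b_sign <- function(family) if (family == "W22") 1 else -1

.grouped_binom_loglik <- function(k, n, p) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(lchoose(n, k) + k * log(p) + (n - k) * log(1 - p))
}

.new_zfet_fit <- function(family, b = NA_real_, e = NA_real_,
                          loglik = NA_real_, n_params, vcov = NULL,
                          data = NULL, converged = FALSE,
                          valid = FALSE, invalid_reasons = character(),
                          flat_p = NA_real_) {
  structure(
    list(family = family, b = b, e = e, loglik = loglik,
         aic = 2 * n_params - 2 * loglik, n_params = n_params,
         vcov = vcov, data = data, converged = converged,
         valid = valid, invalid_reasons = invalid_reasons, flat_p = flat_p),
    class = "zfet_fit"
  )
}

#' Derive grouped binomial responses for a substance
#'
#' Builds the per-concentration affected/total counts for dose-response
#' modelling from raw observations. Under the `"lethal"` endpoint an embryo
#' is affected iff it carries the "coagulated" effect at `observation_hpf`;
#' under `"cumulative"` iff it carries any lethal or sublethal effect (i.e.
#' anything but "normal"; uninformative and quantitative terms do not count).
#' Embryos whose record at the observation time is "no embryo" are excluded
#' from the denominators. Controls (concentration 0) are excluded; replicate
#' experiments with the same design (substance, exposure start) are pooled.
#'
#' @param set A `zfet_set`.
#' @param substance_id Substance identifier as used in the treatments table.
#' @param endpoint `"cumulative"` or `"lethal"`.
#' @param exposure_start_hpf Exposure start of the experiments to use.
#' @param observation_hpf Observation time at which responses are scored.
#' @param vocab Effect vocabulary.
#' @return A tibble (class `zfet_drdata`) with columns
#'   `concentration_umol_L`, `n_affected`, `n_total`, sorted by
#'   concentration; design fields are carried in attributes.
#' @export
derive_responses <- function(set, substance_id,
                             endpoint = c("cumulative", "lethal"),
                             exposure_start_hpf = 0, observation_hpf = 96,
                             vocab = zfet_vocabulary()) {
  endpoint <- match.arg(endpoint)
  exp_ids <- set$experiments$experiment_id[
    set$experiments$exposure_start_hpf == exposure_start_hpf]
  trts <- dplyr::filter(set$treatments,
                        .data$experiment_id %in% exp_ids,
                        .data$substance_id == !!substance_id,
                        !.data$is_control, !.data$is_solvent_control,
                        .data$concentration_umol_L > 0)
  if (nrow(trts) == 0) {
    stop("no matching treatments for substance ", substance_id,
         " with exposure start ", exposure_start_hpf, " hpf", call. = FALSE)
  }
  obs <- dplyr::filter(set$observations,
                       .data$treatment_id %in% trts$treatment_id,
                       .data$time_hpf == observation_hpf)
  if (nrow(obs) == 0) {
    stop("no observations at ", observation_hpf, " hpf for substance ",
         substance_id, call. = FALSE)
  }
  affected_ids <- if (endpoint == "lethal") {
    vocab$effect_id[vocab$category == "lethal"]
  } else {
    vocab$effect_id[vocab$category %in% c("lethal", "sublethal")]
  }
  no_embryo <- vocab$effect_id[vocab$effect == "no embryo"]
  out <- obs |>
    dplyr::left_join(dplyr::select(trts, "treatment_id",
                                   "concentration_umol_L"),
                     by = "treatment_id") |>
    dplyr::group_by(.data$concentration_umol_L, .data$experiment_id,
                    .data$embryo_id) |>
    dplyr::summarise(
      affected = any(.data$effect_id %in% affected_ids),
      absent = all(.data$effect_id %in% no_embryo),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$absent) |>
    dplyr::group_by(concentration_umol_L = .data$concentration_umol_L) |>
    dplyr::summarise(n_affected = sum(.data$affected),
                     n_total = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$concentration_umol_L)
  if (nrow(out) < 2) {
    stop("fewer than 2 distinct positive concentrations for substance ",
         substance_id, call. = FALSE)
  }
  structure(out, class = c("zfet_drdata", class(out)),
            substance_id = substance_id, endpoint = endpoint,
            exposure_start_hpf = exposure_start_hpf,
            observation_hpf = observation_hpf)
}

.check_drdata <- function(data) {
  stopifnot(all(c("concentration_umol_L", "n_affected", "n_total") %in%
                  names(data)))
  if (any(data$concentration_umol_L <= 0))
    stop("concentrations must be strictly positive (controls excluded)",
         call. = FALSE)
  if (any(data$n_affected > data$n_total))
    stop("n_affected exceeds n_total", call. = FALSE)
  if (dplyr::n_distinct(data$concentration_umol_L) < 2)
    stop("need at least 2 distinct concentrations", call. = FALSE)
  invisible(data)
}

#' Fit a two-parameter dose-response model by maximum likelihood
#'
#' Fits the binomial response with one of three two-parameter mean curves
#' (log-logistic `"LL2"`, Weibull-1 `"W12"`, Weibull-2 `"W22"`), constrained
#' to be non-decreasing in concentration by a sign restriction on the slope.
#' Optimisation is over `(b, ln e)` with multiple starts: `ln e` at the
#' concentrations bracketing 50% observed response and `|b|` over a small
#' grid; the best start wins. The covariance of `(b, ln e)` comes from the
#' observed information at the optimum; the log-likelihood is the grouped
#' binomial one, binomial coefficients included.
#'
#' @param data A `zfet_drdata` tibble (or any tibble with
#'   `concentration_umol_L`, `n_affected`, `n_total`).
#' @param family `"LL2"`, `"W12"` or `"W22"`.
#' @return A `zfet_fit` object with elements `family`, `b`, `e`, `loglik`,
#'   `aic`, `vcov` (2x2 over `(b, ln e)`), `converged`, `valid`,
#'   `invalid_reasons`.
#' @export
fit_drm <- function(data, family = c("LL2", "W12", "W22")) {
  family <- match.arg(family)
  .check_drdata(data)
  k <- data$n_affected; n <- data$n_total; conc <- data$concentration_umol_L
  if (sum(k) == 0 || sum(k) == sum(n)) {
    return(.new_zfet_fit(family, n_params = 2, data = data,
                         invalid_reasons = "degenerate data (all or none affected)"))
  }
  sgn <- .drm_b_sign(family)
  negll <- function(par) {
    b <- sgn * exp(par[1])
    -.grouped_binom_loglik(k, n, .drm_p(family, b, par[2], conc))
  }
  # starts: ln e near the 50%-response bracket and at the log-midpoint
  prop <- k / n
  lc <- log(conc)
  eta_starts <- unique(c(lc[which.min(abs(prop - 0.5))], mean(range(lc))))
  b_starts <- log(c(0.5, 1, 2, 4))
  best <- NULL
  for (eta0 in eta_starts) {
    for (lb0 in b_starts) {
      opt <- tryCatch(
        stats::optim(c(lb0, eta0), negll, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
        best <- opt
      }
    }
  }
  if (is.null(best) || !is.finite(best$value)) {
    return(.new_zfet_fit(family, n_params = 2, data = data,
                         invalid_reasons = "no convergence"))
  }
  b_hat <- sgn * exp(best$par[1])
  eta_hat <- best$par[2]
  # observed information in the (b, ln e) parameterization
  negll_raw <- function(par) {
    -.grouped_binom_loglik(k, n, .drm_p(family, par[1], par[2], conc))
  }
  vcov <- tryCatch({
    H <- stats::optimHess(c(b_hat, eta_hat), negll_raw)
    V <- solve(H)
    dimnames(V) <- list(c("b", "log_e"), c("b", "log_e"))
    V
  }, error = function(e) NULL)
  reasons <- character()
  if (is.null(vcov) || any(!is.finite(vcov)) || any(diag(vcov) < 0)) {
    vcov <- NULL
    reasons <- "unstable information matrix"
  }
  .new_zfet_fit(family, b = b_hat, e = exp(eta_hat), loglik = -best$value,
                n_params = 2, vcov = vcov, data = data,
                converged = best$convergence == 0,
                invalid_reasons = reasons)
}

#' Fit the flat (no dose effect) null model
#'
#' Constant-probability binomial model with MLE
#' `p = sum(n_affected) / sum(n_total)`, one parameter, same likelihood
#' convention as [fit_drm()]. Its AIC is the bar a sigmoid fit must beat to
#' count as evidence of a dose effect.
#'
#' @inheritParams fit_drm
#' @return A `zfet_fit` with `family = "flat"` and `flat_p` the fitted
#'   proportion.
#' @export
fit_flat_null <- function(data) {
  .check_drdata(data)
  p_hat <- sum(data$n_affected) / sum(data$n_total)
  ll <- .grouped_binom_loglik(data$n_affected, data$n_total,
                              rep(p_hat, nrow(data)))
  .new_zfet_fit("flat", loglik = ll, n_params = 1, data = data,
                converged = TRUE, flat_p = p_hat)
}

# ECx without the validity check (used while applying the validity gates)
.ecx <- function(fit, level) {
  p <- level / 100
  if (p <= 0 || p >= 1) stop("level must be in (0, 100)", call. = FALSE)
  g <- .drm_g(fit$family, p)
  log_c <- log(fit$e) + g / fit$b
  value <- exp(log_c)
  se <- NA_real_
  if (!is.null(fit$vcov)) {
    grad <- c(-g / fit$b^2, 1)  # d ln c / d(b, ln e)
    var_log_c <- drop(t(grad) %*% fit$vcov %*% grad)
    if (is.finite(var_log_c) && var_log_c >= 0) se <- value * sqrt(var_log_c)
  }
  tibble::tibble(level = level, value = value, se = se)
}

#' Effective concentration at a response level
#'
#' Inverts the fitted curve in closed form: the concentration at which the
#' modelled response equals `level`% (absolute 0-1 scale). The standard error
#' follows by the delta method from the `(b, ln e)` covariance. For the LL2
#' family the EC50 equals the location parameter `e` exactly.
#'
#' @param fit A valid `zfet_fit` from [fit_drm()] or [select_drm()].
#' @param level Response level(s) in percent, in (0, 100).
#' @param check_valid Refuse fits that failed the validity gates
#'   (default `TRUE`).
#' @return A tibble with columns `level`, `value` (umol/L), `se`.
#' @export
effective_concentration <- function(fit, level, check_valid = TRUE) {
  stopifnot(inherits(fit, "zfet_fit"))
  if (fit$family == "flat") {
    stop("effective concentrations are undefined for the flat null",
         call. = FALSE)
  }
  if (check_valid && !isTRUE(fit$valid)) {
    stop("fit is not valid (", paste(fit$invalid_reasons, collapse = "; "),
         ")", call. = FALSE)
  }
  if (!is.finite(fit$b)) stop("fit did not converge", call. = FALSE)
  purrr::map_dfr(level, function(l) .ecx(fit, l))
}

#' Fit all families, select by AIC and apply the validity gates
#'
#' Fits the LL2, W12 and W22 families plus the flat null, selects the
#' lowest-AIC sigmoid (ties below 1e-6 broken in the fixed order LL2, W12,
#' W22) and marks it valid only if all three gates hold: (i) its AIC is
#' lower than the flat null's, (ii) the predicted EC50 is below the maximum
#' tested concentration, and (iii) the standard error of the EC50 is smaller
#' than the EC50 itself.
#'
#' @inheritParams fit_drm
#' @param cmax Maximum tested concentration (defaults to the largest
#'   concentration in `data`).
#' @return The selected `zfet_fit` with `valid`/`invalid_reasons` set and the
#'   flat-null AIC in `$aic_flat`; all candidate fits in
#'   `attr(fit, "all_fits")`.
#' @export
select_drm <- function(data, cmax = max(data$concentration_umol_L)) {
  .check_drdata(data)
  flat <- fit_flat_null(data)
  fits <- purrr::map(.drm_families, function(f) fit_drm(data, f))
  names(fits) <- .drm_families
  ok <- purrr::map_lgl(fits, function(f) is.finite(f$aic))
  if (!any(ok)) {
    out <- .new_zfet_fit("none", n_params = 2, data = data,
                         invalid_reasons = unique(unlist(
                           purrr::map(fits, "invalid_reasons"))))
    out$aic_flat <- flat$aic
    attr(out, "all_fits") <- c(fits, list(flat = flat))
    return(out)
  }
  aics <- purrr::map_dbl(fits, "aic")
  aics[!ok] <- Inf
  best <- fits[[which(aics <= min(aics) + 1e-6)[1]]]  # fixed-order tie break
  reasons <- character()
  if (!best$converged) reasons <- c(reasons, "no convergence")
  if (!(best$aic < flat$aic)) reasons <- c(reasons, "AIC not below flat null")
  ec50 <- .ecx(best, 50)
  if (!is.finite(ec50$value) || ec50$value >= cmax) {
    reasons <- c(reasons, "EC50 above maximum tested concentration")
  }
  if (!is.finite(ec50$se) || ec50$se >= ec50$value) {
    reasons <- c(reasons, "EC50 standard error not below EC50")
  }
  best$valid <- length(reasons) == 0
  best$invalid_reasons <- c(best$invalid_reasons, reasons)
  best$aic_flat <- flat$aic
  attr(best, "all_fits") <- c(fits, list(flat = flat))
  best
}

#' Sensitivity ratio of lethal to overall toxicity
#'
#' The sensitivity ratio SR = LC50 / EC50 compares the lethal median
#' concentration with the median concentration for any effect. Values close
#' to 1 mean sublethal effects appear only near lethal concentrations;
#' values well above 1 flag substances with sublethal or teratogenic effects
#' far below lethal levels (the teratogenic-index idea).
#'
#' @param lc50,ec50 One-row tibbles from [effective_concentration()] (level
#'   50) for the lethal and cumulative fits of the same substance/design.
#' @return A one-row tibble: `lc50`, `lc50_se`, `ec50`, `ec50_se`, `sr`.
#' @export
sensitivity_ratio <- function(lc50, ec50) {
  stopifnot(nrow(lc50) == 1, nrow(ec50) == 1)
  lv <- lc50$value; ls <- lc50$se; ev <- ec50$value; es <- ec50$se
  tibble::tibble(lc50 = lv, lc50_se = ls, ec50 = ev, ec50_se = es,
                 sr = lv / ev)
}

#' Fit dose-response models for every substance and design in a set
#'
#' Convenience wrapper around [derive_responses()] and [select_drm()]:
#' iterates over all single-substance treatments, exposure starts and the
#' two endpoints, and returns one row per (substance, exposure start,
#' endpoint) with the selected model, its parameters, the EC50 and the
#' validity verdict. Substances/designs whose data cannot support a fit
#' (e.g. a single concentration) are reported with `family = NA`.
#'
#' @param set A `zfet_set`.
#' @param observation_hpf Observation time (default 96).
#' @param endpoints Endpoints to fit (default both).
#' @param vocab Effect vocabulary.
#' @return A tibble with columns `substance_id`, `substance_name`,
#'   `endpoint`, `exposure_start_hpf`, `observation_hpf`, `family`, `b`,
#'   `e`, `aic`, `aic_flat`, `ec50`, `ec50_se`, `valid`, `invalid_reasons`
#'   and a `fit` list-column.
#' @export
fit_all_drms <- function(set, observation_hpf = 96,
                         endpoints = c("cumulative", "lethal"),
                         vocab = zfet_vocabulary()) {
  single_exps <- set$experiments |>
    dplyr::filter(.data$substance_type == "single")
  designs <- set$treatments |>
    dplyr::filter(!.data$is_control, !.data$is_solvent_control) |>
    dplyr::inner_join(dplyr::select(single_exps, "experiment_id",
                                    "exposure_start_hpf"),
                      by = "experiment_id") |>
    dplyr::distinct(.data$substance_id, .data$substance_name,
                    .data$exposure_start_hpf)
  grid <- tidyr::expand_grid(designs, endpoint = endpoints)
  res <- purrr::pmap(grid, function(substance_id, substance_name,
                                    exposure_start_hpf, endpoint) {
    fit <- tryCatch({
      dat <- derive_responses(set, substance_id, endpoint,
                              exposure_start_hpf, observation_hpf, vocab)
      select_drm(dat)
    }, error = function(e) NULL)
    row <- tibble::tibble(
      substance_id = substance_id, substance_name = substance_name,
      endpoint = endpoint, exposure_start_hpf = exposure_start_hpf,
      observation_hpf = observation_hpf
    )
    if (is.null(fit)) {
      return(dplyr::mutate(row, family = NA_character_, b = NA_real_,
                           e = NA_real_, aic = NA_real_, aic_flat = NA_real_,
                           ec50 = NA_real_, ec50_se = NA_real_, valid = FALSE,
                           invalid_reasons = "no usable data",
                           fit = list(NULL)))
    }
    ec <- if (is.finite(fit$b)) .ecx(fit, 50) else
      tibble::tibble(value = NA_real_, se = NA_real_)
    dplyr::mutate(row, family = fit$family, b = fit$b, e = fit$e,
                  aic = fit$aic, aic_flat = fit$aic_flat %||% NA_real_,
                  ec50 = ec$value, ec50_se = ec$se, valid = fit$valid,
                  invalid_reasons = paste(fit$invalid_reasons,
                                          collapse = "; "),
                  fit = list(fit))
  })
  dplyr::bind_rows(res)
}

#' Sensitivity ratios for all substances in a fitted table
#'
#' Pairs each substance/design's valid cumulative fit (EC50) with its valid
#' lethal fit (LC50) and computes SR = LC50 / EC50. Designs missing either
#' valid component are omitted (SR is undefined, not zero).
#'
#' @param fits Output of [fit_all_drms()] covering both endpoints.
#' @return A tibble with one row per (substance, exposure start) for which
#'   both components are valid: `substance_id`, `substance_name`,
#'   `exposure_start_hpf`, `lc50`, `lc50_se`, `ec50`, `ec50_se`, `sr`.
#' @export
sensitivity_ratios <- function(fits) {
  valid <- dplyr::filter(fits, .data$valid)
  wide <- valid |>
    dplyr::select("substance_id", "substance_name", "exposure_start_hpf",
                  "endpoint", "ec50", "ec50_se") |>
    tidyr::pivot_wider(names_from = "endpoint",
                       values_from = c("ec50", "ec50_se"))
  if (!all(c("ec50_cumulative", "ec50_lethal") %in% names(wide))) {
    return(tibble::tibble(substance_id = character(),
                          substance_name = character(),
                          exposure_start_hpf = integer(),
                          lc50 = double(), lc50_se = double(),
                          ec50 = double(), ec50_se = double(), sr = double()))
  }
  wide |>
    dplyr::filter(!is.na(.data$ec50_cumulative), !is.na(.data$ec50_lethal)) |>
    dplyr::transmute(
      .data$substance_id, .data$substance_name, .data$exposure_start_hpf,
      lc50 = .data$ec50_lethal, lc50_se = .data$ec50_se_lethal,
      ec50 = .data$ec50_cumulative, ec50_se = .data$ec50_se_cumulative,
      sr = .data$lc50 / .data$ec50
    )
}

# broom-style accessors --------------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dose-response fit
#'
#' @param x A `zfet_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`b`, `log_e`) and columns
#'   `term`, `estimate`, `std.error`.
#' @export
tidy.zfet_fit <- function(x, ...) {
  if (x$family == "flat") {
    return(tibble::tibble(term = "p", estimate = x$flat_p,
                          std.error = NA_real_))
  }
  se <- if (!is.null(x$vcov)) sqrt(diag(x$vcov)) else rep(NA_real_, 2)
  tibble::tibble(term = c("b", "log_e"),
                 estimate = c(x$b, log(x$e)),
                 std.error = unname(se))
}

#' One-row summary of a dose-response fit
#'
#' @param x A `zfet_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `family`, `b`, `e`, `loglik`, `aic`,
#'   `n_params`, `converged`, `valid`, `invalid_reasons`.
#' @export
glance.zfet_fit <- function(x, ...) {
  tibble::tibble(family = x$family, b = x$b, e = x$e, loglik = x$loglik,
                 aic = x$aic, n_params = x$n_params, converged = x$converged,
                 valid = x$valid,
                 invalid_reasons = paste(x$invalid_reasons, collapse = "; "))
}

#' @export
print.zfet_fit <- function(x, ...) {
  cat("<zfet_fit> family:", x$family)
  if (is.finite(x$b)) {
    cat(sprintf("  b = %.4g, e = %.4g umol/L, AIC = %.2f", x$b, x$e, x$aic))
  }
  cat("\n  valid:", x$valid)
  if (length(x$invalid_reasons) > 0) {
    cat("  (", paste(x$invalid_reasons, collapse = "; "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}
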