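# Experiment pre-filter and binomial control-quality gate ---------------------

#' Quality-control configuration
#'
#' Bundles the thresholds of the control-quality workflow. The defaults are
#' the study values: controls are tested against a binomial null with
#' p(normal) = 0.936 at significance 0.05 (one-sided, lower tail, no
#' multiplicity adjustment — the aim is to limit type II error, i.e. to keep
#' only experiments whose controls are compatible with the pooled rate), and
#' experiments with fewer than 9 control embryos, fewer than 15 embryos in
#' total or fewer than 2 experimental conditions are excluded outright.
#'
#' @param p_normal Null probability that an unexposed embryo is "normal" at
#'   the final observation (default 0.936, the pooled rate of the study).
#' @param alpha One-sided significance level (default 0.05).
#' @param min_controls Minimum control embryos at the final observation
#'   (default 9).
#' @param min_embryos Pre-filter: minimum embryos per experiment (default 15).
#' @param min_conditions Pre-filter: minimum distinct experimental conditions
#'   including the control (default 2).
#' @param adjust_pvalues Apply Benjamini-Hochberg adjustment across the set
#'   before gating (default `FALSE`; enabling it is logged as a deviation
#'   from the reference workflow).
#' @param survival_gate Use the alternative 90%-control-survival rule
#'   (OECD TG 236) instead of the binomial normality gate (default `FALSE`).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(p_normal = 0.936, alpha = 0.05, min_controls = 9,
                      min_embryos = 15, min_conditions = 2,
                      adjust_pvalues = FALSE, survival_gate = FALSE) {
  stopifnot(p_normal > 0, p_normal < 1, alpha > 0, alpha < 1)
  structure(list(p_normal = p_normal, alpha = alpha,
                 min_controls = min_controls, min_embryos = min_embryos,
                 min_conditions = min_conditions,
                 adjust_pvalues = adjust_pvalues,
                 survival_gate = survival_gate),
            class = "qc_config")
}

# per-experiment final control observation: one row per control embryo with
# its status at the experiment's last time point that has control records.
# "no embryo" rows terminate an embryo's record and drop it from denominators.
.final_control_status <- function(set) {
  ctrl_ids <- .control_treatment_ids(set)
  ctrl_obs <- dplyr::filter(set$observations,
                            .data$treatment_id %in% ctrl_ids)
  if (nrow(ctrl_obs) == 0) {
    stop("experiment set contains no control observations", call. = FALSE)
  }
  ctrl_obs |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::mutate(final_hpf = max(.data$time_hpf)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$time_hpf == .data$final_hpf) |>
    dplyr::group_by(.data$experiment_id, .data$embryo_id, .data$final_hpf) |>
    dplyr::summarise(
      is_normal = any(.data$effect_id == .normal_id),
      is_coagulated = any(.data$effect_id == .lethal_id),
      is_absent = all(.data$effect_id == .uninformative_ids[1]),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$is_absent)
}

#' Pooled control normal and survival rates
#'
#' Pools control embryos over all experiments and reports the proportion that
#' are "normal" at their experiment's final observation time, and separately
#' the proportion that survive (are not "coagulated") until then. The pooled
#' normal rate is the empirical estimate behind the binomial null of
#' [control_quality_test()].
#'
#' @param set A `zfet_set` containing control treatments.
#' @return A one-row tibble: `n_controls`, `n_normal`, `normal_rate`,
#'   `n_surviving`, `survival_rate`.
#' @export
pooled_control_rates <- function(set) {
  status <- .final_control_status(set)
  tibble::tibble(
    n_controls = nrow(status),
    n_normal = sum(status$is_normal),
    normal_rate = mean(status$is_normal),
    n_surviving = sum(!status$is_coagulated),
    survival_rate = mean(!status$is_coagulated)
  )
}

#' Pre-filter experiments with limited data
#'
#' Fails an experiment if it has fewer than `min_embryos` embryos in total or
#' fewer than `min_conditions` distinct experimental conditions (distinct
#' exposure concentrations, counting the control as one condition).
#'
#' @param set A `zfet_set`.
#' @param config A [qc_config()].
#' @return A tibble with one row per experiment: `experiment_id`,
#'   `n_embryos`, `n_conditions`, `passed_prefilter`, `reasons`.
#' @export
qc_prefilter <- function(set, config = qc_config()) {
  n_embryos <- set$observations |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::summarise(n_embryos = dplyr::n_distinct(.data$embryo_id),
                     .groups = "drop")
  n_cond <- set$treatments |>
    dplyr::mutate(condition = dplyr::if_else(
      .data$is_control | .data$is_solvent_control,
      "control", as.character(.data$concentration_umol_L))) |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::summarise(n_conditions = dplyr::n_distinct(.data$condition),
                     .groups = "drop")
  set$experiments |>
    dplyr::select("experiment_id") |>
    dplyr::left_join(n_embryos, by = "experiment_id") |>
    dplyr::left_join(n_cond, by = "experiment_id") |>
    dplyr::mutate(
      n_embryos = dplyr::coalesce(.data$n_embryos, 0L),
      n_conditions = dplyr::coalesce(.data$n_conditions, 0L),
      passed_prefilter = .data$n_embryos >= config$min_embryos &
        .data$n_conditions >= config$min_conditions,
      reasons = purrr::map2_chr(
        .data$n_embryos, .data$n_conditions,
        function(ne, nc) {
          r <- character()
          if (ne < config$min_embryos)
            r <- c(r, sprintf("fewer than %d embryos", config$min_embryos))
          if (nc < config$min_conditions)
            r <- c(r, "only one tested experimental condition")
          paste(r, collapse = "; ")
        })
    )
}

#' Lower-tail binomial p-value of a control count
#'
#' The elementary statistic of the control gate: the exact probability that
#' a `Binomial(n_controls, p_normal)` variable is at most
#' `n_normal`. Vectorised.
#'
#' @param n_normal Number of "normal" control embryos observed.
#' @param n_controls Number of control embryos.
#' @param p_normal Null normal probability (default 0.936).
#' @return Numeric p-value(s) in `[0, 1]`.
#' @export
control_quality_pvalue <- function(n_normal, n_controls, p_normal = 0.936) {
  stopifnot(all(n_normal >= 0), all(n_normal <= n_controls))
  stats::pbinom(n_normal, n_controls, p_normal)
}

#' One-sided binomial control-quality test
#'
#' For each experiment, tests whether the number of "normal" control embryos
#' at the final observation time is compatible with a binomial null
#' `X ~ Binomial(n, p_normal)`. The p-value is the exact lower-tail
#' cumulative probability `P(X <= k)`; the experiment fails the gate when the
#' p-value is below `alpha` (the alternative p(normal) < p_normal is
#' accepted) or when fewer than `min_controls` control embryos are available.
#' P-values are not multiplicity-adjusted unless `config$adjust_pvalues`.
#'
#' With `config$survival_gate = TRUE` the binomial test is replaced by the
#' fixed-threshold rule that at least 90% of control embryos survive.
#'
#' @inheritParams qc_prefilter
#' @return A tibble with one row per experiment that has control
#'   observations: `experiment_id`, `final_hpf`, `n_controls`,
#'   `n_normal_controls`, `p_value`, `passed_control_gate`, `reasons`.
#' @export
control_quality_test <- function(set, config = qc_config()) {
  status <- .final_control_status(set)
  res <- status |>
    dplyr::group_by(.data$experiment_id, .data$final_hpf) |>
    dplyr::summarise(
      n_controls = dplyr::n(),
      n_normal_controls = sum(.data$is_normal),
      n_surviving = sum(!.data$is_coagulated),
      .groups = "drop"
    )
  if (config$survival_gate) {
    res <- res |>
      dplyr::mutate(
        p_value = NA_real_,
        survival = .data$n_surviving / .data$n_controls,
        passed_control_gate = .data$survival >= 0.9 &
          .data$n_controls >= config$min_controls,
        reasons = dplyr::case_when(
          .data$n_controls < config$min_controls ~
            sprintf("fewer than %d control embryos", config$min_controls),
          .data$survival < 0.9 ~ "control survival below 90%",
          .default = ""
        )
      ) |>
      dplyr::select(-"survival")
    return(res)
  }
  res <- dplyr::mutate(
    res,
    p_value = control_quality_pvalue(.data$n_normal_controls,
                                     .data$n_controls, config$p_normal)
  )
  if (config$adjust_pvalues) {
    message("control_quality_test: applying BH p-value adjustment ",
            "(deviation from the unadjusted reference workflow)")
    res$p_value <- stats::p.adjust(res$p_value, method = "BH")
  }
  dplyr::mutate(
    res,
    passed_control_gate = .data$p_value >= config$alpha &
      .data$n_controls >= config$min_controls,
    reasons = dplyr::case_when(
      .data$n_controls < config$min_controls &
        .data$p_value < config$alpha ~
        sprintf("fewer than %d control embryos; control quality below null",
                config$min_controls),
      .data$n_controls < config$min_controls ~
        sprintf("fewer than %d control embryos", config$min_controls),
      .data$p_value < config$alpha ~ "control quality below binomial null",
      .default = ""
    )
  )
}

#' Apply the full quality-control cascade
#'
#' Runs the pre-filter and the control-quality gate and returns the surviving
#' subset of experiments, with the per-experiment report attached as
#' `attr(result, "qc_report")`. Filtering is idempotent.
#'
#' @inheritParams qc_prefilter
#' @return A filtered `zfet_set`.
#' @export
qc_filter <- function(set, config = qc_config()) {
  pre <- qc_prefilter(set, config)
  gate <- control_quality_test(set, config)
  report <- pre |>
    dplyr::left_join(dplyr::select(gate, -"reasons"), by = "experiment_id") |>
    dplyr::left_join(dplyr::select(gate, "experiment_id",
                                   gate_reasons = "reasons"),
                     by = "experiment_id") |>
    dplyr::mutate(
      passed_control_gate = dplyr::coalesce(.data$passed_control_gate, FALSE),
      passed = .data$passed_prefilter & .data$passed_control_gate,
      reasons = dplyr::if_else(
        .data$reasons == "" | is.na(.data$reasons),
        dplyr::coalesce(.data$gate_reasons, "no control observations"),
        .data$reasons)
    ) |>
    dplyr::select(-"gate_reasons")
  out <- filter_experiments(set, report$experiment_id[report$passed])
  attr(out, "qc_report") <- report
  out
}
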