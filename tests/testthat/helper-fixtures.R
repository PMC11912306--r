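# Hand-built fixtures used across test files

# A minimal two-experiment set built row by row: one experiment with a
# concentration series and mixed outcomes, one small control-heavy one.
make_tiny_set <- function() {
  experiments <- tibble::tibble(
    experiment_id = c("E1", "E2"),
    substance_type = "single",
    exposure_start_hpf = 0L,
    container_type = c("well24", "vial"),
    temperature_C = 26, date = NA_character_, strain = "wt"
  )
  treatments <- tibble::tibble(
    treatment_id = c("E1_C", "E1_T1", "E1_T2", "E2_C", "E2_T1"),
    experiment_id = c("E1", "E1", "E1", "E2", "E2"),
    substance_id = c("CONTROL", "S1", "S1", "CONTROL", "S1"),
    substance_name = c("control", "subst1", "subst1", "control", "subst1"),
    concentration_umol_L = c(0, 1, 10, 0, 5),
    is_control = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    is_solvent_control = FALSE
  )
  obs_row <- function(exp, emb, trt, t, eff, val = 1, row = "A", col = 1L) {
    tibble::tibble(experiment_id = exp, embryo_id = emb, treatment_id = trt,
                   well_row = row, well_col = col, time_hpf = t,
                   effect_id = eff, value = val)
  }
  observations <- dplyr::bind_rows(
    # E1: 2 controls normal, 2 exposed embryos at 1 umol/L (one with edema),
    # 2 at 10 umol/L (one coagulated, one with two effects)
    obs_row("E1", "c1", "E1_C", 48, 3), obs_row("E1", "c1", "E1_C", 96, 3),
    obs_row("E1", "c2", "E1_C", 48, 3), obs_row("E1", "c2", "E1_C", 96, 3),
    obs_row("E1", "t1", "E1_T1", 48, 3), obs_row("E1", "t1", "E1_T1", 96, 44),
    obs_row("E1", "t2", "E1_T1", 48, 3), obs_row("E1", "t2", "E1_T1", 96, 3),
    obs_row("E1", "t3", "E1_T2", 48, 2), obs_row("E1", "t3", "E1_T2", 96, 2),
    obs_row("E1", "t4", "E1_T2", 48, 25),
    obs_row("E1", "t4", "E1_T2", 96, 44), obs_row("E1", "t4", "E1_T2", 96, 50),
    # E2: one control, one exposed with a quantitative heart rate
    obs_row("E2", "c1", "E2_C", 96, 3),
    obs_row("E2", "t1", "E2_T1", 96, 41, val = 132)
  )
  zfet_set(experiments, treatments, observations)
}

# grouped binomial counts from a known curve, for fitting tests
simulate_counts <- function(family, b, e, conc, n) {
  p <- switch(family,
              LL2 = 1 / (1 + exp(b * (log(conc) - log(e)))),
              W12 = exp(-exp(b * (log(conc) - log(e)))),
              W22 = 1 - exp(-exp(b * (log(conc) - log(e)))))
  tibble::tibble(
    concentration_umol_L = conc,
    n_affected = stats::rbinom(length(conc), n, p),
    n_total = n
  )
}

# independent log-likelihood oracle: plain sum over groups, written directly
loglik_oracle <- function(k, n, p) {
  sum(lchoose(n, k) + k * log(p) + (n - k) * log(1 - p))
}

# curve evaluation independent of the package internals
curve_oracle <- function(family, b, e, conc) {
  z <- b * (log(conc) - log(e))
  switch(family,
         LL2 = 1 / (1 + exp(z)),
         W12 = exp(-exp(z)),
         W22 = 1 - exp(-exp(z)))
}

# controls-only fixture: n controls of which k normal at 96 hpf, plus a
# dose group so the set is well-formed
make_control_set <- function(k_normal_by_exp, n_by_exp) {
  stopifnot(length(k_normal_by_exp) == length(n_by_exp))
  ids <- sprintf("E%d", seq_along(n_by_exp))
  experiments <- tibble::tibble(
    experiment_id = ids, substance_type = "single",
    exposure_start_hpf = 0L, container_type = "well96",
    temperature_C = NA_real_, date = NA_character_, strain = NA_character_)
  treatments <- dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    tibble::tibble(
      treatment_id = paste0(ids[i], c("_C", "_T1", "_T2")),
      experiment_id = ids[i],
      substance_id = c("CONTROL", "S", "S"),
      substance_name = c("control", "s", "s"),
      concentration_umol_L = c(0, 1, 10),
      is_control = c(TRUE, FALSE, FALSE), is_solvent_control = FALSE)
  }))
  observations <- dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    n <- n_by_exp[i]; k <- k_normal_by_exp[i]
    dplyr::bind_rows(
      tibble::tibble(
        experiment_id = ids[i], embryo_id = sprintf("c%03d", seq_len(n)),
        treatment_id = paste0(ids[i], "_C"), well_row = "A",
        well_col = 1L, time_hpf = 96L,
        effect_id = c(rep(3L, k), rep(44L, n - k)), value = 1),
      tibble::tibble(
        experiment_id = ids[i], embryo_id = c("t1", "t2"),
        treatment_id = paste0(ids[i], c("_T1", "_T2")), well_row = "B",
        well_col = 1L, time_hpf = 96L, effect_id = 2L, value = 1))
  }))
  zfet_set(experiments, treatments, observations)
}
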