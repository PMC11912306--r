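# Seeded synthetic ZFET studies with known ground truth ------------------------

#' Default substance archetype library
#'
#' Four effect-profile archetypes used by the study generator, loosely
#' covering the kinds of phenotypic clusters seen in real screens: a
#' coagulant (lethality dominates, sensitivity ratio near 1), a
#' hatching/cardiovascular profile (strong sublethal effects far below
#' lethal concentrations, with a planted "decreased heartbeat" to
#' "no heartbeat" worsening over time), a hypopigmentation profile, and a
#' behavioural profile. Labels are descriptive only.
#'
#' Each archetype carries the true two-parameter lethal and cumulative
#' dose-response curves (family, slope `b`, location `e` in umol/L; the
#' cumulative `e` is at or below the lethal `e`), a conditional effect
#' profile — the probability that an affected-but-alive embryo exhibits each
#' effect — and optional transition rules mapping an early effect to its
#' later, typically more severe, successor.
#'
#' @return A named list of archetypes; each is a list with elements `name`,
#'   `lethal` (`family`, `b`, `e`), `cumulative` (`family`, `b`, `e`),
#'   `profile` (named numeric, names are effect ids) and `transitions`
#'   (list of `list(from, to, prob)`).
#' @export
zfet_archetypes <- function() {
  list(
    coagulant = list(
      name = "coagulant",
      lethal = list(family = "LL2", b = -3, e = 10),
      cumulative = list(family = "LL2", b = -3, e = 8),
      profile = c("15" = 0.5, "25" = 0.3),  # necrosis, developmental delay
      transitions = list()
    ),
    no_hatch_heartbeat = list(
      name = "no_hatch_heartbeat",
      lethal = list(family = "LL2", b = -2, e = 50),
      cumulative = list(family = "LL2", b = -2, e = 5),
      profile = c("50" = 0.9,   # no hatching (72-120 hpf)
                  "38" = 0.7,   # decreased heartbeat
                  "44" = 0.4, "45" = 0.35,  # edemas
                  "25" = 0.3),
      transitions = list(list(from = 38L, to = 40L, prob = 0.8))
    ),
    hypopigmentation = list(
      name = "hypopigmentation",
      lethal = list(family = "W22", b = 2, e = 80),
      cumulative = list(family = "LL2", b = -2.5, e = 8),
      profile = c("47" = 0.9,   # low pigmentation
                  "28" = 0.2, "18" = 0.15),
      transitions = list()
    ),
    behavioral = list(
      name = "behavioral",
      lethal = list(family = "W12", b = -2, e = 60),
      cumulative = list(family = "LL2", b = -1.8, e = 12),
      profile = c("37" = 0.8,   # no movement after hatching (72-120 hpf)
                  "34" = 0.7,   # shivering
                  "25" = 0.2),
      transitions = list(list(from = 34L, to = 35L, prob = 0.7))
    )
  )
}

#' Configuration for a synthetic ZFET study
#'
#' The defaults emulate the design of a typical archive-scale ZFET study:
#' 7 exposure concentrations per experiment, 12 embryos per concentration
#' plus 11 controls (95 embryos per experiment), exposure start at 0 hpf,
#' observations at 48 and 96 hpf in 96-well plates, and a control normal
#' probability of 0.936 (control survival 0.959 when control mortality is
#' modelled).
#'
#' @param n_substances Number of substances (default 8); archetypes are
#'   assigned cyclically from `archetypes`.
#' @param experiments_per_substance Replicate experiments per substance
#'   (default 1).
#' @param archetypes Archetype library (default [zfet_archetypes()]).
#' @param n_concentrations Exposure concentrations per experiment
#'   (default 7, log-spaced).
#' @param embryos_per_concentration Embryos per concentration (default 12).
#' @param n_controls Control embryos per experiment (default 11).
#' @param conc_span Multiplicative half-width of the log-spaced
#'   concentration range around the true curves: concentrations run from
#'   `cumulative e / conc_span` to `lethal e * conc_span` (default 10).
#' @param control_normal_p Probability that a control embryo is "normal"
#'   (default 0.936).
#' @param control_survival_p Probability that a control embryo survives,
#'   used only when `model_control_survival` (default 0.959).
#' @param model_control_survival Allow "coagulated" among control
#'   background abnormalities (default `FALSE`).
#' @param observation_times Observation times in hpf (default `c(48, 96)`).
#' @param exposure_start_hpf Exposure start (default 0).
#' @param container_type Container (default `"well96"`).
#' @param n_bad_control_experiments Number of experiments planted with
#'   degraded controls (normal probability `bad_control_normal_p`), for
#'   exercising the QC gate (default 0).
#' @param bad_control_normal_p Control normal probability in planted bad
#'   experiments (default 0.2, low enough that a planted experiment fails
#'   the binomial gate with near certainty at typical control counts).
#' @return A list of class `zfet_study_config`.
#' @export
study_config <- function(n_substances = 8, experiments_per_substance = 1,
                         archetypes = zfet_archetypes(),
                         n_concentrations = 7,
                         embryos_per_concentration = 12, n_controls = 11,
                         conc_span = 10,
                         control_normal_p = 0.936,
                         control_survival_p = 0.959,
                         model_control_survival = FALSE,
                         observation_times = c(48, 96),
                         exposure_start_hpf = 0,
                         container_type = "well96",
                         n_bad_control_experiments = 0,
                         bad_control_normal_p = 0.2) {
  stopifnot(n_substances >= 1, experiments_per_substance >= 1,
            n_concentrations >= 1, embryos_per_concentration >= 1,
            n_controls >= 0, length(observation_times) >= 1,
            control_normal_p > 0, control_normal_p <= 1)
  structure(as.list(environment()), class = "zfet_study_config")
}

# curve evaluation for a truth parameter triple
.truth_p <- function(params, conc) {
  .drm_p(params$family, params$b, log(params$e), conc)
}

#' Simulate one embryo's observation rows
#'
#' Draws an embryo's trajectory under an archetype at a fixed exposure
#' concentration. A single latent uniform drives both endpoints, so
#' coagulation implies affectedness and both are absorbing over time:
#' the embryo is coagulated at time t if the uniform falls below the lethal
#' curve value scaled by the time ramp (the fraction of exposure time
#' elapsed, 1 at the final observation), and affected if it falls below the
#' corresponding cumulative value. Affected-but-alive embryos carry effects
#' drawn once per term from the archetype's conditional profile, shown at
#' every time where the term's vocabulary window allows it; transition
#' rules replace an early effect by its successor from the final
#' observation time onward. An affected embryo with no drawable effect
#' falls back to "developmental delay". Controls (`concentration = 0`) are
#' "normal" with probability `control_normal_p`, otherwise they carry one
#' background sublethal effect (never "coagulated" unless
#' `model_control_survival`).
#'
#' @param archetype One element of [zfet_archetypes()].
#' @param concentration Exposure concentration in umol/L (0 for controls).
#' @param times Observation times in hpf.
#' @param config A [study_config()].
#' @param vocab Effect vocabulary.
#' @return A tibble with columns `time_hpf`, `effect_id`, `value`.
#' @export
simulate_embryo <- function(archetype, concentration,
                            times = c(48, 96), config = study_config(),
                            vocab = zfet_vocabulary()) {
  times <- sort(times)
  t_final <- max(times)
  rows <- list()
  emit <- function(t, ids) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      time_hpf = t, effect_id = as.integer(ids), value = 1)
  }

  if (concentration == 0) {
    u <- stats::runif(1)
    if (u <= config$control_normal_p) {
      for (t in times) emit(t, .normal_id)
    } else {
      coag <- config$model_control_survival &&
        u > config$control_survival_p  # top slice of the abnormal mass
      if (coag) {
        for (t in times) emit(t, .lethal_id)
      } else {
        candidates <- vocab$effect_id[vocab$category == "sublethal" &
                                        term_valid_at(vocab, vocab$effect_id,
                                                      t_final)]
        eff <- sample(candidates, 1)
        for (t in times) {
          if (term_valid_at(vocab, eff, t)) emit(t, eff) else emit(t, .normal_id)
        }
      }
    }
    return(dplyr::bind_rows(rows))
  }

  p_let <- .truth_p(archetype$lethal, concentration)
  p_cum <- max(.truth_p(archetype$cumulative, concentration), p_let)
  u <- stats::runif(1)
  profile <- archetype$profile
  drawn <- names(profile)[stats::runif(length(profile)) < profile]
  drawn <- as.integer(drawn)
  # transitions: successor replaces the early effect from the final time on
  trans <- purrr::keep(archetype$transitions,
                       function(tr) tr$from %in% drawn)
  fired <- purrr::keep(trans, function(tr) stats::runif(1) < tr$prob)
  exposure_start <- config$exposure_start_hpf
  shown_prior <- integer(0)  # effects actually observed at earlier times
  for (t in times) {
    ramp <- if (t_final > exposure_start) {
      min(1, max(0, (t - exposure_start) / (t_final - exposure_start)))
    } else 1
    if (u < p_let * ramp) {
      emit(t, .lethal_id)
      next
    }
    if (u < p_cum * ramp) {
      ids <- drawn[term_valid_at(vocab, drawn, t)]
      if (t == t_final && length(fired) > 0) {
        # a worsening applies only when the precursor was actually shown
        # at an earlier observation of this embryo
        for (tr in fired) {
          if (tr$from %in% shown_prior) {
            ids <- setdiff(ids, tr$from)
            if (term_valid_at(vocab, tr$to, t)) ids <- union(ids, tr$to)
          }
        }
      }
      if (length(ids) == 0) ids <- 25L  # developmental delay, valid 0-120
      ids <- sort(ids)
      emit(t, ids)
      shown_prior <- union(shown_prior, ids)
    } else {
      emit(t, .normal_id)
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate a seeded ZFET study with ground truth
#'
#' Generates a full multi-experiment study in the package's data model:
#' per substance, `experiments_per_substance` experiments with a control
#' group and a log-spaced concentration series spanning the true curves,
#' per-embryo trajectories drawn by [simulate_embryo()], one embryo per
#' well. Output is deterministic given `seed` and always passes strict
#' validation (vocabulary windows, normal exclusivity, absorbing
#' coagulation).
#'
#' @param config A [study_config()].
#' @param seed Integer RNG seed.
#' @param vocab Effect vocabulary.
#' @return A list with elements `set` (a `zfet_set`) and `truth` — a list
#'   holding the per-substance true curve parameters
#'   (`$substances` tibble with `substance_id`, `archetype`, lethal and
#'   cumulative `family`/`b`/`e`), the archetype library, the config and
#'   the ids of experiments planted with degraded controls.
#' @examples
#' study <- simulate_study(study_config(n_substances = 2), seed = 1)
#' experiment_summary(study$set)
#' @export
simulate_study <- function(config = study_config(), seed = 1,
                           vocab = zfet_vocabulary()) {
  stopifnot(inherits(config, "zfet_study_config"))
  set.seed(seed)
  arche_names <- names(config$archetypes)
  n_exp_total <- config$n_substances * config$experiments_per_substance
  bad_ids <- character()

  exps <- list(); trts <- list(); obs <- list()
  exp_counter <- 0
  well_dims <- switch(config$container_type,
                      well24 = c(4, 6), well48 = c(6, 8), well96 = c(8, 12),
                      c(8, 12))

  truth_rows <- list()
  for (s in seq_len(config$n_substances)) {
    arche <- config$archetypes[[arche_names[((s - 1) %% length(arche_names)) + 1]]]
    substance_id <- sprintf("SYN%03d", s)
    substance_name <- sprintf("%s_%03d", arche$name, s)
    truth_rows[[s]] <- tibble::tibble(
      substance_id = substance_id, substance_name = substance_name,
      archetype = arche$name,
      lethal_family = arche$lethal$family, lethal_b = arche$lethal$b,
      lethal_e = arche$lethal$e,
      cumulative_family = arche$cumulative$family,
      cumulative_b = arche$cumulative$b, cumulative_e = arche$cumulative$e
    )
    concs <- exp(seq(log(arche$cumulative$e / config$conc_span),
                     log(arche$lethal$e * config$conc_span),
                     length.out = config$n_concentrations))
    for (r in seq_len(config$experiments_per_substance)) {
      exp_counter <- exp_counter + 1
      experiment_id <- sprintf("EXP%04d", exp_counter)
      is_bad <- exp_counter <= config$n_bad_control_experiments
      if (is_bad) bad_ids <- c(bad_ids, experiment_id)
      exps[[exp_counter]] <- tibble::tibble(
        experiment_id = experiment_id, substance_type = "single",
        exposure_start_hpf = config$exposure_start_hpf,
        container_type = config$container_type,
        temperature_C = 26, date = NA_character_, strain = "wild-type"
      )
      trt_ctrl <- tibble::tibble(
        treatment_id = paste0(experiment_id, "_T00"),
        experiment_id = experiment_id,
        substance_id = "CONTROL", substance_name = "control",
        concentration_umol_L = 0, is_control = TRUE,
        is_solvent_control = FALSE
      )
      trt_dose <- tibble::tibble(
        treatment_id = sprintf("%s_T%02d", experiment_id,
                               seq_along(concs)),
        experiment_id = experiment_id,
        substance_id = substance_id, substance_name = substance_name,
        concentration_umol_L = concs, is_control = FALSE,
        is_solvent_control = FALSE
      )
      trts[[exp_counter]] <- dplyr::bind_rows(trt_ctrl, trt_dose)

      ctrl_cfg <- config
      if (is_bad) ctrl_cfg$control_normal_p <- config$bad_control_normal_p
      embryo_counter <- 0
      plan <- dplyr::bind_rows(
        tibble::tibble(treatment_id = trt_ctrl$treatment_id,
                       concentration = 0, n = config$n_controls),
        tibble::tibble(treatment_id = trt_dose$treatment_id,
                       concentration = concs,
                       n = config$embryos_per_concentration)
      )
      exp_obs <- purrr::pmap(plan, function(treatment_id, concentration, n) {
        purrr::map(seq_len(n), function(i) {
          embryo_counter <<- embryo_counter + 1
          idx <- embryo_counter - 1
          rows <- simulate_embryo(
            arche, concentration, times = config$observation_times,
            config = if (concentration == 0) ctrl_cfg else config,
            vocab = vocab)
          dplyr::mutate(
            rows,
            experiment_id = experiment_id,
            embryo_id = sprintf("e%03d", embryo_counter),
            treatment_id = treatment_id,
            well_row = LETTERS[(idx %/% well_dims[2]) %% well_dims[1] + 1],
            well_col = idx %% well_dims[2] + 1L,
            .before = 1
          )
        })
      })
      obs[[exp_counter]] <- dplyr::bind_rows(exp_obs)
    }
  }

  set <- zfet_set(dplyr::bind_rows(exps), dplyr::bind_rows(trts),
                  dplyr::bind_rows(obs)[, .observation_cols],
                  mode = "strict", vocab = vocab)
  truth <- list(substances = dplyr::bind_rows(truth_rows),
                archetypes = config$archetypes,
                config = config, seed = seed,
                bad_control_experiments = bad_ids)
  list(set = set, truth = truth)
}
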