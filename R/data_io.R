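# Experiment / treatment / observation data model and CSV dialect -------------

.well_containers <- c("well24", "well48", "well96")
.container_types <- c("vial", "dish", .well_containers)
.substance_types <- c("single", "mixture", "environmental_sample", "other")

.experiment_cols <- c("experiment_id", "substance_type", "exposure_start_hpf",
                      "container_type", "temperature_C", "date", "strain")
.treatment_cols <- c("treatment_id", "experiment_id", "substance_id",
                     "substance_name", "concentration_umol_L",
                     "is_control", "is_solvent_control")
.observation_cols <- c("experiment_id", "embryo_id", "treatment_id",
                       "well_row", "well_col", "time_hpf", "effect_id",
                       "value")

#' Construct a validated experiment set
#'
#' Bundles the three tables of the ZFET data model — experiment metadata,
#' treatments (concentration series plus controls) and per-embryo,
#' per-time-point effect observations — into a `zfet_set` after validation.
#'
#' Observations use the long format: one row per embryo x time x effect, with
#' `value = 1` for qualitative presence and the measured value for the two
#' quantitative terms. An unaffected embryo carries a single "normal" row at
#' each observed time point.
#'
#' Validation enforces, per row: effect ids known to the vocabulary and
#' observed inside their time windows; referential integrity between the
#' three tables; controls at concentration 0; "normal" exclusive of any other
#' effect for the same embryo and time; and coagulation absorbing (once
#' "coagulated" is recorded, later records may only be "coagulated" or
#' "no embryo"). In `"strict"` mode any violation aborts with an itemised
#' message; in `"lenient"` mode offending observation rows are dropped and
#' the counts recorded in `attr(set, "validation")`.
#'
#' @param experiments Tibble with columns
#'   `experiment_id, substance_type, exposure_start_hpf, container_type,
#'   temperature_C, date, strain` (the last three optional).
#' @param treatments Tibble with columns
#'   `treatment_id, experiment_id, substance_id, substance_name,
#'   concentration_umol_L, is_control, is_solvent_control`.
#' @param observations Tibble with columns
#'   `experiment_id, embryo_id, treatment_id, well_row, well_col, time_hpf,
#'   effect_id, value`.
#' @param mode `"strict"` (default) or `"lenient"`.
#' @param vocab Effect vocabulary; defaults to the packaged one.
#' @return A `zfet_set`: a named list of the three validated tibbles with a
#'   `validation` attribute summarising dropped rows.
#' @export
zfet_set <- function(experiments, treatments, observations,
                     mode = c("strict", "lenient"),
                     vocab = zfet_vocabulary()) {
  mode <- match.arg(mode)
  experiments <- .coerce_experiments(tibble::as_tibble(experiments))
  treatments <- .coerce_treatments(tibble::as_tibble(treatments))
  observations <- .coerce_observations(tibble::as_tibble(observations))
  .validate_set(experiments, treatments, observations, mode, vocab)
}

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

.coerce_experiments <- function(df) {
  df <- .require_cols(df, setdiff(.experiment_cols,
                                  c("temperature_C", "date", "strain")),
                      "experiments")
  if (!"temperature_C" %in% names(df)) df$temperature_C <- NA_real_
  if (!"date" %in% names(df)) df$date <- NA_character_
  if (!"strain" %in% names(df)) df$strain <- NA_character_
  dplyr::mutate(
    df[.experiment_cols],
    experiment_id = as.character(.data$experiment_id),
    exposure_start_hpf = as.integer(.data$exposure_start_hpf),
    temperature_C = as.numeric(.data$temperature_C),
    date = as.character(.data$date),
    strain = as.character(.data$strain)
  )
}

.coerce_treatments <- function(df) {
  df <- .require_cols(df, .treatment_cols, "treatments")
  dplyr::mutate(
    df[.treatment_cols],
    dplyr::across(c("treatment_id", "experiment_id", "substance_id",
                    "substance_name"), as.character),
    concentration_umol_L = as.numeric(.data$concentration_umol_L),
    dplyr::across(c("is_control", "is_solvent_control"), as.logical)
  )
}

.coerce_observations <- function(df) {
  df <- .require_cols(df, setdiff(.observation_cols, c("well_row", "well_col")),
                      "observations")
  if (!"well_row" %in% names(df)) df$well_row <- NA_character_
  if (!"well_col" %in% names(df)) df$well_col <- NA_integer_
  dplyr::mutate(
    df[.observation_cols],
    dplyr::across(c("experiment_id", "embryo_id", "treatment_id", "well_row"),
                  as.character),
    well_col = as.integer(.data$well_col),
    time_hpf = as.integer(.data$time_hpf),
    effect_id = as.integer(.data$effect_id),
    value = as.numeric(.data$value)
  )
}

.validate_set <- function(experiments, treatments, observations, mode, vocab) {
  problems <- character()
  add_problem <- function(msg) problems <<- c(problems, msg)

  if (anyDuplicated(experiments$experiment_id)) {
    add_problem("duplicate experiment_id in experiments table")
  }
  bad_start <- experiments$exposure_start_hpf < 0 |
    experiments$exposure_start_hpf >= 120
  if (any(bad_start)) {
    add_problem(paste0("exposure_start_hpf outside [0,120) for experiment(s) ",
                       paste(experiments$experiment_id[bad_start],
                             collapse = ", ")))
  }
  bad_container <- !experiments$container_type %in% .container_types
  if (any(bad_container)) {
    add_problem(paste0("unknown container_type for experiment(s) ",
                       paste(experiments$experiment_id[bad_container],
                             collapse = ", ")))
  }
  bad_stype <- !experiments$substance_type %in% .substance_types
  if (any(bad_stype)) {
    add_problem(paste0("unknown substance_type for experiment(s) ",
                       paste(experiments$experiment_id[bad_stype],
                             collapse = ", ")))
  }
  if (anyDuplicated(treatments$treatment_id)) {
    add_problem("duplicate treatment_id in treatments table")
  }
  orphan_trt <- !treatments$experiment_id %in% experiments$experiment_id
  if (any(orphan_trt)) {
    add_problem(paste0("treatment(s) reference unknown experiment_id: ",
                       paste(unique(treatments$experiment_id[orphan_trt]),
                             collapse = ", ")))
  }
  ctrl_conc <- treatments$is_control & treatments$concentration_umol_L != 0
  if (any(ctrl_conc)) {
    add_problem(paste0("control treatment(s) with nonzero concentration: ",
                       paste(treatments$treatment_id[ctrl_conc],
                             collapse = ", ")))
  }
  if (any(treatments$concentration_umol_L < 0)) {
    add_problem("negative concentrations in treatments table")
  }

  # row-level observation checks (droppable in lenient mode)
  obs <- observations
  drop <- rep(FALSE, nrow(obs))
  note <- rep(NA_character_, nrow(obs))
  flag <- function(idx, why) {
    idx <- idx & !drop
    drop[idx] <<- TRUE
    note[idx] <<- why
  }

  flag(!obs$effect_id %in% vocab$effect_id, "unknown effect_id")
  known <- !drop
  in_window <- rep(TRUE, nrow(obs))
  if (any(known)) {
    in_window[known] <- term_valid_at(vocab, obs$effect_id[known],
                                      obs$time_hpf[known])
  }
  flag(!in_window, "effect outside vocabulary time window")
  flag(!obs$treatment_id %in% treatments$treatment_id,
       "unknown treatment_id")
  flag(!obs$experiment_id %in% experiments$experiment_id,
       "unknown experiment_id")

  # normal-exclusivity and coagulation absorbency need per-embryo context
  keep <- obs[!drop, , drop = FALSE]
  if (nrow(keep) > 0) {
    key <- paste(keep$experiment_id, keep$embryo_id, sep = "\r")
    tkey <- paste(key, keep$time_hpf, sep = "\r")
    n_at_time <- table(tkey)
    has_normal <- tapply(keep$effect_id == .normal_id, tkey, any)
    excl_bad_t <- names(n_at_time)[as.vector(n_at_time) > 1 &
                                     as.vector(has_normal[names(n_at_time)])]
    if (length(excl_bad_t) > 0) {
      bad <- tkey %in% excl_bad_t & keep$effect_id != .normal_id
      idx <- rep(FALSE, nrow(obs))
      idx[which(!drop)[bad]] <- TRUE
      flag(idx, "effect recorded alongside 'normal'")
    }
    coag_t <- tapply(ifelse(keep$effect_id == .lethal_id, keep$time_hpf, NA),
                     key, function(x) suppressWarnings(min(x, na.rm = TRUE)))
    coag_t <- coag_t[is.finite(coag_t)]
    if (length(coag_t) > 0) {
      first_coag <- coag_t[key]
      bad <- !is.na(first_coag) & keep$time_hpf > first_coag &
        !keep$effect_id %in% c(.lethal_id, .uninformative_ids[1])
      if (any(bad)) {
        idx <- rep(FALSE, nrow(obs))
        idx[which(!drop)[bad]] <- TRUE
        flag(idx, "effect recorded after coagulation")
      }
    }
  }

  n_dropped <- sum(drop)
  if (n_dropped > 0) {
    counts <- table(note[drop])
    detail <- paste(sprintf("%s (%d row%s)", names(counts), counts,
                            ifelse(counts > 1, "s", "")), collapse = "; ")
    if (mode == "strict") {
      add_problem(paste0("invalid observation rows: ", detail))
    } else {
      message("zfet_set: dropped ", n_dropped,
              " invalid observation row(s): ", detail)
      observations <- obs[!drop, , drop = FALSE]
    }
  }

  if (length(problems) > 0) {
    stop("invalid experiment set:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }

  structure(
    list(experiments = experiments, treatments = treatments,
         observations = observations),
    validation = list(mode = mode, n_dropped = n_dropped,
                      dropped_reasons = if (n_dropped > 0)
                        as.list(table(note[drop])) else list()),
    class = "zfet_set"
  )
}

#' @export
print.zfet_set <- function(x, ...) {
  cat("<zfet_set>\n")
  cat("  experiments: ", nrow(x$experiments), "\n", sep = "")
  cat("  treatments:  ", nrow(x$treatments), "\n", sep = "")
  cat("  observations:", nrow(x$observations), "rows,",
      dplyr::n_distinct(x$observations$experiment_id,
                        x$observations$embryo_id), "embryos\n")
  invisible(x)
}

#' Read an experiment set from CSV files
#'
#' Reads `experiments.csv`, `treatments.csv` and `observations.csv` from a
#' directory (or three explicit paths) in the package's CSV dialect — UTF-8,
#' comma-separated, RFC 4180, booleans as `"true"`/`"false"` — and validates
#' them with [zfet_set()].
#'
#' @param path Directory containing the three files, or the path to
#'   `experiments.csv` when `treatments` and `observations` are given.
#' @param treatments,observations Optional explicit file paths.
#' @inheritParams zfet_set
#' @return A `zfet_set`.
#' @export
read_zfet_experiments <- function(path, treatments = NULL,
                                  observations = NULL,
                                  mode = c("strict", "lenient"),
                                  vocab = zfet_vocabulary()) {
  if (is.null(treatments) && is.null(observations)) {
    exp_path <- file.path(path, "experiments.csv")
    trt_path <- file.path(path, "treatments.csv")
    obs_path <- file.path(path, "observations.csv")
  } else {
    exp_path <- path
    trt_path <- treatments
    obs_path <- observations
  }
  read1 <- function(p) {
    readr::read_csv(p, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, na = "")
  }
  exps <- read1(exp_path)
  trts <- dplyr::mutate(
    read1(trt_path),
    dplyr::across(dplyr::any_of(c("is_control", "is_solvent_control")),
                  ~ .x == "true")
  )
  obs <- read1(obs_path)
  zfet_set(exps, trts, obs, mode = match.arg(mode), vocab = vocab)
}

#' Write an experiment set to CSV files
#'
#' Writes `experiments.csv`, `treatments.csv` and `observations.csv` in the
#' package's CSV dialect. Output is byte-stable: fixed column order, fixed row
#' sort (observations by experiment, embryo, time, effect), booleans as
#' `"true"`/`"false"`, empty string for missing optional values.
#'
#' @param set A `zfet_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_zfet_experiments <- function(set, dir) {
  stopifnot(inherits(set, "zfet_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt_bool <- function(x) ifelse(x, "true", "false")
  exps <- dplyr::arrange(set$experiments, .data$experiment_id)
  trts <- set$treatments |>
    dplyr::arrange(.data$experiment_id, .data$treatment_id) |>
    dplyr::mutate(dplyr::across(c("is_control", "is_solvent_control"),
                                fmt_bool))
  obs <- dplyr::arrange(set$observations, .data$experiment_id,
                        .data$embryo_id, .data$time_hpf, .data$effect_id)
  readr::write_csv(exps, file.path(dir, "experiments.csv"), na = "",
                   progress = FALSE)
  readr::write_csv(trts, file.path(dir, "treatments.csv"), na = "",
                   progress = FALSE)
  readr::write_csv(obs, file.path(dir, "observations.csv"), na = "",
                   progress = FALSE)
  invisible(dir)
}

#' Per-experiment summary counts
#'
#' @param set A `zfet_set`.
#' @return A tibble with one row per experiment: number of distinct embryos,
#'   number of distinct nonzero exposure concentrations (controls excluded),
#'   observation time points, and the substance(s) tested.
#' @export
experiment_summary <- function(set) {
  stopifnot(inherits(set, "zfet_set"))
  conc <- set$treatments |>
    dplyr::filter(!.data$is_control, !.data$is_solvent_control) |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::summarise(
      n_concentrations = dplyr::n_distinct(.data$concentration_umol_L),
      substances = paste(sort(unique(.data$substance_name)), collapse = ";"),
      .groups = "drop"
    )
  obs <- set$observations |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::summarise(
      n_embryos = dplyr::n_distinct(.data$embryo_id),
      n_time_points = dplyr::n_distinct(.data$time_hpf),
      time_points = paste(sort(unique(.data$time_hpf)), collapse = ","),
      .groups = "drop"
    )
  set$experiments |>
    dplyr::select("experiment_id", "substance_type", "exposure_start_hpf",
                  "container_type") |>
    dplyr::left_join(obs, by = "experiment_id") |>
    dplyr::left_join(conc, by = "experiment_id") |>
    dplyr::mutate(
      n_embryos = dplyr::coalesce(.data$n_embryos, 0L),
      n_time_points = dplyr::coalesce(.data$n_time_points, 0L),
      n_concentrations = dplyr::coalesce(.data$n_concentrations, 0L)
    )
}

# final control observation time per experiment (latest time with any
# control observation); embryos whose record was terminated by "no embryo"
# before that time are excluded from denominators by the callers.
.control_treatment_ids <- function(set) {
  set$treatments$treatment_id[set$treatments$is_control |
                                set$treatments$is_solvent_control]
}

#' Subset an experiment set to given experiments
#'
#' Keeps the listed experiments with their treatments and observations;
#' referential integrity is preserved by construction.
#'
#' @param set A `zfet_set`.
#' @param experiment_ids Character vector of experiment ids to keep.
#' @return A `zfet_set`.
#' @export
filter_experiments <- function(set, experiment_ids) {
  stopifnot(inherits(set, "zfet_set"))
  structure(
    list(
      experiments = dplyr::filter(set$experiments,
                                  .data$experiment_id %in% experiment_ids),
      treatments = dplyr::filter(set$treatments,
                                 .data$experiment_id %in% experiment_ids),
      observations = dplyr::filter(set$observations,
                                   .data$experiment_id %in% experiment_ids)
    ),
    validation = attr(set, "validation"),
    class = "zfet_set"
  )
}
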