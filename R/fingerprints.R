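# Phenotypic effect fingerprints ----------------------------------------------

#' Concentration window for fingerprinting
#'
#' Fingerprints are built from exposures between the EC5 of the cumulative
#' dose-response fit and the LC99 of the lethal fit, so that differently
#' chosen exposure ranges across studies do not distort the effect
#' proportions. When the lethal model failed, the window is open above
#' (all concentrations larger than the EC5 are used).
#'
#' @param cumulative_fit A valid `zfet_fit` for the cumulative endpoint.
#' @param lethal_fit A `zfet_fit` for the lethal endpoint, or `NULL`.
#' @return A one-row tibble `low`, `high` (umol/L; `high = Inf` when the
#'   lethal fit is missing or invalid). If `high < low` (possible with a
#'   steep lethal curve) the window is empty and the substance should be
#'   excluded; a warning is raised.
#' @export
concentration_window <- function(cumulative_fit, lethal_fit = NULL) {
  stopifnot(inherits(cumulative_fit, "zfet_fit"))
  if (!isTRUE(cumulative_fit$valid)) {
    stop("cumulative fit is not valid; no fingerprint window", call. = FALSE)
  }
  low <- .ecx(cumulative_fit, 5)$value
  high <- Inf
  if (!is.null(lethal_fit) && isTRUE(lethal_fit$valid)) {
    high <- .ecx(lethal_fit, 99)$value
  }
  if (high < low) {
    warning("empty fingerprint window (LC99 < EC5)", call. = FALSE)
  }
  tibble::tibble(low = low, high = high)
}

#' Build a substance's phenotypic fingerprint
#'
#' Among embryos exposed to concentrations inside `window` (inclusive
#' bounds) and observed at `observation_hpf`, normal embryos are excluded;
#' for each qualitative effect term the proportion of the remaining embryos
#' exhibiting it is computed. Proportions do not sum to one — an embryo can
#' carry several effects. Uninformative ("no embryo", "miscellaneous") and
#' quantitative terms never enter the vector; embryos recorded as
#' "no embryo" are excluded altogether. Embryos are pooled over all
#' exposure-start designs for the substance.
#'
#' @param set A `zfet_set`.
#' @param substance_id Substance identifier.
#' @param observation_hpf Observation time (default 96).
#' @param window One-row tibble `low`/`high` from [concentration_window()];
#'   defaults to all positive concentrations.
#' @param vocab Effect vocabulary.
#' @return A tibble (class `zfet_fingerprint`) with columns `effect_id`,
#'   `effect`, `proportion`; the number of embryos used is in
#'   `attr(x, "n_embryos")`.
#' @export
build_fingerprint <- function(set, substance_id, observation_hpf = 96,
                              window = tibble::tibble(low = 0, high = Inf),
                              vocab = zfet_vocabulary()) {
  trts <- dplyr::filter(set$treatments,
                        .data$substance_id == !!substance_id,
                        !.data$is_control, !.data$is_solvent_control,
                        .data$concentration_umol_L >= window$low,
                        .data$concentration_umol_L <= window$high)
  qualitative <- dplyr::filter(vocab,
                               .data$category %in% c("lethal", "sublethal"))
  obs <- set$observations |>
    dplyr::filter(.data$treatment_id %in% trts$treatment_id,
                  .data$time_hpf == observation_hpf)
  status <- obs |>
    dplyr::group_by(.data$experiment_id, .data$embryo_id) |>
    dplyr::summarise(
      is_normal = any(.data$effect_id == .normal_id),
      is_absent = all(.data$effect_id == .uninformative_ids[1]),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$is_normal, !.data$is_absent)
  n_used <- nrow(status)
  counts <- obs |>
    dplyr::semi_join(status, by = c("experiment_id", "embryo_id")) |>
    dplyr::filter(.data$effect_id %in% qualitative$effect_id) |>
    dplyr::distinct(.data$experiment_id, .data$embryo_id, .data$effect_id) |>
    dplyr::count(.data$effect_id)
  fp <- qualitative |>
    dplyr::select("effect_id", "effect") |>
    dplyr::left_join(counts, by = "effect_id") |>
    dplyr::mutate(proportion = dplyr::coalesce(.data$n, 0L) /
                    max(n_used, 1L)) |>
    dplyr::select(-"n") |>
    dplyr::arrange(.data$effect_id)
  structure(fp, class = c("zfet_fingerprint", class(fp)),
            substance_id = substance_id, observation_hpf = observation_hpf,
            n_embryos = n_used, window = window)
}

#' Assemble fingerprints into a filtered matrix
#'
#' Stacks per-substance fingerprints into a substances x effects matrix,
#' then drops rows (substances) built from fewer than `min_embryos` embryos
#' and, after that, columns (effects) whose mean proportion across the
#' remaining substances is below `min_mean_prop`. The row filter is applied
#' before the column filter. Column order follows vocabulary id order.
#'
#' @param fingerprints A list of `zfet_fingerprint` objects.
#' @param min_embryos Row filter threshold (default 30).
#' @param min_mean_prop Column filter threshold (default 0.01, i.e. effects
#'   occurring on average in less than 1% of embryos are dropped).
#' @return A numeric matrix with substance ids as row names and effect names
#'   as column names; per-row embryo counts in `attr(x, "n_embryos")`.
#' @export
assemble_fingerprint_matrix <- function(fingerprints, min_embryos = 30,
                                        min_mean_prop = 0.01) {
  stopifnot(length(fingerprints) >= 2)
  ids <- purrr::map_chr(fingerprints, function(f) attr(f, "substance_id"))
  n_embryos <- purrr::map_int(fingerprints, function(f)
    as.integer(attr(f, "n_embryos")))
  mat <- do.call(rbind, purrr::map(fingerprints, function(f) {
    stats::setNames(f$proportion, f$effect)
  }))
  rownames(mat) <- ids
  keep_rows <- n_embryos >= min_embryos
  mat <- mat[keep_rows, , drop = FALSE]
  n_embryos <- n_embryos[keep_rows]
  if (nrow(mat) < 2) {
    stop("fewer than 2 substances survive the ", min_embryos,
         "-embryo filter", call. = FALSE)
  }
  keep_cols <- colMeans(mat) >= min_mean_prop
  mat <- mat[, keep_cols, drop = FALSE]
  attr(mat, "n_embryos") <- stats::setNames(n_embryos, rownames(mat))
  mat
}

#' Cluster substances by fingerprint similarity
#'
#' Agglomerative hierarchical clustering of the fingerprint rows with the
#' Ward minimum-variance criterion on Euclidean distances
#' (`stats::hclust(method = "ward.D2")`), cut into `k` clusters.
#' Deterministic for a given input; row order only relabels clusters.
#'
#' @param mat A fingerprint matrix from [assemble_fingerprint_matrix()].
#' @param k Number of clusters (default 6).
#' @return A tibble `substance_id`, `cluster`; the `hclust` tree is attached
#'   as `attr(x, "hclust")`.
#' @export
cluster_fingerprints <- function(mat, k = 6) {
  if (k > nrow(mat)) {
    stop("k = ", k, " exceeds the number of substances (", nrow(mat), ")",
         call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  out <- tibble::tibble(substance_id = rownames(mat),
                        cluster = unname(cl))
  attr(out, "hclust") <- hc
  out
}

#' Rank effects by their importance in a PCA of the fingerprints
#'
#' Principal component analysis of the fingerprint matrix (centred, not
#' scaled — all variables are proportions on a common scale); each effect's
#' importance is the Euclidean norm of its contributions to the first
#' `n_components` components. With `method = "variance"` (default) the
#' contribution of an effect to a component is its loading weighted by the
#' component's standard deviation, so components explaining more variance
#' count more; `method = "loadings"` uses the raw rotation entries.
#' Importance is invariant to component sign flips.
#'
#' @param mat A fingerprint matrix.
#' @param n_components Number of leading components (default 5).
#' @param method `"variance"` (default) or `"loadings"`.
#' @return A tibble `effect`, `importance`, `rank`, sorted by decreasing
#'   importance.
#' @export
pca_effect_importance <- function(mat, n_components = 5,
                                  method = c("variance", "loadings")) {
  method <- match.arg(method)
  if (nrow(mat) < 2 || all(apply(mat, 2, stats::var) == 0)) {
    stop("fingerprint matrix has no variance to decompose", call. = FALSE)
  }
  n_components <- min(n_components, nrow(mat) - 1, ncol(mat))
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  if (method == "variance") {
    rot <- sweep(rot, 2, pc$sdev[seq_len(n_components)], `*`)
  }
  imp <- sqrt(rowSums(rot^2))
  tibble::tibble(effect = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance)) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Fingerprints for every eligible substance in a set
#'
#' Runs the whole fingerprint derivation: per substance and exposure-start
#' design, fits cumulative (and lethal) dose-response models at
#' `observation_hpf`, takes the EC5-LC99 window per design, pools the
#' windowed embryos across designs, and returns the per-substance
#' fingerprints. Substances without any valid cumulative fit are skipped.
#'
#' @param set A `zfet_set`.
#' @param fits Optional precomputed [fit_all_drms()] table.
#' @param observation_hpf Observation time (default 96).
#' @param vocab Effect vocabulary.
#' @return A named list of `zfet_fingerprint` objects.
#' @export
build_all_fingerprints <- function(set, fits = NULL, observation_hpf = 96,
                                   vocab = zfet_vocabulary()) {
  if (is.null(fits)) {
    fits <- fit_all_drms(set, observation_hpf = observation_hpf,
                         vocab = vocab)
  }
  valid_cum <- dplyr::filter(fits, .data$endpoint == "cumulative",
                             .data$valid)
  out <- list()
  for (sid in unique(valid_cum$substance_id)) {
    # one window per design; pooled embryo selection via per-design windows
    rows <- dplyr::filter(valid_cum, .data$substance_id == sid)
    windows <- purrr::map(seq_len(nrow(rows)), function(i) {
      lf_row <- dplyr::filter(fits, .data$substance_id == sid,
                              .data$endpoint == "lethal",
                              .data$exposure_start_hpf ==
                                rows$exposure_start_hpf[i])
      lethal_fit <- if (nrow(lf_row) == 1) lf_row$fit[[1]] else NULL
      suppressWarnings(
        concentration_window(rows$fit[[i]], lethal_fit))
    })
    win <- dplyr::bind_rows(windows)
    # pooled window: union of per-design windows collapsed to its hull
    window <- tibble::tibble(low = min(win$low), high = max(win$high))
    if (window$high < window$low) next
    fp <- build_fingerprint(set, sid, observation_hpf, window, vocab)
    if (attr(fp, "n_embryos") > 0) out[[sid]] <- fp
  }
  out
}
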