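# End-to-end pipeline orchestration -------------------------------------------

#' Pipeline configuration
#'
#' Surfaces every threshold of the analysis cascade as a named key, with the
#' reference workflow's values as defaults: the QC thresholds (see
#' [qc_config()]), the observation time for dose-response modelling, the
#' fingerprint window levels (EC5 lower, LC99 upper), the fingerprint
#' filters (30 embryos, 1% mean prevalence), the number of fingerprint
#' clusters (6) and the propagation time points (48 and 96 hpf).
#'
#' @param qc A [qc_config()].
#' @param observation_hpf Observation time for DRM and fingerprints
#'   (default 96).
#' @param ec_level,lc_level Fingerprint window levels in percent
#'   (defaults 5 and 99).
#' @param min_fingerprint_embryos,min_effect_prevalence Fingerprint filters
#'   (defaults 30 and 0.01).
#' @param k_clusters Fingerprint cluster count (default 6).
#' @param propagation_t1,propagation_t2 Propagation time points
#'   (defaults 48, 96).
#' @return A list of class `zfet_pipeline_config`.
#' @export
pipeline_config <- function(qc = qc_config(), observation_hpf = 96,
                            ec_level = 5, lc_level = 99,
                            min_fingerprint_embryos = 30,
                            min_effect_prevalence = 0.01,
                            k_clusters = 6,
                            propagation_t1 = 48, propagation_t2 = 96) {
  structure(as.list(environment()), class = "zfet_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order — validation, pre-filter, control
#' quality gate, dose-response modelling, sensitivity ratios, phenotypic
#' fingerprints (clustering and PCA ranking), effect propagation — each
#' stage consuming only the previous stage's output. Per-stage row counts
#' are recorded in a machine-readable manifest; a rerun on the same input
#' and config reproduces the same manifest hashes. Stages whose inputs do
#' not qualify (e.g. too few fingerprints to cluster) are skipped with the
#' reason recorded.
#'
#' @param set A `zfet_set` (or a directory path readable by
#'   [read_zfet_experiments()]).
#' @param config A [pipeline_config()].
#' @param vocab Effect vocabulary.
#' @return A list with elements `qc_report`, `fits`, `sensitivity_ratios`,
#'   `fingerprints`, `fingerprint_matrix`, `clusters`, `effect_importance`,
#'   `propagation`, and `manifest` (stage counts, config snapshot, content
#'   hashes).
#' @export
run_zfet_pipeline <- function(set, config = pipeline_config(),
                              vocab = zfet_vocabulary()) {
  if (is.character(set)) set <- read_zfet_experiments(set, vocab = vocab)
  stopifnot(inherits(set, "zfet_set"),
            inherits(config, "zfet_pipeline_config"))
  counts <- list(experiments_in = nrow(set$experiments))
  skipped <- list()

  filtered <- qc_filter(set, config$qc)
  report <- attr(filtered, "qc_report")
  counts$prefilter_survivors <- sum(report$passed_prefilter)
  counts$qc_survivors <- nrow(filtered$experiments)

  fits <- fit_all_drms(filtered, observation_hpf = config$observation_hpf,
                       vocab = vocab)
  counts$drm_designs_fitted <- nrow(fits)
  counts$drm_valid_fits <- sum(fits$valid)

  srs <- sensitivity_ratios(fits)
  counts$sensitivity_ratios <- nrow(srs)

  fps <- build_all_fingerprints(filtered, fits = fits,
                                observation_hpf = config$observation_hpf,
                                vocab = vocab)
  counts$fingerprint_candidates <- length(fps)
  fp_mat <- NULL; clusters <- NULL; importance <- NULL
  if (length(fps) >= 2) {
    fp_mat <- tryCatch(
      assemble_fingerprint_matrix(
        fps, min_embryos = config$min_fingerprint_embryos,
        min_mean_prop = config$min_effect_prevalence),
      error = function(e) {skipped$fingerprints <<- conditionMessage(e); NULL})
  } else {
    skipped$fingerprints <- "fewer than 2 fingerprints"
  }
  counts$fingerprint_substances <- if (is.null(fp_mat)) 0L else nrow(fp_mat)
  if (!is.null(fp_mat)) {
    k <- min(config$k_clusters, nrow(fp_mat))
    clusters <- cluster_fingerprints(fp_mat, k = k)
    importance <- tryCatch(pca_effect_importance(fp_mat),
                           error = function(e) NULL)
  }

  propagation <- tryCatch({
    paired <- pair_embryo_observations(filtered, t1 = config$propagation_t1,
                                       t2 = config$propagation_t2,
                                       vocab = vocab)
    counts$propagation_embryos <- nrow(paired)
    effect_correlation_matrix(paired)
  }, error = function(e) {
    skipped$propagation <<- conditionMessage(e)
    NULL
  })
  if (is.null(propagation)) counts$propagation_embryos <- 0L

  manifest <- list(
    package_version = as.character(utils::packageVersion("zfetr")),
    config = unclass(config),
    counts = counts,
    skipped = skipped,
    hashes = list(
      input = rlang::hash(unclass(set)),
      fits = rlang::hash(dplyr::select(fits, -"fit")),
      fingerprint_matrix = rlang::hash(fp_mat)
    )
  )
  list(qc_report = report, fits = fits, sensitivity_ratios = srs,
       fingerprints = fps, fingerprint_matrix = fp_mat,
       clusters = clusters, effect_importance = importance,
       propagation = propagation, manifest = manifest)
}

#' Write a pipeline manifest to JSON
#'
#' @param manifest The `manifest` element of a [run_zfet_pipeline()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  manifest$config$qc <- unclass(manifest$config$qc)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
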