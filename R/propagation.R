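# Effect propagation between developmental time points ------------------------

#' Pair per-embryo effect indicators at two time points
#'
#' Builds the table used to correlate effects over developmental time: one
#' row per non-control embryo observed at both `t1` and `t2` in an
#' experiment using a well-type container (24-, 48- or 96-well plate —
#' the only containers in which an individual embryo can be tracked across
#' observations), with a binary indicator column per qualitative effect and
#' time point. Uninformative terms ("miscellaneous", "no embryo") and the
#' two quantitative terms are excluded; embryos recorded as "no embryo" at
#' either time are dropped. Embryos are matched by experiment and embryo id,
#' and must carry identical well coordinates at both times (mismatches are
#' dropped with a message).
#'
#' @param set A `zfet_set`.
#' @param t1,t2 Early and late observation times in hpf (defaults 48, 96).
#' @param vocab Effect vocabulary.
#' @return A tibble (class `zfet_paired`) with key columns `experiment_id`,
#'   `embryo_id` and indicator columns named `"<effect>@<t>"`, 0/1.
#' @export
pair_embryo_observations <- function(set, t1 = 48, t2 = 96,
                                     vocab = zfet_vocabulary()) {
  well_exps <- set$experiments$experiment_id[
    set$experiments$container_type %in% .well_containers]
  ctrl_ids <- .control_treatment_ids(set)
  keep_effects <- dplyr::filter(
    vocab, .data$category %in% c("normal", "lethal", "sublethal"))
  obs <- set$observations |>
    dplyr::filter(.data$experiment_id %in% well_exps,
                  !.data$treatment_id %in% ctrl_ids,
                  .data$time_hpf %in% c(t1, t2))
  if (nrow(obs) == 0) {
    stop("no non-control observations at ", t1, " and ", t2,
         " hpf in well-type containers", call. = FALSE)
  }
  no_embryo <- .uninformative_ids[1]
  per_embryo <- obs |>
    dplyr::group_by(.data$experiment_id, .data$embryo_id) |>
    dplyr::summarise(
      n_times = dplyr::n_distinct(.data$time_hpf),
      absent = any(.data$effect_id == no_embryo),
      n_wells = dplyr::n_distinct(paste(.data$well_row, .data$well_col)),
      .groups = "drop"
    )
  mismatched <- sum(per_embryo$n_wells > 1)
  if (mismatched > 0) {
    message("pair_embryo_observations: dropped ", mismatched,
            " embryo(s) with inconsistent well coordinates")
  }
  eligible <- dplyr::filter(per_embryo, .data$n_times == 2, !.data$absent,
                            .data$n_wells == 1)
  if (nrow(eligible) == 0) {
    stop("no embryos observed at both ", t1, " and ", t2, " hpf",
         call. = FALSE)
  }
  ind <- obs |>
    dplyr::semi_join(eligible, by = c("experiment_id", "embryo_id")) |>
    dplyr::filter(.data$effect_id %in% keep_effects$effect_id) |>
    dplyr::left_join(dplyr::select(keep_effects, "effect_id", "effect"),
                     by = "effect_id") |>
    dplyr::mutate(column = paste0(.data$effect, "@", .data$time_hpf),
                  present = 1L) |>
    dplyr::distinct(.data$experiment_id, .data$embryo_id, .data$column,
                    .data$present) |>
    tidyr::pivot_wider(names_from = "column", values_from = "present",
                       values_fill = 0L)
  # stable column order: t1 block then t2 block, vocabulary id order
  ordered_cols <- c(paste0(keep_effects$effect, "@", t1),
                    paste0(keep_effects$effect, "@", t2))
  ordered_cols <- intersect(ordered_cols, names(ind))
  out <- ind[, c("experiment_id", "embryo_id", ordered_cols)]
  structure(out, class = c("zfet_paired", class(out)), t1 = t1, t2 = t2)
}

#' Correlation of effects between two time points
#'
#' Pearson correlation coefficients between every effect indicator at the
#' early time point and every effect indicator at the late one, over
#' embryos; two-sided p-values from the t statistic with n - 2 degrees of
#' freedom; significance mask at p < 0.01, unadjusted. Columns with zero
#' variance yield `NA` entries with `defined = FALSE` — never a silent 0.
#'
#' @param paired A `zfet_paired` table from [pair_embryo_observations()].
#' @return A `zfet_propagation` object: list with matrices `pcc`, `p_value`,
#'   `significant`, `defined` (t1 effects in rows, t2 effects in columns)
#'   and `n_embryos`.
#' @export
effect_correlation_matrix <- function(paired) {
  t1 <- attr(paired, "t1"); t2 <- attr(paired, "t2")
  cols <- setdiff(names(paired), c("experiment_id", "embryo_id"))
  x_cols <- cols[endsWith(cols, paste0("@", t1))]
  y_cols <- cols[endsWith(cols, paste0("@", t2))]
  n <- nrow(paired)
  if (n < 3) stop("need at least 3 embryos", call. = FALSE)
  X <- as.matrix(paired[, x_cols, drop = FALSE])
  Y <- as.matrix(paired[, y_cols, drop = FALSE])
  sd_x <- apply(X, 2, stats::sd)
  sd_y <- apply(Y, 2, stats::sd)
  pcc <- suppressWarnings(stats::cor(X, Y))
  defined <- outer(sd_x > 0, sd_y > 0, `&`)
  pcc[!defined] <- NA_real_
  r <- pmin(pmax(pcc, -1 + 1e-15), 1 - 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p_value <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  significant <- !is.na(p_value) & p_value < 0.01
  structure(list(pcc = pcc, p_value = p_value, significant = significant,
                 defined = defined, n_embryos = n, t1 = t1, t2 = t2),
            class = "zfet_propagation")
}

#' @export
print.zfet_propagation <- function(x, ...) {
  cat("<zfet_propagation> ", nrow(x$pcc), " x ", ncol(x$pcc),
      " effects (", x$t1, " -> ", x$t2, " hpf), n = ", x$n_embryos,
      " embryos, ", sum(x$significant), " significant at p < 0.01\n",
      sep = "")
  invisible(x)
}

#' Hierarchical orderings for displaying a propagation matrix
#'
#' Orders the rows and columns of the correlation matrix by hierarchical
#' clustering (complete linkage on Euclidean distances) so that blocks of
#' co-varying effects are contiguous in a heatmap. Undefined entries are
#' imputed as 0 for the ordering only; the `defined` flags are untouched.
#' Display machinery only — not part of the correlation analysis.
#'
#' @param pm A `zfet_propagation` object.
#' @return A list with integer vectors `row_order` and `col_order` and the
#'   two `hclust` trees.
#' @export
cluster_propagation <- function(pm) {
  stopifnot(inherits(pm, "zfet_propagation"))
  m <- pm$pcc
  m[!pm$defined] <- 0
  order1 <- function(mm) {
    if (nrow(mm) < 2) return(list(order = seq_len(nrow(mm)), tree = NULL))
    hc <- stats::hclust(stats::dist(mm, method = "euclidean"),
                        method = "complete")
    list(order = hc$order, tree = hc)
  }
  rows <- order1(m)
  cols <- order1(t(m))
  list(row_order = rows$order, col_order = cols$order,
       row_tree = rows$tree, col_tree = cols$tree)
}

#' Tidy a propagation matrix
#'
#' @param x A `zfet_propagation` object.
#' @param ... Unused.
#' @return A long tibble: `effect_t1`, `effect_t2`, `pcc`, `p_value`,
#'   `significant`, `defined`.
#' @export
tidy.zfet_propagation <- function(x, ...) {
  tibble::tibble(
    effect_t1 = rep(rownames(x$pcc), times = ncol(x$pcc)),
    effect_t2 = rep(colnames(x$pcc), each = nrow(x$pcc)),
    pcc = as.vector(x$pcc),
    p_value = as.vector(x$p_value),
    significant = as.vector(x$significant),
    defined = as.vector(x$defined)
  )
}
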