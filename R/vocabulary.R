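# Controlled vocabulary of morphological effects ------------------------------

# ids with special category semantics on the packaged vocabulary
.uninformative_ids <- c(1L, 16L)   # "no embryo", "miscellaneous"
.lethal_id         <- 2L           # "coagulated"
.normal_id         <- 3L           # "normal"
.quantitative_ids  <- c(26L, 41L)  # "hours post fertilization", "beats per minute"

#' The packaged controlled effect vocabulary
#'
#' Returns the 52-term controlled vocabulary of morphological effects used to
#' score zebrafish embryos, as a validated tibble. Terms form a two-level tree
#' (a parent effect can entail several more detailed child effects) and each
#' term carries the developmental time window, in hours post fertilization
#' (hpf), during which it can be observed. Windows are inclusive on both ends.
#'
#' Five terms have special semantics captured by the `category` column:
#' "coagulated" is the sole lethal endpoint, "normal" marks an unaffected
#' embryo, "no embryo" and "miscellaneous" are uninformative, and
#' "beats per minute" / "hours post fertilization" are quantitative
#' measurements rather than yes/no observations. Every other term is a
#' sublethal qualitative effect.
#'
#' @return A tibble with one row per term and columns `effect_id`,
#'   `parent_id` (`NA` for top-level terms), `effect` (the term name),
#'   `window_start_hpf`, `window_end_hpf`, `is_quantitative`, `category`
#'   (one of `"normal"`, `"lethal"`, `"sublethal"`, `"uninformative"`,
#'   `"quantitative"`).
#' @examples
#' vocab <- zfet_vocabulary()
#' nrow(vocab)
#' dplyr::count(vocab, category)
#' @export
zfet_vocabulary <- function() {
  path <- system.file("extdata", "effect_vocabulary.csv", package = "zfetr",
                      mustWork = TRUE)
  read_vocabulary(path)
}

#' Read an effect vocabulary from CSV
#'
#' Reads a vocabulary table (columns `effect_id`, `parent_id`, `effect`,
#' `time_point_start`, `time_point_end`, optionally `category`) and validates
#' it: ids must be unique, parent references must resolve to top-level terms
#' (two-level tree), and time windows must satisfy
#' `0 <= start < end <= 120` hpf. When no `category` column is present,
#' categories are assigned by the packaged id conventions (see
#' [zfet_vocabulary()]); vocabularies extended beyond the packaged 52 terms
#' must declare categories explicitly.
#'
#' @param path Path to a CSV file.
#' @return A validated vocabulary tibble (see [zfet_vocabulary()]).
#' @export
read_vocabulary <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      effect_id = readr::col_integer(),
      parent_id = readr::col_integer(),
      effect = readr::col_character(),
      time_point_start = readr::col_integer(),
      time_point_end = readr::col_integer(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  required <- c("effect_id", "parent_id", "effect",
                "time_point_start", "time_point_end")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("vocabulary file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vocab <- tibble::tibble(
    effect_id = raw$effect_id,
    parent_id = raw$parent_id,
    effect = raw$effect,
    window_start_hpf = raw$time_point_start,
    window_end_hpf = raw$time_point_end
  )
  vocab$is_quantitative <- if ("is_quantitative" %in% names(raw)) {
    as.logical(raw$is_quantitative)
  } else if ("category" %in% names(raw)) {
    raw$category == "quantitative"
  } else {
    vocab$effect_id %in% .quantitative_ids
  }
  vocab$category <- if ("category" %in% names(raw)) {
    raw$category
  } else {
    .default_categories(vocab$effect_id)
  }
  validate_vocabulary(vocab)
}

.default_categories <- function(effect_id) {
  dplyr::case_when(
    effect_id == .lethal_id ~ "lethal",
    effect_id == .normal_id ~ "normal",
    effect_id %in% .uninformative_ids ~ "uninformative",
    effect_id %in% .quantitative_ids ~ "quantitative",
    .default = "sublethal"
  )
}

#' Write an effect vocabulary to CSV
#'
#' Inverse of [read_vocabulary()]: writes the five dialect columns
#' (`effect_id,parent_id,effect,time_point_start,time_point_end`) so that a
#' read/write round trip reproduces the input field for field.
#'
#' @param vocab A vocabulary tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  out <- tibble::tibble(
    effect_id = vocab$effect_id,
    parent_id = vocab$parent_id,
    effect = vocab$effect,
    time_point_start = vocab$window_start_hpf,
    time_point_end = vocab$window_end_hpf
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

validate_vocabulary <- function(vocab) {
  dup <- vocab$effect_id[duplicated(vocab$effect_id)]
  if (length(dup) > 0) {
    stop("duplicate effect_id in vocabulary: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (anyNA(vocab$effect_id)) {
    stop("vocabulary rows with missing effect_id", call. = FALSE)
  }
  bad_window <- vocab$window_start_hpf >= vocab$window_end_hpf |
    vocab$window_start_hpf < 0 | vocab$window_end_hpf > 120
  if (any(bad_window)) {
    stop("invalid time window for effect_id ",
         paste(vocab$effect_id[bad_window], collapse = ", "),
         " (need 0 <= start < end <= 120)", call. = FALSE)
  }
  has_parent <- !is.na(vocab$parent_id)
  dangling <- has_parent & !(vocab$parent_id %in% vocab$effect_id)
  if (any(dangling)) {
    stop("dangling parent_id for effect_id ",
         paste(vocab$effect_id[dangling], collapse = ", "), call. = FALSE)
  }
  # two-level tree: a parent may not itself have a parent
  parent_rows <- match(vocab$parent_id[has_parent], vocab$effect_id)
  grandparent <- !is.na(vocab$parent_id[parent_rows])
  if (any(grandparent)) {
    stop("vocabulary tree is deeper than two levels at effect_id ",
         paste(vocab$effect_id[has_parent][grandparent], collapse = ", "),
         call. = FALSE)
  }
  ok_cat <- c("normal", "lethal", "sublethal", "uninformative", "quantitative")
  if (!all(vocab$category %in% ok_cat)) {
    stop("unknown category: ",
         paste(setdiff(vocab$category, ok_cat), collapse = ", "),
         call. = FALSE)
  }
  vocab
}

.check_effect_ids <- function(vocab, effect_id) {
  unknown <- setdiff(effect_id, vocab$effect_id)
  if (length(unknown) > 0) {
    stop("unknown effect_id: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Is an effect term observable at a given time?
#'
#' Checks whether `time_hpf` falls inside the term's observation window
#' (inclusive on both ends). Vectorised over `effect_id` and `time_hpf`.
#'
#' @param vocab A vocabulary tibble.
#' @param effect_id Integer effect id(s); must exist in `vocab`.
#' @param time_hpf Observation time(s) in hours post fertilization.
#' @return Logical vector.
#' @examples
#' vocab <- zfet_vocabulary()
#' term_valid_at(vocab, 2, 0)    # coagulated, valid from 0 hpf
#' term_valid_at(vocab, 51, 48)  # no swim bladder only from 72 hpf
#' @export
term_valid_at <- function(vocab, effect_id, time_hpf) {
  .check_effect_ids(vocab, effect_id)
  i <- match(effect_id, vocab$effect_id)
  vocab$window_start_hpf[i] <= time_hpf & time_hpf <= vocab$window_end_hpf[i]
}

#' Effect category of a term
#'
#' Maps effect ids to their analysis category: `"lethal"` (coagulated only),
#' `"normal"`, `"uninformative"` (no embryo, miscellaneous), `"quantitative"`
#' (beats per minute, hours post fertilization) or `"sublethal"` (everything
#' else). Vectorised.
#'
#' @inheritParams term_valid_at
#' @return Character vector of categories.
#' @export
effect_category <- function(vocab, effect_id) {
  .check_effect_ids(vocab, effect_id)
  vocab$category[match(effect_id, vocab$effect_id)]
}

#' Term plus all of its children
#'
#' @inheritParams term_valid_at
#' @param effect_id A single effect id.
#' @return Integer vector of effect ids: the term itself followed by its
#'   children in id order (the tree has only two levels, so children have no
#'   descendants of their own).
#' @examples
#' effect_subtree(zfet_vocabulary(), 11)  # edema and its two child terms
#' @export
effect_subtree <- function(vocab, effect_id) {
  stopifnot(length(effect_id) == 1)
  .check_effect_ids(vocab, effect_id)
  children <- vocab$effect_id[!is.na(vocab$parent_id) &
                                vocab$parent_id == effect_id]
  c(as.integer(effect_id), sort(children))
}
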