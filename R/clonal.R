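# Map from user-facing key names to table columns.
.key_columns <- c(loop = "loop_aa", v_gene = "v_call", j_gene = "j_call")

#' Group sequences into clones
#'
#' Groups records sharing 100% amino-acid identity of the H-CDR3 loop
#' (optionally refined by V and/or J gene) into clones. Clones are ordered
#' by descending size, ties broken lexicographically on the key, so the
#' result is deterministic.
#'
#' @param tbl Non-empty rearrangement tibble; loop columns derived if
#'   absent. Typically pre-filtered with [filter_productive()].
#' @param key Subset of `c("loop", "v_gene", "j_gene")`; default `"loop"`.
#' @param compartment Optional label stored on the result (e.g. `"SPL"`).
#' @return A tibble of class `hcdr3_strat`: one row per clone with the key
#'   columns, `clone_id`, `n`, `frequency` and a `member_ids` list column.
#'   Attributes: `total_sequences`, `key_fields`, `compartment`.
#' @export
group_clones <- function(tbl, key = "loop", compartment = NULL) {
  if (nrow(tbl) == 0L) stop("empty table", call. = FALSE)
  if (!all(key %in% names(.key_columns))) {
    stop("key must be a subset of: ", paste(names(.key_columns), collapse = ", "),
         call. = FALSE)
  }
  if (!"loop_aa" %in% names(tbl)) tbl <- annotate_loops(tbl)
  cols <- unname(.key_columns[key])
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0L) {
    stop("key column(s) absent from table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dat <- tbl[stats::complete.cases(tbl[, cols, drop = FALSE]), , drop = FALSE]
  if (nrow(dat) == 0L) stop("no records with complete clone keys", call. = FALSE)
  total <- nrow(dat)
  out <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cols))) |>
    dplyr::summarise(
      n = dplyr::n(),
      member_ids = list(.data$sequence_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(frequency = .data$n / total) |>
    dplyr::arrange(dplyr::desc(.data$n),
                   dplyr::across(dplyr::all_of(cols))) |>
    dplyr::mutate(clone_id = dplyr::row_number(), .before = 1L)
  attr(out, "total_sequences") <- total
  attr(out, "key_fields") <- key
  attr(out, "compartment") <- compartment
  class(out) <- c("hcdr3_strat", class(out))
  out
}

#' Classify clonal expansion categories
#'
#' Applies the three-way expansion rule: a clone of one sequence is
#' `single`; a clone of two or more sequences is `expanded_lt1` when its
#' frequency is below the highly-expanded threshold and `highly_expanded`
#' when at or above it. A clone of size one is always `single`, even if
#' `1/total` reaches the threshold.
#'
#' @param strat Stratification from [group_clones()].
#' @param he_threshold Highly-expanded frequency threshold, fraction of all
#'   sequences in the compartment (default `0.01`).
#' @return `strat` with a `category` factor column and attribute
#'   `he_threshold`.
#' @export
classify_expansion <- function(strat, he_threshold = 0.01) {
  stopifnot(inherits(strat, "hcdr3_strat"))
  if (!(he_threshold > 0 && he_threshold <= 1)) {
    stop("he_threshold must be in (0, 1]", call. = FALSE)
  }
  strat$category <- factor(
    dplyr::case_when(
      strat$n == 1L ~ "single",
      strat$frequency >= he_threshold ~ "highly_expanded",
      TRUE ~ "expanded_lt1"
    ),
    levels = c("single", "expanded_lt1", "highly_expanded")
  )
  attr(strat, "he_threshold") <- he_threshold
  strat
}

#' Smallest clone size reaching the highly-expanded threshold
#'
#' The smallest integer `n` with `n / total >= threshold`, i.e. the
#' ceiling of `threshold * total` (computed with a guard against
#' floating-point overshoot).
#'
#' @param total_sequences Positive sequence count of the compartment.
#' @param threshold Frequency threshold (default `0.01`).
#' @return Integer minimum clone size.
#' @export
#' @examples
#' min_he_clone_size(3299)  # 33
min_he_clone_size <- function(total_sequences, threshold = 0.01) {
  stopifnot(total_sequences > 0, threshold > 0)
  as.integer(ceiling(threshold * total_sequences - 1e-9))
}

#' Clones present in two compartments
#'
#' Intersects two stratifications on their clone keys and reports the
#' per-compartment sizes (and categories when present).
#'
#' @param strat_a,strat_b Stratifications built with identical `key`
#'   fields.
#' @param suffix Column suffixes for the two compartments.
#' @return A tibble with the key columns and suffixed `n`, `frequency`
#'   (and `category`) columns; zero rows when no clone is shared.
#' @export
shared_clones <- function(strat_a, strat_b, suffix = c("_a", "_b")) {
  ka <- attr(strat_a, "key_fields")
  kb <- attr(strat_b, "key_fields")
  if (!identical(ka, kb)) {
    stop("stratifications use different key fields: ",
         paste(ka, collapse = "+"), " vs ", paste(kb, collapse = "+"),
         call. = FALSE)
  }
  cols <- unname(.key_columns[ka])
  keep <- c(cols, "n", "frequency", intersect("category", names(strat_a)))
  a <- tibble::as_tibble(strat_a)[, keep]
  b <- tibble::as_tibble(strat_b)[, c(cols, "n", "frequency",
                                      intersect("category", names(strat_b)))]
  dplyr::inner_join(a, b, by = cols, suffix = suffix)
}

#' Isotype counts per clone
#'
#' Counts `c_call` isotype labels among each clone's member sequences;
#' records lacking an isotype are tallied as `"unknown"`.
#'
#' @param strat Stratification from [group_clones()].
#' @param tbl The rearrangement tibble the stratification was built from.
#' @return A long tibble: `clone_id`, key columns, `c_call`, `n_isotype`.
#' @export
tabulate_isotypes <- function(strat, tbl) {
  stopifnot(inherits(strat, "hcdr3_strat"))
  cols <- unname(.key_columns[attr(strat, "key_fields")])
  iso <- if ("c_call" %in% names(tbl)) tbl$c_call else rep(NA_character_, nrow(tbl))
  iso_by_id <- stats::setNames(ifelse(is.na(iso) | !nzchar(iso), "unknown", iso),
                               tbl$sequence_id)
  tibble::as_tibble(strat) |>
    dplyr::select(dplyr::all_of(c("clone_id", cols, "member_ids"))) |>
    tidyr::unnest(dplyr::all_of("member_ids")) |>
    dplyr::mutate(c_call = unname(iso_by_id[.data$member_ids])) |>
    dplyr::count(dplyr::across(dplyr::all_of(c("clone_id", cols, "c_call"))),
                 name = "n_isotype")
}

#' @exportS3Method generics::glance
glance.hcdr3_strat <- function(x, ...) {
  total <- attr(x, "total_sequences")
  has_cat <- "category" %in% names(x)
  tibble::tibble(
    n_clones = nrow(x),
    total_sequences = total,
    key = paste(attr(x, "key_fields"), collapse = "+"),
    n_single = if (has_cat) sum(x$n[x$category == "single"]) else sum(x$n == 1L),
    expanded_share = if (has_cat) {
      sum(x$n[x$category != "single"]) / total
    } else {
      sum(x$n[x$n > 1L]) / total
    }
  )
}

#' @exportS3Method generics::tidy
tidy.hcdr3_strat <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$member_ids <- NULL
  out
}

#' @export
print.hcdr3_strat <- function(x, ...) {
  cat(sprintf(
    "H-CDR3 stratification: %d clones / %d sequences (key: %s)\n",
    nrow(x), attr(x, "total_sequences"),
    paste(attr(x, "key_fields"), collapse = "+")
  ))
  NextMethod()
}
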