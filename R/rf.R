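#' Normalise a D gene call
#'
#' Strips the allele suffix (`*01`) and a leading `IGH` prefix so that
#' `IGHD1-1*01`, `IGHD1-1` and `D1-1` all resolve to `D1-1`.
#'
#' @param x Character vector of gene calls.
#' @return Character vector of normalised gene names.
#' @export
normalize_d_gene <- function(x) {
  sub("^IGH", "", sub("\\*.*$", "", x))
}

#' Reading-frame anchor map for D segments
#'
#' Loads the per-gene map from translation offset (0/1/2, germline-relative)
#' to reading-frame label I/II/III. The bundled map anchors the tyrosine-
#' enriched frame of each bundled mouse D gene to RFI, with the hydrophobic
#' (valine) frame as RFII and the arginine/stop-bearing frame as RFIII;
#' genes without an entry use the `default` mapping.
#'
#' @param path JSON file; default the map shipped with the package.
#' @return A list with elements `default` (named character vector,
#'   names `"0"`, `"1"`, `"2"`) and `genes` (named list of such vectors).
#' @export
rf_anchor_map <- function(path = system.file("extdata", "rf_anchors.json",
                                             package = "hcdr3")) {
  raw <- jsonlite::read_json(path)
  as_vec <- function(x) vapply(x, as.character, character(1))
  list(
    default = if (!is.null(raw$default)) as_vec(raw$default) else NULL,
    genes = purrr::map(raw$genes, as_vec)
  )
}

.lookup_rf <- function(gene, offset, anchors) {
  map <- anchors$genes[[gene]]
  if (is.null(map)) map <- anchors$default
  if (is.null(map)) {
    stop("D gene absent from anchor map: ", gene, call. = FALSE)
  }
  unname(map[as.character(offset)])
}

#' Assign the D-segment reading frame of each record
#'
#' The translation offset into the germline D segment is
#' `(d_germline_start - d_junction_start) mod 3` under the internal
#' 0-based convention (the junction is codon-aligned, beginning at the
#' Cys-104 codon), and is mapped to the I/II/III label through the anchor
#' map. Records without a D alignment (missing call, coordinates, or
#' `d_length` 0) are returned with `NA` labels ("unassignable") and a
#' message stating the count.
#'
#' @param tbl Rearrangement tibble with `d_call`, `d_junction_start`,
#'   `d_germline_start` (internal 0-based) and `d_length` columns.
#' @param anchors Anchor map, see [rf_anchor_map()] (the default).
#' @return A tibble: `sequence_id`, `d_gene` (normalised), `frame_offset`,
#'   `rf_label`.
#' @export
assign_rf <- function(tbl, anchors = rf_anchor_map()) {
  need <- c("sequence_id", "d_call", "d_junction_start", "d_germline_start")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0L) {
    stop("column(s) required for RF assignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d_len <- if ("d_length" %in% names(tbl)) tbl$d_length else rep(NA_integer_, nrow(tbl))
  assignable <- !is.na(tbl$d_call) & nzchar(tbl$d_call) &
    !is.na(tbl$d_junction_start) & !is.na(tbl$d_germline_start) &
    (is.na(d_len) | d_len > 0L)
  n_drop <- sum(!assignable)
  if (n_drop > 0L) {
    message(n_drop, " record(s) without a usable D alignment left unassigned")
  }
  gene <- ifelse(assignable, normalize_d_gene(tbl$d_call), NA_character_)
  offset <- rep(NA_integer_, nrow(tbl))
  offset[assignable] <- as.integer(
    (tbl$d_germline_start[assignable] - tbl$d_junction_start[assignable]) %% 3L
  )
  label <- rep(NA_character_, nrow(tbl))
  if (any(assignable)) {
    pairs <- unique(data.frame(gene = gene[assignable],
                               offset = offset[assignable]))
    pairs$label <- mapply(.lookup_rf, pairs$gene, pairs$offset,
                          MoreArgs = list(anchors = anchors))
    key <- paste(gene, offset)
    label <- pairs$label[match(key, paste(pairs$gene, pairs$offset))]
  }
  tibble::tibble(
    sequence_id = tbl$sequence_id,
    d_gene = gene,
    frame_offset = offset,
    rf_label = factor(label, levels = c("I", "II", "III"))
  )
}

#' Reading-frame usage distribution
#'
#' Proportions of reading frames I/II/III over assignable records; the
#' unassignable ("no-D") fraction is reported as an attribute, not mixed
#' into the proportions.
#'
#' @param assignments Tibble from [assign_rf()] (or a rearrangement tibble,
#'   in which case [assign_rf()] is applied with default anchors).
#' @return A tibble `rf`, `n`, `proportion` (all three frames always
#'   present), attributes `n_assigned`, `no_d_fraction` and
#'   `weighting = "per_sequence"`.
#' @export
rf_distribution <- function(assignments) {
  if (!"rf_label" %in% names(assignments)) {
    assignments <- assign_rf(assignments)
  }
  lab <- assignments$rf_label[!is.na(assignments$rf_label)]
  if (length(lab) == 0L) stop("no assignable records", call. = FALSE)
  counts <- table(factor(lab, levels = c("I", "II", "III")))
  out <- tibble::tibble(
    rf = names(counts),
    n = as.integer(counts),
    proportion = as.integer(counts) / length(lab)
  )
  attr(out, "n_assigned") <- length(lab)
  attr(out, "no_d_fraction") <-
    1 - length(lab) / nrow(assignments)
  attr(out, "weighting") <- "per_sequence"
  out
}

#' Per-clone reading-frame distribution
#'
#' Each clone contributes one count, regardless of its size. A clone whose
#' members disagree on the reading frame is counted by majority (ties
#' broken towards the lower frame label) with a warning.
#'
#' @param strat Stratification from [group_clones()].
#' @param assignments Tibble from [assign_rf()] covering the member
#'   sequences.
#' @return A tibble as in [rf_distribution()], with
#'   `weighting = "per_clone"`.
#' @export
rf_distribution_per_clone <- function(strat, assignments) {
  stopifnot(inherits(strat, "hcdr3_strat"))
  rf_by_id <- stats::setNames(as.character(assignments$rf_label),
                              assignments$sequence_id)
  discordant <- 0L
  clone_rf <- purrr::map_chr(strat$member_ids, function(ids) {
    labs <- rf_by_id[ids]
    labs <- labs[!is.na(labs)]
    if (length(labs) == 0L) return(NA_character_)
    tab <- table(factor(labs, levels = c("I", "II", "III")))
    if (sum(tab > 0L) > 1L) discordant <<- discordant + 1L
    names(tab)[which.max(tab)]
  })
  if (discordant > 0L) {
    warning(discordant, " clone(s) with discordant member reading frames",
            " counted by majority", call. = FALSE)
  }
  lab <- clone_rf[!is.na(clone_rf)]
  if (length(lab) == 0L) stop("no assignable clones", call. = FALSE)
  counts <- table(factor(lab, levels = c("I", "II", "III")))
  out <- tibble::tibble(
    rf = names(counts),
    n = as.integer(counts),
    proportion = as.integer(counts) / length(lab)
  )
  attr(out, "n_assigned") <- length(lab)
  attr(out, "weighting") <- "per_clone"
  out
}

#' D gene and family usage
#'
#' Counts and proportions of D gene calls (normalised) and of D families
#' (name prefix before the dash, e.g. `D1`). Records without a D call are
#' tallied under `"unresolved"`.
#'
#' @param tbl Rearrangement tibble with a `d_call` column.
#' @return A tibble: `d_gene`, `d_family`, `n`, `proportion`.
#' @export
d_usage <- function(tbl) {
  d <- if ("d_call" %in% names(tbl)) tbl$d_call else rep(NA_character_, nrow(tbl))
  gene <- ifelse(is.na(d) | !nzchar(d), "unresolved", normalize_d_gene(d))
  fam <- ifelse(gene == "unresolved", "unresolved", sub("-.*$", "", gene))
  tibble::tibble(d_gene = gene, d_family = fam) |>
    dplyr::count(.data$d_gene, .data$d_family, name = "n") |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$d_gene)
}
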