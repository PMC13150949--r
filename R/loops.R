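#' Extract the H-CDR3 loop from an IMGT junction
#'
#' The H-CDR3 loop is the junction amino-acid sequence with the three
#' N-terminal residues (IMGT positions 104-106, typically `C-x-x`) and the
#' single C-terminal residue (position 118, the conserved Trp/Phe) removed.
#' A junction of exactly four residues yields an empty loop, flagged
#' degenerate.
#'
#' @param junction_aa Character vector of junction amino-acid strings, each
#'   of length >= 4.
#' @return A tibble with one row per input: `junction_aa`, `loop_aa`,
#'   `loop_length`, `degenerate`.
#' @export
#' @examples
#' extract_loop(c("CTTIRYW", "CARGRFDYW"))
extract_loop <- function(junction_aa) {
  if (length(junction_aa) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(junction_aa) || any(!nzchar(junction_aa))) {
    stop("junction_aa contains empty or missing values", call. = FALSE)
  }
  n <- nchar(junction_aa)
  if (any(n < 4L)) {
    stop("junction shorter than 4 residues: ",
         paste(junction_aa[n < 4L], collapse = ", "), call. = FALSE)
  }
  loop <- substr(junction_aa, 4L, n - 1L)
  tibble::tibble(
    junction_aa = junction_aa,
    loop_aa = loop,
    loop_length = nchar(loop),
    degenerate = nchar(loop) == 0L
  )
}

#' Annotate a rearrangement table with loop columns
#'
#' Adds `loop_aa`, `loop_length` and `degenerate` columns derived from
#' `junction_aa`. Rows with a missing or too-short junction get `NA` loops.
#'
#' @param tbl Rearrangement tibble with a `junction_aa` column.
#' @return `tbl` with loop columns added (existing ones replaced).
#' @export
annotate_loops <- function(tbl) {
  stopifnot("junction_aa" %in% names(tbl))
  aa <- tbl$junction_aa
  ok <- !is.na(aa) & nchar(aa) >= 4L
  loop <- rep(NA_character_, length(aa))
  loop[ok] <- substr(aa[ok], 4L, nchar(aa[ok]) - 1L)
  tbl$loop_aa <- loop
  tbl$loop_length <- ifelse(is.na(loop), NA_integer_, nchar(loop))
  tbl$degenerate <- ifelse(is.na(loop), NA, nchar(loop) == 0L)
  tbl
}

#' H-CDR3 loop length distribution
#'
#' Histogram of loop lengths over a table (degenerate loops counted at
#' length 0), with per-length proportions and the mean length.
#'
#' @param tbl Rearrangement tibble; loop columns are derived on the fly if
#'   absent.
#' @param by Optional character vector of grouping columns (e.g.
#'   `c("population", "genotype")`).
#' @return A tibble with columns `<by>`, `loop_length`, `n`, `proportion`,
#'   plus attributes `total` and `mean_length` (`NA` and flagged for an
#'   empty table). Proportions are within group when `by` is given.
#' @export
length_distribution <- function(tbl, by = NULL) {
  if (!"loop_length" %in% names(tbl)) tbl <- annotate_loops(tbl)
  dat <- tbl[!is.na(tbl$loop_length), , drop = FALSE]
  if (nrow(dat) == 0L) {
    out <- tibble::tibble(loop_length = integer(0), n = integer(0),
                          proportion = numeric(0))
    attr(out, "total") <- 0L
    attr(out, "mean_length") <- NA_real_
    return(out)
  }
  grp <- c(by, "loop_length")
  out <- dat |>
    dplyr::count(dplyr::across(dplyr::all_of(grp)), name = "n") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grp)))
  attr(out, "total") <- nrow(dat)
  attr(out, "mean_length") <- mean(dat$loop_length)
  out
}

#' Compare short-loop usage between two tables
#'
#' For each loop length in `lengths` (default 2-7 aa, the very-short range),
#' reports the proportion of loops of that length in each table and a
#' two-sided exact two-proportion test (Fisher) with Bonferroni correction
#' over the lengths tested.
#'
#' @param tbl_a,tbl_b Non-empty rearrangement tibbles.
#' @param lengths Integer vector of loop lengths to test (default `2:7`).
#' @param labels Length-2 character vector naming the two tables.
#' @return A tibble with columns `loop_length`, `prop_a`, `prop_b`,
#'   `n_a`, `n_b`, `p_value`, `p_adjusted`.
#' @export
short_loop_profile <- function(tbl_a, tbl_b, lengths = 2:7,
                               labels = c("a", "b")) {
  if (length(lengths) == 0L) stop("empty length range", call. = FALSE)
  if (!"loop_length" %in% names(tbl_a)) tbl_a <- annotate_loops(tbl_a)
  if (!"loop_length" %in% names(tbl_b)) tbl_b <- annotate_loops(tbl_b)
  la <- tbl_a$loop_length[!is.na(tbl_a$loop_length)]
  lb <- tbl_b$loop_length[!is.na(tbl_b$loop_length)]
  if (length(la) == 0L || length(lb) == 0L) {
    stop("both tables must contain loops", call. = FALSE)
  }
  res <- purrr::map(lengths, function(len) {
    ka <- sum(la == len)
    kb <- sum(lb == len)
    p <- stats::fisher.test(
      matrix(c(ka, length(la) - ka, kb, length(lb) - kb), nrow = 2L),
      alternative = "two.sided"
    )$p.value
    tibble::tibble(
      loop_length = len,
      prop_a = ka / length(la), prop_b = kb / length(lb),
      n_a = length(la), n_b = length(lb),
      p_value = p
    )
  }) |> purrr::list_rbind()
  res$p_adjusted <- bonferroni(res$p_value, m = length(lengths))
  attr(res, "labels") <- labels
  res
}

#' Count germline V mutations
#'
#' Hamming distance between an observed V region and its aligned germline,
#' over positions where neither carries a gap/alignment symbol
#' (anything outside `A`, `C`, `G`, `T`).
#'
#' @param record_nt Character vector of aligned observed V sequences.
#' @param germline_nt Character vector (recycled if scalar) of aligned
#'   germline V sequences of matching lengths.
#' @return Integer vector of mutation counts.
#' @export
#' @examples
#' count_v_mutations("ACGT", "ACGA")
count_v_mutations <- function(record_nt, germline_nt) {
  if (length(germline_nt) == 1L) {
    germline_nt <- rep(germline_nt, length(record_nt))
  }
  if (length(record_nt) != length(germline_nt)) {
    stop("record and germline vectors differ in length", call. = FALSE)
  }
  if (any(nchar(record_nt) != nchar(germline_nt))) {
    stop("aligned sequences differ in length", call. = FALSE)
  }
  purrr::map2_int(record_nt, germline_nt, function(r, g) {
    a <- strsplit(r, "", fixed = TRUE)[[1]]
    b <- strsplit(g, "", fixed = TRUE)[[1]]
    valid <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    sum(a[valid] != b[valid])
  })
}

#' Plot a loop length distribution
#'
#' @param tbl Rearrangement tibble.
#' @param by Optional grouping columns used for facetting/fill.
#' @return A ggplot object (normalised histogram of loop lengths).
#' @export
plot_length_distribution <- function(tbl, by = NULL) {
  dist <- length_distribution(tbl, by = by)
  p <- ggplot2::ggplot(dist, ggplot2::aes(x = .data$loop_length,
                                          y = .data$proportion)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "H-CDR3 loop length (aa)", y = "frequency") +
    ggplot2::theme_minimal()
  if (!is.null(by)) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(
      paste("~", paste(by, collapse = "+"))))
  }
  p
}
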