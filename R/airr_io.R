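#' @importFrom rlang .data
NULL

# Columns the reader treats as mandatory in a rearrangement TSV.
.mandatory_cols <- c("sequence_id", "junction_aa", "v_call")

# 1-based closed start coordinates on disk; 0-based half-open internally.
.start_coord_cols <- c("d_junction_start", "d_germline_start")

#' Convert AIRR (1-based closed) start coordinates to internal 0-based
#'
#' Internal arithmetic (reading-frame offsets, slicing) uses 0-based
#' half-open coordinates; rearrangement TSVs on disk use the AIRR standard
#' 1-based closed convention. These two helpers convert start positions and
#' are exact inverses of each other.
#'
#' @param x Integer vector of start positions.
#' @return Integer vector in the other convention.
#' @export
#' @examples
#' coord_to_internal(1L)  # first base -> 0
#' coord_to_airr(coord_to_internal(7L))
coord_to_internal <- function(x) as.integer(x) - 1L

#' @rdname coord_to_internal
#' @export
coord_to_airr <- function(x) as.integer(x) + 1L

#' Read an AIRR-style rearrangement table
#'
#' Reads a tab-delimited rearrangement table (one row per sequence) into a
#' tibble, converting start coordinates to the internal 0-based convention.
#' Missing optional columns are simply absent from the result; rows lacking
#' `junction_aa` are kept and excluded later by [filter_productive()].
#'
#' @param path Path to a UTF-8, tab-delimited file with a header containing
#'   at least `sequence_id`, `junction_aa` and `v_call`.
#' @param population,genotype Optional labels stored in the `population` /
#'   `genotype` columns of every row (overriding any columns in the file).
#' @param validate Check coordinate and junction-length invariants
#'   (default `TRUE`).
#' @return A tibble of rearrangement records with attribute `provenance`
#'   set to `path`.
#' @export
read_rearrangements <- function(path, population = NULL, genotype = NULL,
                                validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(.mandatory_cols, names(tbl))
  if (length(missing) > 0L) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- tbl$sequence_id[duplicated(tbl$sequence_id)]
  if (length(dup) > 0L) {
    stop("duplicate sequence_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if ("productive" %in% names(tbl)) {
    tbl$productive <- toupper(tbl$productive) %in% c("T", "TRUE")
  }
  for (col in intersect(.start_coord_cols, names(tbl))) {
    tbl[[col]] <- coord_to_internal(tbl[[col]])
  }
  if ("d_length" %in% names(tbl)) tbl$d_length <- as.integer(tbl$d_length)
  for (col in intersect(c("loop_length", "v_mutation_count"), names(tbl))) {
    tbl[[col]] <- as.integer(tbl[[col]])
  }
  num_cols <- intersect(c("net_charge", "gravy", paste0("fasgai_f", 1:6)),
                        names(tbl))
  for (col in num_cols) tbl[[col]] <- as.numeric(tbl[[col]])
  if (!is.null(population)) tbl$population <- population
  if (!is.null(genotype)) tbl$genotype <- genotype
  if (validate) validate_rearrangements(tbl)
  attr(tbl, "provenance") <- path
  tbl
}

#' Validate rearrangement-record invariants
#'
#' Checks, where the relevant columns are present: nucleotide/amino-acid
#' junction lengths consistent (3:1), D alignment contained in the junction,
#' and non-negative internal coordinates.
#'
#' @param tbl Rearrangement tibble (internal coordinates).
#' @return Invisibly `tbl`; aborts with offending `sequence_id`s otherwise.
#' @export
validate_rearrangements <- function(tbl) {
  bad <- character(0)
  if (all(c("junction", "junction_aa") %in% names(tbl))) {
    both <- !is.na(tbl$junction) & !is.na(tbl$junction_aa)
    off <- both & nchar(tbl$junction) != 3L * nchar(tbl$junction_aa)
    bad <- c(bad, tbl$sequence_id[off])
  }
  if (all(c("junction", "d_junction_start", "d_length") %in% names(tbl))) {
    has <- !is.na(tbl$d_junction_start) & !is.na(tbl$d_length) &
      !is.na(tbl$junction)
    off <- has & (tbl$d_junction_start < 0L | tbl$d_length < 0L |
                    tbl$d_junction_start + tbl$d_length > nchar(tbl$junction))
    bad <- c(bad, tbl$sequence_id[off])
  }
  if ("d_germline_start" %in% names(tbl)) {
    off <- !is.na(tbl$d_germline_start) & tbl$d_germline_start < 0L
    bad <- c(bad, tbl$sequence_id[off])
  }
  if (length(bad) > 0L) {
    stop("invalid rearrangement record(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  invisible(tbl)
}

#' Write a rearrangement table to AIRR-style TSV
#'
#' The on-disk file uses 1-based closed start coordinates; reading it back
#' with [read_rearrangements()] reproduces the input fields.
#'
#' @param tbl Rearrangement tibble (internal coordinates).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rearrangements <- function(tbl, path) {
  out <- tbl
  for (col in intersect(.start_coord_cols, names(out))) {
    out[[col]] <- coord_to_airr(out[[col]])
  }
  if ("productive" %in% names(out)) {
    out$productive <- ifelse(out$productive, "T", "F")
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a germline segment set from FASTA
#'
#' @param path FASTA file of nucleotide segments.
#' @param kind One of `"V"`, `"D"`, `"J"`.
#' @return A tibble with columns `name`, `kind`, `sequence_nt`, `family`
#'   (family parsed from the name prefix before the first dash, e.g.
#'   `D1-1` -> `D1`).
#' @export
read_germline_fasta <- function(path, kind = c("V", "D", "J")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate segment name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  sq <- as.character(seqs)
  if (any(!grepl("^[ACGT]+$", sq))) {
    stop("non-ACGT characters in segment(s): ",
         paste(nm[!grepl("^[ACGT]+$", sq)], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    name = nm,
    kind = kind,
    sequence_nt = unname(sq),
    family = sub("-.*$", "", nm)
  )
}

#' Write a germline segment set to FASTA
#'
#' @param segments Tibble as returned by [read_germline_fasta()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_germline_fasta <- function(segments, path) {
  x <- Biostrings::DNAStringSet(segments$sequence_nt)
  names(x) <- segments$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Keep productive records
#'
#' Restricts a table to the analysis universe: records flagged productive
#' whose junction has no stop codon, a nucleotide length that is a multiple
#' of three (when the nucleotide junction is present), and an amino-acid
#' junction bounded by the conserved Cys-104 and Trp/Phe-118. Row order is
#' preserved and the filter is idempotent.
#'
#' @param tbl Rearrangement tibble.
#' @param dedupe Also deduplicate on exact nucleotide junction within each
#'   population (default `FALSE`; the first occurrence is kept).
#' @return The filtered tibble.
#' @export
filter_productive <- function(tbl, dedupe = FALSE) {
  keep <- rep(TRUE, nrow(tbl))
  if ("productive" %in% names(tbl)) keep <- keep & !is.na(tbl$productive) & tbl$productive
  aa <- tbl$junction_aa
  keep <- keep & !is.na(aa) & nzchar(aa) &
    !grepl("*", aa, fixed = TRUE) &
    substr(aa, 1L, 1L) == "C" &
    substr(aa, nchar(aa), nchar(aa)) %in% c("W", "F")
  if ("junction" %in% names(tbl)) {
    keep <- keep & !is.na(tbl$junction) & nchar(tbl$junction) %% 3L == 0L
  }
  out <- tbl[keep & !is.na(keep), , drop = FALSE]
  if (dedupe && "junction" %in% names(out)) {
    grp <- if ("population" %in% names(out)) {
      paste(out$population, out$junction, sep = "\r")
    } else {
      out$junction
    }
    out <- out[!duplicated(grp), , drop = FALSE]
  }
  out
}
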