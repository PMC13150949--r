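#' Henderson--Hasselbalch net charge of a peptide
#'
#' Net charge in elementary-charge units at a given pH: the sum over basic
#' groups (Arg, Lys, His side chains, optionally the free amino terminus) of
#' `1 / (1 + 10^(pH - pKa))` minus the sum over acidic groups (Asp, Glu,
#' Cys, Tyr side chains, optionally the free carboxyl terminus) of
#' `1 / (1 + 10^(pKa - pH))`.
#'
#' @param peptide Character vector of peptides (standard one-letter codes).
#' @param pH Dimensionless pH (default 7).
#' @param pka Named pKa vector, see [pka_lehninger()] (the default).
#' @param include_termini Count the free N-/C-terminal groups
#'   (default `TRUE`). An excised loop is chemically an internal fragment,
#'   so the toggle is provided; the default matches common peptide-property
#'   software.
#' @return Numeric vector of net charges.
#' @export
#' @examples
#' net_charge("GRFDY") - net_charge("GGFDY")  # ~ +1: one guanidinium
net_charge <- function(peptide, pH = 7, pka = pka_lehninger(),
                       include_termini = TRUE) {
  vapply(peptide, function(p) {
    res <- check_standard_peptide(p)
    pos <- sum(1 / (1 + 10^(pH - pka[res[res %in% .basic_residues]])))
    neg <- sum(1 / (1 + 10^(pka[res[res %in% .acidic_residues]] - pH)))
    if (include_termini) {
      pos <- pos + 1 / (1 + 10^(pH - pka[["nTer"]]))
      neg <- neg + 1 / (1 + 10^(pka[["cTer"]] - pH))
    }
    pos - neg
  }, numeric(1), USE.NAMES = FALSE)
}

#' GRAVY hydropathy index
#'
#' Grand average of hydropathy: the arithmetic mean of per-residue
#' Kyte--Doolittle hydropathy values over the peptide.
#'
#' @param peptide Character vector of peptides.
#' @param table Named hydropathy vector over the 20 standard residues
#'   (default [kyte_doolittle()]).
#' @return Numeric vector of dimensionless scores.
#' @export
#' @examples
#' gravy("IRY")
gravy <- function(peptide, table = kyte_doolittle()) {
  stopifnot(setequal(names(table), .standard_aa))
  vapply(peptide, function(p) {
    res <- check_standard_peptide(p)
    mean(table[res])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Six-factor descriptor vector of a peptide
#'
#' Element-wise mean of the per-residue six-factor descriptor values
#' (see [fasgai_factors()]) across the peptide.
#'
#' @param peptide Character vector of peptides.
#' @param table Descriptor tibble with columns `aa`, `F1` ... `F6`.
#' @return A tibble with one row per peptide and columns `F1` ... `F6`.
#' @export
#' @examples
#' fasgai_vector("IRY")
fasgai_vector <- function(peptide, table = fasgai_factors()) {
  m <- as.matrix(table[, paste0("F", 1:6)])
  rownames(m) <- table$aa
  out <- t(vapply(peptide, function(p) {
    res <- check_standard_peptide(p)
    colMeans(m[res, , drop = FALSE])
  }, numeric(6), USE.NAMES = FALSE))
  tibble::as_tibble(out, .name_repair = ~ paste0("F", 1:6))
}

#' Annotate a table with loop physicochemical properties
#'
#' Adds `net_charge`, `gravy` and `fasgai_f1` ... `fasgai_f6` columns
#' computed on the H-CDR3 loop (never the full junction). Degenerate
#' (empty) loops and loops with non-standard residues get `NA`s.
#'
#' @param tbl Rearrangement tibble; loop columns are derived if absent.
#' @param pH pH for the net-charge calculation (default 7).
#' @param include_termini Passed to [net_charge()].
#' @return `tbl` with property columns added.
#' @export
annotate_physchem <- function(tbl, pH = 7, include_termini = TRUE) {
  if (!"loop_aa" %in% names(tbl)) tbl <- annotate_loops(tbl)
  eligible <- !is.na(tbl$loop_aa) & nchar(tbl$loop_aa) > 0L &
    !grepl(paste0("[^", paste(.standard_aa, collapse = ""), "]"), tbl$loop_aa)
  tbl$net_charge <- NA_real_
  tbl$gravy <- NA_real_
  for (k in 1:6) tbl[[paste0("fasgai_f", k)]] <- NA_real_
  if (any(eligible)) {
    loops <- tbl$loop_aa[eligible]
    uniq <- unique(loops)
    idx <- match(loops, uniq)
    ch <- net_charge(uniq, pH = pH, include_termini = include_termini)
    gr <- gravy(uniq)
    fv <- fasgai_vector(uniq)
    tbl$net_charge[eligible] <- ch[idx]
    tbl$gravy[eligible] <- gr[idx]
    for (k in 1:6) {
      tbl[[paste0("fasgai_f", k)]][eligible] <- fv[[paste0("F", k)]][idx]
    }
  }
  tbl
}

#' Per-population mean physicochemical profiles
#'
#' Arithmetic means of loop length, net charge, GRAVY and each six-factor
#' descriptor per group, over loops eligible for property calculation
#' (non-degenerate, standard residues). Ineligible records are excluded
#' with a message stating the count; groups with no eligible loop are
#' dropped with a warning.
#'
#' @param tbl Rearrangement tibble (property columns derived if absent).
#' @param by Grouping columns (default `c("population", "genotype")`,
#'   intersected with the columns present).
#' @param pH,include_termini Passed to [annotate_physchem()] when needed.
#' @return A tibble with one row per group: `<by>`, `n`, `mean_length`,
#'   `mean_charge`, `mean_gravy`, `F1` ... `F6`.
#' @export
population_profiles <- function(tbl, by = c("population", "genotype"),
                                pH = 7, include_termini = TRUE) {
  by <- intersect(by, names(tbl))
  if (length(by) == 0L) stop("no grouping columns present", call. = FALSE)
  if (!"net_charge" %in% names(tbl)) {
    tbl <- annotate_physchem(tbl, pH = pH, include_termini = include_termini)
  }
  n_excluded <- sum(is.na(tbl$net_charge))
  if (n_excluded > 0L) {
    message(n_excluded,
            " record(s) without an eligible loop excluded from profiles")
  }
  groups_all <- dplyr::distinct(tbl, dplyr::across(dplyr::all_of(by)))
  dat <- tbl[!is.na(tbl$net_charge), , drop = FALSE]
  out <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_length = mean(.data$loop_length),
      mean_charge = mean(.data$net_charge),
      mean_gravy = mean(.data$gravy),
      F1 = mean(.data$fasgai_f1), F2 = mean(.data$fasgai_f2),
      F3 = mean(.data$fasgai_f3), F4 = mean(.data$fasgai_f4),
      F5 = mean(.data$fasgai_f5), F6 = mean(.data$fasgai_f6),
      .groups = "drop"
    )
  if (nrow(out) < nrow(groups_all)) {
    warning("group(s) with zero eligible loops omitted", call. = FALSE)
  }
  out
}
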