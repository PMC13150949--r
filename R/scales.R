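#' Lehninger side-chain and terminal pKa values
#'
#' Dissociation constants used for Henderson--Hasselbalch net-charge
#' calculations, as tabulated in Nelson & Cox, *Lehninger Principles of
#' Biochemistry* (standard free amino-acid values). Basic groups: Arg, Lys,
#' His and the free alpha-amino terminus; acidic groups: Asp, Glu, Cys, Tyr
#' and the free alpha-carboxyl terminus.
#'
#' @return A named numeric vector with elements `nTer`, `cTer`, `C`, `D`,
#'   `E`, `H`, `K`, `R`, `Y` (pKa units).
#' @export
#' @examples
#' pka_lehninger()["R"]
pka_lehninger <- function() {
  c(
    nTer = 9.69, cTer = 2.34,
    C = 8.33, D = 3.65, E = 4.25, H = 6.00,
    K = 10.53, R = 12.48, Y = 10.07
  )
}

# residues whose side chain gains a proton (positive when protonated)
.basic_residues <- c("R", "K", "H")
# residues whose side chain loses a proton (negative when deprotonated)
.acidic_residues <- c("D", "E", "C", "Y")

#' Kyte--Doolittle hydropathy scale
#'
#' Per-residue hydropathy values of Kyte & Doolittle (1982, J Mol Biol 157)
#' used for the GRAVY (grand average of hydropathy) index. Positive values
#' are hydrophobic.
#'
#' @return A named numeric vector over the 20 standard residues
#'   (one-letter codes), dimensionless.
#' @export
#' @examples
#' kyte_doolittle()[c("I", "R", "Y")]
kyte_doolittle <- function() {
  c(
    A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
  )
}

.standard_aa <- names(kyte_doolittle())

#' Check a peptide for standard residues
#'
#' @param peptide Character scalar, one-letter amino-acid codes.
#' @param what Label used in error messages.
#' @return Invisibly, the vector of residues.
#' @keywords internal
check_standard_peptide <- function(peptide, what = "peptide") {
  if (length(peptide) != 1L || is.na(peptide) || !nzchar(peptide)) {
    stop(what, " must be a non-empty amino-acid string", call. = FALSE)
  }
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  bad <- which(!res %in% .standard_aa)
  if (length(bad) > 0L) {
    stop(
      sprintf(
        "non-standard residue '%s' at position %d of %s '%s'",
        res[bad[1]], bad[1], what, peptide
      ),
      call. = FALSE
    )
  }
  invisible(res)
}
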