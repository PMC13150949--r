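#' Six-factor amino-acid descriptor set (synthetic)
#'
#' A six-factor per-residue descriptor table in the style of factor-analysis
#' amino-acid scales (FASGAI-like), used to summarise H-CDR3 loops as
#' 6-vectors. This table is a **synthetic reconstruction**, not the published
#' FASGAI matrix: each factor is a single well-established property scale,
#' standardised to mean 0 and unit standard deviation over the 20 standard
#' residues, chosen to carry the same semantics as the six published factors:
#'
#' * `F1` hydrophobicity — Kyte--Doolittle hydropathy;
#' * `F2` alpha/turn propensity — Chou--Fasman helix propensity (P-alpha);
#' * `F3` bulky properties — Zamyatnin side-chain volume;
#' * `F4` compositional characteristics — Grantham composition
#'   (non-carbon to carbon atomic-weight ratio of the side chain);
#' * `F5` local flexibility — side-chain rotatable-bond count;
#' * `F6` electronic properties — fractional side-chain charge at pH 7
#'   under the Lehninger pKa table.
#'
#' Because every factor is a per-residue lookup averaged over the loop, all
#' downstream operations (loop means, population means, PCA) have exactly the
#' same form as with the published matrix; absolute factor values differ.
#'
#' @return A tibble with columns `aa`, `F1` ... `F6` (20 rows, dimensionless).
#' @export
#' @examples
#' fasgai_factors()
fasgai_factors <- function() {
  aa <- .standard_aa
  # Chou & Fasman (1978) helix propensity P-alpha
  chou_fasman_alpha <- c(
    A = 1.42, R = 0.98, N = 0.67, D = 1.01, C = 0.70,
    Q = 1.11, E = 1.51, G = 0.57, H = 1.00, I = 1.08,
    L = 1.21, K = 1.16, M = 1.45, F = 1.13, P = 0.57,
    S = 0.77, T = 0.83, W = 1.08, Y = 0.69, V = 1.06
  )
  # Zamyatnin (1972) residue volume, cubic Angstrom
  volume <- c(
    A =  88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
    Q = 143.8, E = 138.4, G =  60.1, H = 153.2, I = 166.7,
    L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
    S =  89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0
  )
  # Grantham (1974) composition c
  grantham_c <- c(
    A = 0.00, R = 0.65, N = 1.33, D = 1.38, C = 2.75,
    Q = 0.89, E = 0.92, G = 0.74, H = 0.58, I = 0.00,
    L = 0.00, K = 0.33, M = 0.00, F = 0.00, P = 0.39,
    S = 1.42, T = 0.71, W = 0.13, Y = 0.20, V = 0.00
  )
  # freely rotatable side-chain bonds (chemical structure count)
  rotatable <- c(
    A = 0, R = 4, N = 2, D = 2, C = 1,
    Q = 3, E = 3, G = 0, H = 2, I = 2,
    L = 2, K = 4, M = 3, F = 2, P = 0,
    S = 1, T = 1, W = 2, Y = 2, V = 1
  )
  pka <- pka_lehninger()
  side_charge <- stats::setNames(numeric(20), aa)
  side_charge[.basic_residues] <- 1 / (1 + 10^(7 - pka[.basic_residues]))
  side_charge[.acidic_residues] <- -1 / (1 + 10^(pka[.acidic_residues] - 7))

  std <- function(x) as.numeric(scale(x[aa]))
  tibble::tibble(
    aa = aa,
    F1 = std(kyte_doolittle()),
    F2 = std(chou_fasman_alpha),
    F3 = std(volume),
    F4 = std(grantham_c),
    F5 = std(rotatable),
    F6 = std(side_charge)
  )
}
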