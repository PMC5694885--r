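# Residue masses (Da). Average masses are the default because gel-scale
# (SDS-PAGE) molecular masses are what virion proteomics reports compare to;
# a monoisotopic table is available for MS-level work.

.AA_AVERAGE <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.AA_MONO <- c(
  G = 57.02146,  A = 71.03711,  S = 87.03203,  P = 97.05276,  V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.WATER_AVERAGE <- 18.01524
.WATER_MONO <- 18.010565

#' Molecular mass of a polypeptide chain
#'
#' Sums residue masses over the sequence and adds one water. The empty
#' sequence therefore returns the mass of water. Average residue masses are
#' the default; monoisotopic masses can be requested for MS-level work.
#'
#' @param sequence Amino-acid string over the 20 standard one-letter codes.
#' @param monoisotopic Use monoisotopic instead of average residue masses.
#' @param tolerate_x If `TRUE`, `X` (unknown residue) is permitted and
#'   contributes the mean residue mass of the table in use.
#' @return Mass in Da (numeric scalar). Vectorised over `sequence`.
#' @examples
#' average_mass("G")            # 75.07 Da
#' mass_kda(average_mass("G"))  # 0.1
#' @export
average_mass <- function(sequence, monoisotopic = FALSE, tolerate_x = FALSE) {
  table <- if (monoisotopic) .AA_MONO else .AA_AVERAGE
  water <- if (monoisotopic) .WATER_MONO else .WATER_AVERAGE
  if (tolerate_x) table <- c(table, X = mean(table))
  vapply(sequence, function(s) {
    if (is.na(s)) return(NA_real_)
    if (!nzchar(s)) return(water)
    aa <- strsplit(s, "", fixed = TRUE)[[1]]
    m <- table[aa]
    if (anyNA(m)) {
      bad <- which(is.na(m))[1]
      stop("unknown residue '", aa[bad], "' at position ", bad,
           " in sequence", call. = FALSE)
    }
    sum(m) + water
  }, numeric(1), USE.NAMES = FALSE)
}

#' Report-scale molecular mass in kDa
#'
#' Divides a mass in Da by 1000 and rounds half-up to one decimal, the
#' precision at which gel-scale protein masses are reported. Internal
#' computations keep full precision; use this only at report time.
#'
#' @param mass_da Mass in Da.
#' @return Mass in kDa rounded to 1 decimal.
#' @export
mass_kda <- function(mass_da) {
  round_half_up(mass_da / 1000, 1)
}

# round() in R rounds half to even; reported tables round half away from zero.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
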