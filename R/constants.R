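# Physical constants and reference tables used throughout the package.
# Isotope masses and abundances are fixed IUPAC values compiled in; nothing
# is fetched at run time.

## mass of a proton (H+), Da
PROTON_MASS <- 1.007276

## centroided spacing between adjacent isotopomer peaks, Da.  This is the
## conventional averaged mass difference between neighbouring isotopomer
## clusters of peptides/proteins, not the physical neutron mass; using it
## reproduces the ~1.00235/z Th peak spacing of centroided envelopes.
ISOTOPE_SPACING <- 1.00235

## monoisotopic masses of the neutral-loss molecules, Da
H2O_MASS <- 18.010565
NH3_MASS <- 17.026549

## averagine unit (Senko-style average amino-acid residue):
## C4.9384 H7.7583 N1.3577 O1.4773 S0.0417, average mass 111.1254 Da
AVERAGINE_UNIT <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
AVERAGINE_UNIT_MASS <- 111.1254

## isotope tables (IUPAC standard values) for the CHNOS element set.
## `shift` is the neutron count relative to the lightest isotope; note the
## hole at shift 3 for sulfur (no 35S in the natural table).
ELEMENT_ISOTOPES <- list(
  C = data.frame(shift = c(0L, 1L),
                 mass = c(12.0000000, 13.0033548),
                 abundance = c(0.9893, 0.0107)),
  H = data.frame(shift = c(0L, 1L),
                 mass = c(1.0078250, 2.0141018),
                 abundance = c(0.999885, 0.000115)),
  N = data.frame(shift = c(0L, 1L),
                 mass = c(14.0030740, 15.0001089),
                 abundance = c(0.99636, 0.00364)),
  O = data.frame(shift = c(0L, 1L, 2L),
                 mass = c(15.9949146, 16.9991318, 17.9991596),
                 abundance = c(0.99757, 0.00038, 0.00205)),
  S = data.frame(shift = c(0L, 1L, 2L, 4L),
                 mass = c(31.9720710, 32.9714588, 33.9678669, 35.9670808),
                 abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
)

## per-element monoisotopic mass (most abundant isotope) and average mass
ELEMENT_MONO_MASS <- vapply(ELEMENT_ISOTOPES, function(d) {
  d$mass[which.max(d$abundance)]
}, numeric(1))

ELEMENT_AVG_MASS <- vapply(ELEMENT_ISOTOPES, function(d) {
  sum(d$mass * d$abundance)
}, numeric(1))

## monoisotopic masses of the 20 standard amino-acid residues, Da
RESIDUE_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

## average masses of the 20 standard amino-acid residues, Da
RESIDUE_AVG_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

#' Average amino-acid residue mass
#'
#' Unweighted mean of the average masses of the 20 standard amino-acid
#' residues (about 118.89 Da). Used to estimate protein length, and from it
#' the number of envelope matches to report, from a precursor mass.
#'
#' @return Average residue mass in Da.
#' @export
average_residue_mass <- function() {
  mean(RESIDUE_AVG_MASS)
}

## package-level cache (memoised default FDR table etc.)
.ldeconv_cache <- new.env(parent = emptyenv())
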