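# Monoisotopic mass arithmetic for the derivatization-product identity check.
#
# Sulfide dibimane (SDB), the fluorescent product of H2S + 2 MBB, has
# elemental composition C20H22N4O4S; its protonated molecular ion is the
# identity anchor used when a mass spectrometer confirms the FLD peak.

# Monoisotopic masses of the most abundant isotope (u), CODATA/IUPAC values.
.MONOISOTOPIC <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268,
  Br = 78.9183371,
  Fe = 55.9349375
)

.PROTON_MASS <- 1.007276466879

#' Parse a molecular formula string into element counts
#'
#' @param formula a Hill-style formula string such as `"C20H22N4O4S"`.
#' @return named integer vector of element counts.
#' @examples
#' parse_formula("C20H22N4O4S")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (!nzchar(formula)) stopf("empty molecular formula")
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  parts <- regmatches(formula, list(tokens))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stopf("could not parse molecular formula '%s'", formula)
  }
  elements <- sub("[0-9]*$", "", parts)
  counts <- as.integer(ifelse(grepl("[0-9]+$", parts),
                              sub("^[A-Za-z]+", "", parts), "1"))
  tapply(counts, elements, sum)
}

#' Monoisotopic mass-to-charge ratio of an elemental formula
#'
#' Computes the monoisotopic mass of a neutral formula and, for a charged
#' species, the m/z after optional protonation.  The SDB molecular ion
#' \eqn{[M+H]^+} of C20H22N4O4S evaluates to 415.14 at two decimals, the
#' value used to confirm the peak identity by UPLC-QTOF-MS.
#'
#' @param formula molecular formula string or named count vector
#'   (e.g. `c(C = 20, H = 22, N = 4, O = 4, S = 1)`).
#' @param adduct `"none"` or `"plus_H"`; `"plus_H"` adds one proton mass.
#' @param charge integer charge; 0 returns the neutral (adducted) mass,
#'   otherwise the mass is divided by `abs(charge)`.
#' @param decimals decimals for the reported value (default 2, matching the
#'   instrument's printout); the raw value is returned in `mz_raw`.
#' @return list with `mz` (rounded) and `mz_raw`.
#' @examples
#' monoisotopic_mz("C20H22N4O4S", adduct = "plus_H", charge = 1)$mz  # 415.14
#' monoisotopic_mz("H2S", decimals = 4)$mz                           # 33.9877
#' @export
monoisotopic_mz <- function(formula, adduct = c("none", "plus_H"),
                            charge = 0L, decimals = 2L) {
  adduct <- match.arg(adduct)
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (length(counts) == 0L) stopf("formula has no elements")
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stopf("element counts must be named")
  }
  if (any(counts < 0)) stopf("element counts must be non-negative")
  unknown <- setdiff(names(counts), names(.MONOISOTOPIC))
  if (length(unknown)) {
    stopf("unknown element symbol(s): %s", paste(unknown, collapse = ", "))
  }
  mass <- sum(.MONOISOTOPIC[names(counts)] * as.numeric(counts))
  if (adduct == "plus_H") mass <- mass + .PROTON_MASS
  mz <- if (charge == 0L) mass else mass / abs(charge)
  list(mz = round(mz, decimals), mz_raw = mz)
}
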