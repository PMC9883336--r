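#' Monoisotopic atomic masses
#'
#' Monoisotopic masses (Da) of the elements used throughout the package,
#' taken from the CODATA/AME2020 values commonly tabulated for mass
#' spectrometry: C = 12 (exact), H = 1.00782503207, O = 15.9949146196,
#' N = 14.0030740048.
#'
#' @return Named numeric vector of monoisotopic masses in Da.
#' @examples
#' element_masses()[["O"]]
#' @export
element_masses <- function() {
  c(C = 12, H = 1.00782503207, O = 15.9949146196, N = 14.0030740048)
}

# rest mass of the electron in Da
ELECTRON_MASS <- 0.00054857990924

# mass of a proton adduct (one H atom; the electron is handled separately)
.adduct_formula <- function(adduct) {
  switch(adduct,
    H    = c(H = 1L),
    NH4  = c(N = 1L, H = 4L),
    none = integer(0),
    stop("unknown adduct kind: ", adduct, call. = FALSE)
  )
}

#' Round half away from zero
#'
#' Display rounding used for m/z (4 decimals) and ppm (3 decimals) so that
#' values ending in 5 round up, matching conventional table formatting, unlike
#' [base::round()]'s round-half-even.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.canonical_formula <- function(f) {
  f <- f[f != 0]
  if (length(f) == 0) return(structure(integer(0), names = character(0)))
  syms <- names(f)
  # Hill order: C first, H second, remaining elements alphabetical
  ord <- order(match(syms, c("C", "H"), nomatch = 3L), syms)
  storage.mode(f) <- "integer"
  f[ord]
}

.as_formula <- function(f) {
  if (is.character(f)) return(formula_parse(f))
  if (is.numeric(f) && !is.null(names(f))) {
    if (any(f < 0)) stop("negative element count in formula", call. = FALSE)
    if (any(f != round(f))) stop("non-integer element count", call. = FALSE)
    return(.canonical_formula(f))
  }
  if (is.numeric(f) && length(f) == 0) return(.canonical_formula(integer(0)))
  stop("not a molecular formula: supply a string like \"C22H38O3\" or a named count vector",
       call. = FALSE)
}

#' Parse a molecular formula string
#'
#' Parses Hill-notation formula strings such as `"C22H38O3"` into a named
#' integer vector of element counts. Element symbols must be known to
#' [element_masses()]; a missing count means 1.
#'
#' @param text formula string, e.g. `"C22H38O3"`, `"CH4"`, `"O"`
#' @return named integer vector (element -> count) in Hill order
#' @seealso [formula_format()] for the inverse
#' @examples
#' formula_parse("C22H38O3")
#' @export
formula_parse <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  if (text == "" || text == "0") return(.canonical_formula(integer(0)))
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", text))
    stop("malformed formula string: ", text, call. = FALSE)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  parts <- regmatches(text, list(m))[[1]]
  syms <- sub("[0-9]*$", "", parts)
  cnts <- sub("^[A-Z][a-z]?", "", parts)
  cnts <- ifelse(cnts == "", 1L, suppressWarnings(as.integer(cnts)))
  if (anyNA(cnts) || any(cnts <= 0))
    stop("malformed count in formula string: ", text, call. = FALSE)
  unknown <- setdiff(syms, names(element_masses()))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  out <- tapply(cnts, syms, sum)
  .canonical_formula(structure(as.integer(out), names = names(out)))
}

#' Format a molecular formula
#'
#' Inverse of [formula_parse()]: writes a count vector as a Hill-notation
#' string (C, H, then alphabetical; count 1 implicit).
#'
#' @param f formula (string or named count vector)
#' @return character scalar
#' @examples
#' formula_format(c(O = 3, H = 38, C = 22))
#' @export
formula_format <- function(f) {
  f <- .as_formula(f)
  if (length(f) == 0) return("")
  paste0(names(f), ifelse(f == 1, "", f), collapse = "")
}

#' Formula arithmetic
#'
#' Element-wise addition and subtraction of molecular formulas. Subtraction
#' below zero is an error (an ion cannot lose atoms it does not have).
#'
#' @param a,b formulas (strings or named count vectors)
#' @return named integer vector in Hill order
#' @examples
#' formula_add("C18H32O2", "C3H8O3")
#' formula_subtract("C19H32O3", "HO")
#' @export
formula_add <- function(a, b) {
  a <- .as_formula(a); b <- .as_formula(b)
  syms <- union(names(a), names(b))
  out <- structure(integer(length(syms)), names = syms)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  .canonical_formula(out)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  a <- .as_formula(a); b <- .as_formula(b)
  syms <- union(names(a), names(b))
  out <- structure(integer(length(syms)), names = syms)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0))
    stop("formula subtraction below zero (", formula_format(a), " - ",
         formula_format(b), ")", call. = FALSE)
  .canonical_formula(out)
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times monoisotopic atomic mass.
#'
#' @param f formula (string or named count vector)
#' @return mass in Da (full precision; use [round_half_up()] for display)
#' @examples
#' monoisotopic_mass("CH4")     # 16.0313
#' monoisotopic_mass("C22H38O3")
#' @export
monoisotopic_mass <- function(f) {
  f <- .as_formula(f)
  if (length(f) == 0) return(0)
  unknown <- setdiff(names(f), names(element_masses()))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sum(f * element_masses()[names(f)])
}

#' m/z of a positive ion
#'
#' Computes the mass-to-charge ratio of a positive ion from its neutral
#' formula and adduct kind. With `electron_correction = FALSE` (the default)
#' the proton adduct adds the mass of a whole H atom and fragment cations
#' (`adduct = "none"`) return the plain atom-inventory mass; with the
#' correction on, one electron mass (0.000549 Da) per charge is subtracted,
#' which is the physically exact convention. The default reproduces the usual
#' printed reference m/z values of TAG work at 4 decimals.
#'
#' @param formula neutral formula, or the full atom inventory of a fragment
#'   cation when `adduct = "none"`
#' @param adduct `"H"` (protonation), `"NH4"` (ammonium) or `"none"`
#' @param charge positive integer, default 1
#' @param electron_correction subtract one electron mass per charge?
#' @return m/z in Th
#' @examples
#' ion_mz("C57H98O6")                      # [M+H]+ of trilinolein, 879.7442
#' ion_mz("C19H31O2", adduct = "none")     # an acylium cation
#' @export
ion_mz <- function(formula, adduct = c("H", "NH4", "none"), charge = 1L,
                   electron_correction = FALSE) {
  adduct <- match.arg(adduct)
  stopifnot(charge >= 1)
  mass <- monoisotopic_mass(formula) + monoisotopic_mass(.adduct_formula(adduct))
  if (electron_correction) mass <- mass - charge * ELECTRON_MASS
  mass / charge
}

#' Relative mass deviation in ppm
#'
#' `(measured - calculated) / calculated * 1e6`, sign preserved.
#'
#' @param measured measured m/z
#' @param calculated calculated (reference) m/z; must be > 0
#' @return deviation in ppm
#' @examples
#' ppm_error(879.7458, 879.7442)  # 1.819 at 3 decimals
#' @export
ppm_error <- function(measured, calculated) {
  if (any(calculated <= 0)) stop("calculated m/z must be positive", call. = FALSE)
  (measured - calculated) / calculated * 1e6
}

#' Mass resolution required to separate an isobaric pair
#'
#' The m/delta-m resolution needed to distinguish two ions `delta_m` apart at
#' a reference m/z.
#'
#' @param reference_mz reference m/z of the pair
#' @param delta_m exact-mass difference in Da; must be > 0
#' @return dimensionless resolution
#' @examples
#' required_resolution(925.7285, 0.0575)  # ~16,100
#' @export
required_resolution <- function(reference_mz, delta_m) {
  if (any(delta_m <= 0)) stop("delta_m must be positive", call. = FALSE)
  reference_mz / delta_m
}

#' Elemental difference between nominally isobaric formulas
#'
#' Returns the element-wise surplus of each formula over the other together
#' with the signed exact-mass difference `mass(f1) - mass(f2)`. For the
#' classic TAG interferences this yields the "O vs CH4" (delta 0.0364 Da) and
#' "C2 vs H8O" (delta 0.0575 Da) classes.
#'
#' @param f1,f2 formulas (strings or named count vectors)
#' @return list with `surplus1`, `surplus2` (formulas), `delta_m` (Da) and
#'   `class` (a label such as `"O vs CH4"`, `"C2 vs H8O"`, `"identical"` or
#'   `"other"`)
#' @examples
#' isobar_delta("C22H38O3", "C23H42O2")
#' @export
isobar_delta <- function(f1, f2) {
  f1 <- .as_formula(f1); f2 <- .as_formula(f2)
  syms <- union(names(f1), names(f2))
  d <- structure(integer(length(syms)), names = syms)
  d[names(f1)] <- d[names(f1)] + f1
  d[names(f2)] <- d[names(f2)] - f2
  s1 <- .canonical_formula(pmax(d, 0L))
  s2 <- .canonical_formula(pmax(-d, 0L))
  lab <- sort(c(formula_format(s1), formula_format(s2)))
  cls <- if (all(lab == "")) "identical"
    else if (identical(lab, sort(c("O", "CH4")))) "O vs CH4"
    else if (identical(lab, sort(c("C2", "H8O")))) "C2 vs H8O"
    else "other"
  list(surplus1 = s1, surplus2 = s2,
       delta_m = monoisotopic_mass(s1) - monoisotopic_mass(s2), class = cls)
}
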