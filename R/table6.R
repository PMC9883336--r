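# Printed identification table for the king oyster mushroom (Pleurotus
# eryngii) extract: 18 FuFA-containing TAGs with retention time, neutral
# formula, observed [M+H]+, the diagnostic ions (McLafferty, furan core,
# [FCO]+) and the observed diacyl [M-RCOO]+ ions, carbon number, and the
# [FCO]+ signal intensity in thousands of counts. The first row is the
# FuFA-only identification: co-elution hid the diacyl ions, so only the
# FuFA (9D5) could be assigned.
.MUSHROOM_ROWS <- list(
  list(name = "XY9D5",      rt = 20.80, formula = "C57H96O7",  prec = 893.7233,
       mcl = 123.0808, core = 179.1432, fco = 305.2478,
       diacyl = numeric(0),                        carbon = 54, inten = 570),
  list(name = "LL7D5",      rt = 20.80, formula = "C57H96O7",  prec = 893.7233,
       mcl = 123.0808, core = 179.1432, fco = 277.2165,
       diacyl = c(599.5031, 613.4835),             carbon = 54, inten = 284),
  list(name = "15:0-Ln9D5", rt = 21.65, formula = "C56H96O7",  prec = 881.7230,
       mcl = 123.0808, core = 179.1432, fco = 305.2479,
       diacyl = c(559.4725, 601.4830, 639.4975),   carbon = 53, inten = 1010),
  list(name = "LL9M5",      rt = 21.66, formula = "C58H98O7",  prec = 907.7379,
       mcl = 109.0653, core = 165.1276, fco = 291.2321,
       diacyl = c(599.5036, 627.4988),             carbon = 55, inten = 230),
  list(name = "L9D59D5",    rt = 21.89, formula = "C61H102O8", prec = 963.7649,
       mcl = 123.0808, core = 179.1431, fco = 305.2480,
       diacyl = c(641.5142, 683.5248),             carbon = 58, inten = 9980),
  list(name = "PnL9D5",     rt = 22.03, formula = "C57H98O7",  prec = 895.7386,
       mcl = 123.0807, core = 179.1431, fco = 305.2478,
       diacyl = c(573.4880, 615.4988, 641.5142),   carbon = 54, inten = 2110),
  list(name = "LO7D5",      rt = 22.14, formula = "C57H98O7",  prec = 895.7384,
       mcl = 123.0807, core = 179.1431, fco = 277.2164,
       diacyl = c(601.5197, 613.4827, 615.4984),   carbon = 54, inten = 278),
  list(name = "LL9D5",      rt = 22.24, formula = "C59H100O7", prec = 921.7543,
       mcl = 123.0807, core = 179.1431, fco = 305.2479,
       diacyl = c(599.5035, 641.5142),             carbon = 56, inten = 66800),
  list(name = "15:0-L9D5",  rt = 22.83, formula = "C56H98O7",  prec = 883.7387,
       mcl = 123.0808, core = 179.1431, fco = 305.2479,
       diacyl = c(561.4880, 603.4987, 641.5143),   carbon = 53, inten = 3770),
  list(name = "LO9M5",      rt = 23.30, formula = "C58H100O7", prec = 909.7537,
       mcl = 109.0653, core = 165.1275, fco = 291.2321,
       diacyl = c(601.5195, 627.4985, 629.5150),   carbon = 55, inten = 339),
  list(name = "O9D59D5",    rt = 23.34, formula = "C61H104O8", prec = 965.7803,
       mcl = 123.0808, core = 179.1431, fco = 305.2478,
       diacyl = c(643.5302, 683.5249),             carbon = 58, inten = 1430),
  list(name = "LO9D5",      rt = 23.71, formula = "C59H102O7", prec = 923.7696,
       mcl = 123.0807, core = 179.1430, fco = 305.2478,
       diacyl = c(601.5192, 641.5139, 643.5297),   carbon = 56, inten = 29100),
  list(name = "15:0-O9D5",  rt = 24.34, formula = "C56H100O7", prec = 885.7546,
       mcl = 123.0808, core = 179.1432, fco = 305.2478,
       diacyl = c(563.5038, 603.4987, 643.5302),   carbon = 53, inten = 1280),
  list(name = "17:0-L9D5",  rt = 24.59, formula = "C58H102O7", prec = 911.7698,
       mcl = 123.0807, core = 179.1432, fco = 305.2477,
       diacyl = c(589.5192, 631.5297, 641.5143),   carbon = 55, inten = 815),
  list(name = "OO9M5",      rt = 24.69, formula = "C58H102O7", prec = 911.7711,
       mcl = 109.0653, core = 165.1274, fco = 291.2321,
       diacyl = c(603.5348, 629.5142),             carbon = 55, inten = 121),
  list(name = "PO9D5",      rt = 25.13, formula = "C57H102O7", prec = 899.7696,
       mcl = 123.0807, core = 179.1431, fco = 305.2479,
       diacyl = c(577.5192, 617.5142, 643.5298),   carbon = 54, inten = 9550),
  list(name = "OO9D5",      rt = 25.18, formula = "C59H104O7", prec = 925.7855,
       mcl = 123.0807, core = 179.1431, fco = 305.2479,
       diacyl = c(603.5349, 643.5300),             carbon = 56, inten = 10100),
  list(name = "OS9D5",      rt = 26.80, formula = "C59H106O7", prec = 927.8011,
       mcl = 123.0808, core = 179.1431, fco = 305.2477,
       diacyl = c(605.5505, 643.5300, 645.5455),   carbon = 56, inten = 977)
)

#' Deterministic mushroom identification fixture
#'
#' Reconstructs, spectrum by spectrum, the 18 FuFA-TAG identifications
#' reported for a king oyster mushroom extract: one MS2 spectrum per
#' identified TAG, with the *observed* (printed) m/z values as peak
#' positions — the observed `[M+H]+` as precursor and in-spectrum peak, the
#' McLafferty, furan core and `[FCO]+` ions, and the observed diacyl ions.
#' The `[FCO]+` intensity is the reported signal intensity (reported in
#' thousands, stored here in counts); the remaining ions get fixed
#' sub-maximal heights (diacyl 0.35, McLafferty 0.15, core 0.10, precursor
#' 0.08 of the `[FCO]+` height), since the source table prints only the
#' base-peak intensity. The first spectrum contains no diacyl ions and must
#' screen as FUFA_ONLY. Fully deterministic: no random numbers.
#'
#' @return list of 18 `ms2_spectrum`
#' @seealso [table6_reference()] for the expected annotations
#' @examples
#' length(table6_fixture())
#' @export
table6_fixture <- function() {
  lapply(seq_along(.MUSHROOM_ROWS), function(i) {
    r <- .MUSHROOM_ROWS[[i]]
    base <- r$inten * 1000
    mz <- c(r$mcl, r$core, r$fco, r$diacyl, r$prec)
    intensity <- c(0.15, 0.10, 1, rep(0.35, length(r$diacyl)), 0.08) * base
    ms2_spectrum(mz, intensity, precursor_mz = r$prec,
                 id = sprintf("mushroom_%02d", i), rt = r$rt,
                 source = "printed mushroom identification table")
  })
}

#' Expected annotations for the mushroom fixture
#'
#' The published identification outcome the fixture must reproduce: TAG
#' name, retention time, neutral formula, carbon number, `[FCO]+` intensity
#' (counts) and tier (FUFA_ONLY for the co-eluting first row, FULL
#' otherwise).
#'
#' @return data frame with columns `name`, `rt`, `formula`,
#'   `carbon_number`, `intensity`, `tier`
#' @export
table6_reference <- function() {
  data.frame(
    name = vapply(.MUSHROOM_ROWS, `[[`, "", "name"),
    rt = vapply(.MUSHROOM_ROWS, `[[`, 0, "rt"),
    formula = vapply(.MUSHROOM_ROWS, `[[`, "", "formula"),
    carbon_number = vapply(.MUSHROOM_ROWS, function(r) as.integer(r$carbon), 0L),
    intensity = vapply(.MUSHROOM_ROWS, function(r) r$inten * 1000, 0),
    tier = ifelse(vapply(.MUSHROOM_ROWS, function(r) length(r$diacyl), 0L) > 0,
                  "FULL", "FUFA_ONLY"),
    stringsAsFactors = FALSE)
}
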