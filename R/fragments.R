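#' Diacyl fragment ions of a TAG
#'
#' The `[M-RCOO]+` ions formed by release of one fatty acid (as RCOOH) from
#' the protonated TAG. One record is produced per distinct leaving fatty
#' acid, so a TAG with three identical acyls yields one ion, with two
#' distinct acyls two ions, and with three distinct acyls three. By exact
#' mass conservation, diacyl m/z plus the leaving acid's neutral mass equals
#' the protonated precursor m/z.
#'
#' @param tag a `tag_composition`
#' @param electron_correction see [ion_mz()]
#' @return data frame with columns `leaving` (token), `pair` (remaining acyl
#'   pair label), `formula`, `mz`
#' @examples
#' diacyl_ions(build_tag("L", "L", "9M5"))   # [L9M5]+ 627.4989, [LL]+ 599.5039
#' @export
diacyl_ions <- function(tag, electron_correction = FALSE) {
  stopifnot(inherits(tag, "tag_composition"))
  tokens <- vapply(tag$fas, `[[`, "", "token")
  keep <- !duplicated(tokens)
  prot <- formula_add(tag$formula, c(H = 1L))
  rows <- lapply(which(keep), function(i) {
    fa <- tag$fas[[i]]
    remaining <- tag$fas[-i]
    frm <- formula_subtract(prot, fa_neutral_formula(fa))
    data.frame(
      leaving = fa$token,
      pair = .tag_name(.canonical_fa_order(remaining)),
      formula = formula_format(frm),
      mz = ion_mz(frm, adduct = "none", electron_correction = electron_correction),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Diagnostic acylium [FCO]+ ion of a FuFA
#'
#' The furan-fatty-acid acylium ion (the fatty acid minus its hydroxyl),
#' written `[FCO]+`. It is the base peak of FuFA-TAG MS2 spectra and the
#' first diagnostic filter ion. Each `[FCO]+` m/z is shared by exactly two
#' FuFAs whose chain lengths trade two carbons (e.g. 9M5 and 11M3), so this
#' ion alone narrows the FuFA to a positional-isomer pair.
#'
#' @param fa a FuFA `fatty_acid`
#' @param electron_correction see [ion_mz()]
#' @return one-row data frame with columns `token`, `formula`, `mz`
#' @examples
#' fco_ion(parse_fufa_short_form("9D5"))   # C20H33O2, m/z 305.2481
#' @export
fco_ion <- function(fa, electron_correction = FALSE) {
  stopifnot(is_fufa(fa))
  frm <- acyl_cation_formula(fa)
  data.frame(token = fa$token, formula = formula_format(frm),
             mz = ion_mz(frm, adduct = "none",
                         electron_correction = electron_correction),
             stringsAsFactors = FALSE)
}

#' Furan core ion of a FuFA
#'
#' The allylic `[CH2-(furan moiety)-alkyl chain]+` fragment that retains the
#' ring, its methyls and the alpha' alkyl chain: formula `C_n H_(2n-5) O`
#' with `n = 5 + methyl count + alkyl length` (one exocyclic CH2, four ring
#' carbons, the ring methyls and the alkyl chain). Because it keeps the
#' alkyl chain but not the carboxyalkyl chain, it differs between the two
#' members of every `[FCO]+`-degenerate pair and is the ion that pins down
#' the concrete FuFA.
#'
#' @inheritParams fco_ion
#' @return one-row data frame with columns `token`, `formula`, `mz`
#' @examples
#' furan_core_ion(parse_fufa_short_form("9M5"))   # C11H17O, m/z ~165.128
#' @export
furan_core_ion <- function(fa, electron_correction = FALSE) {
  stopifnot(is_fufa(fa))
  n <- 5L + ifelse(fa$methylation == "M", 1L, 2L) + fa$alkyl_len
  frm <- .canonical_formula(c(C = n, H = 2L * n - 5L, O = 1L))
  data.frame(token = fa$token, formula = formula_format(frm),
             mz = ion_mz(frm, adduct = "none",
                         electron_correction = electron_correction),
             stringsAsFactors = FALSE)
}

#' McLafferty rearrangement ion of a FuFA
#'
#' The rearrangement product depends only on the ring methylation degree:
#' monomethyl FuFAs give C7H9O (m/z 109.0653) and dimethyl FuFAs give C8H11O
#' (m/z ~123.081), independent of either chain length. It confirms the
#' methylation degree during filtering.
#'
#' @inheritParams fco_ion
#' @return one-row data frame with columns `token`, `formula`, `mz`
#' @examples
#' mclafferty_ion(parse_fufa_short_form("11D3"))
#' @export
mclafferty_ion <- function(fa, electron_correction = FALSE) {
  stopifnot(is_fufa(fa))
  frm <- if (fa$methylation == "M") c(C = 7L, H = 9L, O = 1L)
         else c(C = 8L, H = 11L, O = 1L)
  frm <- .canonical_formula(frm)
  data.frame(token = fa$token, formula = formula_format(frm),
             mz = ion_mz(frm, adduct = "none",
                         electron_correction = electron_correction),
             stringsAsFactors = FALSE)
}

#' Predicted diagnostic ion set of a TAG
#'
#' Assembles everything the identification filter needs for one TAG: both
#' precursor m/z values, the diacyl `[M-RCOO]+` ions, the acylium ions of
#' every distinct fatty acid (flagged `is_fufa`; conventional acylium ions
#' are predicted but carry no weight in identification), and — per distinct
#' FuFA species — the `[FCO]+`, furan core and McLafferty ions.
#'
#' @inheritParams diacyl_ions
#' @return object of class `fragment_set`: a list with elements `tag`,
#'   `precursor_h`, `precursor_nh4`, `diacyl`, `acylium`, `core`,
#'   `mclafferty`
#' @examples
#' fs <- fragment_set(build_tag("L", "L", "9M5"))
#' fs$diacyl
#' @export
fragment_set <- function(tag, electron_correction = FALSE) {
  stopifnot(inherits(tag, "tag_composition"))
  tokens <- vapply(tag$fas, `[[`, "", "token")
  fas <- tag$fas[!duplicated(tokens)]
  fufas <- Filter(is_fufa, fas)
  acylium <- do.call(rbind, lapply(fas, function(fa) {
    frm <- acyl_cation_formula(fa)
    data.frame(token = fa$token, formula = formula_format(frm),
               mz = ion_mz(frm, adduct = "none",
                           electron_correction = electron_correction),
               is_fufa = is_fufa(fa), stringsAsFactors = FALSE)
  }))
  rownames(acylium) <- NULL
  bind_or_empty <- function(lst) {
    if (length(lst) == 0)
      return(data.frame(token = character(0), formula = character(0),
                        mz = numeric(0), stringsAsFactors = FALSE))
    out <- do.call(rbind, lst); rownames(out) <- NULL; out
  }
  structure(list(
    tag = tag,
    precursor_h = tag_precursor_mz(tag, "H", electron_correction),
    precursor_nh4 = tag_precursor_mz(tag, "NH4", electron_correction),
    diacyl = diacyl_ions(tag, electron_correction),
    acylium = acylium,
    core = bind_or_empty(lapply(fufas, furan_core_ion, electron_correction)),
    mclafferty = bind_or_empty(lapply(fufas, mclafferty_ion, electron_correction))
  ), class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("Fragment set for %s: [M+H]+ %.4f, [M+NH4]+ %.4f\n",
              x$tag$name, x$precursor_h, x$precursor_nh4))
  print(fragment_table(x))
  invisible(x)
}

#' Flat transition-list view of a fragment set
#'
#' One row per predicted ion (precursors, diacyl ions, acylium ions, furan
#' core, McLafferty), suitable for export as an inclusion list.
#'
#' @param x a `fragment_set` or a `tag_composition`
#' @param ... passed to [fragment_set()] when `x` is a TAG
#' @return data frame with columns `tag`, `ion_type`, `label`, `formula`, `mz`
#' @export
fragment_table <- function(x, ...) {
  if (inherits(x, "tag_composition")) x <- fragment_set(x, ...)
  stopifnot(inherits(x, "fragment_set"))
  nm <- x$tag$name
  prot <- formula_format(formula_add(x$tag$formula, c(H = 1L)))
  rows <- list(
    data.frame(tag = nm, ion_type = "precursor_h", label = paste0("[", nm, "+H]+"),
               formula = prot, mz = x$precursor_h, stringsAsFactors = FALSE),
    data.frame(tag = nm, ion_type = "precursor_nh4", label = paste0("[", nm, "+NH4]+"),
               formula = formula_format(formula_add(x$tag$formula, c(N = 1L, H = 4L))),
               mz = x$precursor_nh4, stringsAsFactors = FALSE))
  if (nrow(x$diacyl))
    rows <- c(rows, list(data.frame(tag = nm, ion_type = "diacyl",
                                    label = paste0("[", x$diacyl$pair, "]+"),
                                    formula = x$diacyl$formula,
                                    mz = x$diacyl$mz, stringsAsFactors = FALSE)))
  if (nrow(x$acylium))
    rows <- c(rows, list(data.frame(tag = nm,
                                    ion_type = ifelse(x$acylium$is_fufa, "fco", "acylium"),
                                    label = paste0("acyl(", x$acylium$token, ")"),
                                    formula = x$acylium$formula,
                                    mz = x$acylium$mz, stringsAsFactors = FALSE)))
  if (nrow(x$core))
    rows <- c(rows, list(data.frame(tag = nm, ion_type = "furan_core",
                                    label = paste0("core(", x$core$token, ")"),
                                    formula = x$core$formula,
                                    mz = x$core$mz, stringsAsFactors = FALSE)))
  if (nrow(x$mclafferty))
    rows <- c(rows, list(data.frame(tag = nm, ion_type = "mclafferty",
                                    label = paste0("McL(", x$mclafferty$token, ")"),
                                    formula = x$mclafferty$formula,
                                    mz = x$mclafferty$mz, stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
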