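#' Conventional fatty-acid building block
#'
#' A conventional (non-furan) fatty acid identified by its carbon count and
#' number of double bonds; neutral formula `C_n H_(2n-2d) O2`. Double-bond
#' positions and geometry are not modelled — the MS2 screen cannot resolve
#' them.
#'
#' @param carbons total carbon count (>= 2)
#' @param double_bonds number of C=C double bonds (>= 0)
#' @param token short name used in TAG names, e.g. `"P"`, `"L"`, `"15:0"`;
#'   defaults to the `"carbons:double_bonds"` style
#' @param trivial optional trivial name, e.g. `"Palmitic acid"`
#' @return object of class `fatty_acid`
#' @examples
#' conventional_fa(18, 2, "L", "Linoleic acid")
#' @export
conventional_fa <- function(carbons, double_bonds = 0L,
                            token = paste0(carbons, ":", double_bonds),
                            trivial = NULL) {
  carbons <- as.integer(carbons); double_bonds <- as.integer(double_bonds)
  if (carbons < 2) stop("a fatty acid needs at least 2 carbons", call. = FALSE)
  if (double_bonds < 0 || double_bonds > (carbons - 2) %/% 2)
    stop("impossible double-bond count ", double_bonds, " for ", carbons,
         " carbons", call. = FALSE)
  structure(list(type = "conventional", token = token, carbons = carbons,
                 double_bonds = double_bonds, trivial = trivial),
            class = "fatty_acid")
}

#' Furan fatty-acid building block
#'
#' A furan fatty acid (FuFA): a carboxyalkyl chain of `carboxy_len` carbons in
#' alpha-position of a furan ring, an alkyl chain of `alkyl_len` carbons in
#' alpha'-position, and one (`"M"`) or two (`"D"`) ring methyls. Total carbon
#' count is `carboxy_len + alkyl_len + 5` (M) or `+ 6` (D): four ring carbons
#' plus the methyls. The neutral formula is `C_n H_(2n-6) O3` (one ring, two
#' ring double bonds and the carboxyl give four degrees of unsaturation).
#'
#' @param carboxy_len carbons of the carboxyalkyl chain (odd, typically 7-13)
#' @param methylation `"M"` (monomethyl) or `"D"` (dimethyl)
#' @param alkyl_len carbons of the alkyl chain (odd, typically 3 or 5)
#' @param allow_even accept even chain lengths (off by default: natural FuFAs
#'   have odd chains, so an even length is almost surely a typo)
#' @return object of class `fatty_acid`
#' @examples
#' fufa(9, "M", 5)   # 9-(3-methyl-5-pentylfuran-2-yl)-nonanoic acid
#' @export
fufa <- function(carboxy_len, methylation = c("M", "D"), alkyl_len,
                 allow_even = FALSE) {
  methylation <- match.arg(methylation)
  carboxy_len <- as.integer(carboxy_len); alkyl_len <- as.integer(alkyl_len)
  if (carboxy_len < 1 || alkyl_len < 1)
    stop("chain lengths must be positive", call. = FALSE)
  if (!allow_even && (carboxy_len %% 2 == 0 || alkyl_len %% 2 == 0))
    stop("even FuFA chain length (", carboxy_len, ", ", alkyl_len,
         "); natural FuFAs have odd chains - use allow_even = TRUE to override",
         call. = FALSE)
  carbons <- carboxy_len + alkyl_len + 4L + ifelse(methylation == "M", 1L, 2L)
  structure(list(type = "fufa",
                 token = paste0(carboxy_len, methylation, alkyl_len),
                 carboxy_len = carboxy_len, methylation = methylation,
                 alkyl_len = alkyl_len, carbons = carbons),
            class = "fatty_acid")
}

#' Parse a FuFA number-letter-number short form
#'
#' Tokens like `"9M5"` encode carboxyalkyl length, methylation degree and
#' alkyl length. [format_fufa_short_form()] inverts the parse exactly.
#'
#' @param text token such as `"9M5"` or `"11D3"`
#' @inheritParams fufa
#' @return object of class `fatty_acid`
#' @examples
#' parse_fufa_short_form("11D5")
#' @export
parse_fufa_short_form <- function(text, allow_even = FALSE) {
  stopifnot(is.character(text), length(text) == 1)
  m <- regmatches(text, regexec("^([0-9]+)([MD])([0-9]+)$", text))[[1]]
  if (length(m) == 0)
    stop("malformed FuFA short form: \"", text,
         "\" (expected <digits><M|D><digits>, e.g. 9M5)", call. = FALSE)
  fufa(as.integer(m[2]), m[3], as.integer(m[4]), allow_even = allow_even)
}

#' @rdname parse_fufa_short_form
#' @param fa a FuFA `fatty_acid`
#' @export
format_fufa_short_form <- function(fa) {
  stopifnot(inherits(fa, "fatty_acid"), fa$type == "fufa")
  fa$token
}

#' @export
print.fatty_acid <- function(x, ...) {
  if (x$type == "fufa") {
    cat(sprintf("FuFA %s (C%d, %s-methyl; %s, %.4f Da)\n", x$token, x$carbons,
                ifelse(x$methylation == "M", "mono", "di"),
                formula_format(fa_neutral_formula(x)), fa_mass(x)))
  } else {
    cat(sprintf("FA %s (%d:%d%s; %s, %.4f Da)\n", x$token, x$carbons,
                x$double_bonds,
                if (!is.null(x$trivial)) paste0(", ", x$trivial) else "",
                formula_format(fa_neutral_formula(x)), fa_mass(x)))
  }
  invisible(x)
}

#' Neutral formula of a building block
#'
#' Conventional fatty acids follow `C_n H_(2n-2d) O2`; FuFAs follow
#' `C_n H_(2n-6) O3`.
#'
#' @param fa a `fatty_acid`
#' @return named integer formula vector
#' @examples
#' fa_neutral_formula(fufa(11, "D", 5))   # C22H38O3
#' @export
fa_neutral_formula <- function(fa) {
  stopifnot(inherits(fa, "fatty_acid"))
  n <- fa$carbons
  h <- if (fa$type == "fufa") 2L * n - 6L else 2L * n - 2L * fa$double_bonds
  o <- if (fa$type == "fufa") 3L else 2L
  .canonical_formula(c(C = n, H = h, O = o))
}

#' @rdname fa_neutral_formula
#' @export
fa_mass <- function(fa) monoisotopic_mass(fa_neutral_formula(fa))

#' @rdname fa_neutral_formula
#' @export
fa_carbons <- function(fa) fa$carbons

#' @rdname fa_neutral_formula
#' @export
is_fufa <- function(fa) inherits(fa, "fatty_acid") && fa$type == "fufa"

#' Acylium cation of a fatty acid
#'
#' The `[RCO]+` ion: the fatty acid after loss of the hydroxyl. For FuFAs this
#' is the diagnostic `[FCO]+` ion, the base peak of FuFA-TAG MS2 spectra.
#'
#' @param fa a `fatty_acid`
#' @return named integer formula vector (the cation's atom inventory)
#' @examples
#' acyl_cation_formula(conventional_fa(18, 0, "S"))  # C18H35O, m/z 267.2
#' @export
acyl_cation_formula <- function(fa) {
  formula_subtract(fa_neutral_formula(fa), c(O = 1L, H = 1L))
}

#' Building-block set
#'
#' Bundles conventional and furan fatty acids for candidate enumeration.
#' Short names must be unique within the set.
#'
#' @param conventional list of conventional `fatty_acid` objects
#' @param fufas list of FuFA `fatty_acid` objects
#' @return object of class `building_block_set`
#' @seealso [default_building_blocks()]
#' @export
building_block_set <- function(conventional = list(), fufas = list()) {
  stopifnot(all(vapply(conventional, inherits, TRUE, "fatty_acid")),
            all(vapply(fufas, inherits, TRUE, "fatty_acid")))
  if (any(vapply(conventional, is_fufa, TRUE)) ||
      !all(vapply(fufas, is_fufa, TRUE)))
    stop("building blocks sorted into the wrong slot", call. = FALSE)
  tokens <- c(vapply(conventional, `[[`, "", "token"),
              vapply(fufas, `[[`, "", "token"))
  if (anyDuplicated(tokens))
    stop("duplicate short names in building-block set: ",
         paste(unique(tokens[duplicated(tokens)]), collapse = ", "),
         call. = FALSE)
  names(conventional) <- vapply(conventional, `[[`, "", "token")
  names(fufas) <- vapply(fufas, `[[`, "", "token")
  structure(list(conventional = conventional, fufas = fufas),
            class = "building_block_set")
}

#' @export
print.building_block_set <- function(x, ...) {
  cat(sprintf("Building blocks: %d conventional FA (%s), %d FuFA (%s)\n",
              length(x$conventional), paste(names(x$conventional), collapse = " "),
              length(x$fufas), paste(names(x$fufas), collapse = " ")))
  invisible(x)
}

#' Default fatty-acid building blocks
#'
#' The shipped screening library: the eight most relevant FuFAs (9M3, 9D3,
#' 9M5, 11M3, 9D5, 11D3, 11M5, 11D5) plus the four acylium-degenerate chain
#' partners 7M5, 7D5, 13M3 and 13D3 (each `[FCO]+` m/z is shared by exactly
#' two FuFAs, so the partners must be screenable even though they are rare),
#' and eleven conventional fatty acids: the seven typical of fish and plant
#' oils (P, O, L, Ln, Ep, Dp, Dh) plus Pn, S and the odd-chain 15:0 and 17:0
#' observed in mushroom TAGs.
#'
#' @return object of class `building_block_set`
#' @examples
#' default_building_blocks()
#' @export
default_building_blocks <- function() {
  conv <- list(
    conventional_fa(15, 0, "15:0", "Pentadecanoic acid"),
    conventional_fa(16, 0, "P",    "Palmitic acid"),
    conventional_fa(16, 1, "Pn",   "Palmitoleic acid"),
    conventional_fa(17, 0, "17:0", "Margaric acid"),
    conventional_fa(18, 0, "S",    "Stearic acid"),
    conventional_fa(18, 1, "O",    "Oleic acid"),
    conventional_fa(18, 2, "L",    "Linoleic acid"),
    conventional_fa(18, 3, "Ln",   "alpha-Linolenic acid"),
    conventional_fa(20, 5, "Ep",   "Eicosapentaenoic acid"),
    conventional_fa(22, 5, "Dp",   "Docosapentaenoic acid"),
    conventional_fa(22, 6, "Dh",   "Docosahexaenoic acid")
  )
  ff <- lapply(c("7M5", "7D5", "9M3", "9D3", "9M5", "9D5",
                 "11M3", "11D3", "11M5", "11D5", "13M3", "13D3"),
               parse_fufa_short_form)
  building_block_set(conv, ff)
}

#' Resolve a fatty-acid token
#'
#' Looks a token up in a building-block set: letter codes and `"n:d"` styles
#' resolve to conventional fatty acids, number-letter-number forms to FuFAs.
#' Tokens absent from the set but well-formed (`"19:1"`, `"13M5"`) are
#' constructed on the fly.
#'
#' @param token short name, e.g. `"L"`, `"15:0"`, `"9M5"`
#' @param blocks a `building_block_set` used for lookup
#' @return object of class `fatty_acid`
#' @examples
#' parse_fa_token("Ln")
#' parse_fa_token("9D5")
#' @export
parse_fa_token <- function(token, blocks = default_building_blocks()) {
  stopifnot(is.character(token), length(token) == 1)
  if (token %in% names(blocks$conventional)) return(blocks$conventional[[token]])
  if (token %in% names(blocks$fufas)) return(blocks$fufas[[token]])
  if (grepl("^[0-9]+:[0-9]+$", token)) {
    nd <- as.integer(strsplit(token, ":", fixed = TRUE)[[1]])
    return(conventional_fa(nd[1], nd[2], token))
  }
  if (grepl("^[0-9]+[MD][0-9]+$", token)) return(parse_fufa_short_form(token))
  stop("unknown fatty-acid token: \"", token, "\"", call. = FALSE)
}

#' Read and write building-block configuration files
#'
#' A human-editable tab-separated format with one record per fatty acid:
#' columns `token`, `type` (`conventional` or `fufa`), `carbons`,
#' `double_bonds` (conventional only), `carboxy_len`, `methylation`,
#' `alkyl_len` (FuFA only) and `trivial`.
#'
#' @param path file path
#' @param blocks a `building_block_set`
#' @return `read_building_blocks()` returns a `building_block_set`;
#'   `write_building_blocks()` returns `path` invisibly.
#' @export
write_building_blocks <- function(blocks, path) {
  stopifnot(inherits(blocks, "building_block_set"))
  row1 <- function(fa) {
    data.frame(token = fa$token, type = fa$type,
               carbons = if (fa$type == "conventional") fa$carbons else NA,
               double_bonds = if (fa$type == "conventional") fa$double_bonds else NA,
               carboxy_len = if (fa$type == "fufa") fa$carboxy_len else NA,
               methylation = if (fa$type == "fufa") fa$methylation else NA,
               alkyl_len = if (fa$type == "fufa") fa$alkyl_len else NA,
               trivial = if (!is.null(fa$trivial)) fa$trivial else NA,
               stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, lapply(c(blocks$conventional, blocks$fufas), row1))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' @rdname write_building_blocks
#' @export
read_building_blocks <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8", na.strings = "")
  conv <- list(); ff <- list()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (identical(r$type, "conventional")) {
      conv[[length(conv) + 1L]] <- conventional_fa(
        r$carbons, r$double_bonds, r$token,
        if (!is.na(r$trivial)) r$trivial else NULL)
    } else if (identical(r$type, "fufa")) {
      ff[[length(ff) + 1L]] <- fufa(r$carboxy_len, r$methylation, r$alkyl_len)
    } else {
      stop("unknown building-block type in ", path, ": ", r$type, call. = FALSE)
    }
  }
  building_block_set(conv, ff)
}
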