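GLYCEROL <- c(C = 3L, H = 8L, O = 3L)
WATER <- c(H = 2L, O = 1L)

# canonical display order: conventional FAs ascending in molecular weight,
# FuFAs last (also ascending). The order is a naming convention only; the
# MS2 method cannot resolve sn-positions.
.canonical_fa_order <- function(fas) {
  fu <- vapply(fas, is_fufa, TRUE)
  mass <- vapply(fas, fa_mass, 0)
  fas[order(fu, mass)]
}

.tag_name <- function(fas) {
  tokens <- vapply(fas, `[[`, "", "token")
  # tokens like "15:0" get a dash after them so names stay parseable
  sep <- ifelse(grepl(":", tokens), "-", "")
  sep[length(sep)] <- ""
  paste0(tokens, sep, collapse = "")
}

#' Build a triacylglycerol composition
#'
#' Assembles a TAG from three fatty-acid building blocks. The neutral formula
#' is glycerol (C3H8O3) plus the three fatty acids minus three waters; the
#' carbon number is the sum of acyl carbons (glycerol excluded). The
#' composition has multiset semantics — argument order does not matter — and
#' the stored name is canonical: conventional fatty acids in ascending
#' molecular weight first, FuFAs last. The name is a display convention;
#' positional (sn) isomers are not resolved by the MS2 method.
#'
#' @param fa1,fa2,fa3 `fatty_acid` objects or tokens resolvable by
#'   [parse_fa_token()]
#' @param blocks building-block set used to resolve character tokens
#' @return object of class `tag_composition` with fields `fas`, `name`,
#'   `formula`, `carbon_number`, `n_fufa`
#' @examples
#' build_tag("L", "L", "9M5")   # LL9M5, neutral C58H98O7
#' @export
build_tag <- function(fa1, fa2, fa3, blocks = default_building_blocks()) {
  fas <- lapply(list(fa1, fa2, fa3), function(x) {
    if (is.character(x)) parse_fa_token(x, blocks) else x
  })
  stopifnot(all(vapply(fas, inherits, TRUE, "fatty_acid")))
  fas <- .canonical_fa_order(fas)
  f <- Reduce(formula_add, lapply(fas, fa_neutral_formula), GLYCEROL)
  f <- formula_subtract(f, c(H = 6L, O = 3L))
  structure(list(
    fas = fas,
    name = .tag_name(fas),
    formula = f,
    carbon_number = sum(vapply(fas, fa_carbons, 0L)),
    n_fufa = sum(vapply(fas, is_fufa, TRUE))
  ), class = "tag_composition")
}

#' @export
print.tag_composition <- function(x, ...) {
  cat(sprintf("TAG %s (%s; CN %d; %d FuFA; [M+H]+ %.4f)\n", x$name,
              formula_format(x$formula), x$carbon_number, x$n_fufa,
              tag_precursor_mz(x)))
  cat("  positional isomers unresolved: the acyl order is a naming convention\n")
  invisible(x)
}

#' Precursor m/z of a TAG
#'
#' Protonated or ammoniated quasi-molecular ion of the neutral TAG. In
#' positive ESI both are observed; the protonated ion is usually the more
#' abundant and is the one screened against by default.
#'
#' @param tag a `tag_composition`
#' @param adduct `"H"` or `"NH4"`
#' @param electron_correction see [ion_mz()]
#' @return m/z in Th
#' @examples
#' tag_precursor_mz(build_tag("L", "L", "9M5"))   # 907.7391
#' @export
tag_precursor_mz <- function(tag, adduct = c("H", "NH4"),
                             electron_correction = FALSE) {
  adduct <- match.arg(adduct)
  ion_mz(tag$formula, adduct = adduct, electron_correction = electron_correction)
}

#' Parse a canonical TAG name
#'
#' Tokenizes names like `"LL9M5"`, `"PnL9D5"` or `"15:0-Ln9D5"` back into
#' their three fatty-acid tokens and rebuilds the composition. Tokens are
#' matched greedily, longest known token first.
#'
#' @param name TAG name string
#' @param blocks building-block set providing the known letter codes
#' @return object of class `tag_composition`
#' @examples
#' parse_tag_name("15:0-Ln9D5")$carbon_number   # 53
#' @export
parse_tag_name <- function(name, blocks = default_building_blocks()) {
  rest <- name
  tokens <- character(0)
  letter_tokens <- names(blocks$conventional)
  letter_tokens <- letter_tokens[order(-nchar(letter_tokens))]
  while (nchar(rest) > 0) {
    if (length(tokens) > 3) break
    m <- regmatches(rest, regexec("^([0-9]+:[0-9]+)-?", rest))[[1]]
    if (length(m)) {
      tokens <- c(tokens, m[2]); rest <- substring(rest, nchar(m[1]) + 1)
      next
    }
    # non-greedy alkyl length so concatenated FuFA tokens split correctly
    # (e.g. "9D59D5" is 9D5 + 9D5, not 9D59 + D5)
    m <- regmatches(rest,
                    regexec("^([0-9]+[MD][0-9]+?)(?=$|[0-9]+[MD])", rest,
                            perl = TRUE))[[1]]
    if (length(m)) {
      tokens <- c(tokens, m[2]); rest <- substring(rest, nchar(m[1]) + 1)
      next
    }
    hit <- letter_tokens[startsWith(rest, letter_tokens)]
    if (length(hit) == 0)
      stop("cannot tokenize TAG name at \"", rest, "\" (in \"", name, "\")",
           call. = FALSE)
    tokens <- c(tokens, hit[1]); rest <- substring(rest, nchar(hit[1]) + 1)
  }
  if (length(tokens) != 3)
    stop("TAG name \"", name, "\" does not contain exactly three fatty-acid ",
         "tokens (got: ", paste(tokens, collapse = ", "), ")", call. = FALSE)
  build_tag(tokens[1], tokens[2], tokens[3], blocks = blocks)
}

.multiset_pairs <- function(n) {
  if (n == 0) return(matrix(integer(0), ncol = 2))
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  as.matrix(idx[idx$i <= idx$j, , drop = FALSE])
}

.multiset_triples <- function(n) {
  if (n == 0) return(matrix(integer(0), ncol = 3))
  idx <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  as.matrix(idx[idx$i <= idx$j & idx$j <= idx$k, , drop = FALSE])
}

#' Enumerate TAG candidates
#'
#' Builds the screening candidate database: all multisets of three fatty
#' acids drawn from a building-block set with the requested number of FuFA
#' moieties per TAG. With one FuFA per TAG, `f` FuFAs and `k` conventional
#' fatty acids the count is `f * k * (k + 1) / 2`. Each candidate carries its
#' protonated and ammoniated precursor m/z and a precomputed diagnostic
#' fragment set; the database is deduplicated by composition and sorted by
#' `[M+H]+`.
#'
#' @param blocks a `building_block_set`
#' @param fufa_per_tag integer vector of FuFA counts to enumerate, each in
#'   0..3 (0 gives FuFA-free TAGs, used for interference analysis)
#' @param conv optional character vector restricting the conventional tokens
#' @param fufas optional character vector restricting the FuFA tokens
#' @param electron_correction see [ion_mz()]
#' @return a `candidate_db` data frame with columns `name`, `formula`,
#'   `mz_h`, `mz_nh4`, `carbon_number`, `n_fufa`, `fufa_tokens`,
#'   `conv_tokens` and list-columns `tag`, `frags`
#' @examples
#' db <- enumerate_candidates(default_building_blocks(),
#'                            fufas = c("9M5", "11M3", "9D5", "11D3", "11D5", "13D3"),
#'                            conv = c("P", "O", "L", "Ln", "Ep", "Dp", "Dh"))
#' nrow(db)   # 6 FuFAs x 28 conventional pairs = 168
#' @export
enumerate_candidates <- function(blocks = default_building_blocks(),
                                 fufa_per_tag = 1L, conv = NULL, fufas = NULL,
                                 electron_correction = FALSE) {
  stopifnot(all(fufa_per_tag %in% 0:3))
  cv <- blocks$conventional
  ff <- blocks$fufas
  if (!is.null(conv)) cv <- cv[conv]
  if (!is.null(fufas)) ff <- ff[fufas]
  if (anyNA(names(cv)) || anyNA(names(ff)))
    stop("requested token not in building-block set", call. = FALSE)
  k <- length(cv); f <- length(ff)

  triples <- list()
  for (nf in sort(unique(as.integer(fufa_per_tag)))) {
    if (nf == 0) {
      if (k == 0) stop("no conventional fatty acids for a FuFA-free TAG", call. = FALSE)
      m <- .multiset_triples(k)
      triples <- c(triples, lapply(seq_len(nrow(m)), function(r)
        list(cv[[m[r, 1]]], cv[[m[r, 2]]], cv[[m[r, 3]]])))
    } else if (nf == 1) {
      if (f == 0 || k == 0) stop("empty building-block slot for one-FuFA TAGs", call. = FALSE)
      m <- .multiset_pairs(k)
      for (a in seq_len(f)) triples <- c(triples, lapply(seq_len(nrow(m)), function(r)
        list(ff[[a]], cv[[m[r, 1]]], cv[[m[r, 2]]])))
    } else if (nf == 2) {
      if (f == 0 || k == 0) stop("empty building-block slot for two-FuFA TAGs", call. = FALSE)
      m <- .multiset_pairs(f)
      for (a in seq_len(k)) triples <- c(triples, lapply(seq_len(nrow(m)), function(r)
        list(cv[[a]], ff[[m[r, 1]]], ff[[m[r, 2]]])))
    } else {
      if (f == 0) stop("no FuFAs for a tri-FuFA TAG", call. = FALSE)
      m <- .multiset_triples(f)
      triples <- c(triples, lapply(seq_len(nrow(m)), function(r)
        list(ff[[m[r, 1]]], ff[[m[r, 2]]], ff[[m[r, 3]]])))
    }
  }

  tags <- lapply(triples, function(tr) build_tag(tr[[1]], tr[[2]], tr[[3]], blocks))
  nms <- vapply(tags, `[[`, "", "name")
  keep <- !duplicated(nms)
  tags <- tags[keep]; nms <- nms[keep]

  frags <- lapply(tags, fragment_set, electron_correction = electron_correction)
  db <- data.frame(
    name = nms,
    formula = vapply(tags, function(t) formula_format(t$formula), ""),
    mz_h = vapply(tags, tag_precursor_mz, 0, adduct = "H",
                  electron_correction = electron_correction),
    mz_nh4 = vapply(tags, tag_precursor_mz, 0, adduct = "NH4",
                    electron_correction = electron_correction),
    carbon_number = vapply(tags, `[[`, 0L, "carbon_number"),
    n_fufa = vapply(tags, `[[`, 0L, "n_fufa"),
    fufa_tokens = vapply(tags, function(t)
      paste(sort(unique(vapply(Filter(is_fufa, t$fas), `[[`, "", "token"))),
            collapse = ","), ""),
    conv_tokens = vapply(tags, function(t)
      paste(vapply(Filter(Negate(is_fufa), t$fas), `[[`, "", "token"),
            collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  db$tag <- tags
  db$frags <- frags
  db <- db[order(db$mz_h), , drop = FALSE]
  rownames(db) <- NULL
  attr(db, "blocks") <- blocks
  attr(db, "electron_correction") <- electron_correction
  class(db) <- c("candidate_db", "data.frame")
  db
}

#' @export
print.candidate_db <- function(x, ...) {
  cat(sprintf("Candidate database: %d TAG compositions, [M+H]+ %.4f-%.4f\n",
              nrow(x), min(x$mz_h), max(x$mz_h)))
  invisible(x)
}

#' Export a candidate database as a tab-separated table
#'
#' Writes the enumeration (name, neutral formula, both precursor m/z values,
#' FuFA and conventional tokens, carbon number), one row per candidate.
#'
#' @param db a `candidate_db`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_candidates <- function(db, path) {
  tab <- db[, c("name", "formula", "mz_h", "mz_nh4", "fufa_tokens",
                "conv_tokens", "carbon_number")]
  tab$mz_h <- sprintf("%.4f", tab$mz_h)
  tab$mz_nh4 <- sprintf("%.4f", tab$mz_nh4)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Find isobaric conflicts between two candidate databases
#'
#' Reports pairs of candidates (one from each database) whose protonated
#' precursors are closer than the peak width implied by a mass resolution,
#' FWHM = m/R at the lower mass of the pair. Pairs are labelled with their
#' formula-difference class ("O vs CH4", "C2 vs H8O", "identical", "other").
#'
#' @param db a `candidate_db` (typically FuFA-containing TAGs)
#' @param other_db a second `candidate_db` (e.g. FuFA-free TAGs); defaults to
#'   `db` itself
#' @param resolution instrument resolving power m/delta-m
#' @return data frame with columns `name1`, `name2`, `mz1`, `mz2`, `delta_m`,
#'   `fwhm`, `class`
#' @examples
#' blocks <- default_building_blocks()
#' fdb <- enumerate_candidates(blocks, 1, conv = c("O"), fufas = c("9D5"))
#' cdb <- enumerate_candidates(blocks, 0, conv = c("O", "Ep"))
#' find_isobaric_conflicts(fdb, cdb, resolution = 10000)
#' @export
find_isobaric_conflicts <- function(db, other_db = db, resolution) {
  stopifnot(resolution > 0)
  same <- identical(db$name, other_db$name)
  out <- list()
  for (i in seq_len(nrow(db))) {
    jj <- seq_len(nrow(other_db))
    if (same) jj <- jj[jj > i]
    if (length(jj) == 0) next
    dm <- db$mz_h[i] - other_db$mz_h[jj]
    fwhm <- pmin(db$mz_h[i], other_db$mz_h[jj]) / resolution
    hit <- jj[abs(dm) < fwhm & db$name[i] != other_db$name[jj]]
    for (j in hit) {
      idel <- isobar_delta(formula_add(formula_parse(db$formula[i]), c(H = 1L)),
                           formula_add(formula_parse(other_db$formula[j]), c(H = 1L)))
      out[[length(out) + 1L]] <- data.frame(
        name1 = db$name[i], name2 = other_db$name[j],
        mz1 = db$mz_h[i], mz2 = other_db$mz_h[j],
        delta_m = db$mz_h[i] - other_db$mz_h[j],
        fwhm = min(db$mz_h[i], other_db$mz_h[j]) / resolution,
        class = idel$class, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(name1 = character(0), name2 = character(0),
                      mz1 = numeric(0), mz2 = numeric(0), delta_m = numeric(0),
                      fwhm = numeric(0), class = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
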