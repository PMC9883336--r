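.empty_annotations <- function() {
  out <- data.frame(
    spectrum_id = character(0), name = character(0), tier = character(0),
    fufa = character(0), rt = numeric(0), formula = character(0),
    carbon_number = integer(0), precursor_calc = numeric(0),
    precursor_obs = numeric(0), precursor_ppm = numeric(0),
    intensity = numeric(0), n_diacyl_matched = integer(0),
    n_diacyl_expected = integer(0), ambiguous = logical(0),
    positional_isomers = character(0), stringsAsFactors = FALSE)
  out$ions <- list()
  out
}

.ion_row <- function(ion_type, label, mz_calc, m) {
  data.frame(ion_type = ion_type, label = label, mz_calc = mz_calc,
             mz_obs = m$mz, ppm = m$ppm, intensity = m$intensity,
             stringsAsFactors = FALSE)
}

#' Screen one MS2 spectrum for FuFA-containing TAGs
#'
#' The multi-step identification filter. Step 1 keeps the candidates whose
#' protonated precursor lies within `tol_ppm` of the spectrum's precursor
#' (optionally also via the ammoniated precursor); an in-spectrum precursor
#' peak, when present, is recorded as corroborating evidence. Step 2 requires
#' a matched `[FCO]+` ion, which narrows the FuFA to a positional-isomer
#' pair. Step 3 requires the furan core ion — the ion that selects the
#' concrete FuFA within the pair — and a McLafferty ion consistent with the
#' methylation degree; for TAGs with two distinct FuFA species the trio is
#' required once per species. Step 4 matches the diacyl `[M-RCOO]+` ions,
#' which assign the conventional fatty acids.
#'
#' Among candidates that share the spectrum and the FuFA, the ones matching
#' the largest fraction of their expected diacyl ions are kept: isomeric acyl
#' pairs (e.g. L+L vs O+Ln) always share one pair-ion mass, so a candidate
#' explaining all observed diacyl ions outranks one explaining a subset.
#' Candidates matching every filter except any diacyl ion yield a single
#' FUFA_ONLY annotation named `XY<fufa>` — the FuFA is proven, the
#' conventional fatty acids are not — unless a FULL annotation for the same
#' FuFA exists in the spectrum. If several surviving annotations differ in
#' the FuFA while sharing the `[FCO]+` mass (pathological spectra where both
#' members of an isomer pair show core ions), all are flagged `ambiguous`.
#'
#' The reported `intensity` is that of the matched `[FCO]+` peak, the base
#' peak of clean FuFA-TAG spectra. With `require_base_peak = TRUE` the
#' `[FCO]+` match must additionally be the spectrum base peak (strict mode;
#' off by default because co-eluting TAGs share spectra in which at most one
#' `[FCO]+` can be the base peak).
#'
#' @param spectrum an `ms2_spectrum`
#' @param db a `candidate_db` from [enumerate_candidates()]
#' @param tol_ppm matching tolerance in ppm (default 4, the filter tolerance)
#' @param require_base_peak require `[FCO]+` to be the base peak?
#' @param use_ammonium also admit candidates via the `[M+NH4]+` precursor?
#' @return annotation data frame (possibly 0 rows): one row per identified
#'   TAG with columns `spectrum_id`, `name`, `tier` (`"FULL"` or
#'   `"FUFA_ONLY"`), `fufa`, `rt`, `formula`, `carbon_number`,
#'   `precursor_calc`, `precursor_obs`, `precursor_ppm`, `intensity`,
#'   `n_diacyl_matched`, `n_diacyl_expected`, `ambiguous`,
#'   `positional_isomers` and a list-column `ions` holding the matched-ion
#'   evidence. The attribute `"rejections"` logs, per rejected candidate, the
#'   filter step that failed.
#' @examples
#' db <- enumerate_candidates(conv = c("L", "O"), fufas = c("9M5", "11M3"))
#' s <- ms2_spectrum(c(109.0653, 165.1280, 291.2324, 599.5039, 627.4989),
#'                   c(150, 100, 1000, 400, 420), precursor_mz = 907.7391)
#' screen_spectrum(s, db)
#' @export
screen_spectrum <- function(spectrum, db, tol_ppm = 4,
                            require_base_peak = FALSE, use_ammonium = FALSE) {
  stopifnot(inherits(spectrum, "ms2_spectrum"), inherits(db, "candidate_db"),
            tol_ppm > 0)
  rejections <- list()
  reject <- function(name, step) {
    rejections[[length(rejections) + 1L]] <<- data.frame(
      spectrum_id = spectrum$id, candidate = name, failed_step = step,
      stringsAsFactors = FALSE)
  }

  prec <- spectrum$precursor_mz
  hit_h <- abs(ppm_error(prec, db$mz_h)) <= tol_ppm
  hit <- if (use_ammonium) hit_h | abs(ppm_error(prec, db$mz_nh4)) <= tol_ppm
         else hit_h
  cand_idx <- which(hit)
  out <- .empty_annotations()
  if (length(cand_idx) == 0) {
    attr(out, "rejections") <- do.call(rbind, rejections)
    return(out)
  }
  bp <- if (nrow(spectrum$peaks)) base_peak(spectrum) else NULL

  passed <- list()
  for (i in cand_idx) {
    fs <- db$frags[[i]]
    nm <- db$name[i]
    # step 2/3: the diagnostic trio, once per distinct FuFA species
    trio_ok <- TRUE
    trio_ions <- list()
    fco_main <- NULL
    for (r in seq_len(nrow(fs$acylium))) {
      if (!fs$acylium$is_fufa[r]) next
      token <- fs$acylium$token[r]
      mf <- match_peak(spectrum, fs$acylium$mz[r], tol_ppm)
      if (is.null(mf)) { reject(nm, "fco"); trio_ok <- FALSE; break }
      if (require_base_peak && !isTRUE(all.equal(mf$mz, bp$mz))) {
        reject(nm, "fco_base_peak"); trio_ok <- FALSE; break
      }
      core <- fs$core[fs$core$token == token, ]
      mc <- match_peak(spectrum, core$mz, tol_ppm)
      if (is.null(mc)) { reject(nm, "furan_core"); trio_ok <- FALSE; break }
      mcl <- fs$mclafferty[fs$mclafferty$token == token, ]
      mm <- match_peak(spectrum, mcl$mz, tol_ppm)
      if (is.null(mm)) { reject(nm, "mclafferty"); trio_ok <- FALSE; break }
      if (is.null(fco_main) || mf$intensity > fco_main$intensity) fco_main <- mf
      trio_ions <- c(trio_ions, list(
        .ion_row("fco", paste0("[FCO]+ ", token), fs$acylium$mz[r], mf),
        .ion_row("furan_core", paste0("core ", token), core$mz, mc),
        .ion_row("mclafferty", paste0("McLafferty ", token), mcl$mz, mm)))
    }
    if (!trio_ok) next

    # step 4: diacyl ions assign the conventional fatty acids
    dia <- fs$diacyl
    dia_ions <- list()
    n_matched <- 0L
    for (r in seq_len(nrow(dia))) {
      md <- match_peak(spectrum, dia$mz[r], tol_ppm)
      if (!is.null(md)) {
        n_matched <- n_matched + 1L
        dia_ions <- c(dia_ions, list(
          .ion_row("diacyl", paste0("[", dia$pair[r], "]+"), dia$mz[r], md)))
      }
    }

    prec_ions <- list(data.frame(
      ion_type = "precursor", label = "[M+H]+", mz_calc = db$mz_h[i],
      mz_obs = prec, ppm = ppm_error(prec, db$mz_h[i]), intensity = NA_real_,
      stringsAsFactors = FALSE))
    inspec <- match_peak(spectrum, db$mz_h[i], tol_ppm)
    if (!is.null(inspec))
      prec_ions <- c(prec_ions, list(
        .ion_row("precursor_peak", "[M+H]+ in-spectrum", db$mz_h[i], inspec)))

    passed[[length(passed) + 1L]] <- list(
      idx = i, name = nm, fufa = db$fufa_tokens[i],
      fco = fco_main, n_matched = n_matched, n_expected = nrow(dia),
      coverage = n_matched / nrow(dia),
      ions = do.call(rbind, c(prec_ions, trio_ions, dia_ions)))
  }

  if (length(passed) == 0) {
    attr(out, "rejections") <- do.call(rbind, rejections)
    return(out)
  }

  keys <- vapply(passed, `[[`, "", "fufa")
  rows <- list()
  for (key in unique(keys)) {
    grp <- passed[keys == key]
    covered <- vapply(grp, `[[`, 0, "coverage")
    full <- grp[covered > 0]
    if (length(full)) {
      best <- max(vapply(full, `[[`, 0, "coverage"))
      keep <- full[vapply(full, `[[`, 0, "coverage") == best]
      for (g in keep) {
        i <- g$idx
        rows[[length(rows) + 1L]] <- data.frame(
          spectrum_id = spectrum$id, name = g$name, tier = "FULL",
          fufa = key, rt = spectrum$rt, formula = db$formula[i],
          carbon_number = db$carbon_number[i], precursor_calc = db$mz_h[i],
          precursor_obs = prec, precursor_ppm = ppm_error(prec, db$mz_h[i]),
          intensity = g$fco$intensity, n_diacyl_matched = g$n_matched,
          n_diacyl_expected = g$n_expected,
          ambiguous = length(keep) > 1,
          positional_isomers = "unresolved", stringsAsFactors = FALSE)
        rows[[length(rows)]]$ions <- list(g$ions)
      }
      for (g in full[vapply(full, `[[`, 0, "coverage") < best])
        reject(g$name, "diacyl_outranked")
      for (g in grp[covered == 0]) reject(g$name, "diacyl_superseded")
    } else {
      # the FuFA is proven, the conventional fatty acids are not
      g <- grp[[1]]
      i <- g$idx
      cn <- unname(formula_parse(db$formula[i])["C"]) - 3L
      rows[[length(rows) + 1L]] <- data.frame(
        spectrum_id = spectrum$id, name = paste0("XY", gsub(",", "", key)),
        tier = "FUFA_ONLY", fufa = key, rt = spectrum$rt,
        formula = db$formula[i], carbon_number = cn,
        precursor_calc = db$mz_h[i], precursor_obs = prec,
        precursor_ppm = ppm_error(prec, db$mz_h[i]),
        intensity = g$fco$intensity, n_diacyl_matched = 0L,
        n_diacyl_expected = g$n_expected, ambiguous = FALSE,
        positional_isomers = "unresolved", stringsAsFactors = FALSE)
      rows[[length(rows)]]$ions <- list(g$ions)
      for (g2 in grp[-1]) reject(g2$name, "diacyl")
    }
  }
  out <- do.call(rbind, rows)

  # cross-candidate arbitration: an annotation whose matched diagnostic
  # peaks are a strict subset of another annotation's is an isobaric shadow
  # of it (acyl-pair and acylium degeneracies always leave such shadows) and
  # is dropped; annotations explaining identical peak sets, or differing
  # FuFAs sharing the [FCO]+ mass (both cores present), are flagged
  # ambiguous rather than guessed between.
  if (nrow(out) > 1) {
    diag_types <- c("fco", "furan_core", "mclafferty", "diacyl")
    expl <- lapply(seq_len(nrow(out)), function(r) {
      ir <- out$ions[[r]]
      sort(unique(round(ir$mz_obs[ir$ion_type %in% diag_types], 6)))
    })
    drop <- rep(FALSE, nrow(out))
    for (a in seq_len(nrow(out))) for (b in seq_len(nrow(out))) {
      if (a == b || drop[b]) next
      if (length(expl[[a]]) < length(expl[[b]]) &&
          all(expl[[a]] %in% expl[[b]])) {
        drop[a] <- TRUE
        reject(out$name[a], "evidence_subsumed")
        break
      }
    }
    out <- out[!drop, , drop = FALSE]
    expl <- expl[!drop]
    if (nrow(out) > 1) {
      fcomz <- vapply(seq_len(nrow(out)), function(r) {
        ir <- out$ions[[r]]
        ir$mz_calc[ir$ion_type == "fco"][1]
      }, 0)
      for (a in seq_len(nrow(out) - 1)) for (b in (a + 1):nrow(out)) {
        same_set <- identical(expl[[a]], expl[[b]])
        shared_fco <- abs(ppm_error(fcomz[a], fcomz[b])) <= 2 * tol_ppm
        if (out$fufa[a] != out$fufa[b] && (same_set || shared_fco))
          out$ambiguous[c(a, b)] <- TRUE
      }
    }
  }
  rownames(out) <- NULL
  attr(out, "rejections") <- do.call(rbind, rejections)
  out
}

#' Annotate a whole run of MS2 spectra
#'
#' Screens every spectrum and merges the results into one report table:
#' annotations sharing a TAG name are deduplicated keeping the occurrence
#' with the highest `[FCO]+` intensity, and rows are ordered by retention
#' time. This mirrors a one-row-per-TAG identification report.
#'
#' @param spectra list of `ms2_spectrum`
#' @param db a `candidate_db`
#' @param ... passed on to [screen_spectrum()] (`tol_ppm`,
#'   `require_base_peak`, `use_ammonium`)
#' @return annotation data frame as in [screen_spectrum()], one row per
#'   distinct TAG, with attribute `"rejections"`
#' @export
annotate_run <- function(spectra, db, ...) {
  if (inherits(spectra, "ms2_spectrum")) spectra <- list(spectra)
  parts <- lapply(spectra, screen_spectrum, db = db, ...)
  rej <- do.call(rbind, lapply(parts, attr, "rejections"))
  tab <- do.call(rbind, parts)
  if (is.null(tab) || nrow(tab) == 0) {
    tab <- .empty_annotations()
    attr(tab, "rejections") <- rej
    return(tab)
  }
  ord <- order(tab$name, -tab$intensity)
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[!duplicated(tab$name), , drop = FALSE]
  tab <- tab[order(tab$rt, tab$precursor_calc), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "rejections") <- rej
  tab
}

#' Write an annotation report
#'
#' Tab-separated report mirroring the identification table (name, retention
#' time, formula, observed precursor, matched-fragment summary, carbon
#' number, intensity), plus optional JSON evidence with every matched ion.
#'
#' @param annotations annotation data frame from [annotate_run()]
#' @param path output TSV path
#' @param evidence_path optional path for a JSON file with full matched-ion
#'   evidence per annotation
#' @return `path`, invisibly
#' @export
write_annotations <- function(annotations, path, evidence_path = NULL) {
  tab <- annotations
  tab$fragments <- vapply(seq_len(nrow(tab)), function(r) {
    ir <- tab$ions[[r]]
    ir <- ir[ir$ion_type %in% c("mclafferty", "furan_core", "fco", "diacyl"), ]
    paste(sprintf("%s=%.4f", ir$ion_type, ir$mz_obs), collapse = ";")
  }, "")
  keep <- c("name", "tier", "rt", "formula", "precursor_obs", "precursor_calc",
            "fragments", "carbon_number", "intensity", "ambiguous")
  out <- tab[, keep, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(evidence_path)) {
    ev <- lapply(seq_len(nrow(tab)), function(r)
      list(name = tab$name[r], tier = tab$tier[r], rt = tab$rt[r],
           formula = tab$formula[r], carbon_number = tab$carbon_number[r],
           intensity = tab$intensity[r], ions = tab$ions[[r]]))
    jsonlite::write_json(ev, evidence_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  }
  invisible(path)
}

#' Relative abundances across replicate runs
#'
#' Expresses each TAG's intensity as a percentage of a reference intensity
#' and reports the spread across runs. The reference is the most abundant
#' TAG of the *first* run, chosen separately within each class (FuFA-
#' containing vs conventional TAGs) and fixed at 100%. Runs missing the
#' reference TAG are flagged rather than dropped.
#'
#' @param tables list (length >= 2) of annotation tables sharing TAG names;
#'   each needs columns `name` and `intensity`, and optionally `n_fufa` or
#'   `tier` to separate classes (absent both, all rows count as
#'   FuFA-containing)
#' @return data frame with one row per TAG: `name`, `class`, one
#'   `percent_run<i>` column per run, `mean_percent` and `rsd_percent` (the
#'   relative standard deviation across runs, in %). The attribute
#'   `"flagged_runs"` lists runs lacking a reference TAG.
#' @export
relative_abundances <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2)
  cls <- function(tab) {
    if (!is.null(tab$n_fufa)) ifelse(tab$n_fufa > 0, "fufa", "conventional")
    else if (!is.null(tab$tier)) rep("fufa", nrow(tab))
    else rep("fufa", nrow(tab))
  }
  first <- tables[[1]]
  first_cls <- cls(first)
  refs <- vapply(split(seq_len(nrow(first)), first_cls), function(ix)
    first$name[ix][which.max(first$intensity[ix])], "")
  names_all <- unique(unlist(lapply(tables, `[[`, "name")))
  classes <- cls(tables[[1]])[match(names_all, tables[[1]]$name)]
  classes[is.na(classes)] <- "fufa"
  flagged <- character(0)
  perc <- matrix(NA_real_, nrow = length(names_all), ncol = length(tables))
  for (j in seq_along(tables)) {
    tab <- tables[[j]]
    for (ci in unique(classes)) {
      ref_name <- refs[[ci]]
      ref_int <- tab$intensity[match(ref_name, tab$name)]
      sel <- which(classes == ci)
      if (is.na(ref_int) || length(ref_int) == 0) {
        flagged <- c(flagged, sprintf("run %d lacks reference %s (%s)", j,
                                      ref_name, ci))
        next
      }
      perc[sel, j] <- tab$intensity[match(names_all[sel], tab$name)] /
        ref_int * 100
    }
  }
  mean_p <- rowMeans(perc, na.rm = TRUE)
  rsd <- apply(perc, 1, function(x)
    if (sum(is.finite(x)) >= 2 && mean(x, na.rm = TRUE) > 0)
      stats::sd(x, na.rm = TRUE) / mean(x, na.rm = TRUE) * 100 else NA_real_)
  out <- data.frame(name = names_all, class = classes,
                    stringsAsFactors = FALSE)
  for (j in seq_along(tables)) out[[paste0("percent_run", j)]] <- perc[, j]
  out$mean_percent <- mean_p
  out$rsd_percent <- rsd
  attr(out, "flagged_runs") <- flagged
  out
}

#' Indirect per-TAG content estimation
#'
#' Distributes a known total FuFA(-TAG) content over the annotated TAGs in
#' proportion to their peak intensities: `content_i = total * I_i / sum(I)`.
#' This assumes all FuFA-TAGs respond similarly in MS2 — plausible because
#' the dominant diagnostic ions arise from the common FuFA substructure —
#' and is how a detection floor can be estimated without authentic
#' standards. When `basis = "lipid"`, contents given per dry weight are
#' converted by dividing by the lipid fraction.
#'
#' @param table annotation table with columns `name` and `intensity`
#' @param total_fufa_content total content to distribute, mg per 100 g dry
#'   weight
#' @param basis report per `"dry-weight"` (default) or per `"lipid"`
#' @param lipid_fraction lipid mass fraction of the dry weight (e.g. 0.05);
#'   required for `basis = "lipid"`
#' @return data frame `name`, `intensity`, `content` (mg/100 g on the chosen
#'   basis), with attribute `"minimum"` = the lowest per-TAG content
#' @examples
#' tab <- data.frame(name = c("A", "B"), intensity = c(3, 1))
#' estimate_contents(tab, total_fufa_content = 4)
#' @export
estimate_contents <- function(table, total_fufa_content,
                              basis = c("dry-weight", "lipid"),
                              lipid_fraction = NULL) {
  basis <- match.arg(basis)
  stopifnot(total_fufa_content > 0)
  total_int <- sum(table$intensity)
  if (!is.finite(total_int) || total_int <= 0)
    stop("total intensity is zero; cannot allocate contents", call. = FALSE)
  content <- total_fufa_content * table$intensity / total_int
  if (basis == "lipid") {
    if (is.null(lipid_fraction) || lipid_fraction <= 0)
      stop("basis = \"lipid\" needs a positive lipid_fraction", call. = FALSE)
    content <- content / lipid_fraction
  }
  out <- data.frame(name = table$name, intensity = table$intensity,
                    content = content, stringsAsFactors = FALSE)
  attr(out, "minimum") <- min(content)
  attr(out, "basis") <- basis
  out
}
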