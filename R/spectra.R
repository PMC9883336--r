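#' Centroided MS2 spectrum
#'
#' A centroided tandem mass spectrum: a peak list sorted by m/z plus the
#' precursor m/z and optional retention time. All identification logic works
#' on this container regardless of the source format.
#'
#' @param mz peak m/z values (> 0)
#' @param intensity peak intensities (>= 0), same length as `mz`
#' @param precursor_mz precursor (isolation target) m/z
#' @param id spectrum identifier
#' @param rt retention time in minutes (carried through for reporting only;
#'   identification is purely mass-based)
#' @param source optional source metadata (e.g. file of origin)
#' @return object of class `ms2_spectrum`
#' @examples
#' ms2_spectrum(c(291.2324, 599.5039), c(1000, 400), precursor_mz = 907.7391)
#' @export
ms2_spectrum <- function(mz, intensity, precursor_mz, id = "spectrum",
                         rt = NA_real_, source = NULL) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) && any(mz <= 0)) stop("peak m/z must be positive", call. = FALSE)
  if (length(intensity) && any(intensity < 0))
    stop("peak intensities must be non-negative", call. = FALSE)
  if (!is.finite(precursor_mz) || precursor_mz <= 0)
    stop("precursor m/z missing or non-positive", call. = FALSE)
  ord <- order(mz)
  structure(list(id = as.character(id), precursor_mz = precursor_mz,
                 rt = as.numeric(rt),
                 peaks = data.frame(mz = mz[ord], intensity = intensity[ord]),
                 source = source),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("MS2 spectrum \"%s\": precursor m/z %.4f, %d peaks%s\n",
              x$id, x$precursor_mz, nrow(x$peaks),
              if (is.finite(x$rt)) sprintf(", rt %.2f min", x$rt) else ""))
  invisible(x)
}

#' Most intense peak of a spectrum
#'
#' Ties are broken towards the lower m/z.
#'
#' @param spectrum an `ms2_spectrum`
#' @return one-row data frame with `mz` and `intensity`
#' @export
base_peak <- function(spectrum) {
  stopifnot(inherits(spectrum, "ms2_spectrum"))
  p <- spectrum$peaks
  if (nrow(p) == 0) stop("empty spectrum has no base peak", call. = FALSE)
  i <- which(p$intensity == max(p$intensity))[1]  # peaks sorted by m/z
  p[i, , drop = FALSE]
}

#' Match a theoretical m/z against a spectrum
#'
#' Among the peaks within `tol_ppm` of `target_mz`, returns the most intense
#' one; intensity ties are broken towards the smallest absolute ppm
#' deviation. The default tolerance of 4 ppm is the screening filter's
#' maximum allowed deviation from the exact masses.
#'
#' @param spectrum an `ms2_spectrum`
#' @param target_mz theoretical m/z to look for
#' @param tol_ppm matching tolerance in ppm (> 0)
#' @return one-row data frame with `mz`, `intensity`, `ppm`, or `NULL` when
#'   no peak qualifies
#' @examples
#' s <- ms2_spectrum(305.2479, 1000, precursor_mz = 921.7543)
#' match_peak(s, 305.2481)
#' @export
match_peak <- function(spectrum, target_mz, tol_ppm = 4) {
  stopifnot(inherits(spectrum, "ms2_spectrum"), tol_ppm > 0)
  p <- spectrum$peaks
  if (nrow(p) == 0) return(NULL)
  ppm <- ppm_error(p$mz, target_mz)
  sel <- which(abs(ppm) <= tol_ppm)
  if (length(sel) == 0) return(NULL)
  best <- sel[order(-p$intensity[sel], abs(ppm[sel]))][1]
  data.frame(mz = p$mz[best], intensity = p$intensity[best], ppm = ppm[best])
}

# ---- MGF ------------------------------------------------------------------

#' Read an MGF peak-list file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks. `PEPMASS` provides the precursor
#' m/z, `TITLE` the spectrum id and `RTINSECONDS` (when present) the
#' retention time, converted to minutes.
#'
#' @param path file path
#' @return list of `ms2_spectrum`
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (!any(nzchar(lines))) {
    warning("empty MGF file: ", path)
    return(list())
  }
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts))
    stop("malformed MGF block structure in ", path, call. = FALSE)
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[(starts[b] + 1):(ends[b] - 1)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- toupper(sub("=.*", "", block[kv]))
    vals <- sub("^[^=]*=", "", block[kv])
    getv <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    prec <- suppressWarnings(as.numeric(strsplit(
      trimws(getv("PEPMASS")), "[ \t]+")[[1]][1]))
    if (!is.finite(prec))
      stop("MGF block ", b, " lacks a numeric PEPMASS", call. = FALSE)
    rtsec <- suppressWarnings(as.numeric(getv("RTINSECONDS")))
    id <- getv("TITLE")
    if (is.na(id)) id <- paste0("mgf_", b)
    peakl <- block[!kv & nzchar(block)]
    pm <- do.call(rbind, lapply(strsplit(peakl, "[ \t]+"), function(x) {
      v <- suppressWarnings(as.numeric(x[1:2]))
      if (anyNA(v)) stop("non-numeric peak line in MGF block ", b, call. = FALSE)
      v
    }))
    if (is.null(pm)) pm <- matrix(numeric(0), ncol = 2)
    out[[b]] <- ms2_spectrum(pm[, 1], pm[, 2], precursor_mz = prec, id = id,
                             rt = if (is.finite(rtsec)) rtsec / 60 else NA_real_,
                             source = path)
  }
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra an `ms2_spectrum` or list thereof
#' @param path output file
#' @return `path`, invisibly
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "ms2_spectrum")) spectra <- list(spectra)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$id),
                 sprintf("PEPMASS=%.6f", s$precursor_mz),
                 if (is.finite(s$rt)) sprintf("RTINSECONDS=%.3f", s$rt * 60),
                 "CHARGE=1+",
                 sprintf("%.6f %.1f", s$peaks$mz, s$peaks$intensity),
                 "END IONS", ""), con)
  }
  invisible(path)
}

# ---- TSV peak-list dialect -------------------------------------------------

#' Read and write the tab-separated peak-list dialect
#'
#' A long-format, human-diffable dialect: UTF-8, tab-separated, header
#' `id  precursor_mz  rt  mz  intensity`, one row per peak, m/z written with
#' six decimals. Rows sharing an `id` form one spectrum; `precursor_mz` and
#' `rt` must be constant within a spectrum (`rt` may be empty).
#'
#' @param path file path
#' @param spectra an `ms2_spectrum` or list thereof
#' @return `read_peaklist_tsv()` returns a list of `ms2_spectrum`;
#'   `write_peaklist_tsv()` returns `path` invisibly.
#' @export
read_peaklist_tsv <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  need <- c("id", "precursor_mz", "rt", "mz", "intensity")
  if (!all(need %in% names(tab)))
    stop("peak-list TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) == 0) {
    warning("empty peak-list file: ", path)
    return(list())
  }
  ids <- unique(tab$id)
  lapply(ids, function(i) {
    rows <- tab[tab$id == i, , drop = FALSE]
    prec <- unique(rows$precursor_mz)
    if (length(prec) != 1)
      stop("inconsistent precursor_mz within spectrum id ", i, call. = FALSE)
    ms2_spectrum(rows$mz, rows$intensity, precursor_mz = prec, id = i,
                 rt = rows$rt[1], source = path)
  })
}

#' @rdname read_peaklist_tsv
#' @export
write_peaklist_tsv <- function(spectra, path) {
  if (inherits(spectra, "ms2_spectrum")) spectra <- list(spectra)
  rows <- lapply(spectra, function(s) {
    data.frame(id = s$id,
               precursor_mz = sprintf("%.6f", s$precursor_mz),
               rt = ifelse(is.finite(s$rt), sprintf("%.3f", s$rt), ""),
               mz = sprintf("%.6f", s$peaks$mz),
               intensity = s$peaks$intensity, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(id = character(0), precursor_mz = character(0),
                      rt = character(0), mz = character(0),
                      intensity = numeric(0))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# ---- mzML ------------------------------------------------------------------

#' Read MS2 spectra from an mzML file
#'
#' Reads an mzML file through Bioconductor's mzR backend and yields the
#' MS-level-2 spectra with their precursor m/z. Level-1 scans are skipped.
#' MS2 scans lacking a precursor annotation are skipped with a warning (the
#' stream continues). Profile-mode spectra are rejected unless
#' `accept_profile = TRUE`, since the matcher assumes centroided data.
#'
#' @param path mzML file path
#' @param accept_profile accept spectra not flagged as centroided?
#' @return list of `ms2_spectrum`
#' @export
read_mzml <- function(path, accept_profile = FALSE) {
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- suppressWarnings(mzR::header(handle))
  sel <- which(hdr$msLevel == 2)
  out <- list()
  for (i in sel) {
    if (!is.finite(hdr$precursorMZ[i]) || hdr$precursorMZ[i] <= 0) {
      warning("skipping MS2 scan ", hdr$seqNum[i], " without precursor m/z")
      next
    }
    centroided <- isTRUE(hdr$centroided[i])
    if (!centroided && !accept_profile)
      stop("scan ", hdr$seqNum[i], " is not flagged centroided; ",
           "use accept_profile = TRUE to override", call. = FALSE)
    pk <- suppressWarnings(mzR::peaks(handle, hdr$seqNum[i]))
    rt <- hdr$retentionTime[i]
    out[[length(out) + 1L]] <- ms2_spectrum(
      pk[, 1], pk[, 2], precursor_mz = hdr$precursorMZ[i],
      id = if (!is.null(hdr$spectrumId)) hdr$spectrumId[i]
           else paste0("scan_", hdr$seqNum[i]),
      rt = if (is.finite(rt)) rt / 60 else NA_real_,
      source = path)
  }
  out
}
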