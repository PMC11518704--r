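# Centroided MS/MS spectrum container and plain-text I/O (MGF and a one-peak-
# per-row CSV dialect). No installed R package reads MGF, so the reader/writer
# here implements the minimal TITLE/PEPMASS/CHARGE/RTINSECONDS dialect.

#' Construct a centroided MS/MS spectrum
#'
#' @param id Spectrum identifier.
#' @param polarity `"positive"` or `"negative"`.
#' @param precursor_mz Precursor m/z (> 0).
#' @param mz,intensity Fragment peak list; intensities are relative, in
#'   \[0, 1\]. Peaks are stored sorted ascending by m/z (annotation is
#'   invariant to input order).
#' @param rt_min Optional retention time in minutes.
#' @return An `ms2_spectrum` object.
#' @export
ms2_spectrum <- function(id, polarity, precursor_mz, mz = numeric(0),
                         intensity = rep(1, length(mz)), rt_min = NA_real_) {
  polarity <- match.arg(polarity, c("positive", "negative"))
  stopifnot(is.numeric(precursor_mz), precursor_mz > 0,
            length(mz) == length(intensity))
  if (length(intensity) && (any(intensity < 0) || any(intensity > 1))) {
    stop("relative intensities must lie in [0, 1]")
  }
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (length(mz) && max(mz) > precursor_mz * (1 + 20e-6)) {
    stop("fragment m/z above the precursor m/z in spectrum ", id)
  }
  structure(list(id = as.character(id), polarity = polarity,
                 precursor_mz = precursor_mz, rt_min = rt_min,
                 peaks = data.frame(mz = mz, intensity = intensity)),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum %s> %s mode, precursor m/z %.4f, %d peaks%s\n",
              x$id, x$polarity, x$precursor_mz, nrow(x$peaks),
              if (is.na(x$rt_min)) "" else sprintf(", RT %.2f min", x$rt_min)))
  invisible(x)
}

#' Read spectra from an MGF file
#'
#' Supports the common BEGIN IONS / END IONS blocks with TITLE, PEPMASS,
#' CHARGE (`1+`/`1-`, giving the polarity) and optional RTINSECONDS headers,
#' followed by `m/z intensity` peak rows. Peak intensities are rescaled to
#' relative intensities in \[0, 1\] per spectrum.
#'
#' @param path MGF file path.
#' @return List of `ms2_spectrum` objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(starts) != length(ends)) stop("unbalanced BEGIN/END IONS in ", path)
  lapply(seq_along(starts), function(k) {
    block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    keys <- toupper(sub("=.*$", "", block[hdr]))
    vals <- sub("^[^=]*=", "", block[hdr])
    get <- function(key) if (key %in% keys) vals[match(key, keys)] else NA_character_
    charge <- get("CHARGE")
    polarity <- if (!is.na(charge) && grepl("-", charge, fixed = TRUE))
      "negative" else "positive"
    rt <- suppressWarnings(as.numeric(get("RTINSECONDS"))) / 60
    peak_rows <- block[!hdr & nzchar(trimws(block))]
    pk <- if (length(peak_rows)) {
      mat <- do.call(rbind, lapply(strsplit(trimws(peak_rows), "\\s+"),
                                   function(x) as.numeric(x[1:2])))
      data.frame(mz = mat[, 1], intensity = mat[, 2])
    } else data.frame(mz = numeric(0), intensity = numeric(0))
    if (nrow(pk) && max(pk$intensity) > 0) pk$intensity <- pk$intensity / max(pk$intensity)
    ms2_spectrum(id = ifelse(is.na(get("TITLE")), paste0("spectrum_", k), get("TITLE")),
                 polarity = polarity,
                 precursor_mz = as.numeric(strsplit(get("PEPMASS"), "\\s+")[[1]][1]),
                 mz = pk$mz, intensity = pk$intensity,
                 rt_min = if (is.na(rt)) NA_real_ else rt)
  })
}

#' Write spectra to an MGF file
#'
#' @param spectra List of `ms2_spectrum` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "ms2_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", sp$id),
      sprintf("PEPMASS=%.6f", sp$precursor_mz),
      paste0("CHARGE=1", if (sp$polarity == "negative") "-" else "+"),
      if (!is.na(sp$rt_min)) sprintf("RTINSECONDS=%.3f", sp$rt_min * 60),
      sprintf("%.6f %.6f", sp$peaks$mz, sp$peaks$intensity),
      "END IONS"
    ), con)
  }
  invisible(path)
}

#' Read spectra from the package's peak-table CSV dialect
#'
#' One fragment peak per row, with columns `id`, `polarity`, `precursor_mz`,
#' `mz`, `intensity` and optionally `rt_min`; spectrum-level fields must be
#' constant within an `id`.
#'
#' @param path CSV file path.
#' @return List of `ms2_spectrum` objects.
#' @export
read_peaks_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "polarity", "precursor_mz", "mz", "intensity")
  if (!all(need %in% names(tab))) {
    stop("peak CSV must have columns: ", paste(need, collapse = ", "))
  }
  lapply(split(tab, tab$id), function(d) {
    ms2_spectrum(id = d$id[1], polarity = d$polarity[1],
                 precursor_mz = d$precursor_mz[1],
                 mz = d$mz, intensity = d$intensity,
                 rt_min = if ("rt_min" %in% names(d)) d$rt_min[1] else NA_real_)
  })
}
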