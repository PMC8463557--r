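#' Construct a raw mass spectrum
#'
#' A raw spectrum is an ascending m/z grid with non-negative intensities and
#' free-form provenance metadata (at least a `label`).
#'
#' @param mass numeric vector of m/z values in Da, strictly increasing.
#' @param intensity numeric vector of intensities (arbitrary units), same
#'   length as `mass`.
#' @param meta named list of metadata (`label`, `id`, `station`, `year`, ...).
#' @return an object of class `raw_spectrum` with elements `mass`,
#'   `intensity`, `meta`.
#' @export
raw_spectrum <- function(mass, intensity, meta = list()) {
  mass <- as.numeric(mass)
  intensity <- as.numeric(intensity)
  if (length(mass) != length(intensity))
    stop_msg("mass and intensity must have equal length")
  if (length(mass) < 2L) stop_msg("a spectrum needs at least 2 points")
  if (any(!is.finite(mass)) || any(!is.finite(intensity)))
    stop_msg("non-finite values in spectrum")
  if (any(diff(mass) <= 0)) stop_msg("mass values must be strictly increasing")
  structure(list(mass = mass, intensity = intensity, meta = as.list(meta)),
            class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("<raw_spectrum> %d points, m/z %.1f-%.1f Da%s\n",
              length(x$mass), min(x$mass), max(x$mass),
              if (!is.null(x$meta$label)) paste0(", label=", x$meta$label) else ""))
  invisible(x)
}

#' @export
length.raw_spectrum <- function(x) length(x$mass)

#' Read a spectrum from two-column ASCII text
#'
#' The dialect is plain text with two whitespace- or tab-separated columns
#' (m/z in Da, intensity); lines starting with `#` are header comments and
#' are ignored. Non-monotone m/z is rejected.
#'
#' @param path file path.
#' @param label optional species label stored in the metadata.
#' @return a [raw_spectrum()].
#' @export
read_spectrum <- function(path, label = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop_msg("no data lines in '%s'", path)
  fields <- strsplit(trimws(lines), "[\t ]+")
  if (any(lengths(fields) < 2L))
    stop_msg("malformed line in '%s' (need two columns)", path)
  mass <- as.numeric(vapply(fields, `[[`, "", 1L))
  intensity <- as.numeric(vapply(fields, `[[`, "", 2L))
  if (anyNA(mass) || anyNA(intensity)) stop_msg("non-numeric value in '%s'", path)
  meta <- list(id = sub("\\.[^.]*$", "", basename(path)))
  if (!is.null(label)) meta$label <- label
  raw_spectrum(mass, intensity, meta)
}

#' Write a spectrum in the two-column ASCII dialect
#'
#' @param s a [raw_spectrum()].
#' @param path output file path.
#' @param digits significant digits for formatting.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, digits = 10) {
  stopifnot(inherits(s, "raw_spectrum"))
  hdr <- c(
    sprintf("# spectrotype spectrum: %s",
            if (!is.null(s$meta$label)) s$meta$label else "unlabeled"),
    "# columns: m/z(Da) intensity")
  body <- paste(format(s$mass, trim = TRUE, digits = digits, scientific = FALSE),
                format(s$intensity, trim = TRUE, digits = digits, scientific = FALSE))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a directory of spectra via its manifest
#'
#' The manifest is a CSV with columns `filename`, `species_label` (and
#' optionally `seed`) as written by [write_spectra()].
#'
#' @param dir directory containing spectrum files and `manifest.csv`.
#' @param manifest manifest filename within `dir`.
#' @return list of [raw_spectrum()] objects, labels in metadata.
#' @export
read_spectra <- function(dir, manifest = "manifest.csv") {
  mf_path <- file.path(dir, manifest)
  if (!file.exists(mf_path)) stop_msg("manifest '%s' not found", mf_path)
  mf <- read.csv(mf_path, stringsAsFactors = FALSE)
  if (!all(c("filename", "species_label") %in% names(mf)))
    stop_msg("manifest must have columns filename, species_label")
  lapply(seq_len(nrow(mf)), function(i)
    read_spectrum(file.path(dir, mf$filename[i]), label = mf$species_label[i]))
}
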