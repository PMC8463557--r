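#' Bin peaks across spectra at a relative mass tolerance
#'
#' Pooled peak masses from all spectra are partitioned into bins by recursive
#' splitting of the sorted masses at the largest gap, until every bin
#' satisfies both constraints: relative spread
#' `(max - min) / mean <= tolerance_rel`, and no bin holds two peaks from the
#' same spectrum. Each peak's mass is then replaced by its bin mean; the bin
#' means define the columns of the feature matrix.
#'
#' @param peaklists list of `peak_list` objects (one per spectrum).
#' @param tolerance_rel relative mass tolerance (dimensionless, default
#'   0.001).
#' @return list with `peaklists` (masses replaced by bin means) and
#'   `bin_masses` (sorted bin means).
#' @export
bin_peaks <- function(peaklists, tolerance_rel = 0.001) {
  if (!length(peaklists)) stop_msg("need at least one peak list")
  stopifnot(all(vapply(peaklists, inherits, TRUE, "peak_list")))
  spec_id <- rep(seq_along(peaklists), vapply(peaklists, function(p) length(p$masses), 0L))
  mass <- unlist(lapply(peaklists, `[[`, "masses"), use.names = FALSE)
  pos <- unlist(lapply(peaklists, function(p) seq_along(p$masses)), use.names = FALSE)
  binned_mass <- mass
  if (length(mass)) {
    ord <- order(mass)
    m_s <- mass[ord]; id_s <- spec_id[ord]
    assign_bin <- numeric(length(m_s))
    # explicit stack instead of recursion: pooled peak counts can be large
    stack <- list(c(1L, length(m_s)))
    while (length(stack)) {
      rng <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      a <- rng[1]; b <- rng[2]
      seg <- m_s[a:b]
      ok <- (max(seg) - min(seg)) / mean(seg) <= tolerance_rel &&
        !anyDuplicated(id_s[a:b])
      if (ok || a == b) {
        assign_bin[a:b] <- mean(seg)
      } else {
        gaps <- diff(seg)
        cut <- which.max(gaps)  # first largest gap
        stack[[length(stack) + 1L]] <- c(a, a + cut - 1L)
        stack[[length(stack) + 1L]] <- c(a + cut, b)
      }
    }
    binned_mass[ord] <- assign_bin
  }
  out <- peaklists
  for (i in seq_along(out)) {
    sel <- spec_id == i
    out[[i]]$masses[pos[sel]] <- binned_mass[sel]
  }
  list(peaklists = out, bin_masses = sort(unique(binned_mass)))
}

#' Build the spectra-by-bins feature matrix
#'
#' Rows are spectra, columns are binned peak masses; a cell holds the peak
#' intensity, or 0 when the spectrum has no peak in that bin. Columns whose
#' occupancy fraction (spectra with a peak / all spectra) is below
#' `min_frequency` are removed; columns at exactly the threshold are kept.
#'
#' @param binned result of [bin_peaks()].
#' @param min_frequency minimum occupancy fraction (default 0.05).
#' @param ids optional spectrum identifiers (default from metadata).
#' @param labels optional species labels (default from metadata).
#' @return numeric matrix with spectrum ids as rownames, bin masses as
#'   column names, and the labels in `attr(, "species")`.
#' @export
build_feature_matrix <- function(binned, min_frequency = 0.05,
                                 ids = NULL, labels = NULL) {
  pls <- binned$peaklists
  n <- length(pls)
  bins <- binned$bin_masses
  if (is.null(ids))
    ids <- vapply(seq_len(n), function(i) {
      id <- pls[[i]]$meta$id
      if (is.null(id)) sprintf("spectrum_%03d", i) else as.character(id)
    }, "")
  if (is.null(labels))
    labels <- vapply(pls, function(p) {
      l <- p$meta$label
      if (is.null(l)) NA_character_ else as.character(l)
    }, "")
  m <- matrix(0, n, length(bins), dimnames = list(ids, format(bins, trim = TRUE)))
  for (i in seq_len(n)) {
    j <- match(pls[[i]]$masses, bins)
    m[i, j] <- pls[[i]]$intensities
  }
  occupancy <- colMeans(m > 0)
  keep <- occupancy >= min_frequency
  if (!any(keep)) stop_msg("all feature columns fall below min_frequency %.3f", min_frequency)
  m <- m[, keep, drop = FALSE]
  attr(m, "bin_masses") <- bins[keep]
  attr(m, "species") <- labels
  m
}

#' Hellinger transformation of a feature matrix
#'
#' Each cell becomes the square root of its row-relative abundance:
#' `x_ij <- sqrt(x_ij / sum_j x_ij)`, so every row's sum of squares is 1 and
#' Euclidean distances between rows equal Hellinger distances.
#'
#' @param m feature matrix (non-negative, no all-zero rows).
#' @return the transformed matrix, attributes preserved.
#' @export
hellinger <- function(m) {
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    bad <- rownames(m)[which(rs <= 0)[1]]
    stop_msg("all-zero row in feature matrix: spectrum '%s'",
             if (is.null(bad)) as.character(which(rs <= 0)[1]) else bad)
  }
  out <- sqrt(sweep(m, 1, rs, `/`))
  attributes(out) <- attributes(m)
  out
}

#' Per-species peak occurrence patterns
#'
#' For each feature column, the fraction of spectra of each species in which
#' the peak occurs. Columns are retained only if that occupancy reaches
#' `pattern_min_frequency` in at least one species, and are ordered by the
#' between-species variance of their occupancy (most discriminating first).
#'
#' @param m feature matrix with species labels (see
#'   [build_feature_matrix()]), or supply `labels`.
#' @param pattern_min_frequency simplification threshold (default 0.8).
#' @param labels species labels per row.
#' @return matrix species x retained features of occupancy fractions, with
#'   `attr(, "variance")` holding the ordering statistic.
#' @export
peak_patterns <- function(m, pattern_min_frequency = 0.8,
                          labels = attr(m, "species")) {
  if (is.null(labels) || anyNA(labels)) stop_msg("species labels are required")
  labels <- as.character(labels)
  present <- m > 0
  freq <- rowsum(present + 0, labels) / as.vector(table(labels)[sort(unique(labels))])
  keep <- apply(freq, 2, max) >= pattern_min_frequency
  if (!any(keep)) {
    out <- freq[, 0, drop = FALSE]
    attr(out, "variance") <- numeric(0)
    return(out)
  }
  freq <- freq[, keep, drop = FALSE]
  v <- apply(freq, 2, var)
  out <- freq[, order(v, decreasing = TRUE), drop = FALSE]
  attr(out, "variance") <- sort(v, decreasing = TRUE)
  out
}

#' Write a feature matrix as CSV
#'
#' Layout: first column spectrum id, second column species label, remaining
#' columns headed by the bin mass rounded to 2 decimals. Full-precision bin
#' masses and values are preserved in the file (values at 17 significant
#' digits, bin masses in a header comment), so
#' `read_feature_matrix(write_feature_matrix(m))` is bit-exact.
#'
#' @param m feature matrix from [build_feature_matrix()].
#' @param path output path.
#' @param comment optional extra `#` header lines (provenance).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path, comment = character()) {
  bins <- attr(m, "bin_masses")
  if (is.null(bins)) bins <- as.numeric(colnames(m))
  labels <- attr(m, "species")
  if (is.null(labels)) labels <- rep(NA_character_, nrow(m))
  hdr <- c(paste0("# ", comment),
           paste0("# bin_masses: ", paste(sprintf("%.17g", bins), collapse = " ")))
  header_row <- paste(c("id", "species", sprintf("%.2f", bins)), collapse = ",")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], labels[i], sprintf("%.17g", m[i, ])), collapse = ","), "")
  writeLines(c(hdr[nzchar(sub("^# ?", "", hdr)) | grepl("bin_masses", hdr)],
               header_row, body), path)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path CSV path.
#' @return the feature matrix with `bin_masses` and `species` attributes.
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path)
  com <- lines[grepl("^#", lines)]
  body <- lines[!grepl("^#", lines)]
  fields <- strsplit(body, ",", fixed = TRUE)
  header <- fields[[1]]
  rows <- fields[-1]
  ids <- vapply(rows, `[[`, "", 1L)
  labels <- vapply(rows, `[[`, "", 2L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-(1:2)]),
                   numeric(length(header) - 2L)))
  bm_line <- com[grepl("bin_masses:", com)]
  bins <- if (length(bm_line))
    as.numeric(strsplit(sub(".*bin_masses: *", "", bm_line[1]), " ")[[1]])
  else as.numeric(header[-(1:2)])
  m <- matrix(vals, nrow = length(ids),
              dimnames = list(ids, format(bins, trim = TRUE)))
  attr(m, "bin_masses") <- bins
  attr(m, "species") <- labels
  m
}
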