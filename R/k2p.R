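#' Read an aligned FASTA file
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @return a character matrix (sequences x sites, uppercase) of class
#'   `alignment`, rownames = sequence ids.
#' @export
read_alignment <- function(path) {
  seqs <- ape::read.FASTA(path)
  if (!length(seqs)) stop_msg("no sequences in '%s'", path)
  chars <- lapply(as.character(seqs), toupper)
  lens <- lengths(chars)
  if (length(unique(lens)) != 1L)
    stop_msg("sequences are not aligned (lengths %s)",
             paste(unique(lens), collapse = ", "))
  m <- do.call(rbind, chars)
  rownames(m) <- names(seqs)
  structure(m, class = c("alignment", "matrix"))
}

#' Construct an alignment from character strings
#' @param seqs named character vector of equal-length sequences.
#' @return an `alignment` matrix.
#' @export
alignment <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1L) stop_msg("sequences must have equal length")
  if (nchar(seqs[1]) < 1L) stop_msg("sequences must be non-empty")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- if (is.null(names(seqs))) sprintf("seq%d", seq_along(seqs)) else names(seqs)
  structure(m, class = c("alignment", "matrix"))
}

# U is an alias of T; anything outside A/C/G/T (gaps, N, IUPAC ambiguity)
# counts as missing
normalize_bases <- function(m) {
  m[m == "U"] <- "T"
  m
}

#' Complete deletion of gapped/ambiguous columns
#'
#' Removes every alignment column containing a gap (`-`), `N`, or any IUPAC
#' ambiguity code in any sequence; only columns where all sequences carry an
#' unambiguous A/C/G/T (U read as T) survive, order preserved.
#'
#' @param a an `alignment`.
#' @return the reduced `alignment`.
#' @export
complete_deletion <- function(a) {
  m <- normalize_bases(unclass(a))
  bad <- matrix(!(m %in% c("A", "C", "G", "T")), nrow = nrow(m))
  ok <- colSums(bad) == 0L
  if (!any(ok)) stop_msg("complete deletion removed all columns")
  structure(m[, ok, drop = FALSE], class = c("alignment", "matrix"))
}

#' Kimura 2-parameter distance between two sequences
#'
#' With transition proportion P (A<->G, C<->T) and transversion proportion Q
#' over the compared sites, `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`
#' substitutions per site. Sequences are assumed already free of gaps and
#' ambiguity (see [complete_deletion()]).
#'
#' @param s1,s2 character vectors (or strings) of equal length over
#'   A/C/G/T/U.
#' @return the K2P distance.
#' @export
k2p_distance <- function(s1, s2) {
  if (length(s1) == 1L && nchar(s1[1]) > 1L) s1 <- strsplit(toupper(s1), "")[[1]]
  if (length(s2) == 1L && nchar(s2[1]) > 1L) s2 <- strsplit(toupper(s2), "")[[1]]
  s1 <- toupper(s1); s2 <- toupper(s2)
  s1[s1 == "U"] <- "T"; s2[s2 == "U"] <- "T"
  if (length(s1) != length(s2)) stop_msg("sequences must have equal length")
  L <- length(s1)
  if (L < 1L) stop_msg("sequences must be non-empty")
  bad <- !(s1 %in% c("A", "C", "G", "T")) | !(s2 %in% c("A", "C", "G", "T"))
  if (any(bad)) stop_msg("ambiguous or gapped site at position %d; run complete_deletion first",
                         which(bad)[1])
  diffs <- s1 != s2
  purine <- c("A", "G")
  transitions <- diffs & ((s1 %in% purine) == (s2 %in% purine))
  P <- sum(transitions) / L
  Q <- sum(diffs & !transitions) / L
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0)
    stop_msg("K2P distance undefined (saturation): P = %.4f, Q = %.4f", P, Q)
  -0.5 * log(arg1 * sqrt(arg2))
}

#' Pairwise K2P distance matrix under complete deletion
#'
#' Columns with gaps or missing data are removed once for the whole
#' alignment, then every pair's K2P distance is computed on the retained
#' sites.
#'
#' @param a an `alignment` (see [read_alignment()] / [alignment()]).
#' @return symmetric distance matrix with zero diagonal, in
#'   substitutions/site; the number of retained sites in `attr(, "n_sites")`.
#' @export
k2p_matrix <- function(a) {
  if (nrow(a) < 2L) stop_msg("need at least 2 sequences")
  m <- complete_deletion(a)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- k2p_distance(m[i, ], m[j, ])
  attr(d, "n_sites") <- ncol(m)
  d
}

#' Write a distance matrix as CSV or lower-triangle text
#'
#' @param d distance matrix.
#' @param path output path.
#' @param format `"csv"` (square, with header) or `"lower"` (the
#'   lower-triangle layout used by common phylogenetics software).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path, format = c("csv", "lower")) {
  format <- match.arg(format)
  d <- as.matrix(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(nrow(d)))
  if (format == "csv") {
    lines <- c(paste(c("id", ids), collapse = ","),
               vapply(seq_len(nrow(d)), function(i)
                 paste(c(ids[i], sprintf("%.6f", d[i, ])), collapse = ","), ""))
  } else {
    lines <- c(sprintf("%d", nrow(d)),
               vapply(seq_len(nrow(d)), function(i) {
                 left <- if (i > 1) paste(sprintf("%.6f", d[i, seq_len(i - 1L)]), collapse = " ") else ""
                 trimws(paste(format(ids[i], width = 10), left))
               }, ""))
  }
  writeLines(lines, path)
  invisible(path)
}
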