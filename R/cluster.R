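#' Euclidean distance matrix between spectra
#' @param m feature matrix (rows = spectra).
#' @return a symmetric distance matrix with zero diagonal (class `matrix`).
#' @export
euclidean_distances <- function(m) {
  if (nrow(m) < 2L) stop_msg("need at least 2 rows")
  as.matrix(dist(m, method = "euclidean"))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d_ij = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk)`; entries lie in
#' \[0, 1\] for non-negative data.
#'
#' @param m feature matrix with non-negative entries and no all-zero rows.
#' @return a symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis <- function(m) {
  if (nrow(m) < 2L) stop_msg("need at least 2 rows")
  if (any(m < 0)) stop_msg("Bray-Curtis requires non-negative entries")
  if (any(rowSums(m) == 0)) stop_msg("all-zero row: Bray-Curtis undefined")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    xi <- m[i, ]
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(abs(xi - m[j, ])) / sum(xi + m[j, ])
    }
  }
  d
}

#' Ward clustering of a distance matrix
#'
#' Agglomerative clustering under the Ward-2D criterion (Lance-Williams on
#' squared distances with square-root heights, `hclust` method `ward.D2`):
#' merging two singletons at distance d gives merge height d, and for
#' Euclidean input the merge heights are monotone non-decreasing.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @return an object of class `ms_dendrogram`: list with the underlying
#'   `hclust` object (`hc`), `labels`, and `edges` (the leaf-index set of
#'   every internal node).
#' @export
ward_cluster <- function(d) {
  dm <- if (inherits(d, "dist")) d else as.dist(d)
  if (attr(dm, "Size") < 2L) stop_msg("need at least 2 observations")
  hc <- hclust(dm, method = "ward.D2")
  structure(list(hc = hc, labels = hc$labels, edges = hclust_edges(hc)),
            class = "ms_dendrogram")
}

# Multiscale-bootstrap AU fit for one edge: probit of clamped per-scale
# recovery proportions, weighted least squares on z(r) = v*sqrt(r) + c/sqrt(r)
# with binomial weights, AU = (1 - pnorm(v - c)) * 100. BP is the raw
# proportion at the scale nearest r = 1. An edge never recovered at any
# scale gets AU = 0 and the degenerate flag.
fit_au <- function(raw_counts, scales, B) {
  degenerate <- all(raw_counts == 0L)
  bp1 <- 100 * raw_counts[which.min(abs(scales - 1))] / B
  # saturated edges: recovered in every replicate at every scale (or none);
  # the probit fit cannot represent a constant, so report the limit directly
  if (all(raw_counts == B))
    return(list(au = 100, bp = bp1, degenerate = FALSE, v = -Inf, c = 0))
  cl <- pmin(pmax(raw_counts, 0.5), B - 0.5)
  bp_r <- cl / B
  z <- qnorm(1 - bp_r)
  w <- B * dnorm(z)^2 / (bp_r * (1 - bp_r))
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  fit <- tryCatch(lm.wfit(X, z, w)$coefficients, error = function(e) c(NA, NA))
  au <- if (anyNA(fit)) 100 * mean(raw_counts / B)
        else 100 * (1 - pnorm(fit[1] - fit[2]))
  if (degenerate) au <- 0
  list(au = unname(au), bp = bp1,
       degenerate = degenerate, v = unname(fit[1]), c = unname(fit[2]))
}

# leaf-index sets of all internal nodes of an hclust tree, in merge order
hclust_edges <- function(hc) {
  n <- nrow(hc$merge) + 1L
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    take <- function(x) if (x < 0) -x else sets[[x]]
    sets[[i]] <- sort(c(take(hc$merge[i, 1]), take(hc$merge[i, 2])))
  }
  sets
}

#' @export
print.ms_dendrogram <- function(x, ...) {
  cat(sprintf("<ms_dendrogram> %d leaves, %d merges%s\n",
              length(x$hc$order), nrow(x$hc$merge),
              if (!is.null(x$au)) ", with AU/BP support" else ""))
  invisible(x)
}

#' Cut a dendrogram into k clusters
#' @param dend an `ms_dendrogram`.
#' @param k number of clusters.
#' @return integer cluster memberships named by leaf labels.
#' @export
cut_dendrogram <- function(dend, k) {
  stopifnot(inherits(dend, "ms_dendrogram"))
  cutree(dend$hc, k = k)
}

#' Multiscale-bootstrap parameters
#' @param scales resampling ratios r (default 0.5 to 1.4 by 0.1; must
#'   include 1 for BP reporting).
#' @param replicates replicates per scale B (published default 10,000; use
#'   100-1000 for tests).
#' @param seed integer seed.
#' @param resample what to resample: `"features"` (columns; the convention
#'   for cluster support of objects) or `"rows"`.
#' @return a list of class `mb_params`.
#' @export
mb_params <- function(scales = seq(0.5, 1.4, by = 0.1), replicates = 10000,
                      seed = 1L, resample = c("features", "rows")) {
  if (any(scales <= 0)) stop_msg("all scales must be positive")
  if (replicates < 1) stop_msg("replicates must be >= 1")
  structure(list(scales = scales, replicates = as.integer(replicates),
                 seed = as.integer(seed), resample = match.arg(resample)),
            class = "mb_params")
}

#' Ward dendrogram with multiscale-bootstrap AU/BP edge support
#'
#' For each scale r, the feature columns are resampled with replacement to
#' size `round(p * r)`, the spectra are reclustered (Euclidean + Ward-2D) and
#' each original internal edge's recovery is counted, giving per-scale
#' bootstrap proportions BP_r. Per edge, `z_r = qnorm(1 - BP_r)` (counts
#' clamped to `[0.5, B - 0.5]`) is fitted by weighted least squares to
#' `z(r) = v * sqrt(r) + c / sqrt(r)` with binomial weights; the
#' approximately unbiased support is `AU = (1 - pnorm(v - c)) * 100` and BP
#' is the raw proportion at r = 1.
#'
#' @param m (Hellinger-transformed) feature matrix.
#' @param params an [mb_params()].
#' @return an `ms_dendrogram` with per-edge vectors `au`, `bp` (percent),
#'   `degenerate` (edge never recovered at any scale, AU forced to 0), and
#'   the per-scale count matrix in `bp_counts`.
#' @export
au_bp <- function(m, params = mb_params()) {
  if (ncol(m) < 2L) stop_msg("need at least 2 features")
  dend <- ward_cluster(euclidean_distances(m))
  sig0 <- vapply(dend$edges, paste, "", collapse = "-")
  n_edges <- length(sig0)
  p <- if (params$resample == "features") ncol(m) else nrow(m)
  counts <- matrix(0L, n_edges, length(params$scales),
                   dimnames = list(NULL, sprintf("r=%g", params$scales)))
  B <- params$replicates
  with_seed(params$seed, {
    for (si in seq_along(params$scales)) {
      size <- max(2L, round(p * params$scales[si]))
      for (b in seq_len(B)) {
        take <- sample.int(p, size, replace = TRUE)
        mb <- if (params$resample == "features") m[, take, drop = FALSE]
              else m[take, , drop = FALSE]
        hb <- hclust(dist(mb), method = "ward.D2")
        sigb <- vapply(hclust_edges(hb), paste, "", collapse = "-")
        hit <- sig0 %in% sigb
        counts[hit, si] <- counts[hit, si] + 1L
      }
    }
  })
  fits <- apply(counts, 1, fit_au, scales = params$scales, B = B)
  dend$au <- vapply(fits, `[[`, 0, "au")
  dend$bp <- vapply(fits, `[[`, 0, "bp")
  dend$degenerate <- vapply(fits, `[[`, TRUE, "degenerate")
  dend$bp_counts <- counts
  dend$params <- params
  dend
}

#' Export a dendrogram as Newick with "AU|BP" node labels
#'
#' Internal node labels carry the support percentages as `AU|BP` with one
#' decimal; branch lengths derive from the merge heights.
#'
#' @param dend an `ms_dendrogram` (support optional).
#' @param path optional output file; when `NULL` the string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
write_newick <- function(dend, path = NULL) {
  stopifnot(inherits(dend, "ms_dendrogram"))
  hc <- dend$hc
  n <- nrow(hc$merge) + 1L
  labels <- if (is.null(hc$labels)) as.character(seq_len(n)) else hc$labels
  height_of <- function(x) if (x < 0) 0 else hc$height[x]
  node_str <- function(i) {
    parts <- vapply(1:2, function(s) {
      ch <- hc$merge[i, s]
      bl <- hc$height[i] - height_of(ch)
      if (ch < 0) sprintf("%s:%g", labels[-ch], bl)
      else sprintf("%s:%g", node_str(ch), bl)
    }, "")
    lab <- if (!is.null(dend$au))
      sprintf("%.1f|%.1f", dend$au[i], dend$bp[i]) else ""
    sprintf("(%s)%s", paste(parts, collapse = ","), lab)
  }
  nwk <- paste0(node_str(n - 1L), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
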