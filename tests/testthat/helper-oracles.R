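# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (loops, enumeration, direct formulas) and share no code
# with the implementation paths they check.

# Greedy minimal-variance-increase agglomeration on raw coordinates:
# at each step merge the pair of clusters whose union increases total
# within-cluster sum of squares the least. Returns the sorted leaf-index set
# of every merge, in merge order.
oracle_ward_merges <- function(X) {
  clusters <- as.list(seq_len(nrow(X)))
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL; best_d <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        a <- clusters[[i]]; b <- clusters[[j]]
        ca <- colMeans(X[a, , drop = FALSE])
        cb <- colMeans(X[b, , drop = FALSE])
        dss <- length(a) * length(b) / (length(a) + length(b)) *
          sum((ca - cb)^2)
        if (dss < best_d) { best_d <- dss; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters[[best[2]]] <- NULL
    clusters[[best[1]]] <- merged
  }
  merges
}

# Exhaustive minimal contiguous partition of sorted pooled peaks subject to
# the two bin constraints, by dynamic programming (min parts, then leftmost
# split for determinism). Returns a list of index ranges into the sorted
# order.
oracle_bin_partition <- function(mass, spec_id, tol) {
  ord <- order(mass)
  m <- mass[ord]; id <- spec_id[ord]
  n <- length(m)
  feasible <- function(a, b) {
    seg <- m[a:b]
    (max(seg) - min(seg)) / mean(seg) <= tol && !anyDuplicated(id[a:b])
  }
  best <- rep(Inf, n + 1L); best[1] <- 0
  back <- integer(n)
  for (b in seq_len(n)) {
    for (a in seq_len(b)) {
      if (feasible(a, b) && best[a] + 1 < best[b + 1L]) {
        best[b + 1L] <- best[a] + 1
        back[b] <- a
      }
    }
  }
  parts <- list(); b <- n
  while (b >= 1L) {
    a <- back[b]
    parts[[length(parts) + 1L]] <- list(lo = m[a], hi = m[b], mean = mean(m[a:b]))
    b <- a - 1L
  }
  list(n_bins = best[n + 1L], parts = rev(parts), order = ord)
}

# Brute-force complete deletion: explicit per-column scan.
oracle_complete_deletion <- function(char_matrix) {
  keep <- logical(ncol(char_matrix))
  for (j in seq_len(ncol(char_matrix))) {
    col <- toupper(char_matrix[, j])
    col[col == "U"] <- "T"
    keep[j] <- all(col %in% c("A", "C", "G", "T"))
  }
  char_matrix[, keep, drop = FALSE]
}

# Brute-force windowed strict-local-maximum scan.
oracle_local_maxima <- function(y, half_window, threshold) {
  n <- length(y)
  out <- integer()
  for (i in seq_len(n)) {
    if (y[i] < threshold || y[i] <= 0) next
    win <- y[max(1, i - half_window):min(n, i + half_window)]
    if (sum(win == y[i]) == 1L && y[i] == max(win)) out <- c(out, i)
  }
  out
}

# Direct SNIP iteration with explicit loops (independent of the vectorized
# implementation).
oracle_snip <- function(y, iterations, decreasing = TRUE) {
  n <- length(y)
  b <- y
  ks <- seq_len(min(iterations, (n - 1L) %/% 2L))
  if (decreasing) ks <- rev(ks)
  for (k in ks) {
    nb <- b
    for (i in seq_len(n)) {
      if (i - k < 1L || i + k > n) next  # boundary points pass through
      nb[i] <- min(b[i], (b[i - k] + b[i + k]) / 2)
    }
    b <- nb
  }
  b
}

# Tiny labeled peak-list factory for binning / feature-matrix tests.
fake_peaklist <- function(masses, intensities = rep(1, length(masses)),
                          id = "s1", label = "spA") {
  structure(list(masses = as.numeric(masses),
                 intensities = as.numeric(intensities),
                 snr = rep(10, length(masses)),
                 meta = list(id = id, label = label)),
            class = "peak_list")
}

# Feature matrix straight from values (rows spectra, cols bins).
fake_matrix <- function(values, labels = NULL, bins = NULL) {
  m <- as.matrix(values)
  if (is.null(bins)) bins <- 2000 + 100 * seq_len(ncol(m))
  rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  colnames(m) <- format(bins, trim = TRUE)
  attr(m, "bin_masses") <- bins
  if (!is.null(labels)) attr(m, "species") <- labels
  m
}

# Rejection-draw n masses with a minimum separation from each other and from
# an existing set (fingerprint construction for the skew scenario).
draw_masses <- function(n, lo = 2000, hi = 19000, min_sep = 60, existing = numeric()) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- runif(1, lo, hi)
    if (all(abs(c(out, existing) - cand) >= min_sep) || !length(c(out, existing)))
      out <- c(out, cand)
  }
  sort(out)
}

# The outlier-skew world: nine core species sharing a family-conserved peak
# set plus their own peaks, and one species with `xfold` as many exclusive
# high-intensity peaks.
make_skew_world <- function(cfg, n_family = 8, n_own = 4, xfold = 3,
                            core_intensity = 80, outlier_intensity = 240) {
  fam <- draw_masses(n_family)
  taken <- fam
  fps <- vector("list", 9)
  for (i in 1:9) {
    own <- draw_masses(n_own, existing = taken)
    taken <- c(taken, own)
    masses <- sort(c(fam, own))
    fps[[i]] <- species_fingerprint(
      sprintf("sp%02d", i), masses,
      rlnorm(length(masses), log(core_intensity), 0.3),
      rep(1, length(masses)), cfg)
  }
  n_out <- xfold * (n_family + n_own)
  own <- draw_masses(n_out, existing = taken)
  outlier <- species_fingerprint(
    "outlier", own, rlnorm(n_out, log(outlier_intensity), 0.3),
    rep(1, n_out), cfg)
  c(fps, list(outlier))
}

# Simulate a pair of sequences under the K2P substitution process at given
# expected transition/transversion rates (per site), for Monte-Carlo checks.
sim_k2p_pair <- function(n_sites, alpha, beta) {
  bases <- c("A", "C", "G", "T")
  s1 <- sample(bases, n_sites, replace = TRUE)
  s2 <- s1
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in seq_len(n_sites)) {
    u <- runif(1)
    if (u < alpha) {
      s2[i] <- transition[[s1[i]]]
    } else if (u < alpha + beta) {
      tv <- setdiff(bases, c(s1[i], transition[[s1[i]]]))
      s2[i] <- sample(tv, 1)
    }
  }
  list(s1 = s1, s2 = s2)
}
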