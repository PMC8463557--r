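#' Diagonal-discriminant t-score feature ranking
#'
#' Feature-independent (diagonal) discriminant scoring: for species g and
#' feature j,
#' `t_gj = (xbar_gj - xbar_j) / (m_g * (s_j + s0))`
#' with `m_g = sqrt(1/n_g - 1/n)`, pooled within-group standard deviation
#' `s_j`, and the variance-stabilizing offset `s0 = median_j(s_j)`. Features
#' are ranked by `sum_g t_gj^2`, descending: top features are those whose
#' group means deviate most from the grand mean relative to within-group
#' spread. Shared peaks get strongly negative scores in the species lacking
#' them; near-exclusive peaks score high where they occur.
#'
#' @param m feature matrix (typically Hellinger-transformed).
#' @param labels species labels per row (default from `attr(m, "species")`).
#' @return a list of class `feature_ranking`: `scores` (species x features
#'   t-score matrix), `rank_stat` (per-feature sum of squared scores),
#'   `order` (feature indices, best first), `s0`.
#' @export
dda_rank <- function(m, labels = attr(m, "species")) {
  if (is.null(labels)) stop_msg("species labels are required")
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop_msg("need at least 2 groups for discriminant ranking")
  n <- nrow(m)
  ng <- table(labels)[groups]
  grand <- colMeans(m)
  gmeans <- rowsum(m, labels)[groups, , drop = FALSE] / as.vector(ng)
  # pooled within-group variance with n - g degrees of freedom
  ssw <- colSums((m - gmeans[labels, , drop = FALSE])^2)
  if (n - length(groups) < 1L) stop_msg("no within-group degrees of freedom")
  s_j <- sqrt(ssw / (n - length(groups)))
  s0 <- median(s_j)
  m_g <- sqrt(1 / as.vector(ng) - 1 / n)
  scores <- sweep(gmeans, 2, grand, `-`) / outer(m_g, s_j + s0)
  rank_stat <- colSums(scores^2)
  structure(list(scores = scores, rank_stat = rank_stat,
                 order = order(rank_stat, decreasing = TRUE), s0 = s0),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  top <- colnames(x$scores)[x$order[seq_len(min(5, length(x$order)))]]
  cat(sprintf("<feature_ranking> %d species x %d features; top: %s\n",
              nrow(x$scores), ncol(x$scores), paste(top, collapse = ", ")))
  invisible(x)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Minimizes Kruskal's stress-1,
#' `sqrt(sum (delta_ij - dhat_ij)^2 / sum delta_ij^2)`, where `delta` are
#' configuration distances and `dhat` the monotone disparities from isotonic
#' regression (primary tie treatment: tied dissimilarities may untie). The
#' descent alternates isotonic fits with a Guttman transform, guarded by
#' step halving so the logged stress trace is non-increasing; it starts from
#' metric MDS (`cmdscale`) plus `n_restarts - 1` random configurations and
#' reports the best.
#'
#' @param d dissimilarity matrix (e.g. [bray_curtis()]).
#' @param k embedding dimension (default 2).
#' @param n_restarts number of starts including the metric start.
#' @param seed integer seed for the random starts.
#' @param maxit maximum descent iterations per start.
#' @param tol stress-decrease convergence tolerance.
#' @return a list of class `ordination`: `points` (n x k), `stress`,
#'   `stress_trace` (best start), `all_traces`, `converged`, `n_restarts`.
#' @export
nmds <- function(d, k = 2, n_restarts = 10, seed = 1L, maxit = 200,
                 tol = 1e-7) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < k + 1L) stop_msg("need at least k + 1 = %d points", k + 1L)
  lower <- which(lower.tri(dm))
  delta_obs <- dm[lower]
  ord <- order(delta_obs)
  denom_pairs <- length(lower)

  stress_fun <- function(conf_d, dhat) sqrt(sum((conf_d - dhat)^2) / sum(conf_d^2))
  disparities <- function(conf_d) {
    # primary ties: within tied blocks of the observed d, order by current
    # configuration distance so ties are free to untie
    o <- order(delta_obs, conf_d)
    fit <- isoreg(conf_d[o])$yf
    dhat <- numeric(denom_pairs)
    dhat[o] <- fit
    dhat
  }
  run_start <- function(X) {
    trace <- numeric(0)
    conv <- FALSE
    D <- as.matrix(dist(X)); cd <- D[lower]
    if (all(cd == 0)) { X <- X + matrix(rnorm(length(X), 0, 1e-6), n); D <- as.matrix(dist(X)); cd <- D[lower] }
    dhat <- disparities(cd)
    s <- stress_fun(cd, dhat)
    trace <- s
    for (it in seq_len(maxit)) {
      # Guttman transform with current disparities
      ratio <- matrix(0, n, n)
      ratio[lower] <- ifelse(cd > 0, dhat / cd, 0)
      ratio <- ratio + t(ratio)
      Bmat <- -ratio
      diag(Bmat) <- rowSums(ratio)
      Xn <- Bmat %*% X / n
      step <- 1
      repeat {
        Xc <- X + step * (Xn - X)
        Dc <- as.matrix(dist(Xc)); cdc <- Dc[lower]
        dhatc <- disparities(cdc)
        sc <- stress_fun(cdc, dhatc)
        if (sc <= s || step < 1 / 64) break
        step <- step / 2
      }
      if (sc > s) { conv <- TRUE; break }   # no descent direction left
      improved <- s - sc
      X <- Xc; cd <- cdc; dhat <- dhatc; s <- sc
      trace <- c(trace, s)
      if (improved < tol) { conv <- TRUE; break }
    }
    list(X = X, stress = s, trace = trace, converged = conv)
  }

  with_seed(seed, {
    starts <- vector("list", n_restarts)
    X0 <- tryCatch(suppressWarnings(cmdscale(dm, k = k)),
                   error = function(e) NULL)
    if (is.null(X0) || ncol(X0) < k)
      X0 <- matrix(rnorm(n * k), n, k)
    starts[[1]] <- X0
    if (n_restarts > 1)
      for (i in 2:n_restarts) starts[[i]] <- matrix(runif(n * k, -1, 1), n, k)
    runs <- lapply(starts, run_start)
    best <- which.min(vapply(runs, `[[`, 0, "stress"))
    pts <- runs[[best]]$X
    pts <- scale(pts, center = TRUE, scale = FALSE)
    rownames(pts) <- rownames(dm)
    structure(list(points = pts, stress = runs[[best]]$stress,
                   stress_trace = runs[[best]]$trace,
                   all_traces = lapply(runs, `[[`, "trace"),
                   converged = runs[[best]]$converged,
                   n_restarts = n_restarts),
              class = "ordination")
  })
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d points in %d dims, stress-1 = %.4f (%s)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Multivariate homogeneity of group dispersions
#'
#' betadisper-style test: the dissimilarity matrix is embedded by principal
#' coordinates (negative eigenvalues retained as imaginary axes); each
#' sample's distance to its group centroid is
#' `sqrt(max(0, d_real^2 - d_imag^2))`, and a one-way ANOVA F on these
#' distances with its parametric p tests whether group spreads differ.
#'
#' @param d dissimilarity matrix.
#' @param labels group labels.
#' @param n_perm if > 0, additionally compute a permutation p-value.
#' @param seed seed for the permutation p.
#' @return list of class `perm_test`: `statistic` (F), `p_value`
#'   (parametric), `p_perm` (or NA), `distances` (to centroids), `df`.
#' @export
dispersion_homogeneity <- function(d, labels, n_perm = 0, seed = 1L) {
  dm <- as.matrix(d)
  labels <- as.character(labels)
  n <- nrow(dm)
  if (length(labels) != n) stop_msg("labels length must match distance matrix")
  ng <- table(labels)
  if (length(ng) < 2L) stop_msg("need at least 2 groups")
  if (any(ng < 2L)) stop_msg("every group needs at least 2 members")
  # PCoA with negative eigenvalues kept as imaginary axes
  G <- -0.5 * dm^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))  # Gower centering: A - r_i - c_j + grand mean
  eg <- eigen(G, symmetric = TRUE)
  keep <- abs(eg$values) > max(abs(eg$values)) * 1e-10
  lambda <- eg$values[keep]
  axes <- sweep(eg$vectors[, keep, drop = FALSE], 2, sqrt(abs(lambda)), `*`)
  pos <- lambda > 0
  centroid_dist <- function(lab) {
    z2 <- numeric(n)
    for (g in unique(lab)) {
      rows <- lab == g
      cen <- colMeans(axes[rows, , drop = FALSE])
      dev2 <- sweep(axes[rows, , drop = FALSE], 2, cen)^2
      z2[rows] <- rowSums(dev2[, pos, drop = FALSE]) -
        rowSums(dev2[, !pos, drop = FALSE])
    }
    sqrt(pmax(z2, 0))
  }
  anova_f <- function(z, lab) {
    gm <- tapply(z, lab, mean)
    nn <- tapply(z, lab, length)
    ssb <- sum(nn * (gm - mean(z))^2)
    ssw <- sum((z - gm[lab])^2)
    df1 <- length(gm) - 1L; df2 <- n - length(gm)
    if (ssw == 0) {
      f <- if (ssb == 0) 0 else Inf
    } else f <- (ssb / df1) / (ssw / df2)
    f
  }
  z <- centroid_dist(labels)
  f_obs <- anova_f(z, labels)
  df1 <- length(ng) - 1L; df2 <- n - length(ng)
  p_par <- if (is.infinite(f_obs)) 0 else pf(f_obs, df1, df2, lower.tail = FALSE)
  if (f_obs == 0) p_par <- 1
  p_perm <- NA_real_
  if (n_perm > 0) {
    p_perm <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        zp <- z[sample.int(n)]   # permute distances-to-centroid among samples
        if (anova_f(zp, labels) >= f_obs) hits <- hits + 1L
      }
      (1 + hits) / (1 + n_perm)
    })
  }
  structure(list(statistic = f_obs, p_value = p_par, p_perm = p_perm,
                 distances = setNames(z, rownames(dm)),
                 df = c(df1 = df1, df2 = df2), n_permutations = n_perm),
            class = "perm_test")
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a dissimilarity
#' matrix: `SS_total = (1/n) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`,
#' `pseudo-F = (SS_between / (g - 1)) / (SS_within / (n - g))`; the p-value
#' is `(1 + #{F_perm >= F_obs}) / (1 + n_perm)` over random label
#' permutations.
#'
#' @param d dissimilarity matrix.
#' @param labels group labels.
#' @param n_perm number of permutations (published default 999).
#' @param seed integer seed.
#' @return list of class `perm_test`: `statistic` (pseudo-F), `p_value`,
#'   `ss` (total/within/between), `n_permutations`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1L) {
  dm <- as.matrix(d)
  labels <- as.character(labels)
  n <- nrow(dm)
  if (length(labels) != n) stop_msg("labels length must match distance matrix")
  groups <- unique(labels)
  g <- length(groups)
  if (g < 2L) stop_msg("need at least 2 groups")
  if (n_perm < 1L) stop_msg("n_perm must be >= 1")
  D2 <- dm^2
  ss_total <- sum(D2[lower.tri(D2)]) / n
  ss_within_of <- function(lab) {
    s <- 0
    for (grp in groups) {
      rows <- which(lab == grp)
      if (length(rows) > 1L)
        s <- s + sum(D2[rows, rows]) / (2 * length(rows))
    }
    s
  }
  f_of <- function(ssw) ((ss_total - ssw) / (g - 1)) / (ssw / (n - g))
  ssw_obs <- ss_within_of(labels)
  f_obs <- f_of(ssw_obs)
  p <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (f_of(ss_within_of(sample(labels))) >= f_obs) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  })
  structure(list(statistic = f_obs, p_value = p,
                 ss = c(total = ss_total, within = ssw_obs,
                        between = ss_total - ssw_obs),
                 df = c(df1 = g - 1L, df2 = n - g),
                 n_permutations = n_perm),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> F = %.4f, p = %.4g%s\n", x$statistic, x$p_value,
              if (!is.null(x$n_permutations) && x$n_permutations > 0)
                sprintf(" (%d permutations)", x$n_permutations) else ""))
  invisible(x)
}
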