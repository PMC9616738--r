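# Look-up / look-down unit typing: each unit is summarized as a z-scored
# bivariate firing-rate histogram over joint quantile bins of body arch and
# overall motion; units are connected when the Spearman correlation of
# their histograms exceeds the population median, and the resulting graph
# is partitioned by leading-eigenvector modularity maximization.

#' Bivariate firing-rate histogram of a unit
#'
#' Mean firing rate per joint quantile cell of two behavioural variables.
#' Cells with fewer than `min_occupancy` bins are imputed with the unit's
#' overall mean rate (and flagged) before the grid is z-scored using the
#' occupied cells' statistics. Units with fewer than half the cells
#' occupied are rejected.
#'
#' @param counts Spike counts per bin.
#' @param var1,var2 Behavioural series aligned with `counts` (var1 on the
#'   rows; by convention body arch x overall motion).
#' @param bin_s Bin duration (s) converting counts to rates.
#' @param n_bins Quantile bins per axis (default 5).
#' @param min_occupancy Minimum bins per cell before imputation (default 5).
#' @return An object of class `rate_histogram2d`: `z` (n_bins x n_bins
#'   z-scored grid), `rate_hz`, `occupancy`, `imputed` (logical grid),
#'   `axes` (variable names).
#' @export
bivariate_rate_histogram <- function(counts, var1, var2, bin_s,
                                     n_bins = 5L, min_occupancy = 5L) {
  ok <- !is.na(var1) & !is.na(var2)
  counts <- counts[ok]; var1 <- var1[ok]; var2 <- var2[ok]
  q1 <- quantile_discretize(var1, n_bins)
  q2 <- quantile_discretize(var2, n_bins)
  occ <- matrix(0L, n_bins, n_bins)
  rate <- matrix(NA_real_, n_bins, n_bins)
  for (i in seq_len(n_bins)) for (j in seq_len(n_bins)) {
    sel <- q1 == i & q2 == j
    occ[i, j] <- sum(sel)
    if (occ[i, j] > 0) rate[i, j] <- mean(counts[sel]) / bin_s
  }
  occupied <- occ >= min_occupancy
  if (sum(occ > 0) < ceiling(n_bins^2 / 2))
    stop_invalid("unit excluded: fewer than half of the cells occupied")
  imput <- !occupied
  rate[imput] <- mean(counts) / bin_s
  mu <- mean(rate[occupied]); sd_ <- stats::sd(rate[occupied])
  z <- if (!is.finite(sd_) || sd_ == 0) matrix(0, n_bins, n_bins)
       else (rate - mu) / sd_
  structure(list(z = z, rate_hz = rate, occupancy = occ, imputed = imput,
                 uninformative = !is.finite(sd_) || sd_ == 0,
                 n_bins = n_bins,
                 axes = c(deparse(substitute(var1))[1],
                          deparse(substitute(var2))[1])),
            class = "rate_histogram2d")
}

#' Build the unit adjacency graph from rate histograms
#'
#' Spearman correlation between flattened z-scored histograms for all unit
#' pairs; two units are connected when their correlation strictly exceeds
#' the median of the off-diagonal correlation distribution, so the edge
#' density is one half up to ties.
#'
#' @param histograms List of `rate_histogram2d` (length >= 4).
#' @return List with `adjacency` (symmetric 0/1 matrix, zero diagonal),
#'   `correlation` (Spearman matrix), `threshold` (the median used).
#' @export
build_adjacency <- function(histograms) {
  if (length(histograms) < 4L) stop_invalid("need at least 4 units")
  Zs <- vapply(histograms, function(h) as.vector(h$z),
               numeric(length(histograms[[1]]$z)))
  C <- suppressWarnings(stats::cor(Zs, method = "spearman"))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  off <- C[upper.tri(C)]
  med <- stats::median(off)
  A <- (C > med) * 1
  diag(A) <- 0
  A <- A * (t(A) == A)  # guard symmetry (always true, C symmetric)
  list(adjacency = A, correlation = C, threshold = med)
}

# Modularity of a labelled partition of the graph with adjacency A.
#' @keywords internal
partition_modularity <- function(A, labels) {
  k <- rowSums(A)
  m2 <- sum(k)
  if (m2 == 0) return(0)
  B <- A - outer(k, k) / m2
  same <- outer(labels, labels, `==`)
  sum(B[same]) / m2
}

# Kernighan-Lin style fine-tuning of a bisection vector s on the
# (generalized) modularity matrix Bg: greedy single-vertex flips while any
# flip increases s' Bg s. Flipping s_i changes the form by
# 4 * (Bg_ii - s_i * (Bg s)_i).
#' @keywords internal
refine_bisection <- function(Bg, s) {
  repeat {
    Bs <- as.vector(Bg %*% s)
    gain <- 4 * (diag(Bg) - s * Bs)
    i <- which.max(gain)
    if (gain[i] <= 1e-12) break
    s[i] <- -s[i]
  }
  s
}

#' Leading-eigenvector community detection
#'
#' Newman's spectral algorithm: the network is bisected along the sign of
#' the leading eigenvector of the modularity matrix, then each part is
#' recursively bisected using the generalized modularity matrix of the
#' subgraph, stopping when the leading eigenvalue is non-positive or the
#' bisection would not increase modularity. Zero eigenvector components are
#' assigned to the positive group. Each bisection is fine-tuned by greedy
#' single-vertex moves (the Kernighan-Lin style stage of the spectral
#' method); set `refine = FALSE` for the bare eigenvector split.
#'
#' @param adjacency Symmetric 0/1 matrix (or the list from
#'   [build_adjacency()]).
#' @param refine Apply the vertex-moving fine-tuning stage (default TRUE).
#' @return An object of class `community_partition`: `labels` (integer per
#'   unit), `n_communities`, `modularity`.
#' @export
newman_communities <- function(adjacency, refine = TRUE) {
  if (is.list(adjacency) && !is.null(adjacency$adjacency))
    adjacency <- adjacency$adjacency
  A <- as.matrix(adjacency)
  n <- nrow(A)
  if (n == 0L) stop_invalid("empty graph")
  if (sum(A) == 0) stop_invalid("graph has no edges")
  k <- rowSums(A)
  m2 <- sum(k)
  B <- A - outer(k, k) / m2
  labels <- rep(1L, n)
  next_label <- 2L
  queue <- list(seq_len(n))
  eps <- 1e-10
  while (length(queue)) {
    g <- queue[[1]]; queue <- queue[-1]
    if (length(g) < 2L) next
    Bg <- B[g, g, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(B[g, g, drop = FALSE])
    eg <- eigen(Bg, symmetric = TRUE)
    if (eg$values[1] <= eps) next
    v <- eg$vectors[, 1]
    s <- ifelse(v >= 0, 1, -1)
    if (refine) s <- refine_bisection(Bg, s)
    if (all(s == 1) || all(s == -1)) next
    dQ <- as.numeric(t(s) %*% Bg %*% s) / (2 * m2)
    if (dQ <= eps) next
    g_pos <- g[s > 0]; g_neg <- g[s < 0]
    labels[g_neg] <- next_label
    next_label <- next_label + 1L
    queue <- c(queue, list(g_pos), list(g_neg))
  }
  labels <- as.integer(factor(labels))
  structure(list(labels = labels,
                 n_communities = length(unique(labels)),
                 modularity = partition_modularity(A, labels)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities over %d units, Q = %.4f\n",
              x$n_communities, length(x$labels), x$modularity))
  invisible(x)
}

#' Semantic look-up / look-down labels for communities
#'
#' The community whose mean z-scored rate in the top row-variable quantile
#' (body arch by convention, averaged over the other axis) is highest is
#' labelled `"look-up"`; all others `"look-down"`. A single community is
#' labelled `"unclassified"`.
#'
#' @param partition A `community_partition`.
#' @param histograms The list of `rate_histogram2d` used to build the graph
#'   (same unit order).
#' @return Character vector of semantic labels per unit, with the per-
#'   community summary in `attr(, "community_score")`.
#' @export
label_communities <- function(partition, histograms) {
  labs <- partition$labels
  if (partition$n_communities < 2L)
    return(structure(rep("unclassified", length(labs)),
                     community_score = NULL))
  nb <- histograms[[1]]$n_bins
  top_score <- vapply(histograms, function(h) mean(h$z[nb, ]), numeric(1))
  comm_score <- tapply(top_score, labs, mean)
  best <- as.integer(names(comm_score)[which.max(comm_score)])
  sem <- ifelse(labs == best, "look-up", "look-down")
  structure(sem, community_score = comm_score)
}
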