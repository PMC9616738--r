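# Bivariate rate histograms, the Spearman adjacency graph, leading-
# eigenvector communities, and the look-up/look-down labelling.

make_hists <- function(n_units = 60, seed = 21, duration = 600,
                       beta_ud = 0.5, all_positive = FALSE) {
  kin <- generate_kinematics(duration, seed = seed)
  st <- behavior_from_kinematics(kin)
  tun <- default_tuning(n_units, beta_ud = beta_ud)
  if (all_positive) tun$beta_ud <- abs(tun$beta_ud)
  spk <- generate_spikes(st, tun, bin_s = 0.67, seed = seed + 1)
  bb <- pose2thal:::bin_frames(st, 0.67)
  bar <- pose2thal:::aggregate_to_bins(st$data$Bar, bb)
  om <- pose2thal:::aggregate_to_bins(st$data$OM, bb)
  ok <- !is.na(bar) & !is.na(om)
  hists <- lapply(seq_len(n_units), function(u)
    bivariate_rate_histogram(spk$counts[ok, u], bar[ok], om[ok], 0.67))
  list(hists = hists, tun = tun)
}

test_that("rate histograms reflect monotone tuning and flag flat units", {
  set.seed(80)
  n <- 3000
  v1 <- rnorm(n); v2 <- rnorm(n)
  counts <- rpois(n, exp(log(3) + 0.8 * v1))
  h <- bivariate_rate_histogram(counts, v1, v2, 0.67)
  # rows monotone along var1 on average, flat along var2
  expect_true(all(diff(rowMeans(h$z)) > 0))
  expect_lt(max(abs(colMeans(h$z))), 0.5)
  expect_lt(abs(mean(h$z)), 1e-9)
  expect_equal(sd(as.vector(h$z)[as.vector(!h$imputed)]), 1, tolerance = 1e-9)
  # constant unit: all-zero grid, flagged uninformative
  h0 <- bivariate_rate_histogram(rep(3L, n), v1, v2, 0.67)
  expect_true(h0$uninformative)
  expect_true(all(h0$z == 0))
})

test_that("median thresholding yields half edge density and clean blocks", {
  fx <- fixture("hists60", function() make_hists())
  g <- build_adjacency(fx$hists)
  n <- length(fx$hists)
  dens <- sum(g$adjacency) / (n * (n - 1))
  expect_equal(dens, 0.5, tolerance = 0.02)
  expect_true(isSymmetric(g$adjacency))
  expect_true(all(diag(g$adjacency) == 0))
  expect_true(isSymmetric(g$correlation))
  expect_true(all(abs(diag(g$correlation) - 1) < 1e-12))
  # duplicated histogram blocks connect within and not between
  hA <- fx$hists[[1]]; hB <- fx$hists[[2]]
  dup <- c(rep(list(hA), 4), rep(list(hB), 4))
  g2 <- build_adjacency(dup)
  expect_true(all(g2$adjacency[1:4, 1:4][upper.tri(diag(4))] == 1))
  expect_true(all(g2$adjacency[1:4, 5:8] == 0))
})

test_that("leading-eigenvector communities solve canonical cases", {
  A <- matrix(0, 12, 12)
  A[1:6, 1:6] <- 1; A[7:12, 7:12] <- 1; diag(A) <- 0
  p <- newman_communities(A)
  expect_equal(p$n_communities, 2)
  expect_length(unique(p$labels[1:6]), 1)
  expect_length(unique(p$labels[7:12]), 1)
  expect_equal(p$modularity, 0.5)
  pK <- newman_communities(matrix(1, 8, 8) - diag(8))
  expect_equal(pK$n_communities, 1)
  expect_equal(pK$modularity, 0)
  expect_error(newman_communities(matrix(0, 4, 4)), "edges")
})

test_that("community detection approaches the exhaustive bipartition optimum", {
  set.seed(81)
  hits <- 0; total <- 40
  for (i in seq_len(total)) {
    n <- sample(6:11, 1)
    A <- matrix(rbinom(n * n, 1, 0.35), n, n)
    A[lower.tri(A)] <- t(A)[lower.tri(A)]; diag(A) <- 0
    if (sum(A) == 0) { total <- total - 1; next }
    q <- newman_communities(A)$modularity
    hits <- hits + (q >= best_bipartition_q(A) * 0.95 - 1e-12)
  }
  expect_gte(hits / total, 0.9)
})

test_that("partitions are invariant to unit relabelling", {
  set.seed(82)
  fx <- fixture("hists60", function() make_hists())
  A <- build_adjacency(fx$hists)$adjacency
  p1 <- newman_communities(A)
  perm <- sample(nrow(A))
  p2 <- newman_communities(A[perm, perm])
  tab <- table(p1$labels[perm], p2$labels)
  expect_equal(sum(apply(tab, 1, max)), nrow(A))
  expect_equal(p1$modularity, p2$modularity, tolerance = 1e-12)
})

test_that("look-up/look-down labels recover the planted population", {
  fx <- fixture("hists60", function() make_hists())
  part <- newman_communities(build_adjacency(fx$hists))
  expect_equal(part$n_communities, 2)
  sem <- label_communities(part, fx$hists)
  truth <- ifelse(fx$tun$ud_sign > 0, "look-up", "look-down")
  expect_gte(mean(sem == truth), 0.9)
  # both communities are positively motion-modulated (z rises along OM)
  for (cm in 1:2) {
    zbar <- Reduce(`+`, lapply(which(part$labels == cm),
                               function(u) fx$hists[[u]]$z))
    zbar <- colMeans(zbar) / sum(part$labels == cm)
    expect_gt(cor(zbar, seq_along(zbar), method = "spearman"), 0)
    expect_gt(zbar[length(zbar)], zbar[1])
  }
  # flipping the up/down axis swaps the semantic labels
  flipped <- lapply(fx$hists, function(h) {
    h$z <- h$z[rev(seq_len(h$n_bins)), ]
    h
  })
  sem_fl <- label_communities(part, flipped)
  expect_true(all((sem == "look-up") == (sem_fl == "look-down")))
})

test_that("a homogeneous population falls back to the unclassified path", {
  fx <- fixture("hists_pos", function()
    make_hists(n_units = 24, seed = 33, all_positive = TRUE))
  part <- newman_communities(build_adjacency(fx$hists))
  sem <- label_communities(part, fx$hists)
  if (part$n_communities < 2) {
    expect_true(all(sem == "unclassified"))
  } else {
    expect_true(all(sem %in% c("look-up", "look-down")))
  }
})

test_that("modularity agrees with an independent graph-library computation", {
  skip_if_not_installed("igraph")
  set.seed(84)
  for (i in 1:10) {
    n <- sample(8:14, 1)
    A <- matrix(rbinom(n * n, 1, 0.4), n, n)
    A[lower.tri(A)] <- t(A)[lower.tri(A)]; diag(A) <- 0
    if (sum(A) == 0) next
    part <- newman_communities(A)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    q_ref <- igraph::modularity(g, part$labels)
    expect_equal(part$modularity, q_ref, tolerance = 1e-12)
    # and the spectral partition is no worse than igraph's own
    q_ig <- igraph::modularity(g, igraph::membership(
      igraph::cluster_leading_eigen(g)))
    expect_gte(part$modularity, q_ig - 0.02)
  }
})
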