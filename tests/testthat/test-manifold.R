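test_that("similarity-to-distance conversion is exact", {
  m <- matrix(c(1, 0.7887, -1, 0.7887, 1, 1, -1, 1, 1), 3)
  d <- ccd_to_distance(m)
  expect_equal(d[1, 2], 0.2113)
  expect_equal(d[1, 3], 2)
  expect_equal(diag(d), rep(0, 3))
})

test_that("MST matches brute force on small instances", {
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 1; d[1, 3] <- d[3, 1] <- 2; d[2, 3] <- d[3, 2] <- 3
  mst <- minimum_spanning_tree(d)
  expect_equal(edge_matrix(list(edges = mst$edges)),
               rbind(c(1, 2), c(1, 3)))
  expect_equal(sum(mst$edges$weight), 3)
  # 2 nodes: the single edge
  d2 <- matrix(c(0, 5, 5, 0), 2)
  expect_equal(nrow(minimum_spanning_tree(d2)$edges), 1)
  # chain distances: the chain is the unique MST
  n <- 6
  pos <- cumsum(c(0, rep(1, n - 1)))
  dc <- abs(outer(pos, pos, "-"))^1.5
  mstc <- minimum_spanning_tree(dc)
  expect_equal(edge_matrix(list(edges = mstc$edges)),
               cbind(1:(n - 1), 2:n))
  expect_error(minimum_spanning_tree(matrix(c(0, NA, NA, 0), 2)), "finite")
})

test_that("MST total weight agrees with igraph on random instances", {
  for (seed in 1:5) {
    d <- random_distance(15, seed)
    mine <- sum(minimum_spanning_tree(d)$edges$weight)
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    ref <- sum(igraph::E(igraph::mst(g))$weight)
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("MST path-max matrix equals per-pair path maxima", {
  d <- random_distance(10, 3)
  mst <- minimum_spanning_tree(d)
  g <- igraph::graph_from_edgelist(
    as.matrix(mst$edges[, c("i", "j")]), directed = FALSE)
  for (i in 1:9) for (j in (i + 1):10) {
    p <- igraph::shortest_paths(g, i, j)$vpath[[1]]
    expect_equal(mst$path_max[i, j],
                 max(d[cbind(p[-length(p)], p[-1])]))
  }
})

test_that("RMST reduces to the MST at gamma = 0", {
  for (seed in 1:20) {
    d <- random_distance(12, seed + 100)
    g <- rmst(d, gamma = 0)
    expect_equal(nrow(g$edges), 11)
    expect_equal(edge_matrix(g),
                 edge_matrix(list(edges = minimum_spanning_tree(d)$edges)))
  }
})

test_that("huge gamma saturates nodes at their relaxation cap", {
  d <- random_distance(5, 9)
  g <- rmst(d, gamma = 1e6, k_n = 10)
  expect_equal(nrow(g$edges), choose(5, 2))  # complete graph
  expect_gt(nrow(g$edges), 4)
})

test_that("RMST equals the brute-force relaxation oracle", {
  for (seed in c(1, 2, 3, 42)) {
    d <- random_distance(6, seed)
    expect_equal(edge_matrix(rmst(d, gamma = 3, k_n = 5, k_local = 1)),
                 unname(rmst_oracle(d, gamma = 3, k_n = 5, k_local = 1)))
  }
  # larger instance, different params
  d <- random_distance(9, 7)
  expect_equal(edge_matrix(rmst(d, gamma = 1, k_n = 2, k_local = 2)),
               unname(rmst_oracle(d, gamma = 1, k_n = 2, k_local = 2)))
})

test_that("RMST edge count is monotone in gamma and contains the MST", {
  for (seed in 1:20) {
    d <- random_distance(12, seed + 200)
    counts <- sapply(c(0, 0.5, 1, 3, 10),
                     function(g) nrow(rmst(d, gamma = g)$edges))
    expect_true(all(diff(counts) >= 0))
    mst_e <- edge_matrix(list(edges = minimum_spanning_tree(d)$edges))
    rmst_e <- edge_matrix(rmst(d, gamma = 3))
    expect_true(all(apply(mst_e, 1, function(e)
      any(rmst_e[, 1] == e[1] & rmst_e[, 2] == e[2]))))
  }
})

test_that("graph Laplacian has the defining algebraic properties", {
  # single weighted edge
  g1 <- structure(list(n_nodes = 2,
                       edges = data.frame(i = 1, j = 2, weight = 0,
                                          type = "mst")),
                  class = "state_graph")
  expect_equal(graph_laplacian(g1), matrix(c(1, -1, -1, 1), 2))
  # path P3 eigenvalues {0, 1, 3}
  p3 <- structure(list(n_nodes = 3,
                       edges = data.frame(i = 1:2, j = 2:3, weight = 0,
                                          type = "mst")),
                  class = "state_graph")
  expect_equal(eigen(graph_laplacian(p3))$values, c(3, 1, 0),
               tolerance = 1e-12)
  # rows sum to zero, PSD, one zero eigenvalue for connected graphs
  d <- random_distance(10, 11)
  L <- graph_laplacian(rmst(d))
  expect_equal(max(abs(rowSums(L))), 0, tolerance = 1e-12)
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
  expect_equal(sum(ev < 1e-8), 1)
  # disconnected input is rejected
  disc <- structure(list(n_nodes = 4,
                         edges = data.frame(i = c(1, 3), j = c(2, 4),
                                            weight = 0, type = "mst")),
                    class = "state_graph")
  expect_error(graph_laplacian(disc), "disconnected")
})

test_that("eigenmap of a path graph matches the closed-form spectrum", {
  n <- 8
  pg <- structure(list(n_nodes = n,
                       edges = data.frame(i = 1:(n - 1), j = 2:n, weight = 0,
                                          type = "mst")),
                  class = "state_graph")
  emb <- laplacian_eigenmaps(graph_laplacian(pg), 3)
  for (k in 1:3) {
    expect_equal(emb$eigenvalues[k], 2 - 2 * cos(pi * k / n),
                 tolerance = 1e-8)
    v_ref <- cos(pi * k * ((1:n) - 0.5) / n)
    v_ref <- v_ref / sqrt(sum(v_ref^2))
    m <- which.max(abs(v_ref))
    if (v_ref[m] < 0) v_ref <- -v_ref
    expect_equal(emb$coords[, k], v_ref, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("eigenmap of K5 gives all non-trivial eigenvalues equal to 5", {
  pairs <- t(utils::combn(5, 2))
  k5 <- structure(list(n_nodes = 5,
                       edges = data.frame(i = pairs[, 1], j = pairs[, 2],
                                          weight = 0, type = "mst")),
                  class = "state_graph")
  emb <- laplacian_eigenmaps(graph_laplacian(k5), 4)
  expect_equal(emb$eigenvalues, rep(5, 4), tolerance = 1e-10)
})

test_that("embedding columns are orthogonal to each other and the constant", {
  d <- ccd_to_distance(ccd(coherence_states(
    attr(two_stage_sim(n_trs = 80, seed = 13)$ts, "phases"))))
  emb <- laplacian_eigenmaps(graph_laplacian(rmst(d)), 5)
  gram <- crossprod(cbind(1 / sqrt(80), emb$coords))
  expect_lt(max(abs(gram - diag(6))), 1e-8)
  expect_true(all(diff(emb$eigenvalues) >= -1e-12))
})

test_that("PCA embedding matches a direct covariance eigen-solve", {
  x <- matrix(c(1, 2, 3, 4, 2, 1, 4, 3, 0, 0, 1, 1), 4)
  emb <- pca_embedding(x, 2)
  es <- eigen(stats::cov(x))
  ref <- sweep(x, 2, colMeans(x)) %*% es$vectors[, 1:2]
  for (k in 1:2)
    expect_equal(abs(emb$coords[, k]), abs(ref[, k]), tolerance = 1e-10,
                 ignore_attr = TRUE)
  expect_equal(emb$eigenvalues, es$values[1:2], tolerance = 1e-12)
  # rank-1 data: first component carries all variance
  r1 <- outer(1:5, c(1, 2, 3))
  e1 <- pca_embedding(r1, 2)
  expect_equal(e1$eigenvalues[2] / e1$eigenvalues[1], 0, tolerance = 1e-12)
  expect_error(pca_embedding(x, 5), "min")
})

test_that("PCA recovers planted coordinates through an orthonormal map", {
  withr::with_seed(22, {
    z <- matrix(stats::rnorm(200 * 2), 200)
    q <- qr.Q(qr(matrix(stats::rnorm(25), 5)))[, 1:2]
  })
  x <- z %*% t(q)
  emb <- pca_embedding(x, 2)
  # recovered scores equal generating coordinates up to rotation/sign
  pro <- fit_alignment(
    structure(list(X = t(emb$coords), stages = "a",
                   roles = c("min", "max")), class = "landmark_set"),
    structure(list(X = t(sweep(z, 2, colMeans(z))), stages = "a",
                   roles = c("min", "max")), class = "landmark_set"))
  expect_lt(pro$residual, 1e-6)
  # trace identity: retained score variance equals retained eigenvalues
  expect_equal(sum(apply(emb$coords, 2, stats::var)),
               sum(emb$eigenvalues), tolerance = 1e-8)
})

test_that("intrinsic dimension estimation finds the accuracy plateau", {
  flat <- lapply(1:5, function(d) rep(0.9, 18))
  names(flat) <- 1:5
  expect_equal(as.integer(estimate_intrinsic_dimension(flat)), 1L)
  # strictly increasing to dim 3 (large gaps), flat beyond
  withr::with_seed(23, {
    acc <- list(`1` = 0.5 + stats::rnorm(18, 0, 0.01),
                `2` = 0.7 + stats::rnorm(18, 0, 0.01),
                `3` = 0.9 + stats::rnorm(18, 0, 0.01),
                `4` = 0.9 + stats::rnorm(18, 0, 0.01),
                `5` = 0.9 + stats::rnorm(18, 0, 0.01))
  })
  est <- estimate_intrinsic_dimension(acc)
  expect_equal(as.integer(est), 3L)
  expect_true(attr(est, "plateau_found"))
  # single dimension: returned as-is
  expect_equal(as.integer(estimate_intrinsic_dimension(list(`4` = rep(0.8, 6)))),
               4L)
  # monotone increase throughout: no plateau, warn and return max
  inc <- lapply(1:4, function(d) d / 10 + stats::rnorm(18, 0, 0.001))
  names(inc) <- 1:4
  expect_warning(est2 <- estimate_intrinsic_dimension(inc), "plateau")
  expect_equal(as.integer(est2), 4L)
})
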