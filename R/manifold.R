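#' Convert a CCD similarity matrix to a distance matrix
#'
#' `d(ti, tj) = 1 - CCD(ti, tj)`, with the diagonal forced to exactly zero.
#'
#' @param x A `ccd_matrix` (or plain T x T similarity matrix in \[-1, 1\]).
#' @return T x T symmetric distance matrix with entries in \[0, 2\].
#' @export
ccd_to_distance <- function(x) {
  m <- if (inherits(x, "ccd_matrix")) x$matrix else as.matrix(x)
  d <- 1 - m
  diag(d) <- 0
  d
}

#' Minimum spanning tree of a distance matrix
#'
#' Kruskal's algorithm with a fully deterministic tie-break: candidate edges
#' are sorted lexicographically on (weight, i, j). Also returns the matrix of
#' maximum edge weights along the (unique) tree path between every pair of
#' nodes, a by-product of the merge order needed by [rmst()].
#'
#' @param dist T x T symmetric matrix of finite distances.
#' @return List with `edges` (data frame `i`, `j`, `weight`, i < j, T-1 rows)
#'   and `path_max` (T x T matrix, `path_max[i, j]` = largest edge weight on
#'   the tree path between i and j; 0 on the diagonal).
#' @export
minimum_spanning_tree <- function(dist) {
  dist <- as.matrix(dist)
  nt <- nrow(dist)
  if (nt < 2L) stop("need at least 2 nodes")
  if (any(!is.finite(dist))) stop("non-finite distances")
  pr <- pair_index(nt)
  w <- dist[cbind(pr$i, pr$j)]
  ord <- order(w, pr$i, pr$j)
  comp <- seq_len(nt)                      # component id per node
  members <- lapply(seq_len(nt), identity) # nodes per live component
  path_max <- matrix(0, nt, nt)
  ei <- integer(nt - 1L); ej <- integer(nt - 1L); ew <- numeric(nt - 1L)
  k <- 0L
  for (e in ord) {
    a <- comp[pr$i[e]]; b <- comp[pr$j[e]]
    if (a == b) next
    k <- k + 1L
    ei[k] <- pr$i[e]; ej[k] <- pr$j[e]; ew[k] <- w[e]
    ma <- members[[a]]; mb <- members[[b]]
    path_max[ma, mb] <- ew[k]
    path_max[mb, ma] <- ew[k]
    comp[mb] <- a
    members[[a]] <- c(ma, mb)
    members[b] <- list(NULL)
    if (k == nt - 1L) break
  }
  list(edges = data.frame(i = ei, j = ej, weight = ew), path_max = path_max)
}

#' Relaxed minimum spanning tree (RMST) graph
#'
#' Starts from the MST and relaxes its degree constraint: a non-tree pair
#' (i, j) is added as an edge when
#' `mw_ij + gamma * (d_i^k + d_j^k) > d_ij`,
#' where `mw_ij` is the largest edge weight on the MST path between i and j
#' and `d_i^k` is node i's distance to its `k_local`-th nearest neighbor.
#' Candidates are examined in ascending `d_ij` (ties broken on (i, j)), and an
#' edge is accepted only while both endpoints have received fewer than `k_n`
#' relaxation additions. `gamma = 0` returns the MST itself (the cycle
#' property makes the strict inequality unsatisfiable).
#'
#' @param dist T x T symmetric distance matrix.
#' @param gamma Relaxation parameter (>= 0, default 3).
#' @param k_n Maximum relaxation-added neighbors per node (default 5); MST
#'   edges do not count against the cap.
#' @param k_local Which nearest-neighbor distance enters the relaxation term
#'   (default 1, the nearest neighbor).
#' @return An object of class `state_graph`: list with `n_nodes`, `edges`
#'   (data frame `i`, `j`, `weight`, `type` in mst/relaxed) and the `params`
#'   used.
#' @export
rmst <- function(dist, gamma = 3, k_n = 5L, k_local = 1L) {
  dist <- as.matrix(dist)
  nt <- nrow(dist)
  stopifnot(gamma >= 0, k_n >= 1L, k_local >= 1L, k_local <= nt - 1L)
  mst <- minimum_spanning_tree(dist)
  # d_i^k: k_local-th smallest off-diagonal distance per node
  dk <- apply(dist + diag(Inf, nt), 1L, function(r) sort(r)[k_local])
  pr <- pair_index(nt)
  in_mst <- matrix(FALSE, nt, nt)
  in_mst[cbind(mst$edges$i, mst$edges$j)] <- TRUE
  cand <- which(!in_mst[cbind(pr$i, pr$j)])
  ci <- pr$i[cand]; cj <- pr$j[cand]
  cw <- dist[cbind(ci, cj)]
  ok <- mst$path_max[cbind(ci, cj)] + gamma * (dk[ci] + dk[cj]) > cw
  ci <- ci[ok]; cj <- cj[ok]; cw <- cw[ok]
  ord <- order(cw, ci, cj)
  added <- integer(nt)
  keep <- logical(length(ord))
  for (idx in seq_along(ord)) {
    e <- ord[idx]
    if (added[ci[e]] < k_n && added[cj[e]] < k_n) {
      keep[idx] <- TRUE
      added[ci[e]] <- added[ci[e]] + 1L
      added[cj[e]] <- added[cj[e]] + 1L
    }
  }
  sel <- ord[keep]
  edges <- data.frame(mst$edges, type = "mst")
  if (length(sel) > 0L)
    edges <- rbind(edges, data.frame(i = ci[sel], j = cj[sel],
                                     weight = cw[sel], type = "relaxed"))
  structure(list(n_nodes = nt, edges = edges,
                 params = list(gamma = gamma, k_n = k_n, k_local = k_local)),
            class = "state_graph")
}

#' @export
print.state_graph <- function(x, ...) {
  cat("State graph:", x$n_nodes, "nodes,", nrow(x$edges), "edges (",
      sum(x$edges$type == "mst"), "MST +",
      sum(x$edges$type == "relaxed"), "relaxed ), gamma =",
      x$params$gamma, ", k_n =", x$params$k_n, "\n")
  invisible(x)
}

graph_adjacency <- function(graph, weighting = c("binary", "similarity")) {
  weighting <- match.arg(weighting)
  a <- matrix(0, graph$n_nodes, graph$n_nodes)
  w <- if (weighting == "binary") rep(1, nrow(graph$edges))
       else 1 - graph$edges$weight
  a[cbind(graph$edges$i, graph$edges$j)] <- w
  a[cbind(graph$edges$j, graph$edges$i)] <- w
  a
}

#' Graph Laplacian of a state graph
#'
#' `L = Deg - A`, the discrete Laplace-Beltrami operator on the graph. The
#' adjacency is binary by default (an edge contributes 1), or similarity
#' weighted (`1 - distance`) on request.
#'
#' @param graph A `state_graph` from [rmst()], or an adjacency matrix.
#' @param weighting `"binary"` (default) or `"similarity"`.
#' @return T x T symmetric positive semidefinite matrix with zero row sums.
#' @export
graph_laplacian <- function(graph, weighting = c("binary", "similarity")) {
  a <- if (inherits(graph, "state_graph"))
    graph_adjacency(graph, weighting) else as.matrix(graph)
  if (!is_connected_adjacency(a))
    stop("graph is disconnected; the Laplacian eigenmap embedding requires ",
         "a connected graph")
  diag(rowSums(a)) - a
}

is_connected_adjacency <- function(a) {
  n <- nrow(a)
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier) > 0L) {
    nxt <- which(colSums(a[frontier, , drop = FALSE] != 0) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

new_embedding <- function(coords, eigenvalues, method, ambient_dim) {
  colnames(coords) <- paste0("dim_", seq_len(ncol(coords)))
  structure(list(coords = coords, eigenvalues = eigenvalues, method = method,
                 d = ncol(coords), D = ambient_dim),
            class = "manifold_embedding")
}

#' @export
print.manifold_embedding <- function(x, ...) {
  cat("Manifold embedding (", x$method, "): ", nrow(x$coords), " points, d = ",
      x$d, " (ambient D = ", x$D, ")\n", sep = "")
  invisible(x)
}

# Largest-magnitude entry of each column made positive (ties: first index).
fix_eigvec_signs <- function(v) {
  for (k in seq_len(ncol(v))) {
    m <- which.max(abs(v[, k]))
    if (v[m, k] < 0) v[, k] <- -v[, k]
  }
  v
}

#' Laplacian eigenmap embedding
#'
#' Embeds the T graph nodes with the eigenvectors of the graph Laplacian for
#' the `d` smallest non-trivial eigenvalues (the constant zero-eigenvalue
#' vector is dropped). Eigenvector signs follow a deterministic convention:
#' the largest-magnitude entry of each coordinate is positive.
#'
#' @param L Graph Laplacian matrix (from [graph_laplacian()]), or a
#'   `state_graph` (the binary-adjacency Laplacian is formed internally).
#' @param d Embedding dimension, `1 <= d <= T - 1`.
#' @return A `manifold_embedding` with `coords` (T x d) and the retained
#'   `eigenvalues` (ascending).
#' @export
laplacian_eigenmaps <- function(L, d) {
  if (inherits(L, "state_graph")) L <- graph_laplacian(L)
  nt <- nrow(L)
  if (d < 1L || d > nt - 1L) stop("d must be in 1..T-1 (T = ", nt, ")")
  es <- eigen(L, symmetric = TRUE)
  vals <- rev(es$values)
  vecs <- es$vectors[, rev(seq_len(nt)), drop = FALSE]
  if (vals[2L] < 1e-8)
    stop("multiple (near-)zero eigenvalues: the graph is numerically ",
         "disconnected")
  keep <- seq.int(2L, d + 1L)
  new_embedding(fix_eigvec_signs(vecs[, keep, drop = FALSE]),
                vals[keep], "laplacian_eigenmaps", nt)
}

#' PCA embedding (linear baseline)
#'
#' Principal-component scores of a feature matrix with timepoints as
#' observations, the linear counterpart the nonlinear eigenmap embedding is
#' compared against. Columns are mean-centered, not scaled.
#'
#' @param features T x D numeric matrix (rows = timepoints).
#' @param d Number of components, `d <= min(T, D)`.
#' @return A `manifold_embedding` with `coords` = scores on the top-d axes and
#'   `eigenvalues` = their variances (descending), same sign convention as
#'   [laplacian_eigenmaps()] applied to the loading vectors.
#' @export
pca_embedding <- function(features, d) {
  features <- as.matrix(features)
  if (d < 1L || d > min(dim(features)))
    stop("d must be in 1..min(T, D) = ", min(dim(features)))
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(d), function(k) {
    m <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[m, k] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(d), drop = FALSE], 2L, flip, "*")
  new_embedding(scores, pc$sdev[seq_len(d)]^2, "pca", ncol(features))
}

#' Estimate the intrinsic dimension from a decoding-accuracy sweep
#'
#' Given decoding-accuracy samples for a contiguous range of embedding
#' dimensions, returns the smallest dimension `d*` beyond which adding
#' dimensions no longer improves decoding: for every `d > d*`, a two-sided
#' Wilcoxon rank-sum test of accuracy(d) against accuracy(d*) is
#' non-significant after Benjamini-Hochberg FDR correction at `alpha`.
#'
#' @param accuracy_by_dim Named list mapping dimension (coercible to integer)
#'   to a numeric vector of >= 5 accuracy samples.
#' @param alpha Significance level (default 0.05).
#' @return Integer dimension estimate; attribute `"plateau_found"` is FALSE
#'   (with a warning) when no dimension below the maximum qualifies.
#' @export
estimate_intrinsic_dimension <- function(accuracy_by_dim, alpha = 0.05) {
  dims <- as.integer(names(accuracy_by_dim))
  if (any(is.na(dims))) stop("accuracy_by_dim must be named by dimension")
  ord <- order(dims)
  dims <- dims[ord]; accuracy_by_dim <- accuracy_by_dim[ord]
  if (length(dims) == 1L)
    return(structure(dims, plateau_found = TRUE))
  if (any(lengths(accuracy_by_dim) < 5L))
    stop("need >= 5 accuracy samples per dimension")
  for (k in seq_len(length(dims) - 1L)) {
    larger <- seq.int(k + 1L, length(dims))
    p <- vapply(larger, function(m)
      rank_sum_test(accuracy_by_dim[[m]], accuracy_by_dim[[k]]), numeric(1))
    if (all(fdr_correct(p, alpha)$q > alpha))
      return(structure(dims[k], plateau_found = TRUE))
  }
  warning("no accuracy plateau found; returning the largest dimension tested")
  structure(dims[length(dims)], plateau_found = FALSE)
}
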