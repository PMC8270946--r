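# Shared fixtures, built in code at test time.

# Tiny two-stage oscillator run with disjoint coupling blocks: the minimal
# planted-structure scenario most pipeline tests reuse.
two_stage_sim <- function(n_trs = 240, n_regions = 10, seed = 1,
                          dwell = 40, gain = 1, phase_noise = 0.05,
                          obs_noise = 0.1,
                          min_stage_trs = min(40, n_trs %/% 4)) {
  blocks_a <- matrix(0, n_regions, n_regions)
  half <- n_regions / 2
  blocks_a[1:half, 1:half] <- 1
  blocks_b <- matrix(0, n_regions, n_regions)
  blocks_b[(half + 1):n_regions, (half + 1):n_regions] <- 1
  diag(blocks_a) <- 0; diag(blocks_b) <- 0
  tmpl <- list(A = blocks_a, B = blocks_b)
  spec <- simulation_spec(n_regions, tmpl, global_gain = gain,
                          dwell_mean_trs = dwell,
                          phase_noise_sd = phase_noise,
                          obs_noise_sd = obs_noise, seed = seed)
  labels <- generate_hypnogram(n_trs, c("A", "B"), dwell_mean_trs = dwell,
                               seed = seed + 500,
                               min_stage_trs = min_stage_trs)
  list(ts = simulate_bold(spec, labels), labels = labels, spec = spec)
}

# Symmetric random distance matrix with zero diagonal.
random_distance <- function(n, seed) {
  withr::with_seed(seed, {
    d <- matrix(stats::runif(n * n, 0.1, 1), n)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    d
  })
}

# Brute-force RMST oracle: enumerates every non-MST pair, finds the MST path
# by depth-first search, applies the relaxation condition, and enforces the
# per-node cap in ascending-distance order. Independent of the package's
# Kruskal/merge implementation.
rmst_oracle <- function(dist, gamma, k_n, k_local) {
  n <- nrow(dist)
  g <- igraph::graph_from_adjacency_matrix(dist, mode = "undirected",
                                           weighted = TRUE)
  mstg <- igraph::mst(g, algorithm = "prim")
  mst_el <- igraph::as_edgelist(mstg)
  mst_el <- t(apply(mst_el, 1, sort))
  path_max <- function(i, j) {
    p <- igraph::shortest_paths(mstg, i, j)$vpath[[1]]
    max(dist[cbind(p[-length(p)], p[-1])])
  }
  dk <- apply(dist + diag(Inf, n), 1, function(r) sort(r)[k_local])
  cand <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (any(mst_el[, 1] == i & mst_el[, 2] == j)) next
    if (path_max(i, j) + gamma * (dk[i] + dk[j]) > dist[i, j])
      cand <- rbind(cand, c(i, j, dist[i, j]))
  }
  added <- NULL
  if (!is.null(cand)) {
    cand <- cand[order(cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
    cnt <- integer(n)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (cnt[i] < k_n && cnt[j] < k_n) {
        added <- rbind(added, cand[r, ])
        cnt[i] <- cnt[i] + 1; cnt[j] <- cnt[j] + 1
      }
    }
  }
  edges <- rbind(mst_el, added[, 1:2, drop = FALSE])
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

edge_matrix <- function(graph) {
  e <- as.matrix(graph$edges[, c("i", "j")])
  dimnames(e) <- NULL
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}
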