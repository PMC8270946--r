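fake_embedding <- function(coords) {
  coords <- as.matrix(coords)
  colnames(coords) <- paste0("dim_", seq_len(ncol(coords)))
  structure(list(coords = coords, eigenvalues = seq_len(ncol(coords)),
                 method = "laplacian_eigenmaps", d = ncol(coords),
                 D = nrow(coords)),
            class = "manifold_embedding")
}

test_that("landmarks are the per-stage extreme-norm points", {
  coords <- rbind(c(0.1, 0), c(0.5, 0), c(0.9, 0),
                  c(0, 0.2), c(0, 0.6))
  lab <- stage_labels(c("A", "A", "A", "B", "B"))
  lm <- extract_landmarks(fake_embedding(coords), lab)
  expect_equal(dim(lm$X), c(2, 4))
  expect_equal(lm$X[, "A.min"], c(0.1, 0))
  expect_equal(lm$X[, "A.max"], c(0.9, 0))
  expect_equal(lm$X[, "B.min"], c(0, 0.2))
  expect_equal(lm$X[, "B.max"], c(0, 0.6))
  # degenerate: all points of a stage identical
  same <- fake_embedding(rbind(c(1, 1), c(1, 1), c(0, 2), c(0, 3)))
  lm2 <- extract_landmarks(same, stage_labels(c("A", "A", "B", "B")))
  expect_equal(lm2$X[, "A.min"], lm2$X[, "A.max"])
  expect_error(extract_landmarks(fake_embedding(coords),
                                 stage_labels(c("A", "A", "A", "A", "B"))),
               "'B'")
})

test_that("landmarks match a brute-force norm scan on seeded embeddings", {
  withr::with_seed(31, coords <- matrix(stats::rnorm(60 * 3), 60))
  lab <- stage_labels(rep(c("A", "B"), each = 30))
  lm <- extract_landmarks(fake_embedding(coords), lab)
  nrm <- sqrt(rowSums(coords^2))
  for (s in c("A", "B")) {
    idx <- which(as.character(lab) == s)
    expect_equal(lm$X[, paste0(s, ".min")],
                 coords[idx[which.min(nrm[idx])], ], ignore_attr = TRUE)
    expect_equal(lm$X[, paste0(s, ".max")],
                 coords[idx[which.max(nrm[idx])], ], ignore_attr = TRUE)
  }
})

test_that("Procrustes fit recovers identity, translation and known transforms", {
  withr::with_seed(32, x <- matrix(stats::rnorm(3 * 8), 3))
  src <- structure(list(X = x, stages = c("A", "B", "C", "D"),
                        roles = rep(c("min", "max"), 4)),
                   class = "landmark_set")
  idt <- fit_alignment(src, src)
  expect_equal(idt$rotation, diag(3), tolerance = 1e-10)
  expect_equal(idt$scale, 1, tolerance = 1e-10)
  expect_equal(idt$translation, rep(0, 3), tolerance = 1e-10)
  expect_equal(idt$residual, 0, tolerance = 1e-10)
  # translation only
  shifted <- src; shifted$X <- src$X + c(1, -2, 3)
  tr <- fit_alignment(src, shifted)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-8)
  expect_equal(tr$scale, 1, tolerance = 1e-10)
  expect_equal(tr$translation, c(1, -2, 3), tolerance = 1e-10)
  # known rotation + scale: oracle is the generating transform
  theta <- 0.8
  r0 <- rbind(c(cos(theta), -sin(theta), 0),
              c(sin(theta), cos(theta), 0),
              c(0, 0, 1))
  ref <- src; ref$X <- 2 * r0 %*% src$X
  tf <- fit_alignment(src, ref)
  expect_equal(tf$rotation, r0, tolerance = 1e-8)
  expect_equal(tf$scale, 2, tolerance = 1e-10)
  expect_lt(tf$residual, 1e-8)
  # degenerate source rejected
  degen <- src; degen$X <- matrix(1, 3, 8)
  expect_error(fit_alignment(degen, src), "degenerate")
})

test_that("fit agrees with vegan's Procrustes solution", {
  skip_if_not_installed("vegan")
  withr::with_seed(33, {
    x <- matrix(stats::rnorm(10 * 3), 10)
    y <- x %*% qr.Q(qr(matrix(stats::rnorm(9), 3))) * 1.7 +
      matrix(c(1, 2, 3), 10, 3, byrow = TRUE) +
      matrix(stats::rnorm(30, 0, 0.05), 10)
  })
  mk <- function(m) structure(list(X = t(m), stages = letters[1:5],
                                   roles = rep(c("min", "max"), 5)),
                              class = "landmark_set")
  tf <- fit_alignment(mk(x), mk(y))
  vg <- vegan::procrustes(y, x, scale = TRUE, symmetric = FALSE)
  expect_equal(tf$scale, vg$scale, tolerance = 1e-10)
  expect_equal(tf$rotation, t(vg$rotation), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(tf$translation, drop(vg$translation), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(tf$residual, sqrt(vg$ss), tolerance = 1e-10)
})

test_that("applying transforms maps coordinates as specified", {
  emb <- fake_embedding(rbind(c(1, 0), c(0, 1), c(2, 2)))
  idt <- structure(list(rotation = diag(2), scale = 1,
                        translation = c(0, 0), residual = 0),
                   class = "alignment_transform")
  expect_equal(apply_alignment(emb, idt)$coords, emb$coords)
  rot90 <- structure(list(rotation = rbind(c(0, -1), c(1, 0)), scale = 3,
                          translation = c(1, 1), residual = 0),
                     class = "alignment_transform")
  out <- apply_alignment(emb, rot90)
  # hand-computed images of the unit vectors under scale*R*x + t
  expect_equal(out$coords[1, ], c(1, 4), ignore_attr = TRUE)
  expect_equal(out$coords[2, ], c(-2, 1), ignore_attr = TRUE)
  # norms scale by |scale| under zero translation
  rot0 <- rot90; rot0$translation <- c(0, 0)
  out0 <- apply_alignment(emb, rot0)
  expect_equal(sqrt(rowSums(out0$coords^2)), 3 * sqrt(rowSums(emb$coords^2)))
  bad <- structure(list(rotation = diag(3), scale = 1,
                        translation = rep(0, 3), residual = 0),
                   class = "alignment_transform")
  expect_error(apply_alignment(emb, bad), "mismatch")
})

test_that("alignment residual is invariant to common rigid motions", {
  withr::with_seed(34, {
    xs <- matrix(stats::rnorm(3 * 8), 3)
    xr <- xs + matrix(stats::rnorm(24, 0, 0.3), 3)
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  })
  mk <- function(m) structure(list(X = m, stages = letters[1:4],
                                   roles = rep(c("min", "max"), 4)),
                              class = "landmark_set")
  r1 <- fit_alignment(mk(xs), mk(xr))$residual
  r2 <- fit_alignment(mk(q %*% xs + 5), mk(q %*% xr + 5))$residual
  expect_equal(r1, r2, tolerance = 1e-8)
})

test_that("group alignment of rotated/scaled copies recovers the template", {
  # d = 3 with two stages: the 4 centered landmarks span the full space, so
  # the fitted rotation is identified (with more dimensions than landmark
  # rank the orthogonal complement would be arbitrary)
  sim <- two_stage_sim(n_trs = 120, seed = 35)
  emb <- laplacian_eigenmaps(graph_laplacian(rmst(ccd_to_distance(
    ccd(coherence_states(instantaneous_phase(bandpass(sim$ts))))))), 3)
  subjects <- lapply(1:4, function(s) {
    withr::with_seed(40 + s, q <- qr.Q(qr(matrix(stats::rnorm(9), 3))))
    out <- emb
    # rotation + scale only: landmark identity (extreme-norm points) is
    # preserved, so correspondence across subjects is exact
    out$coords <- (1 + 0.3 * s) * emb$coords %*% q
    out
  })
  labels <- replicate(4, sim$labels, simplify = FALSE)
  al <- align_group(subjects, labels, reference = 1)
  expect_true(all(al$residuals < 1e-6))
  al2 <- align_group(subjects, labels, method = "gpa")
  expect_true(all(al2$residuals < 1e-6))
  # all aligned clouds coincide with the first (same template)
  for (s in 2:4)
    expect_equal(al$embeddings[[s]]$coords, al$embeddings[[1]]$coords,
                 tolerance = 1e-6)
})
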