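test_that("align_pair recovers rigid + scaled copies and matches vegan", {
  tpl <- test_template(seed = 1)$coords
  expect_equal(align_pair(tpl, tpl)$distance, 0, tolerance = 1e-12)
  for (s in 1:5) {
    copy <- rigid_copy(tpl, seed = s, scale = runif(1, 0.2, 5))
    expect_lt(align_pair(tpl, copy)$distance, 1e-9)
  }

  # random pair: distance matches vegan's symmetric Procrustes analysis,
  # an independent implementation of the same superimposition
  skip_if_not_installed("vegan")
  set.seed(21)
  for (rep_i in 1:5) {
    A <- matrix(rnorm(18), ncol = 3)
    B <- A %*% euler_rotation(runif(1, 0, 2 * pi), runif(1, 0, pi),
                              runif(1, 0, 2 * pi)) +
      matrix(rnorm(18, sd = 0.2), ncol = 3)
    ours <- align_pair(A, B)$distance
    v <- vegan::procrustes(A, B, scale = FALSE, symmetric = TRUE)
    expect_equal(ours, sqrt(v$ss), tolerance = 1e-6)
  }
})

test_that("align_pair rejects mismatched or degenerate input", {
  tpl <- test_template(seed = 1)$coords
  expect_error(align_pair(tpl, tpl[1:10, ]), "differ in size")
  shuffled <- tpl[c(2:1, 3:12), ]
  expect_error(align_pair(tpl, shuffled), "names/order")
  line <- cbind(1:6, 2 * (1:6), -1 * (1:6))  # collinear
  expect_error(align_pair(line, line + rnorm(18, sd = 1e-14)), "collinear")
})

test_that("reflections are never used even when they would fit better", {
  tpl <- test_template(seed = 4)$coords
  mirrored <- tpl %*% diag(c(-1, 1, 1))
  rownames(mirrored) <- rownames(tpl)
  out <- align_pair(tpl, mirrored)
  expect_equal(det(out$rotation), 1, tolerance = 1e-9)
  expect_gt(out$distance, 0.01)  # a proper rotation cannot undo a mirror
})

test_that("gpa aligns rigid-motion copies onto one another exactly", {
  tpl <- test_template(seed = 2)
  configs <- lapply(1:6, function(s) {
    x <- rigid_copy(tpl$coords, seed = s, scale = runif(1, 0.5, 2))
    rownames(x) <- rownames(tpl$coords)
    landmark_config(paste0("s", s), "WT", x, region = tpl$region)
  })
  g <- gpa(specimen_set(configs))
  for (s in 2:6)
    expect_lt(max(abs(g$aligned[, , s] - g$aligned[, , 1])), 1e-7)
  # aligned specimens: centroid at origin, unit centroid size
  for (s in 1:6) {
    expect_lt(max(abs(colMeans(g$aligned[, , s]))), 1e-9)
    expect_equal(sum(g$aligned[, , s]^2), 1, tolerance = 1e-9)
  }
  expect_equal(g$consensus, apply(g$aligned, c(1, 2), mean), tolerance = 1e-12)
  expect_lte(g$final_change, 1e-8)
})

test_that("gpa consensus of two specimens is equidistant from both", {
  set <- sample_cohort(cohort_spec(test_template(), n_control = 2,
                                   n_affected = 2, noise_sd = 0.3, seed = 9))
  g <- gpa(specimen_set(set$configurations[1:2]))
  d1 <- sqrt(sum((g$aligned[, , 1] - g$consensus)^2))
  d2 <- sqrt(sum((g$aligned[, , 2] - g$consensus)^2))
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("gpa output is invariant to per-specimen rigid motion and scale", {
  set <- sample_cohort(cohort_spec(test_template(), n_control = 5,
                                   n_affected = 5, noise_sd = 0.05, seed = 3))
  g0 <- gpa(set)
  perturbed <- set
  perturbed$configurations <- lapply(seq_along(set$configurations), function(i) {
    cf <- set$configurations[[i]]
    x <- rigid_copy(cf$coords, seed = 100 + i, scale = runif(1, 0.3, 3))
    rownames(x) <- rownames(cf$coords)
    cf$coords <- x
    cf
  })
  g1 <- gpa(perturbed)
  # the solution is unique only up to one global rotation (set by the
  # first specimen's pose); remove that gauge before comparing
  r <- align_pair(g0$consensus, g1$consensus)$rotation
  aligned1 <- g1$aligned
  for (s in seq_len(dim(aligned1)[3]))
    aligned1[, , s] <- aligned1[, , s] %*% r
  expect_equal(aligned1, g0$aligned, tolerance = 1e-6)
  # and the shape distances between specimens are gauge-free
  expect_equal(align_pair(g1$aligned[, , 1], g1$aligned[, , 7])$distance,
               align_pair(g0$aligned[, , 1], g0$aligned[, , 7])$distance,
               tolerance = 1e-8)
})

test_that("gpa reaches a local optimum of summed squared deviation", {
  set <- sample_cohort(cohort_spec(build_template(8, seed = 7), n_control = 5,
                                   n_affected = 5, noise_sd = 0.2, seed = 7))
  g <- gpa(set)
  q0 <- sum((g$aligned - array(g$consensus, dim(g$aligned)))^2)
  # perturbing any specimen's rotation must not lower the criterion
  set.seed(30)
  for (probe in 1:100) {
    s <- sample(dim(g$aligned)[3], 1)
    ang <- rnorm(3, sd = 0.05)
    r <- euler_rotation(ang[1], ang[2], ang[3])
    alt <- g$aligned
    alt[, , s] <- alt[, , s] %*% r
    cons <- apply(alt, c(1, 2), mean)
    q1 <- sum((alt - array(cons, dim(alt)))^2)
    expect_gte(q1, q0 - 1e-10)
  }
})

test_that("shape_pca matches an independent covariance eigendecomposition", {
  set <- sample_cohort(cohort_spec(test_template(), n_control = 10,
                                   n_affected = 10, noise_sd = 0.1, seed = 8))
  g <- gpa(set)
  p <- shape_pca(g)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  # orthonormal loadings
  expect_equal(tcrossprod(p$loadings), diag(p$n_components), tolerance = 1e-9,
               ignore_attr = TRUE)

  # oracle: eigen() of the covariance of flattened aligned coordinates
  X <- t(sapply(seq_len(20), function(s) as.vector(g$aligned[, , s])))
  ev <- eigen(cov(X), symmetric = TRUE)$values[seq_len(p$n_components)]
  expect_equal(p$eigenvalues, ev, tolerance = 1e-8)

  # scores of the consensus (= mean shape) are the zero vector
  cons_score <- (as.vector(g$consensus) - p$center) %*% t(p$loadings)
  expect_lt(max(abs(cons_score)), 1e-9)

  # variation along exactly one direction -> PC1 takes ~all variance
  base <- test_template(seed = 2)
  dirn <- matrix(rnorm(36), ncol = 3)
  configs <- lapply(1:8, function(i) {
    x <- base$coords + (i - 4.5) * 0.01 * dirn
    rownames(x) <- rownames(base$coords)
    landmark_config(paste0("s", i), "WT", x, region = base$region)
  })
  p1 <- shape_pca(gpa(specimen_set(configs)))
  expect_gte(p1$variance_fraction[1], 0.999)
})

test_that("procrustes distance behaves as a metric on random triples", {
  set.seed(11)
  for (rep_i in 1:20) {
    A <- matrix(rnorm(24), ncol = 3)
    B <- matrix(rnorm(24), ncol = 3)
    C <- matrix(rnorm(24), ncol = 3)
    dab <- align_pair(A, B)$distance
    dba <- align_pair(B, A)$distance
    dac <- align_pair(A, C)$distance
    dcb <- align_pair(C, B)$distance
    expect_equal(dab, dba, tolerance = 1e-6)
    expect_lte(dab, dac + dcb + 1e-9)
    expect_gt(dab, 0)
  }
})

test_that("group permutation tests are reproducible and label-symmetric", {
  set <- sample_cohort(cohort_spec(test_template(),
                                   effect_spec(c(midface = 0.8)),
                                   noise_sd = 0.02, seed = 5))
  g <- gpa(set)
  p1 <- group_permutation_test(g, n_perm = 200, seed = 3)
  p2 <- group_permutation_test(g, n_perm = 200, seed = 3)
  expect_identical(p1, p2)
  expect_true(isSymmetric(p1$observed_distance))
  expect_equal(unname(diag(p1$observed_distance)), c(0, 0))
  # strong localized effect: minimum attainable p
  expect_equal(p1$p_values["WT", "Mut"], 1 / 201, tolerance = 1e-12)

  relabeled <- rev(g$groups)
  p3 <- group_permutation_test(g, labels = relabeled, n_perm = 200, seed = 3)
  expect_identical(dim(p3$p_values), c(2L, 2L))

  expect_error(group_permutation_test(g, labels = c(rep("a", 19), "b"),
                                      n_perm = 50, seed = 1), ">= 2 specimens")
})

test_that("integrative distance PCA pools models coherently", {
  tpl <- test_template(seed = 1)
  m1 <- sample_cohort(cohort_spec(tpl, effect_spec(c(midface = 0.85)),
                                  noise_sd = 0.02, seed = 2))
  # duplicated set under two labels: groups overlap completely in score space
  dup <- integrative_distance_pca(list(a = m1, b = m1))
  sc <- dup$scores
  ca <- colMeans(sc[dup$labels$model == "a", , drop = FALSE])
  cb <- colMeans(sc[dup$labels$model == "b", , drop = FALSE])
  expect_lt(sqrt(sum((ca - cb)^2)), 1e-9)
  expect_equal(sum(dup$variance_fraction), 1, tolerance = 1e-9)

  # disjoint implanted effects separate the affected groups
  m2 <- sample_cohort(cohort_spec(tpl, effect_spec(c(base = 1.2)),
                                  noise_sd = 0.02, seed = 3))
  p <- integrative_distance_pca(list(midface_model = m1, base_model = m2))
  aff <- p$labels$group == "Mut"
  d_between <- dist(rbind(
    colMeans(p$scores[aff & p$labels$model == "midface_model", 1:3]),
    colMeans(p$scores[aff & p$labels$model == "base_model", 1:3])))
  within_sd <- mean(apply(p$scores[aff, 1:3], 2, sd))
  expect_gt(as.numeric(d_between), within_sd)

  # mismatched inventories are rejected
  other <- sample_cohort(cohort_spec(build_template(10, seed = 4),
                                     noise_sd = 0.02, seed = 5))
  expect_error(integrative_distance_pca(list(a = m1, b = other)),
               "inventory")
})
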