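# Generalized Procrustes superimposition, shape PCA, Procrustes-distance
# permutation tests, and the integrative distance-feature PCA.

# proper (reflection-free) orthogonal fit of B onto A, both pre-centered;
# returns the rotation matrix (Kabsch, determinant-corrected)
kabsch_rotation <- function(A, B) {
  s <- svd(crossprod(B, A))        # 3x3
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

to_coords <- function(x) {
  if (inherits(x, "landmark_config")) x$coords else as.matrix(x)
}

#' Align one configuration onto another (pairwise Procrustes fit)
#'
#' Both configurations are centered and scaled to unit centroid size; B is
#' then rotated (proper rotation only — anatomical landmarks are chiral,
#' so reflections are disallowed) to minimize the summed squared
#' coordinate distance to A. The reported Procrustes distance is the root
#' of that minimized sum.
#'
#' @param A,B [landmark_config()]s or K x 3 matrices with the same
#'   landmarks in the same order.
#' @return list with `aligned` (B after centering, scaling, rotation),
#'   `rotation`, and `distance`.
#' @examples
#' tpl <- build_template(8, seed = 1)$coords
#' rot <- cbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1))
#' out <- align_pair(tpl, 2.5 * tpl %*% rot + 10)
#' out$distance   # ~0: same shape
#' @export
align_pair <- function(A, B) {
  A <- to_coords(A); B <- to_coords(B)
  if (!identical(dim(A), dim(B))) stopf("configurations differ in size")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stopf("landmark names/order differ between configurations")
  Ac <- center_config(A); Bc <- center_config(B)
  sa <- sqrt(sum(Ac^2)); sb <- sqrt(sum(Bc^2))
  if (sa == 0 || sb == 0) stopf("degenerate configuration: zero centroid size")
  Ac <- Ac / sa; Bc <- Bc / sb
  sv <- svd(crossprod(Bc, Ac))$d
  if (sv[2L] < 1e-12 * sv[1L])
    stopf("degenerate configuration: landmarks are collinear, rotation ambiguous")
  R <- kabsch_rotation(Ac, Bc)
  Brot <- Bc %*% R
  list(aligned = Brot, rotation = R,
       distance = sqrt(sum((Brot - Ac)^2)))
}

#' Generalized Procrustes analysis (GPA)
#'
#' Iteratively superimposes all specimens: each configuration is centered,
#' scaled to unit centroid size, and rotated onto the current consensus;
#' the consensus is the coordinate-wise mean of the aligned specimens,
#' renormalized to unit centroid size. Iteration stops when the root
#' summed squared change of the consensus drops below `tol`. The first
#' specimen (after centering and scaling) seeds the consensus, which makes
#' the procedure deterministic given input order; the fixed point itself
#' is order-independent within `tol`.
#'
#' @param set a [specimen_set()] (>= 2 specimens).
#' @param tol convergence tolerance on consensus change (default 1e-8).
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   change trace.
#' @param scale if `TRUE` (default), specimens are scaled to unit centroid
#'   size (full Procrustes); `FALSE` keeps original sizes (partial).
#' @return a `gpa` object: `aligned` (K x 3 x n array), `centroid_sizes`,
#'   `consensus` (K x 3), `iterations`, `final_change`, `trace`, `groups`,
#'   `specimen_ids`, `landmark_names`.
#' @examples
#' set <- sample_cohort(cohort_spec(build_template(10, seed = 1),
#'                                  noise_sd = 0.05, seed = 4))
#' fit <- gpa(set)
#' fit
#' @export
gpa <- function(set, tol = 1e-8, max_iter = 100L, scale = TRUE) {
  stopifnot(inherits(set, "specimen_set"))
  n <- length(set$configurations)
  if (n < 2L) stopf("GPA needs >= 2 specimens")
  arr <- as_landmark_array(set)
  k <- dim(arr)[1L]
  sizes <- numeric(n)
  for (s in seq_len(n)) {
    x <- center_config(arr[, , s])
    sizes[s] <- sqrt(sum(x^2))
    if (sizes[s] == 0) stopf("specimen %d has zero centroid size", s)
    arr[, , s] <- if (scale) x / sizes[s] else x
  }
  consensus <- arr[, , 1L]
  consensus <- consensus / sqrt(sum(consensus^2))
  trace <- numeric(0)
  change <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (s in seq_len(n))
      arr[, , s] <- arr[, , s] %*% kabsch_rotation(consensus, arr[, , s])
    new_consensus <- apply(arr, c(1L, 2L), mean)
    if (scale) new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    change <- sqrt(sum((new_consensus - consensus)^2))
    trace <- c(trace, change)
    consensus <- new_consensus
    if (change < tol) break
  }
  if (change >= tol) {
    err <- simpleError(sprintf(
      "GPA did not converge in %d iterations (last change %.3g)", max_iter, change))
    err$trace <- trace
    stop(err)
  }
  structure(list(aligned = arr, centroid_sizes = sizes,
                 consensus = apply(arr, c(1L, 2L), mean),
                 iterations = iter, final_change = change, trace = trace,
                 scale = scale,
                 groups = vapply(set$configurations, `[[`, character(1), "group"),
                 specimen_ids = dimnames(arr)[[3L]],
                 landmark_names = set$landmark_names,
                 region_map = set$region_map),
            class = "gpa")
}

#' @export
print.gpa <- function(x, ...) {
  cat(sprintf("Generalized Procrustes analysis: %d specimens, %d landmarks\n",
              dim(x$aligned)[3L], dim(x$aligned)[1L]))
  cat(sprintf("  converged in %d iterations (final consensus change %.2e)\n",
              x$iterations, x$final_change))
  cat(sprintf("  centroid size: mean %.3f mm, range [%.3f, %.3f]\n",
              mean(x$centroid_sizes), min(x$centroid_sizes),
              max(x$centroid_sizes)))
  invisible(x)
}

# n x 3K matrix of flattened aligned coordinates
flatten_gpa <- function(g) {
  n <- dim(g$aligned)[3L]
  t(vapply(seq_len(n), function(s) as.vector(g$aligned[, , s]),
           numeric(prod(dim(g$aligned)[1:2]))))
}

#' Shape PCA of superimposed coordinates
#'
#' Principal component analysis of the aligned specimen coordinates about
#' the consensus (covariance eigendecomposition of the flattened
#' residuals). For reproducibility each loading vector's
#' largest-magnitude element is forced positive.
#'
#' @param x a [gpa()] result, or an n x p feature matrix (rows =
#'   specimens) for [integrative_distance_pca()]-style input.
#' @param labels optional specimen labels carried into the scores.
#' @return a `shape_pca`: `scores` (n x m), `loadings` (m x p),
#'   `variance_fraction` (sums to 1 over the m = min(n-1, p) retained
#'   components), `center`, `labels`.
#' @examples
#' set <- sample_cohort(cohort_spec(build_template(10, seed = 1),
#'                                  noise_sd = 0.05, seed = 4))
#' p <- shape_pca(gpa(set))
#' sum(p$variance_fraction)  # 1
#' @export
shape_pca <- function(x, labels = NULL) {
  if (inherits(x, "gpa")) {
    labels <- labels %||% data.frame(specimen_id = x$specimen_ids,
                                     group = x$groups)
    X <- flatten_gpa(x)
  } else {
    X <- as.matrix(x)
  }
  n <- nrow(X)
  if (n < 2L) stopf("PCA needs >= 2 specimens")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc)
  m <- min(n - 1L, ncol(X))
  eig <- sv$d[seq_len(m)]^2 / (n - 1L)
  loadings <- t(sv$v[, seq_len(m), drop = FALSE])
  # sign convention: largest |loading| element positive
  for (c_ in seq_len(m)) {
    j <- which.max(abs(loadings[c_, ]))
    if (loadings[c_, j] < 0) loadings[c_, ] <- -loadings[c_, ]
  }
  scores <- Xc %*% t(loadings)
  colnames(scores) <- rownames(loadings) <- paste0("PC", seq_len(m))
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = eig / sum(eig),
                 eigenvalues = eig, center = ctr, n_components = m,
                 labels = labels),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("Shape PCA: %d specimens, %d components\n",
              nrow(x$scores), x$n_components))
  vf <- utils::head(x$variance_fraction, 5L)
  cat("  variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_along(vf), 100 * vf), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.shape_pca <- function(x, components = c(1L, 2L), ...) {
  grp <- if (!is.null(x$labels) && "group" %in% names(x$labels))
    factor(x$labels$group) else factor(rep("all", nrow(x$scores)))
  cols <- grDevices::hcl.colors(max(2L, nlevels(grp)), "Dark 2")[seq_len(nlevels(grp))]
  i <- components[1L]; j <- components[2L]
  graphics::plot(x$scores[, i], x$scores[, j], col = cols[grp], pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", i, 100 * x$variance_fraction[i]),
                 ylab = sprintf("PC%d (%.1f%%)", j, 100 * x$variance_fraction[j]),
                 main = "Shape PCA", ...)
  graphics::legend("topright", legend = levels(grp), col = cols, pch = 19,
                   bty = "n")
  invisible(x)
}

# Procrustes distance between two mean shapes (center, unit size, rotate)
consensus_distance <- function(A, B) align_pair(A, B)$distance

#' Pairwise Procrustes-distance permutation tests between groups
#'
#' For every pair of groups, the observed statistic is the Procrustes
#' distance between the two group consensus shapes (means of the aligned
#' specimens, re-superimposed pairwise). The null distribution permutes
#' group labels within the pair; `p = (b + 1) / (n_perm + 1)` with `b` the
#' number of permuted distances at least the observed one.
#'
#' @param g a [gpa()] result (its `groups` field supplies labels).
#' @param labels optional replacement group labels.
#' @param n_perm permutations per pair (study default 1000).
#' @param seed integer seed; bit-reproducible.
#' @return a `perm_test_matrix`: symmetric `observed_distance` and
#'   `p_values` matrices, `n_perm`, `seed`.
#' @examples
#' set <- sample_cohort(cohort_spec(build_template(10, seed = 1),
#'                                  effect_spec(c(midface = 0.8)),
#'                                  noise_sd = 0.02, seed = 3))
#' group_permutation_test(gpa(set), n_perm = 200, seed = 1)
#' @export
group_permutation_test <- function(g, labels = NULL, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(g, "gpa"))
  labels <- labels %||% g$groups
  lv <- unique(labels)
  if (length(lv) < 2L) stopf("need >= 2 groups")
  counts <- table(labels)
  if (any(counts < 2L))
    stopf("every group needs >= 2 specimens (offending: %s)",
          paste(names(counts)[counts < 2L], collapse = ", "))
  n_groups <- length(lv)
  obs <- p <- matrix(0, n_groups, n_groups, dimnames = list(lv, lv))
  diag(p) <- NA_real_
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (a in seq_len(n_groups - 1L)) for (b in (a + 1L):n_groups) {
    ia <- which(labels == lv[a]); ib <- which(labels == lv[b])
    pool <- c(ia, ib)
    na <- length(ia)
    mean_shape <- function(idx) apply(g$aligned[, , idx, drop = FALSE],
                                      c(1L, 2L), mean)
    d_obs <- consensus_distance(mean_shape(ia), mean_shape(ib))
    set.seed(derive_seed(seed, a * 1000L + b))
    d_null <- vapply(seq_len(n_perm), function(r) {
      sh <- sample(pool)
      consensus_distance(mean_shape(sh[seq_len(na)]), mean_shape(sh[-seq_len(na)]))
    }, numeric(1))
    obs[a, b] <- obs[b, a] <- d_obs
    p[a, b] <- p[b, a] <- (sum(d_null >= d_obs) + 1) / (n_perm + 1)
  }
  structure(list(groups = lv, observed_distance = obs, p_values = p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "perm_test_matrix")
}

#' @export
print.perm_test_matrix <- function(x, ...) {
  cat(sprintf("Procrustes-distance permutation tests (%d permutations)\n",
              x$n_perm))
  cat("observed consensus distances:\n")
  print(round(x$observed_distance, 4))
  cat("p-values:\n")
  print(round(x$p_values, 4))
  invisible(x)
}

#' Integrative PCA of shape-scaled inter-landmark distances
#'
#' Combines specimens from several studies/models into one ordination:
#' each specimen is represented by its shape-scaled pairwise distance
#' vector (coordinate-system-free, so no joint superimposition is needed),
#' and a single PCA is run across all specimens with scores labeled by
#' model and group.
#'
#' @param sets named list of [specimen_set()]s sharing one landmark
#'   inventory; names are the model labels.
#' @return a `shape_pca` whose `labels` carry `model`, `group`,
#'   `specimen_id`.
#' @examples
#' tpl <- build_template(10, seed = 1)
#' m1 <- sample_cohort(cohort_spec(tpl, effect_spec(c(midface = 0.85)),
#'                                 noise_sd = 0.02, seed = 2))
#' m2 <- sample_cohort(cohort_spec(tpl, effect_spec(c(base = 1.15)),
#'                                 noise_sd = 0.02, seed = 3))
#' integrative_distance_pca(list(modelA = m1, modelB = m2))
#' @export
integrative_distance_pca <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("sets must be a named list (model labels)")
  ref_names <- sets[[1L]]$landmark_names
  for (nm in names(sets))
    if (!identical(sets[[nm]]$landmark_names, ref_names))
      stopf("landmark inventory of set '%s' differs from '%s'",
            nm, names(sets)[1L])
  feats <- list(); labs <- list()
  for (nm in names(sets)) {
    sms <- group_form_matrices(sets[[nm]], mode = "shape")
    feats[[nm]] <- t(vapply(sms, `[[`, sms[[1L]]$distances, "distances"))
    labs[[nm]] <- data.frame(
      model = nm,
      group = vapply(sets[[nm]]$configurations, `[[`, character(1), "group"),
      specimen_id = vapply(sets[[nm]]$configurations, `[[`, character(1),
                           "specimen_id"))
  }
  shape_pca(do.call(rbind, feats), labels = do.call(rbind, labs))
}
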