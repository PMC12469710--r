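# Euclidean Distance Matrix Analysis (EDMA).
#
# A specimen's form is summarized by the vector of all K(K-1)/2 linear
# distances between its landmarks; shape is form divided by a size measure
# (geometric mean of all distances, or optionally centroid size). Group
# differences are per-pair ratios of mean matrices (FDM in form mode, SDM
# in shape mode); each ratio is a relative Euclidean distance (RED).
# Significance comes from a pooled bootstrap on the omnibus statistic
# T = max(RED)/min(RED); localization comes from the RED band and from
# per-pair bootstrap confidence intervals.

#' Pairwise inter-landmark distance vector (form matrix) of one specimen
#'
#' @param config a [landmark_config()] (or a bare K x 3 coordinate matrix
#'   with rownames).
#' @return a `form_matrix`: fields `landmark_names`, `distances` (named
#'   vector of K(K-1)/2 positive lengths in canonical pair order —
#'   lexicographic by landmark index), `scaled = FALSE`.
#' @details Pairs are ordered (1,2), (1,3), ..., (2,3), ... as by
#'   [stats::dist()]. Coincident landmarks (zero distance) are an error
#'   naming the pair.
#' @examples
#' xyz <- rbind(A = c(0, 0, 0), B = c(3, 0, 0), C = c(0, 4, 0), D = c(0, 0, 1))
#' form_matrix(xyz)$distances[c("A-B", "A-C", "B-C")]  # 3, 4, 5
#' @export
form_matrix <- function(config) {
  coords <- if (inherits(config, "landmark_config")) config$coords else as.matrix(config)
  if (nrow(coords) < 2L) stopf("need at least 2 landmarks")
  if (!all(is.finite(coords))) stopf("non-finite coordinates")
  nm <- rownames(coords) %||% paste0("L", seq_len(nrow(coords)))
  d <- as.vector(stats::dist(coords))
  if (any(d <= 0)) {
    idx <- pair_index(nrow(coords))[which(d <= 0)[1L], ]
    stopf("coincident landmarks: %s and %s", nm[idx[1L]], nm[idx[2L]])
  }
  names(d) <- pair_labels(nm)
  structure(list(landmark_names = nm, distances = d, scaled = FALSE),
            class = "form_matrix")
}

#' @export
print.form_matrix <- function(x, ...) {
  cat(sprintf("%s matrix: %d landmarks, %d pairwise distances%s\n",
              if (x$scaled) "Shape" else "Form", length(x$landmark_names),
              length(x$distances),
              if (x$scaled) " (unit geometric mean)" else ""))
  print(utils::head(x$distances, 6L))
  if (length(x$distances) > 6L) cat("...\n")
  invisible(x)
}

#' Scale a form matrix to a shape matrix
#'
#' Divides every distance by the configuration's size so that only shape
#' remains. The default size measure is the geometric mean of all pairwise
#' distances (the resulting shape matrix has unit geometric mean);
#' `"centroid"` uses centroid size, which requires the generating
#' coordinates and is therefore only available through
#' [group_form_matrices()].
#'
#' @param fm an unscaled `form_matrix`.
#' @param size optional explicit size divisor (positive scalar); default
#'   the geometric mean of `fm$distances`.
#' @return a `form_matrix` with `scaled = TRUE`.
#' @examples
#' fm <- form_matrix(rbind(A = c(0,0,0), B = c(3,0,0), C = c(0,4,0), D = c(0,0,1)))
#' sm <- scale_to_shape(fm)
#' exp(mean(log(sm$distances)))  # 1
#' @export
scale_to_shape <- function(fm, size = NULL) {
  stopifnot(inherits(fm, "form_matrix"))
  if (fm$scaled) stopf("form matrix is already scaled")
  size <- size %||% exp(mean(log(fm$distances)))
  if (!is.numeric(size) || size <= 0) stopf("size must be a positive scalar")
  out <- fm
  out$distances <- fm$distances / size
  out$scaled <- TRUE
  out
}

#' Per-specimen form (or shape) matrices of a group
#'
#' @param set a [specimen_set()] or list of [landmark_config()]s.
#' @param mode `"form"` or `"shape"`.
#' @param size_measure for shape mode, `"geometric_mean"` (classic EDMA
#'   scaling, default) or `"centroid"` (centroid size).
#' @return list of `form_matrix` objects.
#' @export
group_form_matrices <- function(set, mode = c("form", "shape"),
                                size_measure = c("geometric_mean", "centroid")) {
  mode <- match.arg(mode)
  size_measure <- match.arg(size_measure)
  configs <- if (inherits(set, "specimen_set")) set$configurations else set
  lapply(configs, function(cf) {
    fm <- form_matrix(cf)
    if (mode == "shape") {
      size <- if (size_measure == "centroid")
        centroid_size(if (inherits(cf, "landmark_config")) cf$coords else cf)
      else NULL
      fm <- scale_to_shape(fm, size = size)
    }
    fm
  })
}

#' Mean form or shape matrix of a group
#'
#' Arithmetic per-pair mean of the specimens' distance vectors (shape
#' matrices are scaled per specimen before averaging).
#'
#' @param group list of `form_matrix` objects with identical landmarks and
#'   a `scaled` flag consistent with `mode` (>= 2 specimens).
#' @param mode `"form"` or `"shape"`.
#' @return a single `form_matrix` of per-pair means.
#' @export
mean_matrix <- function(group, mode = c("form", "shape")) {
  mode <- match.arg(mode)
  if (length(group) < 2L) stopf("need >= 2 specimens to average")
  check_matrix_group(group, mode)
  d <- rowMeans(vapply(group, `[[`, group[[1L]]$distances, "distances"))
  structure(list(landmark_names = group[[1L]]$landmark_names,
                 distances = d, scaled = mode == "shape"),
            class = "form_matrix")
}

check_matrix_group <- function(group, mode) {
  nm <- group[[1L]]$landmark_names
  want_scaled <- mode == "shape"
  for (fm in group) {
    if (!inherits(fm, "form_matrix")) stopf("group elements must be form_matrix")
    if (!identical(fm$landmark_names, nm)) stopf("landmark-name mismatch within group")
    if (fm$scaled != want_scaled)
      stopf("mixed or wrong scaled flags: %s mode needs scaled = %s",
            mode, want_scaled)
  }
  invisible(TRUE)
}

#' Form or shape difference matrix (FDM / SDM) between two groups
#'
#' Per-pair relative Euclidean distances `RED = mean_test / mean_reference`;
#' a ratio above 1 means the distance is larger in the test (mutant) group.
#'
#' @param reference,test lists of per-specimen `form_matrix` objects (see
#'   [group_form_matrices()]), or [specimen_set()]s, for the reference
#'   (wild-type) and test groups.
#' @param mode `"form"` (FDM) or `"shape"` (SDM).
#' @return a `difference_matrix`: `landmark_names`, `red` (named vector),
#'   `mode`, and `ci_lo`/`ci_hi`/`ci_level` once filled by [edma_test()].
#' @examples
#' tpl <- build_template(8, seed = 1)
#' wt  <- sample_cohort(cohort_spec(tpl, n_control = 5, n_affected = 5,
#'                                  noise_sd = 0.01, seed = 3))
#' fdm <- difference_matrix(subset_group(wt, "WT"), subset_group(wt, "Mut"))
#' summary(fdm$red)   # near 1: both groups share the null template
#' @export
difference_matrix <- function(reference, test, mode = c("form", "shape")) {
  mode <- match.arg(mode)
  reference <- as_matrix_group(reference, mode)
  test <- as_matrix_group(test, mode)
  m_ref <- mean_matrix(reference, mode)
  m_test <- mean_matrix(test, mode)
  if (!identical(m_ref$landmark_names, m_test$landmark_names))
    stopf("landmark-name mismatch between groups")
  structure(list(landmark_names = m_ref$landmark_names,
                 red = m_test$distances / m_ref$distances,
                 mode = mode,
                 ci_lo = NULL, ci_hi = NULL, ci_level = NULL),
            class = "difference_matrix")
}

as_matrix_group <- function(x, mode) {
  if (inherits(x, "specimen_set")) group_form_matrices(x, mode) else x
}

#' @export
print.difference_matrix <- function(x, ...) {
  cat(sprintf("%s difference matrix (%s): %d landmark pairs\n",
              if (x$mode == "form") "Form" else "Shape",
              if (x$mode == "form") "FDM" else "SDM", length(x$red)))
  cat(sprintf("  RED range [%.4f, %.4f]; out of band (<0.95 or >1.05): %d\n",
              min(x$red), max(x$red), sum(x$red < 0.95 | x$red > 1.05)))
  if (!is.null(x$ci_lo))
    cat(sprintf("  per-pair bootstrap CIs at %.1f%% attached\n", 100 * x$ci_level))
  invisible(x)
}

#' Tidy data frame of a difference matrix
#' @param x a `difference_matrix`
#' @param band_lo,band_hi RED band used to flag pairs
#' @param ... unused
#' @return data frame: pair, landmark_i, landmark_j, red, ci_lo, ci_hi,
#'   out_of_band
#' @export
as.data.frame.difference_matrix <- function(x, ...,
                                            band_lo = 0.95, band_hi = 1.05) {
  idx <- pair_index(length(x$landmark_names))
  data.frame(pair = names(x$red),
             landmark_i = x$landmark_names[idx[, 1L]],
             landmark_j = x$landmark_names[idx[, 2L]],
             red = unname(x$red),
             ci_lo = if (is.null(x$ci_lo)) NA_real_ else unname(x$ci_lo),
             ci_hi = if (is.null(x$ci_hi)) NA_real_ else unname(x$ci_hi),
             out_of_band = unname(x$red < band_lo | x$red > band_hi),
             row.names = NULL)
}

#' EDMA bootstrap omnibus test on a form or shape difference matrix
#'
#' Tests whether two groups differ in form (FDM) or shape (SDM) using the
#' omnibus statistic `T = max(RED) / min(RED)` and a pooled resampling
#' null: the two groups are pooled (breaking group labels) and pseudo-
#' groups of the original sizes are redrawn, recomputing T each time. The
#' default redraw is a label permutation (sampling without replacement),
#' which is exact under exchangeability and gives uniformly distributed
#' p-values under the null; `null = "bootstrap"` instead resamples both
#' pseudo-groups with replacement (the classic pooled two-sample
#' bootstrap, whose null T distribution is slightly narrower than the
#' sampling one at these group sizes). The p-value uses the finite-sample
#' correction `(b + 1) / (n_boot + 1)` where `b` counts null replicates
#' with T at least the observed value.
#' Per-pair RED confidence intervals come from a separate within-group
#' bootstrap (both groups resampled with replacement independently) using
#' percentile intervals at `ci_level`.
#'
#' Note that T compares the largest to the smallest RED, so a perfectly
#' uniform size change (all REDs equal) is invisible to the omnibus form
#' test; the per-pair CIs and the RED band carry that signal instead.
#'
#' @param reference,test [specimen_set()]s or lists of per-specimen
#'   `form_matrix` objects; `reference` is the wild-type group.
#' @param mode `"form"` or `"shape"`.
#' @param n_boot resampling replicates (study default 10000).
#' @param null null construction: `"permutation"` (default) or
#'   `"bootstrap"`, see Details.
#' @param ci_level per-pair confidence level (study default 0.978, whose
#'   complement splits into 1.1% tails).
#' @param ci_boot replicates for the CI bootstrap; 0 skips CI computation.
#' @param seed integer seed; results are bit-reproducible given the seed.
#' @param size_measure shape-mode size divisor, see [group_form_matrices()].
#' @return an `edma_test`: `observed_T`, `null_T` (length `n_boot`),
#'   `p_value`, `n_boot`, `mode`, `seed`, and `diff` (the
#'   [difference_matrix()] with CIs filled when `ci_boot > 0`).
#' @examples
#' tpl <- build_template(10, seed = 1)
#' set <- sample_cohort(cohort_spec(tpl, effect_spec(c(midface = 0.85)),
#'                                  n_control = 8, n_affected = 8,
#'                                  noise_sd = 0.02, seed = 5))
#' fit <- edma_test(subset_group(set, "WT"), subset_group(set, "Mut"),
#'                  mode = "form", n_boot = 500, ci_boot = 200, seed = 9)
#' fit
#' @export
edma_test <- function(reference, test, mode = c("form", "shape"),
                      n_boot = 10000L, ci_level = 0.978, ci_boot = n_boot,
                      seed = 1L, null = c("permutation", "bootstrap"),
                      size_measure = c("geometric_mean", "centroid")) {
  mode <- match.arg(mode)
  null <- match.arg(null)
  size_measure <- match.arg(size_measure)
  ref_g <- if (inherits(reference, "specimen_set"))
    group_form_matrices(reference, mode, size_measure) else reference
  test_g <- if (inherits(test, "specimen_set"))
    group_form_matrices(test, mode, size_measure) else test
  n1 <- length(ref_g); n2 <- length(test_g)
  if (n1 < 2L || n2 < 2L) stopf("need >= 2 specimens per group")
  if (n_boot < 100L)
    warnf("n_boot = %d is very small; p-values will be coarse", n_boot)
  check_matrix_group(ref_g, mode); check_matrix_group(test_g, mode)

  # rows = specimens, cols = pairs
  D_ref <- t(vapply(ref_g, `[[`, ref_g[[1L]]$distances, "distances"))
  D_test <- t(vapply(test_g, `[[`, test_g[[1L]]$distances, "distances"))
  obs_red <- colMeans(D_test) / colMeans(D_ref)
  observed_T <- max(obs_red) / min(obs_red)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 1L))
  pool <- rbind(D_ref, D_test)
  n <- n1 + n2
  null_T <- if (null == "permutation") {
    vapply(seq_len(n_boot), function(b) {
      sh <- sample.int(n)
      r <- colMeans(pool[sh[-seq_len(n1)], , drop = FALSE]) /
        colMeans(pool[sh[seq_len(n1)], , drop = FALSE])
      max(r) / min(r)
    }, numeric(1))
  } else {
    vapply(seq_len(n_boot), function(b) {
      i1 <- sample.int(n, n1, replace = TRUE)
      i2 <- sample.int(n, n2, replace = TRUE)
      r <- colMeans(pool[i2, , drop = FALSE]) / colMeans(pool[i1, , drop = FALSE])
      max(r) / min(r)
    }, numeric(1))
  }
  p_value <- (sum(null_T >= observed_T) + 1) / (n_boot + 1)

  diff <- structure(list(landmark_names = ref_g[[1L]]$landmark_names,
                         red = obs_red, mode = mode,
                         ci_lo = NULL, ci_hi = NULL, ci_level = NULL),
                    class = "difference_matrix")
  if (ci_boot > 0L) {
    set.seed(derive_seed(seed, 2L))
    reps <- matrix(NA_real_, nrow = ci_boot, ncol = ncol(pool))
    for (b in seq_len(ci_boot)) {
      i1 <- sample.int(n1, n1, replace = TRUE)
      i2 <- sample.int(n2, n2, replace = TRUE)
      reps[b, ] <- colMeans(D_test[i2, , drop = FALSE]) /
        colMeans(D_ref[i1, , drop = FALSE])
    }
    alpha <- 1 - ci_level
    qs <- apply(reps, 2L, stats::quantile,
                probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
    diff$ci_lo <- setNames(qs[1L, ], names(obs_red))
    diff$ci_hi <- setNames(qs[2L, ], names(obs_red))
    diff$ci_level <- ci_level
  }
  structure(list(observed_T = observed_T, null_T = null_T, p_value = p_value,
                 n_boot = as.integer(n_boot), mode = mode, null = null,
                 seed = as.integer(seed), diff = diff,
                 n_reference = n1, n_test = n2),
            class = "edma_test")
}

#' @export
print.edma_test <- function(x, ...) {
  cat(sprintf("EDMA %s omnibus test (%s difference matrix)\n",
              x$mode, if (x$mode == "form") "FDM" else "SDM"))
  cat(sprintf("  groups: n = %d (reference) vs n = %d (test)\n",
              x$n_reference, x$n_test))
  cat(sprintf("  observed T = max(RED)/min(RED) = %.4f\n", x$observed_T))
  cat(sprintf("  null: %d pooled %s resamples, p = %.4g\n",
              x$n_boot,
              if (identical(x$null, "bootstrap")) "bootstrap" else "permutation",
              x$p_value))
  invisible(x)
}

#' @export
summary.edma_test <- function(object, band_lo = 0.95, band_hi = 1.05, ...) {
  red <- object$diff$red
  out <- list(test = object,
              n_pairs = length(red),
              n_out_of_band = sum(red < band_lo | red > band_hi),
              band = c(band_lo, band_hi),
              red_quantiles = stats::quantile(red, c(0, .25, .5, .75, 1)))
  class(out) <- "summary.edma_test"
  out
}

#' @export
print.summary.edma_test <- function(x, ...) {
  print(x$test)
  cat(sprintf("  RED quantiles: %s\n",
              paste(sprintf("%.3f", x$red_quantiles), collapse = " ")))
  cat(sprintf("  %d / %d pairs outside RED band [%.2f, %.2f]\n",
              x$n_out_of_band, x$n_pairs, x$band[1L], x$band[2L]))
  invisible(x)
}

#' @export
plot.edma_test <- function(x, ...) {
  graphics::hist(x$null_T, breaks = 40, col = "grey80", border = "white",
                 main = sprintf("EDMA %s bootstrap null (n = %d)",
                                x$mode, x$n_boot),
                 xlab = "T = max(RED) / min(RED)", ...)
  graphics::abline(v = x$observed_T, col = "firebrick", lwd = 2)
  graphics::legend("topright", bty = "n",
                   legend = sprintf("observed T (p = %.3g)", x$p_value),
                   col = "firebrick", lwd = 2)
  invisible(x)
}

#' Influence-landmark analysis of a difference matrix
#'
#' Identifies which landmarks drive a group difference: for each landmark
#' it counts the incident pairs whose RED falls above `band_hi` or below
#' `band_lo` (the conventional band [0.95, 1.05]) and assigns a dominant
#' direction. When the difference matrix carries per-pair bootstrap CIs,
#' an analogous count of pairs whose CI excludes 1 is reported alongside.
#'
#' Direction rule: `increase` when out-of-band pairs above the band
#' dominate those below at least 2:1 (or there are none below); `decrease`
#' symmetrically; `none` when no incident pair is out of band; `mixed`
#' otherwise.
#'
#' @param diff a [difference_matrix()].
#' @param band_lo,band_hi RED flagging band (defaults 0.95 and 1.05).
#' @return an `influence_result` whose `table` ranks landmarks by
#'   `fraction_outside = (n_above + n_below) / (K - 1)`; the `rank` column
#'   uses competition ranking (ties share the lowest rank).
#' @examples
#' tpl <- build_template(12, seed = 1)
#' set <- sample_cohort(cohort_spec(tpl, effect_spec(c(midface = 0.85)),
#'                                  noise_sd = 0.02, seed = 2))
#' sdm <- difference_matrix(subset_group(set, "WT"), subset_group(set, "Mut"),
#'                          mode = "shape")
#' influence_analysis(sdm)
#' @export
influence_analysis <- function(diff, band_lo = 0.95, band_hi = 1.05) {
  stopifnot(inherits(diff, "difference_matrix"))
  if (band_lo >= band_hi) stopf("band_lo must be < band_hi")
  k <- length(diff$landmark_names)
  idx <- pair_index(k)
  above <- diff$red > band_hi
  below <- diff$red < band_lo
  n_above <- tabulate(c(idx[above, ]), nbins = k)
  n_below <- tabulate(c(idx[below, ]), nbins = k)
  direction <- mapply(function(a, b) {
    if (a + b == 0L) "none"
    else if (b == 0L || a >= 2L * b) "increase"
    else if (a == 0L || b >= 2L * a) "decrease"
    else "mixed"
  }, n_above, n_below)
  tab <- data.frame(landmark = diff$landmark_names,
                    region = NA_character_,
                    n_above = n_above, n_below = n_below,
                    fraction_outside = (n_above + n_below) / (k - 1L),
                    dominant_direction = direction,
                    row.names = NULL)
  if (!is.null(diff$ci_lo)) {
    ci_out <- diff$ci_lo > 1 | diff$ci_hi < 1
    tab$n_ci_outside <- tabulate(c(idx[ci_out, ]), nbins = k)
  }
  tab <- tab[order(-tab$fraction_outside, tab$landmark), ]
  # competition ranking: tied fractions share the lowest rank
  tab$rank <- rank(-tab$fraction_outside, ties.method = "min")
  structure(list(table = tab, band_lo = band_lo, band_hi = band_hi,
                 mode = diff$mode,
                 n_out_of_band_pairs = sum(above | below)),
            class = "influence_result")
}

#' @export
print.influence_result <- function(x, n = 10L, ...) {
  cat(sprintf("Influence landmarks (%s mode), RED band [%.2f, %.2f]: %d pairs out of band\n",
              x$mode, x$band_lo, x$band_hi, x$n_out_of_band_pairs))
  print(utils::head(x$table, n), row.names = FALSE)
  invisible(x)
}

#' @export
plot.influence_result <- function(x, ...) {
  tab <- x$table[order(x$table$fraction_outside), ]
  graphics::dotchart(tab$fraction_outside, labels = tab$landmark,
                     xlab = "fraction of incident pairs out of RED band",
                     main = sprintf("Influence landmarks (%s)", x$mode),
                     pch = 19, ...)
  invisible(x)
}
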