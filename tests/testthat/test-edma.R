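test_that("pairwise distances match known values and a brute-force oracle", {
  fm <- form_matrix(triangle_coords())
  expect_equal(unname(fm$distances[c("A-B", "A-C", "B-C")]), c(3, 4, 5))
  expect_named(fm$distances, c("A-B", "A-C", "A-D", "B-C", "B-D", "C-D"))

  set.seed(7)
  for (rep in 1:5) {
    coords <- matrix(rnorm(21), ncol = 3)
    rownames(coords) <- paste0("L", 1:7)
    expect_equal(unname(form_matrix(coords)$distances),
                 brute_force_distances(coords), tolerance = 1e-12)
  }

  # isometry invariance under random rigid motions and reflection
  base <- form_matrix(triangle_coords())$distances
  for (s in 1:5) {
    moved <- rigid_copy(triangle_coords(), seed = s)
    expect_equal(form_matrix(moved)$distances, base, tolerance = 1e-9)
  }
  reflected <- triangle_coords() %*% diag(c(-1, 1, 1))
  rownames(reflected) <- rownames(triangle_coords())
  expect_equal(form_matrix(reflected)$distances, base, tolerance = 1e-12)

  # coincident landmarks are an error naming the pair
  bad <- triangle_coords(); bad["B", ] <- bad["A", ]
  expect_error(form_matrix(bad), "A and B")
})

test_that("scale_to_shape divides by the geometric mean and is idempotent in effect", {
  xyz <- rbind(A = c(0, 0, 0), B = c(3, 0, 0), C = c(0, 4, 0))
  fm <- structure(list(landmark_names = rownames(xyz),
                       distances = c("A-B" = 3, "A-C" = 4, "B-C" = 5),
                       scaled = FALSE), class = "form_matrix")
  sm <- scale_to_shape(fm)
  gm <- 60^(1 / 3)  # (3*4*5)^(1/3)
  expect_equal(unname(sm$distances), c(3, 4, 5) / gm, tolerance = 1e-12)
  expect_equal(exp(mean(log(sm$distances))), 1, tolerance = 1e-12)
  expect_error(scale_to_shape(sm), "already scaled")

  # uniform rescaling of the input leaves the shape matrix unchanged
  fm2 <- fm; fm2$distances <- fm$distances * 17.3
  expect_equal(scale_to_shape(fm2)$distances, sm$distances, tolerance = 1e-12)
})

test_that("mean_matrix averages per pair and enforces consistency", {
  fms <- group_form_matrices(sample_cohort(cohort_spec(
    test_template(), n_control = 10, n_affected = 2, noise_sd = 0.1,
    seed = 3)), mode = "form")[1:10]
  m <- mean_matrix(fms, "form")
  oracle <- rowMeans(sapply(fms, `[[`, "distances"))
  expect_equal(m$distances, oracle, tolerance = 1e-12)

  expect_identical(mean_matrix(list(fms[[1]], fms[[1]]), "form")$distances,
                   fms[[1]]$distances)
  expect_error(mean_matrix(fms[1], "form"), ">= 2")
  expect_error(mean_matrix(fms, "shape"), "scaled")
})

test_that("difference matrices separate size from shape and are reciprocal", {
  set <- sample_cohort(cohort_spec(test_template(), n_control = 5,
                                   n_affected = 5, noise_sd = 0.05, seed = 6))
  wt <- subset_group(set, "WT")

  # identical groups: all RED exactly 1
  d_same <- difference_matrix(wt, wt, "form")
  expect_equal(unname(d_same$red), rep(1, length(d_same$red)),
               tolerance = 1e-12)

  # uniform x2 scaling: form RED = 2 everywhere, shape RED = 1 everywhere
  doubled <- wt
  doubled$configurations <- lapply(wt$configurations, function(cf) {
    cf$coords <- cf$coords * 2; cf
  })
  expect_equal(unname(difference_matrix(wt, doubled, "form")$red),
               rep(2, 66), tolerance = 1e-12)
  expect_equal(unname(difference_matrix(wt, doubled, "shape")$red),
               rep(1, 66), tolerance = 1e-12)

  # reciprocity: RED(A,B) is the elementwise inverse of RED(B,A)
  mut <- subset_group(set, "Mut")
  ab <- difference_matrix(wt, mut, "form")$red
  ba <- difference_matrix(mut, wt, "form")$red
  expect_equal(ab, 1 / ba, tolerance = 1e-12)

  # shape mode invariant to arbitrary per-specimen rescaling of either group
  rescaled <- mut
  set.seed(4)
  rescaled$configurations <- lapply(mut$configurations, function(cf) {
    cf$coords <- cf$coords * runif(1, 0.5, 2); cf
  })
  expect_equal(difference_matrix(wt, rescaled, "shape")$red,
               difference_matrix(wt, mut, "shape")$red, tolerance = 1e-9)
})

test_that("an implanted within-region contraction appears exactly in the FDM", {
  tpl <- test_template(seed = 5)
  spec <- cohort_spec(tpl, effect_spec(c(midface = 0.9)), n_control = 4,
                      n_affected = 4, noise_sd = 0, seed = 2)
  set <- sample_cohort(spec)
  fdm <- difference_matrix(subset_group(set, "WT"), subset_group(set, "Mut"),
                           "form")
  mid <- which(tpl$region == "midface")
  labels <- outer(rownames(tpl$coords), rownames(tpl$coords), paste, sep = "-")
  within <- labels[mid, mid][upper.tri(diag(length(mid)))]
  within_pairs <- intersect(names(fdm$red), c(within, sapply(
    strsplit(within, "-"), function(p) paste(p[2], p[1], sep = "-"))))
  expect_equal(unname(fdm$red[within_pairs]),
               rep(0.9, length(within_pairs)), tolerance = 1e-12)
  expect_gt(length(within_pairs), 0)
})

test_that("edma_test is seed-reproducible with valid CIs and sane statistics", {
  set <- sample_cohort(cohort_spec(test_template(),
                                   effect_spec(c(midface = 0.8)),
                                   noise_sd = 0.02, seed = 4))
  wt <- subset_group(set, "WT"); mut <- subset_group(set, "Mut")
  t1 <- edma_test(wt, mut, "shape", n_boot = 300, ci_boot = 300, seed = 11)
  t2 <- edma_test(wt, mut, "shape", n_boot = 300, ci_boot = 300, seed = 11)
  expect_identical(t1, t2)
  t3 <- edma_test(wt, mut, "shape", n_boot = 300, ci_boot = 300, seed = 12)
  expect_false(identical(t1$null_T, t3$null_T))

  expect_gte(t1$observed_T, 1)
  expect_length(t1$null_T, 300L)
  expect_true(all(t1$null_T >= 1))
  expect_gte(t1$p_value, 1 / 301)
  expect_lte(t1$p_value, 1)
  expect_true(all(t1$diff$ci_lo <= t1$diff$red + 1e-12))
  expect_true(all(t1$diff$ci_hi >= t1$diff$red - 1e-12))
  # strong localized effect at low noise: minimum attainable p
  expect_equal(t1$p_value, 1 / 301, tolerance = 1e-12)

  expect_warning(edma_test(wt, mut, "form", n_boot = 50, ci_boot = 0, seed = 1),
                 "very small")
})

test_that("influence analysis counts, directions and conservation law", {
  nm <- paste0("L", 1:6)
  mk_diff <- function(red) {
    names(red) <- craniomorph:::pair_labels(nm)
    structure(list(landmark_names = nm, red = red, mode = "shape",
                   ci_lo = NULL, ci_hi = NULL, ci_level = NULL),
              class = "difference_matrix")
  }
  # all RED 1: nothing flagged
  inf0 <- influence_analysis(mk_diff(rep(1, 15)))
  expect_true(all(inf0$table$dominant_direction == "none"))
  expect_true(all(inf0$table$fraction_outside == 0))

  # single pair above band: exactly its two landmarks flagged as increase
  red <- rep(1, 15); red[1] <- 1.06  # pair L1-L2
  inf1 <- influence_analysis(mk_diff(red))
  flagged <- inf1$table$landmark[inf1$table$fraction_outside > 0]
  expect_setequal(flagged, c("L1", "L2"))
  expect_true(all(inf1$table$dominant_direction[
    inf1$table$landmark %in% c("L1", "L2")] == "increase"))
  expect_identical(inf1$n_out_of_band_pairs, 1L)

  # conservation: sum over landmarks of counts = 2 x out-of-band pairs,
  # checked against an independent per-pair recount
  set.seed(15)
  for (rep_i in 1:10) {
    red <- exp(rnorm(15, sd = 0.06))
    inf <- influence_analysis(mk_diff(red))
    n_out <- sum(red < 0.95 | red > 1.05)
    expect_identical(sum(inf$table$n_above + inf$table$n_below), 2L * n_out)
    # brute-force recount per landmark
    idx <- craniomorph:::pair_index(6)
    for (l in 1:6) {
      incident <- which(idx[, 1] == l | idx[, 2] == l)
      row <- inf$table[inf$table$landmark == nm[l], ]
      expect_identical(row$n_above, sum(red[incident] > 1.05))
      expect_identical(row$n_below, sum(red[incident] < 0.95))
      expect_equal(row$fraction_outside,
                   (row$n_above + row$n_below) / 5)
    }
  }
  expect_error(influence_analysis(mk_diff(rep(1, 15)), band_lo = 1.1,
                                  band_hi = 1.0), "band_lo")
})

test_that("direction dominance follows the 2:1 majority rule", {
  # construct REDs giving a landmark 2 above + 1 below (increase),
  # and another 1 above + 1 below (mixed)
  nm <- paste0("L", 1:5)
  red <- rep(1, 10)
  names(red) <- craniomorph:::pair_labels(nm)
  red["L1-L2"] <- 1.1; red["L1-L3"] <- 1.1; red["L1-L4"] <- 0.9
  inf <- influence_analysis(structure(
    list(landmark_names = nm, red = red, mode = "form",
         ci_lo = NULL, ci_hi = NULL, ci_level = NULL),
    class = "difference_matrix"))
  tab <- inf$table
  expect_identical(tab$dominant_direction[tab$landmark == "L1"], "increase")
  expect_identical(tab$dominant_direction[tab$landmark == "L4"], "decrease")
  # L2: 1 above, 0 below -> increase; construct a mixed case
  red2 <- red; red2["L2-L3"] <- 0.9; red2["L1-L2"] <- 1.1
  inf2 <- influence_analysis(structure(
    list(landmark_names = nm, red = red2, mode = "form",
         ci_lo = NULL, ci_hi = NULL, ci_level = NULL),
    class = "difference_matrix"))
  expect_identical(
    inf2$table$dominant_direction[inf2$table$landmark == "L2"], "mixed")
})

test_that("tidy export of a difference matrix carries the band flags", {
  set <- sample_cohort(cohort_spec(test_template(),
                                   effect_spec(c(midface = 0.8)),
                                   noise_sd = 0.01, seed = 4))
  tst <- edma_test(subset_group(set, "WT"), subset_group(set, "Mut"),
                   "shape", n_boot = 200, ci_boot = 100, seed = 3)
  df <- as.data.frame(tst$diff)
  expect_identical(nrow(df), 66L)
  expect_identical(df$out_of_band, df$red < 0.95 | df$red > 1.05)
  expect_true(all(is.finite(df$ci_lo)))
})
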