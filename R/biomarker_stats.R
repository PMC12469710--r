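# Small-sample expression (ddPCR ratio) comparison with the
# normality/variance test-selection cascade, and cell-proliferation
# indices from EdU / PH3 / Hoechst counts.

#' Two-group comparison with the normality/variance selection cascade
#'
#' Runs Shapiro-Wilk on each group; if both are consistent with normality
#' at `alpha`, an F-test compares variances and the location test is a
#' two-tailed unpaired t-test (equal variances) or Welch's t-test
#' (unequal). If either group departs from normality the fallback is the
#' Mann-Whitney (Wilcoxon rank-sum) test, flagged in the result. All
#' intermediate p-values are recorded so the branch choice can be
#' replayed from the output alone.
#'
#' @param a,b numeric vectors of per-animal values (n >= 3 each);
#'   conventionally `a` = euploid (control), `b` = trisomic.
#' @param alpha significance level for the normality and variance
#'   pre-tests (default 0.05).
#' @return a `group_comparison`: `test_used` (`"t_test"`, `"welch"` or
#'   `"mann_whitney"`), `p_value`, `normality_p` (length 2), `variance_p`
#'   (NA when the nonparametric branch is taken), `alpha`, `group_means`,
#'   `ratio` (mean(b)/mean(a)).
#' @examples
#' set.seed(1)
#' eu <- rnorm(10, 1.00, 0.08)
#' ts <- rnorm(10, 1.48, 0.08)   # ~3-copy dosage
#' select_and_test(eu, ts)
#' @export
select_and_test <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L)
    stopf("insufficient sample: need n >= 3 per group (got %d and %d)",
          length(a), length(b))
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stopf("non-finite values in input")
  normality_p <- c(a = stats::shapiro.test(a)$p.value,
                   b = stats::shapiro.test(b)$p.value)
  if (all(normality_p >= alpha)) {
    variance_p <- stats::var.test(a, b)$p.value
    if (variance_p >= alpha) {
      test_used <- "t_test"
      p_value <- stats::t.test(a, b, var.equal = TRUE)$p.value
    } else {
      test_used <- "welch"
      p_value <- stats::t.test(a, b, var.equal = FALSE)$p.value
    }
  } else {
    test_used <- "mann_whitney"
    variance_p <- NA_real_
    p_value <- stats::wilcox.test(a, b, exact = FALSE)$p.value
  }
  structure(list(test_used = test_used, p_value = p_value,
                 normality_p = normality_p, variance_p = variance_p,
                 alpha = alpha,
                 group_means = c(a = mean(a), b = mean(b)),
                 ratio = mean(b) / mean(a),
                 n = c(a = length(a), b = length(b))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  lab <- c(t_test = "two-tailed unpaired t-test (equal variances)",
           welch = "Welch's t-test",
           mann_whitney = "Mann-Whitney U (non-normal fallback)")
  cat("Two-group comparison:", lab[[x$test_used]], "\n")
  cat(sprintf("  Shapiro-Wilk p: %.3g / %.3g; F-test p: %s (alpha = %.2f)\n",
              x$normality_p[1L], x$normality_p[2L],
              if (is.na(x$variance_p)) "-" else sprintf("%.3g", x$variance_p),
              x$alpha))
  cat(sprintf("  means: %.4g vs %.4g (ratio %.3f); p = %.4g\n",
              x$group_means[1L], x$group_means[2L], x$ratio, x$p_value))
  invisible(x)
}

#' Relative expression ratio between groups
#'
#' Ratio of group means, trisomic over euploid; the theoretical
#' expectation under full three-copy dosage is 1.5.
#'
#' @param trisomic,euploid numeric vectors of per-animal
#'   target/housekeeping concentration ratios.
#' @return positive scalar `mean(trisomic) / mean(euploid)`.
#' @export
expression_ratio <- function(trisomic, euploid) {
  if (!length(trisomic) || !length(euploid)) stopf("empty input")
  mean(trisomic) / mean(euploid)
}

#' Compare expression of several genes from a tidy table
#'
#' @param df data frame with columns `gene`, `group` (`"euploid"` /
#'   `"trisomic"`), `value`.
#' @param alpha pre-test level passed to [select_and_test()].
#' @param adjust `"none"` (default, per-gene reporting) or `"holm"`.
#' @return data frame with one row per gene: ratio, test used, p-value and
#'   (optionally adjusted) p.
#' @export
compare_expression <- function(df, alpha = 0.05, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  need <- c("gene", "group", "value")
  if (!all(need %in% names(df)))
    stopf("data frame needs columns: %s", paste(need, collapse = ", "))
  genes <- unique(df$gene)
  rows <- lapply(genes, function(g) {
    sub <- df[df$gene == g, ]
    eu <- sub$value[sub$group == "euploid"]
    tr <- sub$value[sub$group == "trisomic"]
    cmp <- select_and_test(eu, tr, alpha = alpha)
    data.frame(gene = g, n_euploid = length(eu), n_trisomic = length(tr),
               ratio = cmp$ratio, test_used = cmp$test_used,
               p_value = cmp$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (adjust == "holm")
    stats::p.adjust(out$p_value, "holm") else out$p_value
  out
}

#' Cell counts from a labeled micrograph region
#'
#' @param edu_pos number of EdU-positive (S-phase) cells.
#' @param ph3_pos number of PH3-positive (mitotic) cells.
#' @param hoechst_total total cells (Hoechst nuclear stain), > 0.
#' @param region text label for the counted region.
#' @return a `cell_counts` record.
#' @export
cell_counts <- function(edu_pos, ph3_pos, hoechst_total, region = "") {
  edu_pos <- as.integer(edu_pos); ph3_pos <- as.integer(ph3_pos)
  hoechst_total <- as.integer(hoechst_total)
  if (hoechst_total <= 0L) stopf("hoechst_total must be > 0")
  if (edu_pos < 0L || ph3_pos < 0L) stopf("counts must be >= 0")
  if (edu_pos > hoechst_total)
    stopf("edu_pos (%d) exceeds hoechst_total (%d)", edu_pos, hoechst_total)
  if (ph3_pos > hoechst_total)
    stopf("ph3_pos (%d) exceeds hoechst_total (%d)", ph3_pos, hoechst_total)
  structure(list(edu_pos = edu_pos, ph3_pos = ph3_pos,
                 hoechst_total = hoechst_total, region = region),
            class = "cell_counts")
}

#' Proliferation index: percentage of EdU-positive cells
#'
#' The fraction of proliferating (S-phase labeled) cells among all cells,
#' reported as a percentage.
#'
#' @param c a [cell_counts()] record.
#' @return `100 * edu_pos / hoechst_total`.
#' @examples
#' proliferation_index(cell_counts(50, 10, 200))  # 25
#' @export
proliferation_index <- function(c) {
  stopifnot(inherits(c, "cell_counts"))
  100 * c$edu_pos / c$hoechst_total
}

#' Mitotic index from EdU and PH3 counts
#'
#' Relates S-phase labeled cells to mitotic cells to assess progression
#' from S phase to G2/M. The ratio orientation is ambiguous in common
#' usage, so a convention must be chosen explicitly; there is no default.
#'
#' @param c a [cell_counts()] record.
#' @param convention `"ph3_over_edu"` (`ph3_pos / edu_pos`) or
#'   `"edu_over_ph3"` (`edu_pos / ph3_pos`).
#' @return the chosen ratio.
#' @examples
#' mitotic_index(cell_counts(100, 10, 500), "ph3_over_edu")  # 0.1
#' @export
mitotic_index <- function(c, convention) {
  stopifnot(inherits(c, "cell_counts"))
  if (missing(convention))
    stopf("convention is mandatory: choose 'ph3_over_edu' or 'edu_over_ph3'")
  convention <- match.arg(convention, c("ph3_over_edu", "edu_over_ph3"))
  num <- if (convention == "ph3_over_edu") c$ph3_pos else c$edu_pos
  den <- if (convention == "ph3_over_edu") c$edu_pos else c$ph3_pos
  if (den == 0L) stopf("zero denominator under convention '%s'", convention)
  num / den
}
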