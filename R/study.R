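# Config-driven study orchestration: each model against its wild-type
# reference (EDMA form + shape, influence landmarks, GPA + shape PCA),
# then the integrative cross-model stage (distance-feature PCA and
# Procrustes-distance permutation tests).

#' Build a study configuration
#'
#' @param datasets named list of model datasets; each element is either a
#'   [cohort_spec()] (generated at run time) or a file path readable by
#'   [read_specimens()]. Names are the model labels.
#' @param reference_group group label of the wild-type reference present
#'   in every dataset.
#' @param n_boot,ci_level,band EDMA settings: bootstrap replicates,
#'   per-pair CI level, and the RED flagging band (length 2).
#' @param n_perm permutations for the integrative group tests.
#' @param alpha significance level for the severity labels.
#' @param strong_fraction minimum fraction of out-of-band pairs for a
#'   significant result to be labeled `strong` rather than `mild`.
#' @param seed master seed; every resampling stage derives its own
#'   sub-seed from it.
#' @param output_dir optional directory for CSV/JSON artifacts; `NULL`
#'   skips writing.
#' @return a `study_config`.
#' @export
study_config <- function(datasets, reference_group = "WT",
                         n_boot = 10000L, ci_level = 0.978,
                         band = c(0.95, 1.05),
                         n_perm = 1000L, alpha = 0.05,
                         strong_fraction = 0.25,
                         seed = 1L, output_dir = NULL) {
  if (is.null(names(datasets)) || anyDuplicated(names(datasets)))
    stopf("datasets must be a named list with unique model labels")
  stopifnot(length(band) == 2L, band[1L] < band[2L])
  structure(list(datasets = datasets, reference_group = reference_group,
                 n_boot = as.integer(n_boot), ci_level = ci_level,
                 band = band, n_perm = as.integer(n_perm), alpha = alpha,
                 strong_fraction = strong_fraction,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "study_config")
}

#' Severity label from the form and shape tests
#'
#' Labels a model `NS` when the omnibus p-value is not below `alpha`;
#' otherwise `strong` when at least `strong_fraction` of landmark pairs
#' fall outside the RED band, else `mild`. The rule is a stated
#' quantitative convention (the underlying study reports these labels
#' qualitatively), surfaced in the report so users can re-threshold.
#'
#' @param test_form,test_shape [edma_test()] results for the two modes.
#' @param alpha significance level.
#' @param strong_fraction out-of-band fraction threshold.
#' @param band RED band, length 2.
#' @return named character vector `c(form = ..., shape = ...)` with values
#'   in `{"strong", "mild", "NS"}`.
#' @export
classify_severity <- function(test_form, test_shape, alpha = 0.05,
                              strong_fraction = 0.25,
                              band = c(0.95, 1.05)) {
  one <- function(tst) {
    if (tst$p_value >= alpha) return("NS")
    frac <- mean(tst$diff$red < band[1L] | tst$diff$red > band[2L])
    if (frac >= strong_fraction) "strong" else "mild"
  }
  c(form = one(test_form), shape = one(test_shape))
}

#' Run a full multi-model morphometric study
#'
#' For each configured model: loads or generates its cohort, runs the EDMA
#' bootstrap test in form and shape mode against the reference group,
#' influence-landmark analysis on the shape difference matrix, and GPA +
#' shape PCA on the pooled (model + reference) specimens. Then, across all
#' models, the integrative shape-scaled distance PCA and pairwise
#' Procrustes-distance permutation tests. All randomness derives from the
#' config's master seed, so rerunning the same config reproduces every
#' number; per-dataset failures are isolated into the report rather than
#' aborting the study.
#'
#' @param config a [study_config()].
#' @return a `study_report`: per-model results (`models`), `integrative`
#'   (PCA + permutation tests), `severity` table, `config`, `errors`.
#' @examples
#' tpl <- build_template(10, seed = 1)
#' cfg <- study_config(
#'   datasets = list(
#'     null_model = cohort_spec(tpl, null_effect(), noise_sd = 0.02, seed = 11),
#'     midface    = cohort_spec(tpl, effect_spec(c(midface = 0.8)),
#'                              noise_sd = 0.02, seed = 12)),
#'   n_boot = 300, n_perm = 100, seed = 5)
#' rep <- run_study(cfg)
#' rep$severity
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  models <- list()
  errors <- list()
  sets <- list()
  for (i in seq_along(config$datasets)) {
    label <- names(config$datasets)[i]
    res <- tryCatch(
      run_one_model(config, label, config$datasets[[i]],
                    derive_seed(config$seed, i)),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[label]] <- conditionMessage(res)
    } else {
      models[[label]] <- res
      sets[[label]] <- res$set
    }
  }
  integrative <- NULL
  if (length(sets) >= 1L) {
    int_pca <- integrative_distance_pca(sets)
    pooled <- specimen_set(
      unlist(lapply(names(sets), function(nm) {
        lapply(sets[[nm]]$configurations, function(cf) {
          # disambiguate group labels across models; the shared reference
          # keeps one label so wild-types pool together
          if (cf$group != config$reference_group)
            cf$group <- paste(nm, cf$group, sep = ":")
          cf$specimen_id <- paste(nm, cf$specimen_id, sep = ":")
          cf
        })
      }), recursive = FALSE))
    perm <- group_permutation_test(gpa(pooled), n_perm = config$n_perm,
                                   seed = derive_seed(config$seed, 900001L))
    integrative <- list(pca = int_pca, permutation = perm,
                        n_specimens = length(pooled$configurations))
  }
  severity <- do.call(rbind, lapply(names(models), function(nm) {
    sv <- classify_severity(models[[nm]]$form_test, models[[nm]]$shape_test,
                            alpha = config$alpha,
                            strong_fraction = config$strong_fraction,
                            band = config$band)
    data.frame(model = nm, unit = models[[nm]]$set$unit,
               form = sv[["form"]], shape = sv[["shape"]],
               p_form = models[[nm]]$form_test$p_value,
               p_shape = models[[nm]]$shape_test$p_value,
               n_specimens = length(models[[nm]]$set$configurations))
  }))
  report <- structure(list(models = models, integrative = integrative,
                           severity = severity, config = config,
                           errors = errors),
                      class = "study_report")
  if (!is.null(config$output_dir)) write_study_report(report, config$output_dir)
  report
}

run_one_model <- function(config, label, dataset, seed) {
  set <- if (inherits(dataset, "cohort_spec")) sample_cohort(dataset)
  else read_specimens(dataset)
  gl <- groups(set)
  if (!config$reference_group %in% gl)
    stopf("dataset '%s' has no reference group '%s'", label,
          config$reference_group)
  test_groups <- setdiff(gl, config$reference_group)
  if (length(test_groups) != 1L)
    stopf("dataset '%s' must contain the reference and exactly one test group",
          label)
  ref <- subset_group(set, config$reference_group)
  tst <- subset_group(set, test_groups)
  form_test <- edma_test(ref, tst, mode = "form", n_boot = config$n_boot,
                         ci_level = config$ci_level, seed = derive_seed(seed, 1L))
  shape_test <- edma_test(ref, tst, mode = "shape", n_boot = config$n_boot,
                          ci_level = config$ci_level, seed = derive_seed(seed, 2L))
  influence <- influence_analysis(shape_test$diff,
                                  band_lo = config$band[1L],
                                  band_hi = config$band[2L])
  influence$table$region <- set$region_map[influence$table$landmark]
  g <- gpa(set)
  list(label = label, set = set, form_test = form_test,
       shape_test = shape_test, influence = influence,
       gpa = g, pca = shape_pca(g))
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Morphometric study report: %d model(s), reference group '%s'\n",
              length(x$models), x$config$reference_group))
  if (!is.null(x$severity)) {
    cat("severity (form / shape):\n")
    print(x$severity, row.names = FALSE)
  }
  if (length(x$errors))
    cat("failed datasets:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a study report to a directory
#'
#' Writes per-model difference matrices and influence tables as CSV, the
#' severity table, the integrative PCA scores and permutation p-values,
#' and one machine-readable JSON summary capturing every statistic and
#' the full configuration (for provenance).
#'
#' @param report a `study_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$models)) {
    m <- report$models[[nm]]
    utils::write.csv(as.data.frame(m$shape_test$diff,
                                   band_lo = report$config$band[1L],
                                   band_hi = report$config$band[2L]),
                     file.path(dir, paste0(nm, "_sdm.csv")), row.names = FALSE)
    utils::write.csv(as.data.frame(m$form_test$diff,
                                   band_lo = report$config$band[1L],
                                   band_hi = report$config$band[2L]),
                     file.path(dir, paste0(nm, "_fdm.csv")), row.names = FALSE)
    utils::write.csv(m$influence$table,
                     file.path(dir, paste0(nm, "_influence.csv")),
                     row.names = FALSE)
  }
  if (!is.null(report$severity))
    utils::write.csv(report$severity, file.path(dir, "severity.csv"),
                     row.names = FALSE)
  if (!is.null(report$integrative)) {
    sc <- cbind(report$integrative$pca$labels,
                as.data.frame(report$integrative$pca$scores))
    utils::write.csv(sc, file.path(dir, "integrative_pca_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(report$integrative$permutation$p_values),
                     file.path(dir, "permutation_p_values.csv"))
  }
  jsonlite::write_json(study_report_json(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# stable machine-readable summary; numbers only, fully determined by
# (config, seed)
study_report_json <- function(report) {
  cfg <- report$config
  list(
    config = list(
      models = names(cfg$datasets), reference_group = cfg$reference_group,
      n_boot = cfg$n_boot, ci_level = cfg$ci_level, band = cfg$band,
      n_perm = cfg$n_perm, alpha = cfg$alpha,
      strong_fraction = cfg$strong_fraction, seed = cfg$seed),
    models = lapply(report$models, function(m) list(
      n_specimens = length(m$set$configurations),
      unit = m$set$unit,
      form = list(observed_T = m$form_test$observed_T,
                  p_value = m$form_test$p_value),
      shape = list(observed_T = m$shape_test$observed_T,
                   p_value = m$shape_test$p_value),
      red_shape = as.list(m$shape_test$diff$red),
      influence_top = utils::head(m$influence$table$landmark, 5L),
      pc1_variance_fraction = m$pca$variance_fraction[1L],
      gpa_iterations = m$gpa$iterations)),
    severity = report$severity,
    integrative = if (is.null(report$integrative)) NULL else list(
      n_specimens = report$integrative$n_specimens,
      variance_fraction = report$integrative$pca$variance_fraction,
      p_values = report$integrative$permutation$p_values,
      observed_distance = report$integrative$permutation$observed_distance),
    errors = report$errors)
}
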