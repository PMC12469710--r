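# Core containers: one specimen's landmark configuration, and a cohort
# (specimen set) sharing a single landmark inventory.

#' Create a single-specimen landmark configuration
#'
#' A `landmark_config` stores one specimen's named 3D landmark coordinates
#' together with its group (genotype) label and the skeletal unit the
#' landmarks belong to.
#'
#' @param specimen_id character scalar identifying the specimen.
#' @param group character scalar, the genotype/group label (e.g. `"WT"`).
#' @param coords numeric K x 3 matrix of landmark coordinates in mm, with
#'   rownames giving unique landmark names. K must be at least 4.
#' @param region named character vector mapping each landmark name to an
#'   anatomical region tag (e.g. `"midface"`). Must cover every landmark.
#' @param unit `"cranium"` or `"mandible"`.
#' @param sex optional sex label (`"F"`, `"M"` or `NA`).
#' @return an object of class `landmark_config`.
#' @examples
#' xy <- cbind(x = c(0, 3, 0, 1), y = c(0, 0, 4, 1), z = c(0, 0, 0, 2))
#' rownames(xy) <- paste0("L", 1:4)
#' cfg <- landmark_config("m1", "WT", xy,
#'                        region = setNames(rep("face", 4), rownames(xy)))
#' cfg
#' @export
landmark_config <- function(specimen_id, group, coords,
                            region = NULL,
                            unit = c("cranium", "mandible"),
                            sex = NA_character_) {
  unit <- match.arg(unit)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stopf("coords must be a K x 3 matrix, got %d columns", ncol(coords))
  if (nrow(coords) < 4L)
    stopf("at least 4 landmarks are required, got %d", nrow(coords))
  if (is.null(rownames(coords)))
    rownames(coords) <- paste0("L", seq_len(nrow(coords)))
  colnames(coords) <- c("x", "y", "z")
  nm <- rownames(coords)
  if (anyDuplicated(nm))
    stopf("duplicate landmark names in specimen '%s': %s", specimen_id,
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (!all(is.finite(coords)))
    stopf("non-finite coordinates in specimen '%s'", specimen_id)
  if (is.null(region)) region <- setNames(rep("all", length(nm)), nm)
  if (!all(nm %in% names(region)))
    stopf("region map does not cover landmarks: %s",
          paste(setdiff(nm, names(region)), collapse = ", "))
  structure(
    list(specimen_id = as.character(specimen_id),
         group = as.character(group),
         unit = unit,
         sex = as.character(sex),
         coords = coords,
         region = region[nm]),
    class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("Landmark configuration '%s' (%s, group %s): %d landmarks, %d regions\n",
              x$specimen_id, x$unit, x$group, nrow(x$coords),
              length(unique(x$region))))
  invisible(x)
}

#' Assemble landmark configurations into a specimen set
#'
#' A `specimen_set` is the unit all analyses operate on: a list of
#' [landmark_config()] objects guaranteed to share one landmark inventory
#' (same names, same order) and one region map.
#'
#' @param configurations list of `landmark_config` objects.
#' @param validate if `TRUE` (default), invariants are checked and violations
#'   raise an error; see [validate_set()] for a non-throwing report.
#' @return an object of class `specimen_set` with fields `configurations`,
#'   `unit`, `landmark_names`, `region_map`.
#' @seealso [validate_set()], [read_specimens()], [sample_cohort()]
#' @export
specimen_set <- function(configurations, validate = TRUE) {
  if (length(configurations) < 1L)
    stopf("a specimen set needs at least one configuration")
  if (!all(vapply(configurations, inherits, logical(1), "landmark_config")))
    stopf("all elements must be landmark_config objects")
  first <- configurations[[1L]]
  set <- structure(
    list(configurations = configurations,
         unit = first$unit,
         landmark_names = rownames(first$coords),
         region_map = first$region),
    class = "specimen_set")
  if (validate) {
    rep <- validate_set(set)
    if (nrow(rep) > 0L)
      stopf("invalid specimen set:\n%s",
            paste(sprintf("- [%s] %s", rep$specimen, rep$message), collapse = "\n"))
  }
  set
}

#' @export
print.specimen_set <- function(x, ...) {
  g <- groups(x)
  cat(sprintf("Specimen set (%s): %d specimens, %d landmarks, %d regions\n",
              x$unit, length(x$configurations), length(x$landmark_names),
              length(unique(x$region_map))))
  tab <- table(vapply(x$configurations, `[[`, character(1), "group"))
  cat("  groups:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.specimen_set <- function(x) length(x$configurations)

#' Group labels present in a specimen set
#' @param set a `specimen_set`
#' @return character vector of unique group labels, in first-appearance order
#' @export
groups <- function(set) {
  unique(vapply(set$configurations, `[[`, character(1), "group"))
}

#' Extract the specimens of one group as a new specimen set
#' @param set a `specimen_set`
#' @param group group label to keep
#' @export
subset_group <- function(set, group) {
  keep <- vapply(set$configurations, function(cf) cf$group %in% group, logical(1))
  if (!any(keep)) stopf("no specimens in group(s) %s", paste(group, collapse = ", "))
  specimen_set(set$configurations[keep], validate = FALSE)
}

#' Stack a specimen set into a K x 3 x n coordinate array
#' @param set a `specimen_set`
#' @return numeric array with dimnames (landmark, axis, specimen)
#' @export
as_landmark_array <- function(set) {
  k <- length(set$landmark_names)
  n <- length(set$configurations)
  arr <- array(NA_real_, dim = c(k, 3L, n),
               dimnames = list(set$landmark_names, c("x", "y", "z"),
                               vapply(set$configurations, `[[`, character(1),
                                      "specimen_id")))
  for (s in seq_len(n)) arr[, , s] <- set$configurations[[s]]$coords
  arr
}

#' Validate a specimen set and report every violation
#'
#' Report-only companion to the throwing validation in [specimen_set()]:
#' checks for non-finite coordinates, duplicate landmark names, ragged
#' landmark counts, landmark-order mismatches across specimens, unmapped
#' regions and too-few landmarks. Any set with an empty report is accepted
#' by every downstream analysis.
#'
#' @param set a `specimen_set` (possibly built with `validate = FALSE`).
#' @return data frame with columns `specimen`, `check`, `message`; zero rows
#'   iff all invariants hold.
#' @export
validate_set <- function(set) {
  bad <- list()
  note <- function(specimen, check, message)
    bad[[length(bad) + 1L]] <<- data.frame(specimen = specimen, check = check,
                                           message = message)
  ref_names <- set$landmark_names
  if (length(ref_names) < 4L)
    note("<set>", "min_landmarks",
         sprintf("only %d landmarks; at least 4 required", length(ref_names)))
  unmapped <- setdiff(ref_names, names(set$region_map))
  if (length(unmapped))
    note("<set>", "region_map",
         paste("landmarks without region tag:", paste(unmapped, collapse = ", ")))
  for (cf in set$configurations) {
    id <- cf$specimen_id
    nm <- rownames(cf$coords)
    if (!all(is.finite(cf$coords)))
      note(id, "finite", "non-finite coordinate value")
    if (anyDuplicated(nm))
      note(id, "unique_names",
           paste("duplicate landmark names:",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    if (length(nm) != length(ref_names)) {
      note(id, "ragged",
           sprintf("inconsistent configuration: %d landmarks, set declares %d",
                   length(nm), length(ref_names)))
    } else if (!identical(nm, ref_names)) {
      note(id, "order",
           "landmark name order differs from the set inventory")
    }
    if (cf$unit != set$unit)
      note(id, "unit", sprintf("unit '%s' differs from set unit '%s'",
                               cf$unit, set$unit))
  }
  if (length(bad) == 0L)
    return(data.frame(specimen = character(), check = character(),
                      message = character()))
  do.call(rbind, bad)
}

#' Reference landmark inventory for the mouse cranium and mandible
#'
#' A synthetic stand-in dictionary of 39 cranium and 22 mandible landmark
#' names with anatomical region tags, shaped like the inventories used in
#' landmark-based mouse craniofacial phenotyping. The names and region
#' assignments are plausible fixtures for simulation and examples, not a
#' published digitization protocol.
#'
#' @param unit `"cranium"` (39 landmarks) or `"mandible"` (22 landmarks).
#' @return data frame with columns `landmark` and `region`.
#' @examples
#' table(mouse_landmark_inventory("cranium")$region)
#' @export
mouse_landmark_inventory <- function(unit = c("cranium", "mandible")) {
  unit <- match.arg(unit)
  if (unit == "cranium") {
    regions <- c(premaxilla = 4L, nasal = 4L, maxilla = 6L, frontal = 5L,
                 parietal = 5L, interparietal = 3L, occipital = 4L,
                 temporal = 4L, base = 4L)
  } else {
    regions <- c(body = 4L, ramus = 4L, coronoid = 3L, condylar = 3L,
                 angular = 3L, incisor_alveolus = 2L, molar_alveolus = 3L)
  }
  region <- rep(names(regions), times = regions)
  landmark <- unlist(lapply(names(regions), function(r)
    paste0(r, "_", seq_len(regions[[r]]))), use.names = FALSE)
  data.frame(landmark = landmark, region = region)
}
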