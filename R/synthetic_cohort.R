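# Synthetic two-group landmark cohorts with localized regional genotype
# effects, for calibration, power and recovery studies.

#' Build a stylized skull landmark template
#'
#' Places `n_landmarks` uniquely named landmarks on the upper half of a
#' tri-axial ellipsoid (a stylized "skull" surface, semi-axes 12 x 8 x 6 mm,
#' roughly adult mouse cranium proportions), assigns region tags to
#' contiguous sectors ordered along the anteroposterior axis, and recenters
#' the configuration so the centroid is exactly at the origin.
#' Deterministic given `seed`.
#'
#' @param n_landmarks number of landmarks (>= 4).
#' @param regions named integer vector: region tag -> landmark count; the
#'   counts must sum to `n_landmarks`. Defaults to three sectors
#'   (midface / neurocranium / base) of near-equal size.
#' @param seed integer seed controlling the placement.
#' @param unit `"cranium"` or `"mandible"` (metadata only).
#' @return a `landmark_template`: fields `coords` (K x 3, centroid at
#'   origin), `region` (named character), `unit`, `seed`.
#' @examples
#' tpl <- build_template(12, c(midface = 4, neurocranium = 4, base = 4), seed = 1)
#' colMeans(tpl$coords)   # (0, 0, 0)
#' @export
build_template <- function(n_landmarks,
                           regions = NULL,
                           seed = 1L,
                           unit = c("cranium", "mandible")) {
  unit <- match.arg(unit)
  if (n_landmarks < 4L) stopf("n_landmarks must be >= 4")
  if (is.null(regions)) {
    base_n <- n_landmarks %/% 3L
    regions <- c(midface = base_n,
                 neurocranium = base_n,
                 base = n_landmarks - 2L * base_n)
  }
  regions <- as.integer(regions) |> setNames(names(regions))
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stopf("every region must have a non-empty tag")
  if (sum(regions) != n_landmarks)
    stopf("region counts sum to %d, expected %d", sum(regions), n_landmarks)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 0L))

  # stratify longitude by region so tags label contiguous anteroposterior
  # sectors; jitter within sector, latitude restricted to the upper half
  region_tag <- rep(names(regions), times = regions)
  k <- n_landmarks
  sector <- rep(seq_along(regions), times = regions)
  n_sec <- length(regions)
  u <- (sector - stats::runif(k)) / n_sec          # in (0,1), ordered by sector
  theta <- pi * u                                  # longitude 0..pi (front..back)
  phi <- stats::runif(k, 0.05, pi / 2)             # elevation, upper half
  a <- c(12, 8, 6)                                 # mm semi-axes
  coords <- cbind(x = a[1] * cos(theta) * cos(phi),
                  y = a[2] * sin(theta) * cos(phi),
                  z = a[3] * sin(phi))
  # guard against coincident placements (probability ~0, but invariant)
  repeat {
    d <- stats::dist(coords)
    if (min(d) > 1e-6) break
    coords <- coords + matrix(stats::rnorm(3 * k, sd = 1e-3), ncol = 3L)
  }
  coords <- center_config(coords)
  rownames(coords) <- paste0(region_tag, "_",
                             stats::ave(rep(1L, k), region_tag, FUN = seq_along))
  structure(list(coords = coords,
                 region = setNames(region_tag, rownames(coords)),
                 unit = unit, seed = as.integer(seed)),
            class = "landmark_template")
}

#' @export
print.landmark_template <- function(x, ...) {
  cat(sprintf("Landmark template (%s): %d landmarks in %d regions (seed %d)\n",
              x$unit, nrow(x$coords), length(unique(x$region)), x$seed))
  print(table(x$region))
  invisible(x)
}

#' Describe a regional genotype effect
#'
#' An effect is a displacement field applied region by region about each
#' region's own centroid, so a contraction mimics local hypoplasia without
#' moving the rest of the configuration. `region_scale` gives isotropic
#' factors (1 = no effect, < 1 contraction, > 1 expansion); `axis_scale`
#' gives per-axis (x, y, z) factors for anisotropic effects such as lateral
#' widening of the neurocranium. Factors compose multiplicatively when a
#' region appears in both maps. Empty maps describe the null effect.
#'
#' @param region_scale named numeric vector, region tag -> factor (> 0).
#' @param axis_scale named list, region tag -> numeric length-3 factors.
#' @param label text label for reports.
#' @return an `effect_spec`.
#' @examples
#' trisomic_like <- effect_spec(
#'   region_scale = c(midface = 0.9),
#'   axis_scale = list(neurocranium = c(1, 1.1, 1)),
#'   label = "midface hypoplasia + lateral neurocranial expansion")
#' @export
effect_spec <- function(region_scale = numeric(), axis_scale = list(),
                        label = "effect") {
  if (length(region_scale) && (is.null(names(region_scale)) || any(region_scale <= 0)))
    stopf("region_scale must be a named vector of positive factors")
  if (length(axis_scale)) {
    ok <- vapply(axis_scale, function(v) length(v) == 3L && all(v > 0), logical(1))
    if (is.null(names(axis_scale)) || !all(ok))
      stopf("axis_scale must be a named list of positive length-3 factors")
  }
  structure(list(region_scale = region_scale, axis_scale = axis_scale,
                 label = label),
            class = "effect_spec")
}

#' The no-effect specification
#' @return an `effect_spec` with empty maps (identity displacement).
#' @export
null_effect <- function() effect_spec(label = "null")

#' Apply a regional effect to a template
#'
#' Landmarks of each affected region are moved to
#' `region_centroid + f * (x - region_centroid)` with per-axis factors `f`;
#' landmarks of untouched regions are bit-identical to the input. Within an
#' affected region, every pairwise distance therefore scales exactly by the
#' isotropic factor.
#'
#' @param template a `landmark_template`.
#' @param effect an [effect_spec()].
#' @return a new `landmark_template` (centroid NOT recentered, so untouched
#'   regions stay fixed).
#' @export
apply_effect <- function(template, effect) {
  stopifnot(inherits(template, "landmark_template"), inherits(effect, "effect_spec"))
  touched <- union(names(effect$region_scale), names(effect$axis_scale))
  unknown <- setdiff(touched, unique(template$region))
  if (length(unknown))
    stopf("unknown region tag(s): %s", paste(unknown, collapse = ", "))
  coords <- template$coords
  for (r in touched) {
    f <- rep(effect$region_scale[r] %|na|% 1, 3L)
    if (!is.null(effect$axis_scale[[r]])) f <- f * effect$axis_scale[[r]]
    idx <- which(template$region == r)
    ctr <- colMeans(coords[idx, , drop = FALSE])
    for (ax in which(f != 1))    # unit factors leave coordinates bit-identical
      coords[idx, ax] <- ctr[ax] + f[ax] * (coords[idx, ax] - ctr[ax])
  }
  out <- template
  out$coords <- coords
  out
}

`%|na|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

#' Specify a two-group synthetic cohort
#'
#' The control group is the template plus iid per-coordinate Gaussian
#' digitization/biological noise; the affected group is
#' `apply_effect(template, effect)` under the same noise model. Optional
#' nuisance parameters add a random rigid motion (rotation + translation)
#' and uniform size jitter per specimen, emulating arbitrary specimen pose
#' in the scanner; these leave all inter-landmark distances of the
#' underlying form untouched (up to the scale jitter, which form analysis
#' is meant to detect and shape analysis to remove).
#'
#' @param template a `landmark_template`.
#' @param effect an [effect_spec()]; default [null_effect()].
#' @param n_control,n_affected specimens per group (>= 2 each; the study
#'   design this emulates used about ten littermates per genotype).
#' @param noise_sd isotropic per-coordinate landmark noise, mm.
#' @param noise_sd_affected optional distinct noise level for the affected
#'   group (default: same as `noise_sd`).
#' @param rotate,translate_mm,scale_jitter nuisance pose: `rotate = TRUE`
#'   applies a uniform random 3D rotation; `translate_mm` the half-width of
#'   a uniform translation per axis; `scale_jitter` the half-width of a
#'   uniform relative size factor (e.g. 0.05 -> sizes in [0.95, 1.05]).
#' @param group_labels length-2 character, control then affected label.
#' @param seed master seed; per-specimen draws use split sub-streams so
#'   adding specimens never changes existing ones.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(template, effect = null_effect(),
                        n_control = 10L, n_affected = 10L,
                        noise_sd = 0.05, noise_sd_affected = NULL,
                        rotate = FALSE, translate_mm = 0, scale_jitter = 0,
                        group_labels = c("WT", "Mut"),
                        seed = 1L) {
  stopifnot(inherits(template, "landmark_template"), inherits(effect, "effect_spec"))
  if (n_control < 2L || n_affected < 2L) stopf("need >= 2 specimens per group")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(template = template, effect = effect,
                 n_control = as.integer(n_control),
                 n_affected = as.integer(n_affected),
                 noise_sd = noise_sd,
                 noise_sd_affected = noise_sd_affected %||% noise_sd,
                 rotate = isTRUE(rotate), translate_mm = translate_mm,
                 scale_jitter = scale_jitter,
                 group_labels = group_labels, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return a [specimen_set()] with group labels set; fully reproducible
#'   from `spec$seed`.
#' @examples
#' tpl <- build_template(12, seed = 2)
#' set <- sample_cohort(cohort_spec(tpl, effect_spec(c(midface = 0.9)),
#'                                  n_control = 5, n_affected = 5,
#'                                  noise_sd = 0.02, seed = 7))
#' set
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  tpl_c <- spec$template
  tpl_a <- apply_effect(spec$template, spec$effect)
  make_one <- function(base, sd, stream, id, group) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(spec$seed, stream))
    k <- nrow(base$coords)
    x <- base$coords + matrix(stats::rnorm(3L * k, sd = sd), ncol = 3L)
    if (spec$rotate) x <- x %*% random_rotation()
    if (spec$scale_jitter > 0)
      x <- x * stats::runif(1L, 1 - spec$scale_jitter, 1 + spec$scale_jitter)
    if (spec$translate_mm > 0)
      x <- sweep(x, 2L, stats::runif(3L, -spec$translate_mm, spec$translate_mm), `+`)
    rownames(x) <- rownames(base$coords)
    landmark_config(id, group, x, region = base$region, unit = base$unit)
  }
  configs <- c(
    lapply(seq_len(spec$n_control), function(i)
      make_one(tpl_c, spec$noise_sd, i,
               sprintf("%s_%02d", spec$group_labels[1L], i), spec$group_labels[1L])),
    lapply(seq_len(spec$n_affected), function(i)
      make_one(tpl_a, spec$noise_sd_affected, 100000L + i,
               sprintf("%s_%02d", spec$group_labels[2L], i), spec$group_labels[2L])))
  specimen_set(configs)
}

# uniform random proper rotation via QR of a Gaussian matrix with sign fix
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# save/restore the global RNG state so generator calls are pure in `seed`
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Read or write a cohort specification as YAML
#'
#' Serializes every field of a [cohort_spec()] (the template as explicit
#' coordinates) so a cohort is reproducible from the file alone.
#' @param spec a `cohort_spec`.
#' @param path YAML file path.
#' @return `read_cohort_spec` returns a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  tpl <- spec$template
  obj <- list(
    template = list(
      landmarks = rownames(tpl$coords),
      regions = unname(tpl$region),
      # 17 significant digits keep the double-precision values bit-exact
      coords = unname(apply(tpl$coords, 1L, function(p)
        sprintf("%.17g %.17g %.17g", p[1L], p[2L], p[3L]))),
      unit = tpl$unit, seed = tpl$seed),
    effect = list(region_scale = as.list(spec$effect$region_scale),
                  axis_scale = spec$effect$axis_scale,
                  label = spec$effect$label),
    n_control = spec$n_control, n_affected = spec$n_affected,
    noise_sd = spec$noise_sd, noise_sd_affected = spec$noise_sd_affected,
    rotate = spec$rotate, translate_mm = spec$translate_mm,
    scale_jitter = spec$scale_jitter,
    group_labels = spec$group_labels, seed = spec$seed)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  coords <- do.call(rbind, lapply(obj$template$coords, function(s)
    as.numeric(strsplit(s, " ", fixed = TRUE)[[1L]])))
  rownames(coords) <- obj$template$landmarks
  colnames(coords) <- c("x", "y", "z")
  tpl <- structure(list(
    coords = coords,
    region = setNames(obj$template$regions, obj$template$landmarks),
    unit = obj$template$unit, seed = as.integer(obj$template$seed)),
    class = "landmark_template")
  eff <- effect_spec(
    region_scale = unlist(obj$effect$region_scale) %||% numeric(),
    axis_scale = lapply(obj$effect$axis_scale, as.numeric),
    label = obj$effect$label %||% "effect")
  cohort_spec(tpl, eff,
              n_control = obj$n_control, n_affected = obj$n_affected,
              noise_sd = obj$noise_sd, noise_sd_affected = obj$noise_sd_affected,
              rotate = obj$rotate, translate_mm = obj$translate_mm,
              scale_jitter = obj$scale_jitter,
              group_labels = unlist(obj$group_labels), seed = obj$seed)
}
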