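# Landmark file I/O: a 3D TPS dialect and a long-format CSV schema.
#
# TPS dialect: records start with "LM3=K", followed by K "x y z" lines,
# then metadata lines ID=, GROUP=, UNIT=, SEX=. Two optional file-level
# header lines, NAMES= and REGIONS= (comma-separated, one entry per
# landmark), carry the landmark inventory; without them landmarks are
# named L1..LK with region "all". Coordinates are mm; no unit conversion.

#' Read a specimen landmark dataset
#'
#' @param path path to a `.tps` or `.csv` landmark file.
#' @param format `"tps"` or `"csv"`; by default guessed from the file
#'   extension.
#' @return a validated [specimen_set()].
#' @details
#' The TPS dialect is a minimal 3D extension of the de-facto TPS standard:
#' `LM3=K` introduces each record, one `x y z` triple per line, `ID=`
#' carries the specimen id and `GROUP=` the genotype label. The CSV schema
#' is long format with columns `specimen_id, group, unit, sex, landmark,
#' region, x, y, z` (one row per landmark per specimen).
#' @examples
#' set <- sample_cohort(cohort_spec(build_template(8, c(a = 4, b = 4), seed = 1),
#'                                  n_control = 2, n_affected = 2, seed = 1))
#' f <- tempfile(fileext = ".tps")
#' write_specimens(set, f)
#' set2 <- read_specimens(f)
#' stopifnot(all.equal(as_landmark_array(set), as_landmark_array(set2)))
#' @seealso [write_specimens()], [validate_set()]
#' @export
read_specimens <- function(path, format = c("auto", "tps", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "tsv")) "csv" else "tps"
  }
  if (format == "tps") read_tps(path) else read_landmark_csv(path)
}

read_tps <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  names_hdr <- NULL
  regions_hdr <- NULL
  configs <- list()
  i <- 1L
  n_lines <- length(lines)
  while (i <= n_lines) {
    ln <- trimws(lines[[i]])
    if (ln == "" ) { i <- i + 1L; next }
    if (startsWith(ln, "NAMES=")) {
      names_hdr <- trimws(strsplit(sub("^NAMES=", "", ln), ",")[[1L]])
      i <- i + 1L; next
    }
    if (startsWith(ln, "REGIONS=")) {
      regions_hdr <- trimws(strsplit(sub("^REGIONS=", "", ln), ",")[[1L]])
      i <- i + 1L; next
    }
    if (!grepl("^LM3=", ln))
      stopf("TPS parse error at line %d: expected 'LM3=K', got '%s'", i, ln)
    k <- suppressWarnings(as.integer(sub("^LM3=", "", ln)))
    if (is.na(k) || k < 1L)
      stopf("TPS parse error at line %d: invalid landmark count", i)
    if (i + k > n_lines)
      stopf("TPS parse error: record starting at line %d declares %d landmarks but file ends", i, k)
    coords <- matrix(NA_real_, nrow = k, ncol = 3L)
    for (r in seq_len(k)) {
      row_line <- i + r
      vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[[row_line]]), "[ \t]+")[[1L]]))
      if (length(vals) != 3L || anyNA(vals))
        stopf("TPS parse error at line %d: expected three numeric coordinates", row_line)
      coords[r, ] <- vals
    }
    i <- i + k + 1L
    meta <- c(ID = NA_character_, GROUP = NA_character_,
              UNIT = "cranium", SEX = NA_character_)
    while (i <= n_lines && grepl("^(ID|GROUP|UNIT|SEX)=", trimws(lines[[i]]))) {
      kv <- strsplit(trimws(lines[[i]]), "=", fixed = TRUE)[[1L]]
      meta[[kv[1L]]] <- if (length(kv) > 1L) kv[2L] else ""
      i <- i + 1L
    }
    if (is.na(meta[["ID"]]))
      stopf("TPS record ending at line %d has no ID= line", i - 1L)
    nm <- names_hdr %||% paste0("L", seq_len(k))
    if (length(nm) != k)
      stopf("inconsistent configuration: specimen '%s' has %d landmarks, NAMES= header declares %d",
            meta[["ID"]], k, length(nm))
    rg <- regions_hdr %||% rep("all", k)
    rownames(coords) <- nm
    configs[[length(configs) + 1L]] <- landmark_config(
      specimen_id = meta[["ID"]], group = meta[["GROUP"]],
      coords = coords, region = setNames(rg, nm),
      unit = meta[["UNIT"]], sex = meta[["SEX"]])
  }
  if (length(configs) == 0L) stopf("no TPS records found in %s", path)
  check_consistent(configs)
  specimen_set(configs)
}

read_landmark_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("specimen_id", "group", "unit", "landmark", "region", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stopf("CSV missing required columns: %s", paste(missing_cols, collapse = ", "))
  for (ax in c("x", "y", "z")) {
    if (!is.numeric(df[[ax]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[ax]]))))[1L]
      stopf("CSV parse error at data line %d: non-numeric %s coordinate '%s'",
            bad, ax, df[[ax]][bad])
    }
  }
  ids <- unique(df$specimen_id)
  configs <- lapply(ids, function(id) {
    rows <- df[df$specimen_id == id, , drop = FALSE]
    coords <- as.matrix(rows[, c("x", "y", "z")])
    rownames(coords) <- rows$landmark
    landmark_config(
      specimen_id = id, group = rows$group[1L], coords = coords,
      region = setNames(rows$region, rows$landmark), unit = rows$unit[1L],
      sex = if ("sex" %in% names(rows)) rows$sex[1L] else NA_character_)
  })
  check_consistent(configs)
  specimen_set(configs)
}

# raggedness across specimens is reported by specimen id; the majority
# landmark count decides which specimen is the offending one
check_consistent <- function(configs) {
  counts <- vapply(configs, function(cf) nrow(cf$coords), integer(1))
  tab <- table(counts)
  k_ref <- as.integer(names(tab)[which.max(tab)])
  for (cf in configs) {
    if (nrow(cf$coords) != k_ref)
      stopf("inconsistent configuration: specimen '%s' has %d landmarks, expected %d",
            cf$specimen_id, nrow(cf$coords), k_ref)
  }
  ref_idx <- which(counts == k_ref)[1L]
  ref <- rownames(configs[[ref_idx]]$coords)
  for (cf in configs) {
    if (!identical(rownames(cf$coords), ref))
      stopf("inconsistent configuration: specimen '%s' landmark names/order differ from '%s'",
            cf$specimen_id, configs[[ref_idx]]$specimen_id)
  }
  invisible(TRUE)
}

#' Write a specimen landmark dataset
#'
#' Coordinates are emitted with 12 significant digits so that a
#' write/read round trip reproduces them to well below 1e-9 mm.
#'
#' @param set a [specimen_set()].
#' @param path output file path.
#' @param format `"tps"` or `"csv"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(set, path, format = c("auto", "tps", "csv")) {
  format <- match.arg(format)
  if (!inherits(set, "specimen_set")) stopf("set must be a specimen_set")
  if (length(set$configurations) == 0L) stopf("empty specimen set")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "tsv")) "csv" else "tps"
  }
  if (format == "tps") {
    out <- c(
      paste0("NAMES=", paste(set$landmark_names, collapse = ",")),
      paste0("REGIONS=", paste(set$region_map[set$landmark_names], collapse = ",")))
    for (cf in set$configurations) {
      out <- c(out,
               sprintf("LM3=%d", nrow(cf$coords)),
               apply(cf$coords, 1L, function(p)
                 paste(formatC(p, digits = 12, format = "g"), collapse = " ")),
               paste0("ID=", cf$specimen_id),
               paste0("GROUP=", cf$group),
               paste0("UNIT=", cf$unit),
               paste0("SEX=", cf$sex))
    }
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(out, con)
  } else {
    rows <- do.call(rbind, lapply(set$configurations, function(cf) {
      data.frame(specimen_id = cf$specimen_id, group = cf$group,
                 unit = cf$unit, sex = cf$sex,
                 landmark = rownames(cf$coords),
                 region = unname(cf$region[rownames(cf$coords)]),
                 x = cf$coords[, 1L], y = cf$coords[, 2L], z = cf$coords[, 3L],
                 row.names = NULL)
    }))
    utils::write.csv(format(rows, digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
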