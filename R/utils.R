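# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a stream index
#'
#' Counter-based splitting: each (seed, index) pair maps to a fixed 31-bit
#' integer, so adding streams (e.g. extra specimens) never perturbs the
#' draws of existing ones.
#' @param seed master seed (integer)
#' @param index non-negative stream counter
#' @return an integer in [0, 2^31 - 1]
#' @keywords internal
derive_seed <- function(seed, index) {
  # affine hash mod the Mersenne prime 2^31 - 1; constants are the classic
  # MINSTD multiplier and a large prime offset
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(index) * 1299709 + 12345
  as.integer(s %% m)
}

#' Canonical unordered landmark-pair index table
#'
#' Pairs (i, j), i < j, in the order produced by [stats::dist()]:
#' (1,2), (1,3), ..., (1,K), (2,3), ... — lexicographic by (i, j).
#' @param k number of landmarks
#' @return two-column integer matrix with K(K-1)/2 rows
#' @keywords internal
pair_index <- function(k) {
  i <- rep.int(seq_len(k - 1L), times = (k - 1L):1L)
  j <- unlist(lapply(seq_len(k - 1L), function(a) (a + 1L):k), use.names = FALSE)
  cbind(i = i, j = j)
}

#' Names for landmark pairs ("A-B")
#' @keywords internal
pair_labels <- function(landmark_names) {
  idx <- pair_index(length(landmark_names))
  paste(landmark_names[idx[, 1L]], landmark_names[idx[, 2L]], sep = "-")
}

#' Centroid size: root summed squared distances of landmarks to centroid
#' @param x K x 3 coordinate matrix
#' @keywords internal
centroid_size <- function(x) {
  xc <- sweep(x, 2L, colMeans(x))
  sqrt(sum(xc^2))
}

#' Center a configuration at the origin
#' @keywords internal
center_config <- function(x) sweep(x, 2L, colMeans(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
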