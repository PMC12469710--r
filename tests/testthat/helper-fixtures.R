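# Shared fixtures, built in code.

# right-triangle configuration with known distances (3-4-5) plus an
# out-of-plane point so K >= 4 and the configuration is non-degenerate
triangle_coords <- function() {
  rbind(A = c(0, 0, 0), B = c(3, 0, 0), C = c(0, 4, 0), D = c(1, 1, 2))
}

triangle_config <- function(id = "t1", group = "WT") {
  landmark_config(id, group, triangle_coords())
}

# small standard template used across tests: 12 landmarks, 3 regions
test_template <- function(seed = 1) {
  build_template(12, c(midface = 4, neurocranium = 4, base = 4), seed = seed)
}

# brute-force pairwise distance oracle (double loop, independent of dist())
brute_force_distances <- function(coords) {
  k <- nrow(coords)
  out <- numeric(0)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    out <- c(out, sqrt(sum((coords[i, ] - coords[j, ])^2)))
  out
}

# random proper rotation built from Euler angles (independent of the
# package's QR-based sampler)
euler_rotation <- function(a, b, c) {
  rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# apply a random rigid motion (+ optional scaling) to a K x 3 matrix
rigid_copy <- function(coords, seed, scale = 1) {
  set.seed(seed)
  r <- euler_rotation(runif(1, 0, 2 * pi), runif(1, 0, pi), runif(1, 0, 2 * pi))
  out <- scale * coords %*% r
  sweep(out, 2, runif(3, -10, 10), `+`)
}
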