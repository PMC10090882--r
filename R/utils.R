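# Internal helpers shared across modules.

# A plane is a list(point = numeric(3), normal = numeric(3)) in world mm.
# Normals are stored unit length; the normal points toward the side a
# constraint *keeps* (see crop_main_airway()).

plane <- function(point, normal) {
  point <- as.numeric(point)
  normal <- as.numeric(normal)
  if (length(point) != 3 || length(normal) != 3) {
    abort("a plane needs a 3-vector `point` and `normal`", class = "nasallom_error_geometry")
  }
  nn <- sqrt(sum(normal^2))
  if (!is.finite(nn) || nn < .Machine$double.eps) {
    abort("plane normal must be a non-zero vector", class = "nasallom_error_geometry")
  }
  structure(list(point = point, normal = normal / nn), class = "nasallom_plane")
}

# signed distance of points (n x 3) from a plane; positive on the normal side
plane_signed_distance <- function(pts, pl) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  drop(sweep(pts, 2, pl$point) %*% pl$normal)
}

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(paste0("`", name, "` must be a single positive number"),
          class = "nasallom_error_config")
  }
  invisible(x)
}

assert_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort(paste0("`", name, "` must be non-negative"),
          class = "nasallom_error_config")
  }
  invisible(x)
}

# cross products for n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

triangle_areas <- function(v1, v2, v3) {
  cr <- cross3(v2 - v1, v3 - v1)
  0.5 * sqrt(rowSums(cr^2))
}
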