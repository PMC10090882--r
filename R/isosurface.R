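# Isosurface extraction from binary label masks.
#
# The binary mask is padded, optionally smoothed with a separable Gaussian
# (sigma in voxels), and triangulated by marching tetrahedra: each grid cell
# is split into six tetrahedra around its main diagonal and the 0.5 level
# set is interpolated on tetrahedron edges. On a smoothed field this
# recovers curved surface areas to well under 1% at feature radii of ~10
# voxels and above; on the raw binary field (the fallback for objects too
# small to survive smoothing) vertices sit at edge midpoints and the area
# carries a faceting constant (a single 1 mm voxel measures 3.62132 mm^2).

.cube_corner_offsets <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))

.cube_tets <- rbind(
  c(1, 2, 6, 8), c(1, 6, 5, 8), c(1, 5, 7, 8),
  c(1, 7, 3, 8), c(1, 3, 4, 8), c(1, 4, 2, 8))

# separable gaussian smoothing of a 3D array, sigma in voxels,
# edge-renormalised (kernel mass clamped into the grid)
smooth_field <- function(A, sigma) {
  if (sigma <= 0) return(A)
  d <- dim(A)
  band <- function(n) {
    h <- ceiling(3 * sigma)
    w <- dnorm(-h:h, sd = sigma)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmax(1, pmin(n, i + (-h:h)))
      for (t in seq_along(j)) K[i, j[t]] <- K[i, j[t]] + w[t]
    }
    K / rowSums(K)
  }
  A <- array(band(d[1]) %*% matrix(A, d[1]), d)
  A <- aperm(array(band(d[2]) %*% matrix(aperm(A, c(2, 1, 3)), d[2]),
                   c(d[2], d[1], d[3])), c(2, 1, 3))
  aperm(array(band(d[3]) %*% matrix(aperm(A, c(3, 1, 2)), d[3]),
              c(d[3], d[1], d[2])), c(2, 3, 1))
}

#' @importFrom stats dnorm
# marching tetrahedra: returns an n x 9 matrix of triangles
# (v1 xyz, v2 xyz, v3 xyz) in voxel-index coordinates
march_tetrahedra <- function(F3, level = 0.5) {
  d <- dim(F3)
  nx <- d[1] - 1L; ny <- d[2] - 1L; nz <- d[3] - 1L
  B <- F3 > level
  S <- array(0L, c(nx, ny, nz))
  for (c8 in 1:8) {
    o <- .cube_corner_offsets[c8, ]
    S <- S + B[(1 + o[1]):(nx + o[1]), (1 + o[2]):(ny + o[2]),
               (1 + o[3]):(nz + o[3])]
  }
  act <- which(S > 0L & S < 8L)
  if (!length(act)) return(matrix(0, 0, 9))
  ai <- arrayInd(act, c(nx, ny, nz))
  fv <- matrix(0, nrow(ai), 8)
  for (c8 in 1:8) {
    o <- .cube_corner_offsets[c8, ]
    fv[, c8] <- F3[cbind(ai[, 1] + o[1], ai[, 2] + o[2], ai[, 3] + o[3])]
  }
  out <- vector("list", 96)
  k <- 0
  pairs22 <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (t6 in 1:6) {
    cid <- .cube_tets[t6, ]
    f <- fv[, cid, drop = FALSE]
    b <- f > level
    s <- rowSums(b)
    P <- lapply(1:4, function(j) {
      o <- .cube_corner_offsets[cid[j], ]
      cbind(ai[, 1] + o[1], ai[, 2] + o[2], ai[, 3] + o[3])
    })
    ip <- function(i, j, rows) {
      tt <- (level - f[rows, i]) / (f[rows, j] - f[rows, i])
      P[[i]][rows, , drop = FALSE] * (1 - tt) + P[[j]][rows, , drop = FALSE] * tt
    }
    for (odd in 1:4) {
      rows <- which((s == 1 & b[, odd]) | (s == 3 & !b[, odd]))
      if (length(rows)) {
        oth <- setdiff(1:4, odd)
        k <- k + 1
        out[[k]] <- cbind(ip(odd, oth[1], rows), ip(odd, oth[2], rows),
                          ip(odd, oth[3], rows))
      }
    }
    for (pr in 1:6) {
      p <- pairs22[pr, ]; q <- setdiff(1:4, p)
      rows <- which(s == 2 & b[, p[1]] & b[, p[2]])
      if (length(rows)) {
        m11 <- ip(p[1], q[1], rows); m12 <- ip(p[1], q[2], rows)
        m21 <- ip(p[2], q[1], rows); m22 <- ip(p[2], q[2], rows)
        k <- k + 1; out[[k]] <- cbind(m11, m12, m22)
        k <- k + 1; out[[k]] <- cbind(m11, m22, m21)
      }
    }
  }
  do.call(rbind, out[seq_len(k)])
}

# deduplicate triangle-soup vertices into a vertex/face mesh
weld_triangles <- function(tri9, digits = 6) {
  V <- rbind(tri9[, 1:3, drop = FALSE], tri9[, 4:6, drop = FALSE],
             tri9[, 7:9, drop = FALSE])
  key <- paste(round(V[, 1], digits), round(V[, 2], digits),
               round(V[, 3], digits))
  first <- !duplicated(key)
  id <- match(key, key[first])
  ntri <- nrow(tri9)
  list(vertices = V[first, , drop = FALSE],
       faces = cbind(id[seq_len(ntri)], id[ntri + seq_len(ntri)],
                     id[2 * ntri + seq_len(ntri)]))
}

#' Extract the boundary surface mesh of a label
#'
#' The label's binary mask (zero-padded so surfaces close at the grid
#' border) is Gaussian-smoothed and the 0.5 isosurface extracted by
#' marching tetrahedra; if the object is too small for any part of the
#' smoothed field to exceed 0.5, the raw binary mask is triangulated
#' instead (vertices at voxel-edge midpoints).
#'
#' @param vol a [labeled_volume()].
#' @param label label name (or several, treated as their union).
#' @param sigma smoothing bandwidth in voxels; 0 disables smoothing.
#' @return a `surface_mesh`: list with `vertices` (n x 3 world mm) and
#'   `faces` (m x 3 vertex indices).
#' @export
label_isosurface <- function(vol, label, sigma = 0.9) {
  mask <- label_mask(vol, label)
  if (!any(mask)) {
    abort(paste0("label '", paste(label, collapse = "+"), "' is empty"),
          class = "nasallom_error_empty")
  }
  d <- dim(mask)
  padded <- array(0, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  tri <- matrix(0, 0, 9)
  if (sigma > 0) {
    tri <- march_tetrahedra(smooth_field(padded, sigma), 0.5)
  }
  if (!nrow(tri)) {
    tri <- march_tetrahedra(padded, 0.5)
  }
  m <- weld_triangles(tri)
  # padded index -> world: world = origin + (idx - 1 - 0.5) * spacing
  V <- sweep(sweep(m$vertices - 1.5, 2, vol$spacing, `*`), 2, vol$origin, `+`)
  structure(list(vertices = V, faces = m$faces), class = "surface_mesh")
}

#' Total triangle area of a surface mesh
#'
#' @param mesh a `surface_mesh` (or any list with `vertices`, `faces`).
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices; Fc <- mesh$faces
  sum(triangle_areas(V[Fc[, 1], , drop = FALSE], V[Fc[, 2], , drop = FALSE],
                     V[Fc[, 3], , drop = FALSE]))
}

#' Write a surface mesh as Wavefront OBJ
#'
#' @param mesh a `surface_mesh`.
#' @param path output `.obj` path.
#' @return `path`, invisibly.
#' @export
write_mesh_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_mesh_obj
#' @export
read_mesh_obj <- function(path) {
  ln <- readLines(path)
  vs <- ln[startsWith(ln, "v ")]
  fs <- ln[startsWith(ln, "f ")]
  V <- do.call(rbind, lapply(strsplit(vs, " +"), function(p)
    as.numeric(p[2:4])))
  Fc <- do.call(rbind, lapply(strsplit(fs, " +"), function(p)
    as.integer(sub("/.*", "", p[2:4]))))
  structure(list(vertices = V, faces = Fc), class = "surface_mesh")
}
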