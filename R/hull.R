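# 3D convex hull (quickhull) and hull volume.

# quickhull: returns list(faces = m x 3 indices into P, outward-oriented,
# volume). Errors on degenerate (collinear/coplanar) input.
quickhull3 <- function(P, tol = NULL) {
  P <- as.matrix(P)
  storage.mode(P) <- "double"
  n <- nrow(P)
  if (n < 4) {
    abort("convex hull needs at least 4 points",
          class = "nasallom_error_degenerate")
  }
  scale <- max(apply(P, 2, function(v) diff(range(v))), 1e-300)
  if (is.null(tol)) tol <- 1e-9 * max(scale, 1)

  ext <- unique(c(apply(P, 2, which.min), apply(P, 2, which.max)))
  dmax <- -1; a <- ext[1]; b <- ext[1]
  for (i in seq_along(ext)) for (j in seq_along(ext)) if (j > i) {
    dd <- sum((P[ext[i], ] - P[ext[j], ])^2)
    if (dd > dmax) { dmax <- dd; a <- ext[i]; b <- ext[j] }
  }
  if (dmax <= tol^2) {
    abort("degenerate hull input: points are (nearly) identical",
          class = "nasallom_error_degenerate")
  }
  ab <- P[b, ] - P[a, ]
  AP <- sweep(P, 2, P[a, ])
  cr <- cross3(AP, matrix(ab, n, 3, byrow = TRUE))
  d2l <- rowSums(cr^2)
  cpt <- which.max(d2l)
  if (sqrt(d2l[cpt]) / sqrt(sum(ab^2)) < tol) {
    abort("degenerate hull input: points are collinear",
          class = "nasallom_error_degenerate")
  }
  nrm <- cross3(matrix(ab, 1, 3), matrix(P[cpt, ] - P[a, ], 1, 3))[1, ]
  dh <- abs(AP %*% nrm) / sqrt(sum(nrm^2))
  dpt <- which.max(dh)
  if (dh[dpt] < tol) {
    abort("degenerate hull input: points are coplanar",
          class = "nasallom_error_degenerate")
  }

  init <- c(a, b, cpt, dpt)
  ctr <- colMeans(P[init, ])
  orient <- function(f) {
    nn <- cross3(matrix(P[f[2], ] - P[f[1], ], 1, 3),
                 matrix(P[f[3], ] - P[f[1], ], 1, 3))[1, ]
    if (sum(nn * (ctr - P[f[1], ])) > 0) f[c(1, 3, 2)] else f
  }
  fnorm <- function(f) {
    nn <- cross3(matrix(P[f[2], ] - P[f[1], ], 1, 3),
                 matrix(P[f[3], ] - P[f[1], ], 1, 3))[1, ]
    nn / sqrt(sum(nn^2))
  }
  faces <- rbind(c(a, b, cpt), c(a, b, dpt), c(a, cpt, dpt), c(b, cpt, dpt))
  faces <- t(apply(faces, 1, orient))
  N <- t(apply(faces, 1, fnorm))
  offs <- rowSums(N * P[faces[, 1], , drop = FALSE])
  alive <- rep(TRUE, 4)
  out <- vector("list", 4)
  cand <- setdiff(seq_len(n), init)
  if (length(cand)) {
    sd <- P[cand, , drop = FALSE] %*% t(N) -
      matrix(offs, length(cand), 4, byrow = TRUE)
    best <- max.col(sd)
    keep <- sd[cbind(seq_along(cand), best)] > tol
    for (fi in 1:4) out[[fi]] <- cand[keep & best == fi]
  }

  repeat {
    fi <- which(alive & vapply(out, length, 1L) > 0)[1]
    if (is.na(fi)) break
    pts <- out[[fi]]
    sd <- P[pts, , drop = FALSE] %*% N[fi, ] - offs[fi]
    p <- pts[which.max(sd)]
    alive_idx <- which(alive)
    vis <- alive_idx[(P[p, ] %*% t(N[alive_idx, , drop = FALSE]) -
                        offs[alive_idx]) > tol]
    ed <- do.call(rbind, lapply(vis, function(f) {
      fc <- faces[f, ]
      rbind(fc[c(1, 2)], fc[c(2, 3)], fc[c(3, 1)])
    }))
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    horizon <- ed[key %in% names(which(table(key) == 1)), , drop = FALSE]
    pool <- unique(unlist(out[vis]))
    pool <- pool[pool != p]
    alive[vis] <- FALSE
    for (v in vis) out[[v]] <- integer(0)
    for (r in seq_len(nrow(horizon))) {
      f <- orient(c(horizon[r, ], p))
      nn <- fnorm(f)
      faces <- rbind(faces, f)
      N <- rbind(N, nn)
      offs <- c(offs, sum(nn * P[f[1], ]))
      alive <- c(alive, TRUE)
      out <- c(out, list(integer(0)))
    }
    if (length(pool)) {
      newidx <- (nrow(faces) - nrow(horizon) + 1):nrow(faces)
      sd <- P[pool, , drop = FALSE] %*% t(N[newidx, , drop = FALSE]) -
        matrix(offs[newidx], length(pool), length(newidx), byrow = TRUE)
      best <- max.col(sd)
      keep <- sd[cbind(seq_along(pool), best)] > tol
      for (t in seq_along(newidx)) out[[newidx[t]]] <- pool[keep & best == t]
    }
  }
  faces <- faces[alive, , drop = FALSE]
  v1 <- sweep(P[faces[, 1], , drop = FALSE], 2, ctr)
  v2 <- sweep(P[faces[, 2], , drop = FALSE], 2, ctr)
  v3 <- sweep(P[faces[, 3], , drop = FALSE], 2, ctr)
  vol <- sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
             v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
             v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
  list(faces = faces, volume = abs(vol))
}

#' Volume of the minimum convex hull of a point cloud or mesh
#'
#' The hull is computed by quickhull over all input points (all mesh
#' vertices when a `surface_mesh` is given, matching a hull built over
#' every vertex of a skull surface). Adding interior points leaves the
#' result unchanged.
#'
#' @param x an n x 3 matrix/data frame of points (mm), or a `surface_mesh`.
#' @return hull volume in mm^3.
#' @examples
#' convex_hull_volume(as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2))))  # 8
#' @export
convex_hull_volume <- function(x) {
  pts <- if (inherits(x, "surface_mesh")) x$vertices else as.matrix(x)
  if (ncol(pts) != 3) {
    abort("points must have 3 columns", class = "nasallom_error_geometry")
  }
  quickhull3(pts)$volume
}
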