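# Independent oracles used to check the package implementations.
# These deliberately use different algorithms from the code under test.

# Brownian covariance by brute-force path enumeration: for each pair of
# tips, sum the lengths of the edges their root-to-tip paths share.
oracle_path_covariance <- function(tree) {
  ntip <- ape::Ntip(tree)
  parent <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    parent[tree$edge[i, 2]] <- tree$edge[i, 1]
    elen[tree$edge[i, 2]] <- tree$edge.length[i]
  }
  root <- ntip + 1L
  path_edges <- lapply(seq_len(ntip), function(tip) {
    nodes <- integer(0)
    nd <- tip
    while (nd != root) {
      nodes <- c(nodes, nd)   # edge identified by its child node
      nd <- parent[nd]
    }
    nodes
  })
  C <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) {
    for (j in seq_len(ntip)) {
      shared <- intersect(path_edges[[i]], path_edges[[j]])
      C[i, j] <- sum(elen[shared])
    }
  }
  C
}

# GLS by explicit inversion of C (no factorisation tricks)
oracle_gls <- function(x, y, C) {
  X <- cbind(1, x)
  Ci <- solve(C)
  beta <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# OLS by raw normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

random_ultrametric_tree <- function(n, depth = 10) {
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length * (depth / max(ape::node.depth.edgelength(tr)))
  tr
}

# subdivided icosphere with consistently outward-oriented faces
make_icosphere <- function(subdiv = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F0 <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    newF <- matrix(0L, 0, 3)
    midmap <- new.env()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(midmap[[key]])) return(midmap[[key]])
      m <- (V[i, ] + V[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      V <<- rbind(V, m)
      midmap[[key]] <- nrow(V)
      nrow(V)
    }
    for (f in seq_len(nrow(F0))) {
      i <- F0[f, 1]; j <- F0[f, 2]; k <- F0[f, 3]
      a <- midpoint(i, j); b <- midpoint(j, k); cc <- midpoint(k, i)
      newF <- rbind(newF, c(i, a, cc), c(j, b, a), c(k, cc, b), c(a, b, cc))
    }
    F0 <- newF
  }
  # enforce outward orientation face by face
  for (f in seq_len(nrow(F0))) {
    v1 <- V[F0[f, 1], ]; v2 <- V[F0[f, 2], ]; v3 <- V[F0[f, 3], ]
    nn <- c((v2 - v1)[2] * (v3 - v1)[3] - (v2 - v1)[3] * (v3 - v1)[2],
            (v2 - v1)[3] * (v3 - v1)[1] - (v2 - v1)[1] * (v3 - v1)[3],
            (v2 - v1)[1] * (v3 - v1)[2] - (v2 - v1)[2] * (v3 - v1)[1])
    if (sum(nn * (v1 + v2 + v3)) < 0) F0[f, ] <- F0[f, c(1, 3, 2)]
  }
  structure(list(vertices = V * radius, faces = F0), class = "surface_mesh")
}

# closed unit-cube mesh, consistently oriented outward
make_cube_mesh <- function(edge = 1) {
  V <- as.matrix(expand.grid(c(0, edge), c(0, edge), c(0, edge)))
  # vertices: 1(0,0,0) 2(e,0,0) 3(0,e,0) 4(e,e,0) 5(0,0,e) 6(e,0,e) 7(0,e,e) 8(e,e,e)
  Fc <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # bottom (z = 0), outward -z
    c(5, 6, 8), c(5, 8, 7),   # top
    c(1, 2, 6), c(1, 6, 5),   # y = 0
    c(3, 7, 8), c(3, 8, 4),   # y = e
    c(1, 5, 7), c(1, 7, 3),   # x = 0
    c(2, 4, 8), c(2, 8, 6))   # x = e
  structure(list(vertices = V, faces = Fc), class = "surface_mesh")
}

# small two-group dataset generator for test power/calibration checks
make_group_data <- function(n_per = 30, slope = c(1, 1), intercept = c(0, 0),
                            noise_sd = 0.05, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(2 * n_per, 0, 1)
    g <- rep(c("ectotherm", "endotherm"), each = n_per)
    sl <- ifelse(g == "endotherm", slope[1], slope[2])
    ic <- ifelse(g == "endotherm", intercept[1], intercept[2])
    tibble::tibble(species = paste0("s", seq_len(2 * n_per)),
                   thermo_class = g, x = x,
                   y = ic + sl * x + rnorm(2 * n_per, 0, noise_sd))
  })
}
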