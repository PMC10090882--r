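# Voxel and mesh morphometry: volumes, isosurface areas, hulls.

block_volume <- function(dims, at, size, spacing = c(1, 1, 1)) {
  g <- array(0L, dims)
  g[at[1]:(at[1] + size[1] - 1), at[2]:(at[2] + size[2] - 1),
    at[3]:(at[3] + size[3] - 1)] <- 2L
  labeled_volume(g, spacing = spacing)
}

test_that("label volumes are voxel counts times the voxel volume", {
  v <- block_volume(c(20, 20, 20), c(5, 5, 5), c(10, 10, 10))
  expect_equal(label_volume(v, "main_airway"), 1000)
  expect_equal(label_volume(v, "olfactory"), 0)   # present but absent
  expect_error(label_volume(v, "no_such_label"), class = "nasallom_error_label")
})

test_that("volumes are additive over disjoint labels and scale with spacing", {
  g <- array(0L, c(16, 16, 16))
  g[2:5, 2:5, 2:5] <- 2L
  g[9:14, 9:14, 9:14] <- 3L
  v1 <- labeled_volume(g)
  expect_identical(label_volume(v1, c("main_airway", "olfactory")),
                   label_volume(v1, "main_airway") +
                     label_volume(v1, "olfactory"))
  v2 <- labeled_volume(g, spacing = c(2, 2, 2))
  expect_identical(label_volume(v2, "main_airway"),
                   8 * label_volume(v1, "main_airway"))
  a1 <- label_surface_area(v1, "main_airway")
  a2 <- label_surface_area(v2, "main_airway")
  expect_equal(a2, 4 * a1, tolerance = 1e-9)
})

test_that("a voxelised sphere's isosurface area matches 4 pi r^2 within 3%", {
  r <- 15; n <- 2 * r + 11
  idx <- seq_len(n) - (n + 1) / 2
  d2 <- outer(outer(idx^2, idx^2, `+`), idx^2, `+`)
  v <- labeled_volume(array(2L * (d2 <= r^2), c(n, n, n)))
  expect_equal(label_surface_area(v, "main_airway"), 4 * pi * r^2,
               tolerance = 0.03)
  expect_equal(label_volume(v, "main_airway"), (4 / 3) * pi * r^3,
               tolerance = 0.01)
})

test_that("a single voxel measures the documented faceting constant", {
  g <- array(0L, c(5, 5, 5)); g[3, 3, 3] <- 2L
  a <- label_surface_area(labeled_volume(g), "main_airway")
  expect_gt(a, 1.5)
  expect_lt(a, 6.0)
  expect_equal(a, 3.62132, tolerance = 1e-5)   # frozen method constant
  expect_error(label_surface_area(labeled_volume(array(0L, c(5, 5, 5))),
                                  "main_airway"),
               class = "nasallom_error_empty")
})

test_that("areas of well-separated components add up", {
  g <- array(0L, c(40, 16, 16))
  g[3:6, 6:9, 6:9] <- 2L
  a_one <- label_surface_area(labeled_volume(g), "main_airway")
  g[30:33, 6:9, 6:9] <- 2L
  a_two <- label_surface_area(labeled_volume(g), "main_airway")
  expect_equal(a_two, 2 * a_one, tolerance = 1e-6)
})

test_that("mesh volume is exact on a cube and rejects open meshes", {
  cube <- make_cube_mesh(1)
  expect_equal(mesh_volume(cube), 1, tolerance = 1e-12)
  cube2 <- make_cube_mesh(3)
  expect_equal(mesh_volume(cube2), 27, tolerance = 1e-12)
  open <- cube
  open$faces <- open$faces[-1, ]
  expect_error(mesh_volume(open), class = "nasallom_error_mesh")
})

test_that("an icosphere's mesh volume converges to the ball volume", {
  ico <- make_icosphere(subdiv = 4, radius = 1)
  expect_equal(mesh_volume(ico), (4 / 3) * pi, tolerance = 0.005)
})

test_that("convex hull volume is exact on cubes and interior-invariant", {
  corners <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
  expect_equal(convex_hull_volume(corners), 8, tolerance = 1e-12)
  withr::with_seed(1, {
    interior <- matrix(runif(300) * 2, ncol = 3)
  })
  expect_equal(convex_hull_volume(rbind(corners, interior)), 8,
               tolerance = 1e-12)
})

test_that("hull volume of random tetrahedra equals the determinant formula", {
  withr::with_seed(42, {
    for (k in 1:20) {
      P <- matrix(rnorm(12), 4, 3)
      vol_det <- abs(det(cbind(P[2, ] - P[1, ], P[3, ] - P[1, ],
                               P[4, ] - P[1, ]))) / 6
      expect_equal(convex_hull_volume(P), vol_det, tolerance = 1e-10)
    }
  })
})

test_that("hull of two offset cubes matches a Monte-Carlo oracle", {
  cubes <- rbind(as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1))),
                 as.matrix(expand.grid(c(5, 6), c(0, 1), c(0, 1))))
  vol <- convex_hull_volume(cubes)
  # the hull is analytically the box [0,6] x [0,1] x [0,1]; Monte-Carlo
  # rejection sampling in an enclosing box estimates its volume
  withr::with_seed(7, {
    Q <- cbind(runif(1e5, -0.5, 6.5), runif(1e5, -0.25, 1.25),
               runif(1e5, -0.25, 1.25))
  })
  inside <- Q[, 1] >= 0 & Q[, 1] <= 6 & Q[, 2] >= 0 & Q[, 2] <= 1 &
    Q[, 3] >= 0 & Q[, 3] <= 1
  mc <- mean(inside) * 7 * 1.5 * 1.5
  expect_equal(vol, mc, tolerance = 0.01)
})

test_that("degenerate hull inputs are rejected", {
  expect_error(convex_hull_volume(matrix(rnorm(9), 3, 3)),
               class = "nasallom_error_degenerate")
  flat <- cbind(matrix(runif(40), 20, 2), 0)
  expect_error(convex_hull_volume(flat), class = "nasallom_error_degenerate")
})

test_that("measure_specimen recovers phantom truths within tolerance", {
  ph <- generate_skull_phantom(phantom_spec(grid_shape = c(64, 48, 48),
                                            cavity_semiaxes = c(18, 12, 10)))
  m <- measure_specimen(ph$volume)
  tr <- ph$truth
  expect_equal(m$nasal_vol_mm3, tr$cavity_vol, tolerance = 0.01)
  expect_equal(m$nasal_sa_mm2, tr$cavity_area, tolerance = 0.02)
  expect_equal(m$skull_vol_mm3, tr$bone_vol, tolerance = 1e-12)
  expect_equal(m$hull_vol_mm3, tr$outer_box_vol, tolerance = 0.02)
  expect_gte(m$hull_vol_mm3, m$skull_vol_mm3)
  expect_lte(m$resp_vol_mm3, m$nasal_vol_mm3)
})

test_that("with no olfactory part the nasal and respiratory measures agree", {
  sp <- phantom_spec(grid_shape = c(48, 40, 40), cavity_semiaxes = c(12, 9, 8))
  sp$split_plane <- landmark_plane(point = c(46, 20, 20), normal = c(1, 0, 0))
  ph <- generate_skull_phantom(sp)
  m <- measure_specimen(ph$volume)
  expect_identical(m$nasal_vol_mm3, m$resp_vol_mm3)
  expect_identical(m$nasal_sa_mm2, m$resp_sa_mm2)
})

test_that("meshes survive an OBJ round trip", {
  ico <- make_icosphere(subdiv = 1)
  p <- tempfile(fileext = ".obj")
  write_mesh_obj(ico, p)
  back <- read_mesh_obj(p)
  expect_equal(unname(back$vertices), unname(ico$vertices),
               tolerance = 1e-8)
  expect_equal(unname(back$faces), unname(ico$faces),
               ignore_attr = "storage.mode")
  expect_equal(mesh_volume(back), mesh_volume(ico), tolerance = 1e-7)
})
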