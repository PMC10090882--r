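# Constraint cropping, soft-tissue correction, fossil placement.

small_phantom <- function() {
  generate_skull_phantom(phantom_spec(grid_shape = c(64, 48, 48),
                                      cavity_semiaxes = c(18, 12, 10)))
}

test_that("landmarks at the extremes leave the cavity uncropped", {
  ph <- small_phantom()
  ext <- dim(ph$volume$grid) * ph$volume$spacing
  lm <- constraint_landmarks(
    nostril_plane = landmark_plane(c(0.1, 0, 0), c(1, 0, 0)),
    antrum_boundary = landmark_plane(c(0, 0, 0.1), c(0, 0, 1)),
    choana_plane = landmark_plane(c(ext[1] - 0.1, 0, 0), c(-1, 0, 0)),
    mesethmoid_point = c(ext[1] - 0.1, ext[2] / 2, ext[3] / 2))
  cr <- crop_main_airway(ph$volume, lm)
  expect_equal(label_volume(cr, "main_airway"),
               label_volume(ph$volume, c("main_airway", "olfactory")))
  expect_equal(label_volume(cr, "excluded"), 0)
})

test_that("a choana plane through the centre yields the analytic half", {
  ph <- small_phantom()
  va <- label_volume(crop_main_airway(ph$volume, ph$landmarks),
                     "main_airway")
  # voxelisation error at this resolution; the finer default phantom
  # reaches 0.5% (see the acceptance suite)
  expect_equal(va, ph$truth$main_airway_vol, tolerance = 0.01)
})

test_that("a choana rostral of the nostril empties the airway with a warning", {
  ph <- small_phantom()
  lm <- ph$landmarks
  ce <- dim(ph$volume$grid) / 2
  lm$nostril_plane <- landmark_plane(c(ce[1] + 5, 0, 0), c(1, 0, 0))
  lm$choana_plane <- landmark_plane(c(ce[1] - 5, 0, 0), c(-1, 0, 0))
  lm$interior_seed <- NULL
  expect_warning(cr <- crop_main_airway(ph$volume, lm),
                 "empty main airway")
  expect_equal(label_volume(cr, "main_airway"), 0)
})

test_that("cropping partitions the cavity and is monotone in constraints", {
  ph <- small_phantom()
  cavity <- label_volume(ph$volume, c("main_airway", "olfactory"))
  cr1 <- crop_main_airway(ph$volume, ph$landmarks)
  parts <- c(label_volume(cr1, "main_airway"), label_volume(cr1, "olfactory"),
             label_volume(cr1, "excluded"))
  expect_equal(sum(parts), cavity, tolerance = 1e-12)
  # tightening the nostril plane can only shrink the airway
  lm2 <- ph$landmarks
  ce <- dim(ph$volume$grid) / 2
  lm2$nostril_plane <- landmark_plane(c(ce[1] - 8, 0, 0), c(1, 0, 0))
  cr2 <- crop_main_airway(ph$volume, lm2)
  expect_lte(label_volume(cr2, "main_airway"),
             label_volume(cr1, "main_airway"))
  parts2 <- c(label_volume(cr2, "main_airway"), label_volume(cr2, "olfactory"),
              label_volume(cr2, "excluded"))
  expect_equal(sum(parts2), cavity, tolerance = 1e-12)
})

test_that("bad landmarks are rejected", {
  ph <- small_phantom()
  lm <- ph$landmarks
  lm$nostril_plane <- landmark_plane(c(-500, 0, 0), c(1, 0, 0))
  expect_error(crop_main_airway(ph$volume, lm),
               class = "nasallom_error_bounds")
  expect_error(landmark_plane(c(0, 0, 0), c(0, 0, 0)),
               class = "nasallom_error_geometry")
  lm2 <- ph$landmarks
  lm2$antrum_boundary <- landmark_plane(lm2$antrum_boundary$point,
                                        -lm2$antrum_boundary$normal)
  expect_error(crop_main_airway(ph$volume, lm2),
               class = "nasallom_error_geometry")
})

test_that("the soft-tissue correction maps volumes to the stated band", {
  expect_equal(soft_tissue_corrected_range(1000), c(lo = 400, hi = 600))
  expect_equal(soft_tissue_corrected_range(0), c(lo = 0, hi = 0))
  expect_error(soft_tissue_corrected_range(100, 0.7, 0.4),
               class = "nasallom_error_config")
  expect_error(soft_tissue_corrected_range(-5),
               class = "nasallom_error_config")
  # endpoints scale linearly with the bony volume
  v <- soft_tissue_corrected_range(123.4)
  expect_equal(soft_tissue_corrected_range(2 * 123.4), 2 * v)
})

test_that("mirrored bilateral components add", {
  expect_equal(add_mirrored_component(100, 0), 100)
  expect_equal(add_mirrored_component(100, 7), 107)
  expect_error(add_mirrored_component(100, -1),
               class = "nasallom_error_config")
})

make_fit <- function(slope, intercept) {
  nasallom:::new_allom_fit("PGLS", slope, intercept, 10, 0.95, 0.01,
                           diag(c(1e-4, 1e-4)), df_residual = 8)
}

test_that("the relative index is 0.5 at the midpoint and 1 on the endotherm line", {
  fe <- make_fit(1, 1)     # endotherm: y = 1 + x
  fc <- make_fit(1, 0)     # ectotherm: y = x
  x <- 2
  mid <- (predict(fe, x) + predict(fc, x)) / 2
  pl <- place_fossil(x, mid, fe, fc)
  expect_equal(pl$rho_bony, 0.5, tolerance = 1e-12)
  pl2 <- place_fossil(x, predict(fe, x), fe, fc)
  expect_equal(pl2$rho_bony, 1, tolerance = 1e-12)
  pl3 <- place_fossil(x, predict(fc, x), fe, fc)
  expect_equal(pl3$rho_bony, 0, tolerance = 1e-12)
})

test_that("exchanging the two lines flips the index", {
  fe <- make_fit(0.9, 1.2)
  fc <- make_fit(0.9, 0.4)
  pl <- place_fossil(3, 3.1, fe, fc)
  flipped <- place_fossil(3, 3.1, fc, fe)
  expect_equal(flipped$rho_bony, 1 - pl$rho_bony, tolerance = 1e-12)
})

test_that("corrected endpoints match a hand-computed oracle", {
  fe <- make_fit(1, 1)
  fc <- make_fit(1, 0)
  x <- 2
  # fossil sits on the ectotherm line, then y shifted by log10(0.5)
  y <- predict(fc, x) + log10(0.5)
  pl <- place_fossil(x, y, fe, fc)
  # upper corrected endpoint: y + log10(0.6); rho by hand
  rho_hi_oracle <- ((y + log10(0.6)) - predict(fc, x)) /
    (predict(fe, x) - predict(fc, x))
  expect_equal(pl$rho_hi, rho_hi_oracle, tolerance = 1e-10)
  rho_lo_oracle <- ((y + log10(0.4)) - predict(fc, x)) /
    (predict(fe, x) - predict(fc, x))
  expect_equal(pl$rho_lo, rho_lo_oracle, tolerance = 1e-10)
  expect_lte(pl$y_corrected_range[["hi"]], pl$y_bony)
})

test_that("coincident lines make the index undefined", {
  f <- make_fit(1, 1)
  expect_error(place_fossil(2, 3, f, f),
               class = "nasallom_error_degenerate")
})
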