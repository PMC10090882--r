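#' Specification of a voxel skull phantom
#'
#' The phantom stands in for a segmented head: a rectangular bone shell
#' (outer box minus inner air space) enclosing an axis-aligned ellipsoidal
#' cavity that a plane splits into a main-airway and an olfactory part.
#' Every measurement the morphometry stage makes on it has a closed-form
#' truth: ellipsoid volume `(4/3) * pi * a * b * c`, plane partitions by the
#' spherical-cap formula after rescaling the ellipsoid to the unit ball, and
#' surface area by the Thomsen approximation (p = 1.6075, error at most
#' about 1.1%).
#'
#' @param grid_shape voxels per axis (x, y, z).
#' @param spacing mm per voxel per axis.
#' @param margin gap (mm) between grid border and the outer skull box.
#' @param wall_thickness bone shell thickness in mm.
#' @param cavity_center ellipsoid centre in mm (world coordinates);
#'   default: grid centre.
#' @param cavity_semiaxes ellipsoid semi-axes (mm).
#' @param split_plane a plane (see [landmark_plane()]) partitioning the
#'   cavity; voxels on its normal side become olfactory. Default: a
#'   transverse plane through the cavity centre. With the default grid the
#'   centre falls on whole-millimetre coordinates, *between* voxel centres
#'   (which sit at half-millimetres), so no voxel centre lies exactly on
#'   the plane and the voxelised split matches the analytic slab.
#' @return list of class `nasallom_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(88, 68, 64),
                         spacing = c(1, 1, 1),
                         margin = 2,
                         wall_thickness = 3,
                         cavity_center = NULL,
                         cavity_semiaxes = c(26, 18, 16),
                         split_plane = NULL) {
  grid_shape <- as.integer(grid_shape)
  extent <- grid_shape * spacing
  if (is.null(cavity_center)) cavity_center <- extent / 2
  if (is.null(split_plane)) {
    split_plane <- plane(point = cavity_center, normal = c(1, 0, 0))
  }
  inner_lo <- rep(margin, 3) + wall_thickness
  inner_hi <- extent - margin - wall_thickness
  if (any(cavity_center - cavity_semiaxes <= inner_lo) ||
      any(cavity_center + cavity_semiaxes >= inner_hi)) {
    abort("cavity is not strictly inside the skull box",
          class = "nasallom_error_geometry")
  }
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 margin = margin, wall_thickness = wall_thickness,
                 cavity_center = as.numeric(cavity_center),
                 cavity_semiaxes = as.numeric(cavity_semiaxes),
                 split_plane = split_plane),
            class = "nasallom_phantom_spec")
}

#' Analytic ellipsoid surface area (Thomsen approximation)
#'
#' `4 * pi * ((a^p b^p + a^p c^p + b^p c^p) / 3)^(1/p)` with `p = 1.6075`;
#' relative error at most about 1.1% over all aspect ratios.
#'
#' @param semiaxes numeric length 3.
#' @export
ellipsoid_area_thomsen <- function(semiaxes) {
  p <- 1.6075
  a <- semiaxes[1]; b <- semiaxes[2]; cc <- semiaxes[3]
  4 * pi * (((a * b)^p + (a * cc)^p + (b * cc)^p) / 3)^(1 / p)
}

#' Analytic volume of an ellipsoid on one side of a plane
#'
#' Rescaling the ellipsoid to the unit ball turns the cut into a spherical
#' cap of height `h = 1 - t`, where `t` is the scaled signed distance of the
#' plane from the centre; the cap volume `(pi/3) h^2 (3 - h)` is then
#' multiplied back by `a b c`.
#'
#' @param semiaxes,center ellipsoid geometry (mm).
#' @param pl a plane; the volume on its *normal* side is returned.
#' @export
ellipsoid_plane_volume <- function(semiaxes, center, pl) {
  m <- pl$normal * semiaxes
  t <- sum(pl$normal * (pl$point - center)) / sqrt(sum(m^2))
  v_full <- (4 / 3) * pi * prod(semiaxes)
  if (t >= 1) return(0)
  if (t <= -1) return(v_full)
  h <- 1 - t
  prod(semiaxes) * pi * h^2 * (3 - h) / 3
}

#' Generate a voxel skull phantom with analytically known geometry
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [labeled_volume()]: background 0, bone 1,
#'   main_airway 2, olfactory 3), `landmarks` (a [constraint_landmarks()]
#'   set positioned for a no-op crop except the choana plane at the split),
#'   and `truth`, a tibble of analytic values: cavity/main/olfactory
#'   volumes, cavity area, bone volume, outer-box (hull) volume.
#' @export
generate_skull_phantom <- function(spec = phantom_spec()) {
  gs <- spec$grid_shape; sp <- spec$spacing
  cx <- (seq_len(gs[1]) - 0.5) * sp[1]
  cy <- (seq_len(gs[2]) - 0.5) * sp[2]
  cz <- (seq_len(gs[3]) - 0.5) * sp[3]
  X <- array(rep(cx, times = gs[2] * gs[3]), gs)
  Y <- array(rep(rep(cy, each = gs[1]), times = gs[3]), gs)
  Z <- array(rep(cz, each = gs[1] * gs[2]), gs)
  extent <- gs * sp
  lo <- rep(spec$margin, 3); hi <- extent - spec$margin
  ilo <- lo + spec$wall_thickness; ihi <- hi - spec$wall_thickness
  outer_box <- X > lo[1] & X < hi[1] & Y > lo[2] & Y < hi[2] &
    Z > lo[3] & Z < hi[3]
  inner_box <- X > ilo[1] & X < ihi[1] & Y > ilo[2] & Y < ihi[2] &
    Z > ilo[3] & Z < ihi[3]
  ce <- spec$cavity_center; ax <- spec$cavity_semiaxes
  cavity <- ((X - ce[1]) / ax[1])^2 + ((Y - ce[2]) / ax[2])^2 +
    ((Z - ce[3]) / ax[3])^2 <= 1
  grid <- array(0L, gs)
  grid[outer_box & !inner_box] <- 1L
  sd_split <- (X - spec$split_plane$point[1]) * spec$split_plane$normal[1] +
    (Y - spec$split_plane$point[2]) * spec$split_plane$normal[2] +
    (Z - spec$split_plane$point[3]) * spec$split_plane$normal[3]
  grid[cavity & sd_split < 0] <- 2L
  grid[cavity & sd_split >= 0] <- 3L
  vol <- labeled_volume(grid, spacing = sp)

  lm <- constraint_landmarks(
    nostril_plane = plane(point = c(ce[1] - ax[1] - sp[1], 0, 0),
                          normal = c(1, 0, 0)),
    antrum_boundary = plane(point = c(0, 0, ce[3] - ax[3] - sp[3]),
                            normal = c(0, 0, 1)),
    choana_plane = plane(point = spec$split_plane$point,
                         normal = -spec$split_plane$normal),
    mesethmoid_point = c(ce[1] + ax[1] + sp[1], ce[2], ce[3]),
    interior_seed = ce)

  v_cavity <- (4 / 3) * pi * prod(ax)
  v_olf <- ellipsoid_plane_volume(ax, ce, spec$split_plane)
  truth <- tibble::tibble(
    cavity_vol = v_cavity,
    main_airway_vol = v_cavity - v_olf,
    olfactory_vol = v_olf,
    cavity_area = ellipsoid_area_thomsen(ax),
    bone_vol = prod(hi - lo) - prod(ihi - ilo),
    outer_box_vol = prod(hi - lo))
  list(volume = vol, landmarks = lm, truth = truth)
}
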