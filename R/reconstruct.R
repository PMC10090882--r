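#' Osteological constraint landmarks
#'
#' The four spatial constraints used to carve the maximum main airway out
#' of a bony-bounded nasal cavity: (I) a plane at the rostralmost bony
#' nostril (the fleshy nostril sits there); (II) a boundary separating the
#' dorsal main passage from the maxillary antrum; (III) a transverse plane
#' at the caudal edge of the bony choana (the main airway does not extend
#' caudal to it); (IV) the rostral terminus of the mesethmoid's median
#' septum, capping the olfactory cavity caudally.
#'
#' All geometry is in the volume's world coordinates (mm). Plane normals
#' point toward the side that is *kept*: caudal for the nostril plane,
#' rostral for the choana plane, toward the airway for the antrum boundary
#' (validated against `interior_seed` when supplied).
#'
#' @param nostril_plane,antrum_boundary,choana_plane planes created with
#'   [landmark_plane()].
#' @param mesethmoid_point length-3 mm coordinate.
#' @param interior_seed optional point known to lie inside the main airway.
#' @return list of class `nasallom_landmarks`.
#' @export
constraint_landmarks <- function(nostril_plane, antrum_boundary, choana_plane,
                                 mesethmoid_point, interior_seed = NULL) {
  for (pl in list(nostril_plane, antrum_boundary, choana_plane)) {
    if (!inherits(pl, "nasallom_plane")) {
      abort("landmark planes must be built with landmark_plane()",
            class = "nasallom_error_geometry")
    }
  }
  if (length(mesethmoid_point) != 3) {
    abort("`mesethmoid_point` must be a 3-vector",
          class = "nasallom_error_geometry")
  }
  structure(list(nostril_plane = nostril_plane,
                 antrum_boundary = antrum_boundary,
                 choana_plane = choana_plane,
                 mesethmoid_point = as.numeric(mesethmoid_point),
                 interior_seed = if (is.null(interior_seed)) NULL
                                 else as.numeric(interior_seed)),
            class = "nasallom_landmarks")
}

#' @rdname constraint_landmarks
#' @param point,normal plane origin and normal (mm, world coordinates);
#'   the normal is normalised to unit length and must be non-zero.
#' @export
landmark_plane <- function(point, normal) plane(point, normal)

#' Write / read constraint landmarks as a JSON sidecar
#'
#' @param lm a [constraint_landmarks()] set.
#' @param path JSON file path.
#' @export
write_landmarks <- function(lm, path) {
  obj <- list(
    nostril_plane = list(point = lm$nostril_plane$point,
                         normal = lm$nostril_plane$normal),
    antrum_boundary = list(point = lm$antrum_boundary$point,
                           normal = lm$antrum_boundary$normal),
    choana_plane = list(point = lm$choana_plane$point,
                        normal = lm$choana_plane$normal),
    mesethmoid_point = lm$mesethmoid_point)
  if (!is.null(lm$interior_seed)) obj$interior_seed <- lm$interior_seed
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  constraint_landmarks(
    nostril_plane = plane(obj$nostril_plane$point, obj$nostril_plane$normal),
    antrum_boundary = plane(obj$antrum_boundary$point,
                            obj$antrum_boundary$normal),
    choana_plane = plane(obj$choana_plane$point, obj$choana_plane$normal),
    mesethmoid_point = obj$mesethmoid_point,
    interior_seed = obj$interior_seed)
}

#' Crop the maximum main airway out of a bony-bounded cavity
#'
#' Applies the four osteological constraints to the cavity voxels of a
#' labelled volume. A cavity voxel becomes *main airway* if it is caudal
#' of the nostril plane, on the airway (dorsal) side of the antrum
#' boundary, and rostral of the choana plane; voxels caudal of the choana
#' plane up to the mesethmoid cap (a transverse plane through
#' `mesethmoid_point`, the x axis being rostrocaudal) are relabelled
#' *olfactory*; everything else in the cavity is relabelled *excluded*
#' (label 4). The three output labels partition the input cavity exactly.
#'
#' @param vol a [labeled_volume()]; voxels carrying any of `cavity_labels`
#'   form the bony-bounded cavity.
#' @param lm a [constraint_landmarks()] set, in the volume's world
#'   coordinates and inside its bounds.
#' @param cavity_labels labels making up the input cavity.
#' @return a [labeled_volume()] with labels `main_airway` (2), `olfactory`
#'   (3) and `excluded` (4) partitioning the former cavity; other labels
#'   untouched. A warning is issued when the main airway comes out empty
#'   (e.g. a choana plane rostral of the nostril plane).
#' @export
crop_main_airway <- function(vol, lm,
                             cavity_labels = c("main_airway", "olfactory")) {
  stopifnot(inherits(vol, "labeled_volume"),
            inherits(lm, "nasallom_landmarks"))
  bounds_lo <- vol$origin
  bounds_hi <- vol$origin + dim(vol$grid) * vol$spacing
  pts <- rbind(lm$nostril_plane$point, lm$antrum_boundary$point,
               lm$choana_plane$point, lm$mesethmoid_point)
  if (any(t(pts) < bounds_lo - 1e-9) || any(t(pts) > bounds_hi + 1e-9)) {
    abort("landmark outside the volume bounds",
          class = "nasallom_error_bounds")
  }
  antrum <- lm$antrum_boundary
  if (!is.null(lm$interior_seed)) {
    if (plane_signed_distance(matrix(lm$interior_seed, 1), antrum) < 0) {
      abort(paste("antrum boundary normal points away from the airway",
                  "interior seed; flip the normal"),
            class = "nasallom_error_geometry")
    }
  }
  present <- cavity_labels[cavity_labels %in% names(vol$labels)]
  mask <- label_mask(vol, present)
  if (!any(mask)) {
    abort("no cavity voxels to crop", class = "nasallom_error_empty")
  }
  idx <- which(mask)
  W <- mask_world_coords(vol, mask)
  d_nostril <- plane_signed_distance(W, lm$nostril_plane)
  d_antrum <- plane_signed_distance(W, antrum)
  d_choana <- plane_signed_distance(W, lm$choana_plane)
  main <- d_nostril >= 0 & d_antrum >= 0 & d_choana >= 0
  olf <- !main & d_choana < 0 & W[, 1] <= lm$mesethmoid_point[1]
  grid <- vol$grid
  grid[idx] <- 4L
  grid[idx[olf]] <- 3L
  grid[idx[main]] <- 2L
  if (!any(main)) {
    warn("constraint cropping produced an empty main airway")
  }
  labels <- vol$labels
  labels <- labels[setdiff(names(labels), c("main_airway", "olfactory",
                                            "excluded"))]
  labels <- c(labels, c(main_airway = 2L, olfactory = 3L, excluded = 4L))
  labeled_volume(grid, spacing = vol$spacing, origin = vol$origin,
                 labels = labels)
}

#' Soft-tissue correction of a bony-bounded airway volume
#'
#' In extant diapsids the soft-tissue airway occupies roughly 40--60% of
#' the bony-bounded nasal passage, so a bony volume maps to the interval
#' `(lo * V, hi * V)`.
#'
#' @param bony_volume volume in mm^3 (non-negative).
#' @param fraction_lo,fraction_hi fraction bounds, `0 < lo <= hi <= 1`.
#' @return named numeric vector `c(lo = , hi = )` in mm^3.
#' @examples
#' soft_tissue_corrected_range(1000)  # 400, 600
#' @export
soft_tissue_corrected_range <- function(bony_volume, fraction_lo = 0.40,
                                        fraction_hi = 0.60) {
  assert_nonnegative(bony_volume, "bony_volume")
  if (fraction_lo <= 0 || fraction_hi > 1 || fraction_lo > fraction_hi) {
    abort("need 0 < fraction_lo <= fraction_hi <= 1",
          class = "nasallom_error_config")
  }
  c(lo = fraction_lo * bony_volume, hi = fraction_hi * bony_volume)
}

#' Add the mirrored volume of a missing bilateral element
#'
#' For a fossil skull missing bones on one side, the measured volume of the
#' preserved antimeres is added to the total.
#'
#' @param measured_volume,component_volume volumes in mm^3, non-negative.
#' @return their sum.
#' @export
add_mirrored_component <- function(measured_volume, component_volume) {
  assert_nonnegative(measured_volume, "measured_volume")
  assert_nonnegative(component_volume, "component_volume")
  measured_volume + component_volume
}

#' Place a fossil relative to the endotherm and ectotherm lines
#'
#' The relative index `rho = (y - yhat_ecto) / (yhat_endo - yhat_ecto)`
#' locates a point between the two fitted lines at its size `x`: 0 on the
#' ectotherm line, 1 on the endotherm line, 0.5 exactly midway. `rho` is
#' computed for the bony-bounded value and for both endpoints of the
#' soft-tissue corrected range (computed in log10 space, the plotting
#' space).
#'
#' @param x log10 size proxy of the fossil.
#' @param y log10 bony-bounded airway volume.
#' @param fit_endo,fit_ecto `allom_fit`s of the two groups.
#' @param fraction_lo,fraction_hi soft-tissue fractions (see
#'   [soft_tissue_corrected_range()]).
#' @param level coverage of the attached per-group prediction intervals.
#' @return object of class `fossil_placement`; [tidy()] gives a one-row
#'   tibble with `rho_bony`, `rho_lo`, `rho_hi` and predictions.
#' @export
place_fossil <- function(x, y, fit_endo, fit_ecto,
                         fraction_lo = 0.40, fraction_hi = 0.60,
                         level = 0.95) {
  yhat_e <- predict(fit_endo, x)
  yhat_c <- predict(fit_ecto, x)
  if (abs(yhat_e - yhat_c) < 1e-12 * max(1, abs(yhat_e))) {
    abort("fitted lines coincide at x; relative index undefined",
          class = "nasallom_error_degenerate")
  }
  rho <- function(yy) (yy - yhat_c) / (yhat_e - yhat_c)
  rng <- soft_tissue_corrected_range(10^y, fraction_lo, fraction_hi)
  y_lo <- log10(rng[["lo"]])
  y_hi <- log10(rng[["hi"]])
  pred_int <- function(fit) {
    if (is.null(fit$vcov) || anyNA(fit$vcov)) return(c(NA_real_, NA_real_))
    xv <- c(1, x)
    se <- sqrt(drop(t(xv) %*% fit$vcov %*% xv) + fit$sigma2)
    tq <- qt(1 - (1 - level) / 2, max(fit$df_residual, 1))
    predict(fit, x) + c(-1, 1) * tq * se
  }
  structure(list(
    x = x, y_bony = y, y_corrected_range = c(lo = y_lo, hi = y_hi),
    predicted_endo = yhat_e, predicted_ecto = yhat_c,
    rho_bony = rho(y), rho_lo = rho(y_lo), rho_hi = rho(y_hi),
    pi_endo = pred_int(fit_endo), pi_ecto = pred_int(fit_ecto),
    level = level), class = "fossil_placement")
}

#' @export
print.fossil_placement <- function(x, ...) {
  cat(sprintf("<fossil_placement> x = %.3f, bony y = %.3f\n", x$x, x$y_bony))
  cat(sprintf("  rho (0 = ectotherm line, 1 = endotherm line): %.3f\n",
              x$rho_bony))
  cat(sprintf("  soft-tissue corrected y: [%.3f, %.3f] -> rho [%.3f, %.3f]\n",
              x$y_corrected_range[1], x$y_corrected_range[2],
              x$rho_lo, x$rho_hi))
  invisible(x)
}

#' Tidy a fossil placement
#'
#' @param x a `fossil_placement`.
#' @param ... unused.
#' @method tidy fossil_placement
#' @export
tidy.fossil_placement <- function(x, ...) {
  pl <- x   # a column below is also named `x`; avoid data-mask capture
  tibble::tibble(
    x = pl$x, y_bony = pl$y_bony,
    y_corrected_lo = pl$y_corrected_range[["lo"]],
    y_corrected_hi = pl$y_corrected_range[["hi"]],
    predicted_endo = pl$predicted_endo, predicted_ecto = pl$predicted_ecto,
    rho_bony = pl$rho_bony, rho_lo = pl$rho_lo, rho_hi = pl$rho_hi)
}
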