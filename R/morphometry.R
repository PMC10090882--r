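#' Volume of a label region
#'
#' Voxel count times the spacing product. Exact for the voxelised region;
#' zero for labels present in the table but absent from the grid.
#'
#' @param vol a [labeled_volume()].
#' @param label label name (or several, treated as their union).
#' @return volume in mm^3.
#' @export
label_volume <- function(vol, label) {
  sum(label_mask(vol, label)) * prod(vol$spacing)
}

#' Surface area of a label region
#'
#' Area of the triangulated isosurface of the label's boundary (see
#' [label_isosurface()]); spacing-aware and computed on a smoothed field,
#' matching how segmentation packages measure areas of curved structures
#' (raw voxel-face counting would overestimate them by up to ~50%).
#'
#' @inheritParams label_volume
#' @param sigma smoothing bandwidth in voxels passed to
#'   [label_isosurface()].
#' @return area in mm^2.
#' @export
label_surface_area <- function(vol, label, sigma = 0.9) {
  mesh_area(label_isosurface(vol, label, sigma = sigma))
}

#' Volume enclosed by a closed triangle mesh
#'
#' Absolute value of the signed tetrahedron sum over faces, so the result
#' does not depend on whether the mesh is oriented inward or outward --
#' but it must be closed and consistently oriented (every directed edge
#' used exactly once).
#'
#' @param mesh a `surface_mesh` (list with `vertices`, `faces`).
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; Fc <- mesh$faces
  ed <- rbind(Fc[, 1:2], Fc[, 2:3], Fc[, c(3, 1)])
  dir_key <- paste(ed[, 1], ed[, 2])
  rev_key <- paste(ed[, 2], ed[, 1])
  if (anyDuplicated(dir_key) || !all(dir_key %in% rev_key)) {
    abort("mesh is not watertight (or not consistently oriented)",
          class = "nasallom_error_mesh")
  }
  v1 <- V[Fc[, 1], , drop = FALSE]
  v2 <- V[Fc[, 2], , drop = FALSE]
  v3 <- V[Fc[, 3], , drop = FALSE]
  abs(sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
          v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
          v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6)
}

#' Measure the size parameters of one labelled head volume
#'
#' Computes the per-specimen size parameters: skull volume (bone label),
#' convex-hull head-model volume (hull of the bone isosurface vertices),
#' whole nasal cavity surface area and volume (union of the main-airway and
#' olfactory labels), and respiratory-region area and volume (main airway
#' only).
#'
#' @param vol a [labeled_volume()] with a `bone` label and at least one of
#'   `main_airway` / `olfactory`.
#' @param sigma isosurface smoothing bandwidth (voxels).
#' @return one-row tibble with columns `skull_vol_mm3`, `hull_vol_mm3`,
#'   `nasal_sa_mm2`, `nasal_vol_mm3`, `resp_sa_mm2`, `resp_vol_mm3`.
#' @export
measure_specimen <- function(vol, sigma = 0.9) {
  if (!"bone" %in% names(vol$labels) || !any(label_mask(vol, "bone"))) {
    abort("volume has no (non-empty) 'bone' label",
          class = "nasallom_error_label")
  }
  cavity_labels <- intersect(c("main_airway", "olfactory"), names(vol$labels))
  present <- cavity_labels[vapply(cavity_labels,
                                  function(l) any(label_mask(vol, l)),
                                  logical(1))]
  if (!length(present)) {
    abort("volume has no non-empty cavity label",
          class = "nasallom_error_label")
  }
  bone_mesh <- label_isosurface(vol, "bone", sigma = sigma)
  has_olf <- "olfactory" %in% present
  tibble::tibble(
    skull_vol_mm3 = label_volume(vol, "bone"),
    hull_vol_mm3 = convex_hull_volume(bone_mesh),
    nasal_sa_mm2 = label_surface_area(vol, present, sigma = sigma),
    nasal_vol_mm3 = label_volume(vol, present),
    resp_sa_mm2 = if ("main_airway" %in% present)
      label_surface_area(vol, "main_airway", sigma = sigma) else 0,
    resp_vol_mm3 = label_volume(vol, "main_airway")
  )
}
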