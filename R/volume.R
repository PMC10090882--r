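#' Labelled voxel volume
#'
#' A 3D integer label grid with anisotropic voxel spacing. Axes are ordered
#' (x, y, z) with x rostrocaudal by convention. Voxel indices are 0-based in
#' world terms: the centre of grid cell `[i, j, k]` (1-based R indices) lies
#' at `origin + (c(i, j, k) - 0.5) * spacing`.
#'
#' @param grid 3D integer array of labels (non-negative).
#' @param spacing voxel edge lengths in mm, length 3, all positive.
#' @param origin world offset in mm, length 3.
#' @param labels named integer vector mapping label names to grid values;
#'   defaults to the package convention `background = 0, bone = 1,
#'   main_airway = 2, olfactory = 3`.
#' @return object of class `labeled_volume`.
#' @export
labeled_volume <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                           labels = c(background = 0L, bone = 1L,
                                      main_airway = 2L, olfactory = 3L)) {
  if (length(dim(grid)) != 3) {
    abort("`grid` must be a 3D array", class = "nasallom_error_geometry")
  }
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive numbers",
          class = "nasallom_error_geometry")
  }
  if (any(grid < 0)) {
    abort("labels must be non-negative", class = "nasallom_error_geometry")
  }
  storage.mode(grid) <- "integer"
  structure(list(grid = grid, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 labels = labels),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat("<labeled_volume> ", paste(dim(x$grid), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 3), collapse = " x "),
      " mm\n", sep = "")
  tb <- table(x$grid)
  known <- setNames(names(x$labels), x$labels)
  nm <- ifelse(names(tb) %in% names(known), known[names(tb)], names(tb))
  cat("  labels:", paste0(nm, "=", as.integer(tb), collapse = ", "), "\n")
  invisible(x)
}

label_value <- function(vol, label) {
  if (is.numeric(label)) return(as.integer(label))
  if (!label %in% names(vol$labels)) {
    abort(paste0("unknown label '", label, "'"),
          class = "nasallom_error_label")
  }
  as.integer(vol$labels[[label]])
}

label_mask <- function(vol, label) {
  vals <- vapply(label, label_value, integer(1), vol = vol)
  array(vol$grid %in% vals, dim(vol$grid))
}

# world coordinates of voxel centres along one axis
axis_centers <- function(vol, axis) {
  n <- dim(vol$grid)[axis]
  vol$origin[axis] + (seq_len(n) - 0.5) * vol$spacing[axis]
}

# n_voxel x 3 world coordinates for a logical mask (used by cropping)
mask_world_coords <- function(vol, mask) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(sweep(idx - 0.5, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

#' Write / read a labelled volume as NIfTI plus a JSON label table
#'
#' The grid goes to a `.nii` file (spacing in the pixdim header, origin in
#' the sform translation); the label table goes to a sidecar
#' `<path>.labels.json`.
#'
#' @param vol a [labeled_volume()].
#' @param path output path ending in `.nii` (or `.nii.gz`).
#' @return `path`, invisibly (write); a [labeled_volume()] (read).
#' @export
write_labeled_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$grid)
  RNifti::pixdim(img) <- vol$spacing
  xf <- diag(c(vol$spacing, 1))
  xf[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(as.list(vol$labels), paste0(path, ".labels.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_labeled_volume
#' @export
read_labeled_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4]
  lab_path <- paste0(path, ".labels.json")
  labels <- if (file.exists(lab_path)) {
    unlist(jsonlite::read_json(lab_path))
  } else {
    c(background = 0L, bone = 1L, main_airway = 2L, olfactory = 3L)
  }
  labeled_volume(array(as.integer(img), dim(img)[1:3]), spacing = spacing,
                 origin = origin, labels = setNames(as.integer(labels),
                                                    names(labels)))
}
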