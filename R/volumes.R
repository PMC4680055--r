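# Label-volume data model, NIfTI I/O, scheme merging and component masks.

#' Construct a label volume
#'
#' A label volume is a 3D integer label grid together with its physical
#' voxel spacing in millimetres and a label scheme: `"raw"` for the
#' eight-structure annotation scheme (1 cortical GM, 2 basal ganglia,
#' 3 WM, 4 WM lesions, 5 peripheral CSF, 6 lateral ventricles,
#' 7 cerebellum, 8 brainstem) or `"tissue"` for the merged three-class
#' scheme (1 GM, 2 WM, 3 CSF) that is actually scored.
#'
#' The voxel with (1-based) array index `(i, j, k)` has physical center
#' `((i-1) dx, (j-1) dy, (k-1) dz)`. Orientation information beyond the
#' spacing is deliberately ignored: candidate and reference are assumed
#' to live on a common registered grid and are compared voxel by voxel.
#'
#' @param grid 3D array of integer (or integer-valued numeric) labels.
#' @param spacing numeric length-3 voxel spacing `(dx, dy, dz)` in mm,
#'   all entries positive.
#' @param scheme `"raw"`, `"tissue"`, or `NULL` to infer from the label
#'   set (any label above 3 implies `"raw"`).
#' @return an object of class `label_volume` with fields `grid`,
#'   `spacing` and `scheme`.
#' @export
label_volume <- function(grid, spacing, scheme = NULL) {
  if (length(dim(grid)) != 3L)
    stop("`grid` must be a 3D array, got ", length(dim(grid)), " dimensions")
  if (any(dim(grid) < 1L)) stop("grid dimensions must all be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite numbers (mm)")
  if (anyNA(grid)) stop("label grid contains missing values")
  g <- as.vector(grid)
  if (!is.integer(g)) {
    gi <- round(g)
    if (max(abs(g - gi)) > 1e-6)
      stop("voxel values are not integer labels (deviation above 1e-6)")
    g <- as.integer(gi)
  }
  labs <- sort(unique(g))
  if (is.null(scheme)) scheme <- if (any(labs > 3L)) "raw" else "tissue"
  scheme <- match.arg(scheme, c("raw", "tissue"))
  allowed <- if (scheme == "raw") RAW_LABELS else TISSUE_LABELS
  bad <- setdiff(labs, allowed)
  if (length(bad))
    stop(sprintf("labels {%s} are outside the '%s' scheme",
                 paste(bad, collapse = ","), scheme))
  structure(
    list(grid = array(g, dim(grid)), spacing = spacing, scheme = scheme),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s scheme, %s voxels at (%s) mm, labels {%s}\n",
              x$scheme, paste(dim(x$grid), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(sort(unique(as.vector(x$grid))), collapse = ",")))
  invisible(x)
}

#' Read a label volume from NIfTI
#'
#' Reads a `.nii` or `.nii.gz` file, checks that voxel values are
#' integer labels (values within 1e-6 of an integer are rounded; larger
#' deviations are an error, guarding against probabilistic maps passed
#' by mistake), and takes the voxel spacing from the header pixdim
#' fields.
#'
#' @param path path to a NIfTI file holding a 3D label map.
#' @param scheme optional scheme override; by default inferred from the
#'   label set.
#' @return a [label_volume].
#' @export
read_label_volume <- function(path, scheme = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1L, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop("expected a 3D label map in ", path, ", got dims ",
         paste(dim(arr), collapse = "x"))
  sp <- RNifti::pixdim(img)[1:3]
  label_volume(arr, sp, scheme = scheme)
}

#' Write a label volume to NIfTI
#'
#' @param vol a [label_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  img <- RNifti::asNifti(vol$grid)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct a component mask
#'
#' @param grid 3D logical array.
#' @param spacing voxel spacing in mm.
#' @param component one of `"GM"`, `"WM"`, `"CSF"`, `"brain"`, `"ICV"`,
#'   `"WML"`, `"excluded"`.
#' @return an object of class `component_mask`.
#' @export
component_mask_new <- function(grid, spacing, component) {
  if (length(dim(grid)) != 3L) stop("`grid` must be a 3D array")
  component <- match.arg(component, c(COMPONENTS, "WML", "excluded"))
  structure(
    list(grid = array(as.logical(grid), dim(grid)),
         spacing = as.numeric(spacing), component = component),
    class = "component_mask"
  )
}

#' @export
print.component_mask <- function(x, ...) {
  cat(sprintf("<component_mask> %s, %d/%d voxels true, (%s) mm\n",
              x$component, sum(x$grid), length(x$grid),
              paste(format(x$spacing), collapse = ", ")))
  invisible(x)
}

#' Merge the raw annotation scheme into scored tissue classes
#'
#' Cortical gray matter and basal ganglia (raw 1, 2) become GM (1);
#' white matter and white matter lesions (raw 3, 4) become WM (2);
#' peripheral CSF and lateral ventricles (raw 5, 6) become CSF (3).
#' Cerebellum and brainstem (raw 7, 8) are excluded from all evaluation:
#' they map to background and are returned as an exclusion mask that is
#' applied to both reference and candidate before any metric.
#'
#' @param raw a raw-scheme [label_volume].
#' @return a list with `tissue` (tissue-scheme [label_volume]) and
#'   `excluded` ([component_mask] of cerebellum + brainstem voxels).
#' @export
merge_to_tissue <- function(raw) {
  stopifnot(inherits(raw, "label_volume"))
  if (raw$scheme != "raw")
    stop("merge_to_tissue() expects a raw-scheme volume")
  tis <- array(RAW_TO_TISSUE[raw$grid + 1L], dim(raw$grid))
  excl <- array(raw$grid %in% EXCLUDED_RAW, dim(raw$grid))
  list(
    tissue = label_volume(tis, raw$spacing, scheme = "tissue"),
    excluded = component_mask_new(excl, raw$spacing, "excluded")
  )
}

#' Binary mask of one evaluated component
#'
#' Components are built from tissue labels: GM = \{1\}, WM = \{2\},
#' CSF = \{3\}, brain = GM + WM, ICV (intracranial volume) =
#' GM + WM + CSF. Voxels in the exclusion mask (cerebellum/brainstem in
#' the reference) are removed from every component.
#'
#' @param tissue a tissue-scheme [label_volume].
#' @param component one of `"GM"`, `"WM"`, `"CSF"`, `"brain"`, `"ICV"`.
#' @param excluded optional exclusion [component_mask] of the same shape.
#' @return a [component_mask].
#' @export
component_mask <- function(tissue, component, excluded = NULL) {
  stopifnot(inherits(tissue, "label_volume"))
  if (tissue$scheme != "tissue")
    stop("component_mask() expects a tissue-scheme volume; ",
         "merge raw volumes first")
  component <- match.arg(component, COMPONENTS)
  m <- array(tissue$grid %in% COMPONENT_LABELS[[component]], dim(tissue$grid))
  if (!is.null(excluded)) {
    stopifnot(inherits(excluded, "component_mask"))
    if (!identical(dim(excluded$grid), dim(tissue$grid)))
      stop("exclusion mask shape does not match the volume")
    m <- m & !excluded$grid
  }
  component_mask_new(m, tissue$spacing, component)
}

# shared validation: same grid shape and (within tolerance) same spacing
check_same_grid <- function(a, b, what = "inputs") {
  da <- dim(a$grid); db <- dim(b$grid)
  if (!identical(da, db))
    stop(sprintf("%s have different shapes (%s vs %s)", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  if (max(abs(a$spacing - b$spacing)) > 1e-4)
    stop(sprintf("%s have different voxel spacings", what))
  invisible(TRUE)
}
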