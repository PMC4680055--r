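# Synthetic raw-scheme brain-like label volumes (nested ellipsoids) and
# controlled corruptions, so the whole evaluation pipeline is testable
# without clinical data. Geometry is topological, not anatomical: what
# matters is the nesting (CSF shell > GM shell > WM core), the interior
# structures (ventricles, basal ganglia, lesions) and the presence of an
# excluded hindbrain blob — not realism.

#' Specify a synthetic brain phantom
#'
#' The phantom is built from nested ellipsoids on an anisotropic grid
#' whose defaults (128 x 128 x 48 voxels at 0.96 x 0.96 x 3.00 mm)
#' mirror thick-slice 3T acquisitions, so anisotropy errors surface in
#' tests. From outside in: peripheral CSF shell (raw label 5), cortical
#' GM shell (1), WM core (3); inside the WM core sit two lateral
#' ventricles (6), two basal ganglia blobs (2) and randomly placed WM
#' lesion blobs (4). An inferior blob outside the ICV is split into
#' cerebellum (7) and brainstem (8). All randomness (lesion placement)
#' is fixed by `seed`.
#'
#' @param dims grid size `(nx, ny, nz)` in voxels.
#' @param spacing voxel spacing `(dx, dy, dz)` in mm.
#' @param center_frac phantom centre as fractions of the physical grid
#'   extent.
#' @param icv_semiaxes semi-axes (mm) of the outer (intracranial)
#'   ellipsoid.
#' @param csf_thickness,gm_thickness thickness (mm) of the peripheral
#'   CSF and cortical GM shells; the WM core semi-axes are
#'   `icv_semiaxes - csf_thickness - gm_thickness` and must stay
#'   positive.
#' @param ventricle_semiaxes,ventricle_offset semi-axes (mm) and +/- x
#'   offset (mm) of the two lateral-ventricle ellipsoids.
#' @param bg_semiaxes,bg_offset semi-axes and +/- x offset (mm) of the
#'   two basal-ganglia blobs (placed just lateral to the ventricles).
#' @param n_wml number of white-matter-lesion blobs.
#' @param wml_radius_range min/max lesion radius in mm.
#' @param hind_center_frac,hind_semiaxes centre fractions and semi-axes
#'   (mm) of the inferior cerebellum/brainstem blob.
#' @param seed integer seed fixing all randomness.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(128L, 128L, 48L),
                         spacing = c(0.96, 0.96, 3.0),
                         center_frac = c(0.5, 0.5, 0.45),
                         icv_semiaxes = c(52, 55, 55),
                         csf_thickness = 6,
                         gm_thickness = 8,
                         ventricle_semiaxes = c(7, 20, 10),
                         ventricle_offset = 11,
                         bg_semiaxes = c(8, 11, 8),
                         bg_offset = 24,
                         n_wml = 6L,
                         wml_radius_range = c(2, 4),
                         hind_center_frac = c(0.5, 0.58, 0.90),
                         hind_semiaxes = c(28, 22, 11),
                         seed = 1L) {
  spec <- list(dims = as.integer(dims), spacing = as.numeric(spacing),
               center_frac = center_frac, icv_semiaxes = icv_semiaxes,
               csf_thickness = csf_thickness, gm_thickness = gm_thickness,
               ventricle_semiaxes = ventricle_semiaxes,
               ventricle_offset = ventricle_offset,
               bg_semiaxes = bg_semiaxes, bg_offset = bg_offset,
               n_wml = as.integer(n_wml),
               wml_radius_range = as.numeric(wml_radius_range),
               hind_center_frac = hind_center_frac,
               hind_semiaxes = hind_semiaxes, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (length(s$dims) != 3L || any(s$dims < 8L))
    stop("phantom grid must be 3D with at least 8 voxels per axis")
  if (any(s$spacing <= 0)) stop("spacing must be positive")
  wm <- s$icv_semiaxes - s$csf_thickness - s$gm_thickness
  if (any(wm <= 0))
    stop("shell thicknesses exceed the ICV semi-axes: ",
         "WM core would be empty")
  extent <- (s$dims - 1L) * s$spacing
  ctr <- s$center_frac * extent
  if (any(ctr - s$icv_semiaxes < -1e-9) ||
      any(ctr + s$icv_semiaxes > extent + 1e-9))
    stop("ICV ellipsoid does not fit inside the grid")
  if (s$wml_radius_range[1] > s$wml_radius_range[2] ||
      s$wml_radius_range[1] <= 0)
    stop("invalid lesion radius range")
  if (s$n_wml < 1L) stop("need at least one lesion blob")
  invisible(s)
}

# logical array: voxels whose physical centre lies inside the ellipsoid
ellipsoid_grid <- function(dims, spacing, center, semiaxes) {
  e <- lapply(1:3, function(ax)
    (((0:(dims[ax] - 1L)) * spacing[ax] - center[ax]) / semiaxes[ax])^2)
  outer(outer(e[[1]], e[[2]], `+`), e[[3]], `+`) <= 1
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a synthetic raw-scheme phantom
#'
#' Deterministic given the spec's seed; the returned volume contains all
#' eight raw labels.
#'
#' @param spec a [phantom_spec].
#' @return a raw-scheme [label_volume].
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  d <- spec$dims; sp <- spec$spacing
  extent <- (d - 1L) * sp
  ctr <- spec$center_frac * extent
  gm_ax <- spec$icv_semiaxes - spec$csf_thickness
  wm_ax <- gm_ax - spec$gm_thickness

  grid <- array(0L, d)
  grid[ellipsoid_grid(d, sp, ctr, spec$icv_semiaxes)] <- 5L  # peripheral CSF
  grid[ellipsoid_grid(d, sp, ctr, gm_ax)] <- 1L              # cortical GM
  wm_core <- ellipsoid_grid(d, sp, ctr, wm_ax)
  grid[wm_core] <- 3L                                        # white matter

  paint_inside_wm <- function(grid, center, semiaxes, label, what) {
    ell <- ellipsoid_grid(d, sp, center, semiaxes)
    if (any(ell & !wm_core))
      stop(what, " ellipsoid extends outside the WM core; adjust the spec")
    tgt <- ell & grid == 3L
    if (!any(tgt))
      stop(what, " ellipsoid is empty or fully overlapped; adjust the spec")
    grid[tgt] <- label
    grid
  }
  for (sgn in c(-1, 1)) {
    vctr <- ctr + c(sgn * spec$ventricle_offset, 0, 0)
    grid <- paint_inside_wm(grid, vctr, spec$ventricle_semiaxes, 6L,
                            "ventricle")
    bctr <- ctr + c(sgn * spec$bg_offset, 0, 0)
    grid <- paint_inside_wm(grid, bctr, spec$bg_semiaxes, 2L, "basal ganglia")
  }

  # lesion blobs: centres drawn among deep WM voxels (all six face
  # neighbours still WM), blob clipped to the remaining WM so lesions
  # stay strictly inside white matter
  grid <- with_seed(spec$seed, {
    wm_now <- grid == 3L
    deep <- wm_now
    for (ax in 1:3)
      deep <- deep & slice_shift(wm_now, ax, -1L) & slice_shift(wm_now, ax, 1L)
    cand <- which(deep)
    if (length(cand) < spec$n_wml)
      stop("not enough deep WM voxels to place lesions")
    centers <- sample(cand, spec$n_wml)
    radii <- runif(spec$n_wml, spec$wml_radius_range[1],
                   spec$wml_radius_range[2])
    ai <- arrayInd(centers, d)
    for (b in seq_len(spec$n_wml)) {
      cmm <- (ai[b, ] - 1) * sp
      blob <- ellipsoid_grid(d, sp, cmm, rep(radii[b], 3)) & grid == 3L
      grid[blob] <- 4L
    }
    grid
  })

  # inferior hindbrain blob, painted only on background so it never
  # intrudes into the ICV; anterior strip is brainstem (8), rest
  # cerebellum (7)
  hctr <- spec$hind_center_frac * extent
  hind <- ellipsoid_grid(d, sp, hctr, spec$hind_semiaxes) & grid == 0L
  if (!any(hind)) stop("hindbrain blob is empty; adjust the spec")
  ys <- (0:(d[2] - 1L)) * sp[2]
  ymap <- array(rep(ys, each = d[1]), d)
  grid[hind & ymap < hctr[2] - spec$hind_semiaxes[2] / 2] <- 8L
  grid[hind & ymap >= hctr[2] - spec$hind_semiaxes[2] / 2] <- 7L

  missing <- setdiff(1:8, unique(as.vector(grid)))
  if (length(missing))
    stop("phantom is missing labels: ", paste(missing, collapse = ","))
  label_volume(grid, sp, scheme = "raw")
}

#' Relabel a random fraction of one label's voxels
#'
#' Exactly `round(fraction * count(from))` voxels, chosen uniformly at
#' random (deterministic per seed), switch from `from` to `to`. Used to
#' manufacture candidates with a known volume error: relabelling a
#' fraction f of the WM voxels yields AVD_WM = 100 f by construction.
#'
#' @param vol a [label_volume].
#' @param from,to labels valid for the volume's scheme.
#' @param fraction fraction of `from` voxels to switch, in `[0, 1]`.
#' @param seed integer seed.
#' @return the perturbed [label_volume].
#' @export
perturb_relabel <- function(vol, from, to, fraction, seed = 1L) {
  stopifnot(inherits(vol, "label_volume"))
  allowed <- if (vol$scheme == "raw") RAW_LABELS else TISSUE_LABELS
  if (!(from %in% allowed) || !(to %in% allowed))
    stop("labels are outside the volume's scheme")
  if (fraction < 0 || fraction > 1) stop("`fraction` must be in [0, 1]")
  idx <- which(vol$grid == from)
  k <- round(fraction * length(idx))
  if (k > 0L) {
    pick <- with_seed(seed, sample(idx, k))
    vol$grid[pick] <- as.integer(to)
  }
  vol
}

#' Translate all labelled content by a voxel offset
#'
#' Every labelled voxel moves by the integer offset; vacated voxels
#' become background. Shifting a volume by one slice at dz = 3 mm moves
#' every boundary point by exactly 3 mm, giving a known H95.
#'
#' @param vol a [label_volume].
#' @param offset integer length-3 voxel offset `(di, dj, dk)`.
#' @return the shifted [label_volume].
#' @export
perturb_shift <- function(vol, offset) {
  stopifnot(inherits(vol, "label_volume"))
  offset <- as.integer(offset)
  if (length(offset) != 3L) stop("`offset` must have three entries")
  idx <- which(vol$grid != 0L)
  if (length(idx) == 0L) return(vol)
  ai <- arrayInd(idx, dim(vol$grid))
  lo <- apply(ai, 2, min) + offset
  hi <- apply(ai, 2, max) + offset
  if (any(lo < 1L) || any(hi > dim(vol$grid)))
    stop("shift would clip labelled content at the grid edge")
  new <- array(0L, dim(vol$grid))
  dst <- sweep(ai, 2, offset, `+`)
  new[dst] <- vol$grid[ai]
  vol$grid <- new
  vol
}

#' Dilate one structure by face-connected layers
#'
#' Grows the voxels carrying `label` into their 6-connected face
#' neighbours, one layer per iteration. By default growth claims only
#' background voxels; with `overwrite = TRUE` it also claims voxels of
#' other structures.
#'
#' @param vol a [label_volume].
#' @param label the structure label to grow.
#' @param iterations number of one-voxel layers, `>= 0`.
#' @param overwrite if `TRUE`, growth overwrites other labels rather
#'   than only background.
#' @return the dilated [label_volume].
#' @export
perturb_dilate <- function(vol, label, iterations = 1L, overwrite = FALSE) {
  stopifnot(inherits(vol, "label_volume"))
  if (iterations < 0L) stop("`iterations` must be >= 0")
  label <- as.integer(label)
  for (i in seq_len(iterations)) {
    m <- vol$grid == label
    grown <- m
    for (ax in 1:3)
      grown <- grown | slice_shift(m, ax, -1L) | slice_shift(m, ax, 1L)
    claim <- grown & !m
    if (!overwrite) claim <- claim & vol$grid == 0L
    vol$grid[claim] <- label
  }
  vol
}

#' Serialise / restore a phantom spec
#'
#' Round-trips a [phantom_spec] through YAML (or JSON, by extension) so
#' phantom configurations can be version-controlled and fed to the
#' command-line tools.
#'
#' @param spec a [phantom_spec].
#' @param path output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path` invisibly (write) / a [phantom_spec] (read).
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  x <- unclass(spec)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  do.call(phantom_spec, x)
}
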