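# The three evaluation measures (Dice overlap, 95th-percentile Hausdorff
# distance, absolute volume difference), boundary extraction, and white
# matter lesion sensitivity.

#' Dice overlap coefficient (percent)
#'
#' `D = 2|A n G| / (|A| + |G|) * 100`, with set sizes counted in voxels
#' (the voxel volume cancels). `A` is the candidate segmentation, `G`
#' the reference.
#'
#' @param a,g [component_mask]s on the same grid.
#' @return Dice as a percentage in `[0, 100]`.
#' @export
dice <- function(a, g) {
  stopifnot(inherits(a, "component_mask"), inherits(g, "component_mask"))
  check_same_grid(a, g, "masks")
  na <- sum(a$grid); ng <- sum(g$grid)
  if (na + ng == 0L)
    stop("Dice is undefined: both masks are empty")
  200 * sum(a$grid & g$grid) / (na + ng)
}

#' Absolute volume difference (percent)
#'
#' `AVD = |V_a - V_g| / V_g * 100` where `V_a`, `V_g` are the physical
#' volumes of candidate and reference component. The voxel volume
#' cancels, so voxel counts are used. Not symmetric: normalised by the
#' reference volume.
#'
#' @param a,g [component_mask]s on the same grid (`g` is the reference).
#' @return AVD as a percentage, `>= 0`.
#' @export
avd <- function(a, g) {
  stopifnot(inherits(a, "component_mask"), inherits(g, "component_mask"))
  check_same_grid(a, g, "masks")
  vg <- sum(g$grid)
  if (vg == 0L) stop("AVD is undefined: reference mask is empty")
  abs(sum(a$grid) - vg) / vg * 100
}

# logical array of boundary voxels: in the mask with at least one of the
# six face neighbours outside the mask or outside the image
boundary_grid <- function(m) {
  d <- dim(m)
  interior <- array(TRUE, d)
  for (ax in 1:3) {
    n <- d[ax]
    if (n == 1L) { interior[] <- FALSE; break }
    lo <- slice_shift(m, ax, -1L)  # neighbour at index - 1 (border -> FALSE)
    hi <- slice_shift(m, ax, +1L)
    interior <- interior & lo & hi
  }
  m & !interior
}

# neighbour lookup along one axis: value of m at index offset by `by`,
# FALSE outside the image
slice_shift <- function(m, axis, by) {
  d <- dim(m)
  out <- array(FALSE, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) (1L + by):n else 1L:(n + by)
  dst <- if (by > 0) 1L:(n - by) else (1L - by):n
  idx_src <- rep(list(quote(expr = )), 3); idx_dst <- idx_src
  idx_src[[axis]] <- src; idx_dst[[axis]] <- dst
  out <- do.call(`[<-`, c(list(out), idx_dst,
                          list(value = do.call(`[`, c(list(m), idx_src)))))
  out
}

#' Extract the boundary point set of a component mask
#'
#' A voxel is a boundary point iff it belongs to the mask and at least
#' one of its six face neighbours lies outside the mask or outside the
#' image (a masked voxel on the volume edge is boundary). Points are
#' returned as physical voxel-centre coordinates in millimetres, so
#' distances computed from them respect anisotropic voxel spacing.
#'
#' @param mask a nonempty [component_mask].
#' @return an object of class `boundary_points`: list with `points`
#'   (N x 3 numeric matrix, mm), `count`, and `spacing`.
#' @export
extract_boundary <- function(mask) {
  stopifnot(inherits(mask, "component_mask"))
  if (!any(mask$grid))
    stop("cannot extract a boundary from an empty mask")
  b <- boundary_grid(mask$grid)
  idx <- which(b, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, mask$spacing, `*`)
  colnames(pts) <- c("x", "y", "z")
  structure(list(points = pts, count = nrow(pts), spacing = mask$spacing),
            class = "boundary_points")
}

#' @export
print.boundary_points <- function(x, ...) {
  cat(sprintf("<boundary_points> %d points (mm coordinates)\n", x$count))
  invisible(x)
}

# K-th ranked value (1-based order statistic) of the minimum distances,
# K = ceiling(0.95 * N); no interpolation
kth_ranked <- function(dmin, q = 0.95) {
  k <- ceiling(q * length(dmin))
  sort(dmin)[k]
}

# minimum Euclidean distance from each row of `from` to the set `to`,
# chunked so the cross-distance matrix stays small
min_dists <- function(from, to, chunk = 1024L) {
  n <- nrow(from)
  out <- numeric(n)
  to_t <- t(to)
  ss_to <- colSums(to_t^2)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fr <- from[idx, , drop = FALSE]
    # squared distances via the expansion |a-b|^2 = |a|^2 - 2 a.b + |b|^2
    d2 <- outer(rowSums(fr^2), ss_to, `+`) - 2 * (fr %*% to_t)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Directed 95th-percentile Hausdorff distance (mm)
#'
#' For every boundary point `a` of the first set, the minimum Euclidean
#' distance to the second set is computed; the distances are sorted
#' ascending and the K-th order statistic is returned, with
#' `K = ceiling(0.95 N_a)` (so that `K / N_a >= 95%`; no interpolation).
#' Taking the 95th percentile instead of the maximum makes the measure
#' robust to boundary outliers.
#'
#' Inputs may be [boundary_points] or [component_mask]s; masks on a
#' common grid use an exact anisotropic Euclidean distance transform
#' instead of all-pairs distances, which is much faster on full volumes.
#'
#' @param a,g [boundary_points] or [component_mask] objects.
#' @return distance in mm, `>= 0`.
#' @export
directed_h95 <- function(a, g) {
  if (inherits(a, "component_mask") && inherits(g, "component_mask")) {
    check_same_grid(a, g, "masks")
    if (!any(a$grid) || !any(g$grid))
      stop("H95 is undefined for an empty mask")
    return(directed_h95_masks(a, g))
  }
  stopifnot(inherits(a, "boundary_points"), inherits(g, "boundary_points"))
  if (a$count == 0L || g$count == 0L)
    stop("H95 is undefined for an empty boundary set")
  kth_ranked(min_dists(a$points, g$points))
}

# distance-transform fast path: exact distances from every boundary voxel
# of `a` to the boundary voxel set of `g`
directed_h95_masks <- function(a, g) {
  bg <- boundary_grid(g$grid)
  d2 <- .edt_squared(as.vector(bg), dim(g$grid), g$spacing)
  ba <- boundary_grid(a$grid)
  kth_ranked(sqrt(d2[as.vector(ba)]))
}

#' Symmetric 95th-percentile Hausdorff distance (mm)
#'
#' `H95(A, G) = max(h95(A, G), h95(G, A))` — the maximum of the two
#' directed distances, hence symmetric in its arguments.
#'
#' @inheritParams directed_h95
#' @return distance in mm, `>= 0`.
#' @export
h95 <- function(a, g) {
  max(directed_h95(a, g), directed_h95(g, a))
}

#' White matter lesion sensitivity (percent)
#'
#' Lesions are annotated separately (raw label 4) but must be segmented
#' as white matter. The sensitivity is the percentage of reference
#' lesion voxels that the candidate labels WM, pooled over all cases.
#'
#' @param candidates list of tissue-scheme [label_volume]s.
#' @param references list of raw-scheme [label_volume]s, paired with
#'   `candidates`.
#' @return sensitivity as a percentage in `[0, 100]`.
#' @export
wml_sensitivity <- function(candidates, references) {
  if (length(candidates) != length(references))
    stop("candidate and reference lists have different lengths")
  if (length(candidates) == 0L) stop("no cases supplied")
  hit <- 0L; tot <- 0L
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]; ref <- references[[i]]
    stopifnot(inherits(cand, "label_volume"), inherits(ref, "label_volume"))
    if (cand$scheme == "raw") cand <- merge_to_tissue(cand)$tissue
    if (ref$scheme != "raw")
      stop("references must be raw-scheme (lesions need label 4)")
    check_same_grid(cand, ref, sprintf("case %d volumes", i))
    wml <- ref$grid == WML_RAW_LABEL
    tot <- tot + sum(wml)
    hit <- hit + sum(wml & cand$grid == COMPONENT_LABELS$WM)
  }
  if (tot == 0L)
    stop("no white matter lesion voxels in any reference")
  100 * hit / tot
}
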