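# Independent brute-force oracles and small fixtures, deliberately
# written as straight-line code with none of the package's shortcuts.

# random speckle mask with at least `min_true` voxels set
rand_mask <- function(dims, spacing, p = 0.3, seed = 1, min_true = 1L,
                      component = "GM") {
  set.seed(seed)
  g <- array(runif(prod(dims)) < p, dims)
  while (sum(g) < min_true) {
    g[sample(length(g), 1)] <- TRUE
  }
  component_mask_new(g, spacing, component)
}

# per-voxel 6-neighbour scan, explicit loops
oracle_boundary <- function(mask) {
  g <- mask$grid; d <- dim(g)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!g[i, j, k]) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    for (v in nb) {
      if (any(v < 1) || any(v > d) || !g[v[1], v[2], v[3]]) {
        out[i, j, k] <- TRUE
        break
      }
    }
  }
  out
}

# all-pairs Kth-ranked minimum distance, one explicit loop per source point
oracle_directed_h95 <- function(apts, gpts) {
  na <- nrow(apts)
  dmin <- numeric(na)
  for (r in seq_len(na)) {
    dd <- sqrt((gpts[, 1] - apts[r, 1])^2 + (gpts[, 2] - apts[r, 2])^2 +
               (gpts[, 3] - apts[r, 3])^2)
    dmin[r] <- min(dd)
  }
  k <- ceiling(0.95 * na)
  sort(dmin)[k]
}

oracle_h95 <- function(apts, gpts) {
  max(oracle_directed_h95(apts, gpts), oracle_directed_h95(gpts, apts))
}

# boundary voxel centres of a mask, via the oracle boundary scan
oracle_boundary_points <- function(mask) {
  idx <- which(oracle_boundary(mask), arr.ind = TRUE)
  sweep(idx - 1, 2, mask$spacing, `*`)
}

# straight-line recomputation of all three measures for one component,
# starting from the raw arrays
oracle_component_metrics <- function(cand_grid, ref_raw_grid, spacing,
                                     tissue_labels) {
  map <- c(0, 1, 1, 2, 2, 3, 3, 0, 0)
  ref_tis <- array(map[ref_raw_grid + 1], dim(ref_raw_grid))
  excl <- ref_raw_grid == 7 | ref_raw_grid == 8
  a <- array(cand_grid %in% tissue_labels & !excl, dim(cand_grid))
  g <- array(ref_tis %in% tissue_labels & !excl, dim(ref_raw_grid))
  am <- component_mask_new(a, spacing, "GM")
  gm <- component_mask_new(g, spacing, "GM")
  list(
    dice = 2 * sum(a & g) / (sum(a) + sum(g)) * 100,
    h95 = oracle_h95(oracle_boundary_points(am), oracle_boundary_points(gm)),
    avd = abs(sum(a) - sum(g)) / sum(g) * 100
  )
}

# compact phantom specs so geometry-heavy tests stay fast
tiny_phantom_spec <- function(seed = 1L) {
  phantom_spec(dims = c(32L, 32L, 12L), spacing = c(0.96, 0.96, 3.0),
               icv_semiaxes = c(11, 12, 12), csf_thickness = 2.5,
               gm_thickness = 3,
               ventricle_semiaxes = c(1.5, 3.5, 3), ventricle_offset = 2,
               bg_semiaxes = c(1, 1.5, 1.5), bg_offset = 4,
               n_wml = 2L, wml_radius_range = c(1, 2),
               hind_center_frac = c(0.5, 0.58, 0.85),
               hind_semiaxes = c(6, 5, 3), seed = seed)
}

small_phantom_spec <- function(seed = 1L) {
  phantom_spec(dims = c(48L, 48L, 16L), spacing = c(0.96, 0.96, 3.0),
               icv_semiaxes = c(17, 18, 18), csf_thickness = 3,
               gm_thickness = 4,
               ventricle_semiaxes = c(2, 6, 4), ventricle_offset = 3,
               bg_semiaxes = c(2, 3, 2.5), bg_offset = 7,
               n_wml = 3L, wml_radius_range = c(1.5, 3),
               hind_center_frac = c(0.5, 0.58, 0.88),
               hind_semiaxes = c(10, 8, 4), seed = seed)
}

# random continuous method summaries (no ties almost surely)
make_random_summaries <- function(n_methods, seed = 1L) {
  set.seed(seed)
  methods <- sprintf("M%02d", seq_len(n_methods))
  out <- list()
  for (m in methods)
    for (meas in c("dice", "h95", "avd"))
      for (comp in c("GM", "WM", "CSF", "brain", "ICV")) {
        mu <- if (meas == "dice") runif(1, 50, 100) else runif(1, 0, 30)
        out[[length(out) + 1L]] <- data.frame(
          method = m, measure = meas, component = comp,
          mu = mu, sigma = runif(1, 0.1, 10), n = 15L,
          stringsAsFactors = FALSE)
      }
  do.call(rbind, out)
}
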