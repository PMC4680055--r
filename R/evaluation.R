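# Per-case evaluation over the five anatomical components and
# mean / standard-deviation aggregation over a test set.

#' Evaluate one segmentation against its reference standard
#'
#' Computes Dice (%), 95th-percentile Hausdorff distance (mm) and
#' absolute volume difference (%) for the five evaluated components:
#' GM, WM, CSF, brain (GM + WM) and intracranial volume
#' (ICV = GM + WM + CSF). The reference must be in the raw annotation
#' scheme; it is merged to tissue classes and its cerebellum/brainstem
#' voxels are excluded from both volumes before any metric. Raw-scheme
#' candidates are merged automatically.
#'
#' An empty candidate component against a nonempty reference yields
#' Dice 0 and AVD 100 with H95 undefined (`NA`, flagged); an empty
#' reference component leaves all three undefined. Undefined cells are
#' excluded from aggregation by [summarize_cases()] with a warning.
#'
#' @param candidate tissue- (or raw-) scheme [label_volume].
#' @param reference raw-scheme [label_volume] on the same grid.
#' @param case_id identifier recorded in the result.
#' @return a `case_result` data frame with columns `case_id`,
#'   `component`, `dice_pct`, `h95_mm`, `avd_pct`, `flag`.
#' @export
evaluate_case <- function(candidate, reference, case_id = "case") {
  stopifnot(inherits(candidate, "label_volume"),
            inherits(reference, "label_volume"))
  if (reference$scheme != "raw")
    stop("the reference standard must be a raw-scheme volume")
  check_same_grid(candidate, reference, "candidate and reference")
  if (candidate$scheme == "raw") candidate <- merge_to_tissue(candidate)$tissue
  merged <- merge_to_tissue(reference)

  rows <- lapply(COMPONENTS, function(comp) {
    g <- component_mask(merged$tissue, comp, merged$excluded)
    a <- component_mask(candidate, comp, merged$excluded)
    na <- sum(a$grid); ng <- sum(g$grid)
    flag <- ""
    if (ng == 0L) {
      d <- NA_real_; h <- NA_real_; v <- NA_real_
      flag <- "empty-reference"
    } else if (na == 0L) {
      d <- 0; v <- 100; h <- NA_real_
      flag <- "empty-candidate"
    } else {
      d <- dice(a, g)
      h <- h95(a, g)
      v <- avd(a, g)
    }
    data.frame(case_id = case_id, component = comp, dice_pct = d,
               h95_mm = h, avd_pct = v, flag = flag,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("case_result", class(res))
  res
}

#' Aggregate case results into a per-method summary
#'
#' For each (measure, component) cell the arithmetic mean and the sample
#' standard deviation (n - 1 denominator) over cases are computed — the
#' statistics on which the challenge ranking operates. Cases with an
#' undefined value in a cell are dropped from that cell only, with a
#' warning and a reduced `n` recorded.
#'
#' @param results a `case_result` data frame (rows from one or more
#'   calls to [evaluate_case()], e.g. via `rbind`).
#' @param method method name recorded in the summary.
#' @return a `method_summary` data frame with columns `method`,
#'   `measure` (`dice`, `h95`, `avd`), `component`, `mu`, `sigma`, `n`.
#' @export
summarize_cases <- function(results, method = "method") {
  stopifnot(is.data.frame(results), nrow(results) > 0L)
  need <- c("case_id", "component", "dice_pct", "h95_mm", "avd_pct")
  if (!all(need %in% names(results)))
    stop("`results` is missing columns: ",
         paste(setdiff(need, names(results)), collapse = ", "))
  miss <- setdiff(COMPONENTS, unique(results$component))
  if (length(miss))
    stop("results lack components: ", paste(miss, collapse = ", "))
  col_of <- c(dice = "dice_pct", h95 = "h95_mm", avd = "avd_pct")
  out <- expand.grid(measure = MEASURES, component = COMPONENTS,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$method <- method
  out$mu <- NA_real_; out$sigma <- NA_real_; out$n <- 0L
  for (r in seq_len(nrow(out))) {
    vals <- results[results$component == out$component[r], col_of[[out$measure[r]]]]
    ok <- !is.na(vals)
    if (any(!ok))
      warning(sprintf(
        "%s/%s: %d case(s) with undefined %s excluded from the summary",
        method, out$component[r], sum(!ok), out$measure[r]))
    vals <- vals[ok]
    if (length(vals) == 0L)
      stop(sprintf("%s/%s: no defined %s values to aggregate",
                   method, out$component[r], out$measure[r]))
    out$mu[r] <- mean(vals)
    out$sigma[r] <- if (length(vals) > 1L) sd(vals) else 0
    out$n[r] <- length(vals)
  }
  out <- out[, c("method", "measure", "component", "mu", "sigma", "n")]
  class(out) <- c("method_summary", class(out))
  out
}

#' Write per-case results to CSV
#'
#' One row per (method, case, component) with full-precision values.
#'
#' @param results a `case_result` data frame.
#' @param path output CSV path.
#' @param method optional method name column.
#' @return `path`, invisibly.
#' @export
write_case_results <- function(results, path, method = NULL) {
  df <- as.data.frame(results)
  if (!is.null(method)) df <- cbind(method = method, df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a method summary to CSV
#'
#' Wide layout: one row per method, `mu_`/`sigma_` column pairs per
#' measure-component cell (e.g. `mu_dice_GM`, `sigma_h95_CSF`), plus the
#' case count.
#'
#' @param summary a `method_summary` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  write.csv(summary_to_wide(summary), path, row.names = FALSE)
  invisible(path)
}

summary_to_wide <- function(summary) {
  stopifnot(is.data.frame(summary))
  methods <- unique(summary$method)
  rows <- lapply(methods, function(m) {
    s <- summary[summary$method == m, ]
    row <- list(method = m, n_cases = max(s$n))
    for (meas in MEASURES)
      for (comp in COMPONENTS) {
        cell <- s[s$measure == meas & s$component == comp, ]
        if (nrow(cell) != 1L)
          stop(sprintf("summary for %s lacks cell %s/%s", m, meas, comp))
        row[[paste0("mu_", meas, "_", comp)]] <- cell$mu
        row[[paste0("sigma_", meas, "_", comp)]] <- cell$sigma
      }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a wide summary CSV back into a `method_summary`
#'
#' Inverse of [write_summary()]; also accepts files holding several
#' methods (one per row).
#'
#' @param path CSV path as written by [write_summary()].
#' @return a `method_summary` data frame.
#' @export
read_summary <- function(path) {
  wide <- read.csv(path, stringsAsFactors = FALSE)
  if (!"method" %in% names(wide)) stop("summary CSV lacks a `method` column")
  out <- list()
  for (r in seq_len(nrow(wide)))
    for (meas in MEASURES)
      for (comp in COMPONENTS) {
        mu_col <- paste0("mu_", meas, "_", comp)
        sd_col <- paste0("sigma_", meas, "_", comp)
        if (!all(c(mu_col, sd_col) %in% names(wide)))
          stop("summary CSV lacks column ", mu_col, " or ", sd_col)
        out[[length(out) + 1L]] <- data.frame(
          method = wide$method[r], measure = meas, component = comp,
          mu = wide[[mu_col]][r], sigma = wide[[sd_col]][r],
          n = if ("n_cases" %in% names(wide)) wide$n_cases[r] else NA_integer_,
          stringsAsFactors = FALSE)
      }
  res <- do.call(rbind, out)
  class(res) <- c("method_summary", class(res))
  res
}
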