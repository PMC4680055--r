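# Bundled published leaderboard of an 18-method brain tissue
# segmentation challenge (15 test cases, elderly-subject 3T MRI), used
# as reference input for the ranking machinery.

#' Published challenge leaderboard (18 methods, 15 cases)
#'
#' The published results table of a multi-center brain tissue
#' segmentation challenge: for 18 methods (11 workshop participants
#' plus freeware pipelines), the per-column ranks, means and standard
#' deviations of Dice (%), 95th-percentile Hausdorff distance (mm) and
#' absolute volume difference (%) over GM, WM, CSF, brain and ICV,
#' together with the published overall score `s`, final rank, and (for
#' the tied methods) the published sigma rank.
#'
#' Values are as printed (means and sigmas rounded to the published
#' precision); the rank cells and scores are exact integers. This is
#' the canonical input for [overall_score()], [ranks_from_wide()] and
#' [cmd_rank()] when no raw segmentations are available.
#'
#' @return a wide data frame with columns `method`, `published_rank`,
#'   `published_s`, `published_sigma_rank`, and
#'   `rank_`/`mu_`/`sigma_<measure>_<component>` triples for the 15
#'   (measure, component) cells.
#' @export
challenge_table <- function() {
  path <- system.file("extdata", "challenge2013_summary.csv",
                      package = "segrank", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Published per-method summary in long form
#'
#' The same table as [challenge_table()] reshaped to the long
#' `method_summary` layout consumed by the ranking functions (note the
#' means and sigmas carry only the published, rounded precision).
#'
#' @return a `method_summary` data frame.
#' @export
challenge_summaries <- function() {
  wide <- challenge_table()
  out <- list()
  for (r in seq_len(nrow(wide)))
    for (meas in MEASURES)
      for (comp in COMPONENTS)
        out[[length(out) + 1L]] <- data.frame(
          method = wide$method[r], measure = meas, component = comp,
          mu = wide[[paste0("mu_", meas, "_", comp)]][r],
          sigma = wide[[paste0("sigma_", meas, "_", comp)]][r],
          n = 15L, stringsAsFactors = FALSE)
  res <- do.call(rbind, out)
  class(res) <- c("method_summary", class(res))
  res
}
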