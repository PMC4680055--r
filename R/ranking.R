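# Challenge ranking: per-column ranks, overall sum-of-ranks score, and
# the standard-deviation tie-break.
#
# Each method is ranked 1..n in each of the fifteen (measure, component)
# columns from the per-method means: Dice descending (higher is better),
# H95 and AVD ascending. The overall score s is the sum of the nine
# GM/WM/CSF ranks (brain and ICV ranks are reported but not scored);
# final ranks follow s ascending. Methods with equal s are ordered by a
# secondary rank computed by rerunning the whole procedure on the
# standard deviations instead of the means.

MEASURE_DIRECTION <- c(dice = "descending", h95 = "ascending",
                       avd = "ascending")

#' Rank methods within one (measure, component) column
#'
#' The best value receives rank 1. Ties of the value are broken by the
#' supplied standard deviation (ascending — the more consistent method
#' ranks better), then deterministically by method name; every method
#' receives a distinct integer rank.
#'
#' @param values named numeric vector of per-method column values
#'   (names are method names, which must be unique).
#' @param direction `"descending"` (higher is better, Dice) or
#'   `"ascending"` (lower is better, H95 and AVD).
#' @param sigma optional named numeric vector of standard deviations
#'   used for tie-breaking.
#' @return named integer vector of ranks, a permutation of `1..n`.
#' @export
rank_column <- function(values, direction = c("ascending", "descending"),
                        sigma = NULL) {
  direction <- match.arg(direction)
  methods <- names(values)
  if (is.null(methods) || anyNA(methods) || any(methods == ""))
    stop("`values` must be named by method")
  if (anyDuplicated(methods)) stop("duplicate method names")
  if (any(!is.finite(values)))
    stop("non-finite column values; replace undefined cells by a worst ",
         "sentinel before ranking")
  key <- if (direction == "descending") -values else values
  tie <- if (is.null(sigma)) rep(0, length(values)) else sigma[methods]
  ord <- order(key, tie, methods)
  ranks <- integer(length(values))
  ranks[ord] <- seq_along(values)
  names(ranks) <- methods
  ranks
}

# long rank table (method, measure, component, rank) over all 15 columns,
# ranked on `stat` ("mu" or "sigma"). Undefined cells get a worst
# sentinel so a failing method is ranked last, never dropped.
rank_table <- function(summaries, stat = c("mu", "sigma")) {
  stat <- match.arg(stat)
  stopifnot(is.data.frame(summaries))
  methods <- unique(summaries$method)
  if (length(methods) < 1L) stop("no methods to rank")
  out <- list()
  for (meas in MEASURES)
    for (comp in COMPONENTS) {
      cell <- summaries[summaries$measure == meas &
                          summaries$component == comp, ]
      if (!setequal(cell$method, methods) || anyDuplicated(cell$method))
        stop(sprintf("summaries lack a complete %s/%s column", meas, comp))
      vals <- setNames(cell[[stat]], cell$method)[methods]
      sig <- setNames(cell$sigma, cell$method)[methods]
      # means are ranked best-first per measure; standard deviations are
      # always ranked ascending (smaller sigma = more consistent)
      dir <- if (stat == "sigma") "ascending" else MEASURE_DIRECTION[[meas]]
      # finite worst sentinel: an undefined cell ranks last in its column
      worst <- if (dir == "descending") -.Machine$double.xmax
               else .Machine$double.xmax
      vals[!is.finite(vals)] <- worst
      r <- rank_column(vals, dir, sigma = if (stat == "mu") sig else NULL)
      out[[length(out) + 1L]] <- data.frame(
        method = methods, measure = meas, component = comp,
        rank = as.integer(r[methods]), stringsAsFactors = FALSE)
    }
  do.call(rbind, out)
}

#' Overall score: sum of the nine scored ranks
#'
#' Sums a method's ranks over the nine scored (measure, component)
#' columns — Dice, H95 and AVD of GM, WM and CSF. Brain and ICV columns
#' are display-only and never enter the score. Lower is better; with
#' `n` methods the score lies in `[9, 9n]`.
#'
#' @param ranks a long rank table with columns `method`, `measure`,
#'   `component`, `rank` (e.g. from [final_ranking()]'s `ranks`
#'   attribute, or assembled from published rank cells).
#' @param method the method whose score to compute.
#' @return integer score.
#' @export
overall_score <- function(ranks, method) {
  stopifnot(is.data.frame(ranks),
            all(c("method", "measure", "component", "rank") %in% names(ranks)))
  cells <- ranks[ranks$method == method &
                   ranks$component %in% SCORED_COMPONENTS &
                   ranks$measure %in% MEASURES, ]
  if (nrow(cells) != 9L)
    stop(sprintf("expected 9 scored rank cells for '%s', found %d",
                 method, nrow(cells)))
  as.integer(sum(cells$rank))
}

#' Standard-deviation ranks (the tie-break statistic)
#'
#' Reruns the ranking procedure on the standard deviations: per scored
#' column, methods are ranked by sigma ascending (a smaller sigma means
#' more consistent performance across cases); the nine sigma ranks are
#' summed per method and the resulting sigma scores are ranked
#' ascending `1..n`.
#'
#' @param summaries a `method_summary` data frame covering >= 1 methods.
#' @return data frame with columns `method`, `sigma_score`,
#'   `sigma_rank`.
#' @export
sigma_rank <- function(summaries) {
  rt <- rank_table(summaries, stat = "sigma")
  methods <- unique(summaries$method)
  score <- vapply(methods, function(m) overall_score(rt, m), integer(1))
  r <- rank_column(setNames(as.numeric(score), methods), "ascending")
  data.frame(method = methods, sigma_score = as.integer(score),
             sigma_rank = as.integer(r[methods]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the final leaderboard
#'
#' Ranks every (measure, component) column from the per-method means,
#' sums the nine scored ranks into the overall score `s`, and sorts `s`
#' ascending. Methods with equal `s` are ordered by their sigma rank
#' (see [sigma_rank()]); any residual tie falls back to method name and
#' is flagged in the `tie_broken_by` column.
#'
#' @param summaries a `method_summary` data frame covering all methods
#'   (e.g. `rbind` of per-method [summarize_cases()] outputs, or
#'   [read_summary()] on a multi-method CSV).
#' @return a `leaderboard` data frame sorted by final rank, with columns
#'   `rank`, `method`, `s`, `sigma_score`, `sigma_rank`,
#'   `tie_broken_by`, and one `rank_<measure>_<component>` column per
#'   ranked cell (including the unscored brain/ICV columns). The long
#'   rank table is attached as attribute `"ranks"`.
#' @export
final_ranking <- function(summaries) {
  rt <- rank_table(summaries, stat = "mu")
  methods <- unique(summaries$method)
  s <- vapply(methods, function(m) overall_score(rt, m), integer(1))
  sr <- sigma_rank(summaries)
  sig <- setNames(sr$sigma_rank, sr$method)[methods]
  ord <- order(s, sig, methods)
  lb <- data.frame(rank = seq_along(methods), method = methods[ord],
                   s = as.integer(s[ord]),
                   sigma_score = sr$sigma_score[match(methods[ord], sr$method)],
                   sigma_rank = as.integer(sig[ord]),
                   row.names = NULL, stringsAsFactors = FALSE)
  # how was each method separated from the previous one?
  lb$tie_broken_by <- "score"
  if (nrow(lb) > 1L)
    for (i in 2:nrow(lb)) {
      if (lb$s[i] == lb$s[i - 1L])
        lb$tie_broken_by[i] <-
          if (lb$sigma_rank[i] != lb$sigma_rank[i - 1L]) "sigma" else "name"
    }
  for (meas in MEASURES)
    for (comp in COMPONENTS) {
      cell <- rt[rt$measure == meas & rt$component == comp, ]
      lb[[paste0("rank_", meas, "_", comp)]] <-
        cell$rank[match(lb$method, cell$method)]
    }
  attr(lb, "ranks") <- rt
  class(lb) <- c("leaderboard", class(lb))
  lb
}

#' @export
print.leaderboard <- function(x, ...) {
  cat("<leaderboard>\n")
  print.data.frame(head(as.data.frame(
    x[, c("rank", "method", "s", "sigma_rank", "tie_broken_by")]), n = 25))
  invisible(x)
}

#' Assemble a long rank table from published rank cells
#'
#' Converts a wide table with one row per method and one
#' `rank_<measure>_<component>` column per cell (the layout printed by
#' challenge leaderboards) into the long rank table consumed by
#' [overall_score()]. Missing brain/ICV columns are allowed: only the
#' nine scored columns are required.
#'
#' @param wide data frame with a `method` column and rank columns named
#'   `rank_<measure>_<component>` (measures `dice`, `h95`, `avd`).
#' @return long data frame with columns `method`, `measure`,
#'   `component`, `rank`.
#' @export
ranks_from_wide <- function(wide) {
  stopifnot(is.data.frame(wide), "method" %in% names(wide))
  out <- list()
  for (meas in MEASURES)
    for (comp in COMPONENTS) {
      col <- paste0("rank_", meas, "_", comp)
      if (!col %in% names(wide)) {
        if (comp %in% SCORED_COMPONENTS)
          stop("missing scored rank column ", col)
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        method = wide$method, measure = meas, component = comp,
        rank = as.integer(wide[[col]]), stringsAsFactors = FALSE)
    }
  do.call(rbind, out)
}
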