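#' One-dimensional DBSCAN outlier filter
#'
#' Standard DBSCAN specialised to one dimension: a point is a core point
#' when at least `min_samples` points (counting itself) lie within
#' `epsilon`; clusters are maximal chains of core points closer than
#' `epsilon`, plus any border point within `epsilon` of a core point.  All
#' clustered points are kept — whether one or several clusters are present —
#' and noise points are removed as outliers.
#'
#' The one-dimensional case is solved exactly by a sorted sweep (no
#' neighbourhood queries), so the filter is O(n log n).
#'
#' @param distances Numeric vector.
#' @param epsilon Neighbourhood radius (> 0), typically from
#'   [knee_epsilon()].
#' @param min_samples Minimum neighbourhood size for a core point,
#'   counting the point itself (default 5).
#' @return A list with `kept` and `removed` numeric vectors (in input
#'   order); together they are exactly the input as a multiset.
#' @export
dbscan_filter <- function(distances, epsilon, min_samples = 5L) {
  d <- as.numeric(distances)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop_ogmstr("validation", "epsilon must be a single positive number")
  }
  n <- length(d)
  ord <- order(d)
  s <- d[ord]

  # neighbour counts within epsilon, via binary search on the sorted vector
  hi <- findInterval(s + epsilon, s)
  lo <- findInterval(s - epsilon, s, left.open = TRUE) + 1L
  core <- (hi - lo + 1L) >= min_samples

  keep_sorted <- logical(n)
  if (any(core)) {
    keep_sorted[core] <- TRUE
    core_pos <- s[core]
    # border points: non-core within epsilon of the nearest core point
    nc <- which(!core)
    if (length(nc) > 0L) {
      j <- findInterval(s[nc], core_pos)
      left_gap <- ifelse(j >= 1L, s[nc] - core_pos[pmax(j, 1L)], Inf)
      right_gap <- ifelse(j < length(core_pos),
                          core_pos[pmin(j + 1L, length(core_pos))] - s[nc],
                          Inf)
      keep_sorted[nc] <- pmin(left_gap, right_gap) <= epsilon
    }
  }

  keep <- logical(n)
  keep[ord] <- keep_sorted
  if (!any(keep)) {
    stop_ogmstr("all_outliers",
                "DBSCAN removed every point; inspect epsilon (%.3g) and min_samples (%d)",
                epsilon, min_samples)
  }
  list(kept = d[keep], removed = d[!keep])
}
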