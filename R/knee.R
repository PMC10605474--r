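# Automatic DBSCAN radius from the k-nearest-neighbour distance curve.

#' Choose a DBSCAN epsilon from the knee of the k-distance curve
#'
#' Computes each point's distance to its `min_samples`-th nearest neighbour
#' (exact, one-dimensional), sorts these k-distances ascending, and returns
#' the curve value at the knee located by the Kneedle algorithm (convex,
#' increasing convention, sensitivity `S`).  The knee marks where the
#' k-distance curve turns upward, i.e. where points stop being densely
#' packed: it is the classical heuristic for the DBSCAN radius.
#'
#' When the curve has no knee (for example, perfectly uniform k-distances)
#' the maximum k-distance is returned with a warning, which makes the
#' subsequent outlier removal a no-op rather than a failure.
#'
#' @param distances Numeric vector of at least `min_samples + 1` values.
#' @param min_samples The k of the k-distance curve (also DBSCAN's minPts;
#'   default 5).
#' @param S Kneedle sensitivity (default 1).
#' @return A single epsilon value (bp).
#' @seealso [dbscan_filter()]
#' @export
knee_epsilon <- function(distances, min_samples = 5L, S = 1.0) {
  d <- as.numeric(distances)
  n <- length(d)
  if (n < min_samples + 1L) {
    stop_ogmstr("insufficient_data",
                "need at least min_samples + 1 = %d points, got %d",
                min_samples + 1L, n)
  }
  kdist <- sort(kth_neighbour_distance(d, min_samples))
  idx <- kneedle_index(seq_along(kdist), kdist, S = S)
  if (is.na(idx)) {
    warn_ogmstr("no_knee",
                "no knee in the k-distance curve; using its maximum (outlier removal disabled)")
    return(max(kdist))
  }
  kdist[idx]
}

# distance from each point to its k-th nearest OTHER point, computed on the
# sorted vector: the k nearest neighbours of a point in 1-D are a contiguous
# window, so a sliding comparison of the k candidates on each side suffices.
kth_neighbour_distance <- function(d, k) {
  n <- length(d)
  s <- sort(d)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - k)
    hi <- min(n, i + k)
    nb <- abs(s[c(lo:hi)] - s[i])
    nb <- sort(nb[-(i - lo + 1L)])  # drop self
    out[i] <- nb[k]
  }
  out
}

# Kneedle on a convex increasing curve: normalise to the unit square,
# apply the convex-increasing transform (flip the curve so it becomes
# concave increasing) and walk the difference curve: each local maximum
# becomes a knee candidate with threshold `yd - S * mean(dx)`, a local
# minimum resets the threshold to zero, and the candidate is accepted as
# the knee once the difference curve drops below the active threshold.
# Offline variant, first knee returned; NA when the curve is flat or no
# candidate is ever confirmed.
kneedle_index <- function(x, y, S = 1.0) {
  n <- length(x)
  if (n < 3L || diff(range(y)) == 0) return(NA_integer_)
  xn <- (x - min(x)) / diff(range(x))
  yn <- (y - min(y)) / diff(range(y))
  yd <- (max(yn) - rev(yn)) - xn

  is_lmx <- c(FALSE, yd[2:(n - 1)] >= yd[1:(n - 2)] &
                     yd[2:(n - 1)] >= yd[3:n], FALSE)
  is_lmn <- c(FALSE, yd[2:(n - 1)] <= yd[1:(n - 2)] &
                     yd[2:(n - 1)] <= yd[3:n], FALSE)
  if (!any(is_lmx)) return(NA_integer_)

  step <- S * mean(diff(xn))
  threshold <- 0
  candidate <- NA_integer_
  for (i in seq(which(is_lmx)[1], n - 1L)) {
    if (is_lmx[i]) {
      candidate <- i
      threshold <- yd[i] - step
    }
    if (is_lmn[i]) {
      threshold <- 0
    }
    if (!is.na(candidate) && yd[i + 1L] < threshold) {
      # map the flipped index back onto the original curve
      return(n + 1L - candidate)
    }
  }
  NA_integer_
}
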