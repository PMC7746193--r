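# Disease-propensity hotspot calling: per-position mean substitution
# scores, a percentile critical value over the whole protein, and maximal
# runs of consecutive positions above it.

#' Per-position mean disease-propensity score
#'
#' The mean over the 19 possible substitutions at each position.
#'
#' @param smat a `ScoreMatrix`.
#' @return numeric vector named by position.
#' @export
position_mean_dps <- function(smat) {
  n_entries <- rowSums(!is.na(smat$mat))
  if (nrow(smat$mat) && any(n_entries != 19L))
    stop("position without exactly 19 substitution scores", call. = FALSE)
  means <- rowMeans(smat$mat, na.rm = TRUE)
  names(means) <- seq_len(nrow(smat$mat))
  means
}

#' Percentile critical value of the per-position means
#'
#' Linear interpolation between order statistics (R quantile type 7), the
#' default; `method = "nearest_rank"` gives the classical nearest-rank
#' percentile instead. The percentile is taken over the whole protein, not
#' per domain.
#'
#' @param means numeric vector of per-position mean scores.
#' @param percentile percentile in (0, 100\] (default 95).
#' @param method "linear" (default) or "nearest_rank".
#' @return the score threshold.
#' @export
critical_value <- function(means, percentile = 95,
                           method = c("linear", "nearest_rank")) {
  method <- match.arg(method)
  means <- means[!is.na(means)]
  if (length(means) < 2L) stop("need >= 2 defined means", call. = FALSE)
  if (method == "linear")
    unname(stats::quantile(means, percentile / 100, type = 7))
  else
    unname(stats::quantile(means, percentile / 100, type = 1))
}

#' Call disease-propensity hotspots
#'
#' Maximal runs of consecutive positions whose mean score is strictly
#' greater than the threshold; runs shorter than `min_run` are discarded.
#'
#' @param means numeric vector of per-position means (names taken as
#'   positions; unnamed vectors are positioned 1..n).
#' @param threshold critical value, e.g. from [critical_value()].
#' @param min_run minimum run length (default 3).
#' @return object of class `HotspotSet`: list with `runs` (data.frame
#'   `start`, `end`, `length`, `run_mean`), `critical_value`, `min_run`.
#' @export
call_hotspots <- function(means, threshold, min_run = 3L) {
  min_run <- as.integer(min_run)
  if (min_run < 1L) stop("min_run must be >= 1", call. = FALSE)
  pos <- if (is.null(names(means))) seq_along(means)
         else as.integer(names(means))
  above <- !is.na(means) & means > threshold
  runs <- data.frame(start = integer(), end = integer(),
                     length = integer(), run_mean = numeric())
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    if (any(keep)) {
      runs <- data.frame(
        start = pos[starts[keep]],
        end = pos[ends[keep]],
        length = r$lengths[keep],
        run_mean = mapply(function(a, b) mean(means[a:b]),
                          starts[keep], ends[keep]))
    }
  }
  structure(list(runs = runs, critical_value = threshold,
                 min_run = min_run),
            class = "HotspotSet")
}

#' @export
print.HotspotSet <- function(x, ...) {
  cat(sprintf("HotspotSet: %d run(s) above %.2f (min_run = %d)\n",
              nrow(x$runs), x$critical_value, x$min_run))
  if (nrow(x$runs))
    for (i in seq_len(nrow(x$runs)))
      cat(sprintf("  %d-%d (len %d, mean %.2f)\n", x$runs$start[i],
                  x$runs$end[i], x$runs$length[i], x$runs$run_mean[i]))
  invisible(x)
}

# Number of hotspot positions falling inside a domain.
hotspot_positions_in <- function(hs, dom) {
  if (!nrow(hs$runs)) return(0L)
  lo <- pmax(hs$runs$start, dom$start)
  hi <- pmin(hs$runs$end, dom$end)
  sum(pmax(hi - lo + 1L, 0L))
}

#' Means strictly greater than a cutoff
#'
#' Order-preserving filter used for the "scores above 50" views.
#'
#' @param means numeric vector.
#' @param cutoff score cutoff (default 50).
#' @return the sub-vector of entries strictly greater than `cutoff`.
#' @export
high_dps_subset <- function(means, cutoff = 50) {
  means[!is.na(means) & means > cutoff]
}

#' Write called hotspots as TSV
#'
#' Columns: start, end, length, run_mean, threshold.
#'
#' @param hs a `HotspotSet`.
#' @param path output path.
#' @export
write_hotspots <- function(hs, path) {
  df <- hs$runs
  df$run_mean <- sprintf("%.4f", df$run_mean)
  df$threshold <- sprintf("%.4f", rep(hs$critical_value, nrow(df)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
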