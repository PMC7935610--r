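#' Regularize irregular event times into a fixed-width count series
#'
#' Changepoint algorithms assume regularly spaced observations; event data
#' rarely are. `bin_counts()` counts events in half-open bins
#' `[start + i*w, start + (i+1)*w)` over a user-specified range, producing a
#' `regularized_series`: a tibble with `bin_start`, `bin_end`, `count` and
#' `rate` (events per minute; a final partial bin uses its truncated width).
#'
#' @param times Numeric event times in minutes (need not be sorted).
#' @param bin_width Bin width in minutes; must be positive.
#' @param range_start,range_end Range covered, in minutes; events outside
#'   `[range_start, range_end)` are excluded. An event at exactly
#'   `range_end` is excluded (half-open convention).
#' @return A `regularized_series` tibble with attributes `bin_width`,
#'   `range_start`, `range_end`.
#' @export
#' @examples
#' bin_counts(c(0.5, 1.5, 1.6), bin_width = 1, range_start = 0, range_end = 3)
bin_counts <- function(times, bin_width = 1, range_start = 0,
                       range_end = NULL) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("'bin_width' must be a positive number")
  }
  if (is.null(range_end)) {
    range_end <- if (length(times) == 0) {
      range_start + bin_width
    } else {
      # round the last event up to a whole bin; bump if it lands exactly on
      # a boundary so the half-open range still contains it
      re <- range_start + bin_width * ceiling((max(times) - range_start) / bin_width)
      if (re <= max(times)) re + bin_width else re
    }
  }
  if (range_end <= range_start) {
    stop("'range_end' must be greater than 'range_start'")
  }
  n_bins <- ceiling((range_end - range_start) / bin_width - 1e-12)
  starts <- range_start + bin_width * (seq_len(n_bins) - 1)
  ends <- pmin(starts + bin_width, range_end)
  inside <- times[times >= range_start & times < range_end]
  idx <- floor((inside - range_start) / bin_width) + 1
  idx[idx > n_bins] <- n_bins # numerical guard at the truncated last bin
  counts <- tabulate(idx, nbins = n_bins)
  out <- tibble::tibble(
    bin_start = starts,
    bin_end = ends,
    count = counts,
    rate = counts / (ends - starts)
  )
  structure(out,
            class = c("regularized_series", class(out)),
            bin_width = bin_width,
            range_start = range_start,
            range_end = range_end)
}

#' Sliding-window event rate
#'
#' For each window `[s, s + window)`, advancing by `step` from the floor of
#' the first event time to the last event time, returns the event rate
#' (count / window) in events per minute. Intended for sensitivity checks
#' against the segment-based cascade rule.
#'
#' @param times Numeric event times in minutes.
#' @param window Window length in minutes; must be positive.
#' @param step Step between window starts in minutes; must be positive.
#' @return A tibble with `window_start` and `rate`; empty for no events.
#' @export
sliding_rate <- function(times, window = 3, step = 1) {
  if (!is.numeric(window) || length(window) != 1L || window <= 0) {
    stop("'window' must be a positive number")
  }
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    stop("'step' must be a positive number")
  }
  if (length(times) == 0) {
    return(tibble::tibble(window_start = numeric(0), rate = numeric(0)))
  }
  starts <- seq(floor(min(times)), max(times), by = step)
  rates <- vapply(starts, function(s) {
    sum(times >= s & times < s + window) / window
  }, numeric(1))
  tibble::tibble(window_start = starts, rate = rates)
}

#' @export
print.regularized_series <- function(x, ...) {
  cat(sprintf("<regularized_series: %d bins of %g min over [%g, %g), %d events>\n",
              nrow(x), attr(x, "bin_width"), attr(x, "range_start"),
              attr(x, "range_end"), sum(x$count)))
  NextMethod()
}
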