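#' Cascade identification from segmented rate series
#'
#' A cascade is a sustained period of elevated event rate: mean rate at
#' least `rate_threshold` events per minute maintained over at least
#' `min_duration` minutes (defaults 1/min over 3 min). Cascades are built
#' from changepoint segments: adjacent segments at or above the rate
#' threshold are merged into maximal runs, and a run qualifies iff its
#' total duration meets the minimum. Interval membership is half-open,
#' `[start, end)`.
#'
#' @name cascade_detection
NULL

#' Per-segment event rates from a segmentation
#'
#' Converts a changepoint result on a regularized series into contiguous
#' segments with times derived from bin boundaries: for each
#' inter-changepoint run, `mean_rate` = total count / segment duration.
#'
#' @param series A `regularized_series` from [bin_counts()].
#' @param result A `changepoint_result` computed on that series.
#' @return A tibble with `start`, `end`, `duration` (minutes), `count`,
#'   `mean_rate` (events/minute).
#' @export
segment_rates <- function(series, result) {
  stopifnot(inherits(series, "regularized_series"))
  n <- nrow(series)
  if (!is.null(result$n) && result$n != n) {
    stop(sprintf("changepoint result is for length %d, series has %d bins",
                 result$n, n))
  }
  cps <- if (inherits(result, "changepoint_result")) result$changepoints else result
  if (length(cps) && (any(cps < 1L) || any(cps >= n) || is.unsorted(cps, strictly = TRUE))) {
    stop("invalid changepoints for this series")
  }
  bounds <- c(0L, as.integer(cps), n)
  idx <- seq_len(length(bounds) - 1L)
  starts <- series$bin_start[bounds[idx] + 1L]
  ends <- series$bin_end[bounds[idx + 1L]]
  counts <- vapply(idx, function(i) {
    sum(series$count[(bounds[i] + 1L):bounds[i + 1L]])
  }, numeric(1))
  tibble::tibble(
    start = starts,
    end = ends,
    duration = ends - starts,
    count = counts,
    mean_rate = counts / (ends - starts)
  )
}

#' Find cascades among rate segments
#'
#' Merges maximal runs of adjacent segments whose `mean_rate` is at or
#' above `rate_threshold` (or treats each high-rate segment separately when
#' `merge = FALSE`) and keeps the runs whose total duration is at least
#' `min_duration`.
#'
#' @param segments A tibble as returned by [segment_rates()]; segments must
#'   be contiguous and ordered.
#' @param rate_threshold Minimum mean rate, events per minute.
#' @param min_duration Minimum qualifying duration, minutes.
#' @param merge Merge adjacent high-rate segments before the duration test.
#' @return A tibble of cascade intervals: `start`, `end`, `duration`,
#'   `count`, `mean_rate`.
#' @export
find_cascades <- function(segments, rate_threshold = 1, min_duration = 3,
                          merge = TRUE) {
  stopifnot(rate_threshold > 0, min_duration > 0)
  empty <- tibble::tibble(start = numeric(0), end = numeric(0),
                          duration = numeric(0), count = numeric(0),
                          mean_rate = numeric(0))
  if (nrow(segments) == 0) {
    return(empty)
  }
  high <- segments$mean_rate >= rate_threshold
  if (!any(high)) {
    return(empty)
  }
  if (merge) {
    runs <- rle(high)
    last <- cumsum(runs$lengths)
    first <- last - runs$lengths + 1L
    keep <- which(runs$values)
    ivs <- lapply(keep, function(i) {
      tibble::tibble(start = segments$start[first[i]],
                     end = segments$end[last[i]],
                     count = sum(segments$count[first[i]:last[i]]))
    })
    out <- dplyr::bind_rows(ivs)
  } else {
    out <- segments[high, c("start", "end", "count")]
  }
  out$duration <- out$end - out$start
  out$mean_rate <- out$count / out$duration
  out <- out[out$duration >= min_duration - 1e-9, , drop = FALSE]
  out[, c("start", "end", "duration", "count", "mean_rate"), drop = FALSE]
}

#' Flag each event as inside or outside a cascade
#'
#' `in_cascade` is `TRUE` iff the event's `relative_time` lies in some
#' cascade interval `[start, end)` of its case.
#'
#' @param events An [event_table].
#' @param cascades A tibble of cascade intervals with columns `case`,
#'   `start`, `end` (a `cascade_set` from [detect_cascades()], or
#'   [find_cascades()] output augmented with a `case` column).
#' @return `events` with an `in_cascade` logical column.
#' @export
label_events <- function(events, cascades) {
  flag <- rep(FALSE, nrow(events))
  if (nrow(cascades) > 0) {
    ev_case <- if ("case" %in% names(events)) {
      as.character(events$case)
    } else {
      rep(NA_character_, nrow(events))
    }
    for (i in seq_len(nrow(cascades))) {
      same_case <- if ("case" %in% names(cascades) && !is.na(cascades$case[i])) {
        ev_case == cascades$case[i]
      } else {
        rep(TRUE, nrow(events))
      }
      flag <- flag | (same_case &
                        events$relative_time >= cascades$start[i] &
                        events$relative_time < cascades$end[i])
    }
  }
  events$in_cascade <- flag
  new_event_table(events)
}

#' Attribute a trigger event type to each cascade
#'
#' The trigger is the event type of the earliest event inside the cascade
#' interval (ties broken by table order). A cascade with no events violates
#' the rate rule and raises an internal-consistency error.
#'
#' @inheritParams label_events
#' @return `cascades` with `trigger` and `n_events` columns appended.
#' @export
cascade_triggers <- function(events, cascades) {
  if (nrow(cascades) == 0) {
    cascades$trigger <- character(0)
    cascades$n_events <- integer(0)
    return(cascades)
  }
  stopifnot("event_type" %in% names(events))
  ev_case <- if ("case" %in% names(events)) as.character(events$case) else NULL
  trig <- character(nrow(cascades))
  nev <- integer(nrow(cascades))
  for (i in seq_len(nrow(cascades))) {
    sel <- events$relative_time >= cascades$start[i] &
      events$relative_time < cascades$end[i]
    if (!is.null(ev_case) && "case" %in% names(cascades)) {
      sel <- sel & ev_case == cascades$case[i]
    }
    idx <- which(sel)
    if (length(idx) == 0) {
      stop(sprintf(
        "internal consistency error: cascade [%g, %g) contains no events",
        cascades$start[i], cascades$end[i]))
    }
    first <- idx[which.min(events$relative_time[idx])]
    trig[i] <- as.character(events$event_type[first])
    nev[i] <- length(idx)
  }
  cascades$trigger <- trig
  cascades$n_events <- nev
  cascades
}

#' Tally cascade triggers by event type
#'
#' @param cascades A cascade tibble with a `trigger` column (from
#'   [cascade_triggers()] or [detect_cascades()]).
#' @return A tibble with `trigger` and `n`, sorted by count descending.
#' @export
trigger_tally <- function(cascades) {
  stopifnot("trigger" %in% names(cascades))
  tab <- table(cascades$trigger)
  out <- tibble::tibble(trigger = names(tab), n = as.integer(tab))
  out[order(-out$n, out$trigger), , drop = FALSE]
}

#' Distribution of cascade counts over cases
#'
#' @param cascades A cascade tibble with a `case` column.
#' @param cases Character vector of all case identifiers, including cases
#'   with zero cascades (the percentage denominator). Defaults to the
#'   `cases` attribute set by [detect_cascades()], or to the cases present
#'   in `cascades`.
#' @return A list with `per_case` (tibble `case`, `n_cascades`) and
#'   `histogram` (tibble `n_cascades`, `n_cases`, `pct`).
#' @export
cascades_per_case <- function(cascades, cases = NULL) {
  if (is.null(cases)) cases <- attr(cascades, "cases")
  if (is.null(cases)) cases <- unique(as.character(cascades$case))
  cases <- as.character(cases)
  counts <- vapply(unname(cases), function(cs) {
    sum(as.character(cascades$case) == cs)
  }, integer(1), USE.NAMES = FALSE)
  per_case <- tibble::tibble(case = cases, n_cascades = counts)
  tab <- table(factor(counts, levels = sort(unique(c(0L, counts)))))
  histogram <- tibble::tibble(
    n_cascades = as.integer(names(tab)),
    n_cases = as.integer(tab),
    pct = 100 * as.integer(tab) / length(cases)
  )
  list(per_case = per_case, histogram = histogram)
}

#' Run the full cascade-detection pipeline
#'
#' For each case: bins `relative_time` into fixed-width counts over
#' `[0, last event rounded up to a whole bin]`, segments the count series
#' with the chosen changepoint method, converts segments to rates, and
#' applies the cascade rule. Events are then labeled and triggers
#' attributed.
#'
#' @param events An [event_table]; needs `event_type` for trigger
#'   attribution (optional otherwise).
#' @param bin_width Bin width in minutes for regularization.
#' @param method,penalty,max_changepoints,normalize Passed to
#'   [detect_changepoints()].
#' @param rate_threshold,min_duration,merge Passed to [find_cascades()].
#' @return A list of class `cascade_analysis`: `events` (labeled),
#'   `cascades` (tibble with `case`, intervals, `trigger`, `n_events`; the
#'   full case universe in attribute `cases`), `changepoints` and `series`
#'   (named per-case lists), and `params`.
#' @export
detect_cascades <- function(events, bin_width = 1,
                            method = "pelt", penalty = "BIC",
                            max_changepoints = NULL, normalize = NULL,
                            rate_threshold = 1, min_duration = 3,
                            merge = TRUE) {
  has_case <- "case" %in% names(events)
  cases <- if (has_case) unique(as.character(events$case)) else "all"
  series_list <- list()
  cp_list <- list()
  casc_list <- list()
  for (cs in cases) {
    rt <- if (has_case) {
      events$relative_time[as.character(events$case) == cs]
    } else {
      events$relative_time
    }
    series <- bin_counts(rt, bin_width = bin_width, range_start = 0)
    cp <- detect_changepoints(series, method = method, penalty = penalty,
                              max_changepoints = max_changepoints,
                              normalize = normalize)
    segs <- segment_rates(series, cp)
    casc <- find_cascades(segs, rate_threshold = rate_threshold,
                          min_duration = min_duration, merge = merge)
    if (nrow(casc) > 0) casc <- cbind(case = cs, casc)
    series_list[[cs]] <- series
    cp_list[[cs]] <- cp
    casc_list[[cs]] <- casc
  }
  cascades <- dplyr::bind_rows(casc_list)
  if (nrow(cascades) == 0) {
    cascades <- tibble::tibble(case = character(0), start = numeric(0),
                               end = numeric(0), duration = numeric(0),
                               count = numeric(0), mean_rate = numeric(0))
  }
  cascades <- tibble::as_tibble(cascades)
  labeled <- label_events(events, cascades)
  if ("event_type" %in% names(events) && nrow(cascades) > 0) {
    cascades <- cascade_triggers(labeled, cascades)
  }
  attr(cascades, "cases") <- cases
  structure(list(
    events = labeled,
    cascades = cascades,
    changepoints = cp_list,
    series = series_list,
    params = list(bin_width = bin_width, method = method, penalty = penalty,
                  rate_threshold = rate_threshold,
                  min_duration = min_duration, merge = merge)
  ), class = "cascade_analysis")
}

#' @export
print.cascade_analysis <- function(x, ...) {
  cpc <- cascades_per_case(x$cascades)
  cat(sprintf("<cascade_analysis: %d cascades over %d cases>\n",
              nrow(x$cascades), nrow(cpc$per_case)))
  if (nrow(x$cascades) > 0) {
    print(tibble::as_tibble(x$cascades), n = 10)
  }
  invisible(x)
}

#' Export cascade intervals as a BED-like TSV
#'
#' Writes one row per cascade: case, start_min, end_min, trigger, n_events,
#' mean_rate, tab-separated.
#'
#' @param cascades Cascade tibble from [detect_cascades()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cascades <- function(cascades, path) {
  out <- tibble::tibble(
    case = cascades$case,
    start_min = cascades$start,
    end_min = cascades$end,
    trigger = if ("trigger" %in% names(cascades)) cascades$trigger else NA,
    n_events = if ("n_events" %in% names(cascades)) cascades$n_events else NA,
    mean_rate = cascades$mean_rate
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
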