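#' Event tables
#'
#' An `event_table` is a tibble of timestamped event records — one row per
#' event — with a canonical `time` column (numeric minutes), optional `case`
#' and `event_type` columns, and two derived columns: `relative_time`
#' (minutes since the first event of the same case) and `any_event`
#' (constant 1, the default y variable for stem plots). Any further
#' attribute columns from the source file are preserved verbatim.
#'
#' @name event_table
NULL

EVENT_TABLE_CLASS <- c("event_table", "tbl_df", "tbl", "data.frame")

# Display-name aliases used on CSV export and accepted in filter expressions.
CANONICAL_ALIASES <- c(
  Time = "time", Case = "case", EventType = "event_type",
  RelativeTime = "relative_time", AnyEvent = "any_event"
)

new_event_table <- function(df) {
  structure(df, class = EVENT_TABLE_CLASS)
}

#' Validate the invariants of an event table
#'
#' Checks that `time` has no missing values, `any_event` is identically 1,
#' `relative_time` is non-negative with a per-case minimum of exactly 0, and
#' times are non-decreasing within each case.
#'
#' @param events An `event_table`.
#' @return `events`, invisibly, if all invariants hold; otherwise an error.
#' @export
validate_event_table <- function(events) {
  stopifnot(is.data.frame(events), "time" %in% names(events))
  if (anyNA(events$time)) {
    stop("event table invariant violated: missing values in 'time'")
  }
  if (nrow(events) > 0) {
    if (!all(events$any_event == 1)) {
      stop("event table invariant violated: 'any_event' must be 1 for every row")
    }
    if (any(events$relative_time < 0)) {
      stop("event table invariant violated: negative 'relative_time'")
    }
    grp <- if ("case" %in% names(events)) as.character(events$case) else rep("", nrow(events))
    mins <- tapply(events$relative_time, grp, min)
    if (any(abs(mins) > 1e-9)) {
      stop("event table invariant violated: per-case minimum relative_time must be 0")
    }
    unsorted <- tapply(events$time, grp, function(t) any(diff(t) < 0))
    if (any(unlist(unsorted))) {
      stop("event table invariant violated: times must be non-decreasing within a case")
    }
  }
  invisible(events)
}

# Parse a raw time column into numeric minutes. Numeric input passes
# through; datetime strings become minutes since the earliest timestamp.
parse_time_column <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  if (inherits(x, "POSIXct") || inherits(x, "Date")) {
    t0 <- min(x)
    return(as.numeric(difftime(x, t0, units = "mins")))
  }
  xs <- trimws(as.character(x))
  num <- suppressWarnings(as.numeric(xs))
  if (!anyNA(num)) {
    return(num)
  }
  # datetime strings: ISO-8601 first, then common US-style formats
  parsed <- suppressWarnings(readr::parse_datetime(xs))
  if (anyNA(parsed)) {
    fmts <- c(
      "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
      "%m/%d/%Y %H:%M:%S", "%m/%d/%Y %H:%M", "%m/%d/%y %H:%M"
    )
    for (f in fmts) {
      cand <- suppressWarnings(as.POSIXct(xs, format = f, tz = "UTC"))
      if (!anyNA(cand)) {
        parsed <- cand
        break
      }
    }
  }
  if (anyNA(parsed)) {
    bad <- xs[which(is.na(suppressWarnings(readr::parse_datetime(xs))))[1]]
    stop(sprintf("unparseable time value: '%s'", bad))
  }
  t0 <- min(parsed)
  as.numeric(difftime(parsed, t0, units = "mins"))
}

#' Load tabular event data
#'
#' Reads a comma- or tab-separated file with a header row, maps the named
#' columns to the time / case / event-type roles, converts the time column
#' to numeric minutes (datetime strings become minutes since the earliest
#' timestamp in the file), sorts rows by (case, time) with a stable sort,
#' and derives `relative_time` and `any_event`.
#'
#' @param path Path to a CSV or TSV file.
#' @param time_col Name of the time column (required; must exist).
#' @param case_col Optional name of the case-identifier column.
#' @param type_col Optional name of the event-type column.
#' @param delim Field delimiter; inferred from the file extension when `NULL`
#'   (`.tsv`/`.tab` means tab, anything else comma).
#' @return An [event_table].
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("Time,Case,EventType", "5,A,EQ", "7,A,TRN", "10,B,COM"), f)
#' load_events(f, time_col = "Time", case_col = "Case", type_col = "EventType")
load_events <- function(path, time_col = "Time", case_col = NULL,
                        type_col = NULL, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE)
  for (col in c(time_col, case_col, type_col)) {
    if (!col %in% names(raw)) {
      stop(sprintf("column '%s' not found in '%s'", col, path))
    }
  }
  tvals <- raw[[time_col]]
  missing_t <- is.na(tvals) | (is.character(tvals) & trimws(tvals) == "")
  if (any(missing_t)) {
    stop(sprintf("missing value in time column '%s' at row %d",
                 time_col, which(missing_t)[1]))
  }
  as_event_table(raw, time_col = time_col, case_col = case_col,
                 type_col = type_col)
}

#' Coerce a data frame of events to an event table
#'
#' In-memory counterpart of [load_events()]: maps columns to roles, parses
#' the time column, sorts, and derives `relative_time` and `any_event`.
#'
#' @inheritParams load_events
#' @param df A data frame with one row per event.
#' @return An [event_table].
#' @export
as_event_table <- function(df, time_col = "time", case_col = NULL,
                           type_col = NULL) {
  stopifnot(is.data.frame(df))
  if (!time_col %in% names(df)) {
    stop(sprintf("column '%s' not found", time_col))
  }
  if (anyNA(df[[time_col]])) {
    stop(sprintf("missing value in time column '%s' at row %d",
                 time_col, which(is.na(df[[time_col]]))[1]))
  }
  out <- tibble::as_tibble(df)
  time <- parse_time_column(out[[time_col]])
  out[[time_col]] <- NULL
  mapped <- character(0)
  if (!is.null(case_col) && case_col != "case") {
    if (!case_col %in% names(out)) stop(sprintf("column '%s' not found", case_col))
    out$case <- out[[case_col]]
    out[[case_col]] <- NULL
    mapped <- c(mapped, "case")
  }
  if (!is.null(type_col) && type_col != "event_type") {
    if (!type_col %in% names(out)) stop(sprintf("column '%s' not found", type_col))
    out$event_type <- out[[type_col]]
    out[[type_col]] <- NULL
  }
  out$time <- time
  if ("case" %in% names(out)) out$case <- as.character(out$case)
  if ("event_type" %in% names(out)) out$event_type <- as.character(out$event_type)
  ord <- if ("case" %in% names(out)) {
    order(out$case, out$time, method = "radix")
  } else {
    order(out$time, method = "radix")
  }
  out <- out[ord, , drop = FALSE]
  lead <- intersect(c("time", "case", "event_type"), names(out))
  out <- out[, c(lead, setdiff(names(out), lead)), drop = FALSE]
  compute_relative_time(new_event_table(out))
}

#' Derive relative time and the any-event indicator
#'
#' `relative_time` is `time` minus the earliest `time` within the same case
#' (or the global minimum when there is no case column); `any_event` is 1
#' for every row.
#'
#' @param events An `event_table` (or data frame with a `time` column).
#' @return The input with `relative_time` and `any_event` (re)computed.
#' @export
compute_relative_time <- function(events) {
  stopifnot("time" %in% names(events))
  if (nrow(events) == 0) {
    events$relative_time <- numeric(0)
    events$any_event <- integer(0)
    return(new_event_table(events))
  }
  if ("case" %in% names(events)) {
    events$relative_time <-
      events$time - stats::ave(events$time, events$case, FUN = min)
  } else {
    events$relative_time <- events$time - min(events$time)
  }
  events$any_event <- rep(1L, nrow(events))
  validate_event_table(new_event_table(events))
  new_event_table(events)
}

#' Write an event table to CSV
#'
#' Columns are written under their display names (`Time`, `Case`,
#' `EventType`), extra attribute columns verbatim, with the derived
#' `RelativeTime` and `AnyEvent` columns appended last.
#'
#' @param events An `event_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- tibble::as_tibble(as.data.frame(events))
  nm <- names(out)
  display <- stats::setNames(names(CANONICAL_ALIASES), CANONICAL_ALIASES)
  names(out) <- ifelse(nm %in% names(display), display[nm], nm)
  derived <- intersect(c("RelativeTime", "AnyEvent"), names(out))
  out <- out[, c(setdiff(names(out), derived), derived), drop = FALSE]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table: %d events%s%s>\n", nrow(x),
              if ("case" %in% names(x))
                sprintf(", %d cases", length(unique(x$case))) else "",
              if ("event_type" %in% names(x))
                sprintf(", %d event types", length(unique(x$event_type))) else ""))
  NextMethod()
}
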