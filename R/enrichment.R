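#' Event-type enrichment probabilities
#'
#' Given events labeled in/out of cascades, computes per-type counts and
#' four conditional probabilities (pooled over all cases):
#' \itemize{
#'   \item `p_cascade_given_et` = n_in(ET) / n(ET)
#'   \item `p_et` = n(ET) / N
#'   \item `p_et_given_cascade` = n_in(ET) / N_in
#'   \item `p_et_given_notcascade` = (n(ET) - n_in(ET)) / (N - N_in)
#' }
#' plus a pooled "Any Event" row (N_in, N, N_in/N, 1, 1, 1). Probabilities
#' are kept unrounded; rounding to 2 decimals (half away from zero) is
#' applied only for display and by [round_half_up()].
#'
#' @name enrichment
NULL

#' Round half away from zero
#'
#' Unlike base [round()] (banker's rounding), halves round away from zero:
#' `round_half_up(0.125, 2)` is `0.13`.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Compute the enrichment table
#'
#' @param labeled_events An [event_table] with `event_type` and
#'   `in_cascade` columns (see [label_events()]).
#' @return An `enrichment_table` tibble with one row per event type plus a
#'   final `"Any Event"` row; columns `event_type`, `n_in`, `n`, and the
#'   four unrounded probabilities. Rows are ordered by `p_cascade_given_et`
#'   descending (ties by `n` descending). Attributes `N` and `N_in` hold
#'   the totals. With zero in-cascade events, `p_et_given_cascade` is `NA`.
#' @export
#' @examples
#' ev <- as_event_table(data.frame(
#'   time = 1:6, event_type = c("A", "A", "B", "B", "B", "A")
#' ))
#' ev$in_cascade <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
#' enrichment_table(ev)
enrichment_table <- function(labeled_events) {
  stopifnot("event_type" %in% names(labeled_events),
            "in_cascade" %in% names(labeled_events))
  N <- nrow(labeled_events)
  if (N == 0) stop("cannot compute enrichment from zero events")
  et <- as.character(labeled_events$event_type)
  inc <- as.logical(labeled_events$in_cascade)
  N_in <- sum(inc)
  types <- sort(unique(et))
  n <- vapply(types, function(x) sum(et == x), integer(1))
  n_in <- vapply(types, function(x) sum(et == x & inc), integer(1))
  tab <- tibble::tibble(
    event_type = types,
    n_in = as.integer(n_in),
    n = as.integer(n),
    p_cascade_given_et = n_in / n,
    p_et = n / N,
    p_et_given_cascade = if (N_in > 0) n_in / N_in else NA_real_,
    p_et_given_notcascade = if (N > N_in) (n - n_in) / (N - N_in) else NA_real_
  )
  tab <- tab[order(-tab$p_cascade_given_et, -tab$n, tab$event_type), , drop = FALSE]
  any_row <- tibble::tibble(
    event_type = "Any Event",
    n_in = as.integer(N_in),
    n = as.integer(N),
    p_cascade_given_et = N_in / N,
    p_et = 1,
    p_et_given_cascade = if (N_in > 0) 1 else NA_real_,
    p_et_given_notcascade = if (N > N_in) 1 else NA_real_
  )
  out <- dplyr::bind_rows(tab, any_row)
  structure(out, class = c("enrichment_table", class(tibble::tibble())),
            N = N, N_in = N_in)
}

#' Expand per-type counts into a labeled event table
#'
#' Builds a synthetic labeled event stream whose per-type in-cascade and
#' total counts equal the given table — useful for recomputing enrichment
#' probabilities from published count columns.
#'
#' @param counts A data frame with columns `event_type`, `n_in`, `n`
#'   (`0 <= n_in <= n`).
#' @return An [event_table] with `event_type` and `in_cascade`.
#' @export
events_from_counts <- function(counts) {
  stopifnot(all(c("event_type", "n_in", "n") %in% names(counts)),
            all(counts$n_in >= 0), all(counts$n_in <= counts$n))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    tibble::tibble(
      event_type = rep(as.character(counts$event_type[i]), counts$n[i]),
      in_cascade = rep(c(TRUE, FALSE),
                       c(counts$n_in[i], counts$n[i] - counts$n_in[i]))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$time <- seq_len(nrow(out))
  ev <- as_event_table(out)
  ev
}

#' Percentage shares for one event type
#'
#' Returns the three headline percentages for an event type: its share of
#' in-cascade events (`100 * P(ET|cascade)`), of all events (`100 * P(ET)`),
#' and of non-cascade events (`100 * P(ET|notcascade)`), each rounded to
#' the nearest integer percent (half away from zero).
#'
#' @param table An `enrichment_table`.
#' @param type Event type present in the table.
#' @return Named numeric vector `pct_of_cascade`, `pct_overall`,
#'   `pct_of_noncascade`.
#' @export
share_statements <- function(table, type) {
  i <- which(table$event_type == type)
  if (length(i) != 1L) {
    stop(sprintf("unknown event type '%s'", type))
  }
  c(
    pct_of_cascade = round_half_up(100 * table$p_et_given_cascade[i]),
    pct_overall = round_half_up(100 * table$p_et[i]),
    pct_of_noncascade = round_half_up(100 * table$p_et_given_notcascade[i])
  )
}

#' Write an enrichment table as CSV
#'
#' Probabilities are written rounded to 2 decimals, half away from zero,
#' under the column names `P_cascade_given_ET`, `P_ET`, `P_ET_given_cascade`,
#' `P_ET_given_notcascade`.
#'
#' @param table An `enrichment_table`.
#' @param path Output file path.
#' @param digits Decimal places for the probability columns.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(table, path, digits = 2) {
  out <- tibble::tibble(
    EventType = table$event_type,
    InCascadeCount = table$n_in,
    DisruptionCount = table$n,
    P_cascade_given_ET = round_half_up(table$p_cascade_given_et, digits),
    P_ET = round_half_up(table$p_et, digits),
    P_ET_given_cascade = round_half_up(table$p_et_given_cascade, digits),
    P_ET_given_notcascade = round_half_up(table$p_et_given_notcascade, digits)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("<enrichment_table: %d event types, N = %d, N_in = %d>\n",
              nrow(x) - 1L, attr(x, "N"), attr(x, "N_in")))
  shown <- tibble::as_tibble(as.data.frame(x))
  probs <- c("p_cascade_given_et", "p_et", "p_et_given_cascade",
             "p_et_given_notcascade")
  shown[probs] <- lapply(shown[probs], round_half_up, digits = 2)
  print(shown, n = nrow(shown))
  invisible(x)
}
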