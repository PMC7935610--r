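#' Synthetic disruption-stream generator
#'
#' Emulates the structure of observed surgical flow-disruption data: each
#' case is a piecewise-constant-rate point process over `[0, D)` minutes
#' with a low baseline rate, zero or more planted high-rate cascade
#' intervals, and event types drawn from categorical distributions that
#' differ inside versus outside cascades. Ground-truth intervals and
#' labels are returned so recovery can be scored.
#'
#' Defaults describe a study shaped like the motivating 41-case dataset:
#' 41 cases of 240 minutes, baseline 0.16 events/min, one 5-minute cascade
#' at 2 events/min per case (about 48 events per case, about 2,000 events
#' in total), and type distributions shaped from the observed in/out-of-
#' cascade marginals over the 9 disruption-type codes.
#'
#' @name synthetic_data
NULL

DISRUPTION_TYPES <- c("COM", "COO", "EQ", "EXT", "IC", "SDM", "TRN", "ENV", "PF")

#' Default event-type distributions
#'
#' Categorical distributions over the 9 disruption-type codes used outside
#' (`default_p_out`) and inside (`default_p_in`) cascades, shaped from the
#' observed study's pooled marginals: outside cascades EQ and COO dominate;
#' inside cascades TRN is elevated.
#'
#' @return Named probability vector summing to 1.
#' @export
default_p_out <- function() {
  c(COM = 214, COO = 314, EQ = 370, EXT = 112, IC = 100, SDM = 116,
    TRN = 259, ENV = 14, PF = 47) / 1546
}

#' @rdname default_p_out
#' @export
default_p_in <- function() {
  c(COM = 64, COO = 71, EQ = 90, EXT = 13, IC = 26, SDM = 32,
    TRN = 117, ENV = 4, PF = 11) / 428
}

#' Configuration for the synthetic generator
#'
#' @param n_cases Number of cases.
#' @param case_duration Case length D, minutes.
#' @param baseline_rate Baseline event rate lambda0, events/minute
#'   (`>= 0`).
#' @param cascade_rate In-cascade event rate lambda1, events/minute
#'   (`> baseline_rate`).
#' @param cascades_per_case Planted cascades per case: a single count or a
#'   vector of per-case counts (recycled to `n_cases`).
#' @param cascade_duration Length of each planted cascade, minutes.
#' @param p_out,p_in Named probability vectors over event types outside /
#'   inside cascades (each summing to 1).
#' @param forced_trigger Optional event type forced as the first event of
#'   every cascade interval.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_cases = 41, case_duration = 240,
                             baseline_rate = 0.16, cascade_rate = 2,
                             cascades_per_case = 1, cascade_duration = 5,
                             p_out = default_p_out(), p_in = default_p_in(),
                             forced_trigger = NULL) {
  stopifnot(n_cases >= 0, case_duration > 0, cascade_duration > 0)
  if (!(baseline_rate >= 0 && cascade_rate > baseline_rate)) {
    stop("need cascade_rate > baseline_rate >= 0")
  }
  for (p in list(p_out, p_in)) {
    if (is.null(names(p)) || abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      stop("'p_out' and 'p_in' must be named non-negative vectors summing to 1")
    }
  }
  if (!is.null(forced_trigger) && !forced_trigger %in% names(p_in)) {
    stop(sprintf("forced_trigger '%s' is not a known event type", forced_trigger))
  }
  k <- suppressWarnings(as.integer(cascades_per_case))
  if (anyNA(k) || any(k < 0)) stop("'cascades_per_case' must be non-negative counts")
  if (any(k * cascade_duration > case_duration)) {
    stop("cascade intervals cannot be placed without overlap in 'case_duration'")
  }
  structure(list(
    n_cases = as.integer(n_cases), case_duration = case_duration,
    baseline_rate = baseline_rate, cascade_rate = cascade_rate,
    cascades_per_case = k, cascade_duration = cascade_duration,
    p_out = p_out, p_in = p_in, forced_trigger = forced_trigger
  ), class = "synthetic_config")
}

# k non-overlapping intervals of length L uniformly placed in [0, D):
# drop the occupied length, draw sorted starts in the free space, re-inflate.
place_intervals <- function(k, L, D) {
  if (k == 0) {
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  }
  free <- D - k * L
  u <- sort(stats::runif(k, 0, free))
  starts <- u + (seq_len(k) - 1) * L
  tibble::tibble(start = starts, end = starts + L)
}

sample_piece <- function(rate, lo, hi) {
  n <- stats::rpois(1, rate * (hi - lo))
  sort(stats::runif(n, lo, hi))
}

#' Generate one synthetic case
#'
#' Places the case's cascade intervals uniformly without overlap, samples
#' event times from the piecewise-constant-rate process (rate
#' `baseline_rate` outside the intervals, `cascade_rate` inside), draws
#' event types from `p_out` / `p_in` by location, and — if
#' `forced_trigger` is set — overwrites the first event type of each
#' interval. Fully reproducible from `seed`.
#'
#' @param config A [synthetic_config()].
#' @param case_id Case identifier (any scalar; stored as character).
#' @param seed Integer seed for this case.
#' @param n_cascades Number of cascades for this case; defaults to the
#'   first element of `config$cascades_per_case`.
#' @return A `synthetic_case` list: `events` (tibble `time`, `case`,
#'   `event_type`, `true_in_cascade`), `intervals` (ground-truth tibble
#'   `start`, `end`), `case_id`, `seed`.
#' @export
generate_case <- function(config, case_id = "case_1", seed = 1,
                          n_cascades = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(n_cascades)) n_cascades <- config$cascades_per_case[1]
  if (n_cascades * config$cascade_duration > config$case_duration) {
    stop("cascade intervals cannot be placed without overlap")
  }
  set.seed(as.integer(seed))
  D <- config$case_duration
  ivs <- place_intervals(n_cascades, config$cascade_duration, D)
  # complementary baseline pieces
  cuts <- c(0, as.vector(rbind(ivs$start, ivs$end)), D)
  times <- numeric(0)
  inside <- logical(0)
  types <- character(0)
  for (j in seq_len(length(cuts) - 1)) {
    lo <- cuts[j]
    hi <- cuts[j + 1]
    if (hi <= lo) next
    is_cascade <- (j %% 2L == 0L) # odd pieces are baseline, even are cascades
    rate <- if (is_cascade) config$cascade_rate else config$baseline_rate
    tt <- sample_piece(rate, lo, hi)
    if (length(tt) == 0) next
    p <- if (is_cascade) config$p_in else config$p_out
    ty <- sample(names(p), length(tt), replace = TRUE, prob = p)
    if (is_cascade && !is.null(config$forced_trigger)) {
      ty[1] <- config$forced_trigger
    }
    times <- c(times, tt)
    inside <- c(inside, rep(is_cascade, length(tt)))
    types <- c(types, ty)
  }
  ord <- order(times)
  events <- tibble::tibble(
    time = times[ord],
    case = as.character(case_id),
    event_type = types[ord],
    true_in_cascade = inside[ord]
  )
  structure(list(events = events, intervals = ivs,
                 case_id = as.character(case_id), seed = as.integer(seed)),
            class = "synthetic_case")
}

# Deterministic master-seed -> per-case-seed map; kept below 2^31.
case_seed <- function(master_seed, case_index) {
  as.integer((as.numeric(master_seed) + 7919 * case_index) %% 2147483647)
}

#' Generate a synthetic study
#'
#' One case per case id (seeds derived deterministically from the master
#' seed), pooled into a single [event_table] with ground-truth labels, plus
#' the ground-truth enrichment table computed from those labels — the
#' oracle the detection pipeline should approach.
#'
#' @param config A [synthetic_config()].
#' @param seed Master seed.
#' @return A `synthetic_study` list: `events` (pooled `event_table` with
#'   `true_in_cascade`), `truth` (tibble `case`, `start`, `end` on the
#'   absolute per-case clock), `anchors` (tibble `case`, `t0` = first event
#'   time, the offset between absolute and relative clocks),
#'   `truth_enrichment`, `cases`, `config`, `seed`.
#' @export
generate_study <- function(config, seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_cases
  ids <- sprintf("case_%02d", seq_len(n))
  k_per_case <- rep_len(config$cascades_per_case, max(n, 1L))
  case_list <- vector("list", n)
  truth_list <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- generate_case(config, case_id = ids[i], seed = case_seed(seed, i),
                        n_cascades = k_per_case[i])
    case_list[[i]] <- sc$events
    if (nrow(sc$intervals) > 0) {
      truth_list[[i]] <- cbind(case = ids[i], sc$intervals)
    }
  }
  pooled <- dplyr::bind_rows(case_list)
  truth <- tibble::as_tibble(dplyr::bind_rows(truth_list))
  if (nrow(truth) == 0) {
    truth <- tibble::tibble(case = character(0), start = numeric(0),
                            end = numeric(0))
  }
  if (nrow(pooled) == 0) {
    events <- new_event_table(tibble::tibble(
      time = numeric(0), case = character(0), event_type = character(0),
      true_in_cascade = logical(0), relative_time = numeric(0),
      any_event = integer(0)))
    anchors <- tibble::tibble(case = character(0), t0 = numeric(0))
    truth_enr <- NULL
  } else {
    events <- as_event_table(pooled)
    anchors <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(pooled),
                                                .data$case),
                                t0 = min(.data$time), .groups = "drop")
    labeled <- events
    labeled$in_cascade <- labeled$true_in_cascade
    truth_enr <- enrichment_table(labeled)
  }
  structure(list(events = events, truth = truth, anchors = anchors,
                 truth_enrichment = truth_enr, cases = ids,
                 config = config, seed = as.integer(seed)),
            class = "synthetic_study")
}

#' Write a synthetic study to disk
#'
#' Writes the pooled events as CSV (`Time`, `Case`, `EventType` plus the
#' ground-truth label) and the ground-truth intervals as JSON.
#'
#' @param study A `synthetic_study`.
#' @param events_path CSV output path.
#' @param truth_path Optional JSON output path for ground-truth intervals.
#' @return `events_path`, invisibly.
#' @export
write_study <- function(study, events_path, truth_path = NULL) {
  ev <- study$events
  out <- tibble::tibble(Time = ev$time, Case = ev$case,
                        EventType = ev$event_type,
                        TrueInCascade = ev$true_in_cascade)
  readr::write_csv(out, events_path, progress = FALSE)
  if (!is.null(truth_path)) {
    jsonlite::write_json(study$truth, truth_path, digits = NA)
  }
  invisible(events_path)
}

#' Jaccard overlap between two sets of intervals
#'
#' Length of the intersection divided by length of the union of the two
#' interval sets (each a data frame with `start` and `end`). Used to score
#' recovery of planted cascades.
#'
#' @param a,b Data frames of half-open intervals (`start`, `end`).
#' @return Jaccard index in `[0, 1]`; `NaN` when both sets are empty.
#' @export
interval_jaccard <- function(a, b) {
  pts <- sort(unique(c(a$start, a$end, b$start, b$end)))
  if (length(pts) < 2) {
    return(NaN)
  }
  lo <- pts[-length(pts)]
  hi <- pts[-1]
  mid <- (lo + hi) / 2
  in_a <- vapply(mid, function(m) any(m >= a$start & m < a$end), logical(1))
  in_b <- vapply(mid, function(m) any(m >= b$start & m < b$end), logical(1))
  len <- hi - lo
  union_len <- sum(len[in_a | in_b])
  if (union_len == 0) {
    return(NaN)
  }
  sum(len[in_a & in_b]) / union_len
}
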