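make_series <- function(counts, bin_width = 1) {
  # regularized series with known counts: one event at each bin midpoint
  times <- rep((seq_along(counts) - 0.5) * bin_width, counts)
  bin_counts(times, bin_width = bin_width, range_start = 0,
             range_end = length(counts) * bin_width)
}

test_that("segment rates follow the changepoint boundaries", {
  rs <- make_series(c(0, 0, 0, 3, 3, 3))
  fit <- exact_segmentation(rs$count, 1)
  segs <- segment_rates(rs, fit)
  expect_equal(fit$changepoints, 3L)
  expect_equal(segs$start, c(0, 3))
  expect_equal(segs$end, c(3, 6))
  expect_equal(segs$mean_rate, c(0, 3))
  # no changepoints: one segment spanning the range
  whole <- segment_rates(rs, exact_segmentation(rs$count, 1e6))
  expect_equal(nrow(whole), 1)
  expect_equal(whole$duration, 6)
})

test_that("segment rates equal brute-force recounts on random input", {
  set.seed(41)
  times <- sort(runif(120, 0, 40))
  rs <- bin_counts(times, 1, 0, 40)
  fit <- exact_segmentation(rs$count, 4)
  segs <- segment_rates(rs, fit)
  for (i in seq_len(nrow(segs))) {
    n_direct <- sum(times >= segs$start[i] & times < segs$end[i])
    expect_equal(segs$count[i], n_direct)
    expect_equal(segs$mean_rate[i], n_direct / segs$duration[i])
  }
  expect_equal(sum(segs$duration), 40)
  bad <- exact_segmentation(rep(1, 10), 1)
  expect_error(segment_rates(rs, bad), "length")
})

test_that("the cascade rule gates on rate and minimum duration", {
  one <- tibble::tibble(start = 0, end = 4, duration = 4, count = 4.8,
                        mean_rate = 1.2)
  expect_equal(nrow(find_cascades(one)), 1)
  short <- tibble::tibble(start = 0, end = 2, duration = 2, count = 2.4,
                          mean_rate = 1.2)
  expect_equal(nrow(find_cascades(short)), 0)
})

test_that("adjacent high-rate segments merge into one qualifying run", {
  segs <- tibble::tibble(
    start = c(0, 2, 4, 10), end = c(2, 4, 10, 12),
    count = c(3, 2.2, 1, 2), duration = c(2, 2, 6, 2)
  )
  segs$mean_rate <- segs$count / segs$duration
  got <- find_cascades(segs)
  expect_equal(nrow(got), 1)
  expect_equal(got$start, 0)
  expect_equal(got$end, 4)
  expect_equal(got$mean_rate, (3 + 2.2) / 4)
  # non-merging mode treats them separately: both too short
  expect_equal(nrow(find_cascades(segs, merge = FALSE)), 0)
})

test_that("every reported cascade satisfies the rule by construction", {
  set.seed(43)
  for (rep in 1:10) {
    counts <- rpois(40, lambda = sample(c(0.3, 1.5), 40, replace = TRUE))
    rs <- make_series(counts)
    segs <- segment_rates(rs, pelt(rs$count, 2))
    casc <- find_cascades(segs, rate_threshold = 1, min_duration = 3)
    if (nrow(casc)) {
      expect_true(all(casc$duration >= 3 - 1e-9))
      expect_true(all(casc$mean_rate >= 1 - 1e-9))
    }
  }
})

test_that("raising the threshold or duration never yields more cascades", {
  set.seed(47)
  counts <- rpois(60, lambda = rep(c(0.2, 2, 0.2, 1.4), each = 15))
  segs <- segment_rates(make_series(counts), pelt(counts, 2))
  for (sweep in list(
    lapply(c(0.5, 1, 1.5, 2), function(r) find_cascades(segs, rate_threshold = r)),
    lapply(c(1, 3, 5, 8), function(w) find_cascades(segs, min_duration = w))
  )) {
    n <- vapply(sweep, nrow, integer(1))
    expect_true(all(diff(n) <= 0))
  }
})

test_that("event labeling uses half-open intervals per case", {
  # anchor each case at 0 so relative and absolute time coincide
  ev <- as_event_table(data.frame(
    time = c(0, 10, 13.9, 14, 12), case = c("A", "A", "A", "A", "B")
  ), case_col = "case")
  casc <- tibble::tibble(case = "A", start = 10, end = 14)
  lab <- label_events(ev, casc)
  expect_equal(lab$in_cascade[lab$case == "A"], c(FALSE, TRUE, TRUE, FALSE))
  expect_false(any(lab$in_cascade[lab$case == "B"]))
})

test_that("labels agree with a per-event brute-force membership check", {
  set.seed(53)
  ev <- as_event_table(data.frame(time = runif(300, 0, 60),
                                  case = sample(c("A", "B"), 300, TRUE)),
                       case_col = "case")
  casc <- tibble::tibble(case = c("A", "A", "B"),
                         start = c(5, 30, 10), end = c(9, 41, 16))
  lab <- label_events(ev, casc)
  brute <- mapply(function(t, cs) {
    any(casc$case == cs & t >= casc$start & t < casc$end)
  }, ev$relative_time, ev$case)
  expect_equal(lab$in_cascade, unname(brute))
})

test_that("triggers are the earliest in-interval event and tally by type", {
  ev <- as_event_table(data.frame(
    time = c(0, 10.2, 10.9, 11.5, 20.1, 20.5, 31.0),
    case = "A",
    event_type = c("EQ", "TRN", "EQ", "COM", "TRN", "COO", "COM")
  ), case_col = "case", type_col = "event_type")
  casc <- tibble::tibble(case = "A", start = c(10, 20, 30),
                         end = c(14, 24, 34))
  got <- cascade_triggers(ev, casc)
  expect_equal(got$trigger, c("TRN", "TRN", "COM"))
  expect_equal(got$n_events, c(3L, 2L, 1L))
  tal <- trigger_tally(got)
  expect_equal(tal$trigger[1], "TRN")
  expect_equal(tal$n, c(2L, 1L))
  empty <- tibble::tibble(case = "A", start = 50, end = 55)
  expect_error(cascade_triggers(ev, empty), "internal consistency")
})

test_that("per-case cascade counts include zero-cascade cases in percentages", {
  casc <- tibble::tibble(case = c("A", "C", "C"), start = c(1, 1, 10),
                         end = c(5, 5, 15))
  got <- cascades_per_case(casc, cases = c("A", "B", "C"))
  expect_equal(got$per_case$n_cascades, c(1L, 0L, 2L))
  expect_equal(got$histogram$n_cases, c(1L, 1L, 1L))
  expect_equal(got$histogram$pct, rep(100 / 3, 3))
  none <- cascades_per_case(casc[0, ], cases = c("A", "B"))
  expect_equal(none$histogram$n_cases, 2L)
  expect_equal(none$histogram$n_cascades, 0L)
})

test_that("the end-to-end pipeline recovers a strong planted cascade", {
  cfg <- synthetic_config(n_cases = 1, case_duration = 60,
                          baseline_rate = 0.1, cascade_rate = 6,
                          cascades_per_case = 1, cascade_duration = 5,
                          forced_trigger = "TRN")
  sc <- generate_case(cfg, case_id = "X", seed = 99)
  ev <- as_event_table(sc$events)
  an <- detect_cascades(ev)
  expect_gte(nrow(an$cascades), 1)
  truth <- data.frame(start = sc$intervals$start - min(sc$events$time),
                      end = sc$intervals$end - min(sc$events$time))
  expect_gte(interval_jaccard(truth, an$cascades), 0.5)
  expect_true("TRN" %in% an$cascades$trigger)
  # conservation across modules: per-case labeled counts match global
  expect_equal(sum(an$events$in_cascade),
               sum(cascade_triggers(an$events, an$cascades)$n_events))
})
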