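# Shared fixtures and independent oracles used across the suite.

# Published per-type in-cascade / total counts from the motivating 41-case
# study (9 disruption types).
study_type_counts <- function() {
  path <- system.file("extdata", "disruption_type_counts.csv",
                      package = "cascadr")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(event_type = raw$EventType, n_in = raw$InCascadeCount,
             n = raw$DisruptionCount)
}

# Independent oracle: literal enumeration of all 2^(n-1) segmentations,
# two-pass per-segment SSE, same tie-break (fewer changepoints, then
# lexicographically smallest vector). Usable for n <= ~14.
enumerate_best_segmentation <- function(y, beta) {
  n <- length(y)
  seg_cost <- function(a, b) {
    s <- y[a:b]
    sum((s - mean(s))^2)
  }
  best_obj <- Inf
  best_cps <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    cps <- which(bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0)
    bounds <- c(0, cps, n)
    obj <- beta * length(cps)
    for (i in seq_len(length(bounds) - 1)) {
      obj <- obj + seg_cost(bounds[i] + 1, bounds[i + 1])
    }
    better <- obj < best_obj - 1e-9 ||
      (abs(obj - best_obj) <= 1e-9 &&
         (length(cps) < length(best_cps) ||
            (length(cps) == length(best_cps) && length(cps) > 0 &&
               first_smaller(cps, best_cps))))
    if (is.null(best_cps) || better) {
      best_obj <- obj
      best_cps <- cps
    }
  }
  list(changepoints = as.integer(best_cps), objective = best_obj)
}

first_smaller <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  FALSE
}

# Quick labeled event table for enrichment tests.
labeled_events <- function(types, in_cascade) {
  ev <- as_event_table(data.frame(time = seq_along(types),
                                  event_type = types))
  ev$in_cascade <- in_cascade
  ev
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
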