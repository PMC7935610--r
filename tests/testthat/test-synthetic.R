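test_that("configs are validated", {
  expect_error(synthetic_config(baseline_rate = 2, cascade_rate = 1),
               "cascade_rate > baseline_rate")
  expect_error(synthetic_config(p_out = c(A = 0.5, B = 0.4)), "summing to 1")
  expect_error(synthetic_config(forced_trigger = "NOPE"), "forced_trigger")
  expect_error(synthetic_config(case_duration = 10, cascades_per_case = 3,
                                cascade_duration = 5), "overlap")
})

test_that("the same seed reproduces a case exactly, different seeds differ", {
  cfg <- synthetic_config(n_cases = 1, case_duration = 60,
                          baseline_rate = 0.5, cascade_rate = 3)
  a <- generate_case(cfg, "c1", seed = 11)
  b <- generate_case(cfg, "c1", seed = 11)
  expect_identical(a$events, b$events)
  expect_identical(a$intervals, b$intervals)
  c <- generate_case(cfg, "c1", seed = 12)
  expect_false(identical(a$events, c$events))
})

test_that("study CSV export is byte-identical across runs with one seed", {
  cfg <- synthetic_config(n_cases = 3, case_duration = 30)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_study(generate_study(cfg, seed = 5), f1)
  write_study(generate_study(cfg, seed = 5), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a homogeneous process has the Poisson mean event count", {
  # lambda1 > lambda0 is required, so emulate homogeneity with a
  # zero-length contribution: no cascades planted
  cfg <- synthetic_config(n_cases = 1, case_duration = 20,
                          baseline_rate = 1, cascade_rate = 2,
                          cascades_per_case = 0)
  totals <- vapply(1:500, function(s) {
    nrow(generate_case(cfg, "h", seed = s)$events)
  }, numeric(1))
  mu <- 1 * 20
  se <- sqrt(mu / 500)
  expect_lt(abs(mean(totals) - mu), 3 * se)
})

test_that("with zero baseline rate every event lies inside the true interval", {
  cfg <- synthetic_config(n_cases = 1, case_duration = 60,
                          baseline_rate = 0, cascade_rate = 4,
                          cascades_per_case = 1, cascade_duration = 5)
  sc <- generate_case(cfg, "z", seed = 21)
  expect_gt(nrow(sc$events), 0)
  expect_true(all(sc$events$time >= sc$intervals$start &
                    sc$events$time < sc$intervals$end))
  expect_true(all(sc$events$true_in_cascade))
})

test_that("planted intervals fit in the case, never overlap, and keep their length", {
  cfg <- synthetic_config(n_cases = 1, case_duration = 50,
                          baseline_rate = 0.2, cascade_rate = 3,
                          cascades_per_case = 4, cascade_duration = 5)
  for (s in 1:20) {
    iv <- generate_case(cfg, "p", seed = s)$intervals
    expect_equal(iv$end - iv$start, rep(5, 4))
    expect_true(all(iv$start >= 0 & iv$end <= 50))
    expect_true(all(diff(iv$start) >= 5 - 1e-9))
  }
})

test_that("forced triggers appear as the first event of each interval", {
  cfg <- synthetic_config(n_cases = 1, case_duration = 60,
                          baseline_rate = 0.1, cascade_rate = 4,
                          cascades_per_case = 2, cascade_duration = 5,
                          forced_trigger = "TRN")
  sc <- generate_case(cfg, "f", seed = 31)
  for (i in seq_len(nrow(sc$intervals))) {
    inside <- sc$events[sc$events$time >= sc$intervals$start[i] &
                          sc$events$time < sc$intervals$end[i], ]
    if (nrow(inside) > 0) expect_equal(inside$event_type[1], "TRN")
  }
})

test_that("empirical type frequencies match the stated distributions", {
  # one long baseline-only case and one all-cascade stratum, ~10k draws each
  cfg_out <- synthetic_config(n_cases = 1, case_duration = 5000,
                              baseline_rate = 2, cascade_rate = 3,
                              cascades_per_case = 0)
  ev_out <- generate_case(cfg_out, "o", seed = 71)$events
  expect_gt(nrow(ev_out), 5000)
  obs <- table(factor(ev_out$event_type, levels = names(default_p_out())))
  gof <- suppressWarnings(chisq.test(obs, p = default_p_out()))
  expect_gt(gof$p.value, 0.01)

  cfg_in <- synthetic_config(n_cases = 1, case_duration = 2500,
                             baseline_rate = 0, cascade_rate = 4,
                             cascades_per_case = 1, cascade_duration = 2400)
  ev_in <- generate_case(cfg_in, "i", seed = 73)$events
  obs_in <- table(factor(ev_in$event_type, levels = names(default_p_in())))
  gof_in <- suppressWarnings(chisq.test(obs_in, p = default_p_in()))
  expect_gt(gof_in$p.value, 0.01)
})

test_that("studies pool cases with derived seeds and ground-truth enrichment", {
  cfg <- synthetic_config(n_cases = 8, case_duration = 120,
                          baseline_rate = 0.3, cascade_rate = 3)
  st <- generate_study(cfg, seed = 2)
  expect_length(st$cases, 8)
  expect_equal(sort(unique(st$events$case)), sort(st$cases))
  expect_s3_class(st$truth_enrichment, "enrichment_table")
  expect_equal(attr(st$truth_enrichment, "N"), nrow(st$events))
  expect_equal(attr(st$truth_enrichment, "N_in"),
               sum(st$events$true_in_cascade))
  # empty study
  empty <- generate_study(synthetic_config(n_cases = 0), seed = 1)
  expect_equal(nrow(empty$events), 0)
})

test_that("expected pooled event count matches the configuration", {
  cfg <- synthetic_config() # defaults emulate the motivating study
  st <- generate_study(cfg, seed = 3)
  expected_per_case <- with(cfg, baseline_rate * (case_duration - cascade_duration) +
                              cascade_rate * cascade_duration)
  expect_equal(expected_per_case, 47.6, tolerance = 1e-9)
  sdev <- sqrt(41 * expected_per_case)
  expect_lt(abs(nrow(st$events) - 41 * expected_per_case), 4 * sdev)
})

test_that("ground-truth enrichment puts the concentrated type on top", {
  p_in <- c(COM = 0.05, COO = 0.05, EQ = 0.05, EXT = 0.05, IC = 0.05,
            SDM = 0.05, TRN = 0.6, ENV = 0.05, PF = 0.05)
  cfg <- synthetic_config(n_cases = 20, case_duration = 100,
                          baseline_rate = 0.3, cascade_rate = 4,
                          cascade_duration = 8, p_in = p_in)
  st <- generate_study(cfg, seed = 7)
  body <- st$truth_enrichment[st$truth_enrichment$event_type != "Any Event", ]
  expect_equal(body$event_type[which.max(body$p_et_given_cascade)], "TRN")
})

test_that("interval Jaccard behaves on knowns", {
  a <- data.frame(start = 0, end = 10)
  expect_equal(interval_jaccard(a, a), 1)
  expect_equal(interval_jaccard(a, data.frame(start = 5, end = 15)), 1 / 3)
  expect_equal(interval_jaccard(a, data.frame(start = 20, end = 30)), 0)
  expect_true(is.nan(interval_jaccard(a[0, ], a[0, ])))
})
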