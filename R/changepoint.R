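#' Penalized change-in-mean segmentation
#'
#' Four detectors for changes in the mean of a numeric series, implemented
#' from first principles: AMOC (at most one change, a penalized
#' likelihood-ratio scan), binary segmentation (greedy, approximate), exact
#' optimal partitioning (dynamic programming over all segmentations), and
#' PELT (optimal partitioning with provably safe pruning; identical output
#' to the exact solver, near-linear typical cost).
#'
#' The segment cost is the within-segment sum of squared deviations (SSE),
#' i.e. the Gaussian change-in-mean cost with the variance treated as a
#' global constant. The objective minimized is
#' \deqn{\sum_{segments} C(segment) + \beta m,}
#' where \eqn{m} is the number of changepoints and \eqn{\beta \ge 0} the
#' per-changepoint penalty. Changepoints are reported 1-based as the index
#' of the last element of each segment.
#'
#' Tie-breaking: among segmentations of equal objective, fewer changepoints
#' win; among those, the candidate with the smaller previous-changepoint
#' index is kept at every step. PELT and the exact solver share this rule
#' (and identical arithmetic), so their outputs are identical.
#'
#' @name changepoint_detection
NULL

# Prefix-sum closure giving O(1) segment SSE. Negative rounding residue is
# clamped to zero.
make_segment_cost <- function(y) {
  s1 <- c(0, cumsum(y))
  s2 <- c(0, cumsum(y^2))
  function(a, b) {
    k <- b - a + 1
    m <- s1[b + 1] - s1[a]
    max(0, s2[b + 1] - s2[a] - m^2 / k)
  }
}

#' Within-segment sum of squared deviations
#'
#' `cost_sse(y, a, b)` is \eqn{\sum_{i=a}^{b} (y_i - \bar y_{a..b})^2},
#' computed in O(1) from prefix sums.
#'
#' @param series Numeric series.
#' @param a,b 1-based inclusive segment bounds, `1 <= a <= b <= length(series)`.
#' @return The segment cost (non-negative scalar).
#' @export
#' @examples
#' cost_sse(c(0, 2), 1, 2) # mean 1, deviations +/-1 -> 2
cost_sse <- function(series, a, b) {
  n <- length(series)
  if (!(a >= 1 && a <= b && b <= n)) {
    stop(sprintf("invalid segment [%s, %s] for series of length %d", a, b, n))
  }
  make_segment_cost(series)(a, b)
}

resolve_penalty <- function(penalty, n) {
  if (is.character(penalty)) {
    if (toupper(penalty) != "BIC") {
      stop(sprintf("unknown penalty rule '%s' (use \"BIC\" or a number)", penalty))
    }
    return(2 * log(n))
  }
  if (!is.numeric(penalty) || length(penalty) != 1L || penalty < 0) {
    stop("'penalty' must be \"BIC\" or a single non-negative number")
  }
  penalty
}

new_changepoint_result <- function(changepoints, series, beta, method) {
  n <- length(series)
  bounds <- c(0L, changepoints, n)
  means <- vapply(seq_len(length(bounds) - 1L), function(i) {
    mean(series[(bounds[i] + 1L):bounds[i + 1L]])
  }, numeric(1))
  C <- make_segment_cost(series)
  obj <- sum(vapply(seq_len(length(bounds) - 1L), function(i) {
    C(bounds[i] + 1L, bounds[i + 1L])
  }, numeric(1))) + beta * length(changepoints)
  structure(list(
    changepoints = as.integer(changepoints),
    segment_means = means,
    objective = obj,
    method = method,
    penalty = beta,
    n = n
  ), class = "changepoint_result")
}

#' @export
print.changepoint_result <- function(x, ...) {
  cat(sprintf("<changepoint_result: %s, n = %d, beta = %.4g>\n",
              x$method, x$n, x$penalty))
  cat(sprintf("  changepoints: %s\n",
              if (length(x$changepoints)) paste(x$changepoints, collapse = ", ")
              else "(none)"))
  cat(sprintf("  segment means: %s\n",
              paste(signif(x$segment_means, 4), collapse = ", ")))
  cat(sprintf("  objective: %.6g\n", x$objective))
  invisible(x)
}

# Shared optimal-partitioning engine. prune = TRUE gives PELT: after each t,
# drop every candidate s with F(s) + C(s+1, t) > F(t) (safe for SSE with
# K = 0; ties are retained, so pruning never alters the tie-break).
optimal_partition <- function(series, beta, prune) {
  n <- length(series)
  C <- make_segment_cost(series)
  F <- c(-beta, rep(Inf, n))
  ncp <- integer(n + 1)
  prev <- integer(n + 1)
  cand <- 0L
  for (t in seq_len(n)) {
    vals <- vapply(cand, function(s) F[s + 1L] + C(s + 1L, t) + beta, numeric(1))
    best <- Inf
    best_ncp <- Inf
    best_s <- 0L
    for (i in seq_along(cand)) {
      s <- cand[i]
      v <- vals[i]
      k <- if (s == 0L) 0L else ncp[s + 1L] + 1L
      if (v < best || (v == best && k < best_ncp)) {
        best <- v
        best_ncp <- k
        best_s <- s
      }
    }
    F[t + 1L] <- best
    ncp[t + 1L] <- best_ncp
    prev[t + 1L] <- best_s
    if (prune) {
      cand <- cand[vals - beta <= best]
    }
    cand <- c(cand, t)
  }
  cps <- integer(0)
  t <- n
  while (t > 0L) {
    s <- prev[t + 1L]
    if (s > 0L) cps <- c(s, cps)
    t <- s
  }
  cps
}

#' Exact optimal partitioning
#'
#' Minimizes total SSE plus `beta` per changepoint over all segmentations
#' via the optimal-partitioning recursion
#' `F(t) = min_{0 <= s < t} [F(s) + C(y[(s+1)..t]) + beta]`, `F(0) = -beta`,
#' with changepoints recovered by backtracking. Globally optimal.
#'
#' @param series Numeric series (length >= 1).
#' @param penalty Per-changepoint penalty: `"BIC"` (= `2 * log(n)`) or a
#'   non-negative number.
#' @return A `changepoint_result` with `changepoints`, `segment_means`,
#'   `objective`, `method`, `penalty`, `n`.
#' @export
#' @examples
#' exact_segmentation(c(rep(0, 10), rep(5, 10)), penalty = 1)
exact_segmentation <- function(series, penalty = "BIC") {
  if (length(series) < 1L) stop("'series' must be non-empty")
  beta <- resolve_penalty(penalty, length(series))
  cps <- optimal_partition(series, beta, prune = FALSE)
  new_changepoint_result(cps, series, beta, "exact")
}

#' PELT: pruned exact linear time segmentation
#'
#' Same recursion and result as [exact_segmentation()], restricted to a
#' pruned candidate set: after computing `F(t)`, every previous position
#' `s` with `F(s) + C(y[(s+1)..t]) > F(t)` is discarded, which is safe for
#' the SSE cost. Output is identical to the exact solver.
#'
#' @inheritParams exact_segmentation
#' @return A `changepoint_result`.
#' @export
pelt <- function(series, penalty = "BIC") {
  if (length(series) < 1L) stop("'series' must be non-empty")
  beta <- resolve_penalty(penalty, length(series))
  cps <- optimal_partition(series, beta, prune = TRUE)
  new_changepoint_result(cps, series, beta, "pelt")
}

# Best single split of series[a..b]: maximal cost reduction
# C(a,b) - C(a,tau) - C(tau+1,b); first tau wins ties.
best_split <- function(C, a, b) {
  if (b - a < 1L) {
    return(list(gain = -Inf, tau = NA_integer_))
  }
  whole <- C(a, b)
  taus <- a:(b - 1L)
  gains <- vapply(taus, function(tau) whole - C(a, tau) - C(tau + 1L, b),
                  numeric(1))
  i <- which.max(gains)
  list(gain = gains[i], tau = taus[i])
}

#' AMOC: at most one change
#'
#' Scans all split points for the largest reduction in SSE,
#' `Delta(tau) = C(1, n) - C(1, tau) - C(tau + 1, n)`, and reports the
#' argmax as a single changepoint iff `max Delta > beta`.
#'
#' @inheritParams exact_segmentation
#' @return A `changepoint_result` with zero or one changepoint.
#' @export
amoc <- function(series, penalty = "BIC") {
  n <- length(series)
  if (n < 2L) stop("'series' must have length >= 2 for AMOC")
  beta <- resolve_penalty(penalty, n)
  C <- make_segment_cost(series)
  split <- best_split(C, 1L, n)
  cps <- if (split$gain > beta) split$tau else integer(0)
  new_changepoint_result(cps, series, beta, "amoc")
}

#' Binary segmentation
#'
#' Greedy approximate multi-changepoint detection: repeatedly applies the
#' best single split (as in [amoc()]) to the current segment whose best
#' split yields the largest gain, stopping when the best available gain is
#' `<= beta` or `max_changepoints` have been placed. The objective is never
#' below the exact solver's on the same input.
#'
#' @inheritParams exact_segmentation
#' @param max_changepoints Maximum number of changepoints to place.
#' @return A `changepoint_result`.
#' @export
binseg <- function(series, penalty = "BIC", max_changepoints = NULL) {
  n <- length(series)
  if (n < 2L) stop("'series' must have length >= 2 for binary segmentation")
  if (is.null(max_changepoints)) max_changepoints <- n - 1L
  if (max_changepoints < 1L) stop("'max_changepoints' must be >= 1")
  beta <- resolve_penalty(penalty, n)
  C <- make_segment_cost(series)
  segs <- list(list(a = 1L, b = n, split = best_split(C, 1L, n)))
  cps <- integer(0)
  while (length(cps) < max_changepoints) {
    gains <- vapply(segs, function(s) s$split$gain, numeric(1))
    i <- which.max(gains)
    if (gains[i] <= beta) break
    seg <- segs[[i]]
    tau <- seg$split$tau
    cps <- c(cps, tau)
    left <- list(a = seg$a, b = tau, split = best_split(C, seg$a, tau))
    right <- list(a = tau + 1L, b = seg$b, split = best_split(C, tau + 1L, seg$b))
    segs <- c(segs[-i], list(left, right))
  }
  new_changepoint_result(sort(cps), series, beta, "binseg")
}

#' Detect changepoints with a chosen method
#'
#' Single entry point over the four detectors. When `series` is a
#' `regularized_series` (from [bin_counts()]) its `count` column is used;
#' `normalize = TRUE` (the default for count input) rescales the series by a
#' global noise estimate, `sqrt(var(diff(y)) / 2)`, which is robust to
#' segment-mean shifts — this implements the Gaussian cost with the
#' variance profiled out globally as a constant.
#'
#' @param series Numeric vector or `regularized_series`.
#' @param method One of `"pelt"`, `"exact"`, `"binseg"`, `"amoc"`.
#' @param penalty `"BIC"` (= `2 * log(n)`) or a non-negative number.
#' @param max_changepoints Cap for `"binseg"`; ignored otherwise.
#' @param normalize Rescale the series by the global noise scale before
#'   segmentation. Defaults to `TRUE` for `regularized_series` input and
#'   `FALSE` for a bare numeric vector.
#' @return A `changepoint_result` (changepoint indices refer to the
#'   original, unscaled series; segment means are on the original scale).
#' @export
detect_changepoints <- function(series,
                                method = c("pelt", "exact", "binseg", "amoc"),
                                penalty = "BIC", max_changepoints = NULL,
                                normalize = NULL) {
  method <- match.arg(method)
  is_reg <- inherits(series, "regularized_series")
  y <- if (is_reg) series$count else series
  if (is.null(normalize)) normalize <- is_reg
  z <- y
  if (normalize && length(y) >= 3L) {
    s2 <- stats::var(diff(y)) / 2
    if (is.finite(s2) && s2 > 0) z <- y / sqrt(s2)
  }
  res <- switch(method,
    pelt = pelt(z, penalty),
    exact = exact_segmentation(z, penalty),
    binseg = binseg(z, penalty, max_changepoints),
    amoc = amoc(z, penalty)
  )
  # report means and objective on the original scale
  new_changepoint_result(res$changepoints, y, res$penalty, method)
}
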