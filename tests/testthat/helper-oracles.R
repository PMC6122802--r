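# Independent oracles used by unit and acceptance tests. Both deliberately
# avoid the implementation's algorithms: the AUC oracle enumerates all pairs;
# the risk oracle integrates the cause-specific density numerically.

# Brute-force pairwise concordance: count concordant pairs + half the ties.
auc_bruteforce <- function(cases, controls) {
  tot <- 0
  for (cs in cases) for (ct in controls) {
    tot <- tot + (cs > ct) + 0.5 * (cs == ct)
  }
  tot / (length(cases) * length(controls))
}

# Numerical quadrature oracle for the absolute-risk projection: integrate
# rr*h1(t) * exp(-cumhaz(a, t)) over [a, a + horizon], interval by interval.
# The step-function cumulative hazard is accumulated by exact summation; the
# outer integral is adaptive quadrature, independent of the closed-form path.
risk_quadrature <- function(rr, age, horizon, baseline, competing = FALSE) {
  h1 <- stats::approxfun(baseline$age_start, rr * baseline$h1,
                         method = "constant", rule = 2)
  cumhaz <- function(t) {
    vapply(t, function(ti) {
      len <- pmax(pmin(ti, baseline$age_end) - pmax(age, baseline$age_start), 0)
      sum((rr * baseline$h1 +
             if (competing) baseline$competing_mortality else 0) * len)
    }, numeric(1))
  }
  total <- 0
  for (i in seq_len(nrow(baseline))) {
    t0 <- max(age, baseline$age_start[i])
    t1 <- min(age + horizon, baseline$age_end[i])
    if (t1 <= t0) next
    total <- total + stats::integrate(
      function(t) h1(t) * exp(-cumhaz(t)), t0, t1,
      subdivisions = 500L, rel.tol = 1e-10)$value
  }
  total
}

# Random piecewise incidence table with unit reference relative risk.
random_baseline <- function(seed) {
  set.seed(seed)
  k <- sample(3:6, 1)
  starts <- cumsum(c(40, runif(k - 1, 2, 8)))
  ends <- c(starts[-1], starts[k] + runif(1, 2, 8))
  calibrate_baseline_hazard(
    incidence_table(starts, ends,
                    runif(k, 1e-4, 5e-3),
                    runif(k, 1e-4, 1e-2)),
    reference_rr = 1)
}
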