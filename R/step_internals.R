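# Internal step-function survival kernels. The user-facing Kaplan-Meier and
# log-rank functions wrap the survival package; these minimal product-limit /
# Nelson-Aalen helpers exist for the SDR inner loop, where thousands of small
# fits per search make formula-interface calls the bottleneck. They are
# checked against survival::survfit in the test suite.

# Product-limit estimate. Returns times (unique, sorted) and S(t) evaluated
# right-continuously at those times; S before the first time is 1.
.km_fit <- function(time, event) {
  o <- order(time)
  tt <- time[o]; ee <- event[o]
  ut <- unique(tt)
  grp <- match(tt, ut)
  d <- as.numeric(rowsum(ee, grp))          # deaths at each unique time
  m <- as.numeric(rowsum(rep(1, length(tt)), grp))  # removals
  n_risk <- length(tt) - c(0, cumsum(m)[-length(m)])
  s <- cumprod(1 - d / n_risk)
  list(time = ut, surv = s, n_risk = n_risk, n_event = d)
}

# Nelson-Aalen cumulative hazard at each unique time.
.na_fit <- function(time, event) {
  km <- .km_fit(time, event)
  list(time = km$time, cumhaz = cumsum(km$n_event / km$n_risk))
}

# Evaluate a right-continuous step function (value[i] holds on
# [time[i], time[i+1])) at x; `left` gives the left limit f(x-).
.step_eval <- function(x, time, value, init = 1, left = FALSE) {
  idx <- findInterval(x, time, left.open = left)
  c(init, value)[idx + 1L]
}
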