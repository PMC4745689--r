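# Independent oracles used to freeze expected values. Each one is a direct,
# unoptimized transcription of the defining formula, kept separate from the
# package's implementation paths.

# Exact conditional HWE test by direct closed-form enumeration: multinomial
# probability of each heterozygote count given the allele counts, via
# log-factorials (the package uses a probability recurrence instead).
oracle_hwe_exact <- function(counts) {
  hom1 <- counts[1]; het <- counts[2]; hom2 <- counts[3]
  n <- hom1 + het + hom2
  n_a <- 2 * hom1 + het
  n_b <- 2 * hom2 + het
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    a <- (rare - h) / 2
    b <- (2 * n - rare - h) / 2
    lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
      h * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == het)
  sum(p[p <= p[obs] * (1 + 1e-10)])
}

# Literal term-by-term IPCW Brier score: explicit double loop over subjects
# and evaluation times, with the censoring KM computed by its textbook
# product formula.
oracle_ibs <- function(train_time, train_event, test_time, test_event,
                       surv_fun) {
  km_surv <- function(times, time, event, at, left = FALSE) {
    s <- 1
    for (u in sort(unique(time))) {
      if ((left && u >= at) || (!left && u > at)) break
      n_risk <- sum(time >= u)
      d <- sum(time == u & event == 1)
      s <- s * (1 - d / n_risk)
    }
    s
  }
  G <- function(t) km_surv(NULL, train_time, 1 - train_event, t)
  G_left <- function(t) km_surv(NULL, train_time, 1 - train_event, t,
                                left = TRUE)
  ev <- sort(unique(train_time[train_event == 1]))
  ev_pos <- ev[vapply(ev, G, numeric(1)) > 0]
  tau <- max(ev_pos)
  grid <- sort(unique(c(0, test_time[test_event == 1 & test_time <= tau],
                        tau)))
  n <- length(test_time)
  bs <- numeric(length(grid))
  for (j in seq_along(grid)) {
    t <- grid[j]
    acc <- 0
    for (i in seq_len(n)) {
      s_i <- surv_fun(i, t)
      if (test_time[i] <= t && test_event[i] == 1) {
        acc <- acc + (0 - s_i)^2 / G_left(test_time[i])
      } else if (test_time[i] > t) {
        acc <- acc + (1 - s_i)^2 / G(t)
      }
    }
    bs[j] <- acc / n
  }
  ibs <- 0
  for (j in seq_along(grid)[-1]) {
    ibs <- ibs + (grid[j] - grid[j - 1]) * (bs[j] + bs[j - 1]) / 2
  }
  list(bs = bs, grid = grid, tau = tau, ibs = ibs / tau)
}

# Log-rank observed-minus-expected deaths for a subject set versus the whole
# sample, accumulated risk set by risk set.
oracle_logrank_oe <- function(time, event, members) {
  oe <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- sum(time == t & event == 1)
    n_at <- sum(time >= t)
    n_g <- sum(time[members] >= t)
    d_g <- sum(time[members] == t & event[members] == 1)
    oe <- oe + d_g - d * n_g / n_at
  }
  oe
}

# Efron partial log-likelihood for a single covariate (for hand-maximizing
# the Cox toy example).
oracle_efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sum_r <- sum(exp(beta * x[R]))
    sum_d <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_r - (l / d) * sum_d)
    }
  }
  ll
}

# Two-locus haplotype log-likelihood at fixed observed allele frequencies,
# parameterized by the (major, major) haplotype frequency; used as a 1-D
# grid oracle for the EM (allele frequencies are directly observed, so the
# likelihood has a single free parameter for two SNPs).
oracle_hap2_loglik <- function(f11, p_a, p_b, mac) {
  f <- c(f11, p_a - f11, p_b - f11, 1 - p_a - p_b + f11)
  if (any(f < -1e-12)) return(-Inf)
  f <- pmax(f, 1e-300)
  # haplotype order: (maj,maj), (maj,min), (min,maj), (min,min)
  ll <- 0
  for (i in seq_len(nrow(mac))) {
    g <- mac[i, ]
    prob <- 0
    for (a in 0:3) {
      for (b in 0:3) {
        ha <- c(a %/% 2, a %% 2)  # minor indicators (snp1, snp2)
        hb <- c(b %/% 2, b %% 2)
        if (all(ha + hb == g)) prob <- prob + f[a + 1] * f[b + 1]
      }
    }
    ll <- ll + log(prob)
  }
  ll
}
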