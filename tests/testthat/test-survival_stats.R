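test_that("Kaplan-Meier matches hand product-limit calculations", {
  # one subject, event at 12
  km1 <- kaplan_meier(toy_outcome(12, 1))
  expect_equal(km1$curve$surv, 0)
  expect_equal(km1$median, 12)
  # events at 1 and 2, censored at 1.5: S(1) = 2/3, S(2) = 0
  km2 <- kaplan_meier(toy_outcome(c(1, 1.5, 2), c(1, 0, 1)))
  expect_equal(km2$curve$surv[km2$curve$time == 1], 2 / 3)
  expect_equal(km2$curve$surv[km2$curve$time == 2], 0)
  # all censored: S = 1 throughout, median undefined
  km3 <- kaplan_meier(toy_outcome(c(5, 8, 9), c(0, 0, 0)))
  expect_true(all(km3$curve$surv == 1))
  expect_true(is.na(km3$median))
})

test_that("Kaplan-Meier is invariant to subject order and CIs bracket S", {
  set.seed(2)
  time <- round(rexp(60, 0.02), 1) + 0.1
  event <- rbinom(60, 1, 0.8)
  km_a <- kaplan_meier(toy_outcome(time, event))
  o <- sample(60)
  km_b <- kaplan_meier(toy_outcome(time[o], event[o]))
  expect_equal(km_a$curve, km_b$curve)
  ok <- !is.na(km_a$curve$lower)
  expect_true(all(km_a$curve$lower[ok] <= km_a$curve$surv[ok] + 1e-12))
  expect_true(all(km_a$curve$upper[ok] >= km_a$curve$surv[ok] - 1e-12))
})

test_that("log-rank test matches hand computation and is symmetric", {
  # identical groups: statistic exactly 0
  time <- c(3, 5, 8, 3, 5, 8)
  event <- c(1, 1, 0, 1, 1, 0)
  lr0 <- logrank(toy_outcome(time, event), rep(c("a", "b"), each = 3))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)

  # hand O-E/V for groups {1,3} events vs {2,4} one event
  # t=1: d=1 (grp A), risk 4 (2 A), E_A = 0.5, V = 0.25*... computed below
  tt <- c(1, 2, 3, 4); ee <- c(1, 1, 1, 0); gg <- c("A", "B", "A", "B")
  lr <- logrank(toy_outcome(tt, ee), gg)
  # risk sets: t=1 nA=2 nB=2 d=1 dA=1; t=2 nA=1 nB=2 d=1 dA=0; t=3 nA=1
  # nB=1 d=1 dA=1
  oe <- (1 - 2 / 4) + (0 - 1 / 3) + (1 - 1 / 2)
  v <- (2 / 4) * (2 / 4) + (1 / 3) * (2 / 3) + (1 / 2) * (1 / 2)
  expect_equal(lr$chi2, oe^2 / v, tolerance = 1e-10)

  # swapping the group labels leaves the statistic unchanged
  expect_equal(lr$chi2,
               logrank(toy_outcome(tt, ee),
                       ifelse(gg == "A", "B", "A"))$chi2,
               tolerance = 1e-12)
  expect_error(logrank(toy_outcome(tt, ee), rep("A", 4)), "2 non-empty")
})

test_that("log-rank type-I error is calibrated under the null", {
  set.seed(31)
  rejections <- 0
  n_sim <- 2000
  for (i in seq_len(n_sim)) {
    time <- rexp(30, 0.05)
    event <- rbinom(30, 1, 0.85)
    grp <- rep(c("a", "b"), each = 15)
    p <- logrank(toy_outcome(time, event), grp)$p
    rejections <- rejections + (p < 0.05)
  }
  expect_gte(rejections / n_sim, 0.03)
  expect_lte(rejections / n_sim, 0.07)
})

test_that("Cox fit recovers simulated effects and flags degenerate input", {
  set.seed(77)
  # null covariate: CI covers 1
  x <- rbinom(2000, 1, 0.5)
  time <- rexp(2000, 0.02)
  cf0 <- cox_fit(toy_outcome(round(time, 1) + 0.1, rep(1, 2000)),
                 data.frame(x = x))
  expect_true(cf0$table$lower[1] <= 1 && cf0$table$upper[1] >= 1)

  # true HR 0.29 (favorable group), estimate within +-3 SE
  grp <- rbinom(2000, 1, 0.5)
  t2 <- rexp(2000, 0.0106 * ifelse(grp == 1, 0.29, 1))
  cf <- cox_fit(toy_outcome(round(t2, 1) + 0.1, rep(1, 2000)),
                data.frame(favorable = grp))
  se <- sqrt(diag(stats::vcov(cf$fit)))[1]
  expect_lt(abs(cf$table$coef[1] - log(0.29)), 3 * se)

  expect_error(cox_fit(toy_outcome(c(1, 2), c(1, 1)),
                       data.frame(x = c(1, 1))), "constant")
  # complete separation is flagged, not silent
  sep <- cox_fit(toy_outcome(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 1, 1, 1)),
                 data.frame(x = c(1, 1, 1, 0, 0, 0)))
  expect_true(sep$flagged)
})

test_that("Cox coefficient on a tied-time toy matches the hand-maximized
           Efron partial likelihood", {
  time <- c(2, 2, 2, 4, 4, 6, 8, 8)
  event <- c(1, 1, 0, 1, 1, 1, 1, 0)
  x <- c(1, 0, 1, 1, 0, 0, 1, 0)
  cf <- cox_fit(toy_outcome(time, event), data.frame(x = x))
  opt <- stats::optimize(function(b) -oracle_efron_loglik(b, time, event, x),
                         c(-5, 5), tol = 1e-10)
  expect_equal(cf$table$coef[1], opt$minimum, tolerance = 1e-6)
  # binary label flip inverts the hazard ratio
  cf_flip <- cox_fit(toy_outcome(time, event), data.frame(x = 1 - x))
  expect_equal(cf_flip$table$hr[1], 1 / cf$table$hr[1], tolerance = 1e-6)
})

test_that("genetic codings reproduce the study's group sizes", {
  gm <- study_fixture()
  dom <- encode_genotype(gm, "rs2071559", "dominant")
  expect_equal(unname(dom$group_sizes), c(78, 22))
  rec <- encode_genotype(gm, "rs2071559", "recessive")
  expect_equal(unname(rec$group_sizes), c(29, 71))
  add <- encode_genotype(gm, "rs2071559", "additive")
  expect_equal(unname(add$group_sizes), c(29, 49, 22))
  expect_named(add$data, c("AG", "GG"))

  # monomorphic SNP: constant coding flagged unusable
  panel <- snp_panel("m", "A", "G")
  gm_m <- genotype_matrix(matrix(rep("AA", 10), ncol = 1,
                                 dimnames = list(NULL, "m")), panel = panel)
  expect_false(encode_genotype(gm_m, "m", "dominant")$usable)
  expect_error(encode_genotype(gm, "rs2071559", "codominant"))
})

test_that("IPCW Brier score matches closed forms and the summation oracle", {
  # no censoring, constant 0.5 prediction: BS = 0.25 everywhere, IBS = 0.25
  so <- toy_outcome(c(2, 4, 6, 8, 10), rep(1, 5))
  bc <- brier_ibs(so, so, function(t) matrix(0.5, 5, length(t)))
  expect_true(all(abs(bc$bs - 0.25) < 1e-12))
  expect_equal(bc$ibs, 0.25, tolerance = 1e-12)

  # perfect oracle prediction: IBS = 0
  bc0 <- brier_ibs(so, so, function(t) outer(so$time, t, ">") * 1)
  expect_equal(bc0$ibs, 0, tolerance = 1e-12)

  # censored toy set: matches the literal term-by-term IPCW oracle
  tr <- toy_outcome(c(1, 2, 3, 5, 7, 8, 9, 11), c(1, 0, 1, 1, 0, 1, 0, 1))
  te <- toy_outcome(c(2, 3, 4, 6, 8, 10), c(1, 1, 0, 1, 1, 0),
                    ids = paste0("t", 1:6))
  s_fun <- function(i, t) exp(-0.1 * t) ^ (1 + 0.2 * (i %% 2))
  pred <- function(times) t(vapply(seq_len(6), function(i)
    vapply(times, function(u) s_fun(i, u), numeric(1)), numeric(length(times))))
  bc2 <- brier_ibs(tr, te, pred)
  orc <- oracle_ibs(tr$time, tr$event, te$time, te$event, s_fun)
  expect_equal(bc2$tau, orc$tau)
  expect_equal(bc2$bs, orc$bs, tolerance = 1e-10)
  expect_equal(bc2$ibs, orc$ibs, tolerance = 1e-10)

  expect_error(brier_ibs(toy_outcome(c(1, 2), c(0, 0)), te, pred), "no events")
})

test_that("pooled-KM predictor beats the constant-0.5 predictor on
           event-rich data", {
  set.seed(19)
  for (rep in 1:5) {
    time <- round(rexp(80, 0.02), 1) + 0.1
    event <- rbinom(80, 1, 0.9)
    so <- toy_outcome(time, event)
    km <- sdrsurv:::.km_fit(so$time, so$event)
    pooled <- function(t) {
      s <- sdrsurv:::.step_eval(t, km$time, km$surv)
      matrix(rep(s, each = 80), nrow = 80)
    }
    ibs_km <- brier_ibs(so, so, pooled)$ibs
    ibs_const <- brier_ibs(so, so, function(t) matrix(0.5, 80, length(t)))$ibs
    expect_lte(ibs_km, ibs_const)
  }
})

test_that("internal step-function KM agrees with survival::survfit", {
  set.seed(4)
  time <- round(rexp(50, 0.03), 1) + 0.1
  event <- rbinom(50, 1, 0.7)
  km <- sdrsurv:::.km_fit(time, event)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  expect_equal(sdrsurv:::.step_eval(sf$time, km$time, km$surv), sf$surv,
               tolerance = 1e-12)
  na <- sdrsurv:::.na_fit(time, event)
  expect_equal(sdrsurv:::.step_eval(sf$time, na$time, na$cumhaz, init = 0),
               sf$cumhaz, tolerance = 1e-12)
})
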