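test_that("cell partitioning is exhaustive, disjoint, and duplication-safe", {
  coh <- planted_two_way(80, seed = 2)
  cells <- partition_cells(coh$gm, c("rs2071559", "rs11133360",
                                     "rs3751143", "rs208294"))
  expect_lte(length(cells), 81)  # 3^4
  members <- unlist(lapply(cells, `[[`, "members"))
  expect_equal(sort(members), seq_len(80))  # disjoint and exhaustive

  # duplicating every subject: same keys, doubled memberships
  gm2 <- genotype_matrix(rbind(coh$gm$calls, coh$gm$calls),
                         panel = coh$gm$panel,
                         subject_ids = c(coh$gm$subject_ids,
                                         paste0("dup_",
                                                coh$gm$subject_ids)))
  cells2 <- partition_cells(gm2, c("rs2071559", "rs11133360",
                                   "rs3751143", "rs208294"))
  expect_setequal(vapply(cells2, `[[`, "", "key"),
                  vapply(cells, `[[`, "", "key"))
  key_order <- match(vapply(cells, `[[`, "", "key"),
                     vapply(cells2, `[[`, "", "key"))
  expect_equal(lengths(lapply(cells2[key_order], `[[`, "members")),
               2 * lengths(lapply(cells, `[[`, "members")))
  expect_error(partition_cells(coh$gm, "rs2071559", integer(0)), "empty")
})

test_that("cell classification scores equal the risk-set log-rank O-E", {
  set.seed(8)
  time <- round(rexp(40, 0.02), 1) + 0.1
  event <- rbinom(40, 1, 0.85)
  outcome <- toy_outcome(time, event)
  for (rep in 1:10) {
    members <- sort(sample(40, sample(3:15, 1)))
    res <- classify_cell(list(members = members), outcome)
    oe <- oracle_logrank_oe(time, event, members)
    expect_equal(res$score, oe, tolerance = 1e-10)
    expect_equal(res$label,
                 if (oe < -1e-12) "favorable"
                 else if (oe > 1e-12) "unfavorable" else "unclassifiable")
  }
  # zero deaths in the cell while others die: favorable
  oz <- toy_outcome(c(10, 10, 1, 2, 3), c(0, 0, 1, 1, 1))
  expect_equal(classify_cell(list(members = 1:2), oz)$label, "favorable")
  # all cell members die before any outside death: unfavorable
  ou <- toy_outcome(c(1, 2, 10, 11, 12), c(1, 1, 1, 0, 1))
  expect_equal(classify_cell(list(members = 1:2), ou)$label, "unfavorable")
  # single member censored at the earliest time: O - E = 0, unclassifiable
  oc <- toy_outcome(c(0.01, 5, 6), c(0, 1, 1))
  res0 <- classify_cell(list(members = 1), oc)
  expect_equal(res0$score, 0)
  expect_equal(res0$label, "unclassifiable")
})

test_that("derived profiles recover a strong planted interaction", {
  hits <- 0
  n_seeds <- 20
  for (seed in seq_len(n_seeds)) {
    coh <- planted_two_way(400, hr = 0.2, seed = 100 + seed)
    prof <- derive_profiles(coh$gm, coh$outcome,
                            c("rs2071559", "rs208294"))
    lab <- assign_profiles(prof, coh$gm)
    ok <- !is.na(lab)
    agree <- mean(lab[ok] == coh$truth[ok])
    hits <- hits + (agree >= 0.9)
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("profile derivation is symmetric in SNP order and subject order", {
  coh <- planted_two_way(120, seed = 5)
  subset <- c("rs2071559", "rs3751143", "rs208294")
  p1 <- derive_profiles(coh$gm, coh$outcome, subset)
  p2 <- derive_profiles(coh$gm, coh$outcome, rev(subset))
  # same cells up to key component reordering
  rekey <- vapply(strsplit(p2$table$cell, "/"), function(x)
    paste(rev(x), collapse = "/"), character(1))
  m <- match(p1$table$cell, rekey)
  expect_false(anyNA(m))
  expect_equal(p1$table$score, p2$table$score[m], tolerance = 1e-10)
  expect_equal(p1$table$label, p2$table$label[m])

  o <- sample(120)
  gm_o <- genotype_matrix(coh$gm$calls[o, ], panel = coh$gm$panel)
  out_o <- coh$outcome[o, ]; class(out_o) <- class(coh$outcome)
  p3 <- derive_profiles(gm_o, out_o, subset)
  m3 <- match(p1$table$cell, p3$table$cell)
  expect_equal(p1$table$score, p3$table$score[m3], tolerance = 1e-10)
})

test_that("model evaluation: identity split, planted-vs-random, degeneracy", {
  coh <- planted_two_way(150, hr = 0.2, seed = 9)
  subset <- c("rs2071559", "rs208294")
  idx <- seq_len(150)
  prof <- derive_profiles(coh$gm, coh$outcome, subset)
  ev <- evaluate_model(prof, coh$gm, coh$outcome, idx, idx)
  expect_equal(ev$train_ibs, ev$test_ibs, tolerance = 1e-12)
  expect_false(ev$degenerate)

  # planted-truth labels score better than random labels, most of the time
  set.seed(33)
  wins <- 0
  n_rep <- 40
  for (rep in seq_len(n_rep)) {
    coh_r <- planted_two_way(150, hr = 0.2, seed = 500 + rep)
    test <- sample(150, 50)
    train <- setdiff(seq_len(150), test)
    prof_t <- derive_profiles(coh_r$gm, coh_r$outcome, subset,
                              subjects = train)
    ev_t <- evaluate_model(prof_t, coh_r$gm, coh_r$outcome, train, test)
    # random assignment: same cells, shuffled labels
    prof_r <- prof_t
    prof_r$table$label <- sample(prof_t$table$label)
    ev_r <- evaluate_model(prof_r, coh_r$gm, coh_r$outcome, train, test)
    if (is.na(ev_r$test_ibs) || ev_r$degenerate ||
        ev_t$test_ibs < ev_r$test_ibs) {
      wins <- wins + 1
    }
  }
  expect_gte(wins / n_rep, 0.8)

  # all subjects in one profile -> degenerate flag and sentinel IBS
  mono <- prof
  mono$table$label <- rep("favorable", nrow(mono$table))
  ev_m <- evaluate_model(mono, coh$gm, coh$outcome, idx, idx)
  expect_true(ev_m$degenerate)
  expect_equal(ev_m$test_ibs, 1)
})

test_that("cross-validation: duplicate-cohort identity and determinism", {
  coh <- planted_two_way(60, seed = 13)
  # duplicated cohort split into two folds by copy: test fold == train fold
  gm2 <- genotype_matrix(rbind(coh$gm$calls, coh$gm$calls),
                         panel = coh$gm$panel,
                         subject_ids = c(coh$gm$subject_ids,
                                         paste0("dup_",
                                                coh$gm$subject_ids)))
  out2 <- survival_outcome(gm2$subject_ids, rep(coh$outcome$time, 2),
                           rep(coh$outcome$event, 2))
  plan2 <- cv_plan(out2, folds = 2, seed = 1)
  plan2$fold <- rep(1:2, each = 60)  # split exactly by copy
  cv <- cross_validate(gm2, out2, c("rs2071559", "rs208294"), plan2)
  expect_equal(cv$train_ibs, cv$test_ibs, tolerance = 1e-12)

  plan <- cv_plan(coh$outcome, folds = 5, seed = 42)
  cv1 <- cross_validate(coh$gm, coh$outcome, c("rs2071559", "rs208294"),
                        plan)
  cv2 <- cross_validate(coh$gm, coh$outcome, c("rs2071559", "rs208294"),
                        cv_plan(coh$outcome, folds = 5, seed = 42))
  expect_identical(cv1, cv2)

  # fold plans are event-stratified
  ef <- vapply(1:5, function(f)
    mean(coh$outcome$event[plan$fold == f]), numeric(1))
  overall <- mean(coh$outcome$event)
  expect_true(all(abs(ef - overall) <= 1 / min(table(plan$fold)) + 1e-9))
})

test_that("search enumerates all subsets and the argmin rule selects
           the printed best model", {
  coh <- planted_two_way(70, seed = 21)
  plan <- cv_plan(coh$outcome, folds = 3, seed = 2)
  res <- sdr_search(coh$gm, coh$outcome, 1:4, plan)
  expect_equal(nrow(res$log), 6 + 15 + 20 + 15)  # C(6,k), k = 1..4
  expect_equal(res$best$test_ibs, min(res$per_k$test_ibs))

  # selection logic on a candidate table
  cand <- data.frame(k = 1:4,
                     test_ibs = c(0.1877, 0.1852, 0.1784, 0.1689))
  expect_equal(cand$k[select_best_model(cand)], 4)
  # ties break toward smaller k
  tie <- data.frame(k = c(2, 3), test_ibs = c(0.15, 0.15))
  expect_equal(tie$k[select_best_model(tie)], 2)
})

test_that("search recovers a strong planted pair across seeds", {
  hits <- 0
  n_seeds <- 10
  for (seed in seq_len(n_seeds)) {
    coh <- planted_two_way(400, hr = 0.25, seed = 700 + seed)
    plan <- cv_plan(coh$outcome, folds = 5, seed = seed)
    res <- sdr_search(coh$gm, coh$outcome, 2, plan)
    hits <- hits + setequal(res$best$subset, c("rs2071559", "rs208294"))
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("training IBS does not exceed testing IBS on average", {
  set.seed(55)
  diffs <- numeric(20)
  for (rep in 1:20) {
    coh <- planted_two_way(120, hr = 0.3, seed = 900 + rep)
    plan <- cv_plan(coh$outcome, folds = 5, seed = rep)
    res <- sdr_search(coh$gm, coh$outcome, 2, plan)
    best <- res$log[res$log$test_ibs == res$best$test_ibs, ][1, ]
    diffs[rep] <- best$test_ibs - best$train_ibs
  }
  expect_gt(mean(diffs), 0)  # over-fitting direction as a trend
})

test_that("permutation test is deterministic, bounded, and significant on
           a strong planted model", {
  coh <- planted_two_way(100, hr = 0.2, seed = 31)
  plan <- cv_plan(coh$outcome, folds = 5, seed = 3)
  pt1 <- permutation_test(coh$gm, coh$outcome, k = 2, plan, B = 49,
                          seed = 11)
  pt2 <- permutation_test(coh$gm, coh$outcome, k = 2, plan, B = 49,
                          seed = 11)
  expect_identical(pt1$p, pt2$p)
  expect_gte(pt1$p, 1 / 50)
  expect_lte(pt1$p, 1)
  expect_equal(pt1$p, 1 / 50)  # strong effect: no permutation beats it
  expect_error(permutation_test(coh$gm, coh$outcome, 2, plan, B = 0), "B")
})

test_that("fast two-group log-rank matches survival::survdiff", {
  set.seed(23)
  for (rep in 1:10) {
    time <- round(rexp(40, 0.03), 1) + 0.1
    event <- rbinom(40, 1, 0.8)
    grp <- rbinom(40, 1, 0.5) == 1
    if (length(unique(grp)) < 2) next
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
    expect_equal(sdrsurv:::.logrank2(time, event, grp), unname(sd$chisq),
                 tolerance = 1e-9)
  }
})

test_that("selection probability grows with sample size", {
  rate <- function(n, seeds) {
    hits <- 0
    for (s in seeds) {
      cfg <- synthetic_config(n = n,
                              planted_subset = c("rs2071559", "rs208294"),
                              hr_favorable = 0.45, seed = 4000 + s)
      coh <- gen_cohort(cfg)
      plan <- cv_plan(coh$outcome, folds = 5, seed = s)
      res <- sdr_search(coh$gm, coh$outcome, 2, plan)
      hits <- hits + setequal(res$best$subset, c("rs2071559", "rs208294"))
    }
    hits
  }
  hits <- vapply(c(100, 400, 1600), rate, numeric(1), seeds = 1:8)
  expect_gte(hits[3], hits[1])
  expect_gte(hits[3], 7)  # near-certain selection at n = 1600
})
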