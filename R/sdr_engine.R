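# Survival Dimensionality Reduction engine: exhaustive k-way genotype
# combination search, favorable/unfavorable cell classification,
# cross-validated testing-IBS model selection and permutation significance.

#' Build an event-stratified cross-validation plan
#'
#' Subjects are split into folds separately within events and censored
#' observations (round-robin after a seeded shuffle), so each fold's event
#' fraction stays within one subject of the overall fraction.
#'
#' @param outcome A [survival_outcome()].
#' @param folds Number of folds (default 10).
#' @param seed Integer seed; the global RNG state is restored afterwards.
#' @return A `cv_plan`: integer fold id per subject, fold count, seed.
#' @export
cv_plan <- function(outcome, folds = 10L, seed = 1L) {
  stopifnot(inherits(outcome, "survival_outcome"), folds >= 2L)
  n <- nrow(outcome)
  if (folds > n) stop("more folds than subjects")
  fold <- integer(n)
  .with_seed(seed, {
    for (grp in list(which(outcome$event == 1), which(outcome$event == 0))) {
      if (length(grp)) {
        fold[sample(grp)] <- rep_len(seq_len(folds), length(grp))
      }
    }
  })
  structure(list(fold = fold, folds = as.integer(folds), seed = seed),
            class = "cv_plan")
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Integer cell code per subject for a SNP subset: 1 + sum g_j 3^(j-1) with
# g = minor-allele count; NA when any subset call is missing.
.subset_codes <- function(mac, cols) {
  g <- mac[, cols, drop = FALSE]
  code <- rep(1L, nrow(g))
  for (j in seq_along(cols)) code <- code + g[, j] * 3L^(j - 1L)
  code
}

.code_to_key <- function(code, panel, cols) {
  g <- integer(length(cols))
  c0 <- code - 1L
  for (j in seq_along(cols)) {
    g[j] <- c0 %% 3L
    c0 <- c0 %/% 3L
  }
  geno <- vapply(seq_along(cols), function(j) {
    maj <- panel$allele_major[cols[j]]; mnr <- panel$allele_minor[cols[j]]
    c(paste0(maj, maj), paste0(maj, mnr), paste0(mnr, mnr))[g[j] + 1L]
  }, character(1L))
  paste(geno, collapse = "/")
}

#' Partition subjects into multilocus genotype cells
#'
#' One cell per distinct observed genotype combination over the SNP subset;
#' subjects with a missing call at any subset SNP are excluded (listwise
#' within the subset) and counted.
#'
#' @param gm A [genotype_matrix()].
#' @param subset Character vector of SNP ids.
#' @param subjects Optional integer indices restricting the cohort.
#' @return List of cells, each `list(key, code, members)` with members as
#'   cohort indices; attribute `n_excluded` counts missing-call subjects.
#' @export
partition_cells <- function(gm, subset, subjects = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(subset) == 0L) stop("empty SNP subset")
  cols <- match(subset, gm$panel$snp_id)
  if (anyNA(cols)) stop("SNPs not in panel: ",
                        paste(subset[is.na(cols)], collapse = ", "))
  if (is.null(subjects)) subjects <- seq_along(gm$subject_ids)
  if (length(subjects) == 0L) stop("empty subject set")
  mac <- minor_allele_count(gm)
  code <- .subset_codes(mac, cols)[subjects]
  ok <- !is.na(code)
  cells <- lapply(sort(unique(code[ok])), function(cd) {
    list(key = .code_to_key(cd, gm$panel, cols), code = cd,
         members = subjects[ok][code[ok] == cd])
  })
  attr(cells, "n_excluded") <- sum(!ok)
  cells
}

#' Classify one genotype cell against the training sample
#'
#' Default rule (`"logrank-oe"`): the cell's log-rank observed-minus-expected
#' death count versus the full training sample (computed as the sum of
#' members' martingale residuals at the training Nelson-Aalen hazard, which
#' is algebraically the same quantity). Negative scores (fewer deaths than
#' expected) are favorable, positive unfavorable, zero unclassifiable.
#' Alternative rule (`"median"`): the cell's Kaplan-Meier median against the
#' training median; longer is favorable.
#'
#' @param cell A cell from [partition_cells()], with `members` indexing rows
#'   of `training_outcome`.
#' @param training_outcome A [survival_outcome()] for the training sample
#'   (which contains the cell).
#' @param rule `"logrank-oe"` (default) or `"median"`.
#' @return List with `label` and `score`.
#' @export
classify_cell <- function(cell, training_outcome,
                          rule = c("logrank-oe", "median")) {
  rule <- match.arg(rule)
  stopifnot(inherits(training_outcome, "survival_outcome"),
            length(cell$members) >= 1L)
  m <- cell$members
  if (rule == "logrank-oe") {
    na <- .na_fit(training_outcome$time, training_outcome$event)
    H <- .step_eval(training_outcome$time[m], na$time, na$cumhaz, init = 0)
    score <- sum(training_outcome$event[m] - H)
    label <- if (score < -1e-12) "favorable"
      else if (score > 1e-12) "unfavorable" else "unclassifiable"
  } else {
    med_all <- .km_median(training_outcome$time, training_outcome$event)
    med_cell <- .km_median(training_outcome$time[m],
                           training_outcome$event[m])
    score <- .median_score(med_cell, med_all)
    label <- if (is.na(score) || score == 0) "unclassifiable"
      else if (score > 0) "favorable" else "unfavorable"
  }
  list(label = label, score = score)
}

.km_median <- function(time, event) {
  km <- .km_fit(time, event)
  idx <- which(km$surv <= 0.5 + 1e-12)
  if (length(idx) == 0L) NA_real_ else km$time[idx[1L]]
}

# score > 0: cell outlives the training sample; NA cell median counts as
# "never reaches 0.5", i.e. favorable relative to a defined overall median.
.median_score <- function(med_cell, med_all) {
  if (is.na(med_cell) && is.na(med_all)) return(NA_real_)
  if (is.na(med_cell)) return(1)
  if (is.na(med_all)) return(-1)
  med_cell - med_all
}

# ---- fast internal fold evaluation ----------------------------------------

# Scores for every cell in one pass: rowsum of martingale residuals
# (logrank-oe) or per-cell KM medians (median rule).
.cell_scores <- function(code_tr, time_tr, event_tr, rule) {
  cells <- sort(unique(code_tr))
  if (rule == "logrank-oe") {
    na <- .na_fit(time_tr, event_tr)
    H <- .step_eval(time_tr, na$time, na$cumhaz, init = 0)
    sc <- rowsum(event_tr - H, factor(code_tr, levels = cells))[, 1L]
    lab <- ifelse(sc < -1e-12, "favorable",
                  ifelse(sc > 1e-12, "unfavorable", "unclassifiable"))
  } else {
    med_all <- .km_median(time_tr, event_tr)
    sc <- vapply(cells, function(cd) {
      sel <- code_tr == cd
      .median_score(.km_median(time_tr[sel], event_tr[sel]), med_all)
    }, numeric(1L))
    lab <- ifelse(is.na(sc) | sc == 0, "unclassifiable",
                  ifelse(sc > 0, "favorable", "unfavorable"))
  }
  list(cells = cells, score = sc, label = lab)
}

# Evaluate one train/test split of one subset: classify the training cells,
# then score the resulting labeled assignment.
.sdr_eval_split <- function(code, time, event, train, test,
                            rule = "logrank-oe", unseen = "exclude") {
  ct <- code[train]
  ok_tr <- !is.na(ct)
  tt <- time[train][ok_tr]; ee <- event[train][ok_tr]
  ct <- ct[ok_tr]
  if (length(tt) == 0L || sum(ee) == 0) {
    return(list(train_ibs = NA_real_, test_ibs = NA_real_, degenerate = TRUE,
                n_excluded_test = length(test), skipped = TRUE))
  }
  cs <- .cell_scores(ct, tt, ee, rule)
  .eval_labeled(code, time, event, train, test, cs$cells, cs$label, unseen)
}

# Score a labeled cell assignment on a train/test split. Returns train/test
# IBS, degeneracy flag and test exclusion count. Sentinel IBS = 1 for
# degenerate models (a profile group empty in training).
.eval_labeled <- function(code, time, event, train, test, cells, labels,
                          unseen = "exclude") {
  ct <- code[train]
  ok_tr <- !is.na(ct)
  tt <- time[train][ok_tr]; ee <- event[train][ok_tr]
  ct <- ct[ok_tr]
  if (length(tt) == 0L || sum(ee) == 0) {
    return(list(train_ibs = NA_real_, test_ibs = NA_real_, degenerate = TRUE,
                n_excluded_test = length(test), skipped = TRUE))
  }
  lab_tr <- labels[match(ct, cells)]
  fav <- !is.na(lab_tr) & lab_tr == "favorable"
  unf <- !is.na(lab_tr) & lab_tr == "unfavorable"
  if (!any(fav) || !any(unf)) {
    return(list(train_ibs = 1, test_ibs = 1, degenerate = TRUE,
                n_excluded_test = 0L, skipped = FALSE))
  }
  km_f <- .km_fit(tt[fav], ee[fav])
  km_u <- .km_fit(tt[unf], ee[unf])
  G <- .km_fit(tt, 1 - ee)
  ev <- sort(unique(tt[ee == 1]))
  g_at_ev <- .step_eval(ev, G$time, G$surv)
  if (!any(g_at_ev > 0)) {
    return(list(train_ibs = NA_real_, test_ibs = NA_real_, degenerate = TRUE,
                n_excluded_test = length(test), skipped = TRUE))
  }
  tau <- max(ev[g_at_ev > 0])
  score_set <- function(s_time, s_event, s_fav) {
    grid <- sort(unique(c(0, s_time[s_event == 1 & s_time <= tau], tau)))
    sf <- .step_eval(grid, km_f$time, km_f$surv)
    su <- .step_eval(grid, km_u$time, km_u$surv)
    s_mat <- rbind(sf, su)[2L - s_fav, , drop = FALSE]  # fav -> row 1
    bs <- .brier_at(s_time, s_event, s_mat, grid, G)
    .trapz(grid, bs) / tau
  }
  train_ibs <- score_set(tt[fav | unf], ee[fav | unf], fav[fav | unf])
  cte <- code[test]
  lab_te <- labels[match(cte, cells)]
  if (unseen == "unfavorable") {
    lab_te[!is.na(cte) & (is.na(lab_te) | lab_te == "unclassifiable")] <-
      "unfavorable"
  }
  use <- !is.na(lab_te) & lab_te %in% c("favorable", "unfavorable")
  n_excl <- length(test) - sum(use)
  if (!any(use) || sum(event[test][use]) == 0) {
    return(list(train_ibs = train_ibs, test_ibs = NA_real_,
                degenerate = FALSE, n_excluded_test = n_excl,
                skipped = TRUE))
  }
  test_ibs <- score_set(time[test][use], event[test][use],
                        lab_te[use] == "favorable")
  list(train_ibs = train_ibs, test_ibs = test_ibs, degenerate = FALSE,
       n_excluded_test = n_excl, skipped = FALSE)
}

#' Derive favorable/unfavorable profiles for a SNP subset
#'
#' Classifies every genotype cell observed among the training subjects.
#'
#' @param gm A [genotype_matrix()].
#' @param outcome Aligned [survival_outcome()].
#' @param subset Character vector of SNP ids.
#' @param subjects Training subject indices (default all).
#' @param rule Cell classification rule, see [classify_cell()].
#' @return A `profile_assignment`: per-cell table (key, n, events, score,
#'   label), the subset, rule and training indices.
#' @export
derive_profiles <- function(gm, outcome, subset, subjects = NULL,
                            rule = c("logrank-oe", "median")) {
  rule <- match.arg(rule)
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(outcome, "survival_outcome"))
  if (is.null(subjects)) subjects <- seq_along(gm$subject_ids)
  cols <- match(subset, gm$panel$snp_id)
  if (anyNA(cols)) stop("SNPs not in panel: ",
                        paste(subset[is.na(cols)], collapse = ", "))
  mac <- minor_allele_count(gm)
  code <- .subset_codes(mac, cols)
  ct <- code[subjects]
  ok <- !is.na(ct)
  tt <- outcome$time[subjects][ok]; ee <- outcome$event[subjects][ok]
  if (sum(ee) == 0) stop("no events among training subjects")
  cs <- .cell_scores(ct[ok], tt, ee, rule)
  n_cell <- as.integer(table(factor(ct[ok], levels = cs$cells)))
  ev_cell <- as.numeric(rowsum(ee, factor(ct[ok], levels = cs$cells))[, 1L])
  tab <- data.frame(
    cell = vapply(cs$cells, .code_to_key, character(1L),
                  panel = gm$panel, cols = cols),
    code = cs$cells, n = n_cell, events = ev_cell, score = unname(cs$score),
    label = unname(cs$label), stringsAsFactors = FALSE)
  structure(list(table = tab, subset = subset, rule = rule,
                 snp_cols = cols, training = subjects,
                 n_excluded = sum(!ok)),
            class = "profile_assignment")
}

#' @export
print.profile_assignment <- function(x, ...) {
  cat("profile assignment over {", paste(x$subset, collapse = ", "),
      "}: ", nrow(x$table), " cells (",
      sum(x$table$label == "favorable"), " favorable, ",
      sum(x$table$label == "unfavorable"), " unfavorable, ",
      sum(x$table$label == "unclassifiable"), " unclassifiable)\n", sep = "")
  invisible(x)
}

#' Assign profile labels to subjects from a derived assignment
#'
#' @param assignment A [derive_profiles()] result.
#' @param gm The [genotype_matrix()] the assignment was derived on.
#' @param subjects Indices to label (default all).
#' @param unseen Policy for cells unseen (or unclassifiable) in training:
#'   `"exclude"` labels them `NA`, `"unfavorable"` folds them into the
#'   unfavorable profile.
#' @return Character vector of labels (`"favorable"`, `"unfavorable"`, or
#'   `NA`) for the requested subjects.
#' @export
assign_profiles <- function(assignment, gm, subjects = NULL,
                            unseen = c("exclude", "unfavorable")) {
  unseen <- match.arg(unseen)
  stopifnot(inherits(assignment, "profile_assignment"))
  if (is.null(subjects)) subjects <- seq_along(gm$subject_ids)
  mac <- minor_allele_count(gm)
  code <- .subset_codes(mac, assignment$snp_cols)[subjects]
  lab <- assignment$table$label[match(code, assignment$table$code)]
  lab[!is.na(lab) & lab == "unclassifiable"] <- NA_character_
  if (unseen == "unfavorable") lab[!is.na(code) & is.na(lab)] <- "unfavorable"
  lab
}

#' Evaluate a profile assignment as a survival predictor
#'
#' Each subject's predicted survival curve is the training Kaplan-Meier
#' curve of their profile group; performance is the IPCW Integrated Brier
#' Score on the training and test sets (censoring weights and the
#' integration bound always come from the training subjects).
#'
#' @param assignment A [derive_profiles()] result (derived from the training
#'   subjects only).
#' @param gm,outcome The aligned cohort.
#' @param train,test Integer subject indices.
#' @param unseen Policy for test subjects in unseen/unclassifiable cells.
#' @return List with `train_ibs`, `test_ibs`, `degenerate`,
#'   `n_excluded_test`.
#' @export
evaluate_model <- function(assignment, gm, outcome, train, test,
                           unseen = c("exclude", "unfavorable")) {
  unseen <- match.arg(unseen)
  stopifnot(inherits(assignment, "profile_assignment"))
  mac <- minor_allele_count(gm)
  code <- .subset_codes(mac, assignment$snp_cols)
  res <- .eval_labeled(code, outcome$time, outcome$event, train, test,
                       assignment$table$code, assignment$table$label,
                       unseen = unseen)
  res[c("train_ibs", "test_ibs", "degenerate", "n_excluded_test")]
}

#' Cross-validated IBS for one SNP subset
#'
#' For each fold, profiles are derived on the out-of-fold subjects and
#' scored on the held-out fold; fold means of training and testing IBS are
#' returned. Folds whose training or test part has no usable events are
#' skipped and counted.
#'
#' @param gm,outcome Aligned cohort.
#' @param subset Character vector of SNP ids.
#' @param plan A [cv_plan()].
#' @param rule,unseen Classification rule and unseen-cell policy.
#' @return List: `train_ibs`, `test_ibs` (fold means; sentinel 1 when every
#'   fold is degenerate), `n_folds_used`, `n_folds_skipped`,
#'   `n_degenerate`, `n_excluded_test`.
#' @export
cross_validate <- function(gm, outcome, subset, plan,
                           rule = c("logrank-oe", "median"),
                           unseen = c("exclude", "unfavorable")) {
  rule <- match.arg(rule); unseen <- match.arg(unseen)
  stopifnot(inherits(plan, "cv_plan"))
  cols <- match(subset, gm$panel$snp_id)
  if (anyNA(cols)) stop("SNPs not in panel")
  mac <- minor_allele_count(gm)
  code <- .subset_codes(mac, cols)
  .cv_codes(code, outcome$time, outcome$event, plan, rule, unseen)
}

# Shared CV core over precomputed codes.
.cv_codes <- function(code, time, event, plan, rule, unseen) {
  tr_ibs <- te_ibs <- numeric(0)
  skipped <- degen <- excl <- 0L
  for (f in seq_len(plan$folds)) {
    test <- which(plan$fold == f)
    train <- which(plan$fold != f)
    r <- .sdr_eval_split(code, time, event, train, test, rule, unseen)
    excl <- excl + r$n_excluded_test
    if (isTRUE(r$skipped)) { skipped <- skipped + 1L; next }
    if (isTRUE(r$degenerate)) degen <- degen + 1L
    tr_ibs <- c(tr_ibs, r$train_ibs)
    te_ibs <- c(te_ibs, r$test_ibs)
  }
  if (length(te_ibs) == 0L) {
    return(list(train_ibs = 1, test_ibs = 1, n_folds_used = 0L,
                n_folds_skipped = skipped, n_degenerate = degen,
                n_excluded_test = excl))
  }
  list(train_ibs = mean(tr_ibs), test_ibs = mean(te_ibs),
       n_folds_used = length(te_ibs), n_folds_skipped = skipped,
       n_degenerate = degen, n_excluded_test = excl)
}

#' Select the best model from per-k candidate testing IBS values
#'
#' The argmin of the mean testing IBS; ties break toward fewer SNPs
#' (parsimony), then toward the earlier (lexicographically smaller) subset.
#'
#' @param candidates Data frame with columns `k` and `test_ibs` (rows
#'   already in tie-break order within each k).
#' @return Integer row index of the selected model.
#' @export
select_best_model <- function(candidates) {
  stopifnot(all(c("k", "test_ibs") %in% names(candidates)))
  ord <- order(candidates$test_ibs, candidates$k,
               seq_len(nrow(candidates)))
  ord[1L]
}

#' Exhaustive SDR search over k-way SNP subsets
#'
#' Evaluates every size-k subset of the panel for each k in `k_range` by
#' cross-validated IPCW Integrated Brier Score, selects the best model per k
#' and overall (minimum mean testing IBS; ties toward smaller k, then
#' lexicographic subset order), and refits the winning profile assignment on
#' the full cohort.
#'
#' @param gm,outcome Aligned cohort.
#' @param k_range Integer vector of subset sizes.
#' @param plan A [cv_plan()].
#' @param rule,unseen Classification rule and unseen-cell policy.
#' @return An `sdr_search_result`: full evaluation `log`, `per_k` best
#'   models, overall `best` (k, subset, train/test IBS), full-data
#'   `profiles` refit and per-subject `labels`.
#' @export
sdr_search <- function(gm, outcome, k_range, plan,
                       rule = c("logrank-oe", "median"),
                       unseen = c("exclude", "unfavorable")) {
  rule <- match.arg(rule); unseen <- match.arg(unseen)
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(outcome, "survival_outcome"),
            inherits(plan, "cv_plan"))
  p <- nrow(gm$panel)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stop("empty k_range")
  if (any(k_range < 1L | k_range > p)) stop("k_range outside 1..panel size")
  mac <- minor_allele_count(gm)
  subsets <- list(); codes <- list()
  for (k in k_range) {
    cmb <- utils::combn(p, k)
    for (j in seq_len(ncol(cmb))) {
      subsets[[length(subsets) + 1L]] <- cmb[, j]
      codes[[length(codes) + 1L]] <- .subset_codes(mac, cmb[, j])
    }
  }
  res <- .search_codes(codes, subsets, outcome$time, outcome$event, plan,
                       rule, unseen)
  log_df <- res$log
  log_df$subset <- vapply(subsets, function(s)
    paste(gm$panel$snp_id[s], collapse = "+"), character(1L))
  per_k <- do.call(rbind, lapply(k_range, function(k) {
    sub <- log_df[log_df$k == k, , drop = FALSE]
    sub[which.min(sub$test_ibs), , drop = FALSE]
  }))
  best_row <- per_k[select_best_model(per_k), , drop = FALSE]
  best_subset <- strsplit(best_row$subset, "+", fixed = TRUE)[[1L]]
  profiles <- derive_profiles(gm, outcome, best_subset, rule = rule)
  labels <- assign_profiles(profiles, gm, unseen = unseen)
  structure(list(log = log_df, per_k = per_k,
                 best = list(k = best_row$k, subset = best_subset,
                             train_ibs = best_row$train_ibs,
                             test_ibs = best_row$test_ibs),
                 profiles = profiles, labels = labels, plan = plan,
                 rule = rule, unseen = unseen),
            class = "sdr_search_result")
}

# Shared search core over precomputed per-subset codes.
.search_codes <- function(codes, subsets, time, event, plan, rule, unseen) {
  n_sub <- length(codes)
  k <- vapply(subsets, length, integer(1L))
  tr <- te <- numeric(n_sub)
  used <- skipped <- degen <- excl <- integer(n_sub)
  for (i in seq_len(n_sub)) {
    cvr <- .cv_codes(codes[[i]], time, event, plan, rule, unseen)
    tr[i] <- cvr$train_ibs; te[i] <- cvr$test_ibs
    used[i] <- cvr$n_folds_used; skipped[i] <- cvr$n_folds_skipped
    degen[i] <- cvr$n_degenerate; excl[i] <- cvr$n_excluded_test
  }
  list(log = data.frame(k = k, train_ibs = tr, test_ibs = te,
                        n_folds_used = used, n_folds_skipped = skipped,
                        n_degenerate = degen, n_excluded_test = excl))
}

#' @export
print.sdr_search_result <- function(x, ...) {
  cat("SDR search:", nrow(x$log), "subset evaluations\n")
  cat("per-k best models:\n")
  print(x$per_k[, c("k", "subset", "train_ibs", "test_ibs")],
        row.names = FALSE)
  cat("selected:", paste(x$best$subset, collapse = "+"),
      sprintf("(k = %d, testing IBS = %.4f)\n", x$best$k, x$best$test_ibs))
  invisible(x)
}

# Fast two-group log-rank chi-squared (tested against survival::survdiff).
.logrank2 <- function(time, event, grp) {
  o <- order(time)
  tt <- time[o]; ee <- event[o]; g1 <- grp[o]
  ut <- unique(tt[ee == 1])
  st <- tt
  n <- length(tt)
  oe <- v <- 0
  for (t in ut) {
    at_risk <- tt >= t
    n_t <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(ee == 1 & tt == t)
    d1 <- sum(ee == 1 & tt == t & g1)
    oe <- oe + d1 - d * n1 / n_t
    if (n_t > 1) {
      v <- v + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
    }
  }
  if (v <= 0) return(0)
  oe^2 / v
}

#' Permutation test of the selected SDR model
#'
#' The observed statistic is the log-rank chi-squared between the
#' favorable/unfavorable full-data profiles of the model selected at size
#' `k`. Each permutation jointly permutes the outcome rows against the
#' genotype rows, re-runs the full subset search at the same `k` with the
#' same cross-validation plan, and recomputes the statistic for the model
#' that permutation selects; `p = (1 + #{perm >= observed}) / (B + 1)`.
#'
#' @param gm,outcome Aligned cohort.
#' @param k Interaction order to search at.
#' @param plan A [cv_plan()].
#' @param B Number of permutations (default 1000).
#' @param seed Seed for the permutation stream.
#' @param rule,unseen Passed to the search.
#' @return List: `p`, `observed` statistic, `B`, the observed search's
#'   selected subset, and the permutation statistics.
#' @export
permutation_test <- function(gm, outcome, k, plan, B = 1000L, seed = 1L,
                             rule = c("logrank-oe", "median"),
                             unseen = c("exclude", "unfavorable")) {
  rule <- match.arg(rule); unseen <- match.arg(unseen)
  if (B < 1L) stop("B must be >= 1")
  p <- nrow(gm$panel)
  if (k < 1L || k > p) stop("k outside 1..panel size")
  mac <- minor_allele_count(gm)
  cmb <- utils::combn(p, as.integer(k))
  subsets <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  codes <- lapply(subsets, function(s) .subset_codes(mac, s))
  time <- outcome$time; event <- outcome$event
  stat_of <- function(tm, ev) {
    res <- .search_codes(codes, subsets, tm, ev, plan, rule, unseen)
    best <- which.min(res$log$test_ibs)  # single k: argmin suffices
    code <- codes[[best]]
    cs <- tryCatch(
      .cell_scores(code[!is.na(code)], tm[!is.na(code)], ev[!is.na(code)],
                   rule),
      error = function(e) NULL)
    if (is.null(cs)) return(list(stat = 0, best = best))
    lab <- cs$label[match(code, cs$cells)]
    use <- !is.na(lab) & lab %in% c("favorable", "unfavorable")
    if (length(unique(lab[use])) < 2L) return(list(stat = 0, best = best))
    list(stat = .logrank2(tm[use], ev[use], lab[use] == "favorable"),
         best = best)
  }
  obs <- stat_of(time, event)
  n <- length(time)
  perm_stats <- numeric(B)
  .with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n)
      perm_stats[b] <- stat_of(time[idx], event[idx])$stat
    }
  })
  p_val <- (1 + sum(perm_stats >= obs$stat - 1e-12)) / (B + 1)
  list(p = p_val, observed = obs$stat, B = as.integer(B),
       subset = gm$panel$snp_id[subsets[[obs$best]]],
       perm_stats = perm_stats)
}
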