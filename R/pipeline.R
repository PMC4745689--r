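# One-command orchestration: QC table, clinical and per-SNP Cox,
# haplotype dosage Cox, SDR search + permutation, profile table, KM by
# profile and the adjusted multivariate Cox.

#' Configuration for the full analysis pipeline
#'
#' @param genotypes,survival Paths to the canonical TSVs, or `NULL` when
#'   `synthetic` is given.
#' @param synthetic Optional [synthetic_config()] used instead of input
#'   files.
#' @param k_range Subset sizes for the SDR search.
#' @param folds Cross-validation folds.
#' @param permutations Permutation count for model significance.
#' @param seed Master seed (CV plan and permutations derive from it).
#' @param family_size Bonferroni family size for the per-SNP report;
#'   defaults to the panel size at run time.
#' @param haplotype_threshold Common-haplotype frequency threshold.
#' @param gene_regions Optional named list of SNP-id vectors defining the
#'   haplotype regions; defaults to grouping panel SNPs by gene label.
#' @param covariates Covariate columns screened for the adjusted model.
#' @param covariate_screen_p Univariate p-value below which a covariate
#'   enters the adjusted model.
#' @param force_covariates Covariates always included in the adjusted model.
#' @param rule,unseen SDR cell rule and unseen-cell policy.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genotypes = NULL, survival = NULL,
                            synthetic = NULL, k_range = 1:4, folds = 10L,
                            permutations = 1000L, seed = 1L,
                            family_size = NULL, haplotype_threshold = 0.05,
                            gene_regions = NULL,
                            covariates = c("age", "ecog_ps", "gleason_high",
                                           "psa", "mts_sites", "therapy"),
                            covariate_screen_p = 0.05,
                            force_covariates = character(0),
                            rule = "logrank-oe", unseen = "exclude") {
  if (is.null(synthetic) && (is.null(genotypes) || is.null(survival))) {
    stop("either input paths or a synthetic config must be supplied")
  }
  if (haplotype_threshold <= 0 || haplotype_threshold >= 1) {
    stop("haplotype_threshold must be in (0, 1)")
  }
  structure(list(genotypes = genotypes, survival = survival,
                 synthetic = synthetic, k_range = k_range,
                 folds = as.integer(folds),
                 permutations = as.integer(permutations),
                 seed = as.integer(seed), family_size = family_size,
                 haplotype_threshold = haplotype_threshold,
                 gene_regions = gene_regions, covariates = covariates,
                 covariate_screen_p = covariate_screen_p,
                 force_covariates = force_covariates, rule = rule,
                 unseen = unseen),
            class = "pipeline_config")
}

#' Survival probabilities at landmark years
#'
#' Step-function lookup of the Kaplan-Meier estimate at `12 * years`
#' months, with the log-log confidence band at those times; years beyond
#' the last follow-up time are flagged missing.
#'
#' @param km A [kaplan_meier()] estimate.
#' @param years Numeric vector of landmark years.
#' @return Data frame: year, months, surv, lower, upper, `within_followup`.
#' @export
summarize_survival_at <- function(km, years) {
  stopifnot(inherits(km, "km_estimate"))
  months <- 12 * years
  cv <- km$curve
  idx <- findInterval(months, cv$time)
  get <- function(col, default) c(default, cv[[col]])[idx + 1L]
  max_t <- max(c(cv$time, 0))
  out <- data.frame(year = years, months = months, surv = get("surv", 1),
                    lower = get("lower", NA_real_),
                    upper = get("upper", NA_real_),
                    within_followup = months <= max_t)
  out$surv[!out$within_followup] <- NA_real_
  out$lower[!out$within_followup] <- NA_real_
  out$upper[!out$within_followup] <- NA_real_
  out
}

# Univariate Cox per clinical covariate (whole-cohort report).
.clinical_cox_table <- function(outcome, covariates) {
  rows <- list()
  for (cov in covariates) {
    if (!cov %in% names(outcome)) next
    v <- outcome[[cov]]
    keep <- !is.na(v)
    if (length(unique(v[keep])) < 2L) next
    cf <- cox_fit(outcome[keep, , drop = FALSE],
                  stats::setNames(data.frame(as.numeric(v[keep])), cov))
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(variable = cov, n = sum(keep)), cf$table[1L, -1L])
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Haplotype dosage Cox per gene region: common haplotypes vs the most
# common as reference.
.haplotype_cox_table <- function(gm, outcome, regions, threshold) {
  rows <- list()
  for (region in names(regions)) {
    snps <- regions[[region]]
    if (length(snps) < 2L) next
    hf <- em_haplotypes(gm, snps, rare_threshold = threshold)
    common <- names(hf$freq)[!hf$rare]
    if (length(common) < 2L) next
    dos <- haplotype_dosages(gm, hf)
    ref <- common[which.max(hf$freq[common])]
    terms <- setdiff(common, ref)
    keep <- match(rownames(dos), outcome$subject_id)
    cf <- tryCatch(
      cox_fit(outcome[keep, , drop = FALSE],
              as.data.frame(dos[, terms, drop = FALSE])),
      error = function(e) NULL)
    if (is.null(cf)) next
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(region = region, reference = ref,
                 ref_freq = unname(hf$freq[ref]),
                 freq = unname(hf$freq[cf$table$term])),
      cf$table)
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.km_export <- function(outcome, label) {
  km <- kaplan_meier(outcome)
  cbind(data.frame(group = label), km$curve)
}

#' Run the full candidate-SNP survival-epistasis pipeline
#'
#' Executes, in order: the per-SNP QC table; univariate clinical Cox; the
#' per-SNP Cox report under three codings with Bonferroni flags; haplotype
#' dosage Cox per gene region; the SDR search with permutation test; the
#' full-data profile table; Kaplan-Meier exports by profile with medians
#' and 2-/3-year survival; and the adjusted multivariate Cox of profile
#' plus screened covariates. Fails loudly with the stage name on error.
#'
#' @param config A [pipeline_config()].
#' @return A `report_bundle` (named list of data frames) with attributes
#'   `search` (the [sdr_search()] result) and `labels`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (!is.null(config$synthetic)) {
    cohort <- stage("simulate", gen_cohort(config$synthetic))
    gm <- cohort$gm; outcome <- cohort$outcome
  } else {
    gm <- stage("read_genotypes", read_genotypes(config$genotypes))
    outcome <- stage("read_survival", read_survival(config$survival))
    aligned <- stage("join", join_cohort(gm, outcome))
    gm <- aligned$gm; outcome <- aligned$outcome
  }
  bundle <- list()
  bundle$popgen <- stage("popgen", popgen_table(gm))
  bundle$clinical_cox <- stage(
    "clinical_cox", .clinical_cox_table(outcome, config$covariates))
  family <- config$family_size %||% nrow(gm$panel)
  bundle$snp_cox <- stage("snp_cox",
                          snp_cox_table(gm, outcome, family_size = family))
  regions <- config$gene_regions %||%
    split(gm$panel$snp_id, gm$panel$gene)
  bundle$haplotype_cox <- stage(
    "haplotype_cox",
    .haplotype_cox_table(gm, outcome, regions, config$haplotype_threshold))
  plan <- cv_plan(outcome, folds = config$folds, seed = config$seed)
  search <- stage("sdr_search",
                  sdr_search(gm, outcome, config$k_range, plan,
                             rule = config$rule, unseen = config$unseen))
  perm <- stage("permutation",
                permutation_test(gm, outcome, k = search$best$k, plan,
                                 B = config$permutations,
                                 seed = config$seed + 1L,
                                 rule = config$rule,
                                 unseen = config$unseen))
  sdr_tab <- search$per_k[, c("k", "subset", "train_ibs", "test_ibs")]
  sdr_tab$selected <- sdr_tab$k == search$best$k
  sdr_tab$permutation_p <- ifelse(sdr_tab$selected, perm$p, NA_real_)
  bundle$sdr_models <- sdr_tab
  bundle$profile_table <- search$profiles$table
  labels <- search$labels
  keep <- !is.na(labels)
  bundle$km_overall <- stage("km", .km_export(outcome, "all"))
  bundle$km_profiles <- stage("km_profiles", {
    fav <- outcome[keep & labels == "favorable", , drop = FALSE]
    unf <- outcome[keep & labels == "unfavorable", , drop = FALSE]
    class(fav) <- class(unf) <- class(outcome)
    rbind(.km_export(fav, "favorable"), .km_export(unf, "unfavorable"))
  })
  bundle$km_summary <- stage("km_summary", {
    subgroup <- function(sel) {
      x <- outcome[sel, , drop = FALSE]
      class(x) <- class(outcome)
      x
    }
    groups <- list(all = outcome,
                   favorable = subgroup(keep & labels == "favorable"),
                   unfavorable = subgroup(keep & labels == "unfavorable"))
    do.call(rbind, Map(function(g, nm) {
      km <- kaplan_meier(g)
      s <- summarize_survival_at(km, c(2, 3))
      data.frame(group = nm, n = km$n, events = km$n_events,
                 median = km$median, median_lower = km$median_lower,
                 median_upper = km$median_upper,
                 surv_2y = s$surv[1L], surv_2y_lower = s$lower[1L],
                 surv_2y_upper = s$upper[1L],
                 surv_3y = s$surv[2L], surv_3y_lower = s$lower[2L],
                 surv_3y_upper = s$upper[2L])
    }, groups, names(groups)))
  })
  bundle$multivariate_cox <- stage("multivariate_cox", {
    screen <- bundle$clinical_cox
    selected <- union(
      config$force_covariates,
      if (nrow(screen)) screen$variable[screen$p < config$covariate_screen_p]
      else character(0))
    out_sub <- outcome[keep, , drop = FALSE]
    class(out_sub) <- class(outcome)
    covs <- data.frame(profile_favorable =
                         as.numeric(labels[keep] == "favorable"))
    for (cov in selected) {
      if (cov %in% names(out_sub)) covs[[cov]] <- as.numeric(out_sub[[cov]])
    }
    cc <- stats::complete.cases(covs)
    out_cc <- out_sub[cc, , drop = FALSE]
    class(out_cc) <- class(outcome)
    cf <- cox_fit(out_cc, covs[cc, , drop = FALSE])
    lr <- logrank(out_sub, labels[keep])
    tab <- cf$table
    tab$logrank_p <- c(lr$p, rep(NA_real_, nrow(tab) - 1L))
    tab
  })
  class(bundle) <- c("report_bundle", class(bundle))
  attr(bundle, "search") <- search
  attr(bundle, "permutation") <- perm
  attr(bundle, "labels") <- labels
  bundle
}
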