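# Survival statistics: Kaplan-Meier, log-rank, Cox PH under the three
# genetic codings, and IPCW Brier / Integrated Brier scoring.

.as_surv <- function(outcome) {
  survival::Surv(outcome$time, outcome$event)
}

#' Kaplan-Meier estimate with median and confidence band
#'
#' Product-limit estimator with Greenwood variance and log-log 95%
#' confidence band; the median and its confidence interval come from
#' inverting the band (Brookmeyer-Crowley).
#'
#' @param outcome A [survival_outcome()].
#' @return A `km_estimate`: data frame of the curve (time, n_risk, n_event,
#'   surv, lower, upper), the median with CI, and the underlying
#'   `survival::survfit` object.
#' @export
kaplan_meier <- function(outcome) {
  stopifnot(inherits(outcome, "survival_outcome"), nrow(outcome) >= 1L)
  fit <- survival::survfit(.as_surv(outcome) ~ 1, conf.type = "log-log")
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv,
                      lower = fit$lower, upper = fit$upper)
  tab <- summary(fit)$table
  structure(list(curve = curve,
                 median = unname(tab["median"]),
                 median_lower = unname(tab["0.95LCL"]),
                 median_upper = unname(tab["0.95UCL"]),
                 n = nrow(outcome), n_events = sum(outcome$event),
                 fit = fit),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate:", x$n, "subjects,", x$n_events, "events\n")
  cat(sprintf("median %s months (95%% CI %s - %s)\n",
              format(x$median), format(x$median_lower),
              format(x$median_upper)))
  invisible(x)
}

#' Log-rank test between groups
#'
#' Standard (unweighted) log-rank test with `k - 1` degrees of freedom for
#' `k` groups.
#'
#' @param outcome A [survival_outcome()].
#' @param groups Group labels, one per subject.
#' @return List with `chi2`, `df`, `p`.
#' @export
logrank <- function(outcome, groups) {
  stopifnot(inherits(outcome, "survival_outcome"))
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("log-rank test needs at least 2 non-empty groups")
  sd <- survival::survdiff(.as_surv(outcome) ~ groups)
  df <- nlevels(groups) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling and Wald confidence
#' intervals. Non-convergence or monotone likelihood (complete separation,
#' detected as an extreme coefficient or exploding standard error) is
#' flagged in the result rather than raising.
#'
#' @param outcome A [survival_outcome()].
#' @param covariates Data frame or matrix of coded covariate columns.
#' @return A `cox_fit`: per-term table (coef, hr, lower, upper, p),
#'   log-likelihood, n, events, `flagged` + `flag_reason`.
#' @export
cox_fit <- function(outcome, covariates) {
  stopifnot(inherits(outcome, "survival_outcome"))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(outcome)) {
    stop("covariates and outcome differ in length")
  }
  const <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) < 2L,
                  logical(1L))
  if (any(const)) {
    stop("constant covariate column(s): ",
         paste(names(covariates)[const], collapse = ", "))
  }
  if (sum(outcome$event) < 1) stop("no events in outcome")
  dat <- cbind(data.frame(.time = outcome$time, .event = outcome$event),
               covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  flagged <- FALSE; reason <- NA_character_
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|Loglik", conditionMessage(w))) {
        flagged <<- TRUE
        reason <<- conditionMessage(w)
      }
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  if (any(abs(co[, "coef"]) > 15) || any(co[, "se(coef)"] > 100)) {
    flagged <- TRUE
    if (is.na(reason)) reason <- "extreme coefficient: possible separation"
  }
  tab <- data.frame(term = rownames(co),
                    coef = unname(co[, "coef"]),
                    hr = unname(co[, "exp(coef)"]),
                    lower = unname(ci[, "lower .95"]),
                    upper = unname(ci[, "upper .95"]),
                    p = unname(co[, "Pr(>|z|)"]),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, loglik = fit$loglik[2L], n = fit$n,
                 n_events = fit$nevent, flagged = flagged,
                 flag_reason = reason, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox PH fit (Efron ties):", x$n, "subjects,", x$n_events, "events\n")
  print(transform(x$table, hr = round(hr, 3), lower = round(lower, 3),
                  upper = round(upper, 3), p = signif(p, 3),
                  coef = round(coef, 4)))
  if (isTRUE(x$flagged)) cat("FLAGGED:", x$flag_reason, "\n")
  invisible(x)
}

#' Encode a SNP genotype under a genetic model
#'
#' Codings follow the study's orientation, defined with respect to the
#' major (first-listed) allele:
#' \describe{
#'   \item{additive}{two indicator columns, heterozygote and minor
#'     homozygote, with the major homozygote as reference (the genotypic
#'     parametrization that yields one hazard ratio per genotype).}
#'   \item{dominant}{minor homozygote vs (major homozygote + heterozygote).}
#'   \item{recessive}{(heterozygote + minor homozygote) vs major homozygote.}
#' }
#'
#' @param gm A [genotype_matrix()].
#' @param snp SNP id in the panel.
#' @param scheme `"additive"`, `"dominant"` or `"recessive"`.
#' @return A `genetic_coding`: list with the coded column(s) (data frame,
#'   `NA` for missing calls), group sizes, genotype labels and a `usable`
#'   flag (FALSE when the coding is constant, e.g. a monomorphic SNP).
#' @export
encode_genotype <- function(gm, snp, scheme = c("additive", "dominant",
                                                "recessive")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  scheme <- match.arg(scheme)
  j <- match(snp, gm$panel$snp_id)
  if (is.na(j)) stop("SNP not in panel: ", snp)
  mac <- minor_allele_count(gm)[, j]
  maj <- gm$panel$allele_major[j]; mnr <- gm$panel$allele_minor[j]
  g_lab <- c(paste0(maj, maj), paste0(maj, mnr), paste0(mnr, mnr))
  if (scheme == "additive") {
    cols <- data.frame(het = as.numeric(mac == 1L),
                       hom_minor = as.numeric(mac == 2L))
    names(cols) <- c(g_lab[2L], g_lab[3L])
    sizes <- c(sum(mac == 0L, na.rm = TRUE), sum(mac == 1L, na.rm = TRUE),
               sum(mac == 2L, na.rm = TRUE))
    names(sizes) <- g_lab
    usable <- all(sizes > 0L)
  } else if (scheme == "dominant") {
    ind <- as.numeric(mac == 2L)
    cols <- stats::setNames(data.frame(ind), g_lab[3L])
    sizes <- c(sum(mac < 2L, na.rm = TRUE), sum(mac == 2L, na.rm = TRUE))
    names(sizes) <- c(paste(g_lab[1L], g_lab[2L], sep = "/"), g_lab[3L])
    usable <- all(sizes > 0L)
  } else {
    ind <- as.numeric(mac >= 1L)
    cols <- stats::setNames(data.frame(ind),
                            paste(g_lab[2L], g_lab[3L], sep = "/"))
    sizes <- c(sum(mac == 0L, na.rm = TRUE), sum(mac >= 1L, na.rm = TRUE))
    names(sizes) <- c(g_lab[1L], paste(g_lab[2L], g_lab[3L], sep = "/"))
    usable <- all(sizes > 0L)
  }
  structure(list(snp_id = snp, scheme = scheme, data = cols,
                 group_sizes = sizes, usable = usable),
            class = "genetic_coding")
}

#' Per-SNP Cox association table under the three genetic codings
#'
#' Univariate Cox fits for every panel SNP under additive, dominant and
#' recessive codings, with a Bonferroni significance flag at
#' `0.05 / family_size`.
#'
#' @param gm A [genotype_matrix()].
#' @param outcome A [survival_outcome()] aligned with `gm`.
#' @param family_size Number of tests in the Bonferroni family; defaults to
#'   the panel size.
#' @return Data frame: snp_id, gene, scheme, term, group sizes, HR, p,
#'   95% CI, Bonferroni threshold and flag; unusable codings are reported
#'   with NA estimates.
#' @export
snp_cox_table <- function(gm, outcome, family_size = nrow(gm$panel)) {
  stopifnot(inherits(gm, "genotype_matrix"))
  thr <- 0.05 / family_size
  rows <- list()
  for (snp in gm$panel$snp_id) {
    gene <- gm$panel$gene[match(snp, gm$panel$snp_id)]
    for (scheme in c("additive", "dominant", "recessive")) {
      enc <- encode_genotype(gm, snp, scheme)
      keep <- stats::complete.cases(enc$data)
      if (!enc$usable) {
        rows[[length(rows) + 1L]] <- data.frame(
          snp_id = snp, gene = gene, scheme = scheme, term = NA_character_,
          groups = paste(names(enc$group_sizes), enc$group_sizes,
                         sep = "=", collapse = "; "),
          hr = NA_real_, p = NA_real_, lower = NA_real_, upper = NA_real_,
          bonferroni_threshold = thr, significant = NA,
          stringsAsFactors = FALSE)
        next
      }
      cf <- cox_fit(outcome[keep, , drop = FALSE],
                    enc$data[keep, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = snp, gene = gene, scheme = scheme, term = cf$table$term,
        groups = paste(names(enc$group_sizes), enc$group_sizes,
                       sep = "=", collapse = "; "),
        hr = cf$table$hr, p = cf$table$p, lower = cf$table$lower,
        upper = cf$table$upper, bonferroni_threshold = thr,
        significant = cf$table$p < thr, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' IPCW Brier score curve and Integrated Brier Score
#'
#' Graf-style inverse-probability-of-censoring-weighted Brier score:
#' \deqn{BS(t) = n^{-1} \sum_i [ 1\{T_i \le t, \delta_i = 1\}
#'   S_i(t)^2 / G(T_i^-) + 1\{T_i > t\} (1 - S_i(t))^2 / G(t) ]}
#' with censoring survival \eqn{G} estimated by Kaplan-Meier on the
#' *training* outcome only. The integration bound \eqn{\tau} is the largest
#' training event time with positive censoring survival; the IBS is the
#' trapezoid integral of BS over 0 and the unique test event times up to
#' \eqn{\tau}, divided by \eqn{\tau}.
#'
#' @param train_outcome A [survival_outcome()] supplying the censoring
#'   distribution and \eqn{\tau}.
#' @param test_outcome A [survival_outcome()] to score.
#' @param predicted_survival Function `f(times)` returning a matrix of
#'   predicted survival probabilities, one row per test subject and one
#'   column per requested time.
#' @return A `brier_curve`: evaluation times, BS(t), `tau`, scalar `ibs`.
#' @export
brier_ibs <- function(train_outcome, test_outcome, predicted_survival) {
  stopifnot(inherits(train_outcome, "survival_outcome"),
            inherits(test_outcome, "survival_outcome"))
  G <- .km_fit(train_outcome$time, 1 - train_outcome$event)
  ev <- sort(unique(train_outcome$time[train_outcome$event == 1]))
  if (length(ev) == 0L) stop("no events in training outcome: tau undefined")
  g_at_ev <- .step_eval(ev, G$time, G$surv)
  if (!any(g_at_ev > 0)) stop("censoring survival vanishes before any event")
  tau <- max(ev[g_at_ev > 0])
  grid <- sort(unique(c(0, test_outcome$time[test_outcome$event == 1 &
                                               test_outcome$time <= tau], tau)))
  s_mat <- predicted_survival(grid)
  s_mat <- matrix(s_mat, nrow = nrow(test_outcome), ncol = length(grid))
  bs <- .brier_at(test_outcome$time, test_outcome$event, s_mat, grid, G)
  ibs <- .trapz(grid, bs) / tau
  structure(list(times = grid, bs = bs, tau = tau, ibs = ibs),
            class = "brier_curve")
}

# BS(t) over a grid. s_mat: n x length(grid) predictions; G: censoring KM.
.brier_at <- function(time, event, s_mat, grid, G) {
  g_grid <- .step_eval(grid, G$time, G$surv)
  g_left <- .step_eval(time, G$time, G$surv, left = TRUE)
  w_event <- ifelse(event == 1 & g_left > 0, 1 / g_left, 0)
  died <- outer(time, grid, `<=`) & (event == 1)
  alive <- outer(time, grid, `>`)
  n <- length(time)
  term1 <- colSums(died * s_mat^2 * w_event)
  term2 <- colSums(alive * (1 - s_mat)^2)
  term2 <- ifelse(g_grid > 0, term2 / g_grid, 0)
  (term1 + term2) / n
}

.trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

#' @export
print.brier_curve <- function(x, ...) {
  cat(sprintf("IPCW Brier curve: %d evaluation times, tau = %s, IBS = %.4f\n",
              length(x$times), format(x$tau), x$ibs))
  invisible(x)
}
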