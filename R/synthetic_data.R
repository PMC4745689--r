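# Synthetic cohort generation: Hardy-Weinberg genotypes at configurable
# minor-allele frequencies, a planted genotype-profile map, and
# right-censored survival with a configurable profile hazard ratio.

#' Configuration for a synthetic cohort
#'
#' Defaults emulate the study conditions: n = 100 subjects, the six-SNP
#' panel at its published minor-allele frequencies in Hardy-Weinberg
#' equilibrium, a planted 4-way profile over rs2071559, rs11133360,
#' rs3751143 and rs208294 (threshold rule: any minor-allele homozygote among
#' the planted SNPs is unfavorable), exponential baseline survival with a
#' 65.65-month unfavorable median, favorable hazard ratio 0.29, and
#' censoring from an administrative follow-up horizon plus a uniform dropout
#' fraction calibrated so that over 80% of subjects die on study.
#'
#' @param n Number of subjects.
#' @param panel A [snp_panel()]; defaults to the six-SNP study panel.
#' @param mafs Minor-allele frequencies per panel SNP.
#' @param planted_subset SNP ids carrying the planted interaction.
#' @param profile_map Optional named character vector mapping cell keys
#'   (genotypes joined by "/", major-allele-first, in `planted_subset`
#'   order) to `"favorable"`/`"unfavorable"`; cells not in the map fall back
#'   to the threshold rule.
#' @param risk_threshold Minimum count of minor-homozygous planted loci that
#'   makes a subject unfavorable (default 1).
#' @param baseline `"exponential"` or `"weibull"`.
#' @param weibull_shape Shape parameter when `baseline = "weibull"`.
#' @param median_unfavorable Unfavorable-group median survival, months.
#' @param hr_favorable Favorable-vs-unfavorable hazard ratio.
#' @param admin_horizon Administrative censoring time, months.
#' @param dropout_fraction Fraction of subjects with an additional uniform
#'   dropout time on (0, admin_horizon).
#' @param ld_pairs Optional list of `list(snps = c(id, id), r2 = value)`
#'   entries inducing linkage disequilibrium within a SNP pair.
#' @param gleason_shift Added probability of high Gleason in the unfavorable
#'   group (confounding knob; 0 = covariates independent of profile).
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n = 100L,
                             panel = attr(study_snp_table(), "panel"),
                             mafs = c(0.46, 0.06, 0.16, 0.45, 0.25, 0.47),
                             planted_subset = c("rs2071559", "rs11133360",
                                                "rs3751143", "rs208294"),
                             profile_map = NULL,
                             risk_threshold = 1L,
                             baseline = c("exponential", "weibull"),
                             weibull_shape = 1,
                             median_unfavorable = 65.65,
                             hr_favorable = 0.29,
                             admin_horizon = 420,
                             dropout_fraction = 0.05,
                             ld_pairs = NULL,
                             gleason_shift = 0,
                             seed = 1L) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(panel, "snp_panel"))
  if (length(mafs) != nrow(panel)) stop("one MAF per panel SNP required")
  if (any(!is.finite(mafs) | mafs <= 0 | mafs > 0.5)) {
    stop("MAFs must lie in (0, 0.5]")
  }
  if (hr_favorable <= 0) stop("hazard ratio must be positive")
  if (median_unfavorable <= 0) stop("median must be positive")
  if (!all(planted_subset %in% panel$snp_id)) {
    stop("planted subset not in panel")
  }
  structure(list(n = as.integer(n), panel = panel,
                 mafs = stats::setNames(mafs, panel$snp_id),
                 planted_subset = planted_subset,
                 profile_map = profile_map,
                 risk_threshold = as.integer(risk_threshold),
                 baseline = baseline, weibull_shape = weibull_shape,
                 median_unfavorable = median_unfavorable,
                 hr_favorable = hr_favorable,
                 admin_horizon = admin_horizon,
                 dropout_fraction = dropout_fraction,
                 ld_pairs = ld_pairs, gleason_shift = gleason_shift,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate Hardy-Weinberg genotypes
#'
#' SNPs are independent by default (any configured LD pairs are drawn from
#' two-locus haplotype frequencies with the requested r-squared); genotype
#' probabilities are `p^2, 2pq, q^2` at each SNP's minor-allele frequency.
#'
#' @param config A [synthetic_config()].
#' @return A [genotype_matrix()].
#' @export
gen_genotypes <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n; panel <- config$panel
  mac <- matrix(NA_integer_, n, nrow(panel))
  .with_seed(config$seed, {
    ld_snps <- character(0)
    for (pair in config$ld_pairs %||% list()) {
      j <- match(pair$snps, panel$snp_id)
      mac[, j] <- .gen_ld_pair(n, config$mafs[j[1L]], config$mafs[j[2L]],
                               pair$r2)
      ld_snps <- c(ld_snps, pair$snps)
    }
    for (j in which(!panel$snp_id %in% ld_snps)) {
      q <- config$mafs[j]; p <- 1 - q
      mac[, j] <- sample(0:2, n, replace = TRUE,
                         prob = c(p^2, 2 * p * q, q^2))
    }
  })
  .mac_to_gm(mac, panel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.mac_to_gm <- function(mac, panel) {
  n <- nrow(mac)
  calls <- matrix(NA_character_, n, nrow(panel))
  for (j in seq_len(nrow(panel))) {
    geno <- c(paste0(panel$allele_major[j], panel$allele_major[j]),
              paste0(panel$allele_major[j], panel$allele_minor[j]),
              paste0(panel$allele_minor[j], panel$allele_minor[j]))
    calls[, j] <- geno[mac[, j] + 1L]
  }
  dimnames(calls) <- list(sprintf("S%04d", seq_len(n)), panel$snp_id)
  genotype_matrix(calls, panel = panel)
}

# Draw minor-allele counts for a SNP pair with target r2: haplotype
# frequencies with D = sqrt(r2 * p1 q1 p2 q2), clipped to the feasible D.
.gen_ld_pair <- function(n, q1, q2, r2) {
  p1 <- 1 - q1; p2 <- 1 - q2
  d <- sqrt(r2 * p1 * q1 * p2 * q2)
  d <- min(d, p1 * q2, q1 * p2)  # keep all haplotype frequencies >= 0
  # haplotypes (major,major), (major,minor), (minor,major), (minor,minor)
  f <- c(p1 * p2 + d, p1 * q2 - d, q1 * p2 - d, q1 * q2 + d)
  hap <- matrix(sample.int(4L, 2L * n, replace = TRUE, prob = f), ncol = 2L)
  minor1 <- (hap > 2L)            # haplotypes 3,4 carry SNP1 minor allele
  minor2 <- (hap %% 2L == 0L)     # haplotypes 2,4 carry SNP2 minor allele
  cbind(rowSums(minor1), rowSums(minor2))
}

#' Planted per-subject profile labels
#'
#' Applies the configured cell-to-profile map over the planted SNP subset;
#' cells absent from the map are labeled by the threshold rule (at least
#' `risk_threshold` minor-allele-homozygous planted loci is unfavorable).
#'
#' @param gm A [genotype_matrix()].
#' @param config A [synthetic_config()].
#' @return Character vector of `"favorable"`/`"unfavorable"` labels.
#' @export
plant_profiles <- function(gm, config) {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(config, "synthetic_config"))
  cols <- match(config$planted_subset, gm$panel$snp_id)
  if (anyNA(cols)) stop("planted subset not in panel")
  key <- apply(gm$calls[, cols, drop = FALSE], 1L, paste, collapse = "/")
  lab <- rep(NA_character_, length(key))
  if (!is.null(config$profile_map)) {
    bad <- setdiff(unique(unlist(strsplit(names(config$profile_map), "/"))),
                   unlist(lapply(cols, function(j) {
                     maj <- gm$panel$allele_major[j]
                     mnr <- gm$panel$allele_minor[j]
                     c(paste0(maj, maj), paste0(maj, mnr), paste0(mnr, mnr))
                   })))
    if (length(bad)) stop("profile map references unknown genotypes: ",
                          paste(bad, collapse = ", "))
    lab <- unname(config$profile_map[key])
  }
  mac <- minor_allele_count(gm)[, cols, drop = FALSE]
  fallback <- ifelse(rowSums(mac == 2L) >= config$risk_threshold,
                     "unfavorable", "favorable")
  ifelse(is.na(lab), fallback, lab)
}

#' Generate right-censored survival for planted profiles
#'
#' Unfavorable subjects draw from the baseline distribution with the
#' configured median; favorable subjects have their hazard scaled by the
#' configured ratio, so proportional hazards holds by construction.
#' Censoring is the minimum of the administrative horizon and, for a random
#' dropout fraction, a uniform dropout time. Times are reported at 0.1-month
#' resolution (which induces realistic ties).
#'
#' @param labels Character vector of profile labels.
#' @param config A [synthetic_config()].
#' @param seed_offset Added to `config$seed` so genotype and survival draws
#'   use distinct streams.
#' @return A [survival_outcome()] with clinical covariates, plus attributes
#'   `event_fraction` and `truth` (the label vector).
#' @export
gen_survival <- function(labels, config, seed_offset = 1000L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (anyNA(labels)) stop("labels must be complete")
  n <- length(labels)
  hr <- ifelse(labels == "favorable", config$hr_favorable, 1)
  shape <- if (config$baseline == "exponential") 1 else config$weibull_shape
  scale <- config$median_unfavorable / log(2)^(1 / shape)
  out <- NULL
  .with_seed(config$seed + seed_offset, {
    u <- stats::runif(n)
    t_event <- scale * (-log(u) / hr)^(1 / shape)
    cens <- rep(config$admin_horizon, n)
    drop_out <- stats::runif(n) < config$dropout_fraction
    cens[drop_out] <- pmin(cens[drop_out],
                           stats::runif(sum(drop_out), 0,
                                        config$admin_horizon))
    time <- pmax(round(pmin(t_event, cens), 1), 0.1)
    event <- as.numeric(t_event <= cens)
    covs <- data.frame(
      age = round(stats::rnorm(n, 68, 8)),
      ecog_ps = sample(0:2, n, replace = TRUE, prob = c(0.5, 0.4, 0.1)),
      gleason_high = stats::rbinom(
        n, 1, pmin(1, 0.8 + config$gleason_shift *
                     (labels == "unfavorable"))),
      psa = round(exp(stats::rnorm(n, log(99), 1)), 1),
      mts_sites = sample(1:3, n, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
      therapy = stats::rbinom(n, 1, 0.93))
    out <- survival_outcome(sprintf("S%04d", seq_len(n)), time, event,
                            covariates = covs)
  })
  attr(out, "event_fraction") <- mean(out$event)
  attr(out, "truth") <- labels
  out
}

#' Generate a complete synthetic cohort
#'
#' Composes [gen_genotypes()], [plant_profiles()] and [gen_survival()];
#' optionally writes the canonical TSV fixtures (genotypes, survival,
#' ground-truth labels) and a JSON echo of the configuration.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional directory to write fixture files into.
#' @return A `synthetic_cohort`: list with `gm`, `outcome`, `truth`,
#'   `config` and (when written) `files`.
#' @export
gen_cohort <- function(config, dir = NULL) {
  gm <- gen_genotypes(config)
  truth <- plant_profiles(gm, config)
  outcome <- gen_survival(truth, config)
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(genotypes = file.path(dir, "genotypes.tsv"),
               survival = file.path(dir, "survival.tsv"),
               truth = file.path(dir, "truth.tsv"),
               config = file.path(dir, "config.json"))
    write_genotypes(gm, files[["genotypes"]])
    write_survival(outcome, files[["survival"]])
    utils::write.table(
      data.frame(subject_id = gm$subject_ids, profile = truth),
      files[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
    write_config(config, files[["config"]])
  }
  structure(list(gm = gm, outcome = outcome, truth = truth,
                 config = config, files = files),
            class = "synthetic_cohort")
}

#' Write a synthetic configuration as JSON
#'
#' @param config A [synthetic_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  x <- unclass(config)
  x$panel <- as.data.frame(x$panel)
  jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a synthetic configuration from JSON
#'
#' @param path Path to a JSON file written by [write_config()].
#' @return A [synthetic_config()].
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pnl <- snp_panel(x$panel$snp_id, x$panel$allele_major,
                   x$panel$allele_minor, gene = x$panel$gene,
                   assay_id = x$panel$assay_id)
  pm <- if (is.null(x$profile_map) || length(x$profile_map) == 0) NULL
    else unlist(x$profile_map)
  synthetic_config(
    n = x$n, panel = pnl, mafs = unlist(x$mafs),
    planted_subset = x$planted_subset, profile_map = pm,
    risk_threshold = x$risk_threshold, baseline = x$baseline,
    weibull_shape = x$weibull_shape,
    median_unfavorable = x$median_unfavorable,
    hr_favorable = x$hr_favorable, admin_horizon = x$admin_horizon,
    dropout_fraction = x$dropout_fraction,
    ld_pairs = if (length(x$ld_pairs)) x$ld_pairs else NULL,
    gleason_shift = x$gleason_shift, seed = x$seed)
}
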