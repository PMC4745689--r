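# Population-genetics QC: allele frequencies, Hardy-Weinberg tests, pairwise
# LD and EM haplotype-frequency estimation.

.check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be three non-negative integers ",
         "(hom-major, het, hom-minor)")
  }
  if (sum(counts) == 0) stop("all-zero genotype counts")
  counts
}

#' Major-allele frequency from genotype counts
#'
#' @param counts Numeric vector `c(n_hom_major, n_het, n_hom_minor)`.
#' @return Frequency of the major allele, `(2*hom_major + het) / (2*n)`.
#' @export
allele_frequency <- function(counts) {
  counts <- .check_counts(counts)
  (2 * counts[1L] + counts[2L]) / (2 * sum(counts))
}

#' Exact conditional Hardy-Weinberg test
#'
#' Two-sided exact test conditional on the observed allele counts: all
#' heterozygote counts compatible with the allele totals are enumerated (via
#' the standard probability recurrence) and the p-value is the sum of
#' probabilities of configurations no more probable than the observed one.
#'
#' @param counts Numeric vector `c(n_hom_major, n_het, n_hom_minor)`.
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact <- function(counts) {
  counts <- .check_counts(counts)
  n_het <- counts[2L]
  n_a <- 2 * counts[1L] + counts[2L]  # major allele count
  n_b <- 2 * counts[3L] + counts[2L]
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)  # monomorphic: single configuration
  hets <- seq.int(rare %% 2, rare, by = 2L)
  # unnormalized probabilities by recurrence from the smallest het count:
  # P(h+2)/P(h) = 4 * n_AA(h) * n_BB(h) / ((h+2)*(h+1))
  n <- sum(counts)
  common <- 2 * n - rare
  lp <- numeric(length(hets))
  for (i in seq_along(hets)[-1L]) {
    h <- hets[i - 1L]
    haa <- (rare - h) / 2          # rare-allele homozygotes at h
    hbb <- (common - h) / 2
    lp[i] <- lp[i - 1L] + log(4 * haa * hbb) - log((h + 2) * (h + 1))
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- match(n_het, hets)
  min(1, sum(p[p <= p[obs] * (1 + 1e-10)]))
}

#' Pearson chi-squared Hardy-Weinberg test
#'
#' One-degree-of-freedom goodness-of-fit test of the observed genotype
#' counts against the `p^2, 2pq, q^2` expectations, without continuity
#' correction. A monomorphic SNP returns statistic 0 and p = 1.
#'
#' @param counts Numeric vector `c(n_hom_major, n_het, n_hom_minor)`.
#' @return List with `chi2_stat` and `p_chi2`.
#' @export
hwe_chi2 <- function(counts) {
  counts <- .check_counts(counts)
  n <- sum(counts)
  p <- allele_frequency(counts)
  q <- 1 - p
  if (q == 0 || p == 0) return(list(chi2_stat = 0, p_chi2 = 1))
  expected <- n * c(p^2, 2 * p * q, q^2)
  stat <- sum((counts - expected)^2 / expected)
  list(chi2_stat = stat, p_chi2 = stats::pchisq(stat, df = 1,
                                                lower.tail = FALSE))
}

#' Combined Hardy-Weinberg report for one SNP
#'
#' @param counts Numeric vector `c(n_hom_major, n_het, n_hom_minor)`.
#' @return List with `p_exact`, `chi2_stat`, `p_chi2`.
#' @export
hwe_test <- function(counts) {
  chi <- hwe_chi2(counts)
  list(p_exact = hwe_exact(counts), chi2_stat = chi$chi2_stat,
       p_chi2 = chi$p_chi2)
}

# ---- EM haplotype frequency estimation ------------------------------------

# Enumerate, for each distinct multilocus genotype pattern (vector of minor
# allele counts, 0/1/2 per SNP), the ordered haplotype pairs compatible with
# it. Haplotypes are indexed 1..2^k by their minor-allele bit pattern.
.hap_pairs <- function(g) {
  k <- length(g)
  het <- which(g == 1L)
  base <- sum(ifelse(g == 2L, 2L^(seq_len(k) - 1L), 0L))
  if (length(het) == 0L) {
    return(cbind(a = base + 1L, b = base + 1L))
  }
  m <- length(het)
  combos <- as.matrix(expand.grid(rep(list(c(0L, 1L)), m)))
  bits <- 2L^(het - 1L)
  a <- base + as.integer(combos %*% bits)
  b <- base + as.integer((1L - combos) %*% bits)
  cbind(a = a + 1L, b = b + 1L)
}

#' Haplotype frequency estimation by EM under Hardy-Weinberg
#'
#' Maximum-likelihood haplotype frequencies for a small SNP subset (up to 6
#' SNPs) from unphased genotypes, assuming random union of haplotypes.
#' Subjects with a missing call at any subset SNP are excluded (counted in
#' the result). Haplotypes whose estimated frequency falls below
#' `rare_threshold` are flagged rare.
#'
#' @param gm A [genotype_matrix()].
#' @param snp_subset Character vector of SNP ids in the panel.
#' @param rare_threshold Common-haplotype threshold (default 0.05).
#' @param tol Convergence tolerance on the log-likelihood gain.
#' @param max_iter Iteration cap.
#' @return A `haplotype_freqs` object: named frequency vector (haplotypes as
#'   allele strings in subset order), log-likelihood, iteration count, rare
#'   flags, number of excluded subjects.
#' @export
em_haplotypes <- function(gm, snp_subset, rare_threshold = 0.05,
                          tol = 1e-8, max_iter = 1000L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(snp_subset) == 0L) stop("empty SNP subset")
  if (length(snp_subset) > 6L) stop("subset too large for enumeration (> 6)")
  idx <- match(snp_subset, gm$panel$snp_id)
  if (anyNA(idx)) stop("SNPs not in panel: ",
                       paste(snp_subset[is.na(idx)], collapse = ", "))
  mac <- minor_allele_count(gm)[, idx, drop = FALSE]
  complete <- stats::complete.cases(mac)
  n_excluded <- sum(!complete)
  mac <- mac[complete, , drop = FALSE]
  if (nrow(mac) == 0L) stop("no subjects with complete calls on the subset")
  k <- length(idx)
  n_hap <- 2L^k
  # haplotype labels: allele string in subset order
  bit_mat <- as.matrix(expand.grid(rep(list(0:1), k)))[, seq_len(k),
                                                       drop = FALSE]
  # expand.grid varies the first factor fastest = bit 1 fastest; hap index
  # base-2 with SNP j as bit j matches .hap_pairs
  pnl <- gm$panel[idx, , drop = FALSE]
  hap_labels <- apply(bit_mat, 1L, function(b) {
    paste(ifelse(b == 1L, pnl$allele_minor, pnl$allele_major), collapse = "")
  })
  patterns <- unique(mac)
  pat_key <- apply(mac, 1L, paste, collapse = ",")
  upat_key <- apply(patterns, 1L, paste, collapse = ",")
  pat_n <- as.numeric(table(factor(pat_key, levels = upat_key)))
  pairs <- lapply(seq_len(nrow(patterns)), function(i) {
    .hap_pairs(as.integer(patterns[i, ]))
  })
  # init at linkage equilibrium from observed allele frequencies
  maf <- colMeans(mac) / 2
  f <- apply(bit_mat, 1L, function(b) prod(ifelse(b == 1L, maf, 1 - maf)))
  f <- pmax(f, 1e-12); f <- f / sum(f)
  n <- nrow(mac)
  loglik <- -Inf
  for (iter in seq_len(max_iter)) {
    exp_counts <- numeric(n_hap)
    ll <- 0
    for (i in seq_along(pairs)) {
      pr <- pairs[[i]]
      w <- f[pr[, 1L]] * f[pr[, 2L]]
      tot <- sum(w)
      ll <- ll + pat_n[i] * log(tot)
      post <- w / tot * pat_n[i]
      # accumulate both members of each ordered pair
      for (col in 1:2) {
        tab <- rowsum(post, pr[, col])
        exp_counts[as.integer(rownames(tab))] <-
          exp_counts[as.integer(rownames(tab))] + tab[, 1L]
      }
    }
    f_new <- exp_counts / (2 * n)
    gain <- ll - loglik
    loglik <- ll
    f <- f_new
    if (is.finite(gain) && gain < tol) break
  }
  names(f) <- hap_labels
  structure(list(freq = f, loglik = loglik, n_iter = iter,
                 rare = f < rare_threshold, n_excluded = n_excluded,
                 snp_subset = snp_subset),
            class = "haplotype_freqs")
}

#' @export
print.haplotype_freqs <- function(x, ...) {
  cat("EM haplotype frequencies over", length(x$snp_subset), "SNPs (",
      paste(x$snp_subset, collapse = ", "), ")\n")
  print(round(x$freq[order(-x$freq)], 4))
  cat("log-likelihood:", x$loglik, " iterations:", x$n_iter, "\n")
  invisible(x)
}

#' Per-subject expected haplotype dosages
#'
#' Posterior mean count (0-2) of each haplotype per subject, given EM
#' frequency estimates; the standard surrogate for phased haplotypes in
#' haplotype-survival regression.
#'
#' @param gm A [genotype_matrix()].
#' @param hf A [em_haplotypes()] result.
#' @return Numeric matrix (complete-call subjects x haplotypes); row names
#'   are subject ids.
#' @export
haplotype_dosages <- function(gm, hf) {
  stopifnot(inherits(hf, "haplotype_freqs"))
  idx <- match(hf$snp_subset, gm$panel$snp_id)
  mac <- minor_allele_count(gm)[, idx, drop = FALSE]
  complete <- stats::complete.cases(mac)
  mac <- mac[complete, , drop = FALSE]
  f <- hf$freq
  n_hap <- length(f)
  out <- matrix(0, nrow = nrow(mac), ncol = n_hap,
                dimnames = list(gm$subject_ids[complete], names(f)))
  for (i in seq_len(nrow(mac))) {
    pr <- .hap_pairs(as.integer(mac[i, ]))
    w <- f[pr[, 1L]] * f[pr[, 2L]]
    w <- w / sum(w)
    for (r in seq_len(nrow(pr))) {
      out[i, pr[r, 1L]] <- out[i, pr[r, 1L]] + w[r]
      out[i, pr[r, 2L]] <- out[i, pr[r, 2L]] + w[r]
    }
  }
  out
}

#' Pairwise linkage disequilibrium from unphased genotypes
#'
#' Two-locus haplotype frequencies are estimated by [em_haplotypes()] and
#' summarized as D, D' and r-squared with respect to the major alleles.
#'
#' @param gm A [genotype_matrix()].
#' @param snp_a,snp_b SNP ids in the panel.
#' @return List with `d`, `d_prime`, `r_squared` and a `defined` flag
#'   (FALSE, with NA statistics, when either SNP is monomorphic).
#' @export
ld_pair <- function(gm, snp_a, snp_b) {
  stopifnot(inherits(gm, "genotype_matrix"))
  hf <- em_haplotypes(gm, c(snp_a, snp_b))
  f <- hf$freq
  # haplotype order: (maj,maj), (min,maj), (maj,min), (min,min)
  p_a <- f[1L] + f[3L]   # major allele of snp_a
  p_b <- f[1L] + f[2L]
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1) {
    return(list(d = NA_real_, d_prime = NA_real_, r_squared = NA_real_,
                defined = FALSE))
  }
  d <- f[1L] - p_a * p_b
  d_max <- if (d >= 0) min(p_a * (1 - p_b), (1 - p_a) * p_b) else
    min(p_a * p_b, (1 - p_a) * (1 - p_b))
  d_prime <- if (d_max == 0) 0 else abs(d) / d_max
  r2 <- d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  list(d = unname(d), d_prime = unname(min(d_prime, 1)),
       r_squared = unname(min(r2, 1)), defined = TRUE)
}

#' Population-genetics QC table for a panel
#'
#' One row per SNP: gene, genotype tallies, alleles, major-allele frequency,
#' minor-allele frequency, exact HWE p-value and chi-squared HWE test.
#'
#' @param gm A [genotype_matrix()].
#' @return Data frame in the per-SNP QC report schema.
#' @export
popgen_table <- function(gm) {
  gc <- genotype_counts(gm)
  p <- gm$panel
  res <- lapply(seq_len(nrow(gc)), function(j) {
    cts <- c(gc$n_hom_major[j], gc$n_het[j], gc$n_hom_minor[j])
    h <- hwe_test(cts)
    data.frame(snp_id = p$snp_id[j], gene = p$gene[j],
               allele_major = p$allele_major[j],
               allele_minor = p$allele_minor[j],
               n_hom_major = cts[1L], n_het = cts[2L], n_hom_minor = cts[3L],
               n_missing = gc$n_missing[j],
               freq_major = allele_frequency(cts),
               freq_minor = 1 - allele_frequency(cts),
               hwe_p_exact = h$p_exact, hwe_chi2 = h$chi2_stat,
               hwe_p_chi2 = h$p_chi2, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
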