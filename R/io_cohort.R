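# Cohort input/output: genotype and survival tables, SNP panel metadata,
# report writing.

#' Define a panel of candidate SNPs
#'
#' A panel holds per-SNP metadata: identifier, gene label, optional genotyping
#' assay id and the two alleles. The major allele is the reference level for
#' all genotype codings downstream.
#'
#' @param snp_id Character vector of unique SNP identifiers (e.g. rsIDs).
#' @param allele_major,allele_minor Single-character alleles per SNP. The
#'   minor allele may be `NA` for a monomorphic SNP.
#' @param gene Optional gene labels.
#' @param assay_id Optional genotyping assay identifiers.
#' @return A `snp_panel` data frame with one row per SNP.
#' @export
snp_panel <- function(snp_id, allele_major, allele_minor,
                      gene = NA_character_, assay_id = NA_character_) {
  snp_id <- as.character(snp_id)
  if (anyDuplicated(snp_id)) {
    stop("duplicate snp_id in panel: ",
         paste(unique(snp_id[duplicated(snp_id)]), collapse = ", "))
  }
  allele_major <- toupper(as.character(allele_major))
  allele_minor <- toupper(as.character(allele_minor))
  if (any(nchar(allele_major) != 1L)) stop("allele_major must be single characters")
  if (any(!is.na(allele_minor) & nchar(allele_minor) != 1L)) {
    stop("allele_minor must be single characters or NA")
  }
  same <- !is.na(allele_minor) & allele_major == allele_minor
  if (any(same)) {
    stop("allele_major equals allele_minor for: ",
         paste(snp_id[same], collapse = ", "))
  }
  out <- data.frame(
    snp_id = snp_id,
    gene = rep_len(as.character(gene), length(snp_id)),
    assay_id = rep_len(as.character(assay_id), length(snp_id)),
    allele_major = allele_major,
    allele_minor = allele_minor,
    stringsAsFactors = FALSE
  )
  class(out) <- c("snp_panel", "data.frame")
  out
}

#' Build a genotype matrix from diploid calls
#'
#' Calls are unordered allele pairs such as `"AG"` (`"GA"` is equivalent);
#' they are normalized to major-allele-first. When no panel is supplied the
#' major/minor alleles are inferred from observed allele frequencies, with
#' ties broken toward the lexicographically smaller allele as major.
#'
#' @param calls Character matrix (subjects x SNPs) of two-letter genotype
#'   strings, `NA` for missing. Row names are subject ids, column names SNP
#'   ids (required when `panel` is `NULL`).
#' @param panel Optional [snp_panel()]. Inferred from `calls` when missing.
#' @param subject_ids Optional subject ids overriding `rownames(calls)`.
#' @return A `genotype_matrix` object: list with `subject_ids`, `panel` and
#'   the normalized `calls` matrix.
#' @export
genotype_matrix <- function(calls, panel = NULL, subject_ids = NULL) {
  calls <- as.matrix(calls)
  if (is.null(subject_ids)) subject_ids <- rownames(calls)
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(calls)))
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) {
    stop("duplicate subject_id: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  }
  if (nrow(calls) < 1L || ncol(calls) < 1L) {
    stop("genotype matrix needs at least one subject and one SNP")
  }
  storage.mode(calls) <- "character"
  calls[calls %in% c("", "NA", "./.", ".", "..")] <- NA_character_
  calls <- toupper(calls)
  bad_len <- !is.na(calls) & nchar(calls) != 2L
  if (any(bad_len)) {
    idx <- which(bad_len, arr.ind = TRUE)[1L, ]
    stop(sprintf("malformed genotype '%s' for subject '%s', SNP '%s'",
                 calls[bad_len][1L], subject_ids[idx[1L]],
                 colnames(calls)[idx[2L]]))
  }
  if (is.null(panel)) {
    if (is.null(colnames(calls))) stop("calls must have SNP column names")
    panel <- .infer_panel(calls)
  } else {
    if (!inherits(panel, "snp_panel")) stop("panel must be a snp_panel")
    if (ncol(calls) != nrow(panel)) {
      stop("calls has ", ncol(calls), " columns but panel has ",
           nrow(panel), " SNPs")
    }
    if (!is.null(colnames(calls))) {
      if (!setequal(colnames(calls), panel$snp_id)) {
        stop("calls column names do not match panel snp_ids")
      }
      calls <- calls[, panel$snp_id, drop = FALSE]
    }
  }
  colnames(calls) <- panel$snp_id
  rownames(calls) <- subject_ids
  # validate alleles and normalize to major-first
  for (j in seq_len(ncol(calls))) {
    ok_alleles <- c(panel$allele_major[j], panel$allele_minor[j])
    ok_alleles <- ok_alleles[!is.na(ok_alleles)]
    cj <- calls[, j]
    nz <- !is.na(cj)
    a1 <- substr(cj[nz], 1L, 1L)
    a2 <- substr(cj[nz], 2L, 2L)
    bad <- !(a1 %in% ok_alleles) | !(a2 %in% ok_alleles)
    if (any(bad)) {
      s <- subject_ids[nz][bad][1L]
      stop(sprintf(
        "genotype '%s' uses an allele outside {%s} (subject '%s', SNP '%s')",
        cj[nz][bad][1L], paste(ok_alleles, collapse = ","), s, panel$snp_id[j]))
    }
    n_minor <- (a1 == panel$allele_minor[j] & !is.na(panel$allele_minor[j])) +
      (a2 == panel$allele_minor[j] & !is.na(panel$allele_minor[j]))
    norm <- c(paste0(panel$allele_major[j], panel$allele_major[j]),
              paste0(panel$allele_major[j], panel$allele_minor[j]),
              paste0(panel$allele_minor[j], panel$allele_minor[j]))
    calls[nz, j] <- norm[n_minor + 1L]
  }
  structure(list(subject_ids = subject_ids, panel = panel, calls = calls),
            class = "genotype_matrix")
}

.infer_panel <- function(calls) {
  snp_ids <- colnames(calls)
  maj <- character(ncol(calls))
  mnr <- character(ncol(calls))
  for (j in seq_len(ncol(calls))) {
    cj <- calls[!is.na(calls[, j]), j]
    alle <- c(substr(cj, 1, 1), substr(cj, 2, 2))
    tab <- sort(table(alle), decreasing = TRUE)
    if (length(tab) > 2L) {
      stop("SNP '", snp_ids[j], "' has more than two alleles: ",
           paste(names(tab), collapse = ","))
    }
    if (length(tab) == 2L && tab[1L] == tab[2L]) {
      nm <- sort(names(tab))  # tie: lexicographic smaller allele is major
      maj[j] <- nm[1L]; mnr[j] <- nm[2L]
    } else {
      maj[j] <- names(tab)[1L]
      mnr[j] <- if (length(tab) == 2L) names(tab)[2L] else NA_character_
    }
  }
  snp_panel(snp_ids, maj, mnr)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$subject_ids), "subjects x",
      nrow(x$panel), "SNPs\n")
  cat("SNPs:", paste(x$panel$snp_id, collapse = ", "), "\n")
  n_miss <- sum(is.na(x$calls))
  if (n_miss > 0) cat("missing calls:", n_miss, "\n")
  invisible(x)
}

#' Read a genotype table
#'
#' The canonical dialect is a tab-separated table with a `subject_id` column
#' followed by one column per SNP containing two-letter genotype strings
#' (`"AG"`); missing calls may be empty, `NA`, `.` or `./.`. A thin VCF
#' reader (biallelic sites, GT field, via the vcfR package) is also provided.
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @param panel Optional [snp_panel()] declaring alleles; inferred otherwise.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), panel = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, colClasses = "character",
                            check.names = FALSE, na.strings = c("NA", ""))
    if (!"subject_id" %in% names(df)) stop("missing 'subject_id' column")
    calls <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
    rownames(calls) <- df$subject_id
    genotype_matrix(calls, panel = panel)
  } else {
    .read_genotypes_vcf(path)
  }
}

.read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) != 1L |
    nchar(fix[, "ALT"]) != 1L
  if (any(multi)) {
    stop("non-biallelic (or non-SNP) VCF record at site: ",
         paste(fix[multi, "ID"], collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- t(as.matrix(gt))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  calls <- matrix(NA_character_, nrow = ncol(gt), ncol = nrow(gt),
                  dimnames = list(colnames(gt), fix[, "ID"]))
  for (j in seq_len(nrow(gt))) {
    g <- gt[j, ]
    g <- gsub("|", "/", g, fixed = TRUE)
    n_alt <- ifelse(is.na(g) | g %in% c("./.", "."), NA_integer_,
                    (substr(g, 1, 1) == "1") + (substr(g, 3, 3) == "1"))
    geno <- c(paste0(ref[j], ref[j]), paste0(ref[j], alt[j]),
              paste0(alt[j], alt[j]))
    calls[, j] <- ifelse(is.na(n_alt), NA_character_, geno[n_alt + 1L])
  }
  genotype_matrix(calls)
}

#' Write a genotype matrix to the canonical TSV dialect
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  df <- data.frame(subject_id = gm$subject_ids, gm$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Construct a right-censored survival outcome
#'
#' @param subject_id Subject identifiers.
#' @param time Follow-up time in months, strictly positive and finite.
#' @param event Event indicator: 1 = death, 0 = censored.
#' @param covariates Optional data frame of clinical covariates (age, ECOG
#'   performance status, Gleason group, PSA, metastatic-site count, therapy).
#' @return A `survival_outcome` data frame.
#' @export
survival_outcome <- function(subject_id, time, event, covariates = NULL) {
  subject_id <- as.character(subject_id)
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (anyDuplicated(subject_id)) stop("duplicate subject_id in survival table")
  bad_t <- !is.finite(time) | time <= 0
  if (any(bad_t)) {
    stop("time must be strictly positive and finite (subjects: ",
         paste(subject_id[bad_t], collapse = ", "), ")")
  }
  if (!all(event %in% c(0, 1))) {
    stop("event must be 0 (censored) or 1 (death); offending subjects: ",
         paste(subject_id[!event %in% c(0, 1)], collapse = ", "))
  }
  out <- data.frame(subject_id = subject_id, time = time, event = event,
                    stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    reserved <- intersect(names(covariates), names(out))
    if (length(reserved)) stop("covariate names clash with: ",
                               paste(reserved, collapse = ", "))
    out <- cbind(out, covariates)
  }
  class(out) <- c("survival_outcome", "data.frame")
  out
}

#' Read a survival/covariate table
#'
#' Expects a TSV with `subject_id`, `time_months` and `event` columns;
#' remaining columns are carried as covariates.
#'
#' @param path Path to the TSV file.
#' @return A [survival_outcome()].
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(subject_id = "character"))
  need <- c("subject_id", "time_months", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  covs <- df[, setdiff(names(df), need), drop = FALSE]
  survival_outcome(df$subject_id, df$time_months, df$event,
                   covariates = if (ncol(covs)) covs else NULL)
}

#' Write a survival outcome to TSV
#'
#' @param outcome A [survival_outcome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(outcome, path) {
  stopifnot(inherits(outcome, "survival_outcome"))
  df <- as.data.frame(outcome)
  names(df)[names(df) == "time"] <- "time_months"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Join genotypes with survival outcomes into an aligned cohort
#'
#' Every subject in the survival table must be present in the genotype
#' matrix and vice versa; the outcome is reordered to the genotype matrix's
#' subject order.
#'
#' @param gm A [genotype_matrix()].
#' @param outcome A [survival_outcome()].
#' @return List with aligned `gm` and `outcome` (class `sdr_cohort`).
#' @export
join_cohort <- function(gm, outcome) {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(outcome, "survival_outcome"))
  extra <- setdiff(outcome$subject_id, gm$subject_ids)
  if (length(extra)) {
    stop("subjects in survival table but not in genotypes: ",
         paste(extra, collapse = ", "))
  }
  missing_surv <- setdiff(gm$subject_ids, outcome$subject_id)
  if (length(missing_surv)) {
    stop("subjects in genotypes but not in survival table: ",
         paste(missing_surv, collapse = ", "))
  }
  outcome <- outcome[match(gm$subject_ids, outcome$subject_id), , drop = FALSE]
  rownames(outcome) <- NULL
  class(outcome) <- c("survival_outcome", "data.frame")
  structure(list(gm = gm, outcome = outcome), class = "sdr_cohort")
}

#' Per-SNP genotype tallies
#'
#' @param gm A [genotype_matrix()].
#' @return Data frame with one row per SNP: counts of major homozygotes,
#'   heterozygotes, minor homozygotes and missing calls.
#' @export
genotype_counts <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  p <- gm$panel
  out <- data.frame(snp_id = p$snp_id, n_hom_major = 0L, n_het = 0L,
                    n_hom_minor = 0L, n_missing = 0L,
                    stringsAsFactors = FALSE)
  for (j in seq_len(nrow(p))) {
    cj <- gm$calls[, j]
    hom_major <- paste0(p$allele_major[j], p$allele_major[j])
    het <- paste0(p$allele_major[j], p$allele_minor[j])
    hom_minor <- paste0(p$allele_minor[j], p$allele_minor[j])
    out$n_hom_major[j] <- sum(cj == hom_major, na.rm = TRUE)
    out$n_het[j] <- sum(cj == het, na.rm = TRUE)
    out$n_hom_minor[j] <- sum(cj == hom_minor, na.rm = TRUE)
    out$n_missing[j] <- sum(is.na(cj))
  }
  out
}

#' Minor-allele dosage matrix
#'
#' @param gm A [genotype_matrix()].
#' @return Integer matrix (subjects x SNPs) counting minor alleles (0/1/2),
#'   `NA` for missing calls.
#' @export
minor_allele_count <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  p <- gm$panel
  out <- matrix(NA_integer_, nrow = length(gm$subject_ids), ncol = nrow(p),
                dimnames = list(gm$subject_ids, p$snp_id))
  for (j in seq_len(nrow(p))) {
    cj <- gm$calls[, j]
    mnr <- p$allele_minor[j]
    if (is.na(mnr)) {
      out[!is.na(cj), j] <- 0L
    } else {
      out[, j] <- (substr(cj, 1, 1) == mnr) + (substr(cj, 2, 2) == mnr)
    }
  }
  out
}

#' Expand printed genotype tallies into a deterministic genotype matrix
#'
#' Reconstructs a subject-level genotype matrix whose per-SNP tallies equal
#' the given counts. Subjects are filled SNP by SNP in panel order (all major
#' homozygotes first, then heterozygotes, then minor homozygotes), which
#' preserves marginal counts but carries no multilocus information.
#'
#' @param panel A [snp_panel()].
#' @param counts Data frame with columns `n_hom_major`, `n_het`,
#'   `n_hom_minor`, one row per panel SNP; all rows must sum to the same n.
#' @return A [genotype_matrix()].
#' @export
genotypes_from_counts <- function(panel, counts) {
  stopifnot(inherits(panel, "snp_panel"))
  n <- counts$n_hom_major + counts$n_het + counts$n_hom_minor
  if (length(unique(n)) != 1L) stop("per-SNP counts must sum to a common n")
  n <- n[1L]
  calls <- matrix(NA_character_, nrow = n, ncol = nrow(panel))
  for (j in seq_len(nrow(panel))) {
    geno <- c(paste0(panel$allele_major[j], panel$allele_major[j]),
              paste0(panel$allele_major[j], panel$allele_minor[j]),
              paste0(panel$allele_minor[j], panel$allele_minor[j]))
    calls[, j] <- rep(geno, times = c(counts$n_hom_major[j], counts$n_het[j],
                                      counts$n_hom_minor[j]))
  }
  rownames(calls) <- sprintf("S%03d", seq_len(n))
  colnames(calls) <- panel$snp_id
  genotype_matrix(calls, panel = panel)
}

#' The six-SNP VEGFR-2 / P2X7R study panel with published genotype tallies
#'
#' Candidate panel of four VEGFR-2 and two P2X7R polymorphisms genotyped in
#' a 100-patient metastatic prostate cancer cohort, with the published
#' per-SNP genotype counts. These printed tallies are the only subject-level
#' genotype information available; [genotypes_from_counts()] expands them
#' into a marginal-count-faithful genotype matrix.
#'
#' @return Data frame with panel metadata and genotype counts; the panel
#'   itself is available through `attr(, "panel")` or [snp_panel()] on the
#'   allele columns.
#' @export
study_snp_table <- function() {
  out <- data.frame(
    snp_id = c("rs2071559", "rs2305948", "rs1870377",
               "rs11133360", "rs3751143", "rs208294"),
    gene = c("VEGFR-2", "VEGFR-2", "VEGFR-2", "VEGFR-2", "P2X7R", "P2X7R"),
    assay_id = c("C__15869271_10", "C__22271999_20", "C__11895315_20",
                 "C__26111278_10", "C__27495274_10", "C___3019032_1_"),
    allele_major = c("A", "C", "T", "T", "A", "C"),
    allele_minor = c("G", "T", "A", "C", "C", "T"),
    n_hom_major = c(29L, 89L, 72L, 30L, 60L, 29L),
    n_het = c(49L, 10L, 25L, 50L, 30L, 48L),
    n_hom_minor = c(22L, 1L, 3L, 20L, 10L, 23L),
    stringsAsFactors = FALSE
  )
  attr(out, "panel") <- snp_panel(out$snp_id, out$allele_major,
                                  out$allele_minor, gene = out$gene,
                                  assay_id = out$assay_id)
  out
}

#' Write a bundle of report tables as TSV + JSON twins
#'
#' Every table in the bundle is written twice, as `<name>.tsv` and
#' `<name>.json`, with deterministic file names and byte-stable content for
#' a fixed input.
#'
#' @param bundle Named list of data frames (class `report_bundle` or plain
#'   list).
#' @param outdir Output directory, created if needed.
#' @return Data frame manifest (name, tsv, json paths), invisibly the same
#'   manifest is written as `manifest.json` when the bundle is non-empty.
#' @export
write_reports <- function(bundle, outdir) {
  if (!is.list(bundle)) stop("bundle must be a named list of data frames")
  nm <- names(bundle)
  if (length(bundle) && (is.null(nm) || any(nm == ""))) {
    stop("all bundle tables must be named")
  }
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create directory: ", outdir)
  }
  manifest <- data.frame(name = character(), tsv = character(),
                         json = character(), stringsAsFactors = FALSE)
  for (name in nm) {
    tab <- as.data.frame(bundle[[name]])
    tsv <- file.path(outdir, paste0(name, ".tsv"))
    jsn <- file.path(outdir, paste0(name, ".json"))
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    jsonlite::write_json(tab, jsn, dataframe = "rows", na = "null",
                         digits = NA, pretty = TRUE)
    manifest <- rbind(manifest,
                      data.frame(name = name, tsv = tsv, json = jsn,
                                 stringsAsFactors = FALSE))
  }
  if (nrow(manifest)) {
    rel <- transform(manifest, tsv = basename(tsv), json = basename(json))
    jsonlite::write_json(rel, file.path(outdir, "manifest.json"),
                         dataframe = "rows", pretty = TRUE)
  }
  manifest
}
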