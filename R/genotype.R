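#' Hardy-Weinberg chi-square test from genotype counts
#'
#' Expected counts from the observed allele frequencies; 1-df chi-square.
#' Monomorphic SNPs get p = 1 by convention.
#'
#' @param counts length-3 vector (n_AA, n_Aa, n_aa) with A the major allele,
#'   or a genotype vector in {0, 1, 2} (NAs dropped).
#' @return list with `chi2` and `p`.
#' @export
hwe_chisq <- function(counts) {
  if (length(counts) != 3L) {
    g <- counts[!is.na(counts)]
    counts <- c(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }
  n <- sum(counts)
  stopifnot(n >= 1L)
  q <- (counts[2L] + 2 * counts[3L]) / (2 * n)     # minor allele frequency
  if (q <= 0 || q >= 1) return(list(chi2 = 0, p = 1))
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Quality-control filter for SNPs
#'
#' Excludes SNPs with missingness above `missing_thresh`, minor allele
#' frequency below `maf_thresh` (set `literal_maf_rule = TRUE` for the
#' literal "MAF > threshold" exclusion), or Hardy-Weinberg deviation at
#' `hwe_alpha` (1-df chi-square).
#'
#' @param genotypes subjects x SNP integer matrix ({0,1,2}, NA for missing).
#' @param missing_thresh,maf_thresh,hwe_alpha thresholds (0.10 / 0.05 / 0.05).
#' @param literal_maf_rule invert the MAF rule (exclude common instead of
#'   rare variants).
#' @return list with `genotypes` (retained columns) and `exclusions` data
#'   frame (`snp_id`, `reason`); errors if nothing survives.
#' @export
qc_filter_snps <- function(genotypes, missing_thresh = 0.10,
                           maf_thresh = 0.05, hwe_alpha = 0.05,
                           literal_maf_rule = FALSE) {
  snps <- colnames(genotypes)
  excl <- list()
  keep <- logical(length(snps))
  for (j in seq_along(snps)) {
    g <- genotypes[, j]
    miss <- mean(is.na(g))
    gg <- g[!is.na(g)]
    af <- mean(gg) / 2
    maf <- min(af, 1 - af)
    hwe <- hwe_chisq(gg)
    reason <- NULL
    if (miss > missing_thresh) {
      reason <- "missingness"
    } else if (if (literal_maf_rule) maf > maf_thresh else maf < maf_thresh) {
      reason <- "maf"
    } else if (hwe$p < hwe_alpha) {
      reason <- "hwe"
    }
    if (is.null(reason)) keep[j] <- TRUE
    else excl[[snps[j]]] <- reason
  }
  if (!any(keep)) stop("all SNPs excluded by QC")
  list(
    genotypes = genotypes[, keep, drop = FALSE],
    exclusions = data.frame(
      snp_id = names(excl),
      reason = unlist(excl, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  )
}

#' Select convergent candidate genes for genotype validation
#'
#' A gene qualifies when (i) its bootstrap-Z loading weight lies in the top
#' or bottom decile of the ranked list, (ii) it appears in the postmortem
#' differential-expression table, (iii) at least one eQTL SNP targets it, and
#' the three directions agree: top decile ("up") or bottom decile ("down")
#' matched to the DEX direction and the eQTL direction.
#'
#' @param ranked a `ranked_gene_list` (from [bootstrap_loadings()]) or a data
#'   frame with `gene_id` and `z`.
#' @param dex_table data frame `gene_id`, `direction` ("up"/"down").
#' @param eqtl_table data frame `snp_id`, `gene_id`, `direction`
#'   ("up"/"down": effect of the risk allele on expression).
#' @param decile_thresh extreme-decile fraction, default 0.10.
#' @return data frame `gene_id`, `tail` ("up"/"down"), plus a `snps`
#'   attribute mapping genes to their supporting SNPs; zero rows is a valid
#'   result.
#' @export
select_convergent_genes <- function(ranked, dex_table, eqtl_table,
                                    decile_thresh = 0.10) {
  stopifnot(nrow(dex_table) > 0L, nrow(eqtl_table) > 0L)
  r <- as_ranked(ranked)
  G <- nrow(r)
  k <- ceiling(decile_thresh * G)
  tail_dir <- rep(NA_character_, G)
  tail_dir[seq_len(k)] <- "up"
  tail_dir[(G - k + 1L):G] <- "down"
  cand <- data.frame(gene_id = r$gene_id, tail = tail_dir,
                     stringsAsFactors = FALSE)
  cand <- cand[!is.na(cand$tail), , drop = FALSE]
  m <- match(cand$gene_id, dex_table$gene_id)
  cand$dex <- dex_table$direction[m]
  cand <- cand[!is.na(cand$dex) & cand$dex == cand$tail, , drop = FALSE]
  hits <- merge(cand, eqtl_table, by = "gene_id")
  hits <- hits[hits$direction == hits$tail, , drop = FALSE]
  out <- unique(hits[, c("gene_id", "tail")])
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "snps") <- split(hits$snp_id, hits$gene_id)
  out
}

#' Additive risk-allele score
#'
#' Integer sum of risk-allele counts over the given SNPs; subjects with any
#' missing scored genotype are excluded (complete-case) unless
#' `impute_mean = TRUE`, which substitutes the SNP mean count.
#'
#' @param genotypes subjects x SNP matrix (risk-allele counts).
#' @param snp_ids SNPs entering the score (must be columns of `genotypes`).
#' @param impute_mean mean-impute missing genotypes instead of dropping
#'   subjects.
#' @return named numeric vector of scores over retained subjects.
#' @export
risk_allele_score <- function(genotypes, snp_ids, impute_mean = FALSE) {
  stopifnot(all(snp_ids %in% colnames(genotypes)))
  g <- genotypes[, snp_ids, drop = FALSE]
  if (impute_mean) {
    for (j in seq_len(ncol(g))) {
      g[is.na(g[, j]), j] <- mean(g[, j], na.rm = TRUE)
    }
  } else {
    g <- g[stats::complete.cases(g), , drop = FALSE]
  }
  rowSums(g)
}

#' Sex-stratified association of a risk-allele score with an rsFC feature
#'
#' Ordinary least squares of the feature on the score with age as a
#' covariate, within the requested sex stratum; reports the score
#' coefficient's estimate, t and two-sided p.
#'
#' @param scores named per-subject scores (names = subject ids).
#' @param dataset a `connectivity_dataset`.
#' @param feature feature name, or a numeric vector named by subject id.
#' @param sex "M" or "F".
#' @return list with `beta`, `t`, `p`, `n`.
#' @export
score_fc_association <- function(scores, dataset, feature, sex) {
  meta <- dataset$meta
  ids <- intersect(names(scores), meta$subject_id[meta$sex == sex])
  if (length(ids) < 10L) stop("fewer than 10 scored subjects in stratum")
  y <- if (is.character(feature)) {
    dataset$features[ids, feature]
  } else {
    feature[ids]
  }
  s <- scores[ids]
  if (stats::var(s) <= 0) stop("score has zero variance in stratum")
  age <- meta$age[match(ids, meta$subject_id)]
  fit <- stats::lm(y ~ s + age)
  if (any(is.na(stats::coef(fit)))) stop("collinear design")
  sm <- summary(fit)$coefficients
  list(beta = sm["s", "Estimate"], t = sm["s", "t value"],
       p = sm["s", "Pr(>|t|)"], n = length(ids))
}
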