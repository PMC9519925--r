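#' Compute Fisher-z rsFC features from region time series
#'
#' Pearson correlation between every (seed, target) pair followed by the
#' Fisher z-transform `atanh(r)`; |r| = 1 is clipped to 1 - 1e-12 before
#' atanh. Constant series yield missing features with a warning.
#'
#' @param time_series list (one per subject) of region x time matrices with
#'   region rownames, or a single matrix.
#' @param seed_set,target_set region names.
#' @param meta optional subject metadata data frame (`subject_id`, `sex`,
#'   `diagnosis`, `site`, `age`).
#' @return a `connectivity_dataset` (metadata filled with NAs if not given).
#' @export
compute_rsfc <- function(time_series, seed_set, target_set, meta = NULL) {
  if (is.matrix(time_series)) time_series <- list(time_series)
  fi <- make_feature_index(seed_set, target_set)
  feats <- t(vapply(time_series, function(ts) {
    if (ncol(ts) < 3L) stop("need >= 3 time points")
    use <- unique(c(seed_set, target_set))
    x <- ts[use, , drop = FALSE]
    const <- apply(x, 1L, stats::sd) < 1e-15
    if (any(const)) warning("constant time series: ",
                            paste(use[const], collapse = ", "))
    r <- suppressWarnings(stats::cor(t(x)))
    z <- fisher_z(r)
    z[cbind(fi$seed, fi$target)]
  }, numeric(nrow(fi))))
  if (length(time_series) == 1L) feats <- matrix(feats, nrow = 1L)
  if (is.null(meta)) {
    meta <- data.frame(subject_id = sprintf("sub%05d", seq_along(time_series)),
                       sex = NA_character_, diagnosis = NA_character_,
                       site = NA_character_, age = NA_real_,
                       stringsAsFactors = FALSE)
  }
  new_connectivity_dataset(feats, meta, fi)
}

## RSS of each column of Y under the OLS fit on design X, via the QR thin Q.
rss_cols <- function(Y, X) {
  Q <- qr.Q(qr(X))
  colSums(Y^2) - colSums((crossprod(Q, Y))^2)
}

#' Two-way factorial ANOVA per rsFC feature
#'
#' Per feature, a 2 x 2 factorial ANOVA on sex and diagnosis (Type II sums of
#' squares: each main effect adjusted for the other, the interaction adjusted
#' for both; identical to the classic balanced decomposition when cells are
#' balanced), with Benjamini-Hochberg q-values per term across features.
#'
#' @param dataset a `connectivity_dataset`; all four sex x diagnosis cells
#'   must be nonempty.
#' @return data frame per feature: `F_sex`, `F_mdd`, `F_interaction`, their
#'   p-values and BH q-values.
#' @export
factorial_anova <- function(dataset) {
  meta <- dataset$meta
  sex <- as.numeric(meta$sex == "M")
  mdd <- as.numeric(meta$diagnosis == "MDD")
  if (length(unique(paste(sex, mdd))) < 4L) stop("empty sex x diagnosis cell")
  Y <- dataset$features
  n <- nrow(Y)
  one <- rep(1, n)
  X_full <- cbind(one, sex, mdd, sex * mdd)
  rss_full <- rss_cols(Y, X_full)
  df_err <- n - 4L
  Fp <- function(rss_reduced, rss_nested) {
    Fv <- (rss_reduced - rss_nested) / (rss_full / df_err)
    Fv[Fv < 0] <- 0
    list(F = Fv, p = stats::pf(Fv, 1L, df_err, lower.tail = FALSE))
  }
  rss_add <- rss_cols(Y, cbind(one, sex, mdd))
  a_sex <- Fp(rss_cols(Y, cbind(one, mdd)), rss_add)   # sex | mdd
  a_mdd <- Fp(rss_cols(Y, cbind(one, sex)), rss_add)   # mdd | sex
  a_int <- Fp(rss_add, rss_full)                       # interaction | both
  data.frame(
    feature = dataset$feature_info$feature,
    F_sex = a_sex$F, p_sex = a_sex$p, q_sex = stats::p.adjust(a_sex$p, "BH"),
    F_mdd = a_mdd$F, p_mdd = a_mdd$p, q_mdd = stats::p.adjust(a_mdd$p, "BH"),
    F_interaction = a_int$F, p_interaction = a_int$p,
    q_interaction = stats::p.adjust(a_int$p, "BH"),
    stringsAsFactors = FALSE
  )
}

## Vectorized pooled-variance two-sample t over the columns of Y.
## Positive t = higher mean in group a (MDD).
pooled_t_cols <- function(Ya, Yb) {
  na <- nrow(Ya); nb <- nrow(Yb)
  if (na < 2L || nb < 2L) stop("group size < 2")
  ma <- colMeans(Ya); mb <- colMeans(Yb)
  va <- colSums(sweep(Ya, 2L, ma)^2)
  vb <- colSums(sweep(Yb, 2L, mb)^2)
  sp2 <- (va + vb) / (na + nb - 2L)
  t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(abs(t), na + nb - 2L, lower.tail = FALSE)
  data.frame(t = t, p = p)
}

#' Sex-stratified post-hoc MDD-vs-HC t-maps
#'
#' Within each sex stratum, a pooled-variance two-sample t per feature.
#' Positive t denotes increased rsFC in MDD.
#'
#' @param dataset a `connectivity_dataset`.
#' @param welch use Welch (unequal-variance) t instead of pooled (default
#'   pooled, matching classic post-hoc ANOVA contrasts).
#' @return list with data frames `male` and `female` (`feature`, `t`, `p`,
#'   `q`).
#' @export
posthoc_contrasts <- function(dataset, welch = FALSE) {
  out <- lapply(c(M = "M", F = "F"), function(sx) {
    sel <- dataset$meta$sex == sx
    mdd <- sel & dataset$meta$diagnosis == "MDD"
    hc <- sel & dataset$meta$diagnosis == "HC"
    if (sum(mdd) < 2L || sum(hc) < 2L) stop("stratum group size < 2")
    tp <- if (welch) {
      welch_t_cols(dataset$features[mdd, , drop = FALSE],
                   dataset$features[hc, , drop = FALSE])
    } else {
      pooled_t_cols(dataset$features[mdd, , drop = FALSE],
                    dataset$features[hc, , drop = FALSE])
    }
    data.frame(feature = dataset$feature_info$feature, t = tp$t, p = tp$p,
               q = stats::p.adjust(tp$p, "BH"), stringsAsFactors = FALSE)
  })
  list(male = out$M, female = out$F)
}

welch_t_cols <- function(Ya, Yb) {
  na <- nrow(Ya); nb <- nrow(Yb)
  ma <- colMeans(Ya); mb <- colMeans(Yb)
  va <- colSums(sweep(Ya, 2L, ma)^2) / (na - 1L)
  vb <- colSums(sweep(Yb, 2L, mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  data.frame(t = t, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR
#'
#' Step-up BH q-values and the rejection mask at `q_level`.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param q_level FDR level, default 0.05.
#' @return list with `q_values` and `reject`.
#' @export
bh_fdr <- function(p_values, q_level = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, reject = !is.na(q) & q < q_level)
}

#' Classify features as sex-specific or shared
#'
#' At an unadjusted threshold `alpha`, a feature is shared if significant in
#' both sex-stratified contrasts and sex-specific if significant in exactly
#' one.
#'
#' @param t_male,t_female data frames with columns `feature`, `p` (as from
#'   [posthoc_contrasts()]).
#' @param alpha unadjusted p threshold, default 0.05.
#' @return list with `labels` (per-feature factor) and `counts`.
#' @export
classify_shared_specific <- function(t_male, t_female, alpha = 0.05) {
  stopifnot(identical(t_male$feature, t_female$feature))
  sm <- t_male$p < alpha
  sf <- t_female$p < alpha
  lab <- ifelse(sm & sf, "shared",
         ifelse(sm, "male-specific",
         ifelse(sf, "female-specific", "none")))
  labels <- factor(lab, levels = c("male-specific", "female-specific",
                                   "shared", "none"))
  list(labels = stats::setNames(labels, t_male$feature),
       counts = table(labels)[c("male-specific", "female-specific", "shared")])
}

#' Sex-label permutation test for the count of sex-specific effects
#'
#' Permutes sex labels over the full sample, recomputes the sex-stratified
#' MDD-vs-HC contrasts and the sex-specific counts per permutation, and
#' returns one-sided permutation p-values (+1 correction) for the observed
#' male-specific and female-specific counts.
#'
#' @param dataset a `connectivity_dataset`.
#' @param features optional feature-name subset (e.g. one seed's block).
#' @param n_perm number of permutations (>= 100), default 1000.
#' @param alpha unadjusted significance threshold.
#' @param seed integer seed.
#' @return list with observed `counts`, `p_male`, `p_female`, and the null
#'   count matrix.
#' @export
sex_specificity_permutation <- function(dataset, features = NULL,
                                        n_perm = 1000L, alpha = 0.05,
                                        seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  Y <- dataset$features
  if (!is.null(features)) Y <- Y[, features, drop = FALSE]
  mdd <- dataset$meta$diagnosis == "MDD"
  sex <- dataset$meta$sex
  count_specific <- function(sx) {
    tm <- pooled_t_cols(Y[sx == "M" & mdd, , drop = FALSE],
                        Y[sx == "M" & !mdd, , drop = FALSE])
    tf <- pooled_t_cols(Y[sx == "F" & mdd, , drop = FALSE],
                        Y[sx == "F" & !mdd, , drop = FALSE])
    sm <- tm$p < alpha; sf <- tf$p < alpha
    c(male = sum(sm & !sf), female = sum(sf & !sm))
  }
  obs <- count_specific(sex)
  null_counts <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(k) count_specific(sample(sex)),
             numeric(2L)))
  })
  list(counts = obs,
       p_male = perm_pvalue(null_counts[, "male"], obs["male"]),
       p_female = perm_pvalue(null_counts[, "female"], obs["female"]),
       null_counts = null_counts)
}

#' Seed-based depression effect map for one sex
#'
#' Per target parcel, the subject-level Fisher-z values are averaged over the
#' seed parcels' features, then contrasted (MDD - HC, pooled-variance t)
#' within the sex stratum, and the resulting t-map is restricted to covered
#' parcels.
#'
#' @param dataset a `connectivity_dataset`.
#' @param seed_parcels parcel ids used as the seed region.
#' @param sex "M" or "F".
#' @param covered_mask optional named logical (or character vector of parcel
#'   ids) restricting the map to expression-covered parcels.
#' @param subjects optional subject_id subset (used by cross-validation).
#' @return an effect-map data frame `parcel_id`, `t`, `p` with attributes
#'   `seed_label` and `sex`.
#' @export
seed_effect_map <- function(dataset, seed_parcels, sex,
                            covered_mask = NULL, subjects = NULL) {
  stopifnot(length(seed_parcels) >= 1L)
  fi <- dataset$feature_info
  use_f <- fi$seed %in% seed_parcels & !(fi$target %in% seed_parcels)
  if (!any(use_f)) stop("no features for the given seed parcels")
  keep <- dataset$meta$sex == sex
  if (!is.null(subjects)) keep <- keep & dataset$meta$subject_id %in% subjects
  meta <- dataset$meta[keep, , drop = FALSE]
  Y <- dataset$features[keep, use_f, drop = FALSE]
  tgt <- fi$target[use_f]
  ## average over seed parcels at Fisher-z level: subjects x targets
  targets <- unique(tgt)
  M <- t(rowsum(t(Y), factor(tgt, levels = targets)) /
           as.vector(table(factor(tgt, levels = targets))))
  mdd <- meta$diagnosis == "MDD"
  if (sum(mdd) < 2L || sum(!mdd) < 2L) stop("stratum group size < 2")
  tp <- pooled_t_cols(M[mdd, , drop = FALSE], M[!mdd, , drop = FALSE])
  em <- data.frame(parcel_id = targets, t = tp$t, p = tp$p,
                   stringsAsFactors = FALSE)
  if (!is.null(covered_mask)) {
    cov_ids <- if (is.logical(covered_mask)) names(covered_mask)[covered_mask]
               else covered_mask
    dropped <- setdiff(cov_ids, em$parcel_id)
    if (length(dropped)) warning(length(dropped),
                                 " covered parcels missing from dataset")
    em <- em[em$parcel_id %in% cov_ids, , drop = FALSE]
    em <- em[order(match(em$parcel_id, cov_ids)), , drop = FALSE]
    rownames(em) <- NULL
  }
  attr(em, "seed_label") <- paste(seed_parcels, collapse = "+")
  attr(em, "sex") <- sex
  em
}
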