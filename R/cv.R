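#' Corrected resampled t-test for cross-validation fold differences
#'
#' The Nadeau-Bengio variance correction for k overlapping train/test
#' resamples: `t = mean(d) / sqrt((1/k + n_test/n_train) * var(d))`, two-sided
#' p on k - 1 degrees of freedom.
#'
#' @param d per-fold differences (real minus null correlation).
#' @param n_train,n_test training and test sample sizes.
#' @param k number of folds, default `length(d)`.
#' @return list with `t` and `p`. Zero variance with zero mean gives t = 0,
#'   p = 1; zero variance with nonzero mean gives a signed Inf sentinel with
#'   a warning.
#' @export
corrected_resampled_ttest <- function(d, n_train, n_test, k = length(d)) {
  stopifnot(k >= 2L, length(d) == k)
  v <- stats::var(d)
  m <- mean(d)
  if (v < 1e-30) {
    if (abs(m) < 1e-30) return(list(t = 0, p = 1))
    warning("zero variance with nonzero mean: t set to signed Inf")
    return(list(t = sign(m) * Inf, p = 0))
  }
  t_stat <- m / sqrt((1 / k + n_test / n_train) * v)
  list(t = t_stat, p = 2 * stats::pt(abs(t_stat), k - 1L, lower.tail = FALSE))
}

#' Omnibus decision over repeated cross-validation p-values
#'
#' Bonferroni-corrects the per-repeat p-values and rejects if any adjusted
#' p-value falls below `alpha`.
#'
#' @param p_values one p-value per CV repeat (typically 10).
#' @param alpha significance level, default 0.05.
#' @return list with `reject`, `adjusted_p`.
#' @export
omnibus_cv_test <- function(p_values, alpha = 0.05) {
  adj <- pmin(length(p_values) * p_values, 1)
  list(reject = min(adj) < alpha, adjusted_p = adj)
}

## Diagnosis-stratified fold assignment for the subjects in `meta`.
stratified_folds <- function(meta, n_folds) {
  fold <- integer(nrow(meta))
  for (g in unique(meta$diagnosis)) {
    idx <- sample(which(meta$diagnosis == g))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Ten-times ten-fold cross-validated reproducibility of a PLS association
#'
#' Within the requested sex stratum, subjects are split into
#' diagnosis-stratified folds. Per fold, the seed effect map is recomputed
#' from the training subjects, the first PLS component is fit on it, and the
#' held-out correlation `rho_ho = Corr(X u_train, Y_test)` is evaluated
#' against the effect map recomputed from the test subjects. A matched null
#' arm permutes diagnosis labels (within the stratum) once per fold
#' evaluation and repeats the computation. Per repeat, the real-minus-null
#' fold differences enter the corrected resampled t-test; the per-repeat
#' p-values are Bonferroni-corrected and combined by the omnibus rule.
#'
#' @param X covered-parcels x genes `expression_matrix` (or matrix).
#' @param dataset a `connectivity_dataset`.
#' @param seed_parcels seed region parcel ids.
#' @param sex "M" or "F".
#' @param n_repeats,n_folds CV design, default 10 x 10.
#' @param seed integer seed.
#' @param max_retries repartition attempts for degenerate folds.
#' @return a `cv_result` list: `rho_real`, `rho_null` (repeats x folds),
#'   `t`, `p`, `adjusted_p` per repeat, `reject` (omnibus).
#' @export
cross_validate <- function(X, dataset, seed_parcels, sex, n_repeats = 10L,
                           n_folds = 10L, seed = 1L, max_retries = 20L) {
  Xm <- if (inherits(X, "expression_matrix")) X$values else X
  covered <- rownames(Xm)
  stratum <- dataset$meta$sex == sex
  meta <- dataset$meta[stratum, , drop = FALSE]
  rho_real <- matrix(NA_real_, n_repeats, n_folds)
  rho_null <- matrix(NA_real_, n_repeats, n_folds)
  t_rep <- numeric(n_repeats)
  p_rep <- numeric(n_repeats)
  fold_rho <- function(ds, meta_s, fold, f) {
    test_ids <- meta_s$subject_id[fold == f]
    train_ids <- meta_s$subject_id[fold != f]
    y_tr <- seed_effect_map(ds, seed_parcels, sex, covered_mask = covered,
                            subjects = train_ids)
    y_te <- seed_effect_map(ds, seed_parcels, sex, covered_mask = covered,
                            subjects = test_ids)
    fit <- fit_pls(Xm, y_tr, n_components = 1L)
    stats::cor(as.numeric(Xm %*% fit$weights[, 1L]),
               align_effect_map(Xm, y_te))
  }
  with_seed(stage_seed(seed, "cv"), {
    for (r in seq_len(n_repeats)) {
      ## find a partition and null-arm label permutation where every fold's
      ## test stratum has >= 2 per diagnosis group in BOTH arms
      for (try in seq_len(max_retries)) {
        fold <- stratified_folds(meta, n_folds)
        dx_null <- sample(meta$diagnosis)
        ok <- all(vapply(seq_len(n_folds), function(f) {
          tb <- table(meta$diagnosis[fold == f])
          tbn <- table(dx_null[fold == f])
          length(tb) == 2L && all(tb >= 2L) &&
            length(tbn) == 2L && all(tbn >= 2L)
        }, logical(1L)))
        if (ok) break
        if (try == max_retries) stop("could not build non-degenerate folds")
      }
      ## null arm: permuted diagnosis labels within the stratum
      ds_null <- dataset
      ds_null$meta$diagnosis[stratum] <- dx_null
      meta_null <- ds_null$meta[stratum, , drop = FALSE]
      for (f in seq_len(n_folds)) {
        rho_real[r, f] <- fold_rho(dataset, meta, fold, f)
        rho_null[r, f] <- fold_rho(ds_null, meta_null, fold, f)
      }
      d <- rho_real[r, ] - rho_null[r, ]
      n_test <- round(nrow(meta) / n_folds)
      res <- corrected_resampled_ttest(d, nrow(meta) - n_test, n_test,
                                       k = n_folds)
      t_rep[r] <- res$t
      p_rep[r] <- res$p
    }
  })
  omn <- omnibus_cv_test(p_rep)
  structure(list(rho_real = rho_real, rho_null = rho_null, t = t_rep,
                 p = p_rep, adjusted_p = omn$adjusted_p,
                 reject = omn$reject, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "cv_result: mean rho_ho = %.3f (null %.3f); omnibus %s (min adj p = %.4g)\n",
    mean(x$rho_real), mean(x$rho_null),
    if (x$reject) "reject" else "fail to reject", min(x$adjusted_p)))
  invisible(x)
}
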