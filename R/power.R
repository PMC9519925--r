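#' Sex-composition bootstrap of case-control contrasts
#'
#' Per iteration and composition, `n_mdd` patients and `n_hc` controls are
#' subsampled without replacement at the target fraction female (applied to
#' both groups); a two-sample t-test is run at every feature of the
#' requested block and at the subject-level mean over the block, with BH-FDR
#' rejections recorded.
#'
#' @param dataset a `connectivity_dataset`.
#' @param features feature-name subset (e.g. the within-DMN block); default
#'   all features.
#' @param n_mdd,n_hc subsample sizes, defaults 140 / 70.
#' @param compositions fraction-female grid, default the seven canonical
#'   fractions 0, 0.2, 1/3, 0.5, 2/3, 0.8, 1.
#' @param n_iter iterations per composition, default 1000.
#' @param q_level FDR level for the per-feature rejections.
#' @param seed integer seed.
#' @return a `composition_sim` list: `mean_t` (iterations x compositions
#'   matrix of the mean-feature t), `rejection_freq` (features x
#'   compositions), `compositions`.
#' @export
sex_composition_bootstrap <- function(dataset, features = NULL, n_mdd = 140L,
                                      n_hc = 70L,
                                      compositions = c(0, 0.2, 1 / 3, 0.5,
                                                       2 / 3, 0.8, 1),
                                      n_iter = 1000L, q_level = 0.05,
                                      seed = 1L) {
  meta <- dataset$meta
  Y <- dataset$features
  if (!is.null(features)) Y <- Y[, features, drop = FALSE]
  pools <- list(
    mdd_f = which(meta$diagnosis == "MDD" & meta$sex == "F"),
    mdd_m = which(meta$diagnosis == "MDD" & meta$sex == "M"),
    hc_f = which(meta$diagnosis == "HC" & meta$sex == "F"),
    hc_m = which(meta$diagnosis == "HC" & meta$sex == "M")
  )
  need <- function(frac) c(
    mdd_f = round(frac * n_mdd), mdd_m = n_mdd - round(frac * n_mdd),
    hc_f = round(frac * n_hc), hc_m = n_hc - round(frac * n_hc))
  for (frac in compositions) {
    nd <- need(frac)
    short <- nd > vapply(pools, length, integer(1L))[names(nd)]
    if (any(short)) stop("composition ", frac, " infeasible: pool(s) ",
                         paste(names(nd)[short], collapse = ", "), " too small")
  }
  nm <- sprintf("%.0f%%F", 100 * compositions)
  mean_t <- matrix(NA_real_, n_iter, length(compositions),
                   dimnames = list(NULL, nm))
  rej <- matrix(0, ncol(Y), length(compositions),
                dimnames = list(colnames(Y), nm))
  with_seed(seed, {
    for (ci in seq_along(compositions)) {
      nd <- need(compositions[ci])
      for (it in seq_len(n_iter)) {
        take <- c(sample(pools$mdd_f, nd["mdd_f"]),
                  sample(pools$mdd_m, nd["mdd_m"]),
                  sample(pools$hc_f, nd["hc_f"]),
                  sample(pools$hc_m, nd["hc_m"]))
        is_mdd <- c(rep(TRUE, n_mdd), rep(FALSE, n_hc))
        Ys <- Y[take, , drop = FALSE]
        tp <- pooled_t_cols(Ys[is_mdd, , drop = FALSE],
                            Ys[!is_mdd, , drop = FALSE])
        rej[, ci] <- rej[, ci] + (stats::p.adjust(tp$p, "BH") < q_level)
        m <- rowMeans(Ys)
        mt <- stats::t.test(m[is_mdd], m[!is_mdd], var.equal = TRUE)
        mean_t[it, ci] <- unname(mt$statistic)
      }
    }
  })
  structure(list(mean_t = mean_t, rejection_freq = rej / n_iter,
                 compositions = compositions),
            class = "composition_sim")
}

## AUC via the rank-sum statistic; ties handled by midranks.
auc_rank <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label)
  n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train elastic-net diagnostic classifiers over a regularization path
#'
#' Per iteration: disjoint train and test subjects are drawn from the
#' stratum pool; an elastic-net-penalized logistic model (alpha = 0.5 by
#' default) is fit over a shared lambda grid (80 log-spaced values spanning
#' four decades below the pooled lambda_max); held-out AUC is recorded per
#' lambda and coefficient vectors are retained for ROI-level aggregation.
#'
#' @param dataset a `connectivity_dataset`.
#' @param stratum "M", "F" or "pooled".
#' @param n_train,n_test subjects per draw, defaults 145 / 72.
#' @param alpha elastic-net mixing, default 0.5.
#' @param n_lambda path length, default 80.
#' @param n_iter iterations, default 100.
#' @param seed integer seed.
#' @return a `classifier_result` list: `auc` (iterations x lambda), `lambda`,
#'   `mean_auc`, `nzero` (mean active features per lambda), `mean_beta`
#'   (features x lambda, averaged over iterations), `stratum`, `n_redrawn`.
#' @export
train_diagnostic_classifiers <- function(dataset, stratum = "pooled",
                                         n_train = 145L, n_test = 72L,
                                         alpha = 0.5, n_lambda = 80L,
                                         n_iter = 100L, seed = 1L) {
  meta <- dataset$meta
  pool <- if (stratum == "pooled") seq_len(nrow(meta))
          else which(meta$sex == stratum)
  if (length(pool) < n_train + n_test) {
    stop("stratum pool smaller than n_train + n_test")
  }
  Y <- dataset$features
  lab_all <- as.numeric(meta$diagnosis == "MDD")
  ## shared lambda grid from the pooled data
  Xp <- scale(Y[pool, , drop = FALSE])
  lambda_max <- max(abs(crossprod(Xp, lab_all[pool] - mean(lab_all[pool])))) /
    (length(pool) * max(alpha, 1e-3))
  lambda <- exp(seq(log(lambda_max), log(lambda_max * 1e-4),
                    length.out = n_lambda))
  auc <- matrix(NA_real_, n_iter, n_lambda)
  nzero <- matrix(NA_real_, n_iter, n_lambda)
  beta_sum <- matrix(0, ncol(Y), n_lambda)
  n_redrawn <- 0L
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      repeat {
        draw <- sample(pool, n_train + n_test)
        tr <- draw[seq_len(n_train)]
        te <- draw[n_train + seq_len(n_test)]
        if (length(unique(lab_all[tr])) == 2L &&
            length(unique(lab_all[te])) == 2L) break
        n_redrawn <- n_redrawn + 1L
      }
      fit <- glmnet::glmnet(Y[tr, , drop = FALSE], lab_all[tr],
                            family = "binomial", alpha = alpha,
                            lambda = lambda)
      pred <- stats::predict(fit, Y[te, , drop = FALSE], type = "link")
      fitted_l <- fit$lambda
      for (li in seq_len(n_lambda)) {
        ci <- which.min(abs(fitted_l - lambda[li]))
        auc[it, li] <- auc_rank(pred[, ci], lab_all[te] == 1)
        nzero[it, li] <- fit$df[ci]
      }
      B <- as.matrix(fit$beta)
      cols <- vapply(lambda, function(l) which.min(abs(fitted_l - l)),
                     integer(1L))
      beta_sum <- beta_sum + B[, cols, drop = FALSE]
    }
  })
  structure(list(auc = auc, lambda = lambda, mean_auc = colMeans(auc),
                 nzero = colMeans(nzero),
                 mean_beta = beta_sum / n_iter,
                 feature_info = dataset$feature_info,
                 stratum = stratum, n_redrawn = n_redrawn),
            class = "classifier_result")
}

#' Aggregate classifier weights to ROI level
#'
#' Coefficients are first averaged over iterations (already stored as
#' `mean_beta`), then |mean beta| is summed over every feature touching each
#' ROI (mean first, absolute value second).
#'
#' @param result a `classifier_result`.
#' @param lambda_index column of the lambda grid to aggregate, default the
#'   lambda with the best mean AUC.
#' @return named numeric vector: summed |mean beta| per ROI.
#' @export
aggregate_feature_weights <- function(result, lambda_index = NULL) {
  if (is.null(lambda_index)) lambda_index <- which.max(result$mean_auc)
  b <- abs(result$mean_beta[, lambda_index])
  fi <- result$feature_info
  rois <- sort(unique(c(fi$seed, fi$target)))
  out <- stats::setNames(numeric(length(rois)), rois)
  for (i in seq_along(b)) {
    if (b[i] == 0) next
    out[fi$seed[i]] <- out[fi$seed[i]] + b[i]
    out[fi$target[i]] <- out[fi$target[i]] + b[i]
  }
  out
}
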