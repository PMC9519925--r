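#' NIPALS partial least squares regression (single response)
#'
#' Fits K PLS1 components by the NIPALS algorithm with deflation. Weight
#' vectors are unit-norm; for a single response the first-component weights
#' reduce exactly to the normalized covariance `X'y / ||X'y||`. The first
#' component is sign-aligned so its expression-score correlation with the
#' response is nonnegative.
#'
#' @param X covered-parcels x genes matrix (an `expression_matrix` or plain
#'   matrix), columns standardized.
#' @param Y effect map: numeric vector, or a data frame with `parcel_id` and
#'   `t` (row-aligned by parcel_id when X has rownames).
#' @param n_components number of components K, default 2.
#' @param tol,max_iter NIPALS convergence controls (PLS1 converges in one
#'   step; the safeguard matters only for K > 1 deflation stages).
#' @return a `pls_model`: `weights` (genes x K), `scores` (parcels x K,
#'   deflation-aware), `rho` (per-component Eq.-style correlation against the
#'   original X and Y), `y`, `n_components`.
#' @export
fit_pls <- function(X, Y, n_components = 2L, tol = 1e-10, max_iter = 500L) {
  Xm <- if (inherits(X, "expression_matrix")) X$values else X
  y <- align_effect_map(Xm, Y)
  if (nrow(Xm) < 3L) stop("fewer than 3 aligned parcels")
  if (stats::sd(y) < 1e-15) stop("zero-variance Y")
  y0 <- y - mean(y)
  K <- n_components
  G <- ncol(Xm)
  W <- matrix(0, G, K, dimnames = list(colnames(Xm), NULL))
  Tm <- matrix(0, nrow(Xm), K, dimnames = list(rownames(Xm), NULL))
  Xd <- Xm
  yd <- y0
  for (m in seq_len(K)) {
    u <- crossprod(Xd, yd)
    nu <- sqrt(sum(u^2))
    if (nu < 1e-15) { K <- m - 1L; break }
    u <- u / nu
    for (it in seq_len(max_iter)) {            # PLS1: converges immediately
      t_scr <- Xd %*% u
      u_new <- crossprod(Xd, yd)
      u_new <- u_new / sqrt(sum(u_new^2))
      if (sqrt(sum((u_new - u)^2)) < tol) { u <- u_new; break }
      u <- u_new
    }
    t_scr <- as.numeric(Xd %*% u)
    tt <- sum(t_scr^2)
    p_load <- crossprod(Xd, t_scr) / tt
    q_load <- sum(yd * t_scr) / tt
    W[, m] <- u
    Tm[, m] <- t_scr
    Xd <- Xd - tcrossprod(t_scr, p_load)
    yd <- yd - t_scr * q_load
  }
  W <- W[, seq_len(K), drop = FALSE]
  Tm <- Tm[, seq_len(K), drop = FALSE]
  rho <- as.numeric(stats::cor(Xm %*% W, y0))
  if (K >= 1L && rho[1L] < 0) {                # sign-align component 1
    W[, 1L] <- -W[, 1L]
    Tm[, 1L] <- -Tm[, 1L]
    rho[1L] <- -rho[1L]
  }
  structure(list(weights = W, scores = Tm, rho = rho, y = y0,
                 n_components = K),
            class = "pls_model")
}

align_effect_map <- function(Xm, Y) {
  if (is.data.frame(Y)) {
    if (!is.null(rownames(Xm)) && !is.null(Y$parcel_id)) {
      m <- match(rownames(Xm), Y$parcel_id)
      if (anyNA(m)) stop("effect map does not cover all X parcels")
      return(Y$t[m])
    }
    return(Y$t)
  }
  if (!is.null(names(Y)) && !is.null(rownames(Xm))) {
    m <- match(rownames(Xm), names(Y))
    if (!anyNA(m)) return(as.numeric(Y[m]))
  }
  stopifnot(length(Y) == nrow(Xm))
  as.numeric(Y)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d genes, %d components; rho = %s\n",
              nrow(x$weights), x$n_components,
              paste(sprintf("%.3f", x$rho), collapse = ", ")))
  invisible(x)
}

#' Component correlations of a fitted PLS model
#'
#' Pearson correlation between the gene-expression scores `X u_m` and the
#' response, per component, against the original (undeflated) X.
#'
#' @param model a `pls_model`.
#' @param X,Y as in [fit_pls()]; defaults to the training response stored in
#'   the model when `Y` is missing.
#' @return numeric vector of per-component correlations.
#' @export
component_correlation <- function(model, X, Y = NULL) {
  Xm <- if (inherits(X, "expression_matrix")) X$values else X
  y <- if (is.null(Y)) model$y else align_effect_map(Xm, Y)
  as.numeric(stats::cor(Xm %*% model$weights, y))
}

## First-component PLS1 weights for many responses at once:
## u_k = normalize(X' y_k). Ymat columns are (centered internally) responses.
first_component_weights <- function(Xm, Ymat) {
  Yc <- sweep(Ymat, 2L, colMeans(Ymat))
  U <- crossprod(Xm, Yc)
  nu <- sqrt(colSums(U^2))
  nu[nu < 1e-300] <- 1
  sweep(U, 2L, nu, "/")
}

#' Bootstrap stability of first-component loading weights
#'
#' Rows (parcels) of X and Y are resampled jointly with replacement; the
#' first PLS component is refit per replicate and sign-aligned to the
#' empirical weight vector (sign of the dot product); the per-gene standard
#' deviation over replicates standardizes the empirical loading weights into
#' the bootstrap Z used to rank genes (descending).
#'
#' @param X,Y as in [fit_pls()].
#' @param n_boot bootstrap replicates, default 10000.
#' @param seed integer seed.
#' @param chunk replicates per internal block (memory control).
#' @return a `ranked_gene_list` data frame: `gene_id`, `lw` (empirical
#'   first-component weight), `sd`, `z`, `rank` (1 = largest z); genes with
#'   zero bootstrap SD carry `z = NA` and no rank. Attribute `n_redrawn`
#'   counts replicates redrawn for zero-variance Y.
#' @export
bootstrap_loadings <- function(X, Y, n_boot = 10000L, seed = 1L,
                               chunk = 1000L) {
  Xm <- if (inherits(X, "expression_matrix")) X$values else X
  if (is.null(colnames(Xm))) colnames(Xm) <- sprintf("g%05d", seq_len(ncol(Xm)))
  y <- align_effect_map(Xm, Y)
  emp <- fit_pls(Xm, y, n_components = 1L)
  u_emp <- emp$weights[, 1L]
  P <- nrow(Xm)
  y0 <- y - mean(y)
  n_redrawn <- 0L
  sum_u <- numeric(ncol(Xm))
  sum_u2 <- numeric(ncol(Xm))
  with_seed(seed, {
    done <- 0L
    while (done < n_boot) {
      nb <- min(chunk, n_boot - done)
      ## count matrix C: P x nb multinomial resampling weights
      idx <- matrix(sample.int(P, P * nb, replace = TRUE), P, nb)
      C <- matrix(0, P, nb)
      for (j in seq_len(nb)) {
        tb <- tabulate(idx[, j], nbins = P)
        C[, j] <- tb
      }
      ## redraw replicates whose resampled Y is constant
      repeat {
        wy_mean <- colSums(C * y) / P
        wy_var <- colSums(C * (y - rep(wy_mean, each = P))^2)
        bad <- which(wy_var < 1e-15)
        if (!length(bad)) break
        n_redrawn <- n_redrawn + length(bad)
        for (j in bad) C[, j] <- tabulate(sample.int(P, P, replace = TRUE),
                                          nbins = P)
      }
      ## u_b = normalize( sum_i c_{ib} x_i (y_i - mean_b) ); the weighted
      ## centering constant drops after projection onto X columns exactly when
      ## X columns are centered, so center y per replicate explicitly:
      Yw <- C * (y - rep(colSums(C * y) / P, each = P))
      U <- crossprod(Xm, Yw)
      nu <- sqrt(colSums(U^2))
      nu[nu < 1e-300] <- 1
      U <- sweep(U, 2L, nu, "/")
      sgn <- sign(colSums(U * u_emp))
      sgn[sgn == 0] <- 1
      U <- sweep(U, 2L, sgn, "*")
      sum_u <- sum_u + rowSums(U)
      sum_u2 <- sum_u2 + rowSums(U^2)
      done <- done + nb
    }
  })
  sd_u <- sqrt(pmax(sum_u2 / n_boot - (sum_u / n_boot)^2, 0) *
                 n_boot / (n_boot - 1L))
  z <- ifelse(sd_u < 1e-300, NA_real_, u_emp / sd_u)
  out <- data.frame(gene_id = colnames(Xm), lw = u_emp, sd = sd_u, z = z,
                    stringsAsFactors = FALSE)
  out$rank <- NA_integer_
  ok <- is.finite(out$z)
  out$rank[ok] <- rank(-out$z[ok], ties.method = "first")
  out <- out[order(out$rank, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_redrawn") <- n_redrawn
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}
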