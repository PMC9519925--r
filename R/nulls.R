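#' Draw a uniform random 3D rotation
#'
#' Haar-uniform over SO(3): QR of a Gaussian 3 x 3 with the sign correction
#' `Q diag(sign(diag(R)))`; a determinant of -1 is mapped to +1 by global
#' negation (a measure-preserving bijection between the two O(3) components).
#'
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @return 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation <- function(seed = NULL) {
  draw <- function() {
    qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
    Q <- qr.Q(qr_)
    Q <- Q %*% diag(sign(diag(qr.R(qr_))))
    if (det(Q) < 0) Q <- -Q
    Q
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

## Bijective greedy nearest-neighbour assignment of original loci (rows of A)
## to rotated loci (rows of Bp): at each step the rotated locus whose nearest
## remaining original is farthest away gets assigned first (worst-off first).
## Returns perm with perm[i] = index of the original parcel whose value moves
## to slot i.
greedy_assign <- function(A, Bp) {
  n <- nrow(A)
  D <- great_circle_dist(Bp, A)                # rotated x original
  perm <- integer(n)
  free_r <- rep(TRUE, n)                       # rotated slots unassigned
  free_o <- rep(TRUE, n)                       # originals unused
  big <- Inf
  for (step in seq_len(n)) {
    Dv <- D
    Dv[!free_r, ] <- big
    Dv[, !free_o] <- big
    mins <- apply(Dv, 1L, min)
    mins[!free_r] <- -big
    i <- which.max(mins)                       # worst-off rotated slot
    j <- which.min(Dv[i, ])
    perm[i] <- j
    free_r[i] <- FALSE
    free_o[j] <- FALSE
  }
  perm
}

## A random isometry of the left hemisphere (x < 0): rotation about the pole
## (x) axis by a uniform angle, composed with a coin-flip reflection through
## the z = 0 plane. These are exactly the rigid motions that map the
## half-sphere onto itself, so the spun map keeps its spatial autocorrelation
## intact (up to lattice discretization) and the null is exactly exchangeable
## for isotropic fields. A rotation drawn uniformly from all of SO(3) would
## eject most centroids from the half-sphere and collapse the spin toward a
## spatially naive shuffle; see the methods vignette.
random_hemisphere_isometry <- function() {
  phi <- stats::runif(1, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0),
              c(0, cos(phi), -sin(phi)),
              c(0, sin(phi), cos(phi)))
  if (stats::runif(1) < 0.5) Rx <- Rx %*% diag(c(1, 1, -1))
  Rx
}

#' Spatially constrained spin permutations of a parcellation
#'
#' Per permutation, a random isometry of the hemisphere (uniform rotation
#' about the pole axis, with a coin-flip reflection) is applied to the
#' left-hemisphere centroids and its x-mirrored counterpart to the right
#' hemisphere; parcels are then reassigned to the rotated positions within
#' hemisphere by greedy nearest-neighbour without replacement (worst-off
#' first), yielding a true (bijective) index permutation that preserves the
#' spatial autocorrelation structure of any map it is applied to.
#'
#' @param geometry a `parcel_geometry`.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return integer matrix `n_perm` x `nrow(geometry)`; row k permutes a
#'   parcel-indexed vector `v` as `v[perm[k, ]]`.
#' @export
spin_permutation <- function(geometry, n_perm, seed = 1L) {
  xyz <- sphere_coords(geometry)
  lh <- which(geometry$hemisphere == "L")
  rh_of <- match(geometry$homolog_id[lh], geometry$parcel_id)
  A_l <- xyz[lh, , drop = FALSE]
  A_r <- xyz[rh_of, , drop = FALSE]
  M <- diag(c(-1, 1, 1))
  with_seed(seed, {
    out <- matrix(0L, n_perm, nrow(geometry))
    for (k in seq_len(n_perm)) {
      R <- random_hemisphere_isometry()
      R_m <- M %*% R %*% M
      perm_l <- greedy_assign(A_l, A_l %*% t(R))
      perm_r <- greedy_assign(A_r, A_r %*% t(R_m))
      full <- integer(nrow(geometry))
      full[lh] <- lh[perm_l]
      full[rh_of] <- rh_of[perm_r]
      out[k, ] <- full
    }
    out
  })
}

## Correlation rho_k = Corr(X u_k, Y_k) for a bank of permuted responses,
## with per-permutation refit u_k = normalize(X' Y_k). Ymat: P x K matrix of
## permuted responses; NA entries (uncovered values landing on covered
## positions) are excluded pairwise per permutation.
refit_null_rho <- function(Xm, Ymat, refit = TRUE, u_fixed = NULL) {
  obs <- !is.na(Ymat)
  n_k <- colSums(obs)
  Y0 <- Ymat
  Y0[!obs] <- 0
  ymean <- colSums(Y0) / n_k
  Yc <- (Y0 - rep(ymean, each = nrow(Ymat))) * obs
  U <- if (refit) {
    Uraw <- crossprod(Xm, Yc)
    nu <- sqrt(colSums(Uraw^2))
    nu[nu < 1e-300] <- 1
    sweep(Uraw, 2L, nu, "/")
  } else {
    matrix(u_fixed, ncol(Xm), ncol(Ymat))
  }
  S <- Xm %*% U                                # P x K scores
  s_sum <- colSums(S * obs)
  s_mean <- s_sum / n_k
  s_var <- colSums(S^2 * obs) - n_k * s_mean^2
  sy <- colSums(S * Yc)
  y_var <- colSums(Yc^2)
  sy / sqrt(s_var * y_var)
}

#' Spin test of a PLS gene-expression association
#'
#' Builds the null distribution of Eq.-(1)-style correlations by applying
#' spin permutations to the response map, refitting the first PLS component
#' per permuted response and correlating its expression scores with the
#' permuted map. Uncovered parcels participate in the rotation and are
#' dropped afterwards (pairwise per permutation).
#'
#' @param X covered-parcels x genes `expression_matrix` (or matrix with
#'   parcel rownames).
#' @param Y effect map over the covered parcels (vector / data frame as in
#'   [fit_pls()]).
#' @param geometry the full `parcel_geometry`.
#' @param n_perm permutations, default 10000 (< 100 warns).
#' @param seed integer seed.
#' @param permutations optional precomputed [spin_permutation()] bank.
#' @param refit refit the loading weights per permutation (default TRUE, the
#'   quoted convention); FALSE keeps the empirical weights fixed.
#' @return a `null_distribution` list: `rho_null`, `observed`, `p`, `method`,
#'   `n_perm`, `seed`.
#' @export
spin_test <- function(X, Y, geometry, n_perm = 10000L, seed = 1L,
                      permutations = NULL, refit = TRUE) {
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse null")
  Xm <- if (inherits(X, "expression_matrix")) X$values else X
  y <- align_effect_map(Xm, Y)
  model <- fit_pls(Xm, y, n_components = 1L)
  if (is.null(permutations)) {
    permutations <- spin_permutation(geometry, n_perm, seed)
  } else {
    n_perm <- nrow(permutations)
  }
  ## response over the full parcel set; NA where uncovered
  y_full <- rep(NA_real_, nrow(geometry))
  names(y_full) <- geometry$parcel_id
  y_full[rownames(Xm)] <- y
  covered_idx <- match(rownames(Xm), geometry$parcel_id)
  Ymat <- matrix(NA_real_, nrow(Xm), n_perm)
  for (k in seq_len(n_perm)) {
    Ymat[, k] <- y_full[permutations[k, ]][covered_idx]
  }
  rho_null <- refit_null_rho(Xm, Ymat, refit = refit,
                             u_fixed = model$weights[, 1L])
  structure(list(rho_null = rho_null, observed = model$rho[1L],
                 p = perm_pvalue(rho_null, model$rho[1L]),
                 method = "spin", n_perm = n_perm, seed = seed),
            class = "null_distribution")
}

#' Random (spatially naive) permutation test
#'
#' As [spin_test()] but with uniform permutations of the covered response
#' entries.
#'
#' @inheritParams spin_test
#' @return a `null_distribution`.
#' @export
random_test <- function(X, Y, n_perm = 10000L, seed = 1L, refit = TRUE) {
  Xm <- if (inherits(X, "expression_matrix")) X$values else X
  y <- align_effect_map(Xm, Y)
  model <- fit_pls(Xm, y, n_components = 1L)
  P <- nrow(Xm)
  Ymat <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) y[sample.int(P)], numeric(P))
  })
  rho_null <- refit_null_rho(Xm, Ymat, refit = refit,
                             u_fixed = model$weights[, 1L])
  structure(list(rho_null = rho_null, observed = model$rho[1L],
                 p = perm_pvalue(rho_null, model$rho[1L]),
                 method = "random", n_perm = n_perm, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("%s null: observed rho = %.3f, p = %.4g (n_perm = %d)\n",
              x$method, x$observed, x$p, x$n_perm))
  invisible(x)
}

#' BH correction across a family of PLS models
#'
#' @param p_values p-values, one per model (e.g. 5 seed regions x 2 sexes).
#' @param q_level FDR level.
#' @return list with `q_values` and `reject` (see [bh_fdr()]).
#' @export
fdr_across_models <- function(p_values, q_level = 0.05) {
  bh_fdr(p_values, q_level)
}
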