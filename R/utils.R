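#' @keywords internal
"_PACKAGE"

## Seed substreams: a master seed plus a stage name give an independent,
## reproducible RNG stream. Kept below 2^31 - 1 (R integers are 32-bit).
stage_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(master_seed) * 7919 + h * 104729) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

## Great-circle distance (radians) between unit vectors in the rows of a and b.
great_circle_dist <- function(a, b = a) {
  cosd <- tcrossprod(a, b)
  cosd[cosd > 1] <- 1
  cosd[cosd < -1] <- -1
  acos(cosd)
}

#' Moran's I spatial autocorrelation of a vector over a weight matrix
#'
#' Plain double-sum implementation used both by the generator diagnostics and
#' as the oracle in spatial-autocorrelation tests.
#'
#' @param x numeric vector.
#' @param w square weight matrix (diagonal ignored).
#' @return Moran's I statistic.
#' @export
moran_i <- function(x, w) {
  stopifnot(length(x) == nrow(w), nrow(w) == ncol(w))
  diag(w) <- 0
  z <- x - mean(x)
  n <- length(x)
  (n / sum(w)) * sum(w * outer(z, z)) / sum(z^2)
}

## Inverse-distance weights on the sphere, the default spatial weighting for
## Moran's I diagnostics.
inv_dist_weights <- function(xyz) {
  d <- great_circle_dist(xyz)
  w <- 1 / d
  w[!is.finite(w)] <- 0
  w
}

## Column-wise Pearson correlation of matching columns of A and B.
colwise_cor <- function(A, B) {
  A <- sweep(A, 2L, colMeans(A))
  B <- sweep(B, 2L, colMeans(B))
  colSums(A * B) / sqrt(colSums(A^2) * colSums(B^2))
}

## One-sided permutation p with the +1 correction (never returns 0).
perm_pvalue <- function(null, observed) {
  (1 + sum(null >= observed)) / (1 + length(null))
}

fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
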