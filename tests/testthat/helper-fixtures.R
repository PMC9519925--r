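# Shared fixture builders. Everything is generated in code at test time.

tiny_geom <- function(n = 10L, seed = 1L) make_parcellation(n, seed = seed)

# Column-standardized random matrix with parcel rownames, mimicking an X.
std_matrix <- function(P, G, seed = 1L, rownames_from = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(P * G), P, G)
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  rownames(X) <- if (is.null(rownames_from)) sprintf("P%03d", seq_len(P))
                 else rownames_from
  colnames(X) <- sprintf("G%05d", seq_len(G))
  X
}

# Smooth spatial fields over a geometry (exponential-covariance GP draws).
smooth_fields <- function(geom, n_fields, smoothness = 0.5, seed = 1L) {
  xyz <- as.matrix(geom[, c("sx", "sy", "sz")])
  d <- acos(pmin(pmax(tcrossprod(xyz), -1), 1))
  L <- chol(exp(-d / smoothness) + diag(1e-8, nrow(xyz)))
  set.seed(seed)
  f <- crossprod(L, matrix(rnorm(nrow(xyz) * n_fields), ncol = n_fields))
  rownames(f) <- geom$parcel_id
  f
}

# Standardize columns of a matrix (helper for smooth X fixtures).
std_cols <- function(M) {
  M <- scale(M)
  attr(M, "scaled:center") <- NULL
  attr(M, "scaled:scale") <- NULL
  M
}

small_dataset <- function(geom, n_per_cell = 20L, effect_spec = list(),
                          noise_sd = 0.1, seed = 1L, sites = NULL) {
  if (is.null(sites)) {
    simulate_subject_rsfc(geom, n_per_cell, effect_spec,
                          noise_sd = noise_sd, seed = seed)
  } else {
    design <- expand.grid(sex = c("M", "F"), diagnosis = c("HC", "MDD"),
                          site = sites, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
    design$n <- n_per_cell
    simulate_subject_rsfc(geom, design, effect_spec,
                          noise_sd = noise_sd, seed = seed)
  }
}
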