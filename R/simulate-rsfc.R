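#' Construct an rsFC feature index over a parcellation
#'
#' Features are (seed parcel, target parcel) pairs; self-pairs are excluded.
#'
#' @param seed_parcels,target_parcels character vectors of parcel ids.
#' @return data frame with columns `feature`, `seed`, `target`.
#' @export
make_feature_index <- function(seed_parcels, target_parcels) {
  idx <- expand.grid(seed = seed_parcels, target = target_parcels,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  idx <- idx[idx$seed != idx$target, , drop = FALSE]
  idx <- data.frame(feature = paste(idx$seed, idx$target, sep = "~"),
                    seed = idx$seed, target = idx$target,
                    stringsAsFactors = FALSE)
  rownames(idx) <- NULL
  idx
}

new_connectivity_dataset <- function(features, meta, feature_info) {
  stopifnot(nrow(features) == nrow(meta),
            ncol(features) == nrow(feature_info),
            all(feature_info$seed != feature_info$target))
  rownames(features) <- meta$subject_id
  colnames(features) <- feature_info$feature
  structure(list(features = features, meta = meta,
                 feature_info = feature_info),
            class = "connectivity_dataset")
}

#' @export
print.connectivity_dataset <- function(x, ...) {
  cat(sprintf("connectivity_dataset: %d subjects x %d Fisher-z features\n",
              nrow(x$features), ncol(x$features)))
  print(table(sex = x$meta$sex, diagnosis = x$meta$diagnosis))
  invisible(x)
}

#' Simulate subject-level rsFC with a factorial sex x diagnosis design
#'
#' Feature f of subject s is
#' `baseline(f) + site(f) + b_sex(f)*sex + b_mdd(f)*mdd + b_int(f)*sex*mdd + e`,
#' `e ~ N(0, noise_sd)`, with sex and diagnosis coded 0/1 (male = 1, MDD = 1)
#' and the interaction as their product. Values are stored directly at
#' Fisher-z scale; see [simulate_time_series()] for the time-series route.
#'
#' @param geometry a `parcel_geometry`.
#' @param n_per_cell named subject counts. Either a data frame with columns
#'   `sex` ("M"/"F"), `diagnosis` ("HC"/"MDD"), `site`, `n`, or a single
#'   integer used for every sex x diagnosis cell at one site.
#' @param effect_spec list of per-feature effect vectors, each either a scalar
#'   (applied to all features) or a named vector over features: `baseline`,
#'   `beta_sex`, `beta_mdd`, `beta_int`, and `site_shift` (a named list,
#'   site -> scalar or vector). Missing entries default to 0.
#' @param seed_parcels,target_parcels parcel ids defining the feature index;
#'   default: first 4 parcels as seeds against all others.
#' @param noise_sd residual standard deviation at Fisher-z scale.
#' @param age_range uniform age range.
#' @param seed integer seed.
#' @return A `connectivity_dataset` with a `truth` attribute recording the
#'   exact effect vectors used.
#' @export
simulate_subject_rsfc <- function(geometry, n_per_cell, effect_spec = list(),
                                  seed_parcels = NULL, target_parcels = NULL,
                                  noise_sd = 0.1, age_range = c(18, 65),
                                  seed = 1L) {
  stopifnot(inherits(geometry, "parcel_geometry"))
  if (is.null(seed_parcels)) seed_parcels <- geometry$parcel_id[1:4]
  if (is.null(target_parcels)) target_parcels <- geometry$parcel_id
  fi <- make_feature_index(seed_parcels, target_parcels)
  nf <- nrow(fi)

  if (is.data.frame(n_per_cell)) {
    design <- n_per_cell
    if (is.null(design$site)) design$site <- "site1"
  } else {
    design <- expand.grid(sex = c("M", "F"), diagnosis = c("HC", "MDD"),
                          stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    design$site <- "site1"
    design$n <- as.integer(n_per_cell)
  }
  if (any(design$n > 0 & design$n < 2)) stop("need >= 2 subjects per nonempty cell")
  design <- design[design$n > 0, , drop = FALSE]

  expand_effect <- function(x) {
    if (is.null(x)) return(rep(0, nf))
    if (length(x) == 1L) return(rep(x, nf))
    if (length(x) == nf) return(as.numeric(x))
    out <- rep(0, nf)
    if (is.null(names(x))) stop("effect vector must be scalar, full-length, or named")
    miss <- setdiff(names(x), fi$feature)
    if (length(miss)) stop("effect_spec names absent from feature index: ",
                           paste(miss, collapse = ", "))
    out[match(names(x), fi$feature)] <- x
    out
  }
  baseline <- expand_effect(effect_spec$baseline)
  b_sex <- expand_effect(effect_spec$beta_sex)
  b_mdd <- expand_effect(effect_spec$beta_mdd)
  b_int <- expand_effect(effect_spec$beta_int)
  sites <- unique(design$site)
  site_shift <- lapply(sites, function(s) expand_effect(effect_spec$site_shift[[s]]))
  names(site_shift) <- sites

  with_seed(seed, {
    meta <- design[rep(seq_len(nrow(design)), design$n), c("sex", "diagnosis", "site")]
    n <- nrow(meta)
    meta$subject_id <- sprintf("sub%05d", seq_len(n))
    meta$age <- stats::runif(n, age_range[1], age_range[2])
    meta <- meta[, c("subject_id", "sex", "diagnosis", "site", "age")]
    rownames(meta) <- NULL
    sex01 <- as.numeric(meta$sex == "M")
    mdd01 <- as.numeric(meta$diagnosis == "MDD")
    mu <- matrix(baseline, n, nf, byrow = TRUE) +
      outer(sex01, b_sex) + outer(mdd01, b_mdd) + outer(sex01 * mdd01, b_int) +
      do.call(rbind, site_shift[meta$site])
    features <- mu + matrix(stats::rnorm(n * nf, sd = noise_sd), n, nf)
    ds <- new_connectivity_dataset(features, meta, fi)
    attr(ds, "truth") <- list(baseline = baseline, beta_sex = b_sex,
                              beta_mdd = b_mdd, beta_int = b_int,
                              site_shift = site_shift, noise_sd = noise_sd,
                              seed = seed)
    ds
  })
}

#' Simulate parcel time series with shared latent components
#'
#' AR(1) region signals mixing a small set of shared latent components; exists
#' only to exercise [compute_rsfc()], not to imitate BOLD physics.
#'
#' @param n_regions,n_time dimensions of the output.
#' @param n_latent number of shared components.
#' @param ar AR(1) coefficient.
#' @param seed integer seed.
#' @return regions x time matrix.
#' @export
simulate_time_series <- function(n_regions, n_time, n_latent = 3L, ar = 0.3,
                                 seed = 1L) {
  with_seed(seed, {
    lat <- sapply(seq_len(n_latent), function(i)
      as.numeric(stats::arima.sim(list(ar = ar), n_time)))
    mix <- matrix(stats::rnorm(n_regions * n_latent, sd = 0.5),
                  n_regions, n_latent)
    sig <- mix %*% t(lat) +
      t(sapply(seq_len(n_regions), function(i)
        as.numeric(stats::arima.sim(list(ar = ar), n_time))))
    rownames(sig) <- sprintf("R%03d", seq_len(n_regions))
    sig
  })
}

#' Plant a linear gene-expression association into an effect map
#'
#' Draws a sparse gene-weight vector `w`, forms `Y = s * X w + e` with the
#' scaling chosen so `var(s * X w) / var(e) = snr`, and returns `Y` as an
#' effect map over the rows of `X` together with the planted weights.
#'
#' @param X parcels x genes matrix, column-standardized (an
#'   `expression_matrix` or a plain matrix).
#' @param sparsity fraction of genes carrying nonzero weight.
#' @param snr signal-to-noise variance ratio; must be positive.
#' @param seed integer seed.
#' @return list with `effect_map` (data frame `parcel_id`, `t`), `y` (numeric
#'   vector), `gene_weights` (named, full length) and `truth`.
#' @export
plant_gene_association <- function(X, sparsity = 0.01, snr = 2, seed = 1L) {
  if (snr <= 0) stop("snr must be positive")
  Xm <- if (inherits(X, "expression_matrix")) X$values else X
  if (is.null(colnames(Xm))) colnames(Xm) <- sprintf("g%05d", seq_len(ncol(Xm)))
  G <- ncol(Xm)
  k <- ceiling(sparsity * G)
  with_seed(seed, {
    w <- numeric(G)
    nz <- sample.int(G, k)
    w[nz] <- stats::rnorm(k)
    names(w) <- colnames(Xm)
    signal <- as.numeric(Xm %*% w)
    signal <- signal / stats::sd(signal)       # unit variance signal
    e <- stats::rnorm(nrow(Xm))
    e <- e - mean(e)
    e <- e / stats::sd(e) / sqrt(snr)          # var(signal)/var(e) = snr
    y <- signal + e
    em <- data.frame(parcel_id = rownames(Xm), t = y, stringsAsFactors = FALSE)
    list(effect_map = em, y = stats::setNames(y, rownames(Xm)),
         gene_weights = w,
         truth = list(nonzero = names(w)[nz], snr = snr, sparsity = sparsity,
                      seed = seed))
  })
}
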