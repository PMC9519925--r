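#' Simulate donor microarray sample sets over a parcellation
#'
#' Each gene gets a latent spatial field drawn from a zero-mean Gaussian
#' process with covariance `exp(-d / smoothness)` over great-circle distance
#' `d` between parcel centroids (Cholesky at parcel resolution). Each donor
#' then observes a noisy microarray sample near each covered parcel locus,
#' through `probes_per_gene` probes per gene (i.i.d. noisy replicates of the
#' gene field) with a donor-specific affine distortion (scale and shift) that
#' the per-donor Z-normalization of the mapping pipeline must remove. Only
#' `round(right_hemi_donor_fraction * n_donors)` donors (the first ones) carry
#' right-hemisphere samples, emulating the sparse right-hemisphere coverage of
#' postmortem expression atlases.
#'
#' @param geometry a `parcel_geometry`.
#' @param n_genes number of genes (>= 2).
#' @param n_donors number of donors (>= 1).
#' @param smoothness spatial length-scale of the exponential covariance, in
#'   radians of arc; must be positive.
#' @param probes_per_gene probes per gene.
#' @param right_hemi_donor_fraction fraction of donors with right-hemisphere
#'   samples.
#' @param sample_noise_sd,probe_noise_sd measurement noise standard deviations
#'   at the sample and probe level.
#' @param coord_jitter_mm standard deviation of the sample-placement jitter
#'   around the parcel volume locus (keep < radius/2 so samples stay
#'   assignable under the 2 mm rule; 0 gives the noiseless fixture).
#' @param seed integer seed.
#' @return A list with `donors` (list of donor sample sets: `donor_id`,
#'   `samples` data frame, `probe_expression` probes x samples matrix,
#'   `probes` data frame mapping probe to gene), `fields` (the latent parcels
#'   x genes matrix) and `truth`.
#' @export
simulate_expression_atlas <- function(geometry, n_genes, n_donors,
                                      smoothness = 0.5, probes_per_gene = 2L,
                                      right_hemi_donor_fraction = 2 / 6,
                                      sample_noise_sd = 0.2,
                                      probe_noise_sd = 0.2,
                                      coord_jitter_mm = 0.5,
                                      seed = 1L) {
  stopifnot(inherits(geometry, "parcel_geometry"))
  if (n_genes < 2) stop("n_genes must be >= 2")
  if (n_donors < 1) stop("n_donors must be >= 1")
  if (smoothness <= 0) stop("smoothness must be positive")
  P <- nrow(geometry)
  xyz <- sphere_coords(geometry)
  K <- exp(-great_circle_dist(xyz) / smoothness)
  L <- chol(K + diag(1e-8, P))
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  n_rh <- round(right_hemi_donor_fraction * n_donors)

  with_seed(seed, {
    fields <- crossprod(L, matrix(stats::rnorm(P * n_genes), P, n_genes))
    dimnames(fields) <- list(geometry$parcel_id, gene_ids)

    donors <- lapply(seq_len(n_donors), function(d) {
      donor_id <- sprintf("D%04d", d)
      has_right <- d <= n_rh
      keep <- if (has_right) rep(TRUE, P) else geometry$hemisphere == "L"
      parcels <- geometry$parcel_id[keep]
      ns <- length(parcels)
      coords <- volume_coords(geometry)[keep, , drop = FALSE] +
        matrix(stats::rnorm(3L * ns, sd = coord_jitter_mm), ns, 3L)
      samples <- data.frame(
        sample_id = sprintf("%s_S%04d", donor_id, seq_len(ns)),
        x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
        hemisphere = geometry$hemisphere[keep],
        stringsAsFactors = FALSE
      )
      ## donor-specific affine distortion per gene
      g_scale <- exp(stats::rnorm(n_genes, sd = 0.2))
      g_shift <- stats::rnorm(n_genes, sd = 0.5)
      truth_vals <- t(fields[keep, , drop = FALSE])   # genes x samples
      obs <- truth_vals * g_scale + g_shift +
        matrix(stats::rnorm(n_genes * ns, sd = sample_noise_sd), n_genes, ns)
      probe_ids <- sprintf("%s_probe%d", rep(gene_ids, each = probes_per_gene),
                           rep(seq_len(probes_per_gene), n_genes))
      probe_expression <- obs[rep(seq_len(n_genes), each = probes_per_gene), ,
                              drop = FALSE] +
        matrix(stats::rnorm(length(probe_ids) * ns, sd = probe_noise_sd),
               length(probe_ids), ns)
      dimnames(probe_expression) <- list(probe_ids, samples$sample_id)
      list(
        donor_id = donor_id,
        samples = samples,
        probe_expression = probe_expression,
        probes = data.frame(
          probe_id = probe_ids,
          gene_id = rep(gene_ids, each = probes_per_gene),
          stringsAsFactors = FALSE
        )
      )
    })
    structure(
      list(
        donors = donors,
        fields = fields,
        truth = list(
          smoothness = smoothness,
          right_hemi_donors = n_rh,
          sample_noise_sd = sample_noise_sd,
          probe_noise_sd = probe_noise_sd,
          coord_jitter_mm = coord_jitter_mm,
          seed = seed
        )
      ),
      class = "expression_atlas_sim"
    )
  })
}
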