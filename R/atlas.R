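#' Collapse probe-level expression to gene level
#'
#' Probe expression values mapping to the same gene are averaged (unweighted
#' mean); gene rows are ordered lexicographically. Genes with zero probes are
#' simply absent.
#'
#' @param probe_expression probes x samples matrix with probe_id rownames.
#' @param probe_to_gene data frame with columns `probe_id`, `gene_id`; every
#'   probe must be mapped to exactly one gene.
#' @return genes x samples matrix.
#' @export
collapse_probes <- function(probe_expression, probe_to_gene) {
  probes <- rownames(probe_expression)
  m <- match(probes, probe_to_gene$probe_id)
  if (anyNA(m)) stop("unmapped probes: ",
                     paste(utils::head(probes[is.na(m)]), collapse = ", "))
  gene <- probe_to_gene$gene_id[m]
  genes <- sort(unique(gene))
  f <- factor(gene, levels = genes)
  out <- rowsum(probe_expression, f) / as.vector(table(f))
  rownames(out) <- genes
  out
}

#' Assign microarray samples to parcels by the 2 mm rule
#'
#' A sample is assigned to the parcel whose representative volume locus lies
#' within `radius_mm` (Euclidean, millimeter frame); among loci within the
#' radius the nearest wins, with exact ties broken by the lexicographically
#' smaller parcel_id. Samples with no locus in range are dropped (counted in
#' the `n_unassigned` attribute).
#'
#' @param samples data frame with `sample_id`, `x`, `y`, `z`.
#' @param geometry a `parcel_geometry`.
#' @param radius_mm assignment radius, default 2.
#' @return data frame `sample_id`, `parcel_id` for assigned samples, with
#'   attribute `n_unassigned`.
#' @export
assign_samples_to_parcels <- function(samples, geometry, radius_mm = 2.0) {
  loci <- volume_coords(geometry)
  ## order loci by parcel_id so which.min's first-match tie-break is lexicographic
  ord <- order(rownames(loci))
  loci <- loci[ord, , drop = FALSE]
  pts <- as.matrix(samples[, c("x", "y", "z")])
  d2 <- outer(rowSums(pts^2), rep(1, nrow(loci))) +
    outer(rep(1, nrow(pts)), rowSums(loci^2)) - 2 * pts %*% t(loci)
  d2[d2 < 0] <- 0
  nearest <- apply(d2, 1L, which.min)
  dmin <- sqrt(d2[cbind(seq_len(nrow(pts)), nearest)])
  ok <- dmin <= radius_mm
  if (!any(ok)) warning("no samples assigned to any parcel")
  out <- data.frame(sample_id = samples$sample_id[ok],
                    parcel_id = rownames(loci)[nearest[ok]],
                    stringsAsFactors = FALSE)
  attr(out, "n_unassigned") <- sum(!ok)
  out
}

## Z-score each gene column over covered parcels; zero-SD columns are set to 0
## and flagged. values: parcels x genes; covered: logical over rows.
zscore_covered <- function(values, covered) {
  v <- values[covered, , drop = FALSE]
  mu <- colMeans(v)
  sdv <- apply(v, 2L, stats::sd)
  sdv[is.na(sdv)] <- 0                          # single covered parcel
  flat <- sdv < 1e-12
  sdv[flat] <- 1
  out <- values
  out[covered, ] <- sweep(sweep(v, 2L, mu), 2L, sdv, "/")
  if (any(flat)) out[covered, flat] <- 0
  attr(out, "flat_genes") <- colnames(values)[flat]
  out
}

#' Build one donor's parcel x gene matrix
#'
#' Per parcel, the unweighted mean over its assigned samples (at gene level),
#' then per-gene Z-scoring across that donor's covered parcels. Genes constant
#' across covered parcels are set to all-zero and flagged in the
#' `flat_genes` attribute.
#'
#' @param donor a donor sample set (see [simulate_expression_atlas()]), or any
#'   list with `probe_expression` and `probes`.
#' @param assignment output of [assign_samples_to_parcels()].
#' @param geometry a `parcel_geometry` giving the full parcel universe.
#' @return parcels x genes matrix over the full parcel set with a `covered`
#'   logical attribute; uncovered rows are NA.
#' @export
build_donor_matrix <- function(donor, assignment, geometry) {
  if (nrow(assignment) == 0L) stop("empty assignment")
  gene_by_sample <- collapse_probes(donor$probe_expression, donor$probes)
  use <- assignment[assignment$sample_id %in% colnames(gene_by_sample), , drop = FALSE]
  g <- gene_by_sample[, use$sample_id, drop = FALSE]
  f <- factor(use$parcel_id, levels = geometry$parcel_id)
  sums <- rowsum(t(g), f)                      # rows: parcels with >= 1 sample
  counts <- table(f)[rownames(sums)]
  covered <- geometry$parcel_id %in% rownames(sums)
  vals <- matrix(NA_real_, nrow(geometry), nrow(gene_by_sample),
                 dimnames = list(geometry$parcel_id, rownames(gene_by_sample)))
  vals[rownames(sums), ] <- sums / as.vector(counts)
  out <- zscore_covered(vals, covered)
  attr(out, "covered") <- stats::setNames(covered, geometry$parcel_id)
  out
}

#' Mirror donor expression across hemispheres
#'
#' Parcels covered in one hemisphere only have their values copied to the
#' mirror-hemisphere homolog; parcels covered in both get the pairwise mean
#' written to both sides. Idempotent.
#'
#' @param donor_matrix parcels x genes matrix with a `covered` attribute (see
#'   [build_donor_matrix()]).
#' @param geometry a `parcel_geometry` with the homolog bijection.
#' @return matrix of the same shape with updated `covered` attribute.
#' @export
mirror_hemispheres <- function(donor_matrix, geometry) {
  covered <- attr(donor_matrix, "covered")
  if (is.null(covered)) covered <- !is.na(donor_matrix[, 1L])
  hom <- match(geometry$homolog_id, geometry$parcel_id)
  out <- donor_matrix
  self_cov <- covered
  pair_cov <- covered[hom]
  both <- self_cov & pair_cov
  only_pair <- !self_cov & pair_cov
  out[both, ] <- (donor_matrix[both, , drop = FALSE] +
                  donor_matrix[hom[both], , drop = FALSE]) / 2
  out[only_pair, ] <- donor_matrix[hom[only_pair], , drop = FALSE]
  attr(out, "covered") <- self_cov | pair_cov
  attr(out, "flat_genes") <- attr(donor_matrix, "flat_genes")
  out
}

#' Aggregate donor matrices into the final expression matrix
#'
#' A parcel is covered if covered in at least one donor; values are averaged
#' over covering donors, and each gene column is Z-scored a final time over
#' the covered parcels. Uncovered parcels are excluded from the result, not
#' imputed.
#'
#' @param donor_matrices list of mirrored donor matrices sharing parcel and
#'   gene indices.
#' @return An `expression_matrix`: list with `values` (covered parcels x
#'   genes), `parcel_ids`, `gene_ids`, `covered_mask` (over the full parcel
#'   set) and `flat_genes`.
#' @export
aggregate_donors <- function(donor_matrices) {
  stopifnot(length(donor_matrices) >= 1L)
  P <- nrow(donor_matrices[[1L]])
  cov_counts <- Reduce(`+`, lapply(donor_matrices, function(m) {
    cv <- attr(m, "covered")
    if (is.null(cv)) cv <- !is.na(m[, 1L])
    as.numeric(cv)
  }))
  covered <- cov_counts > 0
  if (!any(covered)) stop("zero covered parcels")
  acc <- Reduce(`+`, lapply(donor_matrices, function(m) {
    m[is.na(m)] <- 0
    m
  }))
  vals <- sweep(acc, 1L, pmax(cov_counts, 1), "/")
  vals[!covered, ] <- NA_real_
  z <- zscore_covered(vals, covered)
  flat <- unique(c(attr(z, "flat_genes"),
                   unlist(lapply(donor_matrices, attr, "flat_genes"))))
  structure(
    list(values = z[covered, , drop = FALSE],
         parcel_ids = rownames(z)[covered],
         gene_ids = colnames(z),
         covered_mask = stats::setNames(covered, rownames(z)),
         flat_genes = flat),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d covered parcels x %d genes (%d flat)\n",
              nrow(x$values), ncol(x$values), length(x$flat_genes)))
  invisible(x)
}

#' Run the full donor-to-atlas expression mapping
#'
#' Composition collapse -> assign -> build -> mirror -> aggregate, following
#' the order build/Z, mirror, aggregate, final Z.
#'
#' @param donors list of donor sample sets.
#' @param geometry a `parcel_geometry`.
#' @param radius_mm sample assignment radius.
#' @return an `expression_matrix`.
#' @export
map_expression <- function(donors, geometry, radius_mm = 2.0) {
  mats <- lapply(donors, function(d) {
    asn <- assign_samples_to_parcels(d$samples, geometry, radius_mm)
    mirror_hemispheres(build_donor_matrix(d, asn, geometry), geometry)
  })
  aggregate_donors(mats)
}
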