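#' Simulate gene-set collections with planted decile enrichment
#'
#' Planted sets draw a configurable majority of their members from a stated
#' decile of a supplied gene ranking (decile 1 = top of the ranking); the
#' remainder and all random sets are drawn uniformly from the universe.
#'
#' @param gene_ids ranked character vector (best-ranked first).
#' @param planted data frame with columns `set_size`, `target_decile` (1..10),
#'   `direction` ("+"/"-"), or NULL.
#' @param n_random_sets number of uniform random sets.
#' @param random_set_size size of each random set.
#' @param concentration fraction of planted members forced into the target
#'   decile (default 0.9).
#' @param seed integer seed.
#' @return list with `sets` (named list of member vectors), `truth` (data
#'   frame of set name, planted flag, target decile, direction).
#' @export
simulate_gene_sets <- function(gene_ids, planted = NULL, n_random_sets = 0L,
                               random_set_size = 50L, concentration = 0.9,
                               seed = 1L) {
  G <- length(gene_ids)
  if (!is.null(planted)) {
    if (any(planted$set_size > G)) stop("set size exceeds universe")
    if (any(planted$set_size == G)) stop("set equal to the universe is degenerate")
    if (any(planted$target_decile < 1 | planted$target_decile > 10)) {
      stop("target_decile must be in 1..10")
    }
  }
  if (n_random_sets > 0 && random_set_size >= G) {
    stop("set equal to the universe is degenerate")
  }
  decile <- ceiling(10 * seq_len(G) / G)
  with_seed(seed, {
    sets <- list()
    truth <- data.frame(set_name = character(), planted = logical(),
                        target_decile = integer(), direction = character(),
                        stringsAsFactors = FALSE)
    if (!is.null(planted)) {
      for (i in seq_len(nrow(planted))) {
        sz <- planted$set_size[i]
        dec <- planted$target_decile[i]
        pool <- gene_ids[decile == dec]
        n_in <- min(length(pool), round(concentration * sz))
        members <- c(sample(pool, n_in),
                     sample(setdiff(gene_ids, pool), sz - n_in))
        nm <- sprintf("planted_d%d_%d", dec, i)
        sets[[nm]] <- members
        truth <- rbind(truth, data.frame(
          set_name = nm, planted = TRUE, target_decile = dec,
          direction = planted$direction[i], stringsAsFactors = FALSE))
      }
    }
    for (i in seq_len(n_random_sets)) {
      nm <- sprintf("random_%d", i)
      sets[[nm]] <- sample(gene_ids, random_set_size)
      truth <- rbind(truth, data.frame(
        set_name = nm, planted = FALSE, target_decile = NA_integer_,
        direction = NA_character_, stringsAsFactors = FALSE))
    }
    list(sets = sets, truth = truth)
  })
}

#' Simulate a genotype table, optionally wired into an rsFC feature
#'
#' Genotypes are drawn from Hardy-Weinberg proportions (p^2, 2pq, q^2) unless
#' a violation is flagged, in which case heterozygotes are depleted. For each
#' causal SNP, the named rsFC feature of subjects in the affected sex is
#' shifted by `allele_count * effect` in the returned dataset.
#'
#' @param n_subjects number of subjects (ignored when `dataset` is given).
#' @param snp_spec data frame: `snp_id`, `maf` in (0, 0.5), `missing_rate`,
#'   `hwe_violation` (logical), `risk_allele` (optional).
#' @param causal_spec optional data frame: `snp_id`, `feature`, `effect`
#'   (per-allele shift), `sex` ("M"/"F").
#' @param dataset optional `connectivity_dataset` that causal effects are
#'   injected into.
#' @param seed integer seed.
#' @return list with `genotypes` (subjects x SNP integer matrix with NAs),
#'   `snp_info`, `dataset` (modified copy or NULL) and `truth`.
#' @export
simulate_genotypes <- function(n_subjects = NULL, snp_spec, causal_spec = NULL,
                               dataset = NULL, seed = 1L) {
  stopifnot(all(snp_spec$maf > 0), all(snp_spec$maf < 0.5))
  if (!is.null(dataset)) n_subjects <- nrow(dataset$features)
  if (is.null(n_subjects)) stop("give n_subjects or dataset")
  if (!is.null(causal_spec) && !is.null(dataset)) {
    miss <- setdiff(causal_spec$feature, dataset$feature_info$feature)
    if (length(miss)) stop("causal feature absent from dataset: ",
                           paste(miss, collapse = ", "))
  }
  ns <- nrow(snp_spec)
  with_seed(seed, {
    G <- matrix(NA_integer_, n_subjects, ns,
                dimnames = list(NULL, snp_spec$snp_id))
    for (j in seq_len(ns)) {
      q <- snp_spec$maf[j]
      probs <- if (isTRUE(snp_spec$hwe_violation[j])) {
        ## deplete heterozygotes by half, renormalize
        pr <- c((1 - q)^2, 2 * q * (1 - q) / 2, q^2)
        pr / sum(pr)
      } else {
        c((1 - q)^2, 2 * q * (1 - q), q^2)
      }
      g <- sample(0:2, n_subjects, replace = TRUE, prob = probs)
      mr <- snp_spec$missing_rate[j]
      if (!is.null(mr) && mr > 0) g[stats::runif(n_subjects) < mr] <- NA_integer_
      G[, j] <- g
    }
    out_ds <- NULL
    if (!is.null(dataset)) {
      out_ds <- dataset
      rownames(G) <- dataset$meta$subject_id
      if (!is.null(causal_spec)) {
        for (i in seq_len(nrow(causal_spec))) {
          snp <- causal_spec$snp_id[i]
          fidx <- match(causal_spec$feature[i], dataset$feature_info$feature)
          in_sex <- out_ds$meta$sex == causal_spec$sex[i]
          cnt <- G[, snp]
          cnt[is.na(cnt)] <- 0L
          out_ds$features[in_sex, fidx] <- out_ds$features[in_sex, fidx] +
            cnt[in_sex] * causal_spec$effect[i]
        }
      }
    } else {
      rownames(G) <- sprintf("sub%05d", seq_len(n_subjects))
    }
    snp_info <- snp_spec
    if (is.null(snp_info$risk_allele)) snp_info$risk_allele <- "A"
    list(genotypes = G, snp_info = snp_info, dataset = out_ds,
         truth = list(snp_spec = snp_spec, causal_spec = causal_spec,
                      seed = seed))
  })
}
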