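#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Running-sum statistic over a z-descending ranked gene list: hits increment
#' by `|z|^weight_exponent` (normalized to sum 1 over the set), misses
#' decrement uniformly by `1/(G - K)`; the enrichment score is the running
#' sum's signed extremum.
#'
#' @param ranked data frame with columns `gene_id` and `z`, or a named
#'   numeric vector of scores; sorted internally by decreasing z.
#' @param gene_set character vector of member gene ids; must intersect the
#'   universe and be a proper subset of it.
#' @param weight_exponent GSEA weighting exponent, default 1.
#' @return list with `es`, `running` (length-G curve), `leading_edge`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  r <- as_ranked(ranked)
  G <- nrow(r)
  hit <- r$gene_id %in% gene_set
  K <- sum(hit)
  if (K == 0L) stop("gene set does not intersect the ranked universe")
  if (K == G) stop("gene set equals the universe: ES degenerate")
  w <- abs(r$z)^weight_exponent
  inc <- numeric(G)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (G - K)
  running <- cumsum(inc)
  i_max <- which.max(running)
  i_min <- which.min(running)
  es <- if (running[i_max] >= -running[i_min]) running[i_max] else running[i_min]
  leading <- if (es >= 0) {
    r$gene_id[seq_len(i_max)][hit[seq_len(i_max)]]
  } else {
    r$gene_id[i_min:G][hit[i_min:G]]
  }
  list(es = es, running = running, leading_edge = leading)
}

as_ranked <- function(ranked) {
  r <- if (is.data.frame(ranked)) {
    data.frame(gene_id = ranked$gene_id, z = ranked$z, stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = names(ranked), z = as.numeric(ranked),
               stringsAsFactors = FALSE)
  }
  stopifnot(all(is.finite(r$z)))
  r[order(-r$z, r$gene_id), , drop = FALSE]
}

## ES for many random same-size sets at once, via hit positions.
## pos_list: list of integer hit-position vectors (sorted).
es_from_positions <- function(w, G, pos) {
  pos <- sort(pos)
  K <- length(pos)
  wh <- w[pos]
  cum_hit <- cumsum(wh) / sum(wh)
  miss_before <- (pos - seq_len(K)) / (G - K)      # misses up to each hit
  ## candidate extrema: at each hit (peak) and just before each hit (trough)
  up <- cum_hit - miss_before
  down <- c(0, cum_hit[-K]) - miss_before
  es_max <- max(up)
  es_min <- min(down, 0)   # running sum ends at 0 after the last hit
  if (es_max >= -es_min) es_max else es_min
}

#' Preranked gene-set enrichment with a gene-sampling null
#'
#' For each eligible set, the ES null is built from random same-size gene
#' draws from the universe; `NES = ES / mean(|null ES| of the matching
#' sign)`, the p-value uses the matching-sign null tail with the +1 rule, and
#' q-values are BH across sets.
#'
#' @param ranked as in [enrichment_score()].
#' @param collection named list of gene-id vectors (or the `sets` element of
#'   [simulate_gene_sets()] output, or a GMT read by [read_gmt()]).
#' @param n_perm null draws per set size, default 10000.
#' @param min_size,max_size set-size eligibility bounds (defaults 15 / 500);
#'   sets outside are skipped (recorded in the `skipped` attribute).
#' @param weight_exponent GSEA weighting exponent.
#' @param seed integer seed.
#' @return data frame per set: `set_name`, `size`, `es`, `nes`, `p`, `q`,
#'   `sign`, `leading_edge` (list column).
#' @export
gsea_preranked <- function(ranked, collection, n_perm = 10000L,
                           min_size = 15L, max_size = 500L,
                           weight_exponent = 1, seed = 1L) {
  r <- as_ranked(ranked)
  G <- nrow(r)
  w <- abs(r$z)^weight_exponent
  sizes <- vapply(collection, function(s) sum(r$gene_id %in% s), integer(1L))
  eligible <- sizes >= min_size & sizes <= max_size
  skipped <- names(collection)[!eligible]
  if (!any(eligible)) stop("no eligible gene set")
  res <- with_seed(seed, {
    out <- lapply(names(collection)[eligible], function(nm) {
      members <- collection[[nm]]
      es_obs <- enrichment_score(r, members, weight_exponent)
      K <- sum(r$gene_id %in% members)
      null_es <- vapply(seq_len(n_perm), function(k) {
        es_from_positions(w, G, sample.int(G, K))
      }, numeric(1L))
      pos_null <- null_es[null_es >= 0]
      neg_null <- null_es[null_es < 0]
      if (es_obs$es >= 0) {
        nes <- es_obs$es / mean(abs(pos_null))
        p <- (1 + sum(pos_null >= es_obs$es)) / (1 + length(pos_null))
      } else {
        nes <- -abs(es_obs$es) / mean(abs(neg_null))
        p <- (1 + sum(neg_null <= es_obs$es)) / (1 + length(neg_null))
      }
      list(set_name = nm, size = K, es = es_obs$es, nes = nes, p = p,
           sign = if (es_obs$es >= 0) "+" else "-",
           leading_edge = es_obs$leading_edge)
    })
    out
  })
  df <- data.frame(
    set_name = vapply(res, `[[`, character(1L), "set_name"),
    size = vapply(res, `[[`, integer(1L), "size"),
    es = vapply(res, `[[`, numeric(1L), "es"),
    nes = vapply(res, `[[`, numeric(1L), "nes"),
    p = vapply(res, `[[`, numeric(1L), "p"),
    sign = vapply(res, `[[`, character(1L), "sign"),
    stringsAsFactors = FALSE
  )
  df$q <- stats::p.adjust(df$p, "BH")
  df$leading_edge <- I(lapply(res, `[[`, "leading_edge"))
  attr(df, "skipped") <- skipped
  df
}

#' Count gene-set members per loading-weight decile
#'
#' Deciles are by rank over the full ranked universe (ties broken by
#' gene_id); decile 1 holds the largest z scores.
#'
#' @param ranked as in [enrichment_score()]; needs at least 10 genes.
#' @param gene_set member gene ids.
#' @return integer vector of length 10 summing to the in-universe set size.
#' @export
decile_counts <- function(ranked, gene_set) {
  r <- as_ranked(ranked)
  G <- nrow(r)
  if (G < 10L) stop("need at least 10 genes")
  decile <- ceiling(10 * seq_len(G) / G)
  tab <- tabulate(decile[r$gene_id %in% gene_set], nbins = 10L)
  stats::setNames(tab, paste0("decile", 1:10))
}

#' Null confidence band for per-decile gene-set counts
#'
#' Simulates uniform random gene sets of the stated size and reports the
#' 2.5 and 97.5 percentiles of the per-decile member counts.
#'
#' @param G universe size.
#' @param set_size random-set size (<= G).
#' @param n_sim simulations, default 10000.
#' @param seed integer seed.
#' @return data frame `decile`, `lo`, `hi`, `expected`.
#' @export
decile_null_ci <- function(G, set_size, n_sim = 10000L, seed = 1L) {
  stopifnot(set_size <= G)
  decile <- ceiling(10 * seq_len(G) / G)
  counts <- with_seed(seed, {
    vapply(seq_len(n_sim), function(k) {
      tabulate(decile[sample.int(G, set_size)], nbins = 10L)
    }, integer(10L))
  })
  qs <- apply(counts, 1L, stats::quantile, probs = c(0.025, 0.975))
  data.frame(decile = 1:10, lo = qs[1L, ], hi = qs[2L, ],
             expected = set_size / 10)
}
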