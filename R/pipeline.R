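#' Default run configuration
#'
#' A flat, versioned key tree with every stage parameter at its default;
#' unknown keys passed to [run_workflow()] are rejected.
#'
#' @return named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    config_version = 1L,
    seed = 1L,
    n_per_hemisphere = 50L,
    n_genes = 500L,
    n_donors = 6L,
    smoothness = 0.5,
    probes_per_gene = 2L,
    right_hemi_donor_fraction = 2 / 6,
    n_per_cell = 50L,
    noise_sd = 0.1,
    site_shift = 0,
    sparsity = 0.01,
    snr = 2,
    effect_scale = 0.1,
    n_seed_parcels = 2L,
    radius_mm = 2.0,
    n_perm_spin = 1000L,
    n_perm_rand = 1000L,
    n_boot = 1000L,
    cv_repeats = 10L,
    cv_folds = 10L,
    gsea_n_perm = 1000L,
    gsea_min_size = 15L,
    gsea_max_size = 500L,
    stages = c("simulate", "map_expression", "contrasts", "pls", "nulls_cv",
               "enrichment")
  )
}

read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  base[names(cfg)] <- cfg
  base
}

#' Run the synthetic end-to-end workflow
#'
#' Executes the declared stages in dependency order on fully synthetic
#' inputs: simulate (geometry, donors, rsFC with a planted
#' expression-association), map_expression, contrasts (ANOVA, post-hoc,
#' shared/specific), pls (fit + bootstrap ranking), nulls_cv (spin and
#' random tests, cross-validation), enrichment (GSEA + decile analysis).
#' Every artifact is written under `out_dir` together with the verbatim
#' config, the seed, and a checksum manifest.
#'
#' @param config configuration list (see [default_config()]) or a JSON path.
#' @param out_dir output directory (created).
#' @return invisible list of in-memory stage results.
#' @export
run_workflow <- function(config = default_config(), out_dir = tempfile("run")) {
  cfg <- if (is.character(config)) read_config(config) else validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_truth(cfg, file.path(out_dir, "config.json"))
  log_lines <- character()
  note <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(fmt, ...))
    log_lines <<- c(log_lines, msg)
  }
  res <- list()
  sseed <- function(stage) stage_seed(cfg$seed, stage)

  if ("simulate" %in% cfg$stages) {
    t0 <- proc.time()[3L]
    geom <- make_parcellation(cfg$n_per_hemisphere, seed = sseed("geometry"))
    atlas <- simulate_expression_atlas(
      geom, cfg$n_genes, cfg$n_donors, smoothness = cfg$smoothness,
      probes_per_gene = cfg$probes_per_gene,
      right_hemi_donor_fraction = cfg$right_hemi_donor_fraction,
      seed = sseed("atlas"))
    X0 <- map_expression(atlas$donors, geom, cfg$radius_mm)
    planted <- plant_gene_association(X0, cfg$sparsity, cfg$snr,
                                      seed = sseed("plant"))
    seed_parcels <- geom$parcel_id[seq_len(cfg$n_seed_parcels)]
    ## plant the association as the MDD effect over the seed block
    fi <- make_feature_index(seed_parcels, geom$parcel_id)
    bmdd <- stats::setNames(rep(0, nrow(fi)), fi$feature)
    y_by_target <- stats::setNames(planted$y, names(planted$y))
    hit <- fi$target %in% names(y_by_target)
    bmdd[hit] <- cfg$effect_scale * y_by_target[fi$target[hit]]
    ds <- simulate_subject_rsfc(
      geom, cfg$n_per_cell,
      effect_spec = list(beta_mdd = bmdd, site_shift = list(site1 = cfg$site_shift)),
      seed_parcels = seed_parcels, noise_sd = cfg$noise_sd,
      seed = sseed("rsfc"))
    write_geometry(geom, file.path(out_dir, "geometry.tsv"))
    write_connectivity(ds, file.path(out_dir, "rsfc"))
    write_truth(list(planted_genes = planted$truth$nonzero,
                     snr = cfg$snr, seed = cfg$seed),
                file.path(out_dir, "truth.json"))
    for (d in atlas$donors) write_donor_csv(d, file.path(out_dir, "donors"))
    res$geometry <- geom
    res$atlas <- atlas
    res$planted <- planted
    res$dataset <- ds
    res$seed_parcels <- seed_parcels
    note("simulate: %d parcels, %d genes, %d subjects (%.1fs)",
         nrow(geom), cfg$n_genes, nrow(ds$features), proc.time()[3L] - t0)
  }
  if ("map_expression" %in% cfg$stages) {
    t0 <- proc.time()[3L]
    res$X <- map_expression(res$atlas$donors, res$geometry, cfg$radius_mm)
    write_expression_matrix(res$X, file.path(out_dir, "X.tsv"))
    note("map_expression: %d covered x %d genes (%.1fs)",
         nrow(res$X$values), ncol(res$X$values), proc.time()[3L] - t0)
  }
  if ("contrasts" %in% cfg$stages) {
    t0 <- proc.time()[3L]
    res$anova <- factorial_anova(res$dataset)
    res$posthoc <- posthoc_contrasts(res$dataset)
    res$venn <- classify_shared_specific(res$posthoc$male, res$posthoc$female)
    ## seed parcels are not targets: drop them from the mask up front
    target_mask <- setdiff(names(res$X$covered_mask)[res$X$covered_mask],
                           res$seed_parcels)
    res$Y <- seed_effect_map(res$dataset, res$seed_parcels, "M",
                             covered_mask = target_mask)
    utils::write.table(res$anova, file.path(out_dir, "anova.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(res$Y, file.path(out_dir, "Y.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("contrasts: %d features (%.1fs)", nrow(res$anova),
         proc.time()[3L] - t0)
  }
  if ("pls" %in% cfg$stages) {
    t0 <- proc.time()[3L]
    Xa <- res$X$values[res$X$parcel_ids %in% res$Y$parcel_id, , drop = FALSE]
    res$pls <- fit_pls(Xa, res$Y)
    res$ranked <- bootstrap_loadings(Xa, res$Y, n_boot = cfg$n_boot,
                                     seed = sseed("boot"))
    write_ranked_genes(res$ranked, file.path(out_dir, "ranked_genes.tsv"))
    note("pls: rho1 = %.3f (%.1fs)", res$pls$rho[1L], proc.time()[3L] - t0)
  }
  if ("nulls_cv" %in% cfg$stages) {
    t0 <- proc.time()[3L]
    Xa <- res$X$values[res$X$parcel_ids %in% res$Y$parcel_id, , drop = FALSE]
    res$spin <- spin_test(Xa, res$Y, res$geometry, cfg$n_perm_spin,
                          seed = sseed("spin"))
    res$rand <- random_test(Xa, res$Y, cfg$n_perm_rand, seed = sseed("rand"))
    res$cv <- cross_validate(Xa, res$dataset, res$seed_parcels, "M",
                             n_repeats = cfg$cv_repeats,
                             n_folds = cfg$cv_folds, seed = sseed("cvseed"))
    write_truth(list(p_spin = res$spin$p, p_rand = res$rand$p,
                     rho = res$spin$observed, cv_reject = res$cv$reject,
                     cv_min_adj_p = min(res$cv$adjusted_p)),
                file.path(out_dir, "nulls_cv.json"))
    note("nulls_cv: p_spin = %.4g, p_rand = %.4g, cv %s (%.1fs)",
         res$spin$p, res$rand$p,
         if (res$cv$reject) "reject" else "retain", proc.time()[3L] - t0)
  }
  if ("enrichment" %in% cfg$stages) {
    t0 <- proc.time()[3L]
    gs <- simulate_gene_sets(
      res$ranked$gene_id[order(res$ranked$rank)],
      planted = data.frame(set_size = 50L, target_decile = 1L,
                           direction = "+"),
      n_random_sets = 3L, random_set_size = 50L, seed = sseed("sets"))
    res$gsea <- gsea_preranked(res$ranked, gs$sets,
                               n_perm = cfg$gsea_n_perm,
                               min_size = cfg$gsea_min_size,
                               max_size = cfg$gsea_max_size,
                               seed = sseed("gsea"))
    write_gmt(gs$sets, file.path(out_dir, "gene_sets.gmt"))
    utils::write.table(res$gsea[, setdiff(names(res$gsea), "leading_edge")],
                       file.path(out_dir, "gsea.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("enrichment: %d sets (%.1fs)", nrow(res$gsea), proc.time()[3L] - t0)
  }
  writeLines(log_lines, file.path(out_dir, "run.log"))
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.tsv")
  manifest <- data.frame(
    file = files,
    md5 = as.character(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(res)
}
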