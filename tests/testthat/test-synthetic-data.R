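test_that("make_parcellation geometry contract holds", {
  expect_error(make_parcellation(3), "n_per_hemisphere")
  geom <- make_parcellation(4, seed = 7)
  expect_equal(nrow(geom), 8L)
  expect_true(all(abs(sqrt(geom$sx^2 + geom$sy^2 + geom$sz^2) - 1) < 1e-9))

  geom <- make_parcellation(180, seed = 1)
  expect_equal(nrow(geom), 360L)
  expect_false(any(duplicated(geom$parcel_id)))
  ## homolog relation is a bijection and an exact x-mirror, for every pair
  hom <- match(geom$homolog_id, geom$parcel_id)
  expect_equal(sort(hom), seq_len(nrow(geom)))
  expect_equal(geom$sx, -geom$sx[hom])
  expect_equal(geom$sy, geom$sy[hom])
  expect_equal(geom$sz, geom$sz[hom])
  expect_true(all(geom$hemisphere[hom] != geom$hemisphere))
  ## determinism
  expect_identical(make_parcellation(30, seed = 5), make_parcellation(30, seed = 5))
  expect_false(identical(make_parcellation(30, seed = 5),
                         make_parcellation(30, seed = 6)))
})

test_that("expression atlas fields get smoother as the length-scale grows", {
  geom <- tiny_geom(25, seed = 2)
  xyz <- as.matrix(geom[, c("sx", "sy", "sz")])
  d <- acos(pmin(pmax(tcrossprod(xyz), -1), 1))
  w <- 1 / d; w[!is.finite(w)] <- 0
  mean_moran <- function(sm) {
    atlas <- simulate_expression_atlas(geom, n_genes = 50, n_donors = 1,
                                       smoothness = sm, seed = 11)
    ## Moran's I recomputed by the direct double loop inside moran_i
    mean(apply(atlas$fields, 2L, moran_i, w = w))
  }
  m <- vapply(c(0.05, 0.3, 1.0), mean_moran, numeric(1))
  expect_true(m[1] < m[2] && m[2] < m[3])
})

test_that("right-hemisphere donor fraction is exact and errors are raised", {
  geom <- tiny_geom(6)
  atlas <- simulate_expression_atlas(geom, n_genes = 5, n_donors = 6,
                                     right_hemi_donor_fraction = 2 / 6,
                                     seed = 1)
  has_rh <- vapply(atlas$donors,
                   function(d) any(d$samples$hemisphere == "R"), logical(1))
  expect_equal(sum(has_rh), 2L)
  expect_error(simulate_expression_atlas(geom, 5, 1, smoothness = 0),
               "smoothness")
  expect_error(simulate_expression_atlas(geom, 1, 1), "n_genes")
})

test_that("simulate_subject_rsfc moments match the effect spec", {
  geom <- tiny_geom(6)
  ## site shift of 2*noise_sd: pre-harmonization site-mean difference ~ 2*noise_sd
  noise_sd <- 0.1
  ds <- small_dataset(geom, n_per_cell = 125L,
                      effect_spec = list(beta_mdd = 0.07, beta_int = 0.05,
                                         site_shift = list(s1 = 0, s2 = 2 * noise_sd)),
                      noise_sd = noise_sd, seed = 3, sites = c("s1", "s2"))
  ## sample moments within 3 SE at n = 500/cell equivalents
  s1 <- colMeans(ds$features[ds$meta$site == "s1", ])
  s2 <- colMeans(ds$features[ds$meta$site == "s2", ])
  se <- noise_sd * sqrt(2 / 500)
  expect_lt(abs(mean(s2 - s1) - 2 * noise_sd), 3 * se / sqrt(ncol(ds$features)) * 10)
  expect_true(mean(abs((s2 - s1) - 2 * noise_sd) < 3 * se) > 0.95)
  ## male MDD cell mean reflects beta_mdd + beta_int
  mm <- ds$meta$sex == "M" & ds$meta$diagnosis == "MDD"
  mh <- ds$meta$sex == "M" & ds$meta$diagnosis == "HC"
  diff_m <- mean(colMeans(ds$features[mm, ]) - colMeans(ds$features[mh, ]))
  expect_lt(abs(diff_m - 0.12), 3 * se)
  ## determinism
  ds2 <- small_dataset(geom, n_per_cell = 125L,
                       effect_spec = list(beta_mdd = 0.07, beta_int = 0.05,
                                          site_shift = list(s1 = 0, s2 = 2 * noise_sd)),
                       noise_sd = noise_sd, seed = 3, sites = c("s1", "s2"))
  expect_identical(ds$features, ds2$features)
  expect_error(small_dataset(geom, 1L), "2 subjects")
})

test_that("null rsFC data reject at about the alpha rate", {
  geom <- tiny_geom(5)
  ds <- small_dataset(geom, n_per_cell = 15L, seed = 9)
  an <- factorial_anova(ds)
  rate <- mean(c(an$p_sex, an$p_mdd, an$p_interaction) < 0.05)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.12)
})

test_that("plant_gene_association respects sparsity, snr and the noiseless limit", {
  X <- std_matrix(40, 60, seed = 5)
  pl <- plant_gene_association(X, sparsity = 10 / 60, snr = 1, seed = 2)
  expect_equal(sum(pl$gene_weights != 0), 10L)
  ## noiseless limit
  pl0 <- plant_gene_association(X, sparsity = 0.2, snr = Inf, seed = 2)
  expect_equal(cor(as.numeric(X %*% pl0$gene_weights), pl0$y), 1, tolerance = 1e-9)
  expect_error(plant_gene_association(X, 0.1, snr = 0), "snr")
  ## realized variance ratio: recompute variances directly over seeds
  ratios <- vapply(1:25, function(s) {
    p <- plant_gene_association(X, 0.2, snr = 1, seed = s)
    sig <- as.numeric(X %*% p$gene_weights)
    sig <- sig / sd(sig)
    var(sig) / var(p$y - sig)
  }, numeric(1))
  expect_true(all(ratios > 0.8 & ratios < 1.25))
})

test_that("simulate_gene_sets plants deciles and validates arguments", {
  genes <- sprintf("g%04d", 1:1000)
  gs <- simulate_gene_sets(genes,
                           planted = data.frame(set_size = 50, target_decile = 1,
                                                direction = "+"),
                           n_random_sets = 2, random_set_size = 100, seed = 4)
  members <- gs$sets[[gs$truth$set_name[gs$truth$planted][1]]]
  in_top <- mean(match(members, genes) <= 100)
  expect_gte(in_top, 0.8)
  ## random sets ~ uniform: about 10 per decile for size 100 over G = 1000
  cnt <- table(ceiling(match(gs$sets$random_1, genes) / 100))
  expect_lt(max(abs(as.numeric(cnt) - 10)), 10)
  expect_error(simulate_gene_sets(genes, data.frame(set_size = 10,
                                                    target_decile = 11,
                                                    direction = "+")),
               "target_decile")
  expect_error(simulate_gene_sets(genes, data.frame(set_size = 1000,
                                                    target_decile = 1,
                                                    direction = "+")),
               "degenerate")
})

test_that("simulate_genotypes: HWE calibration, missingness, causal wiring", {
  spec <- data.frame(snp_id = "rs1", maf = 0.3, missing_rate = 0,
                     hwe_violation = FALSE)
  ## HWE chi-square p > 0.05 in >= 94% of replicates at n = 10,000
  ps <- vapply(1:50, function(s) {
    g <- simulate_genotypes(10000, spec, seed = s)$genotypes[, 1]
    hwe_chisq(g)$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.94)
  ## missingness rate honoured
  spec$missing_rate <- 0.15
  g <- simulate_genotypes(5000, spec, seed = 1)$genotypes
  expect_lt(abs(mean(is.na(g)) - 0.15), 0.02)
  expect_error(simulate_genotypes(10, data.frame(snp_id = "a", maf = 0.6,
                                                 missing_rate = 0,
                                                 hwe_violation = FALSE)))
  ## causal SNP shifts the named feature in the affected sex only
  geom <- tiny_geom(5)
  ds <- small_dataset(geom, n_per_cell = 100L, noise_sd = 0.05, seed = 2)
  feat <- ds$feature_info$feature[1]
  sim <- simulate_genotypes(
    snp_spec = data.frame(snp_id = "rs9", maf = 0.4, missing_rate = 0,
                          hwe_violation = FALSE),
    causal_spec = data.frame(snp_id = "rs9", feature = feat, effect = 0.5,
                             sex = "M"),
    dataset = ds, seed = 3)
  males <- sim$dataset$meta$sex == "M"
  shift <- sim$dataset$features[, feat] - ds$features[, feat]
  expect_equal(shift[males], 0.5 * sim$genotypes[males, "rs9"],
               ignore_attr = TRUE)
  expect_true(all(shift[!males] == 0))
  expect_error(simulate_genotypes(snp_spec = data.frame(snp_id = "rs9",
                                                        maf = 0.4,
                                                        missing_rate = 0,
                                                        hwe_violation = FALSE),
                                  causal_spec = data.frame(snp_id = "rs9",
                                                           feature = "nope",
                                                           effect = 1,
                                                           sex = "M"),
                                  dataset = ds),
               "absent")
})

test_that("fixtures round-trip losslessly with their truth records", {
  dir <- withr::local_tempdir()
  geom <- tiny_geom(6, seed = 2)
  write_geometry(geom, file.path(dir, "g.tsv"))
  g2 <- read_geometry(file.path(dir, "g.tsv"))
  expect_equal(g2$parcel_id, geom$parcel_id)
  expect_equal(g2$sx, geom$sx, tolerance = 1e-12)

  ds <- small_dataset(geom, 5L, seed = 3)
  write_connectivity(ds, file.path(dir, "rs"))
  ds2 <- read_connectivity(file.path(dir, "rs"))
  expect_equal(ds2$features, ds$features, tolerance = 1e-12)
  expect_equal(ds2$meta$sex, ds$meta$sex)

  atlas <- simulate_expression_atlas(geom, 4, 2, seed = 5)
  d1 <- atlas$donors[[1]]
  write_donor_csv(d1, dir)
  d1b <- read_donor_csv(file.path(dir, d1$donor_id))
  expect_equal(d1b$probe_expression, d1$probe_expression, tolerance = 1e-12)
  expect_equal(d1b$probes, d1$probes)

  truth <- list(snr = 2, planted = c("a", "b"))
  write_truth(truth, file.path(dir, "t.json"))
  expect_equal(read_truth(file.path(dir, "t.json")), truth)

  sets <- list(s1 = c("g1", "g2"), s2 = c("g3", "g4", "g5"))
  write_gmt(sets, file.path(dir, "s.gmt"))
  expect_equal(read_gmt(file.path(dir, "s.gmt")), sets)

  g <- simulate_genotypes(8, data.frame(snp_id = c("rs1", "rs2"),
                                        maf = c(0.2, 0.4),
                                        missing_rate = c(0, 0.3),
                                        hwe_violation = FALSE),
                          seed = 1)$genotypes
  write_genotypes(g, file.path(dir, "geno.tsv"))
  expect_equal(read_genotypes(file.path(dir, "geno.tsv")), g)
})
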