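test_that("collapse_probes equals the brute-force per-gene mean", {
  set.seed(1)
  genes <- sprintf("g%d", 1:5)
  p2g <- data.frame(probe_id = sprintf("p%d", 1:7),
                    gene_id = c("g1", "g1", "g2", "g3", "g3", "g4", "g5"))
  pe <- matrix(rnorm(70), 7, 10,
               dimnames = list(p2g$probe_id, sprintf("s%d", 1:10)))
  got <- collapse_probes(pe, p2g)
  ## independent brute-force oracle
  for (g in genes) {
    rows <- p2g$probe_id[p2g$gene_id == g]
    expect_equal(got[g, ], colMeans(pe[rows, , drop = FALSE]),
                 tolerance = 1e-12)
  }
  expect_equal(rownames(got), sort(genes))
  ## single-probe gene unchanged; mean of two
  expect_equal(got["g2", ], pe["p3", ])
  expect_equal(unname(got["g1", 1]), mean(pe[c("p1", "p2"), 1]))
  expect_error(collapse_probes(pe, p2g[-1, ]), "unmapped")
})

test_that("assign_samples_to_parcels matches exhaustive search and the 2 mm rule", {
  geom <- tiny_geom(12, seed = 3)
  loci <- as.matrix(geom[, c("vx", "vy", "vz")])
  set.seed(2)
  ## random samples at varying distances
  base <- loci[sample(nrow(loci), 30, replace = TRUE), ]
  pts <- base + matrix(rnorm(90, sd = 1.5), 30, 3)
  samples <- data.frame(sample_id = sprintf("s%02d", 1:30),
                        x = pts[, 1], y = pts[, 2], z = pts[, 3])
  got <- assign_samples_to_parcels(samples, geom, radius_mm = 2)
  ## exhaustive nearest-within-radius oracle
  for (i in 1:30) {
    d <- sqrt(colSums((t(loci) - pts[i, ])^2))
    names(d) <- geom$parcel_id
    inr <- d[d <= 2]
    row <- got[got$sample_id == samples$sample_id[i], ]
    if (length(inr) == 0) {
      expect_equal(nrow(row), 0L)
    } else {
      best <- names(inr)[order(inr, names(inr))][1]
      expect_equal(row$parcel_id, best)
    }
  }
  ## sample exactly at a locus -> that parcel; 5 mm away -> unassigned
  exact <- data.frame(sample_id = "e1", x = loci[3, 1], y = loci[3, 2],
                      z = loci[3, 3])
  expect_equal(assign_samples_to_parcels(exact, geom)$parcel_id,
               geom$parcel_id[3])
  far <- data.frame(sample_id = "f1", x = 0, y = 0, z = 0)  # centre of brain
  gotf <- suppressWarnings(assign_samples_to_parcels(far, geom))
  expect_equal(nrow(gotf), 0L)
  expect_equal(attr(gotf, "n_unassigned"), 1L)
})

test_that("build_donor_matrix means then Z-scores per donor", {
  geom <- tiny_geom(4, seed = 1)
  atlas <- simulate_expression_atlas(geom, n_genes = 6, n_donors = 3, seed = 7)
  for (donor in atlas$donors) {
    asn <- assign_samples_to_parcels(donor$samples, geom)
    m <- build_donor_matrix(donor, asn, geom)
    cov <- attr(m, "covered")
    ## brute-force oracle: mean over assigned samples then Z per gene
    gxs <- collapse_probes(donor$probe_expression, donor$probes)
    raw <- sapply(colnames(m), function(g) {
      v <- rep(NA_real_, nrow(geom))
      for (p in which(cov)) {
        sids <- asn$sample_id[asn$parcel_id == geom$parcel_id[p]]
        v[p] <- mean(gxs[g, sids])
      }
      (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
    })
    expect_equal(unname(m[cov, ]), unname(raw[cov, ]), tolerance = 1e-10)
    ## Z contract
    expect_lt(max(abs(colMeans(m[cov, ]))), 1e-8)
    expect_lt(max(abs(apply(m[cov, ], 2, sd) - 1)), 1e-6)
  }
})

test_that("constant gene columns are zeroed and flagged", {
  geom <- tiny_geom(4, seed = 1)
  atlas <- simulate_expression_atlas(geom, n_genes = 3, n_donors = 1, seed = 2)
  d <- atlas$donors[[1]]
  d$probe_expression[d$probes$gene_id == "G00002", ] <- 5  # constant gene
  asn <- assign_samples_to_parcels(d$samples, geom)
  m <- build_donor_matrix(d, asn, geom)
  expect_true("G00002" %in% attr(m, "flat_genes"))
  expect_true(all(m[attr(m, "covered"), "G00002"] == 0))
})

test_that("mirror_hemispheres copies, averages, and is idempotent", {
  geom <- tiny_geom(5, seed = 2)
  ## left-only coverage: right homolog gets the left value for all genes
  atlas <- simulate_expression_atlas(geom, n_genes = 4, n_donors = 1,
                                     right_hemi_donor_fraction = 0, seed = 3)
  d <- atlas$donors[[1]]
  asn <- assign_samples_to_parcels(d$samples, geom)
  m <- build_donor_matrix(d, asn, geom)
  mm <- mirror_hemispheres(m, geom)
  hom <- match(geom$homolog_id, geom$parcel_id)
  left <- geom$hemisphere == "L"
  expect_equal(mm[!left, ], unname(m[hom[!left], ]) * 1, ignore_attr = TRUE)
  expect_true(all(attr(mm, "covered")))
  ## both covered -> symmetric mean on both sides
  atlas2 <- simulate_expression_atlas(geom, n_genes = 4, n_donors = 1,
                                      right_hemi_donor_fraction = 1, seed = 4)
  d2 <- atlas2$donors[[1]]
  m2 <- build_donor_matrix(d2, assign_samples_to_parcels(d2$samples, geom), geom)
  mm2 <- mirror_hemispheres(m2, geom)
  expect_equal(mm2[1, ], (m2[1, ] + m2[hom[1], ]) / 2, tolerance = 1e-12)
  expect_equal(mm2[hom[1], ], mm2[1, ], tolerance = 1e-12)
  ## idempotence: applying twice equals applying once
  expect_equal(mirror_hemispheres(mm2, geom), mm2, tolerance = 1e-12)
  expect_equal(mirror_hemispheres(mm, geom), mm, tolerance = 1e-12)
})

test_that("aggregate_donors masks, averages and re-normalizes like the oracle", {
  geom <- tiny_geom(5, seed = 5)
  atlas <- simulate_expression_atlas(geom, n_genes = 8, n_donors = 6, seed = 6)
  mats <- lapply(atlas$donors, function(d) {
    mirror_hemispheres(
      build_donor_matrix(d, assign_samples_to_parcels(d$samples, geom), geom),
      geom)
  })
  X <- aggregate_donors(mats)
  ## brute-force oracle
  covs <- sapply(mats, attr, "covered")
  covered <- rowSums(covs) > 0
  manual <- matrix(0, nrow(geom), 8)
  for (p in which(covered)) {
    vals <- sapply(mats[covs[p, ]], function(m) m[p, ])
    manual[p, ] <- if (is.matrix(vals)) rowMeans(vals) else vals
  }
  manual <- manual[covered, ]
  manual <- scale(manual)
  expect_equal(unname(X$values), unname(manual), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(X$parcel_ids, geom$parcel_id[covered])
  ## n identical donors == single donor
  Xid <- aggregate_donors(mats[c(1, 1, 1)])
  X1 <- aggregate_donors(mats[1])
  expect_equal(Xid$values, X1$values, tolerance = 1e-12)
  ## coverage monotone under adding donors
  X12 <- aggregate_donors(mats[1:2])
  expect_true(all(X1$covered_mask <= X12$covered_mask))
})

test_that("noiseless pipeline reproduces the generating fields (corr = 1)", {
  geom <- tiny_geom(8, seed = 9)
  ## left-only coverage: mirroring copies (never averages), so covered left
  ## parcels carry an exact per-gene affine image of the generating field
  atlas <- simulate_expression_atlas(geom, n_genes = 12, n_donors = 1,
                                     right_hemi_donor_fraction = 0,
                                     sample_noise_sd = 0, probe_noise_sd = 0,
                                     coord_jitter_mm = 0, seed = 10)
  X <- map_expression(atlas$donors, geom)
  expect_true(all(X$covered_mask))
  left <- geom$parcel_id[geom$hemisphere == "L"]
  for (g in seq_len(12)) {
    expect_equal(abs(cor(X$values[left, g], atlas$fields[left, g])), 1,
                 tolerance = 1e-8)
  }
  ## final matrix columns Z-normalized to machine tolerance
  expect_lt(max(abs(colMeans(X$values))), 1e-8)
  expect_lt(max(abs(apply(X$values, 2, sd) - 1)), 1e-6)
})
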