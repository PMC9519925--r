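test_that("random_rotation is a seeded uniform rotation", {
  R <- random_rotation(seed = 3)
  expect_equal(R %*% t(R), diag(3), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
  expect_identical(random_rotation(seed = 3), random_rotation(seed = 3))
  ## rotated fixed unit vector uniform on the sphere: z-coordinate ~ U(-1, 1)
  set.seed(1)
  z <- vapply(1:2000, function(i) (random_rotation() %*% c(0, 0, 1))[3],
              numeric(1))
  expect_gt(ks.test(z, "punif", -1, 1)$p.value, 0.01)
})

test_that("identity rotation maps to the identity permutation", {
  geom <- tiny_geom(15, seed = 1)
  xyz <- as.matrix(geom[geom$hemisphere == "L", c("sx", "sy", "sz")])
  perm <- imgtx:::greedy_assign(xyz, xyz)
  expect_equal(perm, seq_len(nrow(xyz)))
})

test_that("spin permutations are bijective and preserve autocorrelation", {
  geom <- tiny_geom(20, seed = 2)
  perms <- spin_permutation(geom, n_perm = 40, seed = 5)
  ## every draw a true permutation
  for (k in 1:40) expect_equal(sort(perms[k, ]), seq_len(nrow(geom)))
  ## value multiset conserved trivially (bijection); spatial autocorrelation
  ## preserved under spin but destroyed by uniform permutation
  f <- smooth_fields(geom, 1, smoothness = 1.0, seed = 3)[, 1]
  xyz <- as.matrix(geom[, c("sx", "sy", "sz")])
  w <- 1 / acos(pmin(pmax(tcrossprod(xyz), -1), 1))
  w[!is.finite(w)] <- 0
  i_obs <- moran_i(f, w)
  i_spin <- vapply(1:40, function(k) moran_i(f[perms[k, ]], w), numeric(1))
  set.seed(6)
  i_rand <- vapply(1:40, function(k) moran_i(sample(f), w), numeric(1))
  expect_gt(mean(i_spin), mean(i_rand) + 2 * sd(i_rand))
  expect_identical(spin_permutation(geom, 5, seed = 9),
                   spin_permutation(geom, 5, seed = 9))
})

test_that("spin_test vectorized rho equals per-permutation fit_pls refits", {
  geom <- tiny_geom(12, seed = 4)
  X <- std_cols(smooth_fields(geom, 40, seed = 7))
  y <- smooth_fields(geom, 1, seed = 8)[, 1]
  expect_warning(st <- spin_test(X, y, geom, n_perm = 25, seed = 9),
                 "coarse null")
  perms <- spin_permutation(geom, 25, seed = 9)
  for (k in c(1, 10, 25)) {
    yk <- unname(y[perms[k, ]])   # unname: fit_pls would realign by parcel id
    mk <- fit_pls(X, yk, n_components = 1)
    rho_k <- cor(as.numeric(X %*% mk$weights[, 1]), yk)
    expect_equal(abs(st$rho_null[k]), abs(rho_k), tolerance = 1e-10)
  }
  expect_equal(st$p, (1 + sum(st$rho_null >= st$observed)) / 26)
  expect_gte(st$p, 1 / 26)
})

test_that("uncovered parcels are dropped after permutation, pairwise", {
  geom <- tiny_geom(10, seed = 5)
  X <- std_cols(smooth_fields(geom, 30, seed = 1))
  covered <- geom$parcel_id[-c(3, 14)]
  Xc <- X[covered, ]
  y <- setNames(smooth_fields(geom, 1, seed = 2)[covered, 1], covered)
  st <- suppressWarnings(spin_test(Xc, y, geom, n_perm = 50, seed = 3))
  expect_length(st$rho_null, 50)
  expect_true(all(is.finite(st$rho_null)))
  ## oracle for one permutation: manual drop-after-rotation
  perms <- spin_permutation(geom, 50, seed = 3)
  k <- 7
  y_full <- setNames(rep(NA_real_, nrow(geom)), geom$parcel_id)
  y_full[covered] <- y
  yk <- unname(y_full[perms[k, ]][match(covered, geom$parcel_id)])
  keep <- !is.na(yk)
  mk <- fit_pls(Xc[keep, ], yk[keep], 1)
  expect_equal(abs(st$rho_null[k]),
               abs(cor(as.numeric(Xc[keep, ] %*% mk$weights[, 1]), yk[keep])),
               tolerance = 1e-10)
})

test_that("random_test agrees with spin_test on spatially white data", {
  geom <- tiny_geom(25, seed = 6)
  ## white (smoothness ~ 0) fields: spin and random nulls coincide in law
  set.seed(11)
  X <- std_matrix(50, 60, seed = 12, rownames_from = geom$parcel_id)
  y <- setNames(rnorm(50), geom$parcel_id)
  st <- spin_test(X, y, geom, n_perm = 300, seed = 13)
  rt <- random_test(X, y, n_perm = 300, seed = 14)
  ## ties expected: the isometry group yields finitely many distinct
  ## lattice permutations
  expect_gt(suppressWarnings(ks.test(st$rho_null, rt$rho_null)$p.value), 0.01)
})

test_that("corrected_resampled_ttest matches the closed form and degenerate rules", {
  d <- c(0.12, 0.08, 0.15, 0.05, 0.1, 0.11, 0.07, 0.13, 0.09, 0.1)
  got <- corrected_resampled_ttest(d, n_train = 90, n_test = 10)
  t_hand <- mean(d) / sqrt((1 / 10 + 10 / 90) * var(d))
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(abs(t_hand), 9, lower.tail = FALSE),
               tolerance = 1e-12)
  ## monotone conservatism vs the naive paired t
  t_naive <- mean(d) / sqrt(var(d) / 10)
  expect_lt(abs(got$t), abs(t_naive))
  expect_equal(corrected_resampled_ttest(rep(0, 10), 90, 10), list(t = 0, p = 1))
  expect_warning(res <- corrected_resampled_ttest(rep(0.1, 10), 90, 10),
                 "zero variance")
  expect_equal(res$t, Inf)
})

test_that("omnibus_cv_test applies Bonferroni then min", {
  expect_true(omnibus_cv_test(c(0.004, rep(0.2, 9)))$reject)     # 10*0.004 < 0.05
  expect_false(omnibus_cv_test(rep(0.5, 10))$reject)
  expect_true(omnibus_cv_test(c(0.0049, rep(1, 9)))$reject)      # boundary
  expect_false(omnibus_cv_test(c(0.005, rep(1, 9)))$reject)
})

test_that("cross_validate: stratified folds, reproducibility, planted recovery", {
  geom <- tiny_geom(15, seed = 3)
  X <- std_cols(smooth_fields(geom, 150, smoothness = 0.5, seed = 21))
  pl <- plant_gene_association(X, sparsity = 0.1, snr = 3, seed = 22)
  seeds <- geom$parcel_id[1:2]
  fi <- make_feature_index(seeds, geom$parcel_id)
  bmdd <- setNames(rep(0, nrow(fi)), fi$feature)
  hit <- fi$target %in% names(pl$y)
  bmdd[hit] <- 0.08 * pl$y[fi$target[hit]]
  ds <- simulate_subject_rsfc(geom, 100, effect_spec = list(beta_mdd = bmdd),
                              seed_parcels = seeds, noise_sd = 0.1, seed = 23)
  Xa <- X[setdiff(rownames(X), seeds), ]
  cv <- cross_validate(Xa, ds, seeds, "M", n_repeats = 3, n_folds = 5, seed = 1)
  expect_true(cv$reject)
  expect_gt(mean(cv$rho_real), mean(cv$rho_null))
  expect_identical(cross_validate(Xa, ds, seeds, "M", 2, 5, seed = 4)$rho_real,
                   cross_validate(Xa, ds, seeds, "M", 2, 5, seed = 4)$rho_real)
  ## null data: usually no rejection
  ds0 <- simulate_subject_rsfc(geom, 100, seed_parcels = seeds,
                               noise_sd = 0.1, seed = 25)
  cv0 <- cross_validate(Xa, ds0, seeds, "M", n_repeats = 3, n_folds = 5, seed = 2)
  expect_gt(min(cv0$p), 1e-4)
})

test_that("fdr_across_models follows bh_fdr over the 10-model family", {
  p <- c(0.001, 0.02, 0.03, 0.2, 0.5, 0.6, 0.7, 0.8, 0.9, 1)
  got <- fdr_across_models(p)
  expect_equal(got$q_values, p.adjust(p, "BH"))
  same <- fdr_across_models(rep(0.3, 10))
  expect_equal(same$q_values, rep(0.3, 10))
})
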