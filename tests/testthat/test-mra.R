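test_that("shape space decomposition is exact and scale-invariant", {
  tab <- make_group_table(list(a = 6L, b = 6L), seed = 4)
  sp <- to_shape_space(tab)
  y <- log(as.matrix(tab[p_chars]))
  # lossless reconstruction and zero-sum rows
  expect_equal(unname(sp$shape + sp$isosize), unname(y), tolerance = 1e-12)
  expect_lt(max(abs(rowSums(sp$shape))), 1e-10)
  # all-equal specimen: isosize = ln c, flat shape
  tab1 <- make_meas_table(matrix(log(0.37), 1, 25), "a")
  sp1 <- to_shape_space(rbind(tab, tab1))
  expect_equal(unname(sp1$isosize[13]), log(0.37))
  expect_lt(max(abs(sp1$shape[13, ])), 1e-12)
  # doubling one specimen shifts only its isosize
  tab2 <- tab; tab2[3, p_chars] <- tab2[3, p_chars] * 2
  sp2 <- to_shape_space(tab2)
  expect_equal(sp2$isosize[3] - sp$isosize[3], log(2))
  expect_equal(sp2$shape[3, ], sp$shape[3, ], tolerance = 1e-12)
  # hand-computed two-level specimen: 12 chars at 4, 13 chars at 1
  lv <- c(rep(log(4), 12), rep(log(1), 13))
  sph <- to_shape_space(rbind(tab, make_meas_table(matrix(lv, 1, 25), "a")))
  expect_equal(unname(sph$isosize[13]), 12 * log(4) / 25)
  expect_equal(unname(sph$shape[13, 1]), log(4) - 12 * log(4) / 25)
  tab_bad <- tab; tab_bad$CL[2] <- -1
  expect_error(to_shape_space(tab_bad), "s002.*CL")
})

test_that("shape PCA recovers a planted single direction", {
  v <- rnorm(25); v <- v - mean(v); v <- v / sqrt(sum(v^2))
  z <- seq(-1, 1, length.out = 12)
  tab <- make_meas_table(outer(z, v), rep("a", 12))
  pca <- shape_pca(to_shape_space(tab))
  expect_equal(pca$percent[1], 100)
  expect_equal(abs(sum(pca$vectors[, 1] * v)), 1, tolerance = 1e-8)
  # sign convention: largest-magnitude loading positive
  expect_gt(pca$vectors[which.max(abs(pca$vectors[, 1])), 1], 0)
  # eigenvectors of the nonzero spectrum stay in the zero-sum hyperplane
  expect_lt(max(abs(colSums(pca$vectors[, seq_len(pca$nonzero), drop = FALSE]))), 1e-8)
  expect_error(shape_pca(to_shape_space(tab[1:2, ])), "at least 3")
})

test_that("isotropic shape noise has a flat eigenvalue spectrum", {
  withr::with_seed(42, {
    lv <- matrix(rnorm(5000 * 25), ncol = 25)
  })
  tab <- make_meas_table(lv, rep("a", 5000))
  pca <- shape_pca(to_shape_space(tab))
  expect_equal(pca$nonzero, 24L)
  expect_lt(max(pca$percent) / 100, 2 / 24)
})

test_that("PCA ratio spectrum puts a planted 2-character signal at the ends", {
  withr::with_seed(8, {
    z <- rnorm(40, 0, 0.3)
    lv <- matrix(rnorm(40 * 25, 0, 0.002), ncol = 25)
  })
  lv[, 1] <- lv[, 1] + z; lv[, 2] <- lv[, 2] - z
  tab <- make_meas_table(lv, rep("a", 40))
  spc <- pca_ratio_spectrum(to_shape_space(tab), 1L, n_boot = 50, seed = 1)
  ends <- spc$spectrum$character[c(1, nrow(spc$spectrum))]
  expect_setequal(ends, c("CL", "CW"))
  expect_true(all(spc$spectrum$ci_lower <= spc$spectrum$loading &
                  spc$spectrum$loading <= spc$spectrum$ci_upper))
  expect_lt(abs(sum(spc$spectrum$loading)), 1e-10)
})

test_that("noiseless one-direction data give zero-width bootstrap CIs", {
  v <- rnorm(25); v <- v - mean(v)
  z <- seq(0.1, 2, length.out = 20)
  tab <- make_meas_table(outer(z, v), rep("a", 20))
  spc <- pca_ratio_spectrum(to_shape_space(tab), 1L, n_boot = 200, seed = 2)
  expect_lt(max(spc$spectrum$ci_upper - spc$spectrum$ci_lower), 1e-10)
  expect_error(pca_ratio_spectrum(to_shape_space(tab), 1L, n_boot = 1), "n_boot")
})

test_that("allometry spectrum recovers planted slopes and sums to zero", {
  withr::with_seed(9, {
    s <- rnorm(60, 0, 0.25)
    noise <- matrix(rnorm(60 * 25, 0, 0.01), ncol = 25)
  })
  slopes <- rep(1, 25); slopes[19] <- 1.6   # ovipositor hyperallometric
  lv <- outer(s, slopes) + noise
  tab <- make_meas_table(lv, rep("a", 60))
  al <- allometry_ratio_spectrum(to_shape_space(tab), n_boot = 50, seed = 3)
  expect_identical(al$spectrum$character[nrow(al$spectrum)], "OV")
  expect_lt(abs(sum(al$spectrum$loading)), 1e-10)
  # isometric data: all loadings vanish
  lv_iso <- outer(s, rep(1, 25))
  tab_iso <- make_meas_table(lv_iso + 0.001 * noise, rep("a", 60))
  al_iso <- allometry_ratio_spectrum(to_shape_space(tab_iso), n_boot = 10, seed = 1)
  expect_lt(max(abs(al_iso$spectrum$loading)), 0.01)
  # constant isosize is degenerate
  flat <- make_meas_table(matrix(rnorm(25 * 10, 0, 0.1), ncol = 25) -
                            rowMeans(matrix(rnorm(25 * 10, 0, 0.1), ncol = 25)),
                          rep("a", 10))
  sp_flat <- to_shape_space(flat)
  sp_flat$isosize[] <- 1
  expect_error(allometry_ratio_spectrum(sp_flat, n_boot = 10, seed = 1),
               "constant isosize")
})

test_that("LDA ratio extractor: planted ratio, oracle agreement, invariances", {
  withr::with_seed(10, {
    lv_a <- matrix(rnorm(30 * 25, 0, 0.05), ncol = 25)
    lv_b <- matrix(rnorm(30 * 25, 0, 0.05), ncol = 25)
  })
  delta_shift <- 5 * sqrt(2) * 0.05
  lv_b[, 5] <- lv_b[, 5] + delta_shift / 2   # F2L
  lv_b[, 21] <- lv_b[, 21] - delta_shift / 2 # PVL
  tab <- make_meas_table(rbind(lv_a, lv_b), rep(c("a", "b"), each = 30))
  sp <- to_shape_space(tab)
  res <- lda_ratio_extract(sp, "a", "b")
  expect_setequal(res$best$characters, c("F2L", "PVL"))
  orc <- oracle_ratio_scan(sp$shape[sp$species == "a", ],
                           sp$shape[sp$species == "b", ])
  expect_setequal(res$best$characters, p_chars[orc$best])
  expect_equal(res$best$D, orc$best_d, tolerance = 1e-10)
  expect_equal(unname(res$D_matrix), unname(orc$D), tolerance = 1e-10)
  # best and second share no character, ordered by D
  expect_length(intersect(res$best$characters, res$second$characters), 0)
  expect_gte(res$best$D, res$second$D)
  # invariant to group order and global scaling
  res_swap <- lda_ratio_extract(sp, "b", "a")
  expect_equal(res_swap$best$D, res$best$D)
  tab10 <- tab; tab10[p_chars] <- tab10[p_chars] * 10
  res10 <- lda_ratio_extract(to_shape_space(tab10), "a", "b")
  expect_equal(res10$D_matrix, res$D_matrix, tolerance = 1e-9)
})

test_that("pure size difference gives delta 1 and no ratio separation", {
  withr::with_seed(12, {
    lv <- matrix(rnorm(40 * 25, 0, 0.05), ncol = 25)
  })
  tab <- make_meas_table(rbind(lv, lv + log(2)), rep(c("a", "b"), each = 40))
  sp <- to_shape_space(tab)
  res <- suppressWarnings(lda_ratio_extract(sp, "a", "b"))
  expect_lt(max(res$D_matrix), 1e-10)
  expect_equal(res$delta, 1, tolerance = 1e-8)
  expect_false(res$separable)
  # identical groups: non-separable, all D zero
  tab_id <- make_meas_table(rbind(lv, lv), rep(c("a", "b"), each = 40))
  res_id <- suppressWarnings(lda_ratio_extract(to_shape_space(tab_id), "a", "b"))
  expect_false(res_id$separable)
  expect_error(lda_ratio_extract(sp, "a", "a"), "disjoint")
})
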