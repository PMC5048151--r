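wing <- matrix(c(0, 0.1, 0.45, 0.22, 0.7, 0.25, 0.95, 0.24,
                 0.8, 0.18, 1.25, 0.05, 0.6, -0.12), ncol = 2, byrow = TRUE)

test_that("TPS files round-trip and malformed records are rejected", {
  land <- make_landmark_set(list(wing, wing + 0.01, random_similarity(wing, 4)))
  path <- withr::local_tempfile(fileext = ".tps")
  write_tps(land, path)
  back <- read_tps(path)
  expect_equal(back$coords, land$coords, tolerance = 1e-9)
  expect_identical(back$ids, land$ids)
  # write -> read -> write -> read is stable
  path2 <- withr::local_tempfile(fileext = ".tps")
  write_tps(back, path2)
  expect_equal(read_tps(path2)$coords, back$coords)
  # minimal single-record file
  one <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=7", sprintf("%g %g", wing[, 1], wing[, 2]), "ID=w1"), one)
  got <- read_tps(one)
  expect_equal(dim(got$coords), c(7L, 2L, 1L))
  expect_identical(got$ids, "w1")
  # wrong landmark count names the record
  bad <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=6", sprintf("%g %g", wing[1:6, 1], wing[1:6, 2]), "ID=w1"),
             bad)
  expect_error(read_tps(bad), "record 1.*LM=6")
  # malformed coordinate names the line
  ugly <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=7", sprintf("%g %g", wing[, 1], wing[, 2])[-3],
               "0.7 oops", "ID=w1"), ugly)
  expect_error(read_tps(ugly), "malformed coordinate")
})

test_that("GPA removes similarity transforms exactly", {
  copies <- lapply(1:6, function(i) random_similarity(wing, i))
  fit <- gpa(make_landmark_set(copies))
  expect_true(fit$converged)
  spread <- apply(fit$aligned, c(1, 2), function(v) diff(range(v)))
  expect_lt(max(spread), 1e-8)
  expect_equal(centroid_size(fit$consensus), 1, tolerance = 1e-10)
  expect_lt(max(abs(colMeans(fit$consensus))), 1e-10)
  # degenerate configuration rejected
  degen <- make_landmark_set(list(wing, matrix(1, 7, 2)))
  expect_error(gpa(degen), "degenerate")
})

test_that("two-shape GPA matches the closed-form superimposition oracle", {
  shape2 <- wing
  shape2[4, ] <- shape2[4, ] + c(0.15, -0.1)
  shape2[6, ] <- shape2[6, ] + c(-0.1, 0.12)
  fit <- gpa(make_landmark_set(list(random_similarity(wing, 1),
                                    random_similarity(shape2, 2))))
  orc <- oracle_opa2(wing, shape2)
  expect_lt(procrustes_rms(fit$consensus, orc$mean), 1e-7)
  # objective non-increasing on a noisy fixture
  noisy <- lapply(1:8, function(i)
    random_similarity(wing + matrix(rnorm(14, 0, 0.03), 7, 2), i))
  fitn <- gpa(make_landmark_set(noisy))
  expect_true(all(diff(fitn$objective) <= 1e-12))
})

test_that("landmark PCA separates planted clusters and respects rank limits", {
  shift <- matrix(0, 7, 2); shift[6, ] <- c(0.2, 0.15)
  withr::with_seed(31, {
    grp1 <- lapply(1:15, function(i) wing + matrix(rnorm(14, 0, 0.01), 7, 2))
    grp2 <- lapply(1:15, function(i) wing + shift + matrix(rnorm(14, 0, 0.01), 7, 2))
  })
  land <- make_landmark_set(c(grp1, grp2),
                            species = rep(c("p", "q"), each = 15))
  fit <- gpa(land)
  pca <- landmark_pca(fit)
  expect_equal(sum(pca$percent), 100, tolerance = 1e-8)
  expect_gte(sum(pca$values < max(pca$values) * 1e-10), 4)
  expect_lte(pca$nonzero, 10)
  pc1 <- pca$scores[, 1]
  expect_true(max(pc1[1:15]) < min(pc1[16:30]) ||
              min(pc1[1:15]) > max(pc1[16:30]))
  expect_error(landmark_pca(gpa(make_landmark_set(list(wing, wing + 0.01)))),
               "at least 3")
})

test_that("CVA separates planted groups and returns min(g-1, n_keep) axes", {
  shift <- matrix(0, 7, 2); shift[4, ] <- c(0.15, 0.1); shift[7, 1] <- -0.1
  withr::with_seed(32, {
    grp1 <- lapply(1:12, function(i) wing + matrix(rnorm(14, 0, 0.005), 7, 2))
    grp2 <- lapply(1:12, function(i) wing + shift + matrix(rnorm(14, 0, 0.005), 7, 2))
    grp3 <- lapply(1:12, function(i) wing - shift + matrix(rnorm(14, 0, 0.005), 7, 2))
  })
  land <- make_landmark_set(c(grp1, grp2, grp3),
                            species = rep(c("p", "q", "r"), each = 12))
  fit <- gpa(land)
  cv <- cva(fit)
  expect_identical(cv$n_axes, 2L)
  cv1 <- cva(fit, n_keep = 1L)
  expect_identical(cv1$n_axes, 1L)
  s <- cv$scores[, 1]
  rng <- tapply(s, fit$species, range)
  # planted clusters do not overlap on CV1
  ord <- order(vapply(rng, mean, numeric(1)))
  for (i in 1:2)
    expect_lt(rng[[ord[i]]][2], rng[[ord[i + 1]]][1])
  expect_error(cva(fit, groups = rep("p", 36)), "at least 2 groups")
})

test_that("null CVA separation is calibrated against label permutations", {
  withr::with_seed(33, {
    cfgs <- lapply(1:30, function(i) wing + matrix(rnorm(14, 0, 0.02), 7, 2))
    labs <- rep(c("p", "q"), each = 15)
    land <- make_landmark_set(cfgs, species = labs)
    fit <- gpa(land)
    obs <- cva(fit)$values[1]
    perm <- replicate(99, {
      fit2 <- fit; fit2$species <- sample(labs)
      cva(fit2)$values[1]
    })
  })
  # identical distributions: observed statistic is not extreme
  expect_gt((1 + sum(perm >= obs)) / 100, 0.05)
})

test_that("covariance-matrix correlation test behaves at its edges", {
  withr::with_seed(34, {
    factor_field <- matrix(rnorm(14), 7, 2)
    make_grp <- function(n) lapply(seq_len(n), function(i)
      wing + rnorm(1, 0, 0.05) * factor_field +
        matrix(rnorm(14, 0, 0.01), 7, 2))
    land <- make_landmark_set(c(make_grp(150), make_grp(150)),
                              species = rep(c("p", "q"), each = 150))
  })
  fit <- gpa(land)
  # same generating covariance, large n: correlation near 1, p small
  ct <- covmat_correlation_test(fit, "p", "q", n_perm = 199, seed = 5)
  expect_gt(ct$correlation, 0.9)
  expect_lte(ct$p_value, 0.05)
  expect_gte(ct$p_value, 1 / 200)
  # self-comparison: correlation exactly 1, minimal p
  fit_self <- fit; fit_self$species <- rep(c("p", "q"), 150)
  half <- fit; half$species[half$species == "q"] <- "p"
  ct_self <- covmat_correlation_test(half, "p", "p", n_perm = 199, seed = 6)
  expect_equal(ct_self$correlation, 1)
  expect_equal(ct_self$p_value, 1 / 200)
  expect_error(covmat_correlation_test(fit, "p", "q", n_perm = 10), "n_perm")
})
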