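random_seqs <- function(n, L, seed, p_n = 0, p_mut = 0.1) {
  # a family of sequences derived from one random base (keeps pairwise
  # divergence well below K2P saturation)
  withr::with_seed(seed, {
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    m <- matrix(base, n, L, byrow = TRUE)
    hit <- matrix(runif(n * L) < p_mut, n, L)
    m[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
    if (p_n > 0) m[runif(n * L) < p_n] <- "N"
  })
  rownames(m) <- sprintf("q%02d", seq_len(n))
  aligned_sequences(m)
}

test_that("pairwise distances match hand counts and handle deletion", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("AC-T", "ACGT"), 0)     # 3 comparable sites
  expect_equal(p_distance("ANGT", "ACGA"), 1 / 3)
  expect_equal(k2p_distance("ACGT", "ACGT"), 0)
  expect_error(p_distance("ACG", "ACGT"), "length")
  expect_error(p_distance("NNNN", "ACGT"), "no comparable sites")
  # saturation: all transversions
  expect_error(k2p_distance("AAAA", "CCCC"), "saturated")
})

test_that("distance matrix agrees with scalar functions and ape::dist.dna", {
  seqs <- random_seqs(8, 120, seed = 2, p_n = 0.03)
  for (metric in c("p", "k2p")) {
    d <- dist_matrix(seqs, metric)
    s <- as.character(seqs)
    for (i in 1:7) for (j in (i + 1):8) {
      ref <- if (metric == "p") p_distance(s[i], s[j]) else
        k2p_distance(s[i], s[j])
      expect_equal(d[i, j], ref, tolerance = 1e-12)
      expect_equal(d[j, i], d[i, j])
    }
  }
  bin <- ape::as.DNAbin(strsplit(tolower(as.character(seqs)), ""))
  ref_k <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
  ref_p <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  expect_equal(unname(dist_matrix(seqs, "k2p")), unname(ref_k),
               tolerance = 1e-10)
  expect_equal(unname(dist_matrix(seqs, "p")), unname(ref_p),
               tolerance = 1e-10)
})

test_that("haplotype collapsing respects species and multiplicity", {
  seqs <- seq_set(a1 = "ACGTACGT", a2 = "ACGTACGT", a3 = "ACGTACGT",
                  b1 = "ACGTACGT", b2 = "ACGTACGA")
  part <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B")
  hap <- collapse_haplotypes(seqs, part)
  expect_setequal(rownames(hap$seqs), c("a1", "b1", "b2"))
  expect_equal(unname(hap$multiplicity[c("a1", "b1", "b2")]), c(3L, 1L, 1L))
  # ambiguity-tolerant identity
  seqs2 <- seq_set(x1 = "ACGTNCGT", x2 = "ACGTACGT")
  hap2 <- collapse_haplotypes(seqs2, c(x1 = "X", x2 = "X"))
  expect_identical(nrow(hap2$seqs), 1L)
  # collapsing never changes distinct within-species distance values
  scn <- tiny_scenario(seed = 6, poly_rate = 0.02)
  sq <- gen_sequences(scn)
  hap3 <- collapse_haplotypes(sq$seqs, sq$partition)
  d_full <- dist_matrix(sq$seqs, "p"); d_hap <- dist_matrix(hap3$seqs, "p")
  for (s in unique(sq$partition)) {
    if1 <- names(sq$partition)[sq$partition == s]
    if2 <- names(hap3$partition)[hap3$partition == s]
    vals_full <- d_full[if1, if1][upper.tri(d_full[if1, if1])]
    vals_hap <- d_hap[if2, if2][upper.tri(d_hap[if2, if2])]
    # zero distances become haplotype multiplicities; all others persist
    expect_setequal(round(unique(vals_full[vals_full > 0]), 12),
                    round(unique(vals_hap), 12))
  }
})

test_that("distance summary matches a hand-enumerated 2+2 toy", {
  seqs <- seq_set(a1 = "AAAAAAAAAA", a2 = "AAAAAAAAAG",
                  b1 = "AAAAATTTTT", b2 = "AAAATTTTTT")
  part <- c(a1 = "sp1", a2 = "sp1", b1 = "sp2", b2 = "sp2")
  ds <- distance_summary(seqs, part, "p")
  expect_equal(ds$intra$mean, c(0.1, 0.1))
  expect_equal(ds$intra$se, c(0, 0))
  inter_vals <- c(0.5, 0.6, 0.5, 0.6)   # a1b1, a1b2, a2b1, a2b2 by hand
  expect_equal(ds$inter$mean, mean(inter_vals))
  expect_equal(ds$inter$min, min(inter_vals))
  expect_equal(ds$inter$max, max(inter_vals))
  expect_equal(ds$inter$se, sd(inter_vals) / 2)
  # symmetric under species relabeling
  part_flip <- setNames(c("sp2", "sp2", "sp1", "sp1"), names(part))
  names(part_flip) <- c("b1", "b2", "a1", "a2")
  ds2 <- distance_summary(seqs, part_flip[names(part)], "p")
  expect_equal(ds2$inter$mean, ds$inter$mean)
})

test_that("barcode gap extremes are attained by real pairs", {
  scn <- tiny_scenario(seed = 13, poly_rate = 0.01)
  sq <- gen_sequences(scn)
  g <- barcode_gap(sq$seqs, sq$partition, "k2p")
  d <- dist_matrix(sq$seqs, "k2p")
  expect_equal(d[g$max_intra_pair[1], g$max_intra_pair[2]], g$max_intra)
  expect_equal(d[g$min_inter_pair[1], g$min_inter_pair[2]], g$min_inter)
  # brute-force rescan of the extremes
  same <- outer(sq$partition, sq$partition, "==")
  ut <- upper.tri(d)
  expect_equal(g$max_intra, max(d[ut & same]))
  expect_equal(g$min_inter, min(d[ut & !same]))
  expect_true(g$gap)
  # one species duplicated under two labels: no gap
  seqs <- seq_set(a1 = "ACGTACGT", a2 = "ACGAACGT",
                  b1 = "ACGTACGT", b2 = "ACGAACGT")
  part <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  g0 <- barcode_gap(seqs, part, "p")
  expect_equal(g0$min_inter, 0)
  expect_false(g0$gap)
})

test_that("NJ solves 3 taxa in closed form and is order-invariant", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  el <- setNames(tr$edge.length,
                 tr$tip.label[tr$edge[, 2]])
  expect_equal(el[["a"]], (3 + 4 - 5) / 2)
  expect_equal(el[["b"]], (3 + 5 - 4) / 2)
  expect_equal(el[["c"]], (4 + 5 - 3) / 2)
  # order invariance on an additive 6-taxon matrix
  gen <- random_additive(6, seed = 40)
  t1 <- nj_tree(gen$d)
  perm <- c(4, 2, 6, 1, 5, 3)
  t2 <- nj_tree(gen$d[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), setNames(0, "PH85"), ignore_attr = TRUE)
  # validation
  bad <- gen$d; bad[1, 2] <- bad[1, 2] + 1
  expect_error(nj_tree(bad), "symmetric")
  neg <- gen$d; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(nj_tree(neg), "negative")
})

test_that("non-additive input never yields negative branch lengths", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      n <- 6
      m <- matrix(runif(n * n, 0.01, 0.3), n, n)
      d <- (m + t(m)) / 2; diag(d) <- 0
      dimnames(d) <- list(letters[1:n], letters[1:n])
      tr <- nj_tree(d)
      expect_true(all(tr$edge.length >= 0))
      expect_setequal(tr$tip.label, letters[1:n])
    }
  })
})

test_that("newick trees round-trip through ape", {
  gen <- random_additive(7, seed = 50)
  tr <- nj_tree(gen$d)
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  back <- ape::read.tree(path)
  expect_equal(ape::dist.topo(tr, back), setNames(0, "PH85"),
               ignore_attr = TRUE)
  expect_setequal(back$tip.label, rownames(gen$d))
})

test_that("bootstrap supports live in [0,100] and degenerate cases are exact", {
  scn <- tiny_scenario(seed = 14, poly_rate = 0.005, L = 200)
  sq <- gen_sequences(scn)
  bs <- bootstrap_support(sq$seqs, "p", n_reps = 50, seed = 9)
  expect_true(all(bs$supports >= 0 & bs$supports <= 100))
  bs1 <- bootstrap_support(sq$seqs, "p", n_reps = 1, seed = 9)
  expect_true(all(bs1$supports %in% c(0, 100)))
  # planted species form supported clades
  for (s in unique(sq$partition)) {
    tips <- names(sq$partition)[sq$partition == s]
    expect_gte(split_support(bs, tips), 95)
  }
  # collapse mode runs on haplotypes
  bsc <- bootstrap_support(sq$seqs, "p", n_reps = 10, seed = 2,
                           partition = sq$partition, collapse = TRUE)
  expect_lte(length(bsc$tree$tip.label), length(sq$partition))
})

test_that("pure diagnostics follow their definition and match a brute-force scan", {
  # polymorphic species is not pure; shared states are pure for neither
  seqs <- seq_set(a1 = "AAG", a2 = "AAG", b1 = "CAG", b2 = "CTG",
                  c1 = "GAC", c2 = "GAC")
  part <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", c2 = "C")
  dt <- pure_diagnostic_characters(seqs, part)
  # position 1: A/C/G all fixed and unique -> pure for all three
  expect_identical(nrow(dt$diagnostics[dt$diagnostics$position == 1, ]), 3L)
  # position 2: B polymorphic A/T; A and C share A -> nobody pure
  expect_identical(nrow(dt$diagnostics[dt$diagnostics$position == 2, ]), 0L)
  ctx2 <- dt$context[dt$context$position == 2 & dt$context$species == "B", ]
  expect_identical(ctx2$states, "A/T")
  # position 3: C has C, others G -> pure for C only
  d3 <- dt$diagnostics[dt$diagnostics$position == 3, ]
  expect_identical(d3$species, "C")
  expect_identical(d3$state, "C")
  # oracle agreement on a noisy generated fixture
  scn <- tiny_scenario(seed = 15, poly_rate = 0.03)
  sq <- gen_sequences(scn)
  mine <- pure_diagnostic_characters(sq$seqs, sq$partition)$diagnostics
  orc <- oracle_diag_scan(sq$seqs, sq$partition)
  expect_equal(mine, orc)
})
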